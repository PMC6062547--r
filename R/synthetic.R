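#' Specification of a synthetic sulfenylation motif
#'
#' Defines the generative model for synthetic cysteine-centred fragments:
#' negative-class flanks are drawn i.i.d. from a background residue
#' distribution, while positive-class flanks are drawn per position from a
#' mixture `(1 - strength) * background + strength * motif`, where the
#' motif concentrates on one preferred residue per flank position. At
#' `strength = 0` the classes are statistically identical; at
#' `strength = 1` every positive flank position is fully determined by the
#' motif. Fragments land near a protein terminus with probability
#' `terminal_x_rate`, producing a contiguous run of X padding on one side.
#'
#' The signal is purely compositional and positional — the kind of signal
#' every feature block (one-hot, property profiles, pair spacing,
#' composition) can pick up. It does not emulate the true biological
#' sulfenylation motif, protein context, or homology structure of real
#' datasets.
#'
#' @param strength Mixing weight in \[0, 1\] (default 0.5).
#' @param terminal_x_rate Probability a fragment is terminal-padded
#'   (default 0.1).
#' @param half_window Flank length per side (default 10).
#' @param background Optional length-20 probability vector over the
#'   canonical residues (default uniform).
#' @param preferred Optional character vector of one preferred residue per
#'   flank position (length `2 * half_window`); default cycles through a
#'   fixed residue set.
#' @return An object of class `motif_spec`.
#' @examples
#' spec <- motif_spec(strength = 0.9)
#' rowSums(spec$positions)[1:3]  # each position distribution sums to 1
#' @export
motif_spec <- function(strength = 0.5, terminal_x_rate = 0.1,
                       half_window = 10L, background = NULL,
                       preferred = NULL) {
  if (!is.numeric(strength) || strength < 0 || strength > 1) {
    stop("'strength' must be in [0, 1]")
  }
  if (!is.numeric(terminal_x_rate) || terminal_x_rate < 0 ||
      terminal_x_rate > 1) {
    stop("'terminal_x_rate' must be in [0, 1]")
  }
  half_window <- as.integer(half_window)
  if (is.na(half_window) || half_window < 1L) {
    stop("'half_window' must be a positive integer")
  }
  n_flank <- 2L * half_window
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA20)
  }
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("'background' must be a length-20 probability vector")
  }
  names(background) <- AA20
  if (is.null(preferred)) {
    # a fixed, position-varying preference so the motif is positional as
    # well as compositional
    preferred <- rep_len(c("D", "K", "S", "L", "E", "G", "R", "P", "N", "T"),
                         n_flank)
  }
  if (length(preferred) != n_flank || !all(preferred %in% AA20)) {
    stop("'preferred' must name one canonical residue per flank position")
  }
  positions <- matrix(rep(background, each = n_flank), nrow = n_flank,
                      dimnames = list(NULL, AA20))
  positions <- (1 - strength) * positions
  for (p in seq_len(n_flank)) {
    positions[p, preferred[p]] <- positions[p, preferred[p]] + strength
  }
  structure(list(positions = positions, background = background,
                 strength = strength, terminal_x_rate = terminal_x_rate,
                 half_window = half_window, preferred = preferred),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("Synthetic motif specification\n")
  cat(sprintf("  strength = %g, terminal_x_rate = %g, half_window = %d\n",
              x$strength, x$terminal_x_rate, x$half_window))
  cat("  preferred residues:", paste(x$preferred, collapse = ""), "\n")
  invisible(x)
}

#' Generate synthetic labelled peptide fragments
#'
#' Draws `n_pos` positive and `n_neg` negative cysteine-centred fragments
#' from a [motif_spec()]. Every window has odd length
#' `2 * half_window + 1` with a central C; X appears only as a contiguous
#' terminal run. Deterministic for a given seed.
#'
#' @param n_pos,n_neg Numbers of positive / negative fragments (>= 0).
#' @param spec A [motif_spec()].
#' @param seed Integer seed.
#' @return A fragment data.frame (`protein_id`, `position`, `window`,
#'   `label`), positives first.
#' @examples
#' frags <- generate_fragments(3, 3, motif_spec(strength = 1), seed = 7)
#' frags$window
#' @export
generate_fragments <- function(n_pos, n_neg, spec = motif_spec(),
                               seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"))
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  if (is.na(n_pos) || is.na(n_neg) || n_pos < 0L || n_neg < 0L) {
    stop("'n_pos' and 'n_neg' must be non-negative")
  }
  h <- spec$half_window
  n_flank <- 2L * h
  bg <- spec$background
  with_seed(seed, {
    draw <- function(n, positional) {
      if (n == 0L) return(character(0))
      flanks <- matrix("", nrow = n, ncol = n_flank)
      for (p in seq_len(n_flank)) {
        probs <- if (positional) spec$positions[p, ] else bg
        flanks[, p] <- sample(AA20, n, replace = TRUE, prob = probs)
      }
      vapply(seq_len(n), function(i) {
        fl <- flanks[i, ]
        if (stats::runif(1) < spec$terminal_x_rate) {
          nx <- sample.int(h, 1L)
          if (stats::runif(1) < 0.5) {
            fl[seq_len(nx)] <- "X"
          } else {
            fl[(n_flank - nx + 1L):n_flank] <- "X"
          }
        }
        paste0(paste(fl[seq_len(h)], collapse = ""), "C",
               paste(fl[(h + 1L):n_flank], collapse = ""))
      }, character(1))
    }
    wpos <- draw(n_pos, positional = TRUE)
    wneg <- draw(n_neg, positional = FALSE)
    windows <- c(wpos, wneg)
    labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
    left_x <- nchar(sub("[^X].*$", "", windows))
    data.frame(
      protein_id = sprintf("SYN%s%05d",
                           rep(c("P", "N"), c(n_pos, n_neg)),
                           c(seq_len(n_pos), seq_len(n_neg))),
      position = h + 1L - left_x,
      window = windows,
      label = factor(labels, levels = c("positive", "negative", "unknown")),
      stringsAsFactors = FALSE)
  })
}

#' Generate a dataset shaped like the curated sulfenylation benchmark
#'
#' Produces a training set of 900 positive / 6,858 negative fragments and
#' an independent test set of 145 positive / 268 negative fragments — the
#' class counts of the curated human S-sulfenylation benchmark this
#' predictor targets — drawn from a single [motif_spec()] of moderate
#' strength. No window string is shared between the two sets.
#'
#' @param seed Integer seed.
#' @param spec A [motif_spec()] (default strength 0.5).
#' @return A list with fragment data.frames `train` and `independent`.
#' @export
generate_benchmark_dataset <- function(seed = 1L,
                                       spec = motif_spec(strength = 0.5)) {
  train <- generate_fragments(900L, 6858L, spec, seed = seed)
  indep <- generate_fragments(145L, 268L, spec, seed = seed + 1000L)
  for (tries in seq_len(20L)) {
    clash <- indep$window %in% train$window
    if (!any(clash)) break
    repl <- generate_fragments(sum(clash & indep$label == "positive"),
                               sum(clash & indep$label == "negative"),
                               spec, seed = seed + 1000L + tries)
    indep$window[clash] <- repl$window
  }
  if (any(indep$window %in% train$window)) {
    stop("could not generate disjoint independent set")
  }
  list(train = train, independent = indep)
}

#' Generate synthetic proteins with embedded labelled sites
#'
#' Builds full-length synthetic proteins in which motif-bearing (positive)
#' and background (negative) cysteine windows are embedded at recorded
#' positions, plus a matching site table — so the complete FASTA ->
#' fragment -> feature -> model path can be exercised without any external
#' data. Unlabelled cysteines arising in the random background become
#' `unknown` fragments, as in real data.
#'
#' @param n_proteins Number of proteins (default 20).
#' @param n_pos,n_neg Numbers of labelled positive / negative sites spread
#'   round-robin across proteins (defaults 20 / 40).
#' @param spec A [motif_spec()] (its `terminal_x_rate` is ignored here;
#'   padding arises only from true proximity to a terminus).
#' @param seed Integer seed.
#' @return A list with `proteins` (data.frame `id`, `sequence`) and `sites`
#'   (data.frame `protein_id`, `position`, `label`).
#' @export
generate_protein_dataset <- function(n_proteins = 20L, n_pos = 20L,
                                     n_neg = 40L, spec = motif_spec(),
                                     seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"))
  h <- spec$half_window
  n_flank <- 2L * h
  total <- n_pos + n_neg
  if (total < 1L || n_proteins < 1L) {
    stop("need at least one protein and one site")
  }
  site_label <- sample_labels_round_robin(n_pos, n_neg, n_proteins)
  with_seed(seed, {
    proteins <- vector("list", n_proteins)
    sites <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      labs <- site_label[[as.character(i)]]
      if (is.null(labs)) labs <- character(0)
      seqparts <- character(0)
      positions <- integer(0)
      cursor <- 0L
      for (lab in labs) {
        gap <- sample.int(15L, 1L)
        gap_seq <- paste(sample(AA20, gap, replace = TRUE,
                                prob = spec$background), collapse = "")
        flanks <- vapply(seq_len(n_flank), function(p) {
          probs <- if (lab == "positive") spec$positions[p, ] else
            spec$background
          sample(AA20, 1L, prob = probs)
        }, character(1))
        win <- paste0(paste(flanks[seq_len(h)], collapse = ""), "C",
                      paste(flanks[(h + 1L):n_flank], collapse = ""))
        seqparts <- c(seqparts, gap_seq, win)
        cursor <- cursor + gap + h + 1L
        positions <- c(positions, cursor)
        cursor <- cursor + h
      }
      tail_seq <- paste(sample(AA20, sample.int(15L, 1L), replace = TRUE,
                               prob = spec$background), collapse = "")
      proteins[[i]] <- paste(c(seqparts, tail_seq), collapse = "")
      sites[[i]] <- if (length(positions) == 0L) NULL else data.frame(
        protein_id = sprintf("SYNPROT%03d", i),
        position = positions,
        label = labs, stringsAsFactors = FALSE)
    }
    list(
      proteins = data.frame(id = sprintf("SYNPROT%03d", seq_len(n_proteins)),
                            sequence = unlist(proteins),
                            stringsAsFactors = FALSE),
      sites = {
        s <- do.call(rbind, sites)
        s$label <- factor(s$label, levels = c("positive", "negative"))
        rownames(s) <- NULL
        s
      })
  })
}

#' @noRd
sample_labels_round_robin <- function(n_pos, n_neg, n_proteins) {
  labs <- rep(c("positive", "negative"), c(n_pos, n_neg))
  idx <- rep_len(seq_len(n_proteins), length(labs))
  split(labs, idx)
}

#' Write a synthetic protein dataset to FASTA + site-table files
#'
#' @param dataset A list from [generate_protein_dataset()].
#' @param fasta_path,sites_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_protein_dataset <- function(dataset, fasta_path, sites_path) {
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(dataset$proteins))) {
    writeLines(c(paste0(">", dataset$proteins$id[i]),
                 gsub("(.{60})", "\\1\n", dataset$proteins$sequence[i])),
               con)
  }
  utils::write.csv(dataset$sites, sites_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(fasta = fasta_path, sites = sites_path))
}
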