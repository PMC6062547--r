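#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file of amino-acid
#' sequences. Sequences are uppercased and non-canonical residue letters
#' (B, J, O, U, Z, stop/gap marks) are normalized to the pseudo-residue X
#' with a warning, so that every returned sequence is over the 21-letter
#' alphabet (20 canonical amino acids + X).
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (accession, the first
#'   whitespace-delimited token of the header) and `sequence`, one row per
#'   record, in file order.
#' @examples
#' fa <- system.file("extdata", "synthetic_proteins.fasta",
#'                   package = "sulfenpred")
#' proteins <- read_fasta(fa)
#' head(proteins$id)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("'path' must be a single file path")
  }
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("no records in FASTA file: ", path)
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: line ", first,
         " is not a header (expected '>'): ", lines[first])
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) {
    stop("no records in FASTA file: ", path)
  }
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1L], character(1)))
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)]
    stop("empty sequence for record(s): ", paste(bad, collapse = ", "))
  }
  seqs <- normalize_sequences(seqs, ids)
  data.frame(id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' @noRd
normalize_sequences <- function(seqs, ids) {
  out <- seqs
  seen <- character(0)
  for (i in seq_along(out)) {
    chars <- strsplit(out[i], "", fixed = TRUE)[[1L]]
    bad <- !(chars %in% AA21)
    if (any(bad)) {
      unknown <- setdiff(unique(chars[bad]), NONCANONICAL)
      if (length(unknown) > 0L) {
        stop("sequence '", ids[i], "' contains unexpected character(s): ",
             paste(unknown, collapse = ", "))
      }
      seen <- union(seen, unique(chars[bad]))
      chars[bad] <- "X"
      out[i] <- paste(chars, collapse = "")
    }
  }
  if (length(seen) > 0L) {
    warning("non-canonical residue letter(s) normalized to X: ",
            paste(sort(seen), collapse = ", "))
  }
  out
}

#' Read a labelled cysteine-site table
#'
#' Parses a delimited text file (comma- or tab-separated, autodetected from
#' the header line) with columns `protein_id`, `position` (1-based residue
#' index) and `label` (`positive` or `negative`). Duplicate
#' (protein, position) rows are rejected. Whether each position actually
#' holds a cysteine is checked later, against the sequences, by
#' [extract_fragments()].
#'
#' @param path Path to the site table.
#' @return A data.frame with columns `protein_id`, `position` (integer) and
#'   `label` (factor with levels `positive`, `negative`).
#' @examples
#' tab <- system.file("extdata", "synthetic_sites.csv",
#'                    package = "sulfenpred")
#' sites <- read_site_table(tab)
#' table(sites$label)
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) {
    stop("site table not found: ", path)
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(tab))) {
    stop("site table must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(tab), collapse = ", "))
  }
  pos_num <- suppressWarnings(as.numeric(tab$position))
  if (anyNA(pos_num) || any(pos_num != as.integer(pos_num)) ||
      any(pos_num < 1)) {
    bad <- which(is.na(pos_num) | pos_num != floor(pos_num) | pos_num < 1)
    stop("non-integer or non-positive position in site table row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  lab <- tolower(trimws(tab$label))
  ok <- lab %in% c("positive", "negative")
  if (!all(ok)) {
    stop("unknown label token(s): ",
         paste(unique(tab$label[!ok]), collapse = ", "),
         " (expected 'positive' or 'negative')")
  }
  key <- paste(tab$protein_id, pos_num, sep = "@")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate site(s) in table: ", paste(utils::head(dup, 5),
                                               collapse = ", "))
  }
  data.frame(protein_id = tab$protein_id,
             position = as.integer(pos_num),
             label = factor(lab, levels = c("positive", "negative")),
             stringsAsFactors = FALSE)
}

#' Extract cysteine-centred peptide windows from protein sequences
#'
#' For every cysteine in every protein, builds the window of
#' `2 * half_window + 1` residues centred on it (default 21). Flanks that
#' extend past either terminus are filled with the pseudo-residue X, so X
#' appears only as a contiguous run at the start and/or end of a window.
#' Cysteines matched by a row of `sites` inherit its label; all other
#' cysteines are labelled `unknown`.
#'
#' Sites whose `protein_id` is absent from `proteins` are reported via a
#' message and skipped. A site whose position is out of bounds or does not
#' hold a cysteine is an error.
#'
#' @param proteins A data.frame as returned by [read_fasta()] (columns `id`,
#'   `sequence`), or a named character vector of sequences.
#' @param sites Optional data.frame as returned by [read_site_table()].
#' @param half_window Number of flanking residues on each side (default 10,
#'   giving 21-residue windows).
#' @return A data.frame with columns `protein_id`, `position` (1-based
#'   central-cysteine index), `window` (character) and `label` (factor with
#'   levels `positive`, `negative`, `unknown`).
#' @examples
#' prot <- data.frame(id = "p1", sequence = "MKCAVLLCW")
#' extract_fragments(prot, half_window = 3)
#' @export
extract_fragments <- function(proteins, sites = NULL, half_window = 10L) {
  proteins <- as_protein_df(proteins)
  half_window <- as.integer(half_window)
  if (is.na(half_window) || half_window < 1L) {
    stop("'half_window' must be a positive integer")
  }
  if (!is.null(sites)) {
    missing_prot <- setdiff(unique(sites$protein_id), proteins$id)
    if (length(missing_prot) > 0L) {
      message("skipping ", sum(sites$protein_id %in% missing_prot),
              " site(s) on protein(s) absent from the FASTA: ",
              paste(utils::head(missing_prot, 5), collapse = ", "))
      sites <- sites[!(sites$protein_id %in% missing_prot), , drop = FALSE]
    }
  }
  out <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]
    seq <- proteins$sequence[i]
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    cpos <- which(chars == "C")
    psites <- if (is.null(sites)) NULL else
      sites[sites$protein_id == id, , drop = FALSE]
    if (!is.null(psites) && nrow(psites) > 0L) {
      oob <- psites$position > length(chars)
      if (any(oob)) {
        stop("site position out of bounds for protein '", id, "': ",
             paste(psites$position[oob], collapse = ", "),
             " (sequence length ", length(chars), ")")
      }
      notc <- chars[psites$position] != "C"
      if (any(notc)) {
        stop("site at a non-cysteine position for protein '", id, "': ",
             "position ", paste(psites$position[notc], collapse = ", "),
             " is '", paste(chars[psites$position][notc], collapse = "','"),
             "', not a cysteine")
      }
    }
    if (length(cpos) == 0L) {
      out[[i]] <- NULL
      next
    }
    windows <- vapply(cpos, function(p) {
      window_at(chars, p, half_window)
    }, character(1))
    lab <- rep("unknown", length(cpos))
    if (!is.null(psites) && nrow(psites) > 0L) {
      m <- match(cpos, psites$position)
      lab[!is.na(m)] <- as.character(psites$label[m[!is.na(m)]])
    }
    out[[i]] <- data.frame(protein_id = id, position = cpos,
                           window = windows,
                           label = lab, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(protein_id = character(0), position = integer(0),
                      window = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res$label <- factor(res$label, levels = c("positive", "negative", "unknown"))
  res
}

#' @noRd
window_at <- function(chars, pos, half_window) {
  idx <- (pos - half_window):(pos + half_window)
  w <- ifelse(idx < 1L | idx > length(chars), "X", chars[pmax(pmin(idx, length(chars)), 1L)])
  paste(w, collapse = "")
}

#' @noRd
as_protein_df <- function(proteins) {
  if (is.character(proteins)) {
    if (is.null(names(proteins))) {
      stop("a character vector of sequences must be named by protein id")
    }
    proteins <- data.frame(id = names(proteins), sequence = unname(proteins),
                           stringsAsFactors = FALSE)
  }
  if (!is.data.frame(proteins) ||
      !all(c("id", "sequence") %in% names(proteins))) {
    stop("'proteins' must be a data.frame with columns 'id' and 'sequence'")
  }
  if (any(!nzchar(proteins$sequence))) {
    stop("empty sequence for protein(s): ",
         paste(proteins$id[!nzchar(proteins$sequence)], collapse = ", "))
  }
  if (anyDuplicated(proteins$id)) {
    stop("duplicate protein id(s): ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "))
  }
  proteins
}

#' Write peptide fragments to CSV
#'
#' @param fragments A fragment data.frame from [extract_fragments()] or
#'   [generate_fragments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.csv(fragments[, c("protein_id", "position", "window", "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read peptide fragments from CSV
#'
#' Reads a fragment table written by [write_fragments()] and validates the
#' window contract (odd length, central cysteine, 21-letter alphabet).
#'
#' @param path Input CSV with columns `protein_id`, `position`, `window`,
#'   `label`.
#' @return A fragment data.frame.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "window", "label")
  if (!all(need %in% names(tab))) {
    stop("fragment table must have columns ", paste(need, collapse = ", "))
  }
  tab$label <- factor(tab$label, levels = c("positive", "negative", "unknown"))
  validate_windows(tab$window)
  tab
}

#' @noRd
validate_windows <- function(windows) {
  len <- unique(nchar(windows))
  if (length(len) > 1L) stop("windows have differing lengths")
  if (length(len) == 1L && len %% 2L == 0L) stop("window length must be odd")
  centre <- (len + 1L) %/% 2L
  ch <- substr(windows, centre, centre)
  if (any(ch != "C")) {
    stop("window(s) without a central cysteine at row(s): ",
         paste(utils::head(which(ch != "C"), 5), collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(AA21, collapse = ""), "]"), windows)
  if (any(bad)) {
    stop("window(s) with characters outside the 21-letter alphabet at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  invisible(windows)
}
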