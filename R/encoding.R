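#' @noRd
window_chars <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 3L || L %% 2L == 0L) {
    stop("window must have odd length >= 3, got ", L)
  }
  if (chars[(L + 1L) %/% 2L] != "C") {
    stop("window central residue must be C: ", window)
  }
  bad <- !(chars %in% AA21)
  if (any(bad)) {
    stop("window contains character(s) outside the 21-letter alphabet: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  chars
}

#' @noRd
flank_chars <- function(chars) {
  chars[-((length(chars) + 1L) %/% 2L)]
}

#' Binary (one-hot) encoding of a peptide window
#'
#' Encodes each flanking residue (the central cysteine is removed) as a
#' 21-length one-hot vector over the fixed alphabet ACDEFGHIKLMNPQRSTVWY + X,
#' concatenated position-major. With the default 21-residue window this
#' yields 20 x 21 = 420 features, each one-hot sub-vector summing to exactly
#' one.
#'
#' @param window A window string (odd length, central C), or a one-row
#'   fragment data.frame.
#' @return A named numeric vector of length `21 * (window length - 1)`.
#' @examples
#' w <- paste0(strrep("A", 10), "C", strrep("A", 10))
#' sum(encode_be(w))  # 20 one-hot blocks
#' @export
encode_be <- function(window) {
  chars <- window_chars(as_window(window))
  fl <- flank_chars(chars)
  idx <- match(fl, AA21)
  v <- numeric(21L * length(fl))
  v[(seq_along(fl) - 1L) * 21L + idx] <- 1
  names(v) <- paste0("BE.p", rep(seq_along(fl), each = 21L), ".",
                     rep(AA21, length(fl)))
  v
}

#' AAindex physicochemical-property encoding of a peptide window
#'
#' For each flanking residue (central cysteine removed), the values of the
#' 14 physicochemical properties from `table`, position-major. X positions
#' contribute 14 zeros. With the default window this yields 20 x 14 = 280
#' features.
#'
#' @inheritParams encode_be
#' @param table An [aa_property_table()].
#' @return A named numeric vector of length `14 * (window length - 1)`.
#' @export
encode_aaindex <- function(window, table = aa_property_table()) {
  encode_property_block(window, table$aaindex14, "AAindex")
}

#' High-quality-index encoding of a peptide window
#'
#' For each flanking residue (central cysteine removed), the values of the
#' 8 high-quality AAindex indices, position-major. X positions contribute 8
#' zeros. With the default window this yields 20 x 8 = 160 features.
#'
#' @inheritParams encode_aaindex
#' @return A named numeric vector of length `8 * (window length - 1)`.
#' @export
encode_hqi <- function(window, table = aa_property_table()) {
  encode_property_block(window, table$hqi8, "HQI")
}

#' @noRd
encode_property_block <- function(window, mat, block) {
  chars <- window_chars(as_window(window))
  fl <- flank_chars(chars)
  missing <- setdiff(AA21, rownames(mat))
  if (length(missing) > 0L) {
    stop("property table is missing residue(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- mat[fl, , drop = FALSE]
  v <- as.numeric(t(vals))
  names(v) <- paste0(block, ".p", rep(seq_along(fl), each = ncol(mat)), ".",
                     rep(colnames(mat), length(fl)))
  v
}

#' k-spaced amino-acid pair (KSAAP/CKSAAP) encoding of a peptide window
#'
#' For each spacer count k in `k_values`, counts every ordered residue pair
#' (a, b) separated by exactly k intervening positions across the full
#' window (central cysteine included), over the 21-letter alphabet. Counts
#' are laid out row-major (first residue fastest over the second), blocks
#' concatenated in k order. With the defaults this yields
#' 21 x 21 x 3 = 1,323 features; within the k-block of a 21-residue window
#' the counts sum to 20 - k.
#'
#' @inheritParams encode_be
#' @param k_values Ordered spacer counts (default `0:2`; k = 0 is the
#'   classical dipeptide composition).
#' @return A named numeric vector of length `441 * length(k_values)`.
#' @examples
#' w <- paste0(strrep("A", 10), "C", strrep("A", 10))
#' v <- encode_ksaap(w, k_values = 0)
#' v[c("KSAAP.k0.AA", "KSAAP.k0.AC", "KSAAP.k0.CA")]
#' @export
encode_ksaap <- function(window, k_values = 0:2) {
  chars <- window_chars(as_window(window))
  check_k_values(k_values, length(chars))
  idx <- match(chars, AA21)
  L <- length(idx)
  out <- numeric(0)
  for (k in k_values) {
    i <- seq_len(L - k - 1L)
    code <- (idx[i] - 1L) * 21L + idx[i + k + 1L]
    counts <- tabulate(code, nbins = 441L)
    names(counts) <- paste0("KSAAP.k", k, ".",
                            rep(AA21, each = 21L), rep(AA21, 21L))
    out <- c(out, counts)
  }
  out
}

#' @noRd
check_k_values <- function(k_values, window_length) {
  if (length(k_values) == 0L) stop("'k_values' must be non-empty")
  if (any(k_values < 0) || any(k_values != floor(k_values))) {
    stop("'k_values' must be non-negative integers")
  }
  if (is.unsorted(k_values, strictly = TRUE)) {
    stop("'k_values' must be strictly increasing")
  }
  if (any(k_values >= window_length - 1L)) {
    stop("k = ", max(k_values), " admits no pairs in a window of length ",
         window_length)
  }
  invisible(k_values)
}

#' Amino-acid composition encoding of a peptide window
#'
#' The frequency of each of the 20 canonical residues among the flanking
#' positions (central cysteine excluded): F_a = R_a / R with R the flank
#' length (20 by default). X positions count toward the denominator but not
#' toward any canonical residue, so the 20 values sum to
#' 1 - (X count) / R.
#'
#' @inheritParams encode_be
#' @return A named numeric vector of length 20 with values in \[0, 1\].
#' @export
encode_aac <- function(window) {
  chars <- window_chars(as_window(window))
  fl <- flank_chars(chars)
  counts <- tabulate(match(fl, AA20), nbins = 20L)
  v <- counts / length(fl)
  names(v) <- paste0("AAC.", AA20)
  v
}

FEATURE_BLOCKS <- c("BE", "AAindex", "KSAAP", "AAC", "HQI")

#' Assemble the full feature vector for one peptide window
#'
#' Concatenates the enabled feature blocks in the fixed order BE, AAindex,
#' KSAAP, AAC, HQI. With all five blocks and the default 21-residue window
#' the result has 420 + 280 + 1,323 + 20 + 160 = 2,203 features. The block
#' layout is recorded in the `block_map` attribute (a data.frame with
#' columns `block`, `start`, `length`; `start` is the 1-based offset of the
#' block's first feature).
#'
#' @inheritParams encode_ksaap
#' @param blocks Character vector of block names to enable, a subset of
#'   `c("BE", "AAindex", "KSAAP", "AAC", "HQI")`.
#' @param table An [aa_property_table()] (used by the AAindex and HQI
#'   blocks).
#' @return A named numeric vector with attribute `block_map`.
#' @examples
#' w <- paste0(strrep("X", 10), "C", strrep("X", 10))
#' length(assemble_features(w))  # 2203
#' @export
assemble_features <- function(window, blocks = FEATURE_BLOCKS,
                              table = aa_property_table(), k_values = 0:2) {
  blocks <- check_blocks(blocks)
  parts <- lapply(blocks, function(b) {
    switch(b,
           BE      = encode_be(window),
           AAindex = encode_aaindex(window, table),
           KSAAP   = encode_ksaap(window, k_values),
           AAC     = encode_aac(window),
           HQI     = encode_hqi(window, table))
  })
  v <- unlist(parts, use.names = TRUE)
  len <- vapply(parts, length, integer(1))
  attr(v, "block_map") <- data.frame(
    block = blocks,
    start = cumsum(c(1L, len[-length(len)])),
    length = len,
    stringsAsFactors = FALSE)
  v
}

#' @noRd
check_blocks <- function(blocks) {
  if (length(blocks) == 0L) stop("at least one feature block must be enabled")
  unknown <- setdiff(blocks, FEATURE_BLOCKS)
  if (length(unknown) > 0L) {
    stop("unknown feature block(s): ", paste(unknown, collapse = ", "),
         " (valid: ", paste(FEATURE_BLOCKS, collapse = ", "), ")")
  }
  # fixed concatenation order regardless of request order
  FEATURE_BLOCKS[FEATURE_BLOCKS %in% blocks]
}

#' Encode a set of peptide fragments into a feature matrix
#'
#' Applies [assemble_features()] to every fragment window and stacks the
#' results into an n x p matrix (p = 2,203 with all blocks at the default
#' window). The `block_map` attribute records each block's column range.
#'
#' @param fragments A fragment data.frame (columns `window` and, optionally,
#'   `label`), or a character vector of window strings.
#' @inheritParams assemble_features
#' @return A numeric matrix with one row per fragment, column names
#'   identifying each feature, and attribute `block_map`.
#' @examples
#' frags <- generate_fragments(5, 5, seed = 1)
#' x <- encode_fragments(frags, blocks = "AAC")
#' dim(x)
#' @export
encode_fragments <- function(fragments, blocks = FEATURE_BLOCKS,
                             table = aa_property_table(), k_values = 0:2) {
  windows <- if (is.data.frame(fragments)) fragments$window else fragments
  if (length(windows) == 0L) stop("no fragments to encode")
  first <- assemble_features(windows[1L], blocks, table, k_values)
  x <- matrix(0, nrow = length(windows), ncol = length(first),
              dimnames = list(NULL, names(first)))
  x[1L, ] <- first
  if (length(windows) > 1L) {
    for (i in 2L:length(windows)) {
      x[i, ] <- assemble_features(windows[i], blocks, table, k_values)
    }
  }
  attr(x, "block_map") <- attr(first, "block_map")
  x
}

#' Extract the columns of one or more feature blocks
#'
#' @param x A feature matrix from [encode_fragments()].
#' @param blocks Block names to keep.
#' @return The sub-matrix, with an updated `block_map` attribute.
#' @export
feature_block <- function(x, blocks) {
  map <- attr(x, "block_map")
  if (is.null(map)) stop("'x' has no block_map attribute")
  blocks <- check_blocks(blocks)
  missing <- setdiff(blocks, map$block)
  if (length(missing) > 0L) {
    stop("block(s) not present in matrix: ", paste(missing, collapse = ", "))
  }
  keep <- map[map$block %in% blocks, , drop = FALSE]
  cols <- unlist(mapply(function(s, l) seq.int(s, length.out = l),
                        keep$start, keep$length, SIMPLIFY = FALSE))
  out <- x[, cols, drop = FALSE]
  keep$start <- cumsum(c(1L, keep$length[-nrow(keep)]))
  rownames(keep) <- NULL
  attr(out, "block_map") <- keep
  out
}

#' @noRd
as_window <- function(window) {
  if (is.data.frame(window)) {
    if (nrow(window) != 1L || is.null(window$window)) {
      stop("expected a single window string or a one-row fragment data.frame")
    }
    window <- window$window
  }
  if (!is.character(window) || length(window) != 1L) {
    stop("expected a single window string")
  }
  window
}

#' Write a feature matrix to CSV
#'
#' One row per fragment, one column per feature named `block[index]`.
#'
#' @param x Feature matrix from [encode_fragments()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
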