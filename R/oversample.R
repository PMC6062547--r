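#' Balance classes by seeded random oversampling of the minority class
#'
#' Randomly replicates rows of the minority class, uniformly with
#' replacement, until both classes have as many rows as the original
#' majority class. Every original row is retained exactly once (no
#' information is lost, the rationale for preferring oversampling to
#' under-sampling on small PTM datasets); the appended rows are copies of
#' minority rows. Deterministic for a given seed.
#'
#' @param x Numeric feature matrix, one row per example.
#' @param y Parallel label vector/factor with values `positive` and
#'   `negative`; both classes must be present.
#' @param seed Integer seed controlling which minority rows are replicated.
#' @return A list with elements `x` (balanced matrix, original rows first in
#'   their original order, replicates appended), `y` (parallel factor) and
#'   `provenance` (integer vector giving, for every balanced row, the index
#'   of the original row it copies).
#' @examples
#' x <- matrix(seq_len(26), ncol = 2)
#' y <- rep(c("positive", "negative"), c(3, 10))
#' bal <- oversample(x, y, seed = 1)
#' table(bal$y)
#' @export
oversample <- function(x, y, seed = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as_label_factor(y)
  if (nrow(x) != length(y)) {
    stop("'x' and 'y' must have the same number of rows")
  }
  counts <- table(y)
  if (any(counts == 0L)) {
    stop("cannot balance: only one class present (",
         names(counts)[counts > 0L], ")")
  }
  map <- attr(x, "block_map")
  minority <- names(counts)[which.min(counts)]
  deficit <- max(counts) - min(counts)
  provenance <- seq_len(nrow(x))
  if (deficit > 0L) {
    pool <- which(y == minority)
    extra <- with_seed(seed, sample(pool, deficit, replace = TRUE))
    x <- rbind(x, x[extra, , drop = FALSE])
    y <- factor(c(as.character(y), as.character(y[extra])),
                levels = levels(y))
    provenance <- c(provenance, extra)
  }
  out <- list(x = x, y = y, provenance = provenance)
  if (!is.null(map)) attr(out$x, "block_map") <- map
  out
}

#' @noRd
as_label_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  ok <- y %in% c("positive", "negative")
  if (!all(ok)) {
    stop("labels must be 'positive' or 'negative'; found: ",
         paste(unique(y[!ok]), collapse = ", "))
  }
  factor(y, levels = c("positive", "negative"))
}
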