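# Independent oracles and small generators used across tests. These stay
# deliberately naive (character loops, all-pairs counting) so they share no
# code path with the implementation they check.

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA21_T <- c(AA20_T, "X")

# Random 21-residue window with a central C and an optional terminal X run.
random_window <- function(half_window = 10) {
  n <- 2 * half_window
  fl <- sample(AA20_T, n, replace = TRUE)
  if (runif(1) < 0.3) {
    nx <- sample.int(half_window, 1)
    if (runif(1) < 0.5) fl[seq_len(nx)] <- "X"
    else fl[(n - nx + 1):n] <- "X"
  }
  paste0(paste(fl[seq_len(half_window)], collapse = ""), "C",
         paste(fl[(half_window + 1):n], collapse = ""))
}

# O(L^2) brute-force k-spaced pair counter over the full window.
brute_force_ksaap <- function(window, k_values = 0:2) {
  chars <- strsplit(window, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (k in k_values) {
    counts <- matrix(0, 21, 21, dimnames = list(AA21_T, AA21_T))
    for (i in seq_len(L)) {
      j <- i + k + 1
      if (j <= L) counts[chars[i], chars[j]] <- counts[chars[i], chars[j]] + 1
    }
    # row-major: first residue outer, second inner
    out <- c(out, as.numeric(t(counts)))
  }
  out
}

# Mann-Whitney U / (n+ * n-), ties counted half, by all-pairs enumeration.
u_statistic_auc <- function(truth, scores) {
  sp <- scores[truth == "positive"]
  sn <- scores[truth == "negative"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Naive window reconstruction by character slicing with explicit padding.
slice_window <- function(sequence, pos, half_window = 10) {
  chars <- strsplit(sequence, "")[[1]]
  out <- character(2 * half_window + 1)
  for (o in -half_window:half_window) {
    i <- pos + o
    out[o + half_window + 1] <- if (i >= 1 && i <= length(chars)) chars[i]
    else "X"
  }
  paste(out, collapse = "")
}

# Fast labelled toy feature data: two shifted Gaussian clouds.
toy_cloud <- function(n_pos, n_neg, sep = 3, d = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_pos * d, sep / 2), n_pos),
             matrix(rnorm(n_neg * d, -sep / 2), n_neg))
  list(x = x, y = factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
                         levels = c("positive", "negative")))
}
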