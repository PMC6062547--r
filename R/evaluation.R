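#' Confusion-matrix counts
#'
#' @param truth True labels (`positive` / `negative`).
#' @param predicted Predicted labels, same length.
#' @return Named integer vector with elements `TP` (true positives: correctly
#'   classified sulfenylation sites), `TN`, `FP`, `FN`; they sum to the
#'   number of examples.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as_label_factor(truth)
  predicted <- as_label_factor(predicted)
  if (length(truth) != length(predicted)) {
    stop("'truth' and 'predicted' must have the same length")
  }
  if (length(truth) == 0L) stop("empty input")
  c(TP = sum(truth == "positive" & predicted == "positive"),
    TN = sum(truth == "negative" & predicted == "negative"),
    FP = sum(truth == "negative" & predicted == "positive"),
    FN = sum(truth == "positive" & predicted == "negative"))
}

#' Accuracy, sensitivity, specificity and Matthews correlation coefficient
#'
#' Standard binary-classification metrics from confusion counts:
#' ACC = (TP+TN)/(TP+TN+FP+FN) x 100, SN = TP/(TP+FN) x 100,
#' SP = TN/(TN+FP) x 100, and
#' MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' When any factor of the MCC denominator is zero the coefficient is
#' undefined; following the usual convention it is reported as 0 with
#' `mcc_degenerate = TRUE`. SN (resp. SP) is `NaN` when there are no true
#' positives+false negatives (resp. negatives) to measure it on.
#'
#' @param counts Named vector with elements `TP`, `TN`, `FP`, `FN` (as from
#'   [confusion_counts()]), or four separate counts via `TP=, TN=, FP=, FN=`.
#' @param TP,TN,FP,FN Alternative scalar interface.
#' @return A list with `acc`, `sn`, `sp` (percentages), `mcc` (in
#'   \[-1, 1\]), `mcc_degenerate` (logical) and the `counts`.
#' @examples
#' classification_metrics(c(TP = 95, TN = 83, FP = 17, FN = 5))
#' @export
classification_metrics <- function(counts = NULL, TP = NULL, TN = NULL,
                                   FP = NULL, FN = NULL) {
  if (is.null(counts)) {
    counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  }
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(counts))) {
    stop("counts must be named TP, TN, FP, FN")
  }
  counts <- counts[need]
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  tp <- as.numeric(counts["TP"]); tn <- as.numeric(counts["TN"])
  fp <- as.numeric(counts["FP"]); fn <- as.numeric(counts["FN"])
  n <- tp + tn + fp + fn
  if (n == 0) stop("all counts are zero")
  acc <- (tp + tn) / n * 100
  sn <- if (tp + fn > 0) tp / (tp + fn) * 100 else NaN
  sp <- if (tn + fp > 0) tn / (tn + fp) * 100 else NaN
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- denom2 == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  list(acc = acc, sn = sn, sp = sp, mcc = mcc,
       mcc_degenerate = degenerate, counts = counts)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over every distinct score (tied scores
#' grouped into a single step) and returns the
#' (false-positive rate, true-positive rate) points, anchored at (0, 0) and
#' ending at (1, 1), with the trapezoid-rule area under the curve. Under
#' this tie-grouping convention a constant-score classifier has AUC exactly
#' 0.5, and the AUC equals the Mann-Whitney U statistic divided by
#' n+ x n- (ties counted half).
#'
#' @param truth True labels (`positive` / `negative`), both classes present.
#' @param scores Finite numeric scores, larger = more positive-like.
#' @return A list with `points` (data.frame `threshold`, `fpr`, `tpr`; a row
#'   classifies as positive every score >= its threshold) and `auc`.
#' @examples
#' roc_curve(c("positive", "negative"), c(2, 1))$auc  # 1
#' @export
roc_curve <- function(truth, scores) {
  truth <- as_label_factor(truth)
  if (length(truth) != length(scores)) {
    stop("'truth' and 'scores' must have the same length")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  npos <- sum(truth == "positive")
  nneg <- sum(truth == "negative")
  if (npos == 0L || nneg == 0L) {
    stop("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- truth[ord] == "positive"
  runs <- rle(s)
  last <- cumsum(runs$lengths)
  tpr <- c(0, cumsum(pos)[last] / npos)
  fpr <- c(0, cumsum(!pos)[last] / nneg)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  list(points = data.frame(threshold = c(Inf, runs$values),
                           fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Stratified k-fold cross-validation of the SVM pipeline
#'
#' Partitions the data into `n_folds` class-stratified folds (per-class fold
#' sizes differ by at most one), trains on k-1 folds and tests on the
#' held-out fold, and averages ACC/SN/SP/MCC/AUC over folds (unweighted, one
#' model per fold). Pooled confusion counts and a pooled ROC over all
#' held-out scores are reported secondarily.
#'
#' `balance` controls where the minority class is oversampled:
#' \describe{
#'   \item{`"paper"`}{(default) oversample the whole dataset once, then
#'     fold the balanced data. Replicates of one fragment can then land in
#'     both a training and a test fold, which inflates cross-validated
#'     sensitivity relative to truly held-out data — the optimistic protocol
#'     this mode reproduces deliberately.}
#'   \item{`"fold-safe"`}{fold the original data, then oversample within
#'     each training fold only; no test-fold fragment (or a replicate of
#'     it) is ever seen in training.}
#'   \item{`"none"`}{no balancing.}
#' }
#'
#' @param x Feature matrix.
#' @param y Labels (`positive` / `negative`).
#' @param n_folds Number of folds (default 10); each class must have at
#'   least `n_folds` members.
#' @param balance Oversampling placement: `"paper"`, `"fold-safe"` or
#'   `"none"`.
#' @param seed Integer seed driving fold assignment and oversampling.
#' @inheritParams sulfen_svm
#' @return An object of class `sulfen_cv`: list with `metrics` (fold-mean
#'   `acc`, `sn`, `sp`, `mcc`, `auc`), `pooled` (metrics and AUC from pooled
#'   counts/scores), `roc` (pooled ROC points), `folds` (per-fold reports
#'   with test indices and training-row provenance) and `config`.
#' @examples
#' frags <- generate_fragments(30, 30, motif_spec(strength = 0.9), seed = 1)
#' x <- encode_fragments(frags, blocks = "AAC")
#' cv <- cross_validate(x, frags$label, n_folds = 3, cost = 1, kw = 0.5)
#' cv$metrics$acc
#' @export
cross_validate <- function(x, y, n_folds = 10L,
                           balance = c("paper", "fold-safe", "none"),
                           cost = 0.1, kw = 0.005,
                           kw_is = c("gamma", "sigma"),
                           standardize = FALSE, seed = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as_label_factor(y)
  balance <- match.arg(balance)
  kw_is <- match.arg(kw_is)
  n_folds <- as.integer(n_folds)
  if (nrow(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (is.na(n_folds) || n_folds < 2L) stop("'n_folds' must be at least 2")
  block_map <- attr(x, "block_map")
  provenance <- seq_len(nrow(x))
  if (balance == "paper") {
    bal <- oversample(x, y, seed)
    x <- bal$x
    y <- bal$y
    provenance <- bal$provenance
  }
  counts <- table(y)
  if (any(counts < n_folds)) {
    small <- names(counts)[counts < n_folds]
    stop("n_folds = ", n_folds, " exceeds the size of class '",
         paste(small, collapse = "', '"), "' (",
         paste(counts[small], collapse = ", "), ")")
  }
  folds <- stratified_folds(y, n_folds, seed)
  fold_reports <- vector("list", n_folds)
  all_scores <- numeric(nrow(x))
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    tx <- x[train, , drop = FALSE]
    ty <- y[train]
    tprov <- provenance[train]
    if (balance == "fold-safe") {
      bal <- oversample(tx, ty, seed + 97L * f)
      tx <- bal$x
      ty <- bal$y
      tprov <- tprov[bal$provenance]
    }
    fit <- sulfen_svm(tx, ty, cost = cost, kw = kw, kw_is = kw_is,
                      standardize = standardize, seed = seed)
    scores <- decision_scores(fit, x[test, , drop = FALSE])
    all_scores[test] <- scores
    pred <- factor(ifelse(scores > 0, "positive", "negative"),
                   levels = c("positive", "negative"))
    cc <- confusion_counts(y[test], pred)
    fold_reports[[f]] <- list(
      fold = f,
      test_rows = test,
      test_provenance = provenance[test],
      train_provenance = tprov,
      counts = cc,
      metrics = classification_metrics(cc),
      auc = roc_curve(y[test], scores)$auc
    )
  }
  fold_stat <- function(get) mean(vapply(fold_reports, get, numeric(1)))
  metrics <- list(
    acc = fold_stat(function(r) r$metrics$acc),
    sn  = fold_stat(function(r) r$metrics$sn),
    sp  = fold_stat(function(r) r$metrics$sp),
    mcc = fold_stat(function(r) r$metrics$mcc),
    auc = fold_stat(function(r) r$auc)
  )
  pooled_counts <- Reduce(`+`, lapply(fold_reports, function(r) r$counts))
  pooled_roc <- roc_curve(y, all_scores)
  structure(list(
    metrics = metrics,
    pooled = c(classification_metrics(pooled_counts)[c("acc", "sn", "sp",
                                                       "mcc")],
               list(auc = pooled_roc$auc)),
    roc = pooled_roc$points,
    folds = fold_reports,
    config = list(n_folds = n_folds, balance = balance, seed = seed,
                  cost = cost, kw = kw, kw_is = kw_is,
                  standardize = standardize,
                  blocks = if (is.null(block_map)) NULL else block_map$block,
                  n_features = ncol(x))
  ), class = "sulfen_cv")
}

#' @noRd
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' @export
print.sulfen_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (balance = %s, seed = %d)\n",
              x$config$n_folds, x$config$balance, x$config$seed))
  if (!is.null(x$config$blocks)) {
    cat("  feature blocks:", paste(x$config$blocks, collapse = ", "), "\n")
  }
  cat(sprintf("  ACC %.0f%%  SN %.0f%%  SP %.0f%%  MCC %.2f  AUC %.2f\n",
              x$metrics$acc, x$metrics$sn, x$metrics$sp, x$metrics$mcc,
              x$metrics$auc))
  invisible(x)
}

#' Per-feature-block ablation by cross-validation
#'
#' Cross-validates the classifier on each requested feature-block subset of
#' a full feature matrix, re-using the same folds and seed across rows so
#' the block sets are directly comparable. The default block sets mirror a
#' one-feature-at-a-time ablation plus the all-features model.
#'
#' @param x Full feature matrix from [encode_fragments()] (must carry a
#'   `block_map`).
#' @param y Labels.
#' @param block_sets Named list of character vectors of block names
#'   (default: each single block, then all blocks present).
#' @inheritParams cross_validate
#' @return A data.frame with one row per block set (`blocks`, `acc`, `sn`,
#'   `sp`, `mcc`, `auc`); the full `sulfen_cv` reports are in the `reports`
#'   attribute.
#' @export
ablation <- function(x, y, block_sets = NULL, n_folds = 10L,
                     balance = c("paper", "fold-safe", "none"), cost = 0.1,
                     kw = 0.005, kw_is = c("gamma", "sigma"),
                     standardize = FALSE, seed = 1L) {
  map <- attr(x, "block_map")
  if (is.null(map)) stop("'x' must carry a block_map attribute")
  balance <- match.arg(balance)
  kw_is <- match.arg(kw_is)
  if (is.null(block_sets)) {
    block_sets <- c(as.list(map$block), list(map$block))
    names(block_sets) <- c(map$block, "All")
  }
  if (is.null(names(block_sets))) {
    names(block_sets) <- vapply(block_sets, paste, character(1),
                                collapse = "+")
  }
  reports <- lapply(block_sets, function(bs) {
    cross_validate(feature_block(x, bs), y, n_folds = n_folds,
                   balance = balance, cost = cost, kw = kw, kw_is = kw_is,
                   standardize = standardize, seed = seed)
  })
  out <- data.frame(
    blocks = names(block_sets),
    acc = vapply(reports, function(r) r$metrics$acc, numeric(1)),
    sn  = vapply(reports, function(r) r$metrics$sn, numeric(1)),
    sp  = vapply(reports, function(r) r$metrics$sp, numeric(1)),
    mcc = vapply(reports, function(r) r$metrics$mcc, numeric(1)),
    auc = vapply(reports, function(r) r$metrics$auc, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Evaluate a fitted model on an independent test set
#'
#' Scores held-out fragments and reports confusion counts, ACC/SN/SP/MCC,
#' and the ROC/AUC — the protocol for a test set kept hidden from training.
#'
#' @param model A [sulfen_svm()] fit.
#' @param x Feature matrix of the held-out fragments.
#' @param y Their true labels.
#' @param threshold Decision threshold (default 0).
#' @return A list with `counts`, `metrics` (from
#'   [classification_metrics()]), `roc` points and `auc`.
#' @export
evaluate_model <- function(model, x, y, threshold = 0) {
  y <- as_label_factor(y)
  scores <- decision_scores(model, x)
  pred <- factor(ifelse(scores > threshold, "positive", "negative"),
                 levels = c("positive", "negative"))
  cc <- confusion_counts(y, pred)
  roc <- roc_curve(y, scores)
  list(counts = cc, metrics = classification_metrics(cc),
       roc = roc$points, auc = roc$auc)
}
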