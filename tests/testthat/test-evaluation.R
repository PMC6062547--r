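test_that("confusion counts partition the examples", {
  y <- rep(c("positive", "negative"), each = 5)
  expect_equal(confusion_counts(y, y),
               c(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  allpos <- rep("positive", 10)
  expect_equal(confusion_counts(y, allpos),
               c(TP = 5L, TN = 0L, FP = 5L, FN = 0L))
  expect_error(confusion_counts(y, y[1:3]), "same length")
  expect_error(confusion_counts(character(0), character(0)), "empty")
})

test_that("metric formulas reproduce hand-computed reference values", {
  perfect <- classification_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$sn, 100)
  expect_equal(perfect$sp, 100)
  expect_equal(perfect$mcc, 1)

  m <- classification_metrics(c(TP = 95, TN = 83, FP = 17, FN = 5))
  expect_equal(m$acc, 89)
  expect_equal(m$sn, 95)
  expect_equal(m$sp, 83)
  expect_equal(round(m$mcc, 2), 0.79)
  expect_false(m$mcc_degenerate)
})

test_that("degenerate confusion tables are flagged, not propagated as NaN", {
  m <- classification_metrics(c(TP = 0, TN = 10, FP = 0, FN = 10))
  expect_equal(m$sn, 0)
  expect_equal(m$sp, 100)
  expect_equal(m$mcc, 0)
  expect_true(m$mcc_degenerate)
  # no positives at all: sensitivity is not measurable
  m2 <- classification_metrics(c(TP = 0, TN = 10, FP = 2, FN = 0))
  expect_true(is.nan(m2$sn))
})

test_that("metrics agree with an independent recomputation on random tables", {
  set.seed(101)
  for (i in 1:2000) {
    cc <- sample(0:40, 4, replace = TRUE)
    if (sum(cc) == 0) next
    names(cc) <- c("TP", "TN", "FP", "FN")
    m <- classification_metrics(cc)
    tp <- cc[["TP"]]; tn <- cc[["TN"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]
    expect_equal(m$acc, 100 * (tp + tn) / sum(cc))
    if (tp + fn > 0) expect_equal(m$sn, 100 * tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$sp, 100 * tn / (tn + fp))
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den > 0) expect_equal(m$mcc, (tp * tn - fp * fn) / den)
  }
})

test_that("MCC equals the Pearson correlation of the binary label vectors", {
  set.seed(55)
  for (i in 1:100) {
    cc <- sample(1:15, 4, replace = TRUE)
    names(cc) <- c("TP", "TN", "FP", "FN")
    truth <- rep(c(1, 0, 0, 1), cc)  # TP, TN, FP, FN
    pred <- rep(c(1, 0, 1, 0), cc)
    expect_equal(classification_metrics(cc)$mcc, stats::cor(truth, pred))
  }
})

test_that("MCC symmetries hold", {
  cc <- c(TP = 12, TN = 30, FP = 4, FN = 9)
  swapped <- c(TP = 30, TN = 12, FP = 9, FN = 4)
  expect_equal(classification_metrics(cc)$mcc,
               classification_metrics(swapped)$mcc)
  negated <- c(TP = 9, TN = 4, FP = 30, FN = 12)
  expect_equal(classification_metrics(negated)$mcc,
               -classification_metrics(cc)$mcc)
})

test_that("ROC endpoints: perfect separation 1.0, constant scores 0.5", {
  y <- rep(c("positive", "negative"), each = 10)
  perfect <- roc_curve(y, rep(c(1, 0), each = 10))
  expect_equal(perfect$auc, 1.0)
  constant <- roc_curve(y, rep(3.7, 20))
  expect_identical(constant$auc, 0.5)
  expect_equal(nrow(constant$points), 2L)
  reversed <- roc_curve(y, rep(c(0, 1), each = 10))
  expect_equal(reversed$auc, 0)
})

test_that("ROC points run from (0,0) to (1,1) and AUC matches the U oracle", {
  set.seed(77)
  for (i in 1:30) {
    n <- 60
    y <- sample(rep(c("positive", "negative"), c(25, 35)))
    scores <- round(rnorm(n, mean = (y == "positive")), 1)  # forces ties
    r <- roc_curve(y, scores)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$auc, u_statistic_auc(y, scores))
  }
})

test_that("AUC matches pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(78)
  y <- sample(rep(c("positive", "negative"), each = 40))
  scores <- rnorm(80, mean = 0.8 * (y == "positive"))
  r <- roc_curve(y, scores)
  ref <- pROC::auc(pROC::roc(response = y, predictor = scores,
                             levels = c("negative", "positive"),
                             direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref))
})

test_that("ROC rejects single-class input and non-finite scores", {
  expect_error(roc_curve(rep("positive", 5), 1:5), "both classes")
  expect_error(roc_curve(c("positive", "negative"), c(1, NA)), "finite")
})

test_that("stratified folds partition each class evenly, each row tested once", {
  d <- toy_cloud(50, 50, seed = 9)
  cv <- cross_validate(d$x, d$y, n_folds = 10, balance = "none",
                       cost = 1, kw = 0.1, seed = 5)
  tested <- sort(unlist(lapply(cv$folds, function(f) f$test_rows)))
  expect_equal(tested, 1:100)
  sizes <- vapply(cv$folds, function(f) length(f$test_rows), numeric(1))
  expect_equal(unname(sizes), rep(10, 10))
  counts <- Reduce(`+`, lapply(cv$folds, function(f) f$counts))
  expect_equal(sum(counts), 100)
})

test_that("cross-validation is deterministic given the seed", {
  d <- toy_cloud(30, 30, seed = 10)
  a <- cross_validate(d$x, d$y, n_folds = 5, cost = 1, kw = 0.1, seed = 3)
  b <- cross_validate(d$x, d$y, n_folds = 5, cost = 1, kw = 0.1, seed = 3)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$folds[[2]]$counts, b$folds[[2]]$counts)
})

test_that("fold counts are validated against class sizes", {
  d <- toy_cloud(5, 40, seed = 11)
  expect_error(cross_validate(d$x, d$y, n_folds = 10, balance = "none",
                              seed = 1),
               "exceeds the size")
  expect_error(cross_validate(d$x, d$y, n_folds = 1, seed = 1),
               "at least 2")
})

test_that("fold-safe balancing never leaks test fragments into training", {
  d <- toy_cloud(8, 40, seed = 12)
  cv <- cross_validate(d$x, d$y, n_folds = 4, balance = "fold-safe",
                       cost = 1, kw = 0.1, seed = 2)
  for (f in cv$folds) {
    expect_length(intersect(f$test_provenance, f$train_provenance), 0L)
  }
  # paper-mode balancing, by contrast, can place replicates across folds
  cvp <- cross_validate(d$x, d$y, n_folds = 4, balance = "paper",
                        cost = 1, kw = 0.1, seed = 2)
  overlap <- vapply(cvp$folds, function(f) {
    length(intersect(f$test_provenance, f$train_provenance))
  }, numeric(1))
  expect_gt(sum(overlap), 0)
})

test_that("headline metrics are the unweighted fold means", {
  d <- toy_cloud(20, 30, seed = 13)
  cv <- cross_validate(d$x, d$y, n_folds = 5, balance = "none",
                       cost = 1, kw = 0.1, seed = 4)
  expect_equal(cv$metrics$acc,
               mean(vapply(cv$folds, function(f) f$metrics$acc, numeric(1))))
  expect_equal(cv$metrics$auc,
               mean(vapply(cv$folds, function(f) f$auc, numeric(1))))
  expect_true(!is.null(cv$pooled$acc))
})

test_that("ablation reuses folds across block subsets and matches plain CV", {
  frags <- generate_fragments(20, 20, motif_spec(strength = 0.8), seed = 14)
  x <- encode_fragments(frags)
  y <- droplevels(frags$label)
  tab <- ablation(x, y, n_folds = 4, cost = 1, kw = 0.01, seed = 6)
  expect_equal(tab$blocks, c("BE", "AAindex", "KSAAP", "AAC", "HQI", "All"))
  expect_equal(nrow(tab), 6L)

  single <- ablation(x, y, block_sets = list(All = attr(x, "block_map")$block),
                     n_folds = 4, cost = 1, kw = 0.01, seed = 6)
  plain <- cross_validate(x, y, n_folds = 4, cost = 1, kw = 0.01, seed = 6)
  expect_equal(single$acc, plain$metrics$acc)
  expect_equal(single$mcc, plain$metrics$mcc)
})

test_that("independent-set evaluation reports counts, metrics and AUC", {
  frags <- generate_fragments(40, 40, motif_spec(strength = 0.9), seed = 15)
  x <- encode_fragments(frags, blocks = c("BE", "AAC"))
  y <- droplevels(frags$label)
  fit <- sulfen_svm(x, y)
  held <- generate_fragments(20, 20, motif_spec(strength = 0.9), seed = 16)
  hx <- encode_fragments(held, blocks = c("BE", "AAC"))
  ev <- evaluate_model(fit, hx, droplevels(held$label))
  expect_equal(sum(ev$counts), 40)
  expect_gte(ev$auc, 0.9)
  expect_gte(ev$metrics$acc, 80)
})
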