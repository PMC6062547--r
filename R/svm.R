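#' Train the RBF-kernel support-vector classifier
#'
#' Fits a C-classification SVM with a radial-basis-function kernel
#' exp(-gamma * ||u - v||^2) on a feature matrix, via libsvm
#' (\pkg{e1071}). The defaults, penalty C = 0.1 and kernel width
#' kw = 0.005, are the operating point of the sulfenylation predictor; `kw`
#' is interpreted as the RBF coefficient gamma by default, with the
#' bandwidth parameterization sigma (gamma = 1 / (2 sigma^2)) selectable via
#' `kw_is`.
#'
#' Features are passed to the kernel as produced by the encoders (already in
#' roughly \[0, 1\] ranges); set `standardize = TRUE` to let libsvm z-score
#' each column first.
#'
#' @param x Numeric feature matrix (rows = fragments). A `block_map`
#'   attribute, if present, is stored with the model and checked at
#'   prediction time.
#' @param y Labels (`positive` / `negative`), both classes present.
#' @param cost Penalty parameter C > 0 (default 0.1).
#' @param kw Kernel width (default 0.005).
#' @param kw_is Either `"gamma"` (default; `kw` is the RBF exponent
#'   coefficient) or `"sigma"` (`kw` is the bandwidth, gamma = 1/(2 kw^2)).
#' @param standardize Z-score columns inside libsvm (default `FALSE`).
#' @param seed Integer recorded in the model configuration (the libsvm
#'   C-classification fit itself is deterministic given data order).
#' @return An object of class `sulfen_svm`.
#' @examples
#' frags <- generate_fragments(30, 30, motif_spec(strength = 1), seed = 1)
#' x <- encode_fragments(frags, blocks = "AAC")
#' fit <- sulfen_svm(x, frags$label, cost = 1, kw = 0.5)
#' fit
#' @export
sulfen_svm <- function(x, y, cost = 0.1, kw = 0.005,
                       kw_is = c("gamma", "sigma"), standardize = FALSE,
                       seed = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as_label_factor(y)
  kw_is <- match.arg(kw_is)
  if (nrow(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(unique(y)) < 2L) {
    stop("cannot train on a single class (", unique(as.character(y)), ")")
  }
  if (!is.numeric(cost) || cost <= 0) stop("'cost' must be > 0")
  if (!is.numeric(kw) || kw <= 0) stop("'kw' must be > 0")
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  gamma <- if (kw_is == "gamma") kw else 1 / (2 * kw^2)
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = standardize)
  # libsvm orients decision values toward whichever class it met first in
  # the data; recover the orientation from the decision-value column name so
  # scores are always positive-class-high.
  probe <- stats::predict(fit, x[1L, , drop = FALSE], decision.values = TRUE)
  dv_name <- colnames(attr(probe, "decision.values"))[1L]
  sign <- if (startsWith(dv_name, "positive/")) 1 else -1
  structure(list(
    fit = fit,
    orientation = sign,
    config = list(cost = cost, kw = kw, kw_is = kw_is, gamma = gamma,
                  kernel = "rbf", standardize = standardize,
                  seed = as.integer(seed)),
    block_map = attr(x, "block_map"),
    n_features = ncol(x),
    class_counts = table(y),
    package_version = as.character(utils::packageVersion("sulfenpred"))
  ), class = "sulfen_svm")
}

#' Continuous decision scores of a fitted model
#'
#' Returns the signed distance of each row to the separating hyperplane in
#' kernel space, oriented so that larger scores mean more positive-like.
#' These scores, not thresholded labels, feed [roc_curve()].
#'
#' @param model A [sulfen_svm()] fit.
#' @param x Feature matrix with the same columns (and feature-block layout)
#'   the model was trained on.
#' @return A numeric vector of scores, one per row of `x` (length 0 for an
#'   empty matrix).
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "sulfen_svm"))
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) == 0L) return(numeric(0))
  check_feature_compat(model, x)
  pred <- stats::predict(model$fit, x, decision.values = TRUE)
  as.numeric(attr(pred, "decision.values")) * model$orientation
}

#' @noRd
check_feature_compat <- function(model, x) {
  if (ncol(x) != model$n_features) {
    stop("feature dimension mismatch: model was trained on ",
         model$n_features, " features, input has ", ncol(x))
  }
  map <- attr(x, "block_map")
  if (!is.null(map) && !is.null(model$block_map)) {
    same <- identical(map$block, model$block_map$block) &&
      identical(as.integer(map$length), as.integer(model$block_map$length))
    if (!same) {
      stop("feature-block layout mismatch: model was trained on blocks [",
           paste(model$block_map$block, collapse = ", "),
           "], input has [", paste(map$block, collapse = ", "), "]")
    }
  }
  invisible(TRUE)
}

#' Predict sulfenylation labels
#'
#' Labels a row `positive` when its decision score strictly exceeds
#' `threshold` (default 0, the decision boundary); ties go to `negative`.
#'
#' @param object A [sulfen_svm()] fit.
#' @param x Feature matrix.
#' @param threshold Score cut-off (default 0).
#' @param ... Unused.
#' @return Factor of `positive` / `negative`, one per row.
#' @export
predict.sulfen_svm <- function(object, x, threshold = 0, ...) {
  scores <- decision_scores(object, x)
  factor(ifelse(scores > threshold, "positive", "negative"),
         levels = c("positive", "negative"))
}

#' @export
print.sulfen_svm <- function(x, ...) {
  cat("RBF-SVM sulfenylation-site classifier\n")
  cat(sprintf("  C = %g, kw = %g (%s; gamma = %g)\n", x$config$cost,
              x$config$kw, x$config$kw_is, x$config$gamma))
  cat(sprintf("  trained on %d features", x$n_features))
  if (!is.null(x$block_map)) {
    cat(" [", paste(x$block_map$block, collapse = ", "), "]", sep = "")
  }
  cat("\n  class counts:",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), "\n")
  cat("  support vectors:", nrow(x$fit$SV), "\n")
  invisible(x)
}

#' Save a fitted model to disk
#'
#' Serializes the model (fit, configuration, feature-block map, package
#' version) to a single file; [load_model()] restores it and scores
#' bit-identically.
#'
#' @param model A [sulfen_svm()] fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sulfen_svm"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a fitted model from disk
#'
#' @param path Path written by [save_model()].
#' @return The `sulfen_svm` object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable model file: ", path, " (",
         conditionMessage(e), ")")
  })
  if (!inherits(model, "sulfen_svm") ||
      !all(c("fit", "orientation", "config", "n_features") %in% names(model))) {
    stop("file does not contain a sulfenpred model: ", path)
  }
  model
}
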