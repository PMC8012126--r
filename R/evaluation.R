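#' Classification metrics from labels and scores
#'
#' ILFS (class 1) is the positive class. Sensitivity, specificity and
#' accuracy come from the confusion table; F1 is the harmonic mean of
#' precision and recall; AUC is the rank-based (Mann-Whitney) area under
#' the ROC curve computed from the continuous scores, with tied scores
#' contributing half a concordance.
#'
#' @param y_true true labels 0/1 (both classes must be present).
#' @param labels predicted labels 0/1.
#' @param scores continuous scores, larger = more ILFS-like.
#' @return Named list: \code{tp, fp, tn, fn, se, sp, acc, precision, f1,
#'   auc}.
#' @export
compute_metrics <- function(y_true, labels, scores) {
  if (length(y_true) != length(labels) || length(y_true) != length(scores))
    stop("y_true, labels and scores must have the same length")
  if (length(unique(y_true)) < 2)
    stop("y_true must contain both classes (Se or Sp undefined otherwise)")
  tp <- sum(labels == 1 & y_true == 1)
  fp <- sum(labels == 1 & y_true == 0)
  tn <- sum(labels == 0 & y_true == 0)
  fn <- sum(labels == 0 & y_true == 1)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + se > 0) 2 * precision * se / (precision + se) else 0
  np <- sum(y_true == 1)
  nn <- sum(y_true == 0)
  r <- rank(scores)                       # average ranks for ties
  auc <- (sum(r[y_true == 1]) - np * (np + 1) / 2) / (np * nn)
  list(tp = tp, fp = fp, tn = tn, fn = fn, se = se, sp = sp, acc = acc,
       precision = precision, f1 = f1, auc = auc)
}

#' Per-feature two-group rank test
#'
#' Two-sided rank-sum (Mann-Whitney) test of each feature between the ILFS
#' and non-ILFS groups, which are independent sets of trials. Reports the
#' p-value, a 0.05 significance flag and the direction of the median
#' difference. A paired signed-rank variant is available for designs with
#' matched observations.
#'
#' @param X_ilfs,X_non feature matrices for the two groups (same columns,
#'   at least 5 rows each).
#' @param paired use the paired signed-rank test (requires equal group
#'   sizes; default FALSE).
#' @return Data frame with one row per feature: \code{feature},
#'   \code{p_value}, \code{significant}, \code{direction} (direction of
#'   the ILFS median relative to non-ILFS).
#' @export
feature_analysis <- function(X_ilfs, X_non, paired = FALSE) {
  X_ilfs <- as.matrix(X_ilfs)
  X_non <- as.matrix(X_non)
  if (ncol(X_ilfs) != ncol(X_non)) stop("group matrices must share columns")
  if (nrow(X_ilfs) < 5 || nrow(X_non) < 5)
    stop("each group needs at least 5 observations")
  nm <- colnames(X_ilfs)
  if (is.null(nm)) nm <- paste0("feature_", seq_len(ncol(X_ilfs)))
  rows <- lapply(seq_len(ncol(X_ilfs)), function(j) {
    a <- X_ilfs[, j]
    b <- X_non[, j]
    if (length(unique(c(a, b))) == 1) {
      warning(sprintf("feature %s: all values tied, p set to 1", nm[j]))
      p <- 1
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(a, b, paired = paired)$p.value)
    }
    dm <- median(a) - median(b)
    data.frame(feature = nm[j], p_value = p, significant = p < 0.05,
               direction = if (dm > 0) "higher" else if (dm < 0) "lower"
                           else "equal")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate the five classifiers on a labeled dataset
#'
#' Runs each classifier either with plain stratified 10-fold
#' cross-validation on all 25 features (\code{mode = "without"}) or with
#' SFFS feature selection nested inside the cross-validation
#' (\code{mode = "with"}), pools predictions over the outer folds, and
#' reports sensitivity, specificity, F1, AUC and accuracy per classifier.
#'
#' @param dataset an \code{ilfs_dataset} from \code{\link{build_dataset}},
#'   or a list with \code{X} and \code{y}.
#' @param mode \code{"without"} (no feature selection) or \code{"with"}
#'   (nested SFFS selection).
#' @param classifiers classifier names to evaluate.
#' @param k_max largest subset size for SFFS (mode \code{"with"}).
#' @param folds CV fold count (default 10).
#' @param seed integer seed.
#' @param params hyperparameter overrides.
#' @return Object of class \code{"ilfs_eval_report"}: data frame with one
#'   row per classifier (columns \code{Se, Sp, F1, AUC, ACC} and confusion
#'   counts); per-classifier details (selected subsets, pooled
#'   predictions) in the \code{"details"} attribute.
#' @export
run_experiment <- function(dataset, mode = c("without", "with"),
                           classifiers = .classifier_names,
                           k_max = 25, folds = 10, seed = 1L,
                           params = list()) {
  mode <- match.arg(mode)
  X <- as.matrix(dataset$X)
  y <- dataset$y
  k_max <- min(k_max, ncol(X))
  rows <- list()
  details <- list()
  for (clf in classifiers) {
    if (mode == "without") {
      fold_id <- make_folds(y, folds, seed)
      labels <- integer(length(y))
      scores <- numeric(length(y))
      for (f in sort(unique(fold_id))) {
        te <- fold_id == f
        pr <- fit_predict(X[!te, , drop = FALSE], y[!te],
                          X[te, , drop = FALSE], clf, seed = seed + f,
                          params = params)
        labels[te] <- pr$labels
        scores[te] <- pr$scores
      }
      det <- list(labels = labels, scores = scores)
    } else {
      ncv <- nested_cv(X, y, clf, k_max, outer_folds = folds,
                       inner_folds = folds, seed = seed, params = params)
      labels <- ncv$labels
      scores <- ncv$scores
      det <- list(labels = labels, scores = scores,
                  subsets = lapply(ncv$folds, `[[`, "subset"))
    }
    m <- compute_metrics(y, labels, scores)
    rows[[clf]] <- data.frame(classifier = clf, Se = m$se, Sp = m$sp,
                              F1 = m$f1, AUC = m$auc, ACC = m$acc,
                              tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn)
    details[[clf]] <- det
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  attr(out, "mode") <- mode
  class(out) <- c("ilfs_eval_report", "data.frame")
  out
}

#' @export
print.ilfs_eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Classifier evaluation (%s feature selection):\n",
              if (attr(x, "mode") == "with") "with nested SFFS" else "no"))
  df <- as.data.frame(x)[, c("classifier", "Se", "Sp", "F1", "AUC", "ACC")]
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
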