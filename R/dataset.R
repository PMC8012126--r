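#' MAD outlier keep-mask
#'
#' Robust outlier rule: with \eqn{MAD = median_i |x_i - median_j(x_j)|},
#' a point is an outlier iff
#' \eqn{x_i \le median(x) - 5 MAD} or \eqn{x_i \ge median(x) + 5 MAD}
#' (closed bounds: boundary points are removed). When MAD = 0 the rule is
#' degenerate and nothing is removed (with a warning).
#'
#' @param x numeric vector (at least 3 values).
#' @param k multiplier of the MAD band (default 5).
#' @return Logical mask, \code{TRUE} for kept points.
#' @export
mad_filter <- function(x, k = 5) {
  if (length(x) < 3) stop("mad_filter needs at least 3 values")
  med <- median(x)
  mad0 <- median(abs(x - med))
  if (mad0 == 0) {
    warning("MAD is zero: degenerate rule, keeping all points")
    return(rep(TRUE, length(x)))
  }
  x > med - k * mad0 & x < med + k * mad0
}

#' Label trials from self reports
#'
#' A trial enters the ILFS class iff its ILFS intensity is 2 or 3 \emph{and}
#' all four Likert dimensions (arousal, valence, dominance, attraction) are
#' at or above the high threshold; it enters the non-ILFS class iff its
#' intensity is 0 \emph{and} all four dimensions are at or below the low
#' threshold. Everything else -- including every intensity-1 trial -- is
#' excluded. Defaults (high >= 5, low <= 3) sit symmetrically around the
#' neutral midpoint 4 of the 1--7 scale.
#'
#' @param ratings data frame with columns \code{ilfs_intensity},
#'   \code{arousal}, \code{valence}, \code{dominance}, \code{attraction}
#'   (plus provenance columns, carried through).
#' @param high high-Likert threshold (default 5).
#' @param low low-Likert threshold (default 3).
#' @param keep_intensity ILFS intensity levels admitted to the ILFS class
#'   (default \code{c(2, 3)}).
#' @return Factor with levels \code{ILFS}, \code{non-ILFS},
#'   \code{excluded}, one per rating row.
#' @export
screen_and_label <- function(ratings, high = 5, low = 3,
                             keep_intensity = c(2, 3)) {
  dims <- c("arousal", "valence", "dominance", "attraction")
  need <- c("ilfs_intensity", dims)
  if (!all(need %in% names(ratings)))
    stop("ratings must have columns: ", paste(need, collapse = ", "))
  ok_int <- ratings$ilfs_intensity %in% 0:3 &
    !Reduce(`|`, lapply(ratings[dims], function(v)
      is.na(v) | v < 1 | v > 7))
  hi <- Reduce(`&`, lapply(ratings[dims], function(v) v >= high))
  lo <- Reduce(`&`, lapply(ratings[dims], function(v) v <= low))
  lab <- rep("excluded", nrow(ratings))
  lab[ok_int & ratings$ilfs_intensity %in% keep_intensity & hi] <- "ILFS"
  lab[ok_int & ratings$ilfs_intensity == 0 & lo] <- "non-ILFS"
  if (any(!ok_int))
    warning(sprintf("%d malformed rating row(s) excluded", sum(!ok_int)))
  factor(lab, levels = c("ILFS", "non-ILFS", "excluded"))
}

#' Build the labeled feature dataset
#'
#' Joins per-trial feature vectors with per-trial class labels, drops
#' excluded trials and trials with missing feature values, then applies the
#' 5-MAD outlier rule per feature within each class and drops any trial
#' flagged on any feature. Retained feature values are never modified.
#'
#' @param features data frame from \code{\link{extract_features_table}}
#'   (\code{subject_id}, \code{trial_id}, 25 feature columns).
#' @param ratings data frame of self reports with \code{subject_id} and
#'   \code{trial_id}, passed to \code{\link{screen_and_label}}.
#' @param high,low,keep_intensity labeling thresholds, see
#'   \code{\link{screen_and_label}}.
#' @param mad_k MAD band multiplier (default 5).
#' @return An object of class \code{"ilfs_dataset"}: list with \code{X}
#'   (n x 25 matrix), \code{y} (integer, ILFS = 1), \code{provenance}
#'   (subject/trial per row) and \code{removed} (drop counts by reason).
#' @export
build_dataset <- function(features, ratings, high = 5, low = 3,
                          keep_intensity = c(2, 3), mad_k = 5) {
  feat_cols <- hrv_feature_names()
  if (!all(feat_cols %in% names(features)))
    stop("features is missing columns: ",
         paste(setdiff(feat_cols, names(features)), collapse = ", "))
  lab <- screen_and_label(ratings, high, low, keep_intensity)
  key_r <- paste(ratings$subject_id, ratings$trial_id)
  key_f <- paste(features$subject_id, features$trial_id)
  m <- match(key_f, key_r)
  if (anyNA(m)) stop("some feature rows have no matching rating")
  lab <- lab[m]
  keep_lab <- lab != "excluded"
  df <- features[keep_lab, , drop = FALSE]
  y <- as.integer(lab[keep_lab] == "ILFS")
  n_excluded <- sum(!keep_lab)

  X <- as.matrix(df[, feat_cols])
  complete <- stats::complete.cases(X)
  n_missing <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  df <- df[complete, , drop = FALSE]
  y <- y[complete]

  keep <- rep(TRUE, nrow(X))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < 3) next
    for (j in seq_len(ncol(X))) {
      mask <- suppressWarnings(mad_filter(X[idx, j], k = mad_k))
      keep[idx[!mask]] <- FALSE
    }
  }
  n_outlier <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  df <- df[keep, , drop = FALSE]
  if (length(unique(y)) < 2)
    stop(sprintf(paste0("a class was emptied (excluded %d, missing %d, ",
                        "outliers %d): cannot build dataset"),
                 n_excluded, n_missing, n_outlier))
  structure(list(X = X, y = y,
                 provenance = df[, c("subject_id", "trial_id")],
                 removed = c(excluded = n_excluded, missing = n_missing,
                             outlier = n_outlier)),
            class = "ilfs_dataset")
}

#' @export
print.ilfs_dataset <- function(x, ...) {
  cat(sprintf("ILFS dataset: %d trials x %d features (%d ILFS, %d non-ILFS)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  cat(sprintf("removed: %d excluded by screening, %d missing, %d MAD outliers\n",
              x$removed["excluded"], x$removed["missing"],
              x$removed["outlier"]))
  invisible(x)
}
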