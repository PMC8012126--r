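#' Cross-validated selection criterion J
#'
#' The criterion driving feature selection: mean accuracy of a classifier
#' over stratified k-fold cross-validation using only the given feature
#' subset (correct predictions pooled over folds). Deterministic for a
#' fixed seed: folds and classifier fits are seeded.
#'
#' @param X feature matrix (rows = samples).
#' @param y class labels 0/1.
#' @param subset integer column indices of the candidate feature subset.
#' @param classifier classifier name, see \code{\link{fit_predict}}.
#' @param folds number of CV folds (default 10; reduced if a class is
#'   smaller).
#' @param seed integer seed.
#' @param params hyperparameter overrides for \code{\link{fit_predict}}.
#' @return Accuracy fraction in [0, 1].
#' @export
criterion_J <- function(X, y, subset, classifier = "rf", folds = 10,
                        seed = 1L, params = list()) {
  if (length(subset) == 0) stop("subset must be non-empty")
  X <- as.matrix(X)
  fold_id <- make_folds(y, folds, seed)
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    pr <- fit_predict(X[!te, subset, drop = FALSE], y[!te],
                      X[te, subset, drop = FALSE], classifier,
                      seed = seed + f, params = params)
    correct <- correct + sum(pr$labels == y[te])
  }
  correct / length(y)
}

# Cached J evaluation; the cache also tracks the best subset seen per size.
.make_J_cache <- function(X, y, classifier, folds, seed, params) {
  env <- new.env(parent = emptyenv())
  env$n_evals <- 0L
  env$best_J <- rep(-Inf, ncol(X))
  env$best_subset <- vector("list", ncol(X))
  env$eval <- function(subset) {
    key <- paste(sort(subset), collapse = ",")
    hit <- env[[paste0("k", key)]]
    if (!is.null(hit)) return(hit)
    j <- criterion_J(X, y, subset, classifier, folds, seed, params)
    env[[paste0("k", key)]] <- j
    env$n_evals <- env$n_evals + 1L
    k <- length(subset)
    if (j > env$best_J[k]) {
      env$best_J[k] <- j
      env$best_subset[[k]] <- sort(subset)
    }
    j
  }
  env
}

#' Sequential floating forward selection (SFFS)
#'
#' Wrapper feature selection maximizing the cross-validated criterion
#' \code{\link{criterion_J}}. Starting from the empty set, each iteration
#' adds the feature whose inclusion maximizes J (inclusion step); after
#' every inclusion, the algorithm repeatedly removes the least useful
#' feature -- the one whose removal maximizes J of the reduced set --
#' whenever that removal strictly beats the best known subset of the
#' smaller size and is not the feature just added (conditional exclusion,
#' the "floating" step), then resumes inclusion until \code{k_max} features
#' have been reached. J is evaluated at most once per distinct subset
#' (cached). Ties are broken toward the lowest feature index. With
#' \code{floating = FALSE} the algorithm reduces to plain sequential
#' forward selection (SFS).
#'
#' @param X feature matrix.
#' @param y class labels 0/1.
#' @param classifier classifier name.
#' @param k_max largest subset size to explore (default all features).
#' @param folds CV folds for J (default 10).
#' @param seed integer seed.
#' @param params hyperparameter overrides.
#' @param floating enable conditional exclusion (default TRUE).
#' @return Object of class \code{"sffs_result"}: list with
#'   \code{best_subset} (feature indices of the best subset found),
#'   \code{best_k}, \code{best_J}, \code{accuracy_curve} (best J per
#'   subset size 1..k_max), \code{subsets} (best subset per size),
#'   \code{trajectory} (data frame logging every inclusion/exclusion) and
#'   \code{n_evals}.
#' @export
sffs <- function(X, y, classifier = "rf", k_max = ncol(X), folds = 10,
                 seed = 1L, params = list(), floating = TRUE) {
  X <- as.matrix(X)
  n_feat <- ncol(X)
  if (k_max < 1 || k_max > n_feat)
    stop("k_max must be between 1 and the number of features")
  cache <- .make_J_cache(X, y, classifier, folds, seed, params)
  cur <- integer(0)
  traj <- list()
  last_added <- NA_integer_
  repeat {
    # inclusion: add the f+ maximizing J(cur + f)
    cand <- setdiff(seq_len(n_feat), cur)
    js <- vapply(cand, function(f) cache$eval(c(cur, f)), numeric(1))
    f_plus <- cand[which.max(js)]        # which.max takes the lowest index on ties
    cur <- sort(c(cur, f_plus))
    last_added <- f_plus
    traj[[length(traj) + 1L]] <- data.frame(step = "add", feature = f_plus,
                                            k = length(cur),
                                            J = max(js))
    if (length(cur) == k_max) break
    # conditional exclusion: drop the least useful feature while doing so
    # strictly improves on the best known subset of the smaller size
    while (floating && length(cur) > 2) {
      cand_rm <- setdiff(cur, last_added)
      js_rm <- vapply(cand_rm, function(f) cache$eval(setdiff(cur, f)),
                      numeric(1))
      f_minus <- cand_rm[which.max(js_rm)]
      j_rm <- max(js_rm)
      if (j_rm > cache$best_J[length(cur) - 1L]) {
        cur <- setdiff(cur, f_minus)
        last_added <- NA_integer_
        traj[[length(traj) + 1L]] <- data.frame(step = "remove",
                                                feature = f_minus,
                                                k = length(cur), J = j_rm)
      } else break
    }
  }
  curve <- cache$best_J[seq_len(k_max)]
  best_k <- which.max(curve)
  structure(list(best_subset = cache$best_subset[[best_k]],
                 best_k = best_k, best_J = curve[best_k],
                 accuracy_curve = curve,
                 subsets = cache$best_subset[seq_len(k_max)],
                 trajectory = do.call(rbind, traj),
                 n_evals = cache$n_evals,
                 classifier = classifier),
            class = "sffs_result")
}

#' @export
print.sffs_result <- function(x, ...) {
  cat(sprintf("SFFS (%s): best J = %.4f at k = %d, subset {%s}; %d J evaluations\n",
              x$classifier, x$best_J, x$best_k,
              paste(x$best_subset, collapse = ", "), x$n_evals))
  invisible(x)
}

#' Nested cross-validated feature selection and evaluation
#'
#' Outer stratified 10-fold split for performance estimation; within each
#' outer training set, SFFS with an inner stratified 10-fold criterion
#' selects the best feature subset, the classifier is refit on the outer
#' training set restricted to that subset, and predictions are made on the
#' held-out outer fold. Nothing from an outer test fold influences
#' selection or fitting for that fold.
#'
#' @param X feature matrix.
#' @param y class labels 0/1 (at least 10 per class recommended).
#' @param classifier classifier name.
#' @param k_max largest subset size explored by SFFS.
#' @param outer_folds,inner_folds fold counts (default 10 each).
#' @param seed integer seed.
#' @param params hyperparameter overrides.
#' @param fold_id optional precomputed outer fold assignment (as returned
#'   by \code{\link{make_folds}}); defaults to a fresh stratified split.
#' @return Object of class \code{"nested_cv_result"}: list with
#'   \code{folds} (per outer fold: test indices, selected subset, labels,
#'   scores), pooled \code{y_true}, \code{labels}, \code{scores} (in
#'   original row order) and pooled \code{accuracy}.
#' @export
nested_cv <- function(X, y, classifier = "rf", k_max = ncol(X),
                      outer_folds = 10, inner_folds = 10, seed = 1L,
                      params = list(), fold_id = NULL) {
  X <- as.matrix(X)
  if (min(table(y)) < 2)
    stop("each class needs at least 2 members; 10 or more are recommended")
  if (is.null(fold_id)) fold_id <- make_folds(y, outer_folds, seed)
  labels <- integer(length(y))
  scores <- numeric(length(y))
  folds <- list()
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    sel <- sffs(X[!te, , drop = FALSE], y[!te], classifier, k_max,
                folds = inner_folds, seed = seed + 1000L * f,
                params = params)
    pr <- fit_predict(X[!te, sel$best_subset, drop = FALSE], y[!te],
                      X[te, sel$best_subset, drop = FALSE], classifier,
                      seed = seed + f, params = params)
    labels[te] <- pr$labels
    scores[te] <- pr$scores
    folds[[length(folds) + 1L]] <- list(test_idx = which(te),
                                        subset = sel$best_subset,
                                        labels = pr$labels,
                                        scores = pr$scores)
  }
  structure(list(folds = folds, y_true = y, labels = labels,
                 scores = scores, accuracy = mean(labels == y),
                 classifier = classifier),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("Nested CV (%s): %d outer folds, pooled accuracy %.4f\n",
              x$classifier, length(x$folds), x$accuracy))
  invisible(x)
}
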