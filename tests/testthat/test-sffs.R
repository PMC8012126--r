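# small synthetic classification problems for selection tests
make_problem <- function(n = 60, n_feat = 8, informative = c(2, 5, 7),
                         shift = 1.2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_feat), n)
  y <- rep(0:1, length.out = n)
  X[y == 1, informative] <- X[y == 1, informative] + shift
  list(X = X, y = y)
}

test_that("a perfectly separated feature reaches criterion 1.0", {
  set.seed(1)
  X <- cbind(c(rnorm(30, -1, 0.01), rnorm(30, 1, 0.01)), rnorm(60))
  y <- rep(0:1, each = 30)
  expect_equal(criterion_J(X, y, 1, "knn", seed = 2), 1.0)
  expect_equal(criterion_J(X, y, 1, "svm", seed = 2), 1.0)
})

test_that("the criterion is calibrated at chance under permuted labels", {
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(200 * 4), 200)
    y <- sample(rep(0:1, each = 100))
    criterion_J(X, y, 1:4, "knn", seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("a duplicated feature leaves the criterion nearly unchanged", {
  pb <- make_problem(seed = 4)
  X2 <- cbind(pb$X, pb$X[, 2])
  j1 <- criterion_J(pb$X, pb$y, c(2, 5), "dt", seed = 3)
  j2 <- criterion_J(X2, pb$y, c(2, 5, 9), "dt", seed = 3)
  expect_lt(abs(j1 - j2), 0.02)
})

test_that("criterion_J is deterministic and validates its inputs", {
  pb <- make_problem(seed = 5)
  expect_identical(criterion_J(pb$X, pb$y, 1:3, "rf", seed = 9),
                   criterion_J(pb$X, pb$y, 1:3, "rf", seed = 9))
  expect_error(criterion_J(pb$X, pb$y, integer(0), "rf"), "non-empty")
})

test_that("k_max = 1 reduces SFFS to the single best feature", {
  pb <- make_problem(seed = 6)
  r <- sffs(pb$X, pb$y, "knn", k_max = 1, seed = 2)
  singles <- vapply(1:8, function(f)
    criterion_J(pb$X, pb$y, f, "knn", seed = 2), numeric(1))
  expect_equal(r$best_J, max(singles))
  expect_equal(r$best_subset, which.max(singles))
  expect_error(sffs(pb$X, pb$y, "knn", k_max = 9), "between")
})

test_that("SFFS recovers a planted informative subset", {
  hits <- vapply(1:20, function(s) {
    pb <- make_problem(n = 300, shift = 1.2, seed = 400 + s)
    r <- sffs(pb$X, pb$y, "knn", k_max = 8, seed = s)
    all(c(2, 5, 7) %in% r$best_subset)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the floating step only fires when it strictly improves", {
  pb <- make_problem(seed = 7)
  r <- sffs(pb$X, pb$y, "knn", k_max = 6, seed = 3)
  # replay the trajectory: each removal must beat the best J previously
  # seen at the size it lands on
  best_seen <- rep(-Inf, 8)
  for (i in seq_len(nrow(r$trajectory))) {
    row <- r$trajectory[i, ]
    if (row$step == "remove") expect_gt(row$J, best_seen[row$k])
    if (row$J > best_seen[row$k]) best_seen[row$k] <- row$J
  }
  # accuracy curve dominates every trajectory point of the same size
  for (i in seq_len(nrow(r$trajectory)))
    expect_gte(r$accuracy_curve[r$trajectory$k[i]], r$trajectory$J[i])
})

test_that("subset evaluations are cached, never repeated", {
  pb <- make_problem(seed = 8)
  r <- sffs(pb$X, pb$y, "knn", k_max = 8, seed = 4)
  traj_subsets <- nrow(r$trajectory)
  # evals count distinct subsets; an uncached run would evaluate one per
  # candidate per step, far more than the trajectory length
  expect_lte(r$n_evals, sum(8:1) + 8 * traj_subsets)
  r2 <- sffs(pb$X, pb$y, "knn", k_max = 8, seed = 4)
  expect_identical(r$accuracy_curve, r2$accuracy_curve)
})

test_that("outer folds partition the samples exactly once", {
  pb <- make_problem(n = 80, seed = 9)
  r <- nested_cv(pb$X, pb$y, "knn", k_max = 3, seed = 5)
  idx <- sort(unlist(lapply(r$folds, `[[`, "test_idx")))
  expect_identical(idx, seq_along(pb$y))
})

test_that("nested CV separates a strong effect", {
  pb <- make_problem(n = 120, shift = 3, seed = 10)
  r <- nested_cv(pb$X, pb$y, "knn", k_max = 4, seed = 6)
  expect_gte(r$accuracy, 0.9)
})

test_that("corrupting held-out labels cannot change subset selection", {
  pb <- make_problem(n = 80, seed = 11)
  fold_id <- make_folds(pb$y, 10, seed = 7)
  r1 <- nested_cv(pb$X, pb$y, "knn", k_max = 3, seed = 7,
                  fold_id = fold_id)
  y2 <- pb$y
  te1 <- which(fold_id == 1)
  y2[te1] <- 1 - y2[te1]   # corrupt fold 1's held-out labels only
  r2 <- nested_cv(pb$X, y2, "knn", k_max = 3, seed = 7, fold_id = fold_id)
  # fold 1 trains on untouched folds 2..10: same subset, same predictions
  expect_identical(r1$folds[[1]]$subset, r2$folds[[1]]$subset)
  expect_identical(r1$folds[[1]]$labels, r2$folds[[1]]$labels)
  # but the reported accuracy changes with the corrupted evaluation labels
  expect_false(isTRUE(all.equal(r1$accuracy, r2$accuracy)))
})
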