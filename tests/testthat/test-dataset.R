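test_that("MAD filter reproduces the worked outlier example", {
  mask <- mad_filter(c(1, 2, 3, 4, 100))
  expect_identical(mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("MAD filter handles degenerate and boundary cases", {
  expect_warning(mask <- mad_filter(rep(5, 6)), "zero")
  expect_true(all(mask))
  x <- c(1, 2, 3, 4, 5)        # median 3, MAD 1, bounds [-2, 8] untouched
  expect_true(all(mad_filter(x)))
  # closed bounds: c(1,2,3,4,5,11) has median 3.5, MAD 1.5, upper bound
  # 3.5 + 5*1.5 = 11, so the boundary point 11 itself is removed
  expect_identical(mad_filter(c(1, 2, 3, 4, 5, 11)),
                   c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(mad_filter(c(1, 2)), "3 values")
})

test_that("MAD mask is invariant to affine rescaling", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(30)
    x[sample(30, 2)] <- x[sample(30, 2)] + 10
    a <- runif(1, 0.1, 5)
    b <- runif(1, -10, 10)
    expect_identical(mad_filter(a * x + b), mad_filter(x))
  }
})

ratings_row <- function(int, dims, sid = "S01", tid = 1) {
  data.frame(subject_id = sid, trial_id = tid, ilfs_intensity = int,
             arousal = dims[1], valence = dims[2], dominance = dims[3],
             attraction = dims[4])
}

test_that("screening implements the two-scale labeling rule", {
  r <- rbind(ratings_row(3, c(6, 6, 6, 6), tid = 1),
             ratings_row(1, c(7, 7, 7, 7), tid = 2),
             ratings_row(0, c(2, 2, 2, 2), tid = 3),
             ratings_row(2, c(6, 4, 6, 6), tid = 4),   # one dim below high
             ratings_row(0, c(2, 5, 2, 2), tid = 5),   # one dim above low
             ratings_row(3, c(5, 5, 5, 5), tid = 6))
  lab <- screen_and_label(r)
  expect_equal(as.character(lab),
               c("ILFS", "excluded", "non-ILFS", "excluded", "excluded",
                 "ILFS"))
  # labeling is a partition: exactly one level per trial
  expect_false(anyNA(lab))
})

test_that("screening thresholds and intensity policy are configurable", {
  r <- rbind(ratings_row(3, c(5, 5, 5, 5), tid = 1),
             ratings_row(2, c(6, 6, 6, 6), tid = 2))
  lab <- screen_and_label(r, high = 6, keep_intensity = 3)
  expect_equal(as.character(lab), c("excluded", "excluded"))
  lab2 <- screen_and_label(r, high = 5)
  expect_equal(as.character(lab2), c("ILFS", "ILFS"))
})

test_that("malformed ratings are excluded with a warning", {
  r <- rbind(ratings_row(3, c(6, 6, 6, 6), tid = 1),
             ratings_row(3, c(9, 6, 6, 6), tid = 2))
  expect_warning(lab <- screen_and_label(r), "malformed")
  expect_equal(as.character(lab), c("ILFS", "excluded"))
})

# a small feature table + matching ratings for dataset assembly tests
make_feature_fixture <- function(n_per_class = 12, seed = 1) {
  set.seed(seed)
  rr_list <- lapply(seq_len(2 * n_per_class), function(i)
    make_rrs(random_rr(14, seed * 1000 + i), trial_id = i))
  feats <- extract_features_table(rr_list)
  cl <- rep(c(1, 0), each = n_per_class)
  ratings <- do.call(rbind, lapply(seq_len(2 * n_per_class), function(i) {
    if (cl[i] == 1) ratings_row(3, c(6, 6, 6, 6), tid = i)
    else ratings_row(0, c(2, 2, 2, 2), tid = i)
  }))
  list(feats = feats, ratings = ratings, cl = cl)
}

test_that("dataset assembly preserves rows when no outliers are present", {
  fx <- make_feature_fixture()
  ds <- suppressWarnings(build_dataset(fx$feats, fx$ratings))
  expect_s3_class(ds, "ilfs_dataset")
  expect_equal(ncol(ds$X), 25)
  expect_identical(colnames(ds$X), hrv_feature_names())
  expect_equal(unname(ds$removed["excluded"]), 0)
  expect_equal(unname(ds$removed["missing"]), 0)
  # filtering is selection only: retained values are unchanged
  key <- paste(ds$provenance$subject_id, ds$provenance$trial_id)
  src <- paste(fx$feats$subject_id, fx$feats$trial_id)
  expect_equal(unname(ds$X[, "Mean_RR"]),
               fx$feats$Mean_RR[match(key, src)])
})

test_that("an injected 20-MAD outlier is the only trial dropped", {
  fx <- make_feature_fixture(seed = 2)
  ds0 <- suppressWarnings(build_dataset(fx$feats, fx$ratings))
  feats <- fx$feats
  idx1 <- which(fx$cl == 1)
  v <- feats$Mean_RR[idx1]
  mad_v <- median(abs(v - median(v)))
  victim <- idx1[3]
  feats$Mean_RR[victim] <- median(v) + 20 * mad_v
  ds <- suppressWarnings(build_dataset(feats, fx$ratings))
  expect_equal(nrow(ds$X), nrow(ds0$X) - 1)
  expect_false(victim %in% ds$provenance$trial_id)
})

test_that("emptying a class is a fatal, informative error", {
  fx <- make_feature_fixture(n_per_class = 6, seed = 3)
  # push every ILFS trial outside the non-ILFS low band so screening
  # excludes the whole ILFS class
  ratings <- fx$ratings
  ratings$arousal[fx$cl == 1] <- 4
  expect_error(suppressWarnings(build_dataset(fx$feats, ratings)),
               "class")
})
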