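test_that("time-domain features on a constant series are degenerate", {
  f <- hrv_time_domain(rep(800, 5))
  expect_equal(unname(f[c("Mean_RR", "SDRR", "RMSSD", "NN50", "QD")]),
               c(800, 0, 0, 0, 0))
  expect_equal(unname(f["Mean_HR"]), 75)
  expect_error(hrv_time_domain(c(800, 810, 790)),
               class = "ilfs_trial_invalid")
})

test_that("time-domain features match a hand-computed example", {
  f <- hrv_time_domain(c(800, 860, 790, 855))
  # successive differences: 60, -70, 65
  expect_equal(unname(f["NN50"]), 3)
  expect_equal(unname(f["PNN50"]), 100)
  expect_equal(unname(f["NN20"]), 3)
  expect_equal(unname(f["MSD"]), 65)
})

test_that("NN20 dominates NN50 on random series", {
  for (s in 1:20) {
    rr <- random_rr(30, s)
    f <- hrv_time_domain(rr)
    expect_gte(f[["NN20"]], f[["NN50"]])
  }
})

test_that("Poincare features handle the degenerate constant series", {
  expect_warning(f <- hrv_poincare(rep(800, 10)), "constant")
  expect_equal(unname(f["SD1"]), 0)
  expect_true(all(is.na(f[c("CSI", "CVI", "Modified_CSI", "SD1_SD2")])))
})

test_that("Poincare geometry identities hold", {
  for (s in 1:20) {
    rr <- random_rr(40, s + 100)
    f <- c(hrv_time_domain(rr), hrv_poincare(rr))
    expect_equal(f[["SD1"]], f[["SDSD"]] / sqrt(2), tolerance = 1e-9)
    expect_equal(f[["SD1"]]^2 + f[["SD2"]]^2, 2 * f[["SDRR"]]^2,
                 tolerance = 1e-9)
    expect_equal(f[["CSI"]], f[["SD2"]] / f[["SD1"]], tolerance = 1e-12)
  }
})

test_that("features scale correctly under rr -> k*rr", {
  rr <- random_rr(40, 5)
  k <- 1.7
  f1 <- c(hrv_time_domain(rr), hrv_poincare(rr))
  f2 <- c(hrv_time_domain(k * rr), hrv_poincare(k * rr))
  scale_like <- c("Mean_RR", "SDRR", "RMSSD", "MSD", "SDSD", "QD",
                  "SD1", "SD2")
  expect_equal(unname(f2[scale_like]), unname(k * f1[scale_like]),
               tolerance = 1e-9)
  invariant <- c("CVRR", "SD1_SD2", "CSI")
  expect_equal(unname(f2[invariant]), unname(f1[invariant]),
               tolerance = 1e-9)
  expect_equal(f2[["Mean_HR"]], f1[["Mean_HR"]] / k, tolerance = 1e-9)
})

test_that("LZ76 phrase counting matches hand parsing and brute force", {
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  # exhaustive-history parse 0|001|10|100|1000|101 = 6 phrases
  expect_equal(lz76_phrases(s), 6)
  expect_equal(oracle_lz76(s), 6)
  expect_equal(lz76_phrases(rep(0L, 16)), 2)
  for (s_i in 1:25) {
    set.seed(s_i)
    b <- sample(0:1, sample(10:60, 1), replace = TRUE)
    expect_equal(lz76_phrases(b), oracle_lz76(b))
  }
})

test_that("normalized LZC behaves as expected", {
  rr <- rep(800, 16)
  expect_equal(unname(lz_complexity(rr)), 2 * log2(16) / 16)
  # invariance to strictly monotone transforms
  rr2 <- random_rr(64, 9)
  expect_equal(lz_complexity(rr2), lz_complexity(exp(rr2 / 500)),
               ignore_attr = TRUE)
  # iid random sequences approach the asymptotic normalization
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    unname(lz_complexity(runif(512)))
  }, numeric(1))
  expect_true(all(vals >= 0.8 & vals <= 1.2))
  expect_error(lz_complexity(rep(800, 5)), class = "ilfs_trial_invalid")
})

test_that("band powers integrate consistently on the shared grid", {
  for (s in 1:5) {
    rr <- generate_rr_series(80, 800, sdrr = 30, lf_amp = 20, hf_amp = 15,
                             seed = s)
    f <- hrv_frequency_domain(make_rrs(rr))
    expect_equal(f[["nLFP"]] + f[["nHFP"]], 1, tolerance = 1e-12)
    expect_lt(abs(f[["TP"]] - (f[["LF"]] + f[["HF"]])) / f[["TP"]], 1e-9)
  }
})

test_that("a pure HF tone concentrates spectral power in the HF band", {
  rr <- generate_rr_series(160, 800, sdrr = 0, hf_amp = 30)
  f <- hrv_frequency_domain(make_rrs(rr))
  expect_gte(f[["nHFP"]], 0.9)
  rr_lf <- generate_rr_series(160, 800, sdrr = 0, lf_amp = 30)
  f_lf <- hrv_frequency_domain(make_rrs(rr_lf))
  expect_gte(f_lf[["nLFP"]], 0.9)
})

test_that("constant tachograms yield zero power and missing ratios", {
  f <- hrv_frequency_domain(make_rrs(rep(800, 14)))
  expect_equal(f[["TP"]], 0)
  expect_true(is.na(f[["LF_HF"]]))
  expect_true(is.na(f[["nLFP"]]))
})

test_that("the full feature vector has the canonical 25-name layout", {
  rr <- random_rr(14, 3)
  fv <- extract_features(make_rrs(rr))
  expect_length(fv, 25)
  expect_identical(names(fv), hrv_feature_names())
  # constant trial: dispersion zero, ratio features missing
  expect_warning(fc <- extract_features(make_rrs(rep(800, 14))))
  expect_equal(unname(fc["SDRR"]), 0)
  expect_true(is.na(fc[["CSI"]]))
})

test_that("feature tables drop invalid trials with a warning", {
  good <- make_rrs(random_rr(14, 4), trial_id = 1)
  bad <- make_rrs(c(800, 810, 790), trial_id = 2)  # too short
  expect_warning(tab <- extract_features_table(list(good, bad)), "dropped")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$trial_id, 1)
  expect_identical(names(tab)[-(1:2)], hrv_feature_names())
})
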