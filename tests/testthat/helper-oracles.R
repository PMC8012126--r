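# Independent brute-force oracles used across the suite.  These reimplement
# the quantities from their definitions with explicit sums, so they share no
# code path with the package functions they check.

oracle_quartile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

oracle_time_domain <- function(rr) {
  n <- length(rr)
  m <- sum(rr) / n
  v <- sum((rr - m)^2) / (n - 1)
  d <- rr[-1] - rr[-n]
  md <- sum(d) / (n - 1)
  c(Mean_RR = m,
    CVRR = sqrt(v) / m,
    SDRR = sqrt(v),
    RMSSD = sqrt(sum(d^2) / (n - 1)),
    MSD = sum(abs(d)) / (n - 1),
    SDSD = sqrt(sum((d - md)^2) / (n - 2)),
    NN50 = sum(abs(d) > 50),
    PNN50 = 100 * sum(abs(d) > 50) / (n - 1),
    NN20 = sum(abs(d) > 20),
    PNN20 = 100 * sum(abs(d) > 20) / (n - 1),
    Mean_HR = sum(60000 / rr) / n,
    QD = (oracle_quartile(rr, 0.75) - oracle_quartile(rr, 0.25)) / 2)
}

oracle_poincare <- function(rr) {
  n <- length(rr)
  d <- rr[-1] - rr[-n]
  md <- sum(d) / (n - 1)
  var_d <- sum((d - md)^2) / (n - 2)
  m <- sum(rr) / n
  var_rr <- sum((rr - m)^2) / (n - 1)
  sd1 <- sqrt(var_d / 2)
  sd2 <- sqrt(max(2 * var_rr - sd1^2, 0))
  T_ax <- 4 * sd1
  L_ax <- 4 * sd2
  c(SD1 = sd1, SD2 = sd2, SD1_SD2 = sd1 / sd2, CSI = L_ax / T_ax,
    CVI = log10(L_ax * T_ax), Modified_CSI = L_ax^2 / T_ax)
}

# Definitional LZ76 parser: each phrase is the longest prefix of the
# remaining text reproducible from the text before the phrase end (the copy
# may start anywhere strictly before the phrase and extend into it), plus
# one new symbol; the final phrase may end without a new symbol.
oracle_lz76 <- function(s) {
  n <- length(s)
  q <- 1L
  cn <- 0L
  while (q <= n) {
    L <- 0L
    while (q + L <= n) {
      found <- FALSE
      len <- L + 1L
      for (j in seq_len(q - 1L)) {
        if (all(s[j:(j + len - 1L)] == s[q:(q + len - 1L)]) &&
            j + len - 1L <= n) { found <- TRUE; break }
      }
      if (found) L <- L + 1L else break
    }
    cn <- cn + 1L
    q <- q + min(L + 1L, n - q + 1L)
  }
  cn
}

# Rank-based AUC by exhaustive pair counting (half credit for ties).
oracle_auc <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact two-sided rank-sum p-value by enumerating all group assignments
# (distinct values assumed).
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# rr_series constructor for feature tests: beat times from the rr series
# itself.
make_rrs <- function(rr, trial_id = 1, subject_id = "S01") {
  ecgilfs:::new_rr_series(cumsum(c(0, rr)) / 1000, rr, trial_id, subject_id)
}

# Match detected peak times against ground truth within a tolerance (s);
# returns confusion counts for detection scoring.
match_beats <- function(truth, detected, tol = 0.02) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (b in truth) {
    j <- which(!used & abs(detected - b) <= tol)
    if (length(j) > 0) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  c(tp = tp, fn = length(truth) - tp, fp = sum(!used))
}

random_rr <- function(n, seed) {
  set.seed(seed)
  700 + cumsum(rnorm(n, 0, 15)) + rnorm(n, 0, 40)
}
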