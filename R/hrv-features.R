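#' Names of the 25 HRV features, in canonical order
#'
#' Feature indices 1--25: 12 time-domain, 7 nonlinear (Poincare indices and
#' Lempel-Ziv complexity), 6 frequency-domain descriptors of the
#' RR-interval series.
#'
#' @return Character vector of length 25.
#' @export
hrv_feature_names <- function() {
  c("Mean_RR", "CVRR", "SDRR", "RMSSD", "MSD", "SDSD", "NN50", "PNN50",
    "NN20", "PNN20", "Mean_HR", "QD",
    "SD1", "SD2", "SD1_SD2", "CSI", "CVI", "Modified_CSI", "LZC",
    "TP", "LF", "HF", "LF_HF", "nLFP", "nHFP")
}

.trial_invalid <- function(msg) {
  stop(errorCondition(msg,
                      class = c("ilfs_trial_invalid", "error", "condition")))
}

#' Time-domain HRV features (features 1--12)
#'
#' \code{Mean_RR} mean RR (ms); \code{CVRR} coefficient of variation;
#' \code{SDRR} sample SD; \code{RMSSD} root mean square of successive
#' differences; \code{MSD} mean absolute successive difference;
#' \code{SDSD} sample SD of successive differences; \code{NN50}/\code{NN20}
#' counts of absolute successive differences exceeding 50/20 ms with their
#' percentages \code{PNN50}/\code{PNN20}; \code{Mean_HR} mean instantaneous
#' heart rate (mean of 60000/RR, bpm); \code{QD} quartile deviation
#' (Q3 - Q1)/2 of the RR intervals.
#'
#' @param rr RR intervals in ms (at least 4).
#' @return Named numeric vector of 12 features.
#' @export
hrv_time_domain <- function(rr) {
  if (length(rr) < 4) .trial_invalid("time-domain features need >= 4 intervals")
  d <- diff(rr)
  q <- quantile(rr, c(0.25, 0.75), names = FALSE)
  c(Mean_RR = mean(rr),
    CVRR = sd(rr) / mean(rr),
    SDRR = sd(rr),
    RMSSD = sqrt(mean(d^2)),
    MSD = mean(abs(d)),
    SDSD = sd(d),
    NN50 = sum(abs(d) > 50),
    PNN50 = 100 * sum(abs(d) > 50) / length(d),
    NN20 = sum(abs(d) > 20),
    PNN20 = 100 * sum(abs(d) > 20) / length(d),
    Mean_HR = mean(60000 / rr),
    QD = (q[2] - q[1]) / 2)
}

#' Poincare-plot HRV features (features 13--18)
#'
#' From the lagged scatter of (RR_i, RR_{i+1}): \code{SD1} is the
#' dispersion along the transverse (-45 degree) axis,
#' \eqn{SD1 = \sqrt{var(\Delta RR)/2}}, and \code{SD2} along the
#' longitudinal axis, \eqn{SD2 = \sqrt{\max(2\,SDRR^2 - SD1^2, 0)}}
#' (sample-variance convention throughout, so \eqn{SD1 = SDSD/\sqrt 2} and
#' \eqn{SD1^2 + SD2^2 = 2\,SDRR^2} hold exactly). With the ellipse axes
#' T = 4 SD1 and L = 4 SD2: \code{CSI} = L/T (cardiac sympathetic index),
#' \code{CVI} = log10(L T) (cardiac vagal index), and
#' \code{Modified_CSI} = L^2/T. For a constant series SD1 = 0 and the
#' ratio indices are returned as \code{NA} with a warning.
#'
#' @param rr RR intervals in ms (at least 4).
#' @return Named numeric vector of 6 features.
#' @export
hrv_poincare <- function(rr) {
  if (length(rr) < 4) .trial_invalid("Poincare features need >= 4 intervals")
  d <- diff(rr)
  sd1 <- sqrt(var(d) / 2)
  sd2 <- sqrt(max(2 * var(rr) - sd1^2, 0))
  if (sd1 == 0) {
    warning("constant RR series: Poincare ratio indices undefined")
    return(c(SD1 = 0, SD2 = sd2, SD1_SD2 = NA_real_, CSI = NA_real_,
             CVI = NA_real_, Modified_CSI = NA_real_))
  }
  T_ax <- 4 * sd1
  L_ax <- 4 * sd2
  c(SD1 = sd1, SD2 = sd2, SD1_SD2 = sd1 / sd2, CSI = L_ax / T_ax,
    CVI = log10(L_ax * T_ax), Modified_CSI = L_ax^2 / T_ax)
}

#' Lempel-Ziv (LZ76) phrase count of a symbol sequence
#'
#' Exhaustive-history parsing: scanning left to right, each new phrase is
#' the shortest continuation that cannot be copied from the already seen
#' text (the copy source may overlap into the phrase being built). Returns
#' the number of phrases c(n).
#'
#' @param s vector of symbols (compared with \code{==}).
#' @return Integer phrase count.
#' @export
lz76_phrases <- function(s) {
  n <- length(s)
  if (n == 0) return(0L)
  cn <- 1L
  l <- 1L; i <- 0L; k <- 1L; kmax <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { cn <- cn + 1L; break }
    } else {
      if (k > kmax) kmax <- k
      i <- i + 1L
      if (i == l) {
        cn <- cn + 1L
        l <- l + kmax
        if (l + 1L > n) break
        i <- 0L; k <- 1L; kmax <- 1L
      } else k <- 1L
    }
  }
  cn
}

#' Normalized Lempel-Ziv complexity of an RR series (feature 19)
#'
#' The RR series is binarized at its median (values >= median map to 1)
#' and parsed with the LZ76 exhaustive history; the phrase count c(n) is
#' normalized as \eqn{LZC = c(n) \log_2(n) / n}. Depending only on ranks
#' relative to the median, the result is invariant to strictly monotone
#' transforms of the series.
#'
#' @param rr RR intervals in ms (at least 8).
#' @return Named numeric scalar \code{LZC}.
#' @export
lz_complexity <- function(rr) {
  if (length(rr) < 8) .trial_invalid("LZ complexity needs >= 8 intervals")
  b <- as.integer(rr >= median(rr))
  n <- length(b)
  c(LZC = lz76_phrases(b) * log2(n) / n)
}

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classic phase-shifted (tau) form, returned as a one-sided spectral
#' density scaled so that a sinusoid of amplitude A integrates to
#' approximately its variance A^2/2 over its spectral peak
#' (\code{psd = 2 T P / n} with T the time span and P the raw
#' Lomb-Scargle power).
#'
#' @param t sample times, s.
#' @param x sample values (mean is removed).
#' @param freq frequencies to evaluate, Hz.
#' @return Numeric vector of spectral density values (x-units^2 per Hz).
#' @export
lomb_scargle <- function(t, x, freq) {
  xc <- x - mean(x)
  Tspan <- max(t) - min(t)
  n <- length(x)
  p <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2))
  }, numeric(1))
  2 * Tspan * p / n
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Frequency-domain HRV features (features 20--25)
#'
#' Lomb-Scargle periodogram of the beat-time/RR tachogram (no resampling;
#' the interval RR_i is attached to the time of its closing beat). Band
#' powers by trapezoidal integration of the density: \code{TP} over
#' 0.04--0.4 Hz, \code{LF} over 0.04--0.15 Hz, \code{HF} over 0.15--0.4 Hz;
#' \code{LF_HF} = LF/HF, \code{nLFP} = LF/(LF+HF), \code{nHFP} =
#' HF/(LF+HF). The band edges are grid points, so TP = LF + HF exactly.
#'
#' @param rrs an \code{rr_series} (at least 4 beats spanning at least 5 s).
#' @param oversample frequency-grid oversampling factor relative to the
#'   1/T Rayleigh resolution (default 4).
#' @return Named numeric vector of 6 features (powers in ms^2).
#' @export
hrv_frequency_domain <- function(rrs, oversample = 4) {
  stopifnot(inherits(rrs, "rr_series"))
  tt <- rrs$peak_times[-1][seq_along(rrs$rr)]
  if (length(rrs$rr) < 4 || (max(tt) - min(tt)) < 5)
    .trial_invalid("frequency features need >= 4 beats spanning >= 5 s")
  Tspan <- max(tt) - min(tt)
  df <- 1 / (oversample * Tspan)
  f_lf <- seq(0.04, 0.15, length.out = max(2L, ceiling(0.11 / df) + 1L))
  f_hf <- seq(0.15, 0.40, length.out = max(2L, ceiling(0.25 / df) + 1L))
  p_lf <- lomb_scargle(tt, rrs$rr, f_lf)
  p_hf <- lomb_scargle(tt, rrs$rr, f_hf)
  lf <- .trapz(f_lf, p_lf)
  hf <- .trapz(f_hf, p_hf)
  tp <- lf + hf
  lf_hf <- if (hf > 0) lf / hf else NA_real_
  if (tp > 0) {
    nlfp <- lf / tp; nhfp <- hf / tp
  } else {
    nlfp <- NA_real_; nhfp <- NA_real_
  }
  c(TP = tp, LF = lf, HF = hf, LF_HF = lf_hf, nLFP = nlfp, nHFP = nhfp)
}

#' Extract the full 25-feature HRV vector for one trial
#'
#' Concatenates the time-domain (1--12), nonlinear (13--19) and
#' frequency-domain (20--25) groups in canonical order. \code{NA}
#' sentinels from degenerate inputs are propagated; a trial failing any
#' group's preconditions raises an \code{"ilfs_trial_invalid"} error.
#'
#' @param rrs an \code{rr_series}.
#' @return Named numeric vector of length 25.
#' @export
extract_features <- function(rrs) {
  stopifnot(inherits(rrs, "rr_series"))
  c(hrv_time_domain(rrs$rr), hrv_poincare(rrs$rr), lz_complexity(rrs$rr),
    hrv_frequency_domain(rrs))
}

#' Feature table for a list of RR series
#'
#' Applies \code{\link{extract_features}} per trial; trials raising
#' \code{"ilfs_trial_invalid"} are dropped with a warning.
#'
#' @param rr_list list of \code{rr_series} objects.
#' @return Data frame with \code{subject_id}, \code{trial_id} and the 25
#'   feature columns.
#' @export
extract_features_table <- function(rr_list) {
  rows <- list()
  for (rrs in rr_list) {
    fv <- tryCatch(extract_features(rrs), ilfs_trial_invalid = function(e) {
      warning(sprintf("trial %s/%s dropped: %s", rrs$subject_id,
                      rrs$trial_id, conditionMessage(e)))
      NULL
    })
    if (is.null(fv)) next
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(subject_id = rrs$subject_id, trial_id = rrs$trial_id),
      as.data.frame(as.list(fv)))
  }
  if (length(rows) == 0)
    return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
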