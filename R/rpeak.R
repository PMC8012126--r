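#' Pan-Tompkins R-peak detection
#'
#' Classic QRS detector stage chain: 5--15 Hz band-pass (zero-phase
#' Butterworth), five-point derivative, point-wise squaring, 150-ms
#' moving-window integration, then dual adaptive thresholds on the
#' integrated signal with running signal/noise peak estimates, a 200-ms
#' refractory period, and search-back at 1.66 times the running RR average
#' when a beat appears to have been missed. Accepted integration peaks are
#' refined to the local maximum of the band-passed signal and finally of
#' the input samples.
#'
#' Thresholds are initialized from the first two seconds of the integrated
#' signal (signal estimate max/2, noise estimate mean/2). On flat or empty
#' input an empty result is returned.
#'
#' @param segment a \code{trial_segment}, an \code{ecg_recording}, or a
#'   numeric vector (then \code{fs} is required).
#' @param fs sampling frequency, Hz; taken from \code{segment} when it is a
#'   recording object.
#' @return Integer vector of R-peak sample indices (1-based), strictly
#'   increasing, spaced by at least 200 ms.
#' @export
pan_tompkins <- function(segment, fs = NULL) {
  if (inherits(segment, c("trial_segment", "ecg_recording"))) {
    fs <- segment$fs
    x <- segment$samples
  } else {
    x <- as.numeric(segment)
    if (is.null(fs)) stop("fs is required for a plain numeric signal")
  }
  n <- length(x)
  if (n < 2 * fs) stop("segment must be at least 2 s long")
  if (sd(x) == 0) return(integer(0))

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  # centered five-point derivative (zero-phase variant of the classic filter)
  der <- numeric(n)
  i <- 3:(n - 2)
  der[i] <- (2 * bp[i + 2] + bp[i + 1] - bp[i - 1] - 2 * bp[i - 2]) / 8
  sq <- der^2
  w <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  refr <- round(0.2 * fs)
  # candidate peaks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0) return(integer(0))

  init <- mwi[seq_len(min(2 * fs, n))]
  spki <- max(init) / 2
  npki <- mean(init) / 2
  thr1 <- npki + 0.25 * (spki - npki)

  beats <- integer(0)
  rr_hist <- numeric(0)
  noise_cand <- integer(0)
  for (p in cand) {
    if (length(beats) > 0 && p - beats[length(beats)] < refr) next
    if (mwi[p] >= thr1) {
      beats <- c(beats, p)
      if (length(beats) > 1) {
        rr_hist <- c(rr_hist, p - beats[length(beats) - 1])
        if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
      }
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      noise_cand <- c(noise_cand, p)
      npki <- 0.125 * mwi[p] + 0.875 * npki
      # search-back: a long gap suggests a missed beat below threshold
      if (length(beats) > 0 && length(rr_hist) > 0 &&
          p - beats[length(beats)] > 1.66 * mean(rr_hist)) {
        gap <- noise_cand[noise_cand > beats[length(beats)] + refr &
                            noise_cand < p]
        gap <- c(gap, p)
        gap <- gap[mwi[gap] >= 0.5 * thr1]
        if (length(gap) > 0) {
          pb <- gap[which.max(mwi[gap])]
          beats <- sort(c(beats, pb))
          spki <- 0.25 * mwi[pb] + 0.75 * spki
          rr_hist <- c(rr_hist, diff(utils::tail(beats, 2)))
          if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(beats) == 0) {
    warning("no R peaks found in segment")
    return(integer(0))
  }

  # refine to the band-passed maximum, then to the raw-signal maximum
  half <- as.integer(round(0.10 * fs))
  fine <- as.integer(round(0.025 * fs))
  refined <- vapply(beats, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    q <- lo + which.max(bp[lo:hi]) - 1L
    lo2 <- max(1L, q - fine); hi2 <- min(n, q + fine)
    lo2 + which.max(x[lo2:hi2]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory spacing after refinement, keeping larger peaks
  keep <- rep(TRUE, length(refined))
  last <- 1L
  for (i in seq_along(refined)[-1]) {
    if (refined[i] - refined[last] < refr) {
      if (x[refined[i]] > x[refined[last]]) {
        keep[last] <- FALSE; last <- i
      } else keep[i] <- FALSE
    } else last <- i
  }
  refined[keep]
}

new_rr_series <- function(peak_times, rr, trial_id = NA, subject_id = NA) {
  structure(list(peak_times = peak_times, rr = rr, trial_id = trial_id,
                 subject_id = subject_id), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series (trial %s, subject %s): %d beats, mean RR %.1f ms\n",
              x$trial_id, x$subject_id, length(x$peak_times), mean(x$rr)))
  invisible(x)
}

#' RR-interval series from detected peaks
#'
#' Converts peak sample indices to beat times and successive RR intervals
#' in ms, screening out intervals outside the physiological range
#' (200, 3000) ms. A trial with fewer than two peaks, or with no valid
#' interval left after screening, raises an error of class
#' \code{"ilfs_trial_invalid"} so that callers can skip the trial.
#'
#' @param peaks integer peak indices (1-based).
#' @param fs sampling frequency, Hz.
#' @param trial_id,subject_id provenance labels.
#' @return An object of class \code{"rr_series"} with \code{peak_times}
#'   (s) and \code{rr} (ms).
#' @export
to_rr <- function(peaks, fs, trial_id = NA, subject_id = NA) {
  if (length(peaks) < 2)
    stop(errorCondition("fewer than 2 peaks: trial invalid",
                        class = c("ilfs_trial_invalid", "error", "condition")))
  peak_times <- (peaks - 1) / fs
  rr <- diff(peak_times) * 1000
  bad <- rr <= 200 | rr >= 3000
  if (any(bad)) {
    message(sprintf("screened %d RR interval(s) outside (200, 3000) ms",
                    sum(bad)))
    rr <- rr[!bad]
  }
  if (length(rr) < 1)
    stop(errorCondition("no valid RR intervals after screening",
                        class = c("ilfs_trial_invalid", "error", "condition")))
  new_rr_series(peak_times, rr, trial_id, subject_id)
}
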