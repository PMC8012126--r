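#' Downsample an ECG recording
#'
#' Anti-alias filters the signal (8th-order Butterworth low-pass at 80% of
#' the output Nyquist frequency, applied forward-backward for zero phase)
#' and decimates when the rate ratio is an integer; otherwise polyphase
#' resampling is used. Event onsets are stored in seconds and are unchanged.
#'
#' @param rec an \code{ecg_recording}.
#' @param fs_out target sampling frequency in Hz (<= \code{rec$fs}).
#' @return The downsampled \code{ecg_recording}.
#' @export
downsample <- function(rec, fs_out = 200) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (fs_out > rec$fs) stop("fs_out must not exceed the input rate")
  if (fs_out == rec$fs) return(rec)
  ratio <- rec$fs / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    r <- round(ratio)
    bf <- signal::butter(8, 0.8 / r, type = "low")
    # odd-symmetric reflection padding absorbs the filter's edge transients
    x <- rec$samples
    n <- length(x)
    L <- min(n - 1, 1000L)
    xp <- c(2 * x[1] - x[(L + 1):2], x, 2 * x[n] - x[(n - 1):(n - L)])
    y <- signal::filtfilt(bf, xp)[(L + 1):(L + n)]
    y <- y[seq(1, length(y), by = r)]
  } else {
    frac <- .rat_approx(fs_out / rec$fs)
    y <- signal::resample(rec$samples, frac[1], frac[2])
  }
  out <- rec
  out$samples <- y
  out$fs <- fs_out
  out
}

.rat_approx <- function(x, max_den = 1000) {
  best <- c(1L, 1L)
  err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err) { err <- e; best <- c(p, q) }
    if (e == 0) break
  }
  best
}

#' Wavelet soft-threshold denoising of an ECG signal
#'
#' Multi-level periodized db4 decomposition; every detail level is shrunk
#' with the soft-threshold rule \eqn{s(c) = sign(c)\,\max(|c| - \lambda, 0)}
#' using the minimax threshold
#' \eqn{\lambda = \sigma (0.3936 + 0.1829 \log_2 N)}, whose smaller shrinkage
#' preserves the large, sparse QRS coefficients that the universal
#' \eqn{\sigma\sqrt{2 \ln N}} rule visibly over-smooths on ECG.
#' The noise scale \eqn{\sigma = MAD(d_1)/0.6745} is estimated from the
#' finest detail level, where the ECG waveform contributes least; at the
#' coarse levels the coefficient vectors are short and signal-dominated,
#' so a per-level estimate there would read the waveform itself as noise
#' and flatten the P and T waves.
#' The coarsest approximation carries the sub-1-Hz baseline drift and
#' is zeroed when \code{remove_baseline = TRUE}; the default depth is chosen
#' so that band reaches below 1 Hz (depth \eqn{\lfloor \log_2 fs \rfloor},
#' i.e. 7 levels at 200 Hz, approximation band 0--0.78 Hz).
#'
#' @param x numeric signal (mV).
#' @param fs sampling frequency, Hz.
#' @param levels decomposition depth; default \code{floor(log2(fs))}.
#' @param wavelet wavelet name (default \code{"db4"}).
#' @param remove_baseline zero the coarsest approximation (default TRUE).
#' @return Denoised signal, same length as \code{x}.
#' @export
denoise_dwt <- function(x, fs, levels = NULL, wavelet = "db4",
                        remove_baseline = TRUE) {
  if (is.null(levels)) levels <- max(1L, floor(log2(fs)))
  n <- length(x)
  if (n < 2^levels)
    stop("signal shorter than the minimum decomposition length 2^levels")
  # pad by edge reflection to a multiple of 2^levels (periodized transform)
  block <- 2^levels
  pad <- (block - n %% block) %% block
  xp <- if (pad > 0) c(x, x[n:(n - pad + 1L)]) else x
  dec <- dwt_decompose(xp, levels, wavelet)
  sigma <- median(abs(dec$details[[1]])) / 0.6745
  lam <- sigma * (0.3936 + 0.1829 * log2(length(xp)))
  for (j in seq_along(dec$details)) {
    d <- dec$details[[j]]
    dec$details[[j]] <- sign(d) * pmax(abs(d) - lam, 0)
  }
  if (remove_baseline) dec$approx[] <- 0
  y <- dwt_reconstruct(dec)
  y[seq_len(n)]
}

#' Cut a recording into fixed-length trial segments
#'
#' One segment per trial event, starting at the nearest sample to the
#' stimulus onset. Trials whose window would run past the end of the
#' recording are skipped with a warning and listed in the
#' \code{"skipped"} attribute.
#'
#' @param rec an \code{ecg_recording} (typically downsampled and denoised).
#' @param duration segment length in seconds (default 10).
#' @return List of \code{trial_segment} objects, each with exactly
#'   \code{round(duration * fs)} samples.
#' @export
segment_trials <- function(rec, duration = 10) {
  stopifnot(inherits(rec, "ecg_recording"))
  n <- length(rec$samples)
  len <- round(duration * rec$fs)
  segs <- list()
  skipped <- integer(0)
  for (i in seq_len(nrow(rec$events))) {
    onset <- rec$events$onset[i]
    tid <- rec$events$trial_id[i]
    start <- round(onset * rec$fs) + 1L
    if (start < 1L || start + len - 1L > n) {
      warning(sprintf("trial %s: onset %.2f s does not fit in recording; skipped",
                      tid, onset))
      skipped <- c(skipped, tid)
      next
    }
    segs[[length(segs) + 1L]] <- structure(
      list(samples = rec$samples[start:(start + len - 1L)], fs = rec$fs,
           trial_id = tid, subject_id = rec$subject_id),
      class = "trial_segment")
  }
  attr(segs, "skipped") <- skipped
  segs
}
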