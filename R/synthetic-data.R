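#' Simulation configuration for a synthetic ILFS study
#'
#' Bundles and validates the parameters of the synthetic study generator.
#' The defaults emulate the acquisition conditions of a laboratory picture
#' paradigm: single-lead ECG sampled at 1000 Hz, 10-s stimulus trials, and
#' two self-report scales per trial (ILFS intensity 0--3 and four Likert
#' dimensions 1--7). The ILFS class is simulated with a shorter mean RR
#' interval (higher heart rate), the direction reported for this state.
#'
#' @param n_subjects number of simulated subjects.
#' @param trials_per_subject trials (10-s stimulus presentations) per subject.
#' @param fs ECG sampling frequency in Hz (>= 100).
#' @param trial_duration trial length in seconds.
#' @param mean_rr_non mean RR interval of the non-ILFS class, ms.
#' @param delta_rr class effect in ms; the ILFS class has mean RR
#'   \code{mean_rr_non - delta_rr}.
#' @param sdrr within-trial SD of the RR noise term, ms.
#' @param lf_amp,hf_amp amplitudes (ms) of the sinusoidal RR modulations at
#'   0.1 Hz and 0.25 Hz, the centers of the LF (0.04--0.15 Hz) and HF
#'   (0.15--0.4 Hz) spectral bands.
#' @param noise_sd additive white measurement noise on the ECG, mV.
#' @param rating_noise_sd SD of the Gaussian noise on the Likert ratings.
#' @param seed integer seed; the whole study is reproducible from it.
#' @return A validated list of class \code{"sim_config"}.
#' @export
simulation_config <- function(n_subjects = 10, trials_per_subject = 20,
                              fs = 1000, trial_duration = 10,
                              mean_rr_non = 800, delta_rr = 80, sdrr = 30,
                              lf_amp = 20, hf_amp = 10, noise_sd = 0.05,
                              rating_noise_sd = 1, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              trials_per_subject = as.integer(trials_per_subject),
              fs = fs, trial_duration = trial_duration,
              mean_rr_non = mean_rr_non, delta_rr = delta_rr, sdrr = sdrr,
              lf_amp = lf_amp, hf_amp = hf_amp, noise_sd = noise_sd,
              rating_noise_sd = rating_noise_sd, seed = as.integer(seed))
  if (cfg$n_subjects < 1 || cfg$trials_per_subject < 1)
    stop("need at least one subject and one trial per subject")
  if (cfg$fs < 100)
    stop("fs must be >= 100 Hz")
  vals <- c(cfg$trial_duration, cfg$sdrr, cfg$lf_amp, cfg$hf_amp,
            cfg$noise_sd, cfg$rating_noise_sd, cfg$delta_rr)
  if (any(vals < 0))
    stop("durations, amplitudes and noise levels must be non-negative")
  if (cfg$mean_rr_non - cfg$delta_rr <= 300)
    stop("mean_rr_non - delta_rr must exceed the 300 ms physiological floor")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic RR-interval series
#'
#' Tachogram model: a constant mean plus two sinusoidal modulations at
#' 0.1 Hz (LF band center) and 0.25 Hz (HF band center) plus white Gaussian
#' noise, evaluated at the cumulative beat time and clipped to the
#' physiological range 300--2000 ms:
#' \deqn{RR_i = \mu + a_{LF}\sin(2\pi 0.1 t_i) + a_{HF}\sin(2\pi 0.25 t_i) + \epsilon_i}
#'
#' @param n_beats number of beats (>= 2); the series has \code{n_beats - 1}
#'   intervals.
#' @param mean_rr mean RR interval, ms (> 0).
#' @param sdrr SD of the Gaussian noise term, ms.
#' @param lf_amp,hf_amp modulation amplitudes, ms.
#' @param seed optional seed; if \code{NULL} the current RNG state is used.
#' @return Numeric vector of RR intervals in ms.
#' @export
generate_rr_series <- function(n_beats, mean_rr, sdrr = 0, lf_amp = 0,
                               hf_amp = 0, seed = NULL) {
  if (n_beats < 2) stop("n_beats must be >= 2")
  if (mean_rr <= 0) stop("mean_rr must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- n_beats - 1L
  rr <- numeric(n)
  eps <- rnorm(n, 0, sdrr)
  t_i <- 0
  for (i in seq_len(n)) {
    rr[i] <- mean_rr +
      lf_amp * sin(2 * pi * 0.10 * t_i) +
      hf_amp * sin(2 * pi * 0.25 * t_i) + eps[i]
    rr[i] <- min(max(rr[i], 300), 2000)
    t_i <- t_i + rr[i] / 1000
  }
  rr
}

# P-QRS-T template as a sum of Gaussian bumps.  Columns: center offset from
# the R peak (s), amplitude (mV), width sigma (s).
.ecg_template <- rbind(
  P = c(-0.200, 0.12, 0.025),
  Q = c(-0.035, -0.10, 0.010),
  R = c( 0.000, 1.00, 0.012),
  S = c( 0.035, -0.15, 0.010),
  T = c( 0.250, 0.30, 0.050)
)

#' Render a synthetic ECG waveform from an RR series
#'
#' Places one P-QRS-T template (a sum of Gaussian bumps with a dominant R
#' wave of 1 mV) at each cumulative beat time and adds white measurement
#' noise. The true beat (R-peak) times are returned so that downstream
#' detectors can be scored against ground truth.
#'
#' @param rr RR-interval series, ms.
#' @param fs sampling frequency, Hz (>= 100).
#' @param noise_sd SD of the additive white noise, mV.
#' @param seed optional seed for the noise.
#' @param lead_in seconds of signal before the first R peak.
#' @param tail_s total lead-in plus tail padding in seconds; the rendered
#'   duration is \code{sum(rr)/1000 + tail_s}.
#' @return An object of class \code{"ecg_recording"}: a list with
#'   \code{samples} (mV), \code{fs}, \code{events} (data frame of trial
#'   onsets, empty here), \code{subject_id} and the ground-truth
#'   \code{beat_times} in seconds.
#' @export
render_ecg <- function(rr, fs, noise_sd = 0, seed = NULL,
                       lead_in = 0.25, tail_s = 0.5) {
  if (fs < 100) stop("fs below 100 Hz cannot represent the QRS complex")
  if (any(rr <= 0)) stop("rr intervals must be positive")
  if (!is.null(seed)) set.seed(seed)
  beat_times <- lead_in + cumsum(c(0, rr)) / 1000
  duration <- sum(rr) / 1000 + tail_s
  n <- round(duration * fs)
  x <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  for (b in beat_times) {
    for (w in seq_len(nrow(.ecg_template))) {
      mu <- b + .ecg_template[w, 1]
      amp <- .ecg_template[w, 2]
      sig <- .ecg_template[w, 3]
      i0 <- max(1L, floor((mu - 4 * sig) * fs) + 1L)
      i1 <- min(n, ceiling((mu + 4 * sig) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      x[idx] <- x[idx] + amp * exp(-0.5 * ((tt[idx] - mu) / sig)^2)
    }
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  new_ecg_recording(x, fs, events = data.frame(trial_id = integer(0),
                                               onset = numeric(0)),
                    subject_id = NA_character_, beat_times = beat_times)
}

new_ecg_recording <- function(samples, fs, events, subject_id,
                              beat_times = NULL) {
  structure(list(samples = samples, fs = fs, events = events,
                 subject_id = subject_id, beat_times = beat_times),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("ECG recording: %d samples at %g Hz (%.1f s), %d trial events\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              nrow(x$events)))
  invisible(x)
}

.clip_likert <- function(x) pmin(pmax(round(x), 1), 7)

#' Generate a full synthetic ILFS study
#'
#' Simulates, per subject, a continuous single-lead ECG recording made of
#' consecutive 10-s stimulus trials, half of which are drawn from the ILFS
#' class (mean RR shortened by \code{delta_rr}) and half from the non-ILFS
#' class, together with per-trial self reports: ILFS trials rate intensity
#' 2 or 3 with the four Likert dimensions centered at 6, non-ILFS trials
#' rate intensity 0 with dimensions centered at 2; Gaussian rating noise is
#' rounded and clipped to the 1--7 scale. The per-trial ground truth (class,
#' beat times, RR series) is returned for oracle use.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return An object of class \code{"ilfs_study"}: list with
#'   \code{recordings} (one \code{ecg_recording} per subject, with trial
#'   events), \code{ratings} (data frame), and \code{truth} (data frame
#'   with list-columns \code{beat_times} and \code{rr}).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  dur <- config$trial_duration
  n_tr <- config$trials_per_subject
  recs <- vector("list", config$n_subjects)
  ratings <- vector("list", config$n_subjects)
  truth <- vector("list", config$n_subjects)
  seg_len <- round(dur * fs)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    cls <- sample(rep(c(1L, 0L), length.out = n_tr))
    samples <- numeric(0)
    tr_truth <- vector("list", n_tr)
    tr_rat <- vector("list", n_tr)
    for (k in seq_len(n_tr)) {
      mu <- config$mean_rr_non - if (cls[k] == 1L) config$delta_rr else 0
      n_beats <- ceiling((dur + 1) * 1000 /
                           max(300, mu - config$lf_amp - config$hf_amp)) + 2L
      rr <- generate_rr_series(n_beats, mu, config$sdrr,
                               config$lf_amp, config$hf_amp)
      rec <- render_ecg(rr, fs, noise_sd = config$noise_sd, lead_in = 0.2,
                        tail_s = 0.4)
      seg <- rec$samples[seq_len(seg_len)]
      onset <- (k - 1) * dur
      keep <- rec$beat_times < dur - 0.05
      bt <- onset + rec$beat_times[keep]
      tr_truth[[k]] <- list(subject_id = sid, trial_id = k, class = cls[k],
                            beat_times = bt,
                            rr = diff(bt) * 1000)
      if (cls[k] == 1L) {
        dims <- .clip_likert(rnorm(4, 6, config$rating_noise_sd))
        inten <- sample(2:3, 1)
      } else {
        dims <- .clip_likert(rnorm(4, 2, config$rating_noise_sd))
        inten <- 0L
      }
      tr_rat[[k]] <- data.frame(subject_id = sid, trial_id = k,
                                ilfs_intensity = inten, arousal = dims[1],
                                valence = dims[2], dominance = dims[3],
                                attraction = dims[4])
      samples <- c(samples, seg)
    }
    events <- data.frame(trial_id = seq_len(n_tr),
                         onset = (seq_len(n_tr) - 1) * dur)
    recs[[s]] <- new_ecg_recording(samples, fs, events, sid)
    ratings[[s]] <- do.call(rbind, tr_rat)
    truth[[s]] <- data.frame(
      subject_id = sid, trial_id = seq_len(n_tr), class = cls)
    truth[[s]]$beat_times <- lapply(tr_truth, `[[`, "beat_times")
    truth[[s]]$rr <- lapply(tr_truth, `[[`, "rr")
  }
  structure(list(recordings = recs,
                 ratings = do.call(rbind, ratings),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "ilfs_study")
}

#' @export
print.ilfs_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic ILFS study: %d subjects x %d trials ",
                     "(%g s at %g Hz), %d ILFS / %d non-ILFS\n"),
              x$config$n_subjects, x$config$trials_per_subject,
              x$config$trial_duration, x$config$fs,
              sum(x$truth$class == 1), sum(x$truth$class == 0)))
  invisible(x)
}

#' Ground-truth RR series of a synthetic study
#'
#' Converts the generator's ground truth into the same \code{rr_series}
#' objects produced by the detection path, for oracle comparisons and for
#' feature-level experiments that do not need the waveform stage.
#'
#' @param study an \code{ilfs_study}.
#' @return List of \code{rr_series} objects (one per trial).
#' @export
truth_rr_series <- function(study) {
  stopifnot(inherits(study, "ilfs_study"))
  out <- vector("list", nrow(study$truth))
  for (i in seq_len(nrow(study$truth))) {
    bt <- study$truth$beat_times[[i]]
    out[[i]] <- new_rr_series(bt - bt[1], diff(bt) * 1000,
                              trial_id = study$truth$trial_id[i],
                              subject_id = study$truth$subject_id[i])
  }
  out
}
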