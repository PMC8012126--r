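#' Process one recording into per-trial RR series
#'
#' The signal path for a single subject: downsample to \code{fs_out},
#' wavelet-denoise the whole recording (so no trial window suffers edge
#' artifacts), cut the 10-s trial segments at the stimulus onsets, detect
#' R peaks per segment with Pan-Tompkins and derive the RR series. Trials
#' with too few valid beats are skipped with a warning.
#'
#' @param rec an \code{ecg_recording} with trial events.
#' @param fs_out processing sampling rate, Hz (default 200).
#' @param duration trial length, s (default 10).
#' @return List of \code{rr_series} objects.
#' @export
process_recording <- function(rec, fs_out = 200, duration = 10) {
  rec <- downsample(rec, fs_out)
  rec$samples <- denoise_dwt(rec$samples, rec$fs)
  segs <- segment_trials(rec, duration)
  out <- list()
  for (seg in segs) {
    rrs <- tryCatch({
      peaks <- pan_tompkins(seg)
      suppressMessages(to_rr(peaks, seg$fs, seg$trial_id, seg$subject_id))
    }, ilfs_trial_invalid = function(e) {
      warning(sprintf("trial %s/%s dropped: %s", seg$subject_id,
                      seg$trial_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(rrs)) out[[length(out) + 1L]] <- rrs
  }
  out
}

#' Run the full feature-extraction pipeline on a study
#'
#' Applies \code{\link{process_recording}} to every subject and extracts
#' the 25 HRV features per trial.
#'
#' @param study an \code{ilfs_study} (or any list of \code{ecg_recording}
#'   objects under \code{$recordings}).
#' @param fs_out processing sampling rate, Hz.
#' @param duration trial length, s.
#' @return Data frame: \code{subject_id}, \code{trial_id}, 25 feature
#'   columns.
#' @export
run_pipeline <- function(study, fs_out = 200, duration = 10) {
  rr_all <- list()
  for (rec in study$recordings)
    rr_all <- c(rr_all, process_recording(rec, fs_out, duration))
  extract_features_table(rr_all)
}

#' Write / read a study to plain-text files
#'
#' \code{write_study} stores each subject's ECG as a one-column CSV with a
#' JSON sidecar (sampling rate, subject id, trial events), plus
#' \code{ratings.csv} and \code{truth.csv}. \code{read_recording} loads one
#' CSV/JSON pair back into an \code{ecg_recording}.
#'
#' @param study an \code{ilfs_study}.
#' @param dir output directory (created if needed).
#' @return \code{write_study}: the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in study$recordings) {
    base <- file.path(dir, paste0("ecg_", rec$subject_id))
    utils::write.csv(data.frame(mV = rec$samples),
                     paste0(base, ".csv"), row.names = FALSE)
    jsonlite::write_json(list(fs = rec$fs, subject_id = rec$subject_id,
                              events = rec$events),
                         paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  utils::write.csv(study$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  truth <- study$truth[, c("subject_id", "trial_id", "class")]
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_study
#' @param csv,json paths of the sample CSV and its JSON sidecar.
#' @return \code{read_recording}: an \code{ecg_recording}.
#' @export
read_recording <- function(csv, json) {
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  samples <- utils::read.csv(csv)[[1]]
  events <- as.data.frame(meta$events)
  if (nrow(events) == 0)
    events <- data.frame(trial_id = integer(0), onset = numeric(0))
  new_ecg_recording(samples, meta$fs, events, meta$subject_id)
}
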