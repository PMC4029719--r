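#' Write / read a trial as delimited text
#'
#' One CSV per trial with a mandatory header: `time_s`, `emg_biceps_uV`,
#' `emg_brachiorad_uV`, `emg_triceps_uV`, `emg_anconeus_uV`, `angle_deg`.
#'
#' @param recording An `emg_recording`.
#' @param path File path.
#' @return `read_trial_csv` returns an `emg_recording`; `fs_hz` is
#'   recovered from the time column.
#' @export
write_trial_csv <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  n <- ncol(recording$emg_uV)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / recording$fs_hz,
    emg_biceps_uV = recording$emg_uV[1, ],
    emg_brachiorad_uV = recording$emg_uV[2, ],
    emg_triceps_uV = recording$emg_uV[3, ],
    emg_anconeus_uV = recording$emg_uV[4, ],
    angle_deg = recording$angle_deg)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "emg_biceps_uV", "emg_brachiorad_uV",
            "emg_triceps_uV", "emg_anconeus_uV", "angle_deg")
  if (!all(need %in% names(df)))
    stop("trial file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  fs <- 1 / stats::median(diff(df$time_s))
  emg <- t(as.matrix(df[, need[2:5]]))
  rownames(emg) <- emg_channel_names()
  new_emg_recording(emg, df$angle_deg, round(fs))
}

#' Write a session to a directory
#'
#' One `trial_XXX.csv` per recording plus a `manifest.json` holding the
#' configuration, activation gains and per-trial seeds.
#'
#' @param session List of `emg_recording` objects from
#'   [generate_session()].
#' @param dir Output directory (created if absent).
#' @param config,params The generating [trial_config()] /
#'   [activation_params()] for the manifest.
#' @return `read_session` returns the list of recordings.
#' @export
write_session <- function(session, dir, config = NULL, params = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- sprintf(file.path(dir, "trial_%03d.csv"), seq_along(session))
  for (i in seq_along(session)) write_trial_csv(session[[i]], paths[i])
  manifest <- list(
    n_trials = length(session),
    files = basename(paths),
    config = if (!is.null(config)) unclass(config),
    params = if (!is.null(params)) unclass(params),
    trial_seeds = if (!is.null(config))
      vapply(seq_along(session), function(i)
        derive_trial_seed(config$seed, i), numeric(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  files <- sort(list.files(dir, pattern = "^trial_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no trial files in ", dir)
  lapply(files, read_trial_csv)
}

#' Feature frame CSV round-trip
#'
#' @param frame A `feature_frame` from [rms_windows()].
#' @param path File path.
#' @export
write_features_csv <- function(frame, path) {
  stopifnot(inherits(frame, "feature_frame"))
  rms <- frame$rms_uV
  if (is.null(colnames(rms)))
    colnames(rms) <- paste0("ch", seq_len(ncol(rms)))
  utils::write.csv(data.frame(t_end_s = frame$t_end_s,
                              rms, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
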