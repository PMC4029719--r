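#' Root-mean-square error between predicted and actual angles
#'
#' \eqn{\mathrm{RMSE} = \sqrt{(1/N) \sum_n (A_n - A'_n)^2}} with
#' \eqn{A_n} the predicted and \eqn{A'_n} the actual angle.
#'
#' @param predicted,actual Equal-length numeric vectors (degrees).
#' @return RMSE in degrees.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) < 1L)
    stop("invalid input: predicted and actual must have equal length >= 1")
  sqrt(mean((predicted - actual)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, residuals taken about the predictions and the
#' total sum of squares about the mean of the actual series. Values close
#' to one indicate good prediction; unlike squared correlation this
#' definition penalizes bias, consistently with RMSE as an error measure.
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @return R-squared (can be negative for predictions worse than the mean).
#' @export
r_squared <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) < 2L)
    stop("invalid input: need equal lengths >= 2")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0)
    stop("undefined statistic: actual series has zero variance")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Optimal regression line of predicted on actual angle
#'
#' Ordinary least squares of the predicted angle on the actual angle
#' (actual on the x-axis). A perfect decoder gives slope `k = 1` and
#' intercept `j = 0` degrees.
#'
#' @param actual Actual angle series (regressor, degrees).
#' @param predicted Predicted angle series (response, degrees).
#' @return List with slope `k` (dimensionless) and intercept `j_deg`.
#' @export
regression_line <- function(actual, predicted) {
  if (length(predicted) != length(actual) || length(actual) < 2L)
    stop("invalid input: need equal lengths >= 2")
  sxx <- sum((actual - mean(actual))^2)
  if (sxx == 0)
    stop("undefined statistic: degenerate regressor")
  k <- sum((actual - mean(actual)) * (predicted - mean(predicted))) / sxx
  list(k = k, j_deg = mean(predicted) - k * mean(actual))
}

#' Evaluate a trained model on a held-out test set
#'
#' Predicts every test row and assembles RMSE, R-squared and the optimal
#' regression line into one report. The test set must come from trials
#' unseen during training ([split_data()] guarantees this).
#'
#' @param model A trained `bpn_model`.
#' @param test_set A `labeled_dataset`.
#' @param period_s Optional motion-period annotation for the report.
#' @return An `evaluation_report`: `rmse_deg`, `r2`, `k`, `j_deg`, `n`,
#'   `period_s`.
#' @export
evaluate_model <- function(model, test_set, period_s = NA_real_) {
  stopifnot(inherits(model, "bpn_model"),
            inherits(test_set, "labeled_dataset"))
  if (nrow(test_set$features) == 0L)
    stop("invalid input: empty test set")
  pred <- bpn_predict(model, test_set$features)
  act <- test_set$targets
  reg <- regression_line(act, pred)
  structure(list(rmse_deg = rmse(pred, act), r2 = r_squared(pred, act),
                 k = reg$k, j_deg = reg$j_deg, n = length(act),
                 period_s = period_s),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report (period %s s, n = %d):\n  RMSE %.2f deg, R2 %.3f, k %.4f, j %.4f deg\n",
    format(x$period_s), x$n, x$rmse_deg, x$r2, x$k, x$j_deg))
  invisible(x)
}

#' Power-assist comparison of recording conditions
#'
#' Computes the per-muscle mean RMS under each labeled condition (e.g.
#' no-exoskeleton, exoskeleton unpowered, exoskeleton powered) and the
#' powered / unpowered reduction ratio per muscle. In synthetic studies the
#' powered condition is emulated by generating with activation gains scaled
#' down by the assist factor.
#'
#' @param sessions Named list of conditions; each condition is a list of
#'   `emg_recording` objects. For the reduction ratio, names must include
#'   `powered` and `unpowered`.
#' @param window A [window_spec()].
#' @return An `assist_comparison`: `mean_rms` (condition x muscle matrix)
#'   and `reduction_ratio` (powered / unpowered per muscle, NULL when the
#'   two conditions are not both present).
#' @export
assist_comparison <- function(sessions, window = window_spec(fs_hz = 1024)) {
  if (length(sessions) == 0L || is.null(names(sessions)) ||
      any(names(sessions) == ""))
    stop("invalid input: `sessions` must be a named list of conditions")
  if (any(vapply(sessions, length, integer(1)) == 0L))
    stop("invalid input: every condition needs at least one recording")
  mean_rms <- t(vapply(sessions, function(recs) {
    per_rec <- vapply(recs, function(rec) {
      colMeans(rms_windows(preprocess(rec), window)$rms_uV)
    }, numeric(4))
    rowMeans(per_rec)
  }, numeric(4)))
  colnames(mean_rms) <- emg_channel_names()
  ratio <- NULL
  if (all(c("powered", "unpowered") %in% rownames(mean_rms)))
    ratio <- mean_rms["powered", ] / mean_rms["unpowered", ]
  structure(list(mean_rms = mean_rms, reduction_ratio = ratio),
            class = "assist_comparison")
}

#' @export
print.assist_comparison <- function(x, ...) {
  cat("assist_comparison: mean per-muscle RMS (uV) by condition\n")
  print(round(x$mean_rms, 2))
  if (!is.null(x$reduction_ratio)) {
    cat("powered / unpowered ratio:\n")
    print(round(x$reduction_ratio, 3))
  }
  invisible(x)
}

#' Run one full decoding experiment
#'
#' The canonical end-to-end protocol used throughout the package's own
#' evaluation: generate a session of `n_trials` movements, build the
#' windowed dataset, split whole trials 80/20, train the 4-3-1 network and
#' evaluate on the held-out trials. The session and the split derive from
#' `master_seed`; the network initialization uses a fixed seed so that
#' experiment-to-experiment variation reflects the data, not the init.
#'
#' @param period_s Motion period in seconds.
#' @param master_seed Master seed for generation and split.
#' @param n_trials Movements per session (default 60).
#' @param params An [activation_params()].
#' @param window A [window_spec()].
#' @param train_fraction Trial fraction for training (default 0.8).
#' @param spec A [train_spec()]; its seed is fixed by default.
#' @return List with `report` (an `evaluation_report`), `model`, `split`
#'   and `loss`.
#' @export
run_experiment <- function(period_s = 4, master_seed = 1L, n_trials = 60L,
                           params = activation_params(),
                           window = window_spec(fs_hz = 1024),
                           train_fraction = 0.8,
                           spec = train_spec(seed = 3L)) {
  cfg <- trial_config(period_s = period_s, seed = master_seed)
  session <- generate_session(cfg, params, n_trials = n_trials)
  ds <- make_dataset(session, window)
  sp <- split_data(ds, train_fraction, seed = master_seed)
  fit <- bpn_train(sp$train, spec)
  report <- evaluate_model(fit$model, sp$test, period_s = period_s)
  list(report = report, model = fit$model, split = sp, loss = fit$loss)
}
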