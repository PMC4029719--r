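#' Streaming control-loop configuration
#'
#' Bundles everything one control tick needs: the trained angle decoder,
#' the actuator model, the analysis window and the RMS noise gate. The
#' window length plus worst-case processing must fit the latency budget a
#' wearer perceives as immediate (300 ms); this is a documented contract,
#' checked at construction against the window length.
#'
#' @param model A trained `bpn_model`.
#' @param window A [window_spec()].
#' @param threshold_uV RMS gate level in microvolts; ticks whose four
#'   channels all fall below it emit exactly 0 V. See
#'   [calibrate_threshold()].
#' @param geom A [joint_geometry()].
#' @param params A [muscle_params()].
#' @param closure Force closure passed to [angle_to_command()].
#' @param load_kg,forearm_m Load model for the closure.
#' @param latency_budget_ms Total window + processing budget (default 300).
#' @return A `control_config` object.
#' @export
control_config <- function(model, window = window_spec(fs_hz = 1024),
                           threshold_uV = 0, geom = joint_geometry(),
                           params = muscle_params(),
                           closure = "gravity", load_kg = 1,
                           forearm_m = 0.25, latency_budget_ms = 300) {
  stopifnot(inherits(model, "bpn_model"), inherits(window, "window_spec"))
  if (threshold_uV < 0) stop("threshold_uV must be >= 0")
  if (window$length_ms >= latency_budget_ms)
    stop("configuration error: window length ", window$length_ms,
         " ms leaves no processing headroom in the ", latency_budget_ms,
         " ms latency budget")
  structure(list(model = model, window = window,
                 threshold_uV = threshold_uV, geom = geom, params = params,
                 closure = closure, load_kg = load_kg,
                 forearm_m = forearm_m,
                 latency_budget_ms = latency_budget_ms),
            class = "control_config")
}

#' RMS noise gate
#'
#' Movement onset is declared when any of the four muscles' RMS reaches the
#' threshold (ties pass: `>=`). Below it the controller outputs no signal
#' (0 V), suppressing noise-driven actuation at rest.
#'
#' @param rms Numeric 4-vector of channel RMS values (>= 0).
#' @param threshold_uV Gate level; 0 always passes.
#' @return `TRUE` to pass (actuate), `FALSE` to block.
#' @export
gate <- function(rms, threshold_uV) {
  if (any(rms < 0)) stop("rms must be >= 0")
  max(rms) >= threshold_uV
}

#' Rest-noise threshold calibration
#'
#' The gate level is set to `factor` times the largest per-channel RMS
#' observed over a rest recording (no movement, co-contraction and sensor
#' noise only).
#'
#' @param rest_recording An `emg_recording` captured at rest.
#' @param window A [window_spec()].
#' @param factor Multiplier over the rest RMS (default 3).
#' @return Threshold in microvolts.
#' @export
calibrate_threshold <- function(rest_recording,
                                window = window_spec(fs_hz = 1024),
                                factor = 3) {
  ff <- rms_windows(preprocess(rest_recording), window)
  factor * max(ff$rms_uV)
}

zero_command <- function() {
  structure(list(theta2_deg = NA_real_, dP_Pa = NA_real_, Pa_Pa = NA_real_,
                 Pb_Pa = NA_real_, F_a = NA_real_, F_b = NA_real_,
                 voltage_V = 0, saturated = FALSE),
            class = "actuator_command")
}

#' One control tick from a conditioned window buffer
#'
#' Computes the four-channel RMS of the buffer, applies the gate, and when
#' it passes decodes the angle, clamps it to the joint range and converts
#' it to a differential-pressure/voltage command. Uses only samples inside
#' the buffer (causal); a gated tick carries a voltage of exactly 0.
#'
#' @param buffer 4 x length_samples matrix of conditioned (enveloped) EMG,
#'   channels in rows — exactly one window.
#' @param config A [control_config()].
#' @param t_s Optional window-end time stamp carried into the tick.
#' @return A `control_tick`: list with `t_s`, `rms`, `gated`,
#'   `theta2_pred_deg` (NA when gated) and `command`.
#' @export
control_step <- function(buffer, config, t_s = NA_real_) {
  stopifnot(inherits(config, "control_config"))
  if (!is.matrix(buffer) || nrow(buffer) != 4L ||
      ncol(buffer) != config$window$length_samples)
    stop("buffer must be 4 x ", config$window$length_samples, " samples")
  rms <- sqrt(rowMeans(buffer^2))
  if (!gate(rms, config$threshold_uV)) {
    return(structure(list(t_s = t_s, rms = rms, gated = TRUE,
                          theta2_pred_deg = NA_real_,
                          command = zero_command()),
                     class = "control_tick"))
  }
  theta <- bpn_predict(config$model, rms)
  rng <- config$geom$theta2_range_deg
  theta <- min(max(theta, rng[1]), rng[2])
  cmd <- angle_to_command(theta, config$geom, config$params,
                          closure = config$closure,
                          load_kg = config$load_kg,
                          forearm_m = config$forearm_m, clamp = TRUE)
  structure(list(t_s = t_s, rms = rms, gated = FALSE,
                 theta2_pred_deg = theta, command = cmd),
            class = "control_tick")
}

#' Replay the control loop over a full recording
#'
#' Conditions the whole recording with the causal chain, then emits one
#' tick per window step — a batch replay of exactly what the streaming
#' loop would do, for testing and offline evaluation. The tick count
#' equals the window-count formula of [n_windows()].
#'
#' @param recording An `emg_recording`.
#' @param config A [control_config()].
#' @return List of `control_tick` objects.
#' @export
run_offline <- function(recording, config) {
  stopifnot(inherits(recording, "emg_recording"),
            inherits(config, "control_config"))
  cond <- preprocess(recording)
  w <- config$window
  nw <- n_windows(ncol(cond), w)
  if (nw < 1L) stop("recording shorter than one window")
  lapply(seq_len(nw), function(k) {
    s <- 1L + (k - 1L) * w$step_samples
    e <- s + w$length_samples - 1L
    control_step(cond[, s:e, drop = FALSE], config, t_s = e / w$fs_hz)
  })
}

#' Tick log as a data frame
#'
#' @param ticks List of `control_tick` objects from [run_offline()].
#' @return data.frame with columns `t_s`, the four RMS channels, `gated`,
#'   `theta2_pred_deg`, `dP_Pa`, `Pa_Pa`, `Pb_Pa`, `voltage_V`.
#' @export
ticks_to_frame <- function(ticks) {
  rms <- t(vapply(ticks, function(tk) tk$rms, numeric(4)))
  colnames(rms) <- paste0("rms_", emg_channel_names(), "_uV")
  data.frame(
    t_s = vapply(ticks, function(tk) tk$t_s, numeric(1)),
    rms,
    gated = vapply(ticks, function(tk) tk$gated, logical(1)),
    theta2_pred_deg = vapply(ticks, function(tk) tk$theta2_pred_deg,
                             numeric(1)),
    dP_Pa = vapply(ticks, function(tk) tk$command$dP_Pa, numeric(1)),
    Pa_Pa = vapply(ticks, function(tk) tk$command$Pa_Pa, numeric(1)),
    Pb_Pa = vapply(ticks, function(tk) tk$command$Pb_Pa, numeric(1)),
    voltage_V = vapply(ticks, function(tk) tk$command$voltage_V,
                       numeric(1)))
}
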