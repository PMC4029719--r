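#' Trial configuration for synthetic flexion-extension recordings
#'
#' Describes one elbow flexion-extension trial: the motion period, sampling
#' rate, number of cycles, held load and peak EMG amplitude. The shoulder is
#' held at a fixed 90 degrees throughout (single degree-of-freedom elbow
#' protocol); the elbow sweeps 0-90 degrees per cycle.
#'
#' @param period_s Motion period T in seconds (protocol values 2, 4 or 8;
#'   any positive value is allowed).
#' @param fs_hz Sampling rate in Hz (default 1024). Must exceed 1000 Hz so
#'   the 20-500 Hz EMG carrier band is representable.
#' @param n_cycles Number of flexion-extension cycles per trial (default 1;
#'   one "movement set" is one cycle).
#' @param load_kg Held mass in kg (default 1).
#' @param seed RNG seed for the trial.
#' @param amplitude_scale_uV Per-muscle peak EMG amplitude in microvolts.
#'   Scalar (recycled) or length 4, each in (0, 1600]; 1600 uV is the
#'   sensor ceiling and generated samples are clipped there.
#' @return A `trial_config` object.
#' @export
trial_config <- function(period_s = 4, fs_hz = 1024, n_cycles = 1L,
                         load_kg = 1, seed = 1L,
                         amplitude_scale_uV = 800) {
  if (!is.numeric(period_s) || length(period_s) != 1L || period_s <= 0)
    stop("invalid configuration: period_s must be a positive scalar")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 2 * 500)
    stop("invalid configuration: fs_hz must exceed 1000 Hz ",
         "(20-500 Hz carrier band must be representable)")
  if (!is.numeric(n_cycles) || n_cycles < 1)
    stop("invalid configuration: n_cycles must be >= 1")
  if (!is.numeric(load_kg) || load_kg < 0)
    stop("invalid configuration: load_kg must be >= 0")
  amp <- rep_len(as.numeric(amplitude_scale_uV), 4L)
  if (any(amp <= 0) || any(amp > 1600))
    stop("invalid configuration: amplitude_scale_uV must lie in (0, 1600]")
  structure(list(period_s = period_s, fs_hz = fs_hz,
                 n_cycles = as.integer(n_cycles), load_kg = load_kg,
                 seed = as.integer(seed), amplitude_scale_uV = amp,
                 shoulder_deg = 90),
            class = "trial_config")
}

#' Activation-model gains for the synthetic generator
#'
#' Gains of the phenomenological activation model that turns the angle
#' trajectory into per-muscle activation envelopes in \[0, 1\]. Flexors
#' (biceps, brachioradialis) are driven by positive angular velocity plus a
#' gravity-load term; extensors (triceps, anconeus) by negative angular
#' velocity. Two period-dependent degradations are explicit and separately
#' switchable: an acceleration-proportional amplitude distortion (largest at
#' short periods, where acceleration scales as 1/T^2) and a slow random-walk
#' drift on the envelope (accumulates most over long periods).
#'
#' @param k_vel Velocity-to-activation gain (flexor on positive, extensor on
#'   negative angular velocity), velocity normalized by the 4-s-period peak.
#' @param k_load Gravity-load gain: activation `k_load * sin(theta2) *
#'   load_kg` added to the flexors (shoulder fixed at 90 degrees, forearm
#'   gravity torque proportional to sin of the elbow angle).
#' @param k_cocontraction Baseline co-contraction of all four muscles.
#' @param k_accel_distort Gain of the acceleration-tracking stochastic
#'   distortion: each channel receives an independent slowly varying
#'   zero-mean modulation whose instantaneous standard deviation is
#'   `k_accel_distort * |accel| / accel_ref`, with acceleration normalized
#'   by the 4-s-period peak, so a 2-s trial sees 4x the distortion of a
#'   4-s trial. Modeled as noise (not a deterministic acceleration term)
#'   because rapid movements perturb muscle drive unpredictably; a
#'   deterministic term would inform rather than degrade the decoder.
#' @param k_drift Random-walk drift gain: independent per-channel Gaussian
#'   increments of standard deviation `k_drift / sqrt(fs)` so drift
#'   variance grows linearly with elapsed time (largest effect on 8-s
#'   trials, emulating uncontrolled speed/effort wander in long periods).
#' @param synergist_ratio Synergist (brachioradialis, anconeus) activation
#'   relative to its agonist, in (0, 1].
#' @return An `activation_params` object.
#' @export
activation_params <- function(k_vel = 0.15, k_load = 0.65,
                              k_cocontraction = 0.02,
                              k_accel_distort = 0.03, k_drift = 0.04,
                              synergist_ratio = 0.6) {
  vals <- c(k_vel = k_vel, k_load = k_load,
            k_cocontraction = k_cocontraction,
            k_accel_distort = k_accel_distort, k_drift = k_drift)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("invalid configuration: all gains must be finite and >= 0")
  if (!is.numeric(synergist_ratio) || synergist_ratio <= 0 ||
      synergist_ratio > 1)
    stop("invalid configuration: synergist_ratio must lie in (0, 1]")
  structure(as.list(c(vals, synergist_ratio = synergist_ratio)),
            class = "activation_params")
}

#' @rdname trial_config
#' @export
emg_channel_names <- function() {
  c("biceps", "brachioradialis", "triceps", "anconeus")
}

# Reference period used to normalize velocity and acceleration so the
# activation magnitude (velocity term) is comparable across periods while
# acceleration distortion scales as (4 / T)^2.
.ref_period_s <- 4

#' Raised-cosine elbow-angle trajectory
#'
#' One flexion-extension cycle follows
#' \eqn{\theta_2(t) = 45 (1 - \cos(2 \pi t / T))}: the elbow starts at 0
#' degrees, peaks at 90 degrees at T/2 and returns to 0 degrees at T, with
#' continuous velocity across cycle boundaries.
#'
#' @param config A [trial_config()].
#' @return Numeric vector of elbow angles in degrees, length
#'   `round(n_cycles * period_s * fs_hz)`, sampled at `t = 0, 1/fs, ...`.
#' @examples
#' th <- angle_trajectory(trial_config(period_s = 4))
#' th[1]  # 0 degrees at t = 0
#' @export
angle_trajectory <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  n <- round(config$n_cycles * config$period_s * config$fs_hz)
  t <- (seq_len(n) - 1) / config$fs_hz
  45 * (1 - cos(2 * pi * t / config$period_s))
}

# Analytic velocity (deg/s) and acceleration (deg/s^2) of the trajectory.
trajectory_derivatives <- function(config) {
  n <- round(config$n_cycles * config$period_s * config$fs_hz)
  t <- (seq_len(n) - 1) / config$fs_hz
  w <- 2 * pi / config$period_s
  list(vel = 45 * w * sin(w * t), acc = 45 * w^2 * cos(w * t))
}

#' Per-muscle activation envelopes
#'
#' Maps an angle trajectory to four activation envelopes in \[0, 1\]
#' (biceps, brachioradialis, triceps, anconeus). Flexor drive is
#' `k_vel * max(vel, 0) / vel_ref + k_load * sin(theta2) * load_kg`;
#' extensor drive mirrors it with `max(-vel, 0)`; synergist drives are the
#' agonist drives scaled by `synergist_ratio`. Every channel then receives
#' the co-contraction baseline plus its own independent stochastic
#' acceleration-tracking distortion and random-walk drift (both seeded from
#' the current RNG state), and is clipped to \[0, 1\].
#'
#' @param angle_deg Elbow-angle trace in degrees (finite). When it is the
#'   trace produced by [angle_trajectory()] for `config`, analytic
#'   derivatives are used; otherwise derivatives are taken by finite
#'   differences.
#' @param config A [trial_config()].
#' @param params An [activation_params()].
#' @return A `length(angle_deg) x 4` matrix of envelopes, columns named as
#'   [emg_channel_names()].
#' @export
activation_envelopes <- function(angle_deg, config, params) {
  stopifnot(inherits(config, "trial_config"),
            inherits(params, "activation_params"))
  if (anyNA(angle_deg) || any(!is.finite(angle_deg)))
    stop("angle trace must be finite")
  n <- length(angle_deg)
  ref <- angle_trajectory(config)
  if (n == length(ref) && isTRUE(all.equal(angle_deg, ref))) {
    d <- trajectory_derivatives(config)
    vel <- d$vel; acc <- d$acc
  } else {
    vel <- c(0, diff(angle_deg)) * config$fs_hz
    acc <- c(0, diff(vel)) * config$fs_hz
  }
  w_ref <- 2 * pi / .ref_period_s
  vel_ref <- 45 * w_ref          # peak speed of the 4-s reference period
  acc_ref <- 45 * w_ref^2        # peak acceleration of the reference period

  flex_drive <- params$k_vel * pmax(vel, 0) / vel_ref +
    params$k_load * sin(angle_deg * pi / 180) * config$load_kg
  ext_drive <- params$k_vel * pmax(-vel, 0) / vel_ref
  r <- params$synergist_ratio
  drives <- cbind(flex_drive, r * flex_drive, ext_drive, r * ext_drive)

  # instantaneous sd of the acceleration-tracking stochastic distortion
  distort_sd <- params$k_accel_distort * abs(acc) / acc_ref
  env <- drives + params$k_cocontraction
  for (ch in 1:4) {
    if (params$k_accel_distort > 0)
      env[, ch] <- env[, ch] + distort_sd * smooth_noise(n, config$fs_hz)
    if (params$k_drift > 0)
      env[, ch] <- env[, ch] +
        cumsum(stats::rnorm(n, sd = params$k_drift / sqrt(config$fs_hz)))
  }
  env <- pmin(pmax(env, 0), 1)
  colnames(env) <- emg_channel_names()
  env
}

# Unit-variance slowly varying Gaussian process (white noise low-passed at
# 2 Hz): the time scale of involuntary drive fluctuation, well below the
# EMG carrier band.
smooth_noise <- function(n, fs_hz, bandwidth_hz = 2) {
  lp <- filter_spec("low_pass", bandwidth_hz, fs_hz, order = 2L)
  x <- butterworth_filter(stats::rnorm(n), lp)
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else x / s
}

#' Generate one synthetic EMG + angle trial
#'
#' Each channel is `amplitude_scale_uV * envelope(t) * carrier(t)`, where
#' the carrier is white Gaussian noise band-pass filtered to 20-500 Hz
#' (4th-order Butterworth high- and low-pass in cascade) and rescaled to
#' unit sample variance. Samples are clipped at +/-1600 uV, the sensor
#' recording ceiling. Identical `(config, params)` including the seed give
#' bit-identical recordings.
#'
#' @param config A [trial_config()].
#' @param params An [activation_params()] (default [activation_params()]).
#' @return An `emg_recording`: list with `emg_uV` (4 x n matrix, channels
#'   in rows), `angle_deg`, `fs_hz`, `labels`.
#' @export
generate_trial <- function(config, params = activation_params()) {
  stopifnot(inherits(config, "trial_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  angle <- angle_trajectory(config)
  env <- activation_envelopes(angle, config, params)
  n <- length(angle)
  hp <- filter_spec("high_pass", 20, config$fs_hz)
  lp <- filter_spec("low_pass", 500, config$fs_hz)
  emg <- matrix(0, nrow = 4L, ncol = n,
                dimnames = list(emg_channel_names(), NULL))
  for (ch in 1:4) {
    carrier <- butterworth_filter(stats::rnorm(n), hp)
    carrier <- butterworth_filter(carrier, lp)
    carrier <- carrier / stats::sd(carrier)
    emg[ch, ] <- config$amplitude_scale_uV[ch] * env[, ch] * carrier
  }
  emg <- pmin(pmax(emg, -1600), 1600)
  new_emg_recording(emg, angle, config$fs_hz)
}

new_emg_recording <- function(emg_uV, angle_deg, fs_hz) {
  stopifnot(nrow(emg_uV) == 4L, ncol(emg_uV) == length(angle_deg))
  if (any(angle_deg < 0 | angle_deg > 145))
    stop("angle trace outside the anthropometric elbow range [0, 145] deg")
  structure(list(emg_uV = emg_uV, angle_deg = angle_deg, fs_hz = fs_hz,
                 labels = emg_channel_names()),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "emg_recording: 4 channels x %d samples at %g Hz (%.2f s), angle %g-%g deg\n",
    ncol(x$emg_uV), x$fs_hz, ncol(x$emg_uV) / x$fs_hz,
    min(x$angle_deg), max(x$angle_deg)))
  invisible(x)
}

# Counter-based per-trial seed derivation: independent trials, reproducible
# sessions, values kept below 2^31.
derive_trial_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + i * 7919) %% 2147483647)
}

#' Generate a session of independent trials
#'
#' Repeats [generate_trial()] `n_trials` times (protocol default 60 movement
#' sets per motion period) with per-trial seeds derived from the master seed
#' in `config` by a counter-based scheme, so sessions are reproducible while
#' trials stay independent.
#'
#' @param config A [trial_config()]; its `seed` acts as the master seed.
#' @param params An [activation_params()].
#' @param n_trials Number of trials (default 60).
#' @return List of `emg_recording` objects.
#' @export
generate_session <- function(config, params = activation_params(),
                             n_trials = 60L) {
  stopifnot(inherits(config, "trial_config"))
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("n_trials must be >= 1")
  lapply(seq_len(n_trials), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_trial_seed(config$seed, i)
    generate_trial(cfg_i, params)
  })
}
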