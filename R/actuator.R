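#' McKibben pneumatic-muscle parameters
#'
#' Constants of the braided pneumatic muscle force law
#' \eqn{F = P [a (1-\varepsilon)^2 - b]} with
#' \eqn{a = 3\pi D_0^2 / (4 \tan^2\theta_0)} and
#' \eqn{b = \pi D_0^2 / (4 \sin^2\theta_0)}. Defaults are the actuator used
#' on the exoskeleton joint: 20 mm initial diameter, 25 degree initial
#' braiding angle, 25% maximum contraction, 0.6 MPa pressure ceiling.
#'
#' @param D0_m Initial diameter in metres (default 0.020).
#' @param theta0_deg Initial fiber braiding angle in degrees (default 25;
#'   must lie in (0, 90)).
#' @param eps_max Maximum contraction rate (default 0.25).
#' @param P_max_Pa Highest admissible pressure in Pa (default 0.6e6).
#' @return A `muscle_params` object with derived geometric constants
#'   `a_m2` and `b_m2`. For braiding angles below 54.7 degrees `a > b`, so
#'   force at zero contraction is positive.
#' @export
muscle_params <- function(D0_m = 0.020, theta0_deg = 25, eps_max = 0.25,
                          P_max_Pa = 0.6e6) {
  if (theta0_deg <= 0 || theta0_deg >= 90)
    stop("theta0_deg must lie in (0, 90)")
  if (D0_m <= 0 || eps_max <= 0 || eps_max >= 1 || P_max_Pa <= 0)
    stop("invalid muscle parameters")
  th <- theta0_deg * pi / 180
  a <- 3 * pi * D0_m^2 / (4 * tan(th)^2)
  b <- pi * D0_m^2 / (4 * sin(th)^2)
  structure(list(D0_m = D0_m, theta0_deg = theta0_deg, eps_max = eps_max,
                 P_max_Pa = P_max_Pa, a_m2 = a, b_m2 = b),
            class = "muscle_params")
}

#' Antagonistic-joint geometry and initial state
#'
#' The two muscles wrap an axis of radius `R_m`; at elbow angle 0 both sit
#' at contraction rate `eps0` under pressure `P0_Pa` with equal force.
#' Defaults (`L0_m = 0.40`, `eps0 = 0.125`, `P0_Pa = 0.3e6`) are chosen so
#' the full 0-90 degree range is reachable within the 25% maximum
#' contraction and the 0.6 MPa ceiling: at 90 degrees the agonist reaches
#' contraction 0.2428 and the antagonist 0.0072.
#'
#' @param R_m Joint axis radius in metres (default 0.03, a 6 cm diameter
#'   nylon axis).
#' @param L0_m Muscle initial length in metres (default 0.40).
#' @param eps0 Initial contraction rate at elbow angle 0 (default 0.125).
#' @param P0_Pa Initial (balanced) air pressure in Pa (default 0.3e6).
#' @param theta2_range_deg Admissible elbow range (default `c(0, 90)`).
#' @param params A [muscle_params()] used for the reachability check.
#' @return A `joint_geometry` object; `F0_N` is the balanced initial force
#'   `P0 [a (1-eps0)^2 - b]`.
#' @export
joint_geometry <- function(R_m = 0.03, L0_m = 0.40, eps0 = 0.125,
                           P0_Pa = 0.3e6, theta2_range_deg = c(0, 90),
                           params = muscle_params()) {
  if (R_m <= 0 || L0_m <= 0) stop("R_m and L0_m must be positive")
  if (P0_Pa <= 0 || P0_Pa > params$P_max_Pa)
    stop("P0_Pa must lie in (0, P_max_Pa]")
  dl_max <- max(abs(theta2_range_deg)) * pi * R_m / 180
  if (eps0 + dl_max / L0_m > params$eps_max)
    stop("unreachable range: eps0 + max delta L / L0 exceeds eps_max")
  if (eps0 - dl_max / L0_m < 0)
    stop("unreachable range: antagonist contraction would become negative")
  F0 <- P0_Pa * (params$a_m2 * (1 - eps0)^2 - params$b_m2)
  structure(list(R_m = R_m, L0_m = L0_m, eps0 = eps0, P0_Pa = P0_Pa,
                 F0_N = F0, theta2_range_deg = theta2_range_deg),
            class = "joint_geometry")
}

#' Pneumatic-muscle contraction force
#'
#' \eqn{F = P [a (1-\varepsilon)^2 - b]}: linear in pressure, decreasing in
#' contraction rate, crossing zero at the zero-force contraction rate
#' \eqn{\varepsilon^* = 1 - 1/(\sqrt{3} \cos\theta_0)} (about 0.363 for a
#' 25 degree braid). Values beyond \eqn{\varepsilon^*} are returned as
#' negative forces; staying in range is the caller's responsibility.
#'
#' @param P_Pa Air pressure in Pa (>= 0). Vectorized.
#' @param eps Contraction rate in \[0, 1). Vectorized.
#' @param params A [muscle_params()].
#' @return Contraction force in newtons.
#' @export
muscle_force <- function(P_Pa, eps, params = muscle_params()) {
  if (any(P_Pa < 0)) stop("invalid input: pressure must be >= 0")
  if (any(eps >= 1) || any(eps < 0))
    stop("invalid input: contraction rate must lie in [0, 1)")
  P_Pa * (params$a_m2 * (1 - eps)^2 - params$b_m2)
}

#' Zero-force contraction rate
#'
#' The contraction rate at which the force law crosses zero:
#' `1 - 1/(sqrt(3) * cos(theta0))`.
#'
#' @param params A [muscle_params()].
#' @return Scalar contraction rate.
#' @export
zero_force_contraction <- function(params = muscle_params()) {
  1 - 1 / (sqrt(3) * cos(params$theta0_deg * pi / 180))
}

#' Muscle length change for an elbow angle
#'
#' Arc length on the joint axis: \eqn{\Delta L = \theta_2 \pi R / 180}
#' (the one place degrees are converted to radians).
#'
#' @param theta2_deg Elbow angle in degrees. Vectorized.
#' @param geom A [joint_geometry()].
#' @return Length change in metres.
#' @export
delta_length <- function(theta2_deg, geom = joint_geometry()) {
  theta2_deg * pi * geom$R_m / 180
}

#' Contraction rates of the antagonistic pair
#'
#' The agonist shortens and the antagonist lengthens by the same arc:
#' \eqn{\varepsilon_a = \varepsilon_0 + \Delta L / L_0},
#' \eqn{\varepsilon_b = \varepsilon_0 - \Delta L / L_0}; their sum is
#' \eqn{2 \varepsilon_0} at every angle.
#'
#' @param theta2_deg Elbow angle in degrees (scalar or vector).
#' @param geom A [joint_geometry()].
#' @param params A [muscle_params()] for the range check.
#' @return List with `eps_a` and `eps_b`.
#' @export
contraction_rates <- function(theta2_deg, geom = joint_geometry(),
                              params = muscle_params()) {
  dl <- delta_length(theta2_deg, geom) / geom$L0_m
  eps_a <- geom$eps0 + dl
  eps_b <- geom$eps0 - dl
  if (any(eps_a > params$eps_max))
    stop("range exceeded: agonist contraction ", max(eps_a),
         " above eps_max ", params$eps_max)
  if (any(eps_b < 0))
    stop("range exceeded: antagonist contraction ", min(eps_b),
         " below zero")
  list(eps_a = eps_a, eps_b = eps_b)
}

#' Forces of the pair under a differential pressure
#'
#' With pressures \eqn{P_0 + \Delta P} and \eqn{P_0 - \Delta P}:
#' \eqn{F_a = (P_0+\Delta P)[a(1-\varepsilon_a)^2 - b]},
#' \eqn{F_b = (P_0-\Delta P)[a(1-\varepsilon_b)^2 - b]}.
#'
#' @param theta2_deg Elbow angle in degrees.
#' @param dP_Pa Differential pressure in Pa.
#' @param geom A [joint_geometry()].
#' @param params A [muscle_params()].
#' @return List with `F_a` and `F_b` in newtons.
#' @export
pair_forces <- function(theta2_deg, dP_Pa, geom = joint_geometry(),
                        params = muscle_params()) {
  Pa <- geom$P0_Pa + dP_Pa
  Pb <- geom$P0_Pa - dP_Pa
  if (any(Pa < 0 | Pa > params$P_max_Pa | Pb < 0 | Pb > params$P_max_Pa))
    stop("saturation: absolute pressure outside [0, P_max]")
  eps <- contraction_rates(theta2_deg, geom, params)
  list(F_a = Pa * (params$a_m2 * (1 - eps$eps_a)^2 - params$b_m2),
       F_b = Pb * (params$a_m2 * (1 - eps$eps_b)^2 - params$b_m2))
}

#' Differential pressure from the pair forces
#'
#' Inverts the force pair at a known angle:
#' \eqn{\Delta P = F_a / (2[a(1-\varepsilon_a)^2-b]) -
#'                 F_b / (2[a(1-\varepsilon_b)^2-b])}
#' with the contraction rates substituted from the joint kinematics. It is
#' the exact algebraic inverse of [pair_forces()] in \eqn{\Delta P}.
#'
#' @param theta2_deg Elbow angle in degrees.
#' @param F_a,F_b Contraction forces in newtons.
#' @param geom A [joint_geometry()].
#' @param params A [muscle_params()].
#' @return Differential pressure in Pa.
#' @export
pressure_signal <- function(theta2_deg, F_a, F_b, geom = joint_geometry(),
                            params = muscle_params()) {
  eps <- contraction_rates(theta2_deg, geom, params)
  Ka <- params$a_m2 * (1 - eps$eps_a)^2 - params$b_m2
  Kb <- params$a_m2 * (1 - eps$eps_b)^2 - params$b_m2
  if (any(abs(Ka) < 1e-12) || any(abs(Kb) < 1e-12))
    stop("singular configuration: contraction at the zero-force rate")
  F_a / (2 * Ka) - F_b / (2 * Kb)
}

#' Convert a target elbow angle to an actuator command
#'
#' The pressure inversion needs a force pair, which requires a torque
#' assumption the hardware description leaves open. Two closures are
#' provided:
#' \describe{
#'   \item{`"gravity"` (default)}{the antagonist holds the force it would
#'     produce at base pressure `P0` at its new length; the agonist force
#'     balances the antagonist plus the gravitational torque
#'     `load_kg * 9.81 * forearm_m * sin(theta2)` of the held mass.}
#'   \item{`"symmetric"`}{total force held at `2 F0` (constant
#'     co-contraction) while the force difference supplies the
#'     gravitational torque.}
#' }
#' The resulting differential pressure is clamped so both absolute
#' pressures stay in `[0, P_max]` (streaming semantics; pass
#' `clamp = FALSE` for a hard error instead), then mapped to a valve
#' voltage via [pressure_to_voltage()].
#'
#' @param theta2_deg Target elbow angle in degrees.
#' @param geom A [joint_geometry()].
#' @param params A [muscle_params()].
#' @param closure `"gravity"` or `"symmetric"`.
#' @param load_kg Held mass in kg (default 1).
#' @param forearm_m Load moment arm in metres (default 0.25, the upper end
#'   of the lower-arm link length).
#' @param clamp Clamp out-of-range pressures (default TRUE) or error.
#' @return An `actuator_command`: list with `theta2_deg`, `dP_Pa`, `Pa_Pa`,
#'   `Pb_Pa`, `F_a`, `F_b`, `voltage_V`, `saturated`.
#' @export
angle_to_command <- function(theta2_deg, geom = joint_geometry(),
                             params = muscle_params(),
                             closure = c("gravity", "symmetric"),
                             load_kg = 1, forearm_m = 0.25, clamp = TRUE) {
  closure <- match.arg(closure)
  rng <- geom$theta2_range_deg
  if (theta2_deg < rng[1] || theta2_deg > rng[2])
    stop("angle ", theta2_deg, " outside admissible range [",
         rng[1], ", ", rng[2], "]")
  eps <- contraction_rates(theta2_deg, geom, params)
  Ka <- params$a_m2 * (1 - eps$eps_a)^2 - params$b_m2
  Kb <- params$a_m2 * (1 - eps$eps_b)^2 - params$b_m2
  tau <- load_kg * 9.81 * forearm_m * sin(theta2_deg * pi / 180)
  if (closure == "gravity") {
    F_b <- geom$P0_Pa * Kb
    F_a <- F_b + tau / geom$R_m
  } else {
    F_a <- geom$F0_N + tau / (2 * geom$R_m)
    F_b <- geom$F0_N - tau / (2 * geom$R_m)
  }
  dP <- pressure_signal(theta2_deg, F_a, F_b, geom, params)
  headroom <- c(-min(geom$P0_Pa, params$P_max_Pa - geom$P0_Pa),
                min(geom$P0_Pa, params$P_max_Pa - geom$P0_Pa))
  saturated <- dP < headroom[1] || dP > headroom[2]
  if (saturated && !clamp)
    stop("saturation: required differential pressure ", signif(dP, 5),
         " Pa outside headroom at angle ", theta2_deg)
  dP <- min(max(dP, headroom[1]), headroom[2])
  structure(list(theta2_deg = theta2_deg, dP_Pa = dP,
                 Pa_Pa = geom$P0_Pa + dP, Pb_Pa = geom$P0_Pa - dP,
                 F_a = F_a, F_b = F_b,
                 voltage_V = pressure_to_voltage(dP, geom, params),
                 saturated = saturated),
            class = "actuator_command")
}

#' Map a differential pressure to a valve voltage
#'
#' The valve relationship is hardware-specific; the default map is affine
#' over the symmetric headroom `[-dP_max, +dP_max]` onto `[0, 10]` V with
#' 5 V at zero differential pressure. A monotone calibration table
#' (`data.frame` with columns `dP_Pa`, `voltage_V`) may be supplied and is
#' linearly interpolated.
#'
#' @param dP_Pa Differential pressure in Pa (scalar or vector).
#' @param geom A [joint_geometry()].
#' @param params A [muscle_params()].
#' @param calibration Optional monotone calibration table.
#' @return Voltage in volts.
#' @export
pressure_to_voltage <- function(dP_Pa, geom = joint_geometry(),
                                params = muscle_params(),
                                calibration = NULL) {
  dP_max <- min(geom$P0_Pa, params$P_max_Pa - geom$P0_Pa)
  if (any(abs(dP_Pa) > dP_max + 1e-9))
    stop("saturation: |dP| exceeds headroom ", dP_max, " Pa")
  if (is.null(calibration))
    return(5 + 5 * dP_Pa / dP_max)
  if (!all(c("dP_Pa", "voltage_V") %in% names(calibration)))
    stop("calibration table needs columns dP_Pa and voltage_V")
  if (is.unsorted(calibration$dP_Pa, strictly = TRUE) ||
      is.unsorted(calibration$voltage_V))
    stop("calibration table must be monotone in both columns")
  stats::approx(calibration$dP_Pa, calibration$voltage_V, xout = dP_Pa,
                rule = 2)$y
}
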