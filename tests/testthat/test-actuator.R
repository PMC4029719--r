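test_that("muscle force: linearity in pressure, zero at P = 0", {
  mp <- muscle_params()
  expect_equal(muscle_force(0, 0.1, mp), 0)
  expect_equal(muscle_force(2e5, 0.1, mp), 2 * muscle_force(1e5, 0.1, mp))
  expect_error(muscle_force(-1, 0.1, mp), "invalid input")
  expect_error(muscle_force(1e5, 1, mp), "invalid input")
})

test_that("zero-force contraction rate matches the closed form and a root find", {
  mp <- muscle_params()  # theta0 = 25 deg
  closed <- 1 - 1 / (sqrt(3) * cos(25 * pi / 180))
  expect_equal(zero_force_contraction(mp), closed, tolerance = 1e-12)
  expect_equal(closed, 0.3630, tolerance = 1e-4)
  root <- uniroot(function(e) muscle_force(1e5, e, mp),
                  c(0.01, 0.9), tol = 1e-14)$root
  expect_equal(root, closed, tolerance = 1e-10)
})

test_that("force decreases in contraction and increases in pressure", {
  mp <- muscle_params()
  eps <- seq(0, 0.3, by = 0.01)
  P <- seq(1e5, 6e5, by = 1e4)
  for (p in c(1e5, 3e5, 6e5))
    expect_true(all(diff(muscle_force(p, eps, mp)) < 0))
  for (e in c(0, 0.125, 0.25))
    expect_true(all(diff(muscle_force(P, e, mp)) > 0))
})

test_that("delta_length is the joint arc length", {
  g <- joint_geometry()
  expect_equal(delta_length(0, g), 0)
  expect_equal(delta_length(90, g), 0.0471239, tolerance = 1e-6)
  expect_equal(delta_length(60, g), 2 * delta_length(30, g))
})

test_that("contraction rates: values, symmetry, range errors", {
  g <- joint_geometry()
  mp <- muscle_params()
  e0 <- contraction_rates(0, g, mp)
  expect_equal(e0$eps_a, g$eps0)
  expect_equal(e0$eps_b, g$eps0)
  e90 <- contraction_rates(90, g, mp)
  expect_equal(e90$eps_a, 0.24281, tolerance = 1e-4)
  expect_equal(e90$eps_b, 0.00719, tolerance = 1e-4)
  th <- seq(0, 90, by = 5)
  ee <- contraction_rates(th, g, mp)
  expect_equal(ee$eps_a + ee$eps_b, rep(2 * g$eps0, length(th)))
  expect_error(contraction_rates(120, g, mp), "range exceeded")
})

test_that("reachability holds across the full default range", {
  g <- joint_geometry()
  mp <- muscle_params()
  ee <- contraction_rates(seq(0, 90, by = 1), g, mp)
  expect_true(all(ee$eps_a <= mp$eps_max))
  expect_true(all(ee$eps_b >= 0))
  expect_error(joint_geometry(R_m = 0.05), "unreachable")
})

test_that("pair forces: balanced initial state and force asymmetry", {
  g <- joint_geometry()
  mp <- muscle_params()
  f0 <- pair_forces(0, 0, g, mp)
  expect_equal(f0$F_a, g$F0_N)
  expect_equal(f0$F_b, g$F0_N)
  f45 <- pair_forces(45, 0, g, mp)
  expect_lt(f45$F_a, f45$F_b)  # more contracted -> less force
  expect_error(pair_forces(0, 0.9e6, g, mp), "saturation")
})

test_that("pressure_signal special cases", {
  g <- joint_geometry()
  mp <- muscle_params()
  expect_equal(pressure_signal(0, 100, 100, g, mp), 0)
  K0 <- mp$a_m2 * (1 - g$eps0)^2 - mp$b_m2
  expect_equal(pressure_signal(0, 100, 0, g, mp), 100 / (2 * K0))
})

test_that("pressure inversion recovers dP across the admissible box", {
  g <- joint_geometry()
  mp <- muscle_params()
  set.seed(12)
  th <- runif(1000, 0, 90)
  dP <- runif(1000, -g$P0_Pa, mp$P_max_Pa - g$P0_Pa)
  for (i in seq_len(1000)) {
    f <- pair_forces(th[i], dP[i], g, mp)
    rec <- pressure_signal(th[i], f$F_a, f$F_b, g, mp)
    expect_equal(rec, dP[i], tolerance = 1e-9)
  }
})

test_that("angle_to_command: neutral at 0, monotone dP, guards", {
  g <- joint_geometry()
  mp <- muscle_params()
  c0 <- angle_to_command(0, g, mp)
  expect_equal(c0$dP_Pa, 0)
  expect_equal(c0$voltage_V, 5)
  dps <- vapply(seq(0, 90, by = 1),
                function(th) angle_to_command(th, g, mp)$dP_Pa,
                numeric(1))
  expect_true(all(diff(dps) >= -1e-9))
  expect_error(angle_to_command(95, g, mp), "outside admissible range")
  # symmetric closure also neutral at zero and finite at 90
  cs <- angle_to_command(90, g, mp, closure = "symmetric")
  expect_true(is.finite(cs$dP_Pa))
  expect_false(cs$saturated)
  expect_equal(angle_to_command(0, g, mp, closure = "symmetric")$dP_Pa, 0)
})

test_that("clamping vs strict mode at saturated angles", {
  g <- joint_geometry()
  mp <- muscle_params()
  # the gravity closure saturates near full flexion with default P0
  c90 <- angle_to_command(90, g, mp)
  expect_true(c90$saturated)
  expect_lte(c90$Pa_Pa, mp$P_max_Pa)
  expect_gte(c90$Pb_Pa, 0)
  expect_error(angle_to_command(90, g, mp, clamp = FALSE), "saturation")
})

test_that("pressure-to-voltage default map and calibration tables", {
  g <- joint_geometry()
  mp <- muscle_params()
  dP_max <- min(g$P0_Pa, mp$P_max_Pa - g$P0_Pa)
  expect_equal(pressure_to_voltage(0, g, mp), 5)
  expect_equal(pressure_to_voltage(dP_max, g, mp), 10)
  expect_equal(pressure_to_voltage(-dP_max, g, mp), 0)
  expect_error(pressure_to_voltage(2 * dP_max, g, mp), "saturation")
  set.seed(13)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    tab <- data.frame(dP_Pa = sort(runif(n, -dP_max, dP_max)),
                      voltage_V = sort(runif(n, 0, 10)))
    dp <- sort(runif(50, min(tab$dP_Pa), max(tab$dP_Pa)))
    v <- pressure_to_voltage(dp, g, mp, calibration = tab)
    expect_true(all(diff(v) >= -1e-12))
  }
})
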