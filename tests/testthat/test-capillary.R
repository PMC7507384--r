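# Single filtering-capillary model: Poiseuille resistance, closed-form
# pressure profile, end flows, CSGFR, protein profile, filtration-resistance
# consistency update.

test_that("Poiseuille resistance has the right value and scaling", {
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  # hand evaluation in CGS: 128 * 0.0124 P * 20.9e-4 cm / (pi * (8.3e-4)^4)
  expect_equal(R, 128 * 0.0124 * 20.9e-4 / (pi * (8.3e-4)^4), tolerance = 1e-12)
  expect_equal(R, 2.225e9, tolerance = 1e-3)
  expect_equal(poiseuille_resistance(16.6, 20.9, 1.24), R / 16, tolerance = 1e-12)
  expect_equal(poiseuille_resistance(8.3, 41.8, 1.24), 2 * R, tolerance = 1e-12)
})

test_that("non-filtering limit reduces to a linear resistor", {
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  prof <- solve_pressure_profile(52, 48, 13, R, Inf, 20.9)
  q <- end_flows(prof)
  expect_equal(q[["Q_in"]], q[["Q_out"]], tolerance = 1e-12)
  expect_equal(q[["Q_in"]], (52 - 48) * 1333.22 / R / (1e-6 / 60),
               tolerance = 1e-10)
  expect_equal(csgfr(prof), 0, tolerance = 1e-15)
  # theta = 1e-6: still a resistor to high accuracy
  prof2 <- solve_pressure_profile(52, 48, 13, R, R / 1e-12, 20.9)
  expect_equal(end_flows(prof2)[["Q_in"]], q[["Q_in"]], tolerance = 1e-10)
})

test_that("equilibrium end pressures give zero flow and zero filtrate", {
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  prof <- solve_pressure_profile(13, 13, 13, R, 100 * R, 20.9)
  expect_equal(unname(end_flows(prof)), c(0, 0))
  expect_equal(csgfr(prof), 0)
  expect_equal(mean_pressure(prof), 13)
})

test_that("symmetric filtering segment: outflow from both ends, closed-form CSGFR", {
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  R_f <- 4 * R # theta = 0.5
  prof <- solve_pressure_profile(50, 50, 13, R, R_f, 20.9)
  q <- end_flows(prof)
  expect_equal(q[["Q_in"]], -q[["Q_out"]], tolerance = 1e-12)
  # CSGFR = 2 u tanh(theta/2) / sqrt(R R_f)
  u <- (50 - 13) * 1333.22
  expected <- 2 * u * tanh(0.25) / sqrt(R * R_f) / (1e-6 / 60)
  expect_equal(csgfr(prof), expected, tolerance = 1e-12)
  expect_equal(csgfr(prof), q[["Q_in"]] - q[["Q_out"]], tolerance = 1e-12)
})

test_that("closed form matches the finite-difference BVP oracle", {
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  prof <- solve_pressure_profile(52, 48, 13, R, R / 0.25, 20.9) # theta = 0.5
  fd <- fd_bvp_rich(52, 48, 13, R, R / 0.25, 20.9)
  q <- end_flows(prof)
  scale <- max(abs(q))
  expect_lt(abs(q[["Q_in"]] - fd$Q_in), 1e-8 * scale)
  expect_lt(abs(q[["Q_out"]] - fd$Q_out), 1e-8 * scale)
  expect_lt(abs(csgfr(prof) - fd$csgfr), 1e-8 * scale)
  # interior pressures (spot check mid-segment)
  fd_u <- fd_bvp(52, 48, 13, R, R / 0.25, 20.9, n = 1e4)
  u_mid <- glomsim:::profile_u(prof, 0.5)
  expect_equal(u_mid, fd_u$u[5001], tolerance = 1e-8)
})

test_that("closed form matches the oracle over a randomized parameter sweep", {
  set.seed(7)
  for (r in 1:100) {
    D <- runif(1, 2.5, 20); L <- runif(1, 3, 100); mu <- runif(1, 1.2, 4)
    R <- poiseuille_resistance(D, L, mu)
    theta <- runif(1, 0.01, 1.5)
    p_i <- runif(1, 45, 60); p_j <- runif(1, 40, p_i); p_BS <- 13
    prof <- solve_pressure_profile(p_i, p_j, p_BS, R, R / theta^2, L)
    fd <- fd_bvp_rich(p_i, p_j, p_BS, R, R / theta^2, L)
    q <- end_flows(prof)
    scale <- max(abs(q)) # one shared flow scale; Q_out may pass through 0
    expect_lt(abs(q[["Q_in"]] - fd$Q_in), 1e-7 * scale)
    expect_lt(abs(q[["Q_out"]] - fd$Q_out), 1e-7 * scale)
    expect_lt(abs(csgfr(prof) - fd$csgfr), 1e-7 * scale)
    expect_equal(csgfr(prof), q[["Q_in"]] - q[["Q_out"]], tolerance = 1e-10)
    # interior pressure profile against the 1e4-point grid (every 10th point)
    fd10 <- fd_bvp(p_i, p_j, p_BS, R, R / theta^2, L, n = 1e4)
    u <- glomsim:::profile_u(prof, seq(0, 1, length.out = 1001))
    expect_lt(max(abs(u - fd10$u[seq(1, 1e4 + 1, by = 10)])),
              1e-7 * max(abs(u)))
  }
})

test_that("pressure profile stays within its sanity envelope for moderate theta", {
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  s <- seq(0, 1, length.out = 101)
  for (theta in c(0.05, 0.3, 1)) {
    prof <- solve_pressure_profile(55, 47, 13, R, R / theta^2, 20.9)
    p <- 13 + glomsim:::profile_u(prof, s) / 1333.22
    expect_true(all(p <= 55 + 1e-9))
    expect_true(all(p >= 13)) # never below Bowman's space while filtering
    if (end_flows(prof)[["Q_out"]] > 0) {
      # while flow still exits the far end the profile is monotone and
      # bounded by its end pressures; at larger theta filtration may drain
      # the segment from both ends, putting the minimum in the interior
      expect_true(all(p >= 47 - 1e-9))
      expect_true(all(diff(p) < 0))
    }
  }
})

test_that("protein profile follows plasma mass balance", {
  expect_equal(protein_profile(5.94, 1, 0.2, 1), 5.94)
  expect_equal(protein_profile(5.94, 1, 0.2, 0.9), 5.94 * 0.8 / 0.7)
  expect_equal(protein_profile(5.94, 1, 0.2, 0.9), 6.789, tolerance = 1e-3)
  expect_error(protein_profile(5.94, 1, 0.2, 0.2), "exhausted")
})

test_that("filtration-resistance update: osmosis-free limit and dense-grid oracle", {
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  prof <- solve_pressure_profile(52, 48, 13, R, R / 0.01, 20.9) # theta = 0.1
  k <- 2e-5
  # Pi = 0 (zero protein): R_f = 1 / (k pi D L)
  rf0 <- update_filtration_resistance(prof, C0 = 0, E = 0, k = k, D = 8.3)
  k_cgs <- k * (1e-6 / 60) / 1333.22 / 1e-8
  expect_equal(as.numeric(rf0), 1 / (k_cgs * pi * 8.3e-4 * 20.9e-4),
               tolerance = 1e-9)
  expect_true(attr(rf0, "filtering"))
  # dense trapezoid oracle for the osmotic integral
  rf <- update_filtration_resistance(prof, C0 = 5.94, E = 0.1, k = k, D = 8.3)
  s <- seq(0, 1, length.out = 1e5 + 1)
  u <- glomsim:::profile_u(prof, s)
  qx <- glomsim:::profile_q(prof, s) / (1e-6 / 60)
  q0 <- qx[1]
  Cx <- 5.94 * (q0 - 0.1) / (qx - 0.1)
  Pi <- (2.1 * Cx + 0.16 * Cx^2 + 0.009 * Cx^3) * 1333.22
  h <- 1 / 1e5
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * h)
  L_cm <- 20.9e-4
  int_u <- trap(u) * L_cm
  int_pi <- trap(Pi) * L_cm
  rf_oracle <- int_u / (k_cgs * pi * 8.3e-4 * L_cm * (int_u - int_pi))
  expect_equal(as.numeric(rf), rf_oracle, tolerance = 1e-8)
})

test_that("osmotic pressure exceeding the hydrostatic drive flags non-filtering", {
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  # transmural pressure ~2 mmHg, Pi(5.94) ~ 20 mmHg
  prof <- solve_pressure_profile(15.5, 14.5, 13, R, R / 0.01, 20.9)
  rf <- update_filtration_resistance(prof, C0 = 5.94, E = 0, k = 2e-5, D = 8.3)
  expect_false(attr(rf, "filtering"))
  expect_identical(as.numeric(rf), Inf)
  prof_nf <- solve_pressure_profile(15.5, 14.5, 13, R, as.numeric(rf), 20.9)
  expect_equal(csgfr(prof_nf), 0)
})
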