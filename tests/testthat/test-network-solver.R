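# Network assembly, protein/erythrocyte propagation, and the fixed-point
# iteration: resistor-algebra checks, independent nodal-analysis oracle,
# conservation laws, and hemodynamic monotonicities.

test_that("two equal non-filtering segments in series form a voltage divider", {
  net <- chain_net(1) # inlet - A - outlet, two identical segments
  R <- poiseuille_resistance(c(8.3, 8.3), c(20.9, 20.9), c(1.24, 1.24))
  bc <- boundary_conditions(p_a = 115, p_e = 13, p_BS = 13,
                            R_AA = 1e10, R_EA = 1e10)
  p <- assemble_and_solve_pressures(net, R, c(Inf, Inf), bc)
  expect_equal(p[["2"]], (p[["1"]] + p[["3"]]) / 2, tolerance = 1e-12)
})

test_that("with all filtration off the solver matches independent nodal analysis", {
  net <- small_net(2)
  ns <- nrow(net$segments)
  set.seed(9)
  mu <- runif(ns, 1.2, 3)
  R <- poiseuille_resistance(net$segments$D_um, net$segments$L_um, mu)
  bc <- boundary_conditions(R_AA = 3e10, R_EA = 1.5e10)
  p <- assemble_and_solve_pressures(net, R, rep(Inf, ns), bc)
  inlet <- which(net$nodes$kind == "afferent_inlet")
  outlet <- which(net$nodes$kind == "efferent_outlet")
  u_oracle <- nodal_analysis(as.matrix(net$segments[, c("i", "j")]), R,
                             nrow(net$nodes), inlet, outlet,
                             bc$R_AA, bc$R_EA,
                             (115 - 13) * 1333.22, 0)
  expect_equal(unname(p), 13 + u_oracle / 1333.22, tolerance = 1e-10)
})

test_that("a single filtering segment draws its filtrate from both ends", {
  net <- two_node_net()
  R <- poiseuille_resistance(8.3, 20.9, 1.24)
  R_f <- 4 * R
  bc <- boundary_conditions(p_a = 60, p_e = 50, p_BS = 13,
                            R_AA = 1e9, R_EA = 1e9)
  p <- assemble_and_solve_pressures(net, R, R_f, bc)
  prof <- solve_pressure_profile(p[["1"]], p[["2"]], 13, R, R_f, 20.9)
  q <- end_flows(prof)
  # Kirchhoff at both nodes: arteriolar inflow equals segment end flow
  q_in_art <- (60 - p[["1"]]) * 1333.22 / 1e9 / (1e-6 / 60)
  q_out_art <- (p[["2"]] - 50) * 1333.22 / 1e9 / (1e-6 / 60)
  expect_equal(q[["Q_in"]], q_in_art, tolerance = 1e-9)
  expect_equal(q[["Q_out"]], q_out_art, tolerance = 1e-9)
  expect_equal(csgfr(prof), q_in_art - q_out_art, tolerance = 1e-9)
})

test_that("protein concentrations chain along a path and mix at junctions", {
  # chain: C0 of each segment equals C at the end of its predecessor
  net <- chain_net(2)
  ns <- nrow(net$segments)
  R <- poiseuille_resistance(net$segments$D_um, net$segments$L_um,
                             rep(1.24, ns))
  bc <- boundary_conditions(R_AA = 1e10, R_EA = 1e10)
  p <- assemble_and_solve_pressures(net, R, rep(2e10, ns), bc)
  pr <- propagate_erythrocytes_and_proteins(net, p, R, rep(2e10, ns), bc)
  expect_equal(pr$C0[2], pr$C_end[1], tolerance = 1e-12)
  expect_equal(pr$C0[3], pr$C_end[2], tolerance = 1e-12)
  expect_equal(pr$C0[1], bc$C_A)
})

test_that("node mixing is the plasma-flow-weighted mean of entering streams", {
  # diamond with equal branches: downstream C0 is the mean of the two branch
  # exit concentrations (equal plasma flows by symmetry)
  net <- diamond_net(D = c(10, 8, 8, 10), L = 20)
  ns <- 4
  R <- poiseuille_resistance(net$segments$D_um, net$segments$L_um,
                             rep(1.24, ns))
  bc <- boundary_conditions(R_AA = 5e9, R_EA = 5e9)
  R_f <- rep(3e10, ns)
  p <- assemble_and_solve_pressures(net, R, R_f, bc)
  pr <- propagate_erythrocytes_and_proteins(net, p, R, R_f, bc)
  expect_equal(pr$C0[4], mean(pr$C_end[2:3]), tolerance = 1e-10)
  expect_equal(pr$C_end[2], pr$C_end[3], tolerance = 1e-10)
})

test_that("k = 0 yields the pure-resistor solution with zero SNGFR", {
  st <- fixed_point_solve(small_net(1), boundary_conditions(), k = 0)
  expect_true(st$metrics$converged)
  expect_equal(st$metrics$SNGFR, 0, tolerance = 1e-8)
  expect_true(all(!st$segments$filtering))
})

test_that("converged states satisfy all conservation laws", {
  st <- default_state()
  m <- st$metrics
  expect_true(m$converged)
  expect_gt(m$SNGFR, 1)
  # sum of per-segment filtrate equals SNGFR
  expect_equal(sum(st$segments$CSGFR), m$SNGFR, tolerance = 1e-10)
  # blood volume: inflow = outflow + filtrate
  expect_equal(m$Q_A_blood, m$Q_E_blood + m$SNGFR,
               tolerance = 1e-8 * m$Q_A_blood)
  # erythrocyte volume conserved exactly (no erythrocyte filtration)
  expect_equal(m$E_in, m$E_out, tolerance = 1e-10 * m$E_in)
  # protein mass: C_A Q_A(plasma) = C_E Q_E(plasma)
  expect_equal(m$Q_A * st$bc$C_A, m$Q_E * m$C_E,
               tolerance = 1e-8 * m$Q_A * st$bc$C_A)
  # corollary: C_E = C_A Q_A / (Q_A - SNGFR)
  expect_equal(m$C_E, st$bc$C_A * m$Q_A / (m$Q_A - m$SNGFR),
               tolerance = 1e-8)
})

test_that("filtration concentrates proteins and raises hematocrit downstream", {
  st <- default_state()
  m <- st$metrics
  expect_gt(m$C_E, st$bc$C_A)
  ht_e <- m$E_out / m$Q_E_blood
  expect_gt(ht_e, m$Ht_A)
  # some downstream segments reach filtration equilibrium
  expect_gt(sum(!st$segments$filtering), 0)
})

test_that("hemodynamics respond monotonically to R_AA and inlet pressure", {
  net <- small_net(1)
  k <- 2e-5
  sol <- function(raa, pa) {
    st <- fixed_point_solve(net, boundary_conditions(p_a = pa, R_AA = raa,
                                                     R_EA = 1.5e10), k = k)
    c(st$metrics$P_GC, st$metrics$Q_A)
  }
  s1 <- sol(2e10, 115); s2 <- sol(4e10, 115); s3 <- sol(8e10, 115)
  expect_true(s1[1] > s2[1] && s2[1] > s3[1]) # P_GC falls with R_AA
  expect_true(s1[2] > s2[2] && s2[2] > s3[2]) # Q_A falls with R_AA
  s4 <- sol(2e10, 130)
  expect_true(s4[1] > s1[1] && s4[2] > s1[2]) # both rise with MAP
})

test_that("solution is stable to the convergence tolerance", {
  net <- small_net(1)
  bc <- boundary_conditions(R_AA = 2.5e10, R_EA = 1.7e10)
  s1 <- fixed_point_solve(net, bc, k = 2e-5,
                          settings = solver_settings(tol = 1e-5))
  s2 <- fixed_point_solve(net, bc, k = 2e-5,
                          settings = solver_settings(tol = 2e-5))
  expect_equal(s1$metrics$SNGFR, s2$metrics$SNGFR, tolerance = 1e-3)
})
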