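# Calibration, filtration coefficient, filtering surface area, scenario runs,
# sweeps and occlusion, on reduced synthetic anatomies.

test_that("k calibration hits its target and recovers a known conductivity", {
  net <- small_net(1)
  bc <- boundary_conditions(R_AA = 2.2e10, R_EA = 1.6e10)
  # zero target
  k0 <- calibrate_k(net, bc, target_SNGFR = 0)
  expect_identical(as.numeric(k0), 0)
  # forward solve at a known k*, then recover it from the achieved SNGFR
  k_star <- 1.8e-5
  st <- fixed_point_solve(net, bc, k = k_star)
  expect_true(st$metrics$converged)
  kfit <- calibrate_k(net, bc, target_SNGFR = st$metrics$SNGFR)
  expect_equal(as.numeric(kfit), k_star, tolerance = 0.01)
  expect_equal(attr(kfit, "state")$metrics$SNGFR, st$metrics$SNGFR,
               tolerance = 1e-3)
})

test_that("unattainable SNGFR targets (beyond filtration equilibrium) error", {
  net <- small_net(1)
  bc <- boundary_conditions(R_AA = 2.2e10, R_EA = 1.6e10)
  st <- fixed_point_solve(net, bc, k = 1e-3) # plateau
  expect_error(calibrate_k(net, bc, target_SNGFR = 2 * st$metrics$SNGFR),
               "unattainable")
})

test_that("resistance calibration recovers forward-simulated resistances", {
  net <- small_net(1)
  k <- 2e-5
  bc_true <- boundary_conditions(R_AA = 3.1e10, R_EA = 1.4e10)
  st <- fixed_point_solve(net, bc_true, k = k)
  fit <- calibrate_arteriolar_resistances(
    net, boundary_conditions(R_AA = 5e10, R_EA = 1e10), k = k,
    target_P_GC = st$metrics$P_GC, target_Q_A = st$metrics$Q_A)
  expect_equal(fit$R_AA, 3.1e10, tolerance = 0.01)
  expect_equal(fit$R_EA, 1.4e10, tolerance = 0.01)
  expect_equal(fit$P_GC, st$metrics$P_GC, tolerance = 0.05 / st$metrics$P_GC)
  expect_equal(fit$Q_A, st$metrics$Q_A, tolerance = 1e-3)
})

test_that("raising the P_GC target lowers fitted R_AA and raises R_EA", {
  net <- small_net(1)
  k <- 2e-5
  bc <- boundary_conditions(R_AA = 2.5e10, R_EA = 1.5e10)
  st <- fixed_point_solve(net, bc, k = k)
  f1 <- calibrate_arteriolar_resistances(net, bc, k = k,
                                         target_P_GC = st$metrics$P_GC,
                                         target_Q_A = st$metrics$Q_A)
  f2 <- calibrate_arteriolar_resistances(net, bc, k = k,
                                         target_P_GC = st$metrics$P_GC + 3,
                                         target_Q_A = st$metrics$Q_A)
  expect_lt(f2$R_AA, f1$R_AA)
  expect_gt(f2$R_EA, f1$R_EA)
})

test_that("filtering surface area: k -> 0 limit and non-increasing k sweep", {
  net <- small_net(1)
  bc <- boundary_conditions(R_AA = 2.2e10, R_EA = 1.6e10)
  total <- summarize_network(net)$total_surface_area
  ks <- c(2e-6, 8e-6, 3e-5, 1e-4, 4e-4)
  states <- lapply(ks, function(k) fixed_point_solve(net, bc, k = k))
  sf <- vapply(states, filtering_surface_area, numeric(1))
  sngfr <- vapply(states, function(s) s$metrics$SNGFR, numeric(1))
  # tiny k: nothing reaches equilibrium, everything filters
  expect_equal(sf[1], total, tolerance = 1e-6)
  expect_true(all(diff(sf) <= 1e-9 * total))
  # SNGFR increases and saturates
  expect_true(all(diff(sngfr) > 0))
  gain_lo <- (sngfr[2] - sngfr[1]) / (ks[2] - ks[1])
  gain_hi <- (sngfr[5] - sngfr[4]) / (ks[5] - ks[4])
  expect_lt(gain_hi, 0.05 * gain_lo)
})

test_that("two-segment chain: equilibrium downstream segment leaves S_f = pi D1 L1", {
  # a long upstream segment concentrates protein past the downstream
  # segment's transmural drive, shutting its filtration off
  net <- glom_network(
    nodes = data.frame(id = 1:3, kind = c("afferent_inlet", "interior",
                                          "efferent_outlet")),
    segments = data.frame(id = 1:2, i = 1:2, j = 2:3,
                          L_um = c(400, 100), D_um = 8.3))
  bc <- boundary_conditions(p_a = 52, p_e = 13, p_BS = 13, R_AA = 1e9,
                            R_EA = 8e10, C_A = 6.5)
  st <- fixed_point_solve(net, bc, k = 3e-4)
  sg <- st$segments
  expect_true(st$metrics$converged)
  # downstream: colloid osmotic pressure exceeds the transmural drive
  expect_gt(colloid_osmotic_pressure(sg$C0[2]), sg$p_mean[2] - bc$p_BS)
  expect_identical(sg$filtering, c(TRUE, FALSE))
  expect_equal(filtering_surface_area(st), pi * 8.3 * 400)
})

test_that("K_f two ways: homogeneous-limit agreement and the network bias", {
  # single segment, negligible protein: both estimates agree
  net <- two_node_net(D = 8.3, L = 20.9)
  bc <- boundary_conditions(R_AA = 1e10, R_EA = 1e10, C_A = 1e-6)
  k <- 2e-5
  st <- fixed_point_solve(net, bc, k = k)
  kf <- kf_two_ways(st)
  expect_equal(kf$K_f_product, k * pi * 8.3 * 20.9, tolerance = 1e-6)
  expect_equal(kf$K_f_equation, kf$K_f_product, tolerance = 5e-3)
  # network case: the filtration-equation estimate is biased low
  st2 <- fixed_point_solve(small_net(1),
                           boundary_conditions(R_AA = 2.2e10, R_EA = 1.6e10),
                           k = k)
  kf2 <- kf_two_ways(st2)
  expect_gt(kf2$K_f_product, kf2$K_f_equation)
})

test_that("scenario runs are deterministic and honour structural changes", {
  net <- small_net(1)
  cfg <- scenario_config(name = "toy", R_AA = 2.5e10, R_EA = 1.5e10,
                         C_A = 5.94, t_bm = 149.82, p_BS = 13, MAP = 115,
                         target_P_GC = 48, target_Q_A = 110,
                         target_SNGFR = 26)
  r1 <- run_scenario(cfg, net)
  r2 <- run_scenario(cfg, net)
  expect_identical(r1$calibration, r2$calibration)
  expect_equal(r1$calibration$P_GC, 48, tolerance = 0.05 / 48)
  expect_equal(r1$calibration$Q_A, 110, tolerance = 1e-3)
  expect_equal(r1$calibration$SNGFR, 26, tolerance = 1e-3)
  expect_gt(r1$calibration$K_f_product, r1$calibration$K_f_equation)
})

test_that("sensitivity sweeps reproduce the expected monotonicities", {
  net <- small_net(1)
  cfg <- scenario_config(name = "toy", R_AA = 2.5e10, R_EA = 1.5e10,
                         C_A = 5.94, t_bm = 149.82, p_BS = 13, MAP = 115,
                         target_P_GC = 48, target_Q_A = 110,
                         target_SNGFR = 26)
  k <- 2e-5
  sw_r <- sensitivity_sweep("R_AA", c(1.5e10, 3e10, 6e10), cfg, net, k)
  expect_true(all(diff(sw_r$mean_tau) < 0))
  expect_true(all(diff(sw_r$mean_sigma) < 0))
  sw_m <- sensitivity_sweep("MAP", c(100, 115, 130), cfg, net, k)
  expect_true(all(diff(sw_m$mean_tau) > 0))
  expect_true(all(diff(sw_m$mean_sigma) > 0))
  sw_h <- sensitivity_sweep("h_pod", c(200, 300, 400), cfg, net, k)
  expect_true(all(diff(sw_h$mean_sigma) < 0)) # thicker wall, lower hoop stress
  expect_equal(sw_h$mean_tau, rep(sw_h$mean_tau[1], 3), tolerance = 1e-10)
})

test_that("single-segment occlusion: total occlusion and near-inlet dominance", {
  # occluding the only segment kills filtration and flow
  net1 <- two_node_net()
  bc1 <- boundary_conditions(R_AA = 1e10, R_EA = 1e10)
  occ <- single_segment_occlusion(net1, bc1, k = 2e-5, segment_id = 1)
  expect_equal(occ$d_SNGFR_pct, -100, tolerance = 0.01)
  # on a network, occluding near the arterioles matters most
  net <- small_net(1)
  bc <- boundary_conditions(R_AA = 2.2e10, R_EA = 1.6e10)
  base <- fixed_point_solve(net, bc, k = 2e-5)
  dist <- bifurcation_distance(net)
  ids <- net$segments$id
  pick <- c(ids[which(dist == 0)[1:2]], ids[order(-dist)[1:2]],
            ids[which(dist == floor(max(dist) / 2))[1:2]])
  pick <- pick[!is.na(pick)]
  occ <- do.call(rbind, lapply(pick, function(id)
    single_segment_occlusion(net, bc, k = 2e-5, segment_id = id,
                             baseline = base)))
  worst <- occ$bifurcation_distance[which.max(abs(occ$d_SNGFR_pct))]
  expect_lte(min(occ$bifurcation_distance), 1)
  expect_true(worst <= 1 || worst >= max(dist) - 1) # nearest either arteriole
})
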