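# Calibration and scenario machinery: fit arteriolar resistances to target
# glomerular pressure and afferent plasma flow, fit hydraulic conductivity to
# target SNGFR, compute the filtration coefficient two ways, and run the
# disease-condition presets and sensitivity sweeps.

#' Scenario configuration
#'
#' One row of the simulation-parameter table: arteriolar resistances, afferent
#' protein concentration, basement-membrane thickness, Bowman's-space
#' pressure, mean arterial pressure, structural remodeling (uniform diameter
#' scale), and the micropuncture calibration targets.
#'
#' @param name scenario label.
#' @param R_AA,R_EA starting arteriolar resistances, dyn s/cm^5.
#' @param C_A afferent plasma protein concentration, g/dl.
#' @param t_bm basement-membrane thickness, nm.
#' @param p_BS Bowman's-space pressure, mmHg.
#' @param MAP mean arterial pressure (inlet boundary), mmHg.
#' @param p_e peritubular capillary pressure (outlet boundary), mmHg.
#' @param diameter_scale uniform factor applied to every capillary diameter
#'   (capillary remodeling; 1 = none).
#' @param target_P_GC,target_Q_A,target_SNGFR calibration targets: mean
#'   glomerular capillary pressure (mmHg), afferent plasma flow (nl/min),
#'   SNGFR (nl/min).
#' @return a list of class \code{scenario_config}.
#' @export
scenario_config <- function(name, R_AA, R_EA, C_A, t_bm, p_BS, MAP,
                            p_e = 13, diameter_scale = 1,
                            target_P_GC, target_Q_A, target_SNGFR) {
  stopifnot(R_AA > 0, R_EA > 0, C_A > 0, t_bm >= 0, diameter_scale > 0,
            MAP > target_P_GC)
  structure(list(name = name, R_AA = R_AA, R_EA = R_EA, C_A = C_A,
                 t_bm = t_bm, p_BS = p_BS, MAP = MAP, p_e = p_e,
                 diameter_scale = diameter_scale,
                 target_P_GC = target_P_GC, target_Q_A = target_Q_A,
                 target_SNGFR = target_SNGFR), class = "scenario_config")
}

#' Bundled scenario presets
#'
#' Reads one of the shipped YAML presets: \code{"base"}, and the paired
#' control/disease rows \code{"zatz_control"}/\code{"dm"} (diabetes),
#' \code{"kasiske_control"}/\code{"nx56"} (5/6-nephrectomy),
#' \code{"franco_control"}/\code{"htn"} (angiotensin II hypertension).
#'
#' @param name preset name.
#' @return a \code{\link{scenario_config}}.
#' @export
scenario_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "glomsim")
  if (path == "") stop("unknown preset: ", name)
  y <- yaml::read_yaml(path)
  # YAML 1.1 only recognises scientific notation with an explicit sign
  # ("5.5e+10"); tolerate the bare form by coercing scalars ourselves
  y <- rapply(y, function(v)
    if (is.character(v) && !is.na(suppressWarnings(as.numeric(v))))
      as.numeric(v) else v, how = "replace")
  scenario_config(name = y$name, R_AA = y$R_AA, R_EA = y$R_EA, C_A = y$C_A,
                  t_bm = y$t_bm_nm, p_BS = y$p_BS, MAP = y$MAP,
                  p_e = if (is.null(y$p_e)) 13 else y$p_e,
                  diameter_scale = y$diameter_scale,
                  target_P_GC = y$targets$P_GC, target_Q_A = y$targets$Q_A,
                  target_SNGFR = y$targets$SNGFR)
}

bc_from_config <- function(cfg, R_AA = cfg$R_AA, R_EA = cfg$R_EA) {
  boundary_conditions(p_a = cfg$MAP, p_e = cfg$p_e, p_BS = cfg$p_BS,
                      R_AA = R_AA, R_EA = R_EA, C_A = cfg$C_A)
}

apply_diameter_scale <- function(net, scale) {
  if (scale == 1) return(net)
  net$segments$D_um[!net$segments$junction] <-
    net$segments$D_um[!net$segments$junction] * scale
  net
}

#' Calibrate hydraulic conductivity to a target SNGFR
#'
#' Bracketed scalar root-find on k (SNGFR is monotone non-decreasing and
#' saturating in k): the converged model SNGFR matches the target within
#' 0.1\%.
#'
#' @param net a \code{\link{glom_network}}.
#' @param bc \code{\link{boundary_conditions}}.
#' @param rheology \code{\link{rheology_params}}.
#' @param target_SNGFR target, nl/min.
#' @param settings \code{\link{solver_settings}}.
#' @param bracket search interval for k, nl/(min mmHg um^2).
#' @return fitted k with attribute \code{state} (the converged
#'   \code{network_state} at the fit).
#' @export
calibrate_k <- function(net, bc, rheology = rheology_params(), target_SNGFR,
                        settings = solver_settings(),
                        bracket = c(1e-6, 1e-3)) {
  if (target_SNGFR == 0) {
    st <- fixed_point_solve(net, bc, rheology, k = 0, settings = settings)
    return(structure(0, state = st))
  }
  f <- function(k) {
    st <- fixed_point_solve(net, bc, rheology, k = k, settings = settings)
    st$metrics$SNGFR - target_SNGFR
  }
  f_hi <- f(bracket[2])
  if (f_hi < 0)
    stop("SNGFR target unattainable: above the filtration-equilibrium plateau")
  f_lo <- f(bracket[1])
  if (f_lo > 0) stop("SNGFR target below the model value at the smallest k")
  root <- stats::uniroot(f, interval = bracket, f.lower = f_lo,
                         f.upper = f_hi, tol = bracket[1] * 1e-3)
  k <- root$root
  st <- fixed_point_solve(net, bc, rheology, k = k, settings = settings)
  if (abs(st$metrics$SNGFR - target_SNGFR) / target_SNGFR > 5e-4) {
    # polish locally (uniroot's tolerance is on k, not on SNGFR)
    root <- stats::uniroot(f, interval = k * c(0.95, 1.05),
                           extendInt = "upX", tol = k * 1e-6)
    k <- root$root
    st <- fixed_point_solve(net, bc, rheology, k = k, settings = settings)
  }
  structure(k, state = st)
}

#' Calibrate arteriolar resistances to target P_GC and Q_A
#'
#' Damped quasi-Newton iteration on (log R_AA, log R_EA) with a
#' finite-difference Jacobian, converged when the achieved mean glomerular
#' capillary pressure is within 0.05 mmHg of its target and the afferent
#' plasma flow within 0.1\%.
#'
#' @inheritParams calibrate_k
#' @param k hydraulic conductivity held fixed during the fit.
#' @param target_P_GC target mean glomerular capillary pressure, mmHg.
#' @param target_Q_A target afferent plasma flow, nl/min.
#' @param max_iter Newton iteration cap.
#' @return list with \code{R_AA}, \code{R_EA}, the achieved \code{P_GC} and
#'   \code{Q_A}, \code{state}, \code{iterations}, \code{converged}.
#' @export
calibrate_arteriolar_resistances <- function(net, bc,
                                             rheology = rheology_params(),
                                             k, target_P_GC, target_Q_A,
                                             settings = solver_settings(),
                                             max_iter = 40) {
  stopifnot(bc$p_a > target_P_GC)
  eval_at <- function(z) {
    bcz <- bc; bcz$R_AA <- exp(z[1]); bcz$R_EA <- exp(z[2])
    st <- fixed_point_solve(net, bcz, rheology, k, settings)
    list(st = st, r = c(st$metrics$P_GC - target_P_GC,
                        100 * (st$metrics$Q_A - target_Q_A) / target_Q_A))
  }
  ok <- function(r) abs(r[1]) < 0.05 && abs(r[2]) < 0.1
  z <- log(c(bc$R_AA, bc$R_EA))
  cur <- eval_at(z)
  it <- 0L
  while (!ok(cur$r) && it < max_iter) {
    it <- it + 1L
    h <- 0.02
    J <- matrix(0, 2, 2)
    for (q in 1:2) {
      zq <- z; zq[q] <- zq[q] + h
      J[, q] <- (eval_at(zq)$r - cur$r) / h
    }
    step <- tryCatch(-solve(J, cur$r),
                     error = function(e) stop("singular Jacobian in resistance calibration"))
    step <- pmin(pmax(step, -1.5), 1.5) # trust region in log units
    lam <- 1
    repeat {
      cand <- eval_at(z + lam * step)
      if (sum(cand$r^2) < sum(cur$r^2) || lam < 1 / 16) break
      lam <- lam / 2
    }
    z <- z + lam * step
    cur <- cand
  }
  if (!ok(cur$r))
    stop(sprintf("resistance calibration did not converge: residuals dP_GC=%.3f mmHg, dQ_A=%.3f%%",
                 cur$r[1], cur$r[2]))
  list(R_AA = exp(z[1]), R_EA = exp(z[2]),
       P_GC = cur$st$metrics$P_GC, Q_A = cur$st$metrics$Q_A,
       state = cur$st, iterations = it, converged = TRUE)
}

#' Filtering surface area
#'
#' Lateral surface area \eqn{\sum \pi D L} over the segments that filter
#' (positive filtrate; segments driven to filtration equilibrium are
#' excluded).
#'
#' @param state a \code{network_state}.
#' @return filtering surface area, um^2.
#' @export
filtering_surface_area <- function(state) {
  sg <- state$segments[!state$segments$junction, ]
  sum(pi * sg$D_um * sg$L_um * (sg$filtering & sg$CSGFR > 0))
}

#' Filtration coefficient computed two ways
#'
#' Direct product \eqn{K_f = k S_f} versus the glomerular filtration equation
#' \eqn{K_f = SNGFR / (\Delta P - \bar\Pi)} with \eqn{\Delta P = P_{GC} -
#' p_{BS}} and \eqn{\bar\Pi} the average of afferent and efferent colloid
#' osmotic pressures. The equation-based estimate is biased low because the
#' two-point average understates the network mean osmotic pressure.
#'
#' @param state a converged \code{network_state}.
#' @param k hydraulic conductivity, nl/(min mmHg um^2); defaults to the
#'   state's.
#' @return list with \code{K_f_product}, \code{K_f_equation} (nl/(min mmHg)),
#'   \code{S_f} (um^2), and \code{filtration_equilibrium} (logical; equation
#'   undefined when the net driving pressure is non-positive).
#' @export
kf_two_ways <- function(state, k = state$k) {
  m <- state$metrics
  s_f <- filtering_surface_area(state)
  dp <- m$P_GC - state$bc$p_BS
  eq_flag <- dp <= m$mean_Pi
  list(K_f_product = k * s_f,
       K_f_equation = if (eq_flag) NA_real_ else m$SNGFR / (dp - m$mean_Pi),
       S_f = s_f, filtration_equilibrium = eq_flag)
}

#' Run a full scenario: structural changes, joint calibration, stress report
#'
#' Applies the scenario's diameter scale and basement-membrane thickness,
#' calibrates the arteriolar resistances to (P_GC, Q_A) and the hydraulic
#' conductivity to SNGFR (alternating to joint convergence), and reports the
#' calibration result plus the stress summary.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param net a \code{\link{glom_network}} (unscaled).
#' @param rheology \code{\link{rheology_params}}.
#' @param settings \code{\link{solver_settings}}.
#' @param wall \code{\link{wall_params}}; the scenario's \code{t_bm}
#'   overrides the basement-membrane thickness.
#' @param k_init starting hydraulic conductivity, nl/(min mmHg um^2).
#' @param rounds cap on resistance/conductivity alternations.
#' @return list of class \code{scenario_result}: \code{calibration} (fitted
#'   R_AA, R_EA, k, achieved targets, K_f both ways, S_f, the reported
#'   micropuncture-convention R_AA), \code{state}, \code{stress}.
#' @export
run_scenario <- function(config, net, rheology = rheology_params(),
                         settings = solver_settings(),
                         wall = wall_params(), k_init = 2e-5, rounds = 10) {
  net_s <- apply_diameter_scale(net, config$diameter_scale)
  wall$t_bm <- config$t_bm
  k <- k_init
  fit <- NULL
  bc <- bc_from_config(config)
  for (r in seq_len(rounds)) {
    fit <- tryCatch(
      calibrate_arteriolar_resistances(net_s, bc, rheology, k,
                                       config$target_P_GC, config$target_Q_A,
                                       settings),
      error = function(e) stop("scenario '", config$name, "': ",
                               conditionMessage(e)))
    bc$R_AA <- fit$R_AA; bc$R_EA <- fit$R_EA
    kfit <- tryCatch(
      calibrate_k(net_s, bc, rheology, config$target_SNGFR, settings),
      error = function(e) stop("scenario '", config$name, "': ",
                               conditionMessage(e)))
    k <- as.numeric(kfit)
    st <- attr(kfit, "state")
    m <- st$metrics
    if (abs(m$P_GC - config$target_P_GC) < 0.05 &&
        abs(m$Q_A - config$target_Q_A) / config$target_Q_A < 1e-3 &&
        abs(m$SNGFR - config$target_SNGFR) / config$target_SNGFR < 1e-3)
      break
  }
  st <- attr(kfit, "state")
  kf <- kf_two_ways(st, k)
  m <- st$metrics
  # micropuncture reporting convention: afferent blood flow computed with the
  # systemic hematocrit (no microvascular reduction)
  qa_blood_rep <- m$Q_A / (1 - rheology$Ht_sys)
  r_aa_rep <- mmHg_to_cgs(config$MAP - m$P_GC) / nlmin_to_cgs(qa_blood_rep)
  stress <- stress_summary(st, wall)
  structure(list(
    calibration = list(name = config$name,
                       R_AA = bc$R_AA, R_EA = bc$R_EA, k = k,
                       R_AA_micropuncture = r_aa_rep,
                       P_GC = m$P_GC, Q_A = m$Q_A, SNGFR = m$SNGFR,
                       FF = m$FF, mean_Pi = m$mean_Pi,
                       K_f_product = kf$K_f_product,
                       K_f_equation = kf$K_f_equation, S_f = kf$S_f,
                       iterations = m$iterations, converged = m$converged),
    state = st, stress = stress, config = config), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cb <- x$calibration
  cat(sprintf("scenario '%s' (calibrated)\n", cb$name))
  cat(sprintf("  R_AA %.3g, R_EA %.3g dyn s/cm^5 | k %.3g nl/(min mmHg um^2)\n",
              cb$R_AA, cb$R_EA, cb$k))
  cat(sprintf("  P_GC %.2f mmHg | Q_A %.2f nl/min | SNGFR %.3f nl/min | FF %.3f\n",
              cb$P_GC, cb$Q_A, cb$SNGFR, cb$FF))
  cat(sprintf("  K_f %.3f (product) vs %.3f (filtration equation) nl/(min mmHg) | S_f %.4g um^2\n",
              cb$K_f_product, cb$K_f_equation, cb$S_f))
  cat(sprintf("  mean tau %.1f dyn/cm^2 | mean sigma %.1f kPa\n",
              x$stress$tau["mean"], x$stress$sigma["mean"]))
  invisible(x)
}

#' Sensitivity sweep of a single parameter
#'
#' Forward solves (fixed k, no recalibration) across a parameter grid and
#' tabulates mean stresses and global hemodynamics.
#'
#' @param parameter one of \code{"R_AA"}, \code{"diameter_scale"},
#'   \code{"MAP"}, \code{"h_pod"}.
#' @param grid numeric vector of parameter values.
#' @param config a \code{\link{scenario_config}} providing the operating
#'   point.
#' @param net a \code{\link{glom_network}}.
#' @param k hydraulic conductivity, nl/(min mmHg um^2).
#' @param rheology,settings,wall see \code{\link{run_scenario}}.
#' @return data.frame: value, mean_tau, mean_sigma, SNGFR, P_GC, Q_A,
#'   converged.
#' @export
sensitivity_sweep <- function(parameter = c("R_AA", "diameter_scale", "MAP",
                                            "h_pod"),
                              grid, config, net, k,
                              rheology = rheology_params(),
                              settings = solver_settings(),
                              wall = wall_params()) {
  parameter <- match.arg(parameter)
  wall$t_bm <- config$t_bm
  rows <- lapply(grid, function(v) {
    cfg <- config; w <- wall
    if (parameter == "diameter_scale") cfg$diameter_scale <- v
    if (parameter == "MAP") cfg$MAP <- v
    if (parameter == "h_pod") w$h_pod <- v
    bc <- bc_from_config(cfg, R_AA = if (parameter == "R_AA") v else cfg$R_AA)
    st <- tryCatch(
      fixed_point_solve(apply_diameter_scale(net, cfg$diameter_scale),
                        bc, rheology, k, settings),
      error = function(e) NULL)
    if (is.null(st) || !st$metrics$converged) {
      if (!is.null(st)) warning("sweep point ", v, " did not converge")
      return(data.frame(value = v, mean_tau = NA, mean_sigma = NA,
                        SNGFR = NA, P_GC = NA, Q_A = NA, converged = FALSE))
    }
    rep <- stress_summary(st, w)
    data.frame(value = v, mean_tau = rep$tau[["mean"]],
               mean_sigma = rep$sigma[["mean"]],
               SNGFR = st$metrics$SNGFR, P_GC = st$metrics$P_GC,
               Q_A = st$metrics$Q_A, converged = TRUE)
  })
  do.call(rbind, rows)
}

#' Effect of occluding a single capillary segment
#'
#' Re-solves the network with one segment's diameter set to 0.1 um (k fixed)
#' and reports percent changes in SNGFR and mean stresses relative to the
#' baseline solve, tagged with the segment's bifurcation distance.
#'
#' @param net a \code{\link{glom_network}}.
#' @param bc \code{\link{boundary_conditions}}.
#' @param k hydraulic conductivity, nl/(min mmHg um^2).
#' @param segment_id segment to occlude.
#' @param rheology,settings,wall see \code{\link{run_scenario}}.
#' @param baseline optional precomputed baseline \code{network_state} (reused
#'   across calls when occluding many segments).
#' @return one-row data.frame: segment_id, bifurcation_distance,
#'   d_SNGFR_pct, d_tau_pct, d_sigma_pct.
#' @export
single_segment_occlusion <- function(net, bc, k, segment_id,
                                     rheology = rheology_params(),
                                     settings = solver_settings(),
                                     wall = wall_params(),
                                     baseline = NULL) {
  if (is.null(baseline))
    baseline <- fixed_point_solve(net, bc, rheology, k, settings)
  base_rep <- stress_summary(baseline, wall, force = TRUE)
  net2 <- net
  idx <- match(segment_id, net2$segments$id)
  if (is.na(idx)) stop("unknown segment id")
  net2$segments$D_um[idx] <- 0.1
  st <- fixed_point_solve(net2, bc, rheology, k, settings)
  rep2 <- stress_summary(st, wall, force = TRUE)
  pct <- function(a, b) 100 * (a - b) / b
  data.frame(segment_id = segment_id,
             bifurcation_distance = bifurcation_distance(net, segment_id),
             d_SNGFR_pct = pct(st$metrics$SNGFR, baseline$metrics$SNGFR),
             d_tau_pct = pct(rep2$tau[["mean"]], base_rep$tau[["mean"]]),
             d_sigma_pct = pct(rep2$sigma[["mean"]], base_rep$sigma[["mean"]]))
}
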