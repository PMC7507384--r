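# Filtering-network solver.
#
# Node pressures solve a sparse symmetric linear system in u = p - p_BS:
# each capillary contributes the hyperbolic two-port of the filtering
# capillary model (end flows Q(0) = alpha u_i - beta u_j,
# Q(L) = beta u_i - alpha u_j with alpha = (theta/tanh theta)/R,
# beta = (theta/sinh theta)/R), and the afferent/efferent arterioles are
# ordinary conductances to the fixed boundary pressures. Erythrocytes and
# plasma proteins are then propagated through the flow-oriented graph, the
# filtration resistances and apparent viscosities are updated, and the whole
# map is iterated to a fixed point.

#' Boundary conditions of the glomerular network
#'
#' @param p_a inlet pressure (mean arterial pressure), mmHg.
#' @param p_e outlet (peritubular capillary) pressure, mmHg.
#' @param p_BS Bowman's-space pressure, mmHg.
#' @param R_AA,R_EA afferent / efferent arteriolar resistances, dyn s/cm^5.
#' @param C_A afferent plasma protein concentration, g/dl.
#' @param Ht_A afferent (discharge) hematocrit; default
#'   \code{f_Ht * Ht_sys} from the rheology parameters at solve time.
#' @return a list of class \code{boundary_conditions}.
#' @export
boundary_conditions <- function(p_a = 115, p_e = 13, p_BS = 13,
                                R_AA = 5.5e10, R_EA = 1.0e10,
                                C_A = 5.94, Ht_A = NULL) {
  stopifnot(p_a > p_e, p_a > p_BS, R_AA > 0, R_EA > 0, C_A > 0)
  structure(list(p_a = p_a, p_e = p_e, p_BS = p_BS,
                 R_AA = R_AA, R_EA = R_EA, C_A = C_A, Ht_A = Ht_A),
            class = "boundary_conditions")
}

#' Fixed-point solver settings
#'
#' @param tol relative convergence tolerance on every apparent viscosity and
#'   filtration resistance (default 1e-5, i.e. 0.001\%).
#' @param max_iter iteration cap.
#' @param relax under-relaxation factor on the filtration-conductance and
#'   viscosity updates (1 recovers plain iteration).
#' @param rf_sentinel_factor the non-filtering sentinel filtration resistance
#'   is this multiple of the largest hydraulic segment resistance.
#' @param stagnant_tol segments with |mean flow| below this fraction of the
#'   afferent blood inflow are treated as quasi-stagnant: they carry no
#'   erythrocytes and keep a uniform protein concentration (steady
#'   convection-dominated transport is meaningless at such flows, and the
#'   spurious concentration amplification on a near-zero flow otherwise
#'   destabilises the fixed point).
#' @param quad_nodes Gauss-Legendre points for the osmotic-pressure integral.
#' @return a list of class \code{solver_settings}.
#' @export
solver_settings <- function(tol = 1e-5, max_iter = 400, relax = 0.5,
                            rf_sentinel_factor = 1e12,
                            stagnant_tol = 1e-4, quad_nodes = 32) {
  stopifnot(tol > 0, tol < 1, max_iter >= 1, relax > 0, relax <= 1)
  structure(list(tol = tol, max_iter = max_iter, relax = relax,
                 rf_sentinel_factor = rf_sentinel_factor,
                 stagnant_tol = stagnant_tol, quad_nodes = quad_nodes),
            class = "solver_settings")
}

.glom_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n) {
  key <- paste0("gl", n)
  if (is.null(.glom_cache[[key]])) {
    g <- pracma::gaussLegendre(n, 0, 1)
    .glom_cache[[key]] <- list(x = g$x, w = g$w)
  }
  .glom_cache[[key]]
}

# precompute index structures for the solver
prep_network <- function(net) {
  sg <- net$segments
  list(net = net, n = nrow(net$nodes),
       node_ids = net$nodes$id,
       ei = match(sg$i, net$nodes$id), ej = match(sg$j, net$nodes$id),
       inlet = match(inlet_id(net), net$nodes$id),
       outlet = match(outlet_id(net), net$nodes$id),
       D_um = sg$D_um, L_um = sg$L_um,
       D_cm = um_to_cm(sg$D_um), L_cm = um_to_cm(sg$L_um),
       junction = sg$junction, seg_id = sg$id)
}

# sparse symmetric nodal solve in u = p - p_BS (CGS); returns node u vector
solve_pressures_cgs <- function(prep, R, R_f, bc) {
  theta <- ifelse(is.finite(R_f), sqrt(R / R_f), 0)
  al <- f_coth(theta) / R
  be <- f_csch(theta) / R
  ii <- c(prep$ei, prep$ej, prep$ei, prep$ej, prep$inlet, prep$outlet)
  jj <- c(prep$ei, prep$ej, prep$ej, prep$ei, prep$inlet, prep$outlet)
  xx <- c(al, al, -be, -be, 1 / bc$R_AA, 1 / bc$R_EA)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(prep$n, prep$n))
  b <- numeric(prep$n)
  b[prep$inlet] <- mmHg_to_cgs(bc$p_a - bc$p_BS) / bc$R_AA
  b[prep$outlet] <- b[prep$outlet] + mmHg_to_cgs(bc$p_e - bc$p_BS) / bc$R_EA
  u <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop("singular nodal system (disconnected network?): ",
                                         conditionMessage(e)))
  u
}

#' Solve node pressures for given segment resistances
#'
#' Assembles and solves the sparse filtration-aware nodal system. Exposed for
#' testing and diagnostics; \code{\link{fixed_point_solve}} drives it.
#'
#' @param net a \code{\link{glom_network}}.
#' @param R per-segment hydraulic resistances, dyn s/cm^5.
#' @param R_f per-segment filtration resistances, dyn s/cm^5 (\code{Inf}
#'   allowed).
#' @param bc \code{\link{boundary_conditions}}.
#' @return named numeric vector of node pressures, mmHg.
#' @export
assemble_and_solve_pressures <- function(net, R, R_f, bc) {
  prep <- prep_network(net)
  u <- solve_pressures_cgs(prep, R, R_f, bc)
  stats::setNames(bc$p_BS + cgs_to_mmHg(u), prep$node_ids)
}

# per-segment derived quantities from node u (all CGS); orientation fwd means
# flow runs i -> j
segment_flows <- function(prep, u, R, R_f) {
  theta <- ifelse(is.finite(R_f), sqrt(R / R_f), 0)
  u_i <- u[prep$ei]; u_j <- u[prep$ej]
  al <- f_coth(theta) / R
  be <- f_csch(theta) / R
  q0 <- al * u_i - be * u_j
  qL <- be * u_i - al * u_j
  list(theta = theta, u_i = u_i, u_j = u_j,
       q0 = q0, qL = qL,
       q_mean = (u_i - u_j) / R,
       csgfr = q0 - qL,
       u_mean = (u_i + u_j) * f_mean(theta))
}

# Propagate erythrocytes and plasma proteins through the flow-oriented graph.
# Node potentials order the sweep (flow always runs down the transmural
# pressure u, so ordering nodes by decreasing u is a topological order).
# Returns per-segment E (CGS), entry concentration C0, exit concentration
# C_end, plus the efferent (outlet) mixed concentration.
propagate_cgs <- function(prep, u, fl, bc, rheo, settings) {
  ns <- length(prep$ei)
  fwd <- fl$q_mean >= 0
  from <- ifelse(fwd, prep$ei, prep$ej)
  to <- ifelse(fwd, prep$ej, prep$ei)
  q_in <- ifelse(fwd, fl$q0, -fl$qL)   # oriented entry flow (>= 0 normally)
  q_out <- ifelse(fwd, fl$qL, -fl$q0)  # oriented exit flow

  Ht_A <- if (is.null(bc$Ht_A)) rheo$f_Ht * rheo$Ht_sys else bc$Ht_A
  qa_blood <- (mmHg_to_cgs(bc$p_a - bc$p_BS) - u[prep$inlet]) / bc$R_AA
  q_rel <- abs(fl$q_mean) / max(qa_blood, 1e-300)
  stag <- q_rel < settings$stagnant_tol
  # smooth stagnancy weight (0 below the threshold, 1 above 3x): used to
  # taper erythrocyte routing continuously, so segments hovering at the
  # threshold do not flip their hematocrit between iterations
  fs <- pmin(1, pmax(0, (q_rel - settings$stagnant_tol) /
                       (2 * settings$stagnant_tol)))

  E <- numeric(ns)
  C0 <- rep(bc$C_A, ns)
  C_end <- rep(bc$C_A, ns)

  node_E <- numeric(prep$n)
  node_mass <- numeric(prep$n)   # protein mass flow, C * plasma flow
  node_plasma <- numeric(prep$n)
  node_blood <- numeric(prep$n)
  node_D <- numeric(prep$n)      # flow-weighted incoming diameter

  node_E[prep$inlet] <- Ht_A * qa_blood
  node_plasma[prep$inlet] <- (1 - Ht_A) * qa_blood
  node_blood[prep$inlet] <- qa_blood
  node_mass[prep$inlet] <- bc$C_A * node_plasma[prep$inlet]

  out_of <- split(seq_len(ns), from)
  ord <- order(u, decreasing = TRUE)
  for (v in ord) {
    segs <- out_of[[as.character(v)]]
    if (is.null(segs)) next
    plasma_v <- node_plasma[v]
    Cv <- if (plasma_v > 0) node_mass[v] / plasma_v else bc$C_A
    Ev <- node_E[v]
    blood_v <- node_blood[v]

    live <- segs[fs[segs] > 0 & q_in[segs] > 0]
    if (!length(live) && Ev > 0)
      live <- segs[q_in[segs] > 0] # all outflows stagnant: pass E through
    C0[segs] <- Cv
    # erythrocyte partition among live outgoing segments; stagnancy weights
    # taper the law's fractions continuously, renormalised so the node
    # conserves erythrocytes exactly
    if (length(live) == 1) {
      E[live] <- Ev
    } else if (length(live) >= 2 && Ev > 0) {
      if (length(live) == 2) {
        fq <- q_in[live[1]] / sum(q_in[live])
        D_par <- if (node_D[v] > 0) node_D[v] else
          sum(prep$D_um[live] * q_in[live]) / sum(q_in[live])
        Ht_f <- if (blood_v > 0) min(Ev / blood_v, 0.99) else 0
        f1 <- split_fraction(fq, prep$D_um[live[1]], prep$D_um[live[2]],
                             D_par, Ht_f, rheo)
        w <- c(f1, 1 - f1) * fs[live]
      } else {
        w <- q_in[live] * fs[live] # no bifurcation law beyond 2 daughters
      }
      if (sum(w) > 0) E[live] <- Ev * w / sum(w)
      else E[live] <- Ev * q_in[live] / sum(q_in[live])
    }
    # hematocrit guard: no daughter may carry more erythrocytes than blood
    if (length(live) > 1 && Ev > 0) {
      cap <- 0.95 * q_in[live]
      for (rep_i in 1:3) {
        over <- E[live] > cap
        if (!any(over)) break
        excess <- sum(E[live][over] - cap[over])
        E[live][over] <- cap[over]
        room <- !over
        if (any(room))
          E[live][room] <- E[live][room] +
            excess * q_in[live][room] / sum(q_in[live][room])
      }
    }

    # exit state of each outgoing segment, accumulated at its far node
    for (s in segs) {
      plasma_in_s <- q_in[s] - E[s]
      plasma_out_s <- q_out[s] - E[s]
      if (q_in[s] <= 0 || plasma_in_s <= 0) { C_end[s] <- Cv; next }
      if (stag[s]) {
        # quasi-stagnant: uniform concentration, no erythrocytes
        C_end[s] <- Cv
        w <- to[s]
        node_plasma[w] <- node_plasma[w] + max(plasma_out_s, 0)
        node_blood[w] <- node_blood[w] + max(q_out[s], 0)
        node_mass[w] <- node_mass[w] + Cv * max(plasma_out_s, 0)
        next
      }
      if (plasma_out_s < 1e-6 * plasma_in_s) {
        # plasma (nearly) exhausted by filtration: cap the concentration;
        # the next filtration-resistance update renders the tail
        # non-filtering, resolving the transient nonphysical state
        C_end[s] <- 15
        plasma_out_s <- max(plasma_out_s, 0)
      } else {
        C_end[s] <- Cv * plasma_in_s / plasma_out_s
      }
      w <- to[s]
      node_E[w] <- node_E[w] + E[s]
      node_plasma[w] <- node_plasma[w] + plasma_out_s
      node_blood[w] <- node_blood[w] + q_out[s]
      node_mass[w] <- node_mass[w] + C_end[s] * plasma_out_s
      node_D[w] <- if (node_blood[w] > 0)
        (node_D[w] * (node_blood[w] - q_out[s]) +
           prep$D_um[s] * q_out[s]) / node_blood[w] else 0
    }
  }

  C_E <- if (node_plasma[prep$outlet] > 0)
    node_mass[prep$outlet] / node_plasma[prep$outlet] else bc$C_A
  list(E = E, C0 = C0, C_end = C_end, fwd = fwd,
       q_in = q_in, q_out = q_out, stag = stag,
       qa_blood = qa_blood, Ht_A = Ht_A, C_E = C_E,
       E_out = node_E[prep$outlet],
       plasma_out = node_plasma[prep$outlet],
       blood_out = node_blood[prep$outlet])
}

#' Propagate erythrocytes and plasma proteins through a solved network
#'
#' Given node pressures and per-segment resistances, orients every segment by
#' the sign of its length-averaged flow, sweeps the graph in topological
#' (decreasing-potential) order, mixes protein mass at nodes, and partitions
#' erythrocytes at diverging bifurcations by the phase-separation law.
#'
#' @inheritParams assemble_and_solve_pressures
#' @param pressures node pressures, mmHg (as returned by
#'   \code{\link{assemble_and_solve_pressures}}).
#' @param rheology a \code{\link{rheology_params}} object.
#' @param settings a \code{\link{solver_settings}} object.
#' @return list with per-segment \code{E} (nl/min), \code{C0}, \code{C_end}
#'   (g/dl), orientation \code{fwd}, and the efferent concentration
#'   \code{C_E}.
#' @export
propagate_erythrocytes_and_proteins <- function(net, pressures, R, R_f, bc,
                                                rheology = rheology_params(),
                                                settings = solver_settings()) {
  prep <- prep_network(net)
  u <- mmHg_to_cgs(pressures[match(prep$node_ids,
                                   as.integer(names(pressures)))] - bc$p_BS)
  fl <- segment_flows(prep, u, R, R_f)
  pr <- propagate_cgs(prep, u, fl, bc, rheology, settings)
  list(E = cgs_to_nlmin(pr$E), C0 = pr$C0, C_end = pr$C_end,
       fwd = pr$fwd, C_E = pr$C_E)
}

# vectorised Eq.-8 filtration-resistance update over all segments (CGS).
# int_u and the osmotic integral use the closed-form profile evaluated at
# Gauss-Legendre nodes; returns list(R_f, filtering).
update_rf_all <- function(prep, fl, pr, k_cgs, rheo, settings, sentinel) {
  ns <- length(prep$ei)
  gl <- gl_nodes(settings$quad_nodes)
  th <- fl$theta
  # oriented ends: entry potential first
  ui <- ifelse(pr$fwd, fl$u_i, fl$u_j)
  uj <- ifelse(pr$fwd, fl$u_j, fl$u_i)
  small <- th < THETA_SERIES_DEFAULT
  S <- matrix(gl$x, ns, settings$quad_nodes, byrow = TRUE)
  e2 <- exp(-2 * th)
  Q <- matrix(0, ns, settings$quad_nodes)
  if (any(!small)) {
    i1 <- which(!small)
    ths <- th[i1] * S[i1, , drop = FALSE]
    thL <- th[i1]
    Q[i1, ] <- thL / (fl$R_seg[i1] * (1 - e2[i1])) *
      (ui[i1] * (exp(-ths) + exp(-(2 * thL - ths))) -
         uj[i1] * (exp(-(thL - ths)) + exp(-(thL + ths))))
  }
  if (any(small)) {
    i0 <- which(small)
    qin <- ifelse(pr$fwd, fl$q0, -fl$qL)[i0]
    qout <- ifelse(pr$fwd, fl$qL, -fl$q0)[i0]
    Q[i0, ] <- qin + (qout - qin) * S[i0, , drop = FALSE]
  }
  # protein concentration along the segment (entry values are oriented)
  plasma_in <- pmax(pr$q_in - pr$E, 1e-300)
  Pl <- pmax(Q - pr$E, 1e-3 * plasma_in) # exhaustion guard -> huge Pi
  Cx <- pr$C0 * plasma_in / Pl
  co <- rheo$osmotic_coef
  Pi_cgs <- mmHg_to_cgs(co[1] * Cx + co[2] * Cx^2 + co[3] * Cx^3)
  int_pi <- as.numeric(Pi_cgs %*% gl$w) * prep$L_cm
  int_u <- fl$u_mean * prep$L_cm
  # filtration conductance g = 1/R_f; g is continuous in the osmotic drive
  # (g -> 0 as the drive vanishes), so the equilibrium boundary is handled by
  # clamping g at zero rather than switching to a discontinuous sentinel
  g <- ifelse(int_u > 0,
              k_cgs * pi * prep$D_cm * prep$L_cm * (int_u - int_pi) / int_u,
              0)
  g <- pmax(g, 0)
  # quasi-stagnant watershed segments (fed from both ends at a vanishing
  # mean flow) would otherwise filter without an osmotic brake, since no
  # steady convective concentration profile exists on them; physically they
  # self-limit to filtration equilibrium. Their conductance is tapered to
  # zero smoothly (a hard clamp at the stagnancy threshold would introduce
  # a new discontinuity and flip-flop across it).
  q_rel <- abs(fl$q_mean) / max(pr$qa_blood, 1e-300)
  s0 <- settings$stagnant_tol
  ramp <- pmin(1, pmax(0, (q_rel - s0) / (2 * s0)))
  g <- g * ramp
  list(g = g, filtering = g > 0)
}

#' Solve the coupled glomerular filtration network to its fixed point
#'
#' Implements the steady-state iteration: initialise apparent viscosities at
#' the plasma value (1.24 cP) and filtration resistances from a
#' no-filtration pressure solve with \eqn{\Pi \equiv \Pi(C_A)}; then repeat
#' \{solve node pressures via the hyperbolic two-ports; compute profiles,
#' flows and filtrate; propagate proteins and erythrocytes; update filtration
#' resistances (consistency integral), apparent viscosities
#' (diameter/hematocrit law) and hydraulic resistances\} until every
#' viscosity and filtration resistance changes by less than the relative
#' tolerance (default 0.001\%).
#'
#' @param net a \code{\link{glom_network}}.
#' @param bc \code{\link{boundary_conditions}}.
#' @param rheology \code{\link{rheology_params}}.
#' @param k hydraulic conductivity of the filtration barrier,
#'   nl/(min mmHg um^2). \code{k = 0} turns filtration off.
#' @param settings \code{\link{solver_settings}}.
#' @return an object of class \code{network_state}: node pressures (mmHg), a
#'   per-segment state table, and global metrics (SNGFR, plasma Q_A, P_GC,
#'   filtration fraction, mean colloid osmotic pressure, convergence info).
#' @export
fixed_point_solve <- function(net, bc, rheology = rheology_params(),
                              k, settings = solver_settings()) {
  stopifnot(inherits(net, "glom_network"), k >= 0)
  prep <- prep_network(net)
  ns <- length(prep$ei)
  k_cgs <- k_to_cgs(k)

  mu <- rep(rheology$mu_ref, ns) # cP
  R <- poiseuille_resistance(prep$D_um, prep$L_um, mu)
  sentinel <- settings$rf_sentinel_factor * max(R)

  # initial filtration conductance: no-filtration pressure solve with
  # Pi = Pi(C_A)
  R_f <- rep(sentinel, ns)
  g_fl <- rep(0, ns)
  u <- solve_pressures_cgs(prep, R, R_f, bc)
  fl <- segment_flows(prep, u, R, R_f)
  pi_A <- mmHg_to_cgs(colloid_osmotic_pressure(bc$C_A, rheology))
  if (k_cgs > 0) {
    drive <- pmax(fl$u_mean - pi_A, 0)
    g_fl <- ifelse(fl$u_mean > 0,
                   k_cgs * pi * prep$D_cm * prep$L_cm * drive / fl$u_mean, 0)
    R_f <- pmin(1 / pmax(g_fl, 1 / sentinel), sentinel)
  }

  converged <- FALSE
  residuals <- numeric(0)
  pr <- NULL
  # per-segment adaptive relaxation: a segment whose update direction
  # alternates (near-stagnant segments at the filtration-equilibrium
  # boundary have a local map slope exceeding 1 in magnitude) gets its
  # factor halved until the damped map contracts; steadily-moving segments
  # recover toward the configured factor
  w_g <- rep(settings$relax, ns)
  w_mu <- rep(settings$relax, ns)
  dg_prev <- numeric(ns)
  dmu_prev <- numeric(ns)
  for (it in seq_len(settings$max_iter)) {
    u <- solve_pressures_cgs(prep, R, R_f, bc)
    fl <- segment_flows(prep, u, R, R_f)
    fl$R_seg <- R
    pr <- propagate_cgs(prep, u, fl, bc, rheology, settings)

    upd <- update_rf_all(prep, fl, pr, k_cgs, rheology, settings, sentinel)
    qm <- abs(fl$q_mean)
    Ht <- ifelse(pr$stag | qm <= 0, 0, pmin(pr$E / pmax(qm, 1e-300), 0.95))
    C_bar <- (pr$C0 + pr$C_end) / 2
    mu_target <- plasma_viscosity(C_bar, rheology) *
      relative_viscosity(prep$D_um, Ht)

    d_g <- upd$g - g_fl
    d_mu <- mu_target - mu
    osc_g <- d_g * dg_prev < 0
    w_g[osc_g] <- pmax(w_g[osc_g] / 2, 0.02)
    w_g[!osc_g] <- pmin(w_g[!osc_g] * 1.1, settings$relax)
    osc_mu <- d_mu * dmu_prev < 0
    w_mu[osc_mu] <- pmax(w_mu[osc_mu] / 2, 0.02)
    w_mu[!osc_mu] <- pmin(w_mu[!osc_mu] * 1.1, settings$relax)
    dg_prev <- d_g
    dmu_prev <- d_mu

    # convergence on the unrelaxed discrepancy; the filtration side is
    # measured on theta^2 = R * g (the quantity the two-port actually
    # depends on) with an additive floor, so segments at filtration
    # equilibrium (g -> 0, R_f astronomically large but irrelevant) do not
    # stall the criterion
    res <- max(abs(d_g) * R / (1e-3 + g_fl * R), abs(d_mu) / mu)
    residuals <- c(residuals, res)

    g_fl <- g_fl + w_g * d_g
    R_f <- pmin(1 / pmax(g_fl, 1 / sentinel), sentinel)
    mu <- mu + w_mu * d_mu
    R <- poiseuille_resistance(prep$D_um, prep$L_um, mu)
    if (res < settings$tol) { converged <- TRUE; break }
  }

  # final consistent pass with the converged parameters
  u <- solve_pressures_cgs(prep, R, R_f, bc)
  fl <- segment_flows(prep, u, R, R_f)
  fl$R_seg <- R
  pr <- propagate_cgs(prep, u, fl, bc, rheology, settings)

  build_network_state(prep, u, fl, pr, R, R_f, mu, bc, rheology, k,
                      settings, sentinel, converged, length(residuals),
                      residuals)
}

build_network_state <- function(prep, u, fl, pr, R, R_f, mu, bc, rheo, k,
                                settings, sentinel, converged, iterations,
                                residuals) {
  nj <- !prep$junction
  csgfr_nl <- cgs_to_nlmin(fl$csgfr)
  sngfr <- sum(csgfr_nl)
  qa_blood <- cgs_to_nlmin(pr$qa_blood)
  qa_plasma <- qa_blood * (1 - pr$Ht_A)
  qe_blood <- cgs_to_nlmin(pr$blood_out)
  p_mean <- bc$p_BS + cgs_to_mmHg(fl$u_mean)
  p_gc <- mean(p_mean[nj])
  pi_a <- colloid_osmotic_pressure(bc$C_A, rheo)
  pi_e <- colloid_osmotic_pressure(pr$C_E, rheo)
  qm <- abs(fl$q_mean)
  segments <- data.frame(
    id = prep$seg_id,
    i = prep$node_ids[prep$ei], j = prep$node_ids[prep$ej],
    D_um = prep$D_um, L_um = prep$L_um, junction = prep$junction,
    Q_in = cgs_to_nlmin(ifelse(pr$fwd, fl$q0, -fl$qL)),
    Q_out = cgs_to_nlmin(ifelse(pr$fwd, fl$qL, -fl$q0)),
    Q_mean = cgs_to_nlmin(qm),
    CSGFR = csgfr_nl,
    E = cgs_to_nlmin(pr$E),
    Ht = ifelse(qm > 0, pmin(pr$E / pmax(qm, 1e-300), 1), 0),
    mu = mu, C0 = pr$C0, C_end = pr$C_end,
    R = R, R_f = R_f, theta = fl$theta,
    p_mean = p_mean,
    filtering = is.finite(R_f) & R_f < 0.5 * sentinel &
      csgfr_nl > 1e-6 * qa_blood,
    fwd = pr$fwd, stagnant = pr$stag)
  structure(list(
    pressures = stats::setNames(bc$p_BS + cgs_to_mmHg(u), prep$node_ids),
    segments = segments,
    metrics = list(
      SNGFR = sngfr, Q_A_blood = qa_blood, Q_A = qa_plasma,
      Q_E_blood = qe_blood, Q_E = cgs_to_nlmin(pr$plasma_out),
      E_in = cgs_to_nlmin(pr$qa_blood) * pr$Ht_A,
      E_out = cgs_to_nlmin(pr$E_out),
      P_GC = p_gc, FF = sngfr / qa_plasma,
      C_E = pr$C_E, Pi_A = pi_a, Pi_E = pi_e,
      mean_Pi = (pi_a + pi_e) / 2,
      Ht_A = pr$Ht_A,
      iterations = iterations, converged = converged),
    residuals = residuals,
    bc = bc, rheology = rheo, k = k, settings = settings,
    net = prep$net), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("network state (%s, %d iterations)\n",
              if (m$converged) "converged" else "NOT converged",
              m$iterations))
  cat(sprintf("  SNGFR %.3f nl/min | Q_A (plasma) %.2f nl/min | P_GC %.2f mmHg\n",
              m$SNGFR, m$Q_A, m$P_GC))
  cat(sprintf("  FF %.3f | C_E %.3f g/dl | mean Pi %.2f mmHg | k %.3g nl/(min mmHg um^2)\n",
              m$FF, m$C_E, m$mean_Pi, x$k))
  invisible(x)
}
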