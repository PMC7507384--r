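# Wall mechanics: capillary wall thickness, endothelial shear stress
# (Poiseuille wall shear at the length-averaged flow) and circumferential
# hoop stress (Young-Laplace at the length-averaged transmural pressure).

#' Glomerular capillary wall-layer parameters
#'
#' @param t_e endothelial layer thickness, nm.
#' @param t_bm basement-membrane thickness, nm (scenario-dependent).
#' @param t_pod_min minimal podocyte-layer thickness (slit diaphragm), nm.
#' @param h_pod podocyte foot-process height, nm.
#' @param w_pod podocyte foot-process width, nm.
#' @return a list of class \code{wall_params}.
#' @export
wall_params <- function(t_e = 40, t_bm = 149.82, t_pod_min = 0,
                        h_pod = 300, w_pod = 170) {
  stopifnot(t_e >= 0, t_bm >= 0, t_pod_min >= 0, h_pod >= 0, w_pod > 0)
  structure(list(t_e = t_e, t_bm = t_bm, t_pod_min = t_pod_min,
                 h_pod = h_pod, w_pod = w_pod), class = "wall_params")
}

#' Average glomerular capillary wall thickness
#'
#' Base layers (endothelium + basement membrane + minimal podocyte layer)
#' plus the averaged interdigitated foot-process layer: a constant pedestal of
#' height \code{h_pod/2} plus the circumferential mean of a cos^2-profiled
#' ridge of amplitude \code{h_pod/2}. The ridges tile the circumference
#' \eqn{\pi D} with period as close to \code{w_pod} as an integer count
#' allows; the mean is evaluated by quadrature of the (injectable) ridge
#' profile and tends to \code{h_pod/4} under full coverage.
#'
#' @param D capillary diameter, um (vectorised).
#' @param wall a \code{\link{wall_params}} object.
#' @param ridge_profile function of the within-period phase \eqn{t \in [0,1)}
#'   returning the relative ridge height in [0, 1]; default
#'   \code{cos(pi t)^2}.
#' @return wall thickness, um.
#' @export
wall_thickness <- function(D, wall = wall_params(),
                           ridge_profile = function(t) cos(pi * t)^2) {
  if (any(D <= 0)) stop("diameter must be positive")
  circ_nm <- pi * D * 1000
  if (any(wall$w_pod > circ_nm))
    stop("foot process wider than the capillary circumference")
  gl <- gl_nodes(64)
  ridge_mean <- sum(ridge_profile(gl$x) * gl$w) # one period; tiling is exact
  t_nm <- wall$t_e + wall$t_bm + wall$t_pod_min +
    wall$h_pod / 2 + (wall$h_pod / 2) * ridge_mean
  rep(t_nm, length(D)) / 1000
}

#' Endothelial wall shear stress
#'
#' Poiseuille wall shear at the length-averaged blood flow:
#' \eqn{\tau = 32 \mu \bar Q / (\pi D^3)}.
#'
#' @param Q_mean length-averaged blood flow, nl/min.
#' @param D diameter, um.
#' @param mu apparent viscosity, cP.
#' @return shear stress, dyn/cm^2.
#' @export
shear_stress <- function(Q_mean, D, mu) {
  if (any(D <= 0) || any(mu <= 0)) stop("D and mu must be positive")
  32 * cp_to_poise(mu) * nlmin_to_cgs(Q_mean) / (pi * um_to_cm(D)^3)
}

#' Circumferential hoop stress (Young-Laplace)
#'
#' \eqn{\sigma = D \Delta p / (2 t)} at the length-averaged transmural
#' pressure.
#'
#' @param dp mean transmural pressure, mmHg.
#' @param D diameter, um.
#' @param t wall thickness, um.
#' @return hoop stress, kPa. Non-positive transmural pressure yields
#'   \eqn{\sigma \le 0} with a warning (collapse regime).
#' @export
hoop_stress <- function(dp, D, t) {
  if (any(t <= 0)) stop("wall thickness must be positive")
  if (any(dp < 0)) warning("non-positive transmural pressure: collapse regime")
  um_to_cm(D) * mmHg_to_cgs(dp) / (2 * um_to_cm(t)) * DYN_CM2_TO_KPA
}

#' Per-segment stress report for a solved network
#'
#' Computes shear and hoop stress for every (non-junction) capillary segment
#' of a converged \code{\link{fixed_point_solve}} state, with distributional
#' summaries, the fraction of segments below a shear threshold, and summaries
#' stratified by bifurcation distance from the afferent inlet.
#'
#' @param state a \code{network_state}.
#' @param wall a \code{\link{wall_params}} object.
#' @param threshold low-shear threshold, dyn/cm^2 (endothelin-secretion
#'   range).
#' @param force compute even for a non-converged state.
#' @return a list of class \code{stress_report} with elements
#'   \code{segments} (per-segment table with \code{tau}, \code{sigma},
#'   \code{t_wall}, \code{bifurcation_distance}), \code{tau}, \code{sigma}
#'   (summary statistics), \code{frac_below_threshold}, and \code{by_distance}.
#' @export
stress_summary <- function(state, wall = wall_params(), threshold = 15,
                           force = FALSE) {
  stopifnot(inherits(state, "network_state"))
  if (!state$metrics$converged && !force)
    stop("state is not converged; pass force = TRUE to summarise anyway")
  sg <- state$segments[!state$segments$junction, ]
  t_wall <- wall_thickness(sg$D_um, wall)
  tau <- shear_stress(sg$Q_mean, sg$D_um, sg$mu)
  dp <- sg$p_mean - state$bc$p_BS
  sigma <- hoop_stress(dp, sg$D_um, t_wall)
  dist <- bifurcation_distance(state$net, sg$id)
  five <- function(x) c(mean = mean(x), median = stats::median(x),
                        min = min(x), max = max(x), sd = stats::sd(x))
  by_dist <- do.call(rbind, lapply(split(seq_along(dist), dist), function(ii)
    data.frame(distance = dist[ii][1], n = length(ii),
               mean_tau = mean(tau[ii]), mean_sigma = mean(sigma[ii]),
               sum_csgfr = sum(sg$CSGFR[ii]))))
  structure(list(
    segments = data.frame(id = sg$id, D_um = sg$D_um, L_um = sg$L_um,
                          tau = tau, sigma = sigma, t_wall = t_wall,
                          bifurcation_distance = dist),
    tau = five(tau), sigma = five(sigma),
    frac_below_threshold = mean(tau < threshold),
    threshold = threshold,
    by_distance = by_dist), class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  cat(sprintf("shear stress  [dyn/cm^2]: mean %.1f, median %.1f, range [%.1f, %.1f]\n",
              x$tau["mean"], x$tau["median"], x$tau["min"], x$tau["max"]))
  cat(sprintf("hoop stress   [kPa]:      mean %.1f, median %.1f, range [%.1f, %.1f]\n",
              x$sigma["mean"], x$sigma["median"], x$sigma["min"], x$sigma["max"]))
  cat(sprintf("fraction of segments with tau < %.0f dyn/cm^2: %.1f%%\n",
              x$threshold, 100 * x$frac_below_threshold))
  invisible(x)
}

#' Write the per-segment results table of a solved state
#'
#' @param state a \code{network_state}.
#' @param path output CSV path.
#' @param wall a \code{\link{wall_params}} object for the stress columns.
#' @export
write_results_csv <- function(state, path, wall = wall_params()) {
  rep <- stress_summary(state, wall, force = TRUE)
  sg <- state$segments[!state$segments$junction, ]
  out <- cbind(sg[c("id", "D_um", "L_um", "Q_in", "Q_out", "CSGFR", "Ht",
                    "mu", "C0", "filtering")],
               rep$segments[c("tau", "sigma", "t_wall",
                              "bifurcation_distance")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
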