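# Filtering-capillary model.
#
# A capillary segment from node i to node j with length L, diameter D,
# hydraulic resistance R and filtration resistance R_f obeys, in the
# transmural variable u(x) = p(x) - p_BS,
#
#     u''(x) = a^2 u(x),   a^2 = R / (R_f L^2),   u(0) = u_i, u(L) = u_j,
#
# whose closed-form solution is hyperbolic in theta = a L = sqrt(R / R_f).
# Flow is Q(x) = -(L/R) u'(x); the filtrate produced by the segment
# (CSGFR) is the integral of u over the segment divided by R_f L, which
# equals Q(0) - Q(L) exactly. theta -> 0 recovers an ordinary resistor.

THETA_SERIES_DEFAULT <- 1e-4

# theta/tanh(theta), theta/sinh(theta), (cosh(theta)-1)/(theta*sinh(theta)),
# evaluated with series fallbacks for small theta (numerically exact limits
# 1, 1, 1/2). Vectorised.
f_coth <- function(th, eps = THETA_SERIES_DEFAULT) {
  out <- numeric(length(th))
  s <- th < eps
  out[s] <- 1 + th[s]^2 / 3 - th[s]^4 / 45
  out[!s] <- th[!s] / tanh(th[!s])
  out
}
f_csch <- function(th, eps = THETA_SERIES_DEFAULT) {
  out <- numeric(length(th))
  s <- th < eps
  out[s] <- 1 - th[s]^2 / 6 + 7 * th[s]^4 / 360
  out[!s] <- th[!s] / sinh(th[!s])
  out
}
f_mean <- function(th, eps = THETA_SERIES_DEFAULT) {
  out <- numeric(length(th))
  s <- th < eps
  out[s] <- 0.5 - th[s]^2 / 24 + th[s]^4 / 240
  out[!s] <- (cosh(th[!s]) - 1) / (th[!s] * sinh(th[!s]))
  out
}

#' Poiseuille hydraulic resistance of a capillary segment
#'
#' \eqn{R = 128 \mu L / (\pi D^4)} in CGS units.
#'
#' @param D diameter, um.
#' @param L length, um.
#' @param mu apparent viscosity, cP.
#' @return hydraulic resistance, dyn s / cm^5.
#' @export
poiseuille_resistance <- function(D, L, mu) {
  if (any(D <= 0) || any(L <= 0) || any(mu <= 0))
    stop("D, L and mu must be positive")
  128 * cp_to_poise(mu) * um_to_cm(L) / (pi * um_to_cm(D)^4)
}

#' Solve the pressure profile of a filtering capillary
#'
#' Closed-form solution of the transmural-pressure two-point boundary value
#' problem \eqn{u'' = a^2 u} with \eqn{u = p - p_{BS}} and Dirichlet end
#' pressures. \code{R_f = Inf} (or \code{theta} below the series threshold)
#' recovers the linear non-filtering profile.
#'
#' @param p_i,p_j end (node) pressures, mmHg.
#' @param p_BS Bowman's-space pressure, mmHg.
#' @param R hydraulic resistance, dyn s/cm^5.
#' @param R_f filtration resistance, dyn s/cm^5 (may be \code{Inf}).
#' @param L segment length, um.
#' @return an object of class \code{capillary_profile}.
#' @export
solve_pressure_profile <- function(p_i, p_j, p_BS, R, R_f, L) {
  stopifnot(R > 0, L > 0)
  if (R_f < 0) stop("negative filtration resistance signals the non-filtering branch; pass R_f = Inf")
  theta <- if (is.finite(R_f)) sqrt(R / R_f) else 0
  structure(list(u_i = mmHg_to_cgs(p_i - p_BS),
                 u_j = mmHg_to_cgs(p_j - p_BS),
                 p_BS = p_BS, theta = theta,
                 R = R, R_f = R_f, L = um_to_cm(L)),
            class = "capillary_profile")
}

#' @export
print.capillary_profile <- function(x, ...) {
  cat(sprintf("capillary profile: u(0)=%.3f u(L)=%.3f mmHg, theta=%.4g\n",
              cgs_to_mmHg(x$u_i), cgs_to_mmHg(x$u_j), x$theta))
  invisible(x)
}

# transmural pressure u(x) (CGS) at fractional positions s = x/L in [0,1];
# written in exponentially scaled form, stable for large theta.
profile_u <- function(prof, s) {
  th <- prof$theta
  if (th < THETA_SERIES_DEFAULT)
    return(prof$u_i * (1 - s) + prof$u_j * s)
  e <- exp(-2 * th)
  num <- prof$u_i * (exp(-th * s) - exp(-th * (2 - s))) +
    prof$u_j * (exp(-th * (1 - s)) - exp(-th * (1 + s)))
  num / (1 - e)
}

# blood flow Q(x) (CGS, cm^3/s) at fractional positions s = x/L.
profile_q <- function(prof, s) {
  th <- prof$theta
  qin <- end_flows_cgs(prof)
  if (th < THETA_SERIES_DEFAULT) {
    # linear interpolation is exact to O(theta^2): dQ/dx is proportional to u
    return(qin[1] + (qin[2] - qin[1]) * s)
  }
  e <- exp(-2 * th)
  num <- prof$u_i * (exp(-th * s) + exp(-th * (2 - s))) -
    prof$u_j * (exp(-th * (1 - s)) + exp(-th * (1 + s)))
  th / (prof$R * (1 - e)) * num
}

# (Q(0), Q(L)) in CGS. Q(0) = alpha u_i - beta u_j, Q(L) = beta u_i - alpha u_j
# with alpha = f_coth(theta)/R, beta = f_csch(theta)/R.
end_flows_cgs <- function(prof) {
  al <- f_coth(prof$theta) / prof$R
  be <- f_csch(prof$theta) / prof$R
  c(al * prof$u_i - be * prof$u_j, be * prof$u_i - al * prof$u_j)
}

#' Blood flow at the two ends of a solved capillary
#'
#' @param profile a \code{\link{solve_pressure_profile}} result.
#' @return named numeric \code{c(Q_in, Q_out)} in nl/min.
#' @export
end_flows <- function(profile) {
  q <- cgs_to_nlmin(end_flows_cgs(profile))
  c(Q_in = q[[1]], Q_out = q[[2]])
}

#' Capillary segment glomerular filtration rate
#'
#' Filtrate produced by one segment: the length integral of the transmural
#' pressure divided by \eqn{R_f L}; identically equal to \eqn{Q(0) - Q(L)}.
#'
#' @param profile a \code{\link{solve_pressure_profile}} result.
#' @return CSGFR, nl/min.
#' @export
csgfr <- function(profile) {
  q <- end_flows_cgs(profile)
  cgs_to_nlmin(q[1] - q[2])
}

# length-averaged transmural pressure (CGS)
mean_u <- function(prof) (prof$u_i + prof$u_j) * f_mean(prof$theta)

#' Length-averaged capillary pressure
#' @param profile a \code{\link{solve_pressure_profile}} result.
#' @return mean of p(x) over the segment, mmHg.
#' @export
mean_pressure <- function(profile) profile$p_BS + cgs_to_mmHg(mean_u(profile))

# length-averaged blood flow (CGS): (1/L) int Q dx = (u_i - u_j)/R exactly.
mean_q_cgs <- function(prof) (prof$u_i - prof$u_j) / prof$R

#' Plasma protein concentration along a filtering capillary
#'
#' Protein mass balance with erythrocyte flow E constant along the segment:
#' \eqn{C(x) = C_0 (Q_0 - E) / (Q(x) - E)}.
#'
#' @param C0 entry concentration, g/dl.
#' @param Q0 entry blood flow, nl/min.
#' @param E erythrocyte flow, nl/min.
#' @param Qx local blood flow, nl/min (vectorised).
#' @return local concentration, g/dl.
#' @export
protein_profile <- function(C0, Q0, E, Qx) {
  if (E < 0 || Q0 <= E) stop("entry plasma flow must be positive")
  if (any(Qx <= E))
    stop("plasma exhausted: local blood flow does not exceed erythrocyte flow")
  C0 * (Q0 - E) / (Qx - E)
}

#' Update the filtration resistance of a capillary segment
#'
#' Consistency condition between the pressure-profile filtration law and the
#' Starling law: \deqn{R_f = \int_0^L (p - p_{BS}) dx /
#'   [k \pi D L \int_0^L (p - p_{BS} - \Pi(C(x))) dx].}
#' The numerator uses the closed-form antiderivative of the hyperbolic
#' profile; the osmotic integral is evaluated by adaptive quadrature with
#' \eqn{C(x)} obtained from the closed-form flow profile. A non-positive
#' denominator means colloid osmotic pressure exceeds the hydrostatic drive on
#' balance: the segment is flagged non-filtering and the sentinel is returned.
#'
#' @param profile a solved \code{\link{solve_pressure_profile}}.
#' @param C0 entry protein concentration, g/dl.
#' @param E erythrocyte flow, nl/min.
#' @param k hydraulic conductivity, nl/(min mmHg um^2).
#' @param D segment diameter, um.
#' @param params a \code{\link{rheology_params}} object.
#' @param sentinel value returned for a non-filtering segment
#'   (default \code{Inf}).
#' @return filtration resistance, dyn s/cm^5, with attribute
#'   \code{filtering} (logical).
#' @export
update_filtration_resistance <- function(profile, C0, E, k, D,
                                         params = rheology_params(),
                                         sentinel = Inf) {
  if (k <= 0) stop("hydraulic conductivity must be positive")
  L_cm <- profile$L
  int_u <- mean_u(profile) * L_cm # dyn/cm^2 * cm
  q0 <- cgs_to_nlmin(end_flows_cgs(profile)[1])
  plasma0 <- q0 - E
  if (plasma0 <= 0) stop("entry plasma flow must exceed the erythrocyte flow")
  pi_fun <- function(s) {
    qx <- cgs_to_nlmin(profile_q(profile, s))
    # soft plasma-exhaustion clamp (mirrors the network update): a segment
    # filtering away (nearly) all its plasma gets a huge local Pi, which
    # drives the consistency update to the non-filtering branch
    Cx <- C0 * plasma0 / pmax(qx - E, 1e-3 * plasma0)
    mmHg_to_cgs(colloid_osmotic_pressure(Cx, params))
  }
  int_pi <- stats::integrate(pi_fun, 0, 1, rel.tol = 1e-10,
                             abs.tol = 1e-12)$value * L_cm
  denom <- k_to_cgs(k) * pi * um_to_cm(D) * L_cm * (int_u - int_pi)
  if (denom <= 0 || int_u <= 0)
    return(structure(sentinel, filtering = FALSE))
  structure(int_u / denom, filtering = TRUE)
}
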