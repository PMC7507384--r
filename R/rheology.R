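#' Constitutive rheology parameters
#'
#' Bundles the constitutive laws used throughout the network model: the cubic
#' colloid osmotic pressure polynomial, the linear plasma-viscosity law, the
#' diameter/hematocrit-dependent relative apparent-viscosity law for blood in
#' narrow tubes, and the logit-linear erythrocyte phase-separation law applied
#' at diverging bifurcations. All coefficients are overridable; the defaults
#' are the published in-vitro coefficient sets.
#'
#' @param osmotic_coef numeric length-3: coefficients \code{(c1, c2, c3)} of
#'   the colloid osmotic pressure cubic \eqn{\Pi = c_1 C + c_2 C^2 + c_3 C^3}
#'   in mmHg for C in g/dl.
#' @param mu_ref plasma viscosity (cP) at the reference protein
#'   concentration \code{C_ref}.
#' @param C_ref reference plasma protein concentration, g/dl.
#' @param mu_slope slope of the linear plasma-viscosity law, cP per g/dl.
#' @param Ht_sys systemic hematocrit (fraction).
#' @param f_Ht microvascular hematocrit factor: the afferent (discharge)
#'   hematocrit entering the network is \code{f_Ht * Ht_sys}.
#' @param split_a,split_b,split_x0 coefficients of the phase-separation law
#'   (diameter-scaled asymmetry, hematocrit sensitivity, and low-flow
#'   threshold respectively); see \code{\link{erythrocyte_split}}.
#' @return an object of class \code{rheology_params} (a named list).
#' @export
rheology_params <- function(osmotic_coef = c(2.1, 0.16, 0.009),
                            mu_ref = 1.24, C_ref = 5.94, mu_slope = 0.035,
                            Ht_sys = 0.45, f_Ht = 0.8,
                            split_a = -6.96, split_b = 6.98, split_x0 = 0.4) {
  stopifnot(length(osmotic_coef) == 3, mu_ref > 0, C_ref >= 0,
            Ht_sys > 0, Ht_sys < 1, f_Ht >= 0, f_Ht <= 1)
  structure(list(osmotic_coef = osmotic_coef,
                 mu_ref = mu_ref, C_ref = C_ref, mu_slope = mu_slope,
                 Ht_sys = Ht_sys, f_Ht = f_Ht,
                 split_a = split_a, split_b = split_b, split_x0 = split_x0),
            class = "rheology_params")
}

#' Colloid osmotic pressure of plasma
#'
#' Cubic polynomial in the plasma protein concentration,
#' \eqn{\Pi(C) = c_1 C + c_2 C^2 + c_3 C^3}.
#'
#' @param C plasma protein concentration, g/dl (vectorised).
#' @param params a \code{\link{rheology_params}} object.
#' @return colloid osmotic pressure, mmHg.
#' @export
colloid_osmotic_pressure <- function(C, params = rheology_params()) {
  if (any(C < 0)) stop("negative protein concentration")
  co <- params$osmotic_coef
  co[1] * C + co[2] * C^2 + co[3] * C^3
}

#' Plasma viscosity as a linear function of protein concentration
#'
#' \eqn{\mu^{pl}(C) = \mu_{ref} + slope (C - C_{ref})}, anchored by default at
#' 1.24 cP for C = 5.94 g/dl.
#'
#' @inheritParams colloid_osmotic_pressure
#' @return plasma viscosity, cP.
#' @export
plasma_viscosity <- function(C, params = rheology_params()) {
  if (any(C < 0)) stop("negative protein concentration")
  mu <- params$mu_ref + params$mu_slope * (C - params$C_ref)
  if (any(mu <= 0)) stop("plasma viscosity law produced a non-positive value")
  mu
}

#' Relative apparent viscosity of blood in a narrow tube
#'
#' Empirical in-vitro law for the relative apparent viscosity
#' \eqn{\lambda(D, Ht)} of blood flowing in a tube of diameter D at discharge
#' hematocrit Ht (the Fahraeus-Lindqvist effect): \eqn{\lambda = 1} for pure
#' plasma, increasing in hematocrit, with a minimum in D near 5-10 um at
#' physiological hematocrit.
#'
#' @param D tube diameter, um (vectorised).
#' @param Ht discharge hematocrit, fraction in [0, 1).
#' @return dimensionless relative viscosity.
#' @export
relative_viscosity <- function(D, Ht) {
  if (any(D <= 0)) stop("diameter must be positive")
  if (any(Ht < 0) || any(Ht >= 1)) stop("hematocrit must lie in [0, 1)")
  mu45 <- 220 * exp(-1.3 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  shape <- 1 / (1 + 1e-11 * D^12)
  Cc <- (0.8 + exp(-0.075 * D)) * (shape - 1) + shape
  1 + (mu45 - 1) * ((1 - Ht)^Cc - 1) / ((1 - 0.45)^Cc - 1)
}

#' Apparent blood viscosity
#'
#' \eqn{\mu = \mu^{pl} \lambda(D, Ht)}.
#'
#' @param D tube diameter, um.
#' @param Ht discharge hematocrit, fraction.
#' @param mu_pl plasma viscosity, cP.
#' @param params a \code{\link{rheology_params}} object.
#' @return apparent viscosity, cP.
#' @export
apparent_viscosity <- function(D, Ht, mu_pl, params = rheology_params()) {
  mu_pl * relative_viscosity(D, Ht)
}

#' Segment hematocrit
#'
#' Hematocrit of a capillary segment: constant erythrocyte flow divided by the
#' length-averaged blood flow, \eqn{Ht = E / \bar Q}.
#'
#' @param E erythrocyte flow, nl/min.
#' @param Q_mean length-averaged blood flow, nl/min.
#' @return hematocrit (fraction).
#' @export
segment_hematocrit <- function(E, Q_mean) {
  if (any(Q_mean <= 0)) stop("mean blood flow must be positive")
  if (any(E < 0)) stop("erythrocyte flow must be non-negative")
  if (any(E > Q_mean)) stop("nonphysical state: erythrocyte flow exceeds blood flow (Ht >= 1)")
  E / Q_mean
}

logit <- function(x) log(x / (1 - x))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Erythrocyte phase separation at a bifurcation
#'
#' Partitions the erythrocyte flow of a parent vessel between two daughter
#' branches using the sigmoidal (logit-linear) phase-separation law: the
#' fraction of erythrocytes entering daughter 1 is a sigmoidal function of its
#' fractional blood flow, with diameter-dependent asymmetry and a
#' hematocrit-dependent slope. Below the low-flow threshold a daughter
#' receives no erythrocytes; above the complementary threshold it receives
#' them all.
#'
#' @param parent list with elements \code{Q} (blood flow, nl/min), \code{E}
#'   (erythrocyte flow, nl/min) and \code{D} (diameter, um).
#' @param daughters list of (two) lists, each with \code{Q} and \code{D}.
#' @param params a \code{\link{rheology_params}} object.
#' @return numeric vector of per-daughter erythrocyte flows (nl/min), summing
#'   to \code{parent$E}.
#' @export
erythrocyte_split <- function(parent, daughters, params = rheology_params()) {
  if (length(daughters) > 2)
    stop("phase-separation law is defined for bifurcations (at most 2 daughters)")
  if (parent$E > parent$Q + 1e-12 * parent$Q)
    stop("parent erythrocyte flow exceeds parent blood flow")
  if (length(daughters) == 1) return(parent$E)
  q <- vapply(daughters, `[[`, numeric(1), "Q")
  if (any(q <= 0)) stop("daughter flows must be positive")
  fq <- q[1] / sum(q)
  fe1 <- split_fraction(fq, daughters[[1]]$D, daughters[[2]]$D, parent$D,
                        Ht_f = if (parent$Q > 0) parent$E / parent$Q else 0,
                        params = params)
  parent$E * c(fe1, 1 - fe1)
}

# Fraction of parent erythrocytes entering daughter "alpha" given its
# fractional blood flow fq; logit-linear in logit((fq - x0)/(1 - 2 x0)).
split_fraction <- function(fq, D_alpha, D_beta, D_parent, Ht_f, params) {
  x0 <- params$split_x0 / D_parent
  if (fq <= x0) return(0)
  if (fq >= 1 - x0) return(1)
  a <- params$split_a * log(D_alpha / D_beta) / D_parent
  b <- 1 + params$split_b * (1 - Ht_f) / D_parent
  inv_logit(a + b * logit((fq - x0) / (1 - 2 * x0)))
}
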