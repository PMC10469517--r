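# Tissue pressure-volume relations and van Genuchten soil water retention.

#' Pressure-volume parameters of a tissue
#'
#' Standard pressure-volume theory: symplast water potential is the sum of an
#' osmotic term pi0 / R and a turgor term that vanishes at the turgor-loss
#' point,
#' \deqn{\psi_{sym}(R) = \pi_0 / R + \max(0,\; -\pi_0 - \epsilon (1 - R))}
#' where R is the relative symplast water content (0-1), pi0 (< 0, MPa) the
#' osmotic potential at full turgor and epsilon (> 0, MPa) the bulk elastic
#' modulus.
#'
#' @param pi0 Osmotic potential at full turgor, MPa (< 0).
#' @param epsilon Bulk elastic modulus, MPa (> 0).
#' @param apoplastic_fraction Fraction of organ water held in the apoplast
#'   (0 <= f < 1); used when partitioning organ water volumes.
#' @return Object of class `pv_params`.
#' @export
pv_params <- function(pi0, epsilon, apoplastic_fraction = 0.15) {
  if (!is.finite(pi0) || pi0 >= 0) stop("pi0 must be negative")
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  if (apoplastic_fraction < 0 || apoplastic_fraction >= 1)
    stop("apoplastic_fraction must lie in [0, 1)")
  structure(list(pi0 = pi0, epsilon = epsilon,
                 apoplastic_fraction = apoplastic_fraction),
            class = "pv_params")
}

#' Symplast water potential from relative water content
#'
#' @param pv A [pv_params()].
#' @param r Relative symplast water content, (0, 1].
#' @param pi0 Optional temperature-adjusted osmotic potential overriding
#'   `pv$pi0` (van't Hoff scaling is applied by the simulator).
#' @return Water potential, MPa (vectorised).
#' @export
pv_psi <- function(pv, r, pi0 = pv$pi0) {
  stopifnot(inherits(pv, "pv_params"))
  r <- pmax(r, 1e-6)
  pi0 / r + pmax(0, -pi0 - pv$epsilon * (1 - r))
}

#' Relative water content from symplast water potential (inverse PV curve)
#'
#' Closed-form inverse: below the turgor-loss point R = pi0 / psi; above it
#' the turgid branch is the root of a quadratic.
#'
#' @inheritParams pv_psi
#' @param psi Water potential, MPa (<= 0).
#' @return Relative water content in (0, 1].
#' @export
pv_r <- function(pv, psi, pi0 = pv$pi0) {
  stopifnot(inherits(pv, "pv_params"))
  eps <- pv$epsilon
  r_tlp <- max(1 + pi0 / eps, 1e-6)   # R where turgor reaches zero
  psi_tlp <- pi0 / r_tlp
  vapply(psi, function(p) {
    if (p >= 0) return(1)
    if (p <= psi_tlp) return(min(1, pi0 / p))
    # turgid branch: eps R^2 + (-pi0 - eps - psi) R + pi0 = 0
    b <- -pi0 - eps - p
    r <- (-b + sqrt(b^2 - 4 * eps * pi0)) / (2 * eps)
    min(1, max(r, r_tlp))
  }, numeric(1))
}

#' Symplast capacitance dW/dpsi (per unit symplast volume)
#'
#' @inheritParams pv_psi
#' @return dR/dpsi, MPa-1 (multiply by symplast volume for mmol MPa-1).
#' @keywords internal
pv_capacitance <- function(pv, r, pi0 = pv$pi0) {
  r <- pmax(r, 1e-6)
  r_tlp <- max(1 + pi0 / pv$epsilon, 1e-6)
  dpsi_dr <- -pi0 / r^2 + ifelse(r > r_tlp, pv$epsilon, 0)
  1 / dpsi_dr
}

#' van Genuchten soil water retention
#'
#' Se = (1 + (alpha |psi|)^n)^(-m), theta = theta_r + Se (theta_s - theta_r),
#' m = 1 - 1/n; relative hydraulic conductivity by Mualem,
#' K_rel = sqrt(Se) (1 - (1 - Se^(1/m))^m)^2.
#'
#' @param theta_r Residual volumetric water content.
#' @param theta_s Saturated volumetric water content.
#' @param alpha Inverse air-entry value, MPa-1 (note units: a textbook alpha
#'   of 3.6 m-1 is 3.6 * 101.97 = 367 MPa-1).
#' @param n Pore-size distribution index (> 1).
#' @return Object of class `vg_params`.
#' @export
vg_params <- function(theta_r = 0.078, theta_s = 0.43, alpha = 367, n = 1.56) {
  stopifnot(theta_r >= 0, theta_s > theta_r, alpha > 0, n > 1)
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha, n = n,
                 m = 1 - 1 / n),
            class = "vg_params")
}

#' @rdname vg_params
#' @param vg A `vg_params` object.
#' @param psi Soil water potential, MPa (<= 0).
#' @export
vg_theta <- function(vg, psi) {
  se <- (1 + (vg$alpha * pmax(-psi, 0))^vg$n)^(-vg$m)
  vg$theta_r + se * (vg$theta_s - vg$theta_r)
}

#' @rdname vg_params
#' @param theta Volumetric water content.
#' @export
vg_psi <- function(vg, theta) {
  se <- (theta - vg$theta_r) / (vg$theta_s - vg$theta_r)
  if (any(se <= 0)) stop("theta at or below residual water content")
  se <- pmin(se, 1)
  -(1 / vg$alpha) * (se^(-1 / vg$m) - 1)^(1 / vg$n)
}

#' @rdname vg_params
#' @export
vg_k_rel <- function(vg, theta) {
  se <- pmin(pmax((theta - vg$theta_r) / (vg$theta_s - vg$theta_r), 1e-12), 1)
  sqrt(se) * (1 - (1 - se^(1 / vg$m))^vg$m)^2
}
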