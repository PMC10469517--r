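# Sigmoid xylem vulnerability curves: evaluation, inversion, fitting.

#' Xylem vulnerability curve
#'
#' Two-parameter sigmoid mapping (signed) water potential to cumulative
#' cavitation:
#' \deqn{C(\psi) = 100 / (1 + e^{a (\psi - P50)})}
#' with `a` (MPa-1) a slope parameter and `P50` (MPa, negative) the water
#' potential at which half the cavitation events have occurred. Water
#' potentials are stored signed everywhere: tension is negative.
#'
#' @param a Slope parameter, MPa-1 (> 0).
#' @param p50 Water potential at 50% cumulative cavitation, MPa (< 0).
#' @param label Optional organ label (e.g. `"flower"`).
#' @return Object of class `vulnerability_curve`.
#' @examples
#' vc <- vulnerability_curve(a = 4.89, p50 = -3.57, label = "flower")
#' cumulative_cavitation(vc, -3.57) # 50
#' @export
vulnerability_curve <- function(a, p50, label = NULL) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(p50), length(p50) == 1L)
  if (!is.finite(a) || a <= 0) stop("slope parameter a must be > 0")
  if (!is.finite(p50) || p50 >= 0)
    stop("P50 must be negative (signed water potential convention)")
  structure(list(a = a, p50 = p50, label = label),
            class = "vulnerability_curve")
}

#' @export
print.vulnerability_curve <- function(x, ...) {
  cat(sprintf("<vulnerability_curve%s> a = %.3f MPa-1, P50 = %.3f MPa (P12 = %.2f)\n",
              if (is.null(x$label)) "" else paste0(": ", x$label),
              x$a, x$p50, psi_at_cumulative(x, 12)))
  invisible(x)
}

#' Cumulative cavitation at a water potential
#'
#' Evaluates the sigmoid; the exponent is clamped to avoid overflow far from
#' the midpoint.
#'
#' @param curve A [vulnerability_curve()].
#' @param psi Water potential, MPa, signed (<= 0 in normal use; vectorised).
#' @return Cumulative cavitation, percent of total (0-100).
#' @export
cumulative_cavitation <- function(curve, psi) {
  stopifnot(inherits(curve, "vulnerability_curve"), is.numeric(psi))
  z <- pmin(pmax(curve$a * (psi - curve$p50), -700), 700)
  100 / (1 + exp(z))
}

#' Water potential at a given cumulative cavitation (Px)
#'
#' Exact inverse of [cumulative_cavitation()]:
#' \deqn{\psi = \ln(100/C - 1)/a + P50.}
#'
#' @param curve A [vulnerability_curve()].
#' @param cumulative Cumulative cavitation, percent, strictly inside (0, 100).
#' @return Water potential, MPa (signed).
#' @examples
#' psi_at_cumulative(vulnerability_curve(4.89, -3.57), 12) # ~ -3.2 MPa
#' @export
psi_at_cumulative <- function(curve, cumulative) {
  stopifnot(inherits(curve, "vulnerability_curve"), is.numeric(cumulative))
  if (any(cumulative <= 0 | cumulative >= 100))
    stop("cumulative must lie strictly inside (0, 100) %")
  log(100 / cumulative - 1) / curve$a + curve$p50
}

#' Px convenience accessors
#'
#' Water potential at 12, 50 or 88 percent cumulative cavitation. P12 marks
#' incipient (air-entry) embolism, P50 the midpoint, P88 near-complete
#' failure.
#'
#' @param curve A [vulnerability_curve()].
#' @return Water potential, MPa.
#' @export
p12 <- function(curve) psi_at_cumulative(curve, 12)

#' @rdname p12
#' @export
p50 <- function(curve) curve$p50

#' @rdname p12
#' @export
p88 <- function(curve) psi_at_cumulative(curve, 88)

#' Fit a vulnerability curve to (psi, cumulative %) observations
#'
#' Nonlinear least squares of the two-parameter sigmoid. Initialisation:
#' P50 starts at the observed psi nearest 50 % cumulative cavitation and the
#' slope at 4 / range(psi); optimisation is bounded (a in (0, 100],
#' P50 in \[-20, 0\)) via L-BFGS-B on the residual sum of squares.
#'
#' @param psi Water potentials, MPa (signed).
#' @param cumulative Cumulative cavitation, percent (0-100), same length.
#' @return A [vulnerability_curve()] with extra fields `rss` (residual sum of
#'   squares), `converged` (logical) and `n` (observations used).
#' @examples
#' vc <- vulnerability_curve(4.89, -3.57)
#' psi <- seq(-5, -2, length.out = 25)
#' fit <- fit_vulnerability_curve(psi, cumulative_cavitation(vc, psi))
#' c(fit$a, fit$p50)
#' @export
fit_vulnerability_curve <- function(psi, cumulative) {
  stopifnot(is.numeric(psi), is.numeric(cumulative),
            length(psi) == length(cumulative))
  ok <- is.finite(psi) & is.finite(cumulative)
  psi <- psi[ok]; cumulative <- cumulative[ok]
  if (length(psi) < 4L)
    stop("need at least 4 observations to fit a vulnerability curve")
  if (any(cumulative < 0 | cumulative > 100))
    stop("cumulative observations must lie in [0, 100] %")
  if (stats::sd(cumulative) == 0)
    stop("degenerate data: all cumulative values identical")
  p50_0 <- psi[which.min(abs(cumulative - 50))]
  rng <- diff(range(psi))
  a_0 <- if (rng > 0) 4 / rng else 1
  obj <- function(par) {
    pred <- 100 / (1 + exp(pmin(pmax(par[1] * (psi - par[2]), -700), 700)))
    sum((cumulative - pred)^2)
  }
  opt <- stats::optim(c(a = a_0, p50 = min(p50_0, -1e-6)), obj,
                      method = "L-BFGS-B",
                      lower = c(1e-6, -20), upper = c(100, -1e-9))
  out <- vulnerability_curve(a = opt$par[[1]], p50 = opt$par[[2]])
  out$rss <- opt$value
  out$converged <- opt$convergence == 0L
  out$n <- length(psi)
  out
}

#' Read / write cavitation observation tables
#'
#' Plain CSV with columns `psi_MPa` and `cumulative_pct`.
#'
#' @param path File path.
#' @return `read_observations`: data.frame with the two columns.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("psi_MPa", "cumulative_pct")
  if (!all(need %in% names(df)))
    stop("observation CSV must have columns psi_MPa, cumulative_pct")
  df[need]
}

#' @rdname read_observations
#' @param observations data.frame with columns `psi_MPa`, `cumulative_pct`.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations[c("psi_MPa", "cumulative_pct")], path,
                   row.names = FALSE)
  invisible(path)
}
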