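# Analytical runaway-cavitation threshold: the loss of conductance beyond
# which residual evaporative demand exceeds the maximum possible xylem supply.

#' Per-organ hydraulic and evaporative parameters
#'
#' Everything the analytical threshold needs for one organ: maximum
#' area-specific hydraulic conductance at a reference temperature, the
#' width parameter of the exponential vulnerability decline, the residual
#' conductance to water vapour, and the sigmoid vulnerability curve.
#'
#' @param name Organ label (e.g. `"flower"`).
#' @param k_max Maximum hydraulic conductance at `reference_temperature`,
#'   mmol m-2 s-1 MPa-1 (> 0), per projected organ area.
#' @param alpha Width parameter of the conductance-vs-tension decline, MPa
#'   (> 0). Stored independently of the sigmoid slope `a` (they are
#'   parameterised separately, although alpha ~ 1/a for these curves).
#' @param g_res Residual conductance to water vapour, mmol m-2 s-1 (>= 0).
#'   May be a length-2 vector `c(at20, at40)` giving values at 20 and 40 degC;
#'   a scalar is used at all temperatures.
#' @param curve A [vulnerability_curve()].
#' @param reference_temperature Temperature at which `k_max` was measured,
#'   degC. Default 20.
#' @return Object of class `organ_params`.
#' @export
organ_params <- function(name, k_max, alpha, g_res, curve,
                         reference_temperature = 20) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(k_max) || k_max <= 0) stop("k_max must be > 0")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (any(!is.finite(g_res)) || any(g_res < 0)) stop("g_res must be >= 0")
  if (!length(g_res) %in% c(1L, 2L)) stop("g_res must have length 1 or 2")
  stopifnot(inherits(curve, "vulnerability_curve"))
  structure(list(name = name, k_max = k_max, alpha = alpha, g_res = g_res,
                 curve = curve, reference_temperature = reference_temperature),
            class = "organ_params")
}

# g_res at temperature t: linear interpolation between the 20/40 degC values
# when two are given (measured T effect on g_res is not significant, but both
# printed values are honoured); flat extrapolation outside [20, 40].
.g_res_at <- function(params, t) {
  g <- params$g_res
  if (length(g) == 1L) return(g)
  stats::approx(c(20, 40), g, xout = t, rule = 2)$y
}

#' Default organ parameter table
#'
#' Reads the packaged organ parameter CSV (flower and leaf of pyrethrum;
#' K_max and vulnerability parameters from rehydration kinetics / the optical
#' technique, evaporative parameters measured gravimetrically) and returns a
#' list of [organ_params()].
#'
#' @param path Optional path to a CSV with columns
#'   `organ, k_max_20C, alpha_MPa, g_res_20C, g_res_40C, a_MPa_inv, p50_MPa`.
#'   Defaults to the packaged table.
#' @return Named list of `organ_params`.
#' @export
default_organ_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "organ_params.csv", package = "floralhydra",
                        mustWork = TRUE)
  df <- utils::read.csv(path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    organ_params(name = df$organ[i], k_max = df$k_max_20C[i],
                 alpha = df$alpha_MPa[i],
                 g_res = c(df$g_res_20C[i], df$g_res_40C[i]),
                 curve = vulnerability_curve(df$a_MPa_inv[i], df$p50_MPa[i],
                                             label = df$organ[i]),
                 reference_temperature = 20)
  })
  names(out) <- df$organ
  out
}

#' Runaway-cavitation threshold for one organ
#'
#' Computes the percentage loss of conductance at which the maximum possible
#' water supply through the organ's xylem just equals its residual
#' evaporative demand:
#' \deqn{PLC_{runaway} = 100\, \frac{\alpha K_{max}/E_{res}}
#'   {1 + \alpha K_{max}/E_{res}}}
#' with K_max viscosity-corrected to the air temperature and E_res obtained
#' from g_res at the prevailing VPD. Beyond this PLC, any further cavitation
#' reduces supply below demand and the feedback runs to complete failure.
#'
#' @param params An [organ_params()].
#' @param air An [air_state()]; must have VPD > 0.
#' @return List of class `runaway_result`: `plc_runaway` (%), `e_res_used`,
#'   `k_max_used`, `temperature`, `j_max_at_threshold` (= `e_res_used`; the
#'   flow at the tipping point equals the residual demand), and `limit_case`
#'   (TRUE when E_res = 0 and the limiting value 100 is returned).
#' @examples
#' fl <- default_organ_params()[["flower"]]
#' plc_runaway(fl, air_state(40, 12))$plc_runaway # ~47.0
#' @export
plc_runaway <- function(params, air) {
  stopifnot(inherits(params, "organ_params"), inherits(air, "air_state"))
  if (vapor_pressure_deficit(air) <= 0)
    stop("VPD must be positive to compute residual transpiration")
  t <- air$temperature
  k <- correct_conductance(params$k_max, params$reference_temperature, t)
  e_res <- convert_flux(.g_res_at(params, t), air, "g2E")
  limit <- e_res == 0
  plc <- if (limit) 100 else {
    r <- params$alpha * k / e_res
    100 * r / (1 + r)
  }
  structure(list(organ = params$name, plc_runaway = plc, e_res_used = e_res,
                 k_max_used = k, temperature = t,
                 j_max_at_threshold = e_res, limit_case = limit),
            class = "runaway_result")
}

#' @export
print.runaway_result <- function(x, ...) {
  cat(sprintf("<runaway_result: %s @ %g degC> PLC_runaway = %.1f %% (E_res = %.3f, K = %.3f)\n",
              x$organ, x$temperature, x$plc_runaway, x$e_res_used, x$k_max_used))
  invisible(x)
}

#' Runaway thresholds for a grid of organs and conditions
#'
#' Cross product of organs and air states; with the packaged defaults and the
#' two growth/heat conditions (20 degC/40 % RH and 40 degC/12 % RH) this
#' reproduces the published four-cell threshold table.
#'
#' @param organs Non-empty list of [organ_params()].
#' @param conditions Non-empty list of [air_state()].
#' @return data.frame with columns `organ, temp_C, rh_pct, vpd_kPa, e_res,
#'   k_max, plc_runaway`.
#' @examples
#' runaway_table(default_organ_params(),
#'               list(air_state(20, 40), air_state(40, 12)))
#' @export
runaway_table <- function(organs, conditions) {
  if (length(organs) == 0L) stop("organ list must be non-empty")
  if (length(conditions) == 0L) stop("condition list must be non-empty")
  rows <- lapply(organs, function(o) {
    do.call(rbind, lapply(conditions, function(air) {
      r <- plc_runaway(o, air)
      data.frame(organ = o$name, temp_C = air$temperature,
                 rh_pct = air$relative_humidity,
                 vpd_kPa = vapor_pressure_deficit(air),
                 e_res = r$e_res_used, k_max = r$k_max_used,
                 plc_runaway = r$plc_runaway)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify an observed PLC against the runaway threshold
#'
#' @param plc_observed Observed percentage loss of conductance (0-100).
#' @param result A [plc_runaway()] result (or a bare threshold in %).
#' @param band Width of the "at risk" band below the threshold, percentage
#'   points. Default 10.
#' @return One of `"below"`, `"at_risk"`, `"beyond"` (vectorised over
#'   `plc_observed`).
#' @export
classify_tipping <- function(plc_observed, result, band = 10) {
  if (any(plc_observed < 0 | plc_observed > 100))
    stop("plc_observed must lie in [0, 100]")
  thr <- if (inherits(result, "runaway_result")) result$plc_runaway else result
  out <- ifelse(plc_observed >= thr, "beyond",
                ifelse(plc_observed >= thr - band, "at_risk", "below"))
  factor(out, levels = c("below", "at_risk", "beyond"))
}
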