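# Seeded generators for every input the pipeline consumes, with ground
# truth returned alongside. Defaults emulate the study system: dehydration
# from 0 to about -2.8 MPa, cavitation events drawn from the flower sigmoid,
# 1-min frame cadence during heat, an analytical balance with 0.1 mg noise.

#' Dehydration trajectory of water potential
#'
#' Monotone-trend decline psi(t) = psi0 - rate * t (days), optionally with a
#' sinusoidal diurnal modulation, plus seeded Gaussian noise. Defaults span
#' the published predawn range 0 to -2.8 MPa over a week of drought.
#'
#' @param psi0 Starting water potential, MPa. Default 0.
#' @param rate Decline rate, MPa per day (> 0). Default 0.4.
#' @param duration_days Length of the series, days. Default 7.
#' @param dt_hours Sampling interval, hours. Default 1.
#' @param diurnal_amplitude Amplitude of a midday depression, MPa. Default 0.
#' @param noise_sd Gaussian noise sd, MPa. Default 0.
#' @param seed RNG seed.
#' @return data.frame with `t_s` and `psi_MPa`.
#' @export
generate_dehydration <- function(psi0 = 0, rate = 0.4, duration_days = 7,
                                 dt_hours = 1, diurnal_amplitude = 0,
                                 noise_sd = 0, seed = 1) {
  if (rate <= 0) stop("rate must be > 0")
  set.seed(seed)
  t_h <- seq(0, duration_days * 24, by = dt_hours)
  psi <- psi0 - rate * t_h / 24
  if (diurnal_amplitude > 0)
    psi <- psi - diurnal_amplitude * pmax(0, sin(2 * pi * (t_h %% 24 - 6) / 24))
  if (noise_sd > 0) psi <- psi + stats::rnorm(length(psi), 0, noise_sd)
  data.frame(t_s = t_h * 3600, psi_MPa = psi)
}

#' Sample cavitation events from a vulnerability curve
#'
#' Each vessel draws its cavitation threshold from the logistic density the
#' sigmoid implies (location P50, scale 1/a); its event time is the first
#' time the psi series crosses that threshold. Vessels whose threshold is
#' never reached remain uncavitated (the series should span enough of the
#' curve that >= 90 % cavitate if a full curve is wanted).
#'
#' @param curve A [vulnerability_curve()].
#' @param psi_series data.frame with `t_s`, `psi_MPa`
#'   (e.g. [generate_dehydration()]).
#' @param n_vessels Number of vessels. Default 200.
#' @param seed RNG seed.
#' @return data.frame of class `event_schedule`: `vessel`, `psi_threshold`,
#'   `t_s` (NA if never cavitated), `frame_index`.
#' @export
sample_cavitation_events <- function(curve, psi_series, n_vessels = 200,
                                     seed = 1) {
  stopifnot(inherits(curve, "vulnerability_curve"), n_vessels >= 1)
  set.seed(seed)
  # logistic threshold: P(cavitated at psi) = 1/(1 + exp(a (psi - P50)))
  # i.e. threshold ~ Logistic(P50, 1/a), cavitation when psi <= threshold
  thr <- stats::rlogis(n_vessels, location = curve$p50, scale = 1 / curve$a)
  idx <- vapply(thr, function(th) {
    hit <- which(psi_series$psi_MPa <= th)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  out <- data.frame(vessel = seq_len(n_vessels),
                    psi_threshold = thr,
                    t_s = psi_series$t_s[idx],
                    frame_index = idx)
  class(out) <- c("event_schedule", "data.frame")
  out
}

#' Render a synthetic xylem time-lapse stack
#'
#' Stem rendered as a bright band of programmed width on a dark background;
#' each vessel is an axial strip inside the stem whose intensity steps at
#' its cavitation frame. Stem width shrinks linearly with the driving water
#' potential; Gaussian and impulse noise are added per frame. The ground
#' truth (per-vessel event frame and pixel area, shrinkage coefficients,
#' noise settings, seed) is attached.
#'
#' @param schedule An [sample_cavitation_events()] result.
#' @param psi_series The driving psi series (for shrinkage), same frames.
#' @param geometry List: `height`, `width` (px), `stem_frac` (stem width at
#'   psi = 0 as a fraction of frame width), `n_frames` (frames rendered; the
#'   psi series is resampled onto them), `cadence_s` (frame interval).
#' @param shrinkage List: `pct_per_MPa` - percent of maximum thickness lost
#'   per MPa of tension (default 2.5, matching the observed 1-8 % range over
#'   0 to -3 MPa).
#' @param noise List: `gaussian_sd` (default 2), `impulse_frac` (default
#'   0.001), `impulse_value` (default 200).
#' @param event_step Intensity step at cavitation (default 60).
#' @param seed RNG seed.
#' @return List `stack` ([image_stack()]) and `truth` (list with the event
#'   table carrying pixel areas, the width series, all parameters).
#' @export
render_stack <- function(schedule, psi_series,
                         geometry = list(height = 128, width = 48,
                                         stem_frac = 0.75, n_frames = 60,
                                         cadence_s = 60),
                         shrinkage = list(pct_per_MPa = 2.5),
                         noise = list(gaussian_sd = 2, impulse_frac = 0.001,
                                      impulse_value = 200),
                         event_step = 60, seed = 1) {
  set.seed(seed)
  h <- geometry$height; w <- geometry$width
  nf <- geometry$n_frames
  # resample psi onto the rendered frames
  ts <- seq(min(psi_series$t_s), max(psi_series$t_s), length.out = nf)
  psi <- stats::approx(psi_series$t_s, psi_series$psi_MPa, xout = ts)$y
  # map event times to rendered frames
  ev_frame <- vapply(schedule$t_s, function(et)
    if (is.na(et)) NA_integer_ else max(findInterval(et, ts), 1L),
    integer(1))
  n_v <- nrow(schedule)
  # vessels: axial strips spanning the stem interior
  strip <- floor(h / n_v)
  if (strip < 1) stop("too many vessels for the frame height")
  base_w0 <- geometry$stem_frac * w
  widths <- base_w0 * (1 + shrinkage$pct_per_MPa / 100 * psi)  # psi <= 0
  if (any(widths < 4)) stop("shrinkage collapses the stem: enlarge the frame")
  truth_area <- integer(n_v)
  frames <- vector("list", nf)
  vessel_rows <- lapply(seq_len(n_v), function(v)
    ((v - 1) * strip + 1):(v * strip))
  # continuous stem edges with fractional (anti-aliased) coverage so that
  # sub-pixel shrinkage between frames stays below the despeckle threshold
  coverage <- function(width) {
    cl <- w / 2 - width / 2; cr <- w / 2 + width / 2
    pmin(pmax(pmin(cr, seq_len(w)) - pmax(cl, seq_len(w) - 1), 0), 1)
  }
  for (f in seq_len(nf)) {
    cov <- coverage(widths[f])
    m <- matrix(20, h, w) + matrix(100 * cov, h, w, byrow = TRUE)
    core <- cov >= 0.5   # columns counted as stem area for event truth
    for (v in seq_len(n_v)) {
      if (!is.na(ev_frame[v]) && f >= ev_frame[v]) {
        rows <- vessel_rows[[v]]
        m[rows, ] <- m[rows, ] +
          matrix(event_step * cov, length(rows), w, byrow = TRUE)
        if (f == ev_frame[v]) truth_area[v] <- length(rows) * sum(core)
      }
    }
    if (noise$gaussian_sd > 0)
      m <- m + matrix(stats::rnorm(h * w, 0, noise$gaussian_sd), h, w)
    if (noise$impulse_frac > 0) {
      n_imp <- round(noise$impulse_frac * h * w)
      if (n_imp > 0) m[sample(h * w, n_imp)] <- noise$impulse_value
    }
    frames[[f]] <- pmin(pmax(round(m), 0), 255)
  }
  truth <- list(events = cbind(schedule, render_frame = ev_frame,
                               area_px = truth_area),
                widths_px = widths, psi = psi, timestamps = ts,
                geometry = geometry, shrinkage = shrinkage, noise = noise,
                event_step = event_step, seed = seed)
  list(stack = image_stack(frames, ts), truth = truth)
}

#' Gravimetric weighing series implied by a residual flux
#'
#' Linear mass loss at E_res * area * 18.015 ug per s with balance noise.
#'
#' @param e_res Residual transpiration, mmol m-2 s-1.
#' @param area Organ projected area, m2.
#' @param interval_s Weighing interval, s. Default 600 (10 min).
#' @param n Number of weighings. Default 2.
#' @param balance_sd Balance noise sd, g. Default 1e-4 (a 0.1 mg balance).
#' @param mass0 Starting mass, g. Default 1.
#' @param seed RNG seed.
#' @return data.frame with `t_s` and `mass_g`.
#' @export
generate_weighing_series <- function(e_res, area, interval_s = 600, n = 2,
                                     balance_sd = 1e-4, mass0 = 1, seed = 1) {
  if (e_res < 0 || area <= 0 || interval_s <= 0 || n < 2)
    stop("need e_res >= 0, area > 0, interval_s > 0, n >= 2")
  set.seed(seed)
  t <- (seq_len(n) - 1) * interval_s
  # e_res [mmol m-2 s-1] * area [m2] = mmol/s; * 18.015 mg/mmol = mg/s
  mass <- mass0 - e_res * area * 18.015 * t / 1000
  if (balance_sd > 0) mass <- mass + stats::rnorm(n, 0, balance_sd)
  data.frame(t_s = t, mass_g = mass)
}

#' Synthetic flower mortality from PLC
#'
#' Logistic death probability centred on the runaway threshold:
#' p(death) = 1 / (1 + exp(-steepness (PLC - threshold))).
#'
#' @param plc_values Observed PLC per flower, percent.
#' @param threshold Tipping point, percent in (0, 100). Default 47.
#' @param steepness Logistic steepness, per percentage point. Default 0.25.
#' @param seed RNG seed.
#' @return data.frame with `plc`, `p_death`, `died` (logical).
#' @export
generate_mortality <- function(plc_values, threshold = 47, steepness = 0.25,
                               seed = 1) {
  if (threshold <= 0 || threshold >= 100) stop("threshold must be in (0, 100)")
  set.seed(seed)
  p <- 1 / (1 + exp(-steepness * (plc_values - threshold)))
  data.frame(plc = plc_values, p_death = p,
             died = stats::runif(length(p)) < p)
}
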