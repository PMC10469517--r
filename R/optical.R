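# Optical-vulnerability pipeline: frame differencing, despeckling,
# cumulative embolism accounting and cavitation rates.
#
# Cavitation events appear as abrupt local reflectance changes between
# successive frames of exposed xylem; everything below is bookkeeping on the
# absolute inter-frame differences.

#' Absolute differences between successive frames
#'
#' @param stack An [image_stack()] (>= 2 frames).
#' @return An `image_stack` of N-1 absolute difference frames with
#'   mid-interval timestamps.
#' @export
difference_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  diffs <- lapply(seq_len(n - 1), function(i)
    abs(stack$frames[[i + 1]] - stack$frames[[i]]))
  ts <- (stack$timestamps[-1] + stack$timestamps[-n]) / 2
  image_stack(diffs, ts, pixel_size = stack$pixel_size)
}

# Disk-shaped neighbourhood offsets (excluding the centre pixel is not
# needed; ImageJ's despeckle-style filter includes it).
.disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, ]
}

# Shift a matrix by (dr, dc), replicating edges.
.shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

#' Local-median outlier removal ("remove outliers" semantics)
#'
#' Each pixel is replaced by the median of a disk neighbourhood of the given
#' radius if and only if it deviates from that median by more than
#' `threshold`; all other pixels are untouched. Impulse (salt) noise is
#' removed while extended bright regions - real cavitation events - survive.
#'
#' @param frame Numeric matrix (a difference frame).
#' @param radius Neighbourhood radius, px (>= 1). Default 2.
#' @param threshold Intensity deviation that triggers replacement (8-bit
#'   scale). Default 20.
#' @return Cleaned matrix.
#' @export
remove_outliers <- function(frame, radius = 2, threshold = 20) {
  stopifnot(is.matrix(frame))
  if (radius < 1) stop("radius must be >= 1")
  off <- .disk_offsets(radius)
  shifted <- vapply(seq_len(nrow(off)),
                    function(i) as.numeric(.shift_pad(frame, off$dr[i], off$dc[i])),
                    numeric(length(frame)))
  med <- matrix(apply(shifted, 1, stats::median), nrow(frame), ncol(frame))
  out <- frame
  hit <- abs(frame - med) > threshold
  out[hit] <- med[hit]
  out
}

# Otsu's threshold on a numeric vector (histogram over 256 bins).
.otsu <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) == 0) return(Inf)
  breaks <- seq(min(x), max(x), length.out = 257)
  h <- hist(x, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Cumulative embolism curve from an image stack
#'
#' Differences successive frames, despeckles each difference, counts pixels
#' at or above the event threshold as embolised area, and expresses the
#' running total as a percentage of the sequence total. If the stack ends
#' with a full dry-down ("the xylem is 100 % cavitated at the end"), the
#' final value of 100 % is an absolute anchor; otherwise the curve is a
#' percentage of the observed total only (`anchored = FALSE`).
#'
#' @param stack An [image_stack()].
#' @param radius,noise_threshold Despeckle parameters
#'   (see [remove_outliers()]).
#' @param event_threshold Intensity at or above which a cleaned difference
#'   pixel counts as embolised area. Default `NULL`: Otsu's threshold on the
#'   pooled non-zero difference histogram.
#' @param anchored Does the stack include the terminal dry-down? Default
#'   TRUE.
#' @return Object of class `embolism_curve`: data.frame with `frame`, `t_s`,
#'   `event_area_px`, `cumulative_pct`; attributes `total_area_px`,
#'   `event_threshold`, `anchored`.
#' @export
cumulative_embolism <- function(stack, radius = 2, noise_threshold = 20,
                                event_threshold = NULL, anchored = TRUE) {
  diffs <- difference_stack(stack)
  cleaned <- lapply(diffs$frames, remove_outliers, radius = radius,
                    threshold = noise_threshold)
  if (is.null(event_threshold)) {
    pooled <- unlist(lapply(cleaned, function(m) m[m > 0]))
    event_threshold <- .otsu(pooled)
    if (!is.finite(event_threshold))
      stop("no cavitation detected: all difference frames are empty")
  }
  areas <- vapply(cleaned, function(m) sum(m >= event_threshold), numeric(1))
  total <- sum(areas)
  if (total == 0) stop("no cavitation detected: zero total embolism area")
  out <- data.frame(frame = seq_along(areas) + 1L,
                    t_s = diffs$timestamps,
                    event_area_px = areas,
                    cumulative_pct = 100 * cumsum(areas) / total)
  structure(out, total_area_px = total, event_threshold = event_threshold,
            anchored = anchored,
            class = c("embolism_curve", "data.frame"))
}

#' Evaluate a cumulative embolism curve at a time point
#'
#' Uses the nearest frame at or before `t` (0 before the first transition).
#'
#' @param curve An `embolism_curve`.
#' @param t Time, s.
#' @return Cumulative embolism, percent.
#' @export
embolism_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- findInterval(tt, curve$t_s)
    if (i == 0) 0 else curve$cumulative_pct[i]
  }, numeric(1))
}

#' Cavitation rate over a time window
#'
#' (cumulative(t1) - cumulative(t0)) / hours elapsed; the published
#' before/after-heat rate statistic.
#'
#' @param curve An `embolism_curve`.
#' @param t0,t1 Window bounds, s, with `t0 < t1`, inside the curve's span.
#' @return Rate, percent of total per hour.
#' @export
cavitation_rate <- function(curve, t0, t1) {
  if (t0 >= t1) stop("need t0 < t1")
  span <- range(curve$t_s)
  if (t0 < span[1] - (curve$t_s[2] - curve$t_s[1]) || t1 > span[2])
    stop("window outside the curve's time span")
  (embolism_at(curve, t1) - embolism_at(curve, t0)) / ((t1 - t0) / 3600)
}

#' Stem thickness from a frame
#'
#' `method = "threshold"`: binarise (Otsu by default) and return the mean,
#' over transects crossing the stem, of the longest contiguous foreground
#' run per transect (robust to isolated noise pixels away from the stem),
#' refined to sub-pixel precision by interpolating the partial coverage of
#' the two edge pixels from their intensities.
#' `method = "line"`: the same measurement along a single chosen transect.
#'
#' @param frame Numeric matrix; bright stem on dark background.
#' @param method `"threshold"` or `"line"`.
#' @param axis Stem axis: `"vertical"` (width measured along rows) or
#'   `"horizontal"`.
#' @param threshold Fixed binarisation intensity; default `NULL` = Otsu.
#' @param line For `method = "line"`: index of the row (vertical axis) or
#'   column (horizontal) to measure along; default the middle.
#' @param reference Optional reference thickness (px); when given the result
#'   includes `pct_of_max`.
#' @return List with `thickness_px` and, if `reference` given, `pct_of_max`.
#' @export
measure_thickness <- function(frame, method = c("threshold", "line"),
                              axis = c("vertical", "horizontal"),
                              threshold = NULL, line = NULL,
                              reference = NULL) {
  method <- match.arg(method)
  axis <- match.arg(axis)
  stopifnot(is.matrix(frame))
  if (axis == "horizontal") frame <- t(frame)  # stem now runs down rows
  if (is.null(threshold)) threshold <- .otsu(as.numeric(frame))
  fg <- frame >= threshold
  if (!any(fg)) stop("empty foreground: nothing to measure")
  # per-transect width: longest contiguous foreground run, plus fractional
  # coverage of the two adjacent edge pixels interpolated from intensity
  transect_width <- function(r) {
    v <- fg[r, ]
    runs <- rle(v)
    if (!any(runs$values)) return(0)
    ends <- cumsum(runs$lengths)
    k <- which(runs$values)[which.max(runs$lengths[runs$values])]
    j1 <- ends[k]; i1 <- j1 - runs$lengths[k] + 1L
    iv <- frame[r, ]
    inside <- stats::median(iv[i1:j1])
    outside_idx <- setdiff(seq_along(iv), max(i1 - 1, 1):min(j1 + 1, length(iv)))
    outside <- if (length(outside_idx)) stats::median(iv[outside_idx]) else 0
    span <- inside - outside
    if (span <= 0) return(j1 - i1 + 1)
    # integrate fractional pixel coverage over the run and its neighbours:
    # exact for a band with intensity-proportional partial edge pixels
    win <- max(i1 - 1, 1):min(j1 + 1, length(iv))
    sum(pmin(pmax((iv[win] - outside) / span, 0), 1))
  }
  thick <- if (method == "threshold") {
    widths <- vapply(seq_len(nrow(frame)), transect_width, numeric(1))
    mean(widths[widths > 0])
  } else {
    r <- if (is.null(line)) nrow(frame) %/% 2 else line
    if (r < 1 || r > nrow(frame)) stop("line index outside frame")
    wr <- transect_width(r)
    if (wr == 0) stop("empty foreground on the chosen transect")
    wr
  }
  out <- list(thickness_px = thick)
  if (!is.null(reference)) out$pct_of_max <- 100 * thick / reference
  out
}

#' Fit the stem-shrinkage water-potential proxy
#'
#' Ordinary least squares of (signed) water potential on stem thickness
#' expressed as percent of the maximum at field capacity:
#' psi = slope * thickness_pct + intercept. The published pooled model is
#' psi = 0.32 * thickness% - 32.03.
#'
#' @param psi Predawn water potentials, MPa (>= 3 points).
#' @param thickness_pct Stem thickness, percent of maximum.
#' @return Object of class `shrinkage_model`: `slope`, `intercept`, `r2`,
#'   `range` (fitted thickness range).
#' @export
fit_shrinkage <- function(psi, thickness_pct) {
  stopifnot(length(psi) == length(thickness_pct))
  if (length(psi) < 3L) stop("need at least 3 paired predawn points")
  if (stats::sd(thickness_pct) == 0) stop("rank-deficient input: constant thickness")
  fit <- stats::lm(psi ~ thickness_pct)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((psi - mean(psi))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 range = range(thickness_pct)),
            class = "shrinkage_model")
}

#' @rdname fit_shrinkage
#' @param model A `shrinkage_model` (or list with `slope`, `intercept`).
#' @param warn_outside Warn when predicting outside the fitted range?
#' @return `predict_psi`: water potential, MPa.
#' @export
predict_psi <- function(model, thickness_pct, warn_outside = TRUE) {
  if (warn_outside && !is.null(model$range) &&
      any(thickness_pct < model$range[1] | thickness_pct > model$range[2]))
    warning("predicting outside the fitted thickness range")
  model$slope * thickness_pct + model$intercept
}

#' Thermal-expansion bound on thickness change
#'
#' Percent change in stem thickness attributable to thermal expansion alone:
#' 100 * coefficient * dT. With the wood radial coefficient 1.34e-5 per degC
#' a 15 degC warming gives ~0.02 %, negligible against the 1-8 % shrinkage
#' observed during dehydration - justifying the thickness-to-psi proxy.
#'
#' @param coefficient Radial thermal expansion coefficient, per degC.
#' @param dT Temperature change, degC.
#' @return Percent thickness change.
#' @export
thermal_expansion_bound <- function(coefficient, dT) {
  100 * coefficient * dT
}
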