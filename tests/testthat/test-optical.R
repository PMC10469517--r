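# Optical cavitation pipeline: differencing, despeckle, accumulation,
# thickness and the shrinkage proxy.

test_that("frame differencing is absolute, symmetric and shape-checked", {
  st <- one_event_stack()
  same <- image_stack(rep(st$frames[1], 3), 1:3)
  d0 <- difference_stack(same)
  expect_true(all(vapply(d0$frames, function(m) all(m == 0), logical(1))))
  d <- difference_stack(st)
  nz <- vapply(d$frames, function(m) any(m > 0), logical(1))
  expect_equal(which(nz), 2L)    # the single programmed transition
  rev_st <- image_stack(rev(st$frames), st$timestamps)
  d_rev <- difference_stack(rev_st)
  expect_identical(d_rev$frames, rev(d$frames))
  expect_error(image_stack(list(matrix(0, 2, 2), matrix(0, 3, 3)), 1:2),
               "same dimensions")
})

test_that("outlier removal despeckles impulses but keeps extended events", {
  flat <- matrix(10, 20, 20)
  salt <- flat; salt[7, 9] <- 200
  expect_equal(remove_outliers(salt, radius = 2, threshold = 20), flat)
  blob <- flat; blob[5:14, 5:14] <- 200   # much larger than 2r
  cleaned <- remove_outliers(blob, radius = 2, threshold = 20)
  expect_equal(cleaned[7:12, 7:12], blob[7:12, 7:12])
})

test_that("seeded impulse noise is removed without eating true events", {
  set.seed(21)
  h <- 60; w <- 60
  truth <- matrix(0, h, w); truth[15:44, 10:49] <- 80
  noisy <- truth
  idx <- sample(h * w, 40)                 # impulse map, known locations
  noisy[idx] <- 220
  cleaned <- remove_outliers(noisy, radius = 2, threshold = 20)
  impulses_outside <- setdiff(idx, which(truth > 0))
  expect_gte(mean(cleaned[impulses_outside] < 20), 0.95)
  true_px <- setdiff(which(truth > 0), idx)
  expect_lte(mean(cleaned[true_px] != 80), 0.01)
})

test_that("cumulative embolism: steps, conservation, offset invariance", {
  st <- one_event_stack()
  cur <- cumulative_embolism(st, event_threshold = 30)
  expect_equal(cur$cumulative_pct, c(0, 100, 0, 0)[seq_len(4)] |> cumsum() |>
                 pmin(100))
  expect_equal(sum(cur$event_area_px), attr(cur, "total_area_px"))
  # uniform brightness offset leaves the curve unchanged
  st_off <- image_stack(lapply(st$frames, function(m) m + 17), st$timestamps)
  cur_off <- cumulative_embolism(st_off, event_threshold = 30)
  expect_equal(cur_off$cumulative_pct, cur$cumulative_pct)
  # pure noise below threshold errors
  flat <- image_stack(rep(list(matrix(5, 8, 8)), 4), 1:4)
  expect_error(cumulative_embolism(flat, event_threshold = 30),
               "no cavitation")
})

test_that("cavitation rate is a difference quotient in per-hour units", {
  cur <- data.frame(frame = 2:4, t_s = c(600, 5000, 14000),
                    event_area_px = c(10, 45, 45),
                    cumulative_pct = c(10, 55, 100))
  class(cur) <- c("embolism_curve", "data.frame")
  # canonical example: 10 % to 55 % over 3.5 h -> 12.857 % per hour
  expect_equal(cavitation_rate(cur, 600, 600 + 3.5 * 3600), (55 - 10) / 3.5,
               tolerance = 1e-9)
  expect_equal((55 - 10) / 3.5, 12.857, tolerance = 1e-3)
  flat <- cur; flat$cumulative_pct <- rep(40, 3)
  expect_equal(cavitation_rate(flat, 600, 1800), 0)
  expect_error(cavitation_rate(cur, 600, 1e6), "span")
})

test_that("thickness measurement recovers programmed widths", {
  m <- matrix(20, 60, 60)
  m[, 21:40] <- 140                         # 20 px wide stem, vertical
  expect_equal(measure_thickness(m)$thickness_px, 20, tolerance = 1)
  expect_equal(measure_thickness(m, reference = 20)$pct_of_max, 100,
               tolerance = 5)
  expect_equal(measure_thickness(t(m), axis = "horizontal")$thickness_px, 20,
               tolerance = 1)
  expect_equal(measure_thickness(m, method = "line", line = 30)$thickness_px,
               20, tolerance = 1)
  expect_error(measure_thickness(matrix(0, 10, 10)), "foreground")
})

test_that("shrinkage proxy matches the published pooled model", {
  pooled <- list(slope = 0.32, intercept = -32.03)
  expect_equal(predict_psi(pooled, 100), -0.03, tolerance = 1e-9)
  expect_equal(predict_psi(pooled, 90), -3.23, tolerance = 1e-9)
})

test_that("shrinkage fitting is exact on a noise-free line and validates", {
  th <- c(100, 96, 92, 88)
  psi <- 0.4 * th - 40
  m <- fit_shrinkage(psi, th)
  expect_equal(m$slope, 0.4, tolerance = 1e-12)
  expect_equal(m$intercept, -40, tolerance = 1e-9)
  expect_gt(m$r2, 0.999)
  expect_warning(predict_psi(m, 70), "outside")
  expect_error(fit_shrinkage(c(-1, -2), c(100, 90)), "at least 3")
  expect_error(fit_shrinkage(c(-1, -2, -3), rep(90, 3)), "rank-deficient")
})

test_that("thickness-to-psi chain recovers generating coefficients", {
  # noise-free shrinking stack -> measured thickness -> linear fit, within 2 %
  vc <- flower_curve()
  d <- generate_dehydration(rate = 0.8, duration_days = 7, seed = 7)
  sched <- sample_cavitation_events(vc, d, n_vessels = 16, seed = 7)
  rs <- render_stack(sched, d,
                     geometry = list(height = 64, width = 48,
                                     stem_frac = 0.75, n_frames = 40,
                                     cadence_s = 60),
                     noise = list(gaussian_sd = 0, impulse_frac = 0,
                                  impulse_value = 200), seed = 7)
  th <- vapply(rs$stack$frames,
               function(f) measure_thickness(f)$thickness_px, numeric(1))
  pct <- 100 * th / th[1]
  m <- fit_shrinkage(rs$truth$psi, pct)
  s <- rs$truth$shrinkage$pct_per_MPa
  expect_equal(m$slope, 1 / s * 100 / 100, tolerance = 0.02)  # psi per %
  expect_equal(m$intercept, -100 / s, tolerance = 0.02)
})

test_that("thermal expansion bound is tiny and linear", {
  expect_lt(abs(thermal_expansion_bound(1.34e-5, 15) - 0.02), 0.001)
  expect_identical(thermal_expansion_bound(1.34e-5, 0), 0)
  expect_equal(thermal_expansion_bound(1.34e-5, 30),
               2 * thermal_expansion_bound(1.34e-5, 15))
})

test_that("PGM stack I/O round-trips", {
  st <- one_event_stack()
  dir <- withr::local_tempdir()
  write_stack(st, dir)
  st2 <- read_stack(dir)
  expect_identical(lapply(st2$frames, as.numeric),
                   lapply(st$frames, as.numeric))
  expect_equal(st2$timestamps, st$timestamps)
  expect_error(read_stack(withr::local_tempdir()), "times.csv")
})
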