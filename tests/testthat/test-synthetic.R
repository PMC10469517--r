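# Seeded generators and their declared statistical structure.

test_that("dehydration series is linear, seeded and spans the stated range", {
  d <- generate_dehydration(noise_sd = 0)
  # defaults: 0.4 MPa/day over 7 days -> 0 .. -2.8 MPa, exactly linear
  expect_equal(range(d$psi_MPa), c(-2.8, 0))
  expect_equal(d$psi_MPa, -0.4 * d$t_s / 86400)
  d1 <- generate_dehydration(noise_sd = 0.05, seed = 3)
  d2 <- generate_dehydration(noise_sd = 0.05, seed = 3)
  expect_identical(d1, d2)
  expect_error(generate_dehydration(rate = -1), "rate")
})

test_that("event thresholds follow the generating sigmoid (KS < 0.05)", {
  vc <- flower_curve()
  d <- generate_dehydration(rate = 1.2, duration_days = 7, noise_sd = 0,
                            seed = 11)
  sched <- sample_cavitation_events(vc, d, n_vessels = 500, seed = 11)
  ks <- suppressWarnings(
    stats::ks.test(sched$psi_threshold, stats::plogis,
                   location = vc$p50, scale = 1 / vc$a))
  expect_lt(unname(ks$statistic), 0.05)
  # median event psi is near P50
  expect_equal(stats::median(sched$psi_threshold), vc$p50, tolerance = 0.05)
  one <- sample_cavitation_events(vc, d, n_vessels = 1, seed = 2)
  expect_equal(nrow(one), 1L)
})

test_that("rendered stacks carry exact single-event ground truth", {
  vc <- flower_curve()
  d <- generate_dehydration(rate = 2, duration_days = 3, noise_sd = 0)
  sched <- sample_cavitation_events(vc, d, n_vessels = 1, seed = 5)
  # fixture sanity: the single event must fall strictly inside the series
  expect_false(is.na(sched$t_s[1]))
  expect_gt(sched$t_s[1], min(d$t_s))
  geom <- list(height = 24, width = 16, stem_frac = 0.75, n_frames = 10,
               cadence_s = 60)
  rs <- render_stack(sched, d, geometry = geom,
                     shrinkage = list(pct_per_MPa = 0),
                     noise = list(gaussian_sd = 0, impulse_frac = 0,
                                  impulse_value = 200), seed = 5)
  diffs <- difference_stack(rs$stack)
  nonzero <- vapply(diffs$frames, function(m) sum(m > 0), numeric(1))
  expect_equal(sum(nonzero > 0), 1L)                 # exactly one transition
  expect_equal(max(nonzero), rs$truth$events$area_px[1])
  # width at psi = 0 equals the configured maximum
  rs0 <- render_stack(sched, d, geometry = geom,
                      noise = list(gaussian_sd = 0, impulse_frac = 0,
                                   impulse_value = 200), seed = 5)
  expect_equal(rs0$truth$widths_px[1], geom$stem_frac * geom$width)
  # determinism: bit-identical regeneration
  rs_a <- render_stack(sched, d, geometry = geom, seed = 9)
  rs_b <- render_stack(sched, d, geometry = geom, seed = 9)
  expect_identical(rs_a$stack$frames, rs_b$stack$frames)
})

test_that("weighing series invert to the generating flux", {
  # 10-min loss at E = 0.13 mmol m-2 s-1 over 10 cm2: ~1.4 mg
  w0 <- generate_weighing_series(0.13, 1e-3, balance_sd = 0)
  expect_equal(1000 * (w0$mass_g[1] - w0$mass_g[2]), 1.4, tolerance = 0.02)
  expect_equal(generate_weighing_series(0, 1e-3, balance_sd = 0)$mass_g,
               rep(1, 2))
  # with balance noise, mass_loss_to_flux recovers E within propagated error
  set.seed(13)
  errs <- replicate(50, {
    w <- generate_weighing_series(0.13, 1e-3, balance_sd = 1e-4,
                                  seed = sample.int(1e6, 1))
    mass_loss_to_flux(max(w$mass_g[1] - w$mass_g[2], 0), 600, 1e-3) - 0.13
  })
  sd_prop <- sqrt(2) * 1e-4 / 18.015 * 1000 / (600 * 1e-3)
  expect_lt(mean(abs(errs)), 2 * sd_prop)
})

test_that("mortality generator is a logistic around the tipping point", {
  m <- generate_mortality(c(0, 47, 100), threshold = 47, seed = 1)
  expect_lt(m$p_death[1], 0.001)
  expect_equal(m$p_death[2], 0.5)
  expect_gt(m$p_death[3], 0.999)
  expect_error(generate_mortality(50, threshold = 0), "threshold")
})
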