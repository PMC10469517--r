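# Mechanistic soil-plant simulator: structure, initialisation, dynamics.
# Runs here use shortened scenarios to stay within the test budget; the full
# published grid is exercised in test-acceptance.R.

test_that("the default plant builds the stated network", {
  p <- build_plant()
  expect_s3_class(p, "plant_state")
  expect_named(p$organs, c("root", "stem", "branch", "leaf", "flower"))
  expect_equal(p$soil$volume, 0.054)
  expect_equal(p$organs$leaf$area + p$organs$flower$area, 0.67)
  # per-area K converts to absolute supply conductance
  expect_equal(p$organs$flower$k_abs, 2.60 * 0.07)
})

test_that("a flowerless plant is valid; bad configs are rejected", {
  cfg <- jsonlite::read_json(system.file("extdata", "plant_default.json",
                                         package = "floralhydra"),
                             simplifyVector = TRUE)
  cfg$organs$flower <- NULL
  p <- build_plant(cfg)
  expect_named(p$organs, c("root", "stem", "branch", "leaf"))
  bad <- cfg; bad$organs$root$k_abs <- -1
  expect_error(build_plant(bad), "non-positive")
  bad2 <- cfg; bad2$organs$leaf <- NULL
  expect_error(build_plant(bad2), "root, stem, branch and leaf")
})

test_that("initialisation equilibrates to the soil water potential", {
  p <- build_plant()
  # saturated soil, saturated air: strict hydrostatic equilibrium at zero
  p0 <- initialize_at_soil_psi(p, 0, init_climate = list(t_air = 15, rh = 100,
                                                         ppfd = 0))
  for (o in p0$organs) expect_equal(o$psi_apo, 0, tolerance = 1e-6)
  # predawn defaults: flower sits below the leaf (higher E_res per K)
  p1 <- initialize_at_soil_psi(p, -1.25)
  expect_lt(p1$organs$flower$psi_apo, p1$organs$leaf$psi_apo)
  expect_lt(p1$organs$leaf$psi_apo, -1.25)
  # mild drought: everything still below 50 % PLC at initialisation
  p2 <- initialize_at_soil_psi(p, -0.75)
  for (o in p2$organs) expect_lt(o$plc, 50)
  expect_error(initialize_at_soil_psi(p, 0.5), "<= 0")
})

test_that("zero-VPD climate is a fixed point of the stepper", {
  p <- initialize_at_soil_psi(build_plant(), -0.5,
                              init_climate = list(t_air = 20, rh = 100,
                                                  ppfd = 0))
  res <- step_plant(p, list(t_air = 20, rh = 100, ppfd = 0))
  expect_equal(sum(unlist(res$fluxes$evaporation)), 0, tolerance = 1e-9)
  for (nm in names(p$organs))
    expect_equal(res$plant$organs[[nm]]$psi_apo, p$organs[[nm]]$psi_apo,
                 tolerance = 1e-6)
})

test_that("steady potentials follow the series-resistance closed form", {
  # saturated soil (huge rhizosphere conductance), mild fixed demand, no
  # cavitation: psi_leaf = psi_soil - E * sum(1/K) along root->stem->branch->leaf
  p <- initialize_at_soil_psi(build_plant(), 0,
                              init_climate = list(t_air = 20, rh = 100,
                                                  ppfd = 0))
  cl <- list(t_air = 20, rh = 80, ppfd = 0)      # dark: residual demand only
  for (i in 1:60) {
    res <- step_plant(p, cl, dt_outer = 60)
    p <- res$plant
    p$soil$theta <- p$soil$vg$theta_s             # keep the soil saturated
  }
  e_leaf <- res$fluxes$evaporation[["leaf"]] / 60
  e_flower <- res$fluxes$evaporation[["flower"]] / 60
  ks <- vapply(p$organs, function(o) o$k_abs, numeric(1)) *
    water_viscosity_ratio(20, 20)
  pred_leaf <- 0 - (e_leaf + e_flower) * (1 / ks["root"] + 1 / ks["stem"]) -
    e_leaf * (1 / ks["branch"] + 1 / ks["leaf"])
  expect_equal(p$organs$leaf$psi_apo, unname(pred_leaf), tolerance = 0.02)
})

test_that("water is conserved and PLC never decreases", {
  p <- initialize_at_soil_psi(build_plant(), -1)
  tr <- simulate_heatwave(p, short_scenario())
  expect_lt(attr(tr, "conservation_error"), 0.001)
  for (nm in names(p$organs))
    expect_true(all(diff(tr[[paste0("plc_", nm)]]) >= -1e-9))
  expect_true(all(diff(tr$t_s) > 0))
})

test_that("halving the inner step barely changes the outcome", {
  p <- initialize_at_soil_psi(build_plant(), -1.25)
  sc <- short_scenario()
  a <- simulate_heatwave(p, sc, dt_inner = 2)
  b <- simulate_heatwave(p, sc, dt_inner = 1)
  ea <- attr(a, "end_of_heat"); eb <- attr(b, "end_of_heat")
  expect_lt(abs(ea$plc_flower - eb$plc_flower), 0.5)
  expect_lt(abs(ea$plc_leaf - eb$plc_leaf), 0.5)
})

test_that("beyond the analytical threshold the flower runs away", {
  p <- initialize_at_soil_psi(build_plant(), -1.25)
  tr <- simulate_heatwave(p, default_scenario())
  thr <- plc_runaway(default_organ_params()$flower, heat_air())$plc_runaway
  crossed <- which(tr$plc_flower > thr & tr$in_heat)
  expect_gt(length(crossed), 0)
  expect_gt(max(tr$plc_flower), 95)   # irreversible completion
  expect_true(all(diff(tr$plc_flower) >= -1e-9))
})

test_that("a three-level mini grid is ordered and soil-stable", {
  p <- build_plant()
  grid <- run_experiment_grid(p, c(0, -0.75, -1.25),
                              scenario = short_scenario())
  expect_equal(nrow(grid), 3L)
  expect_true(all(diff(grid$plc_flower_end) >= -1e-6))   # monotone in drought
  # 0.1-point slack: at wet levels both organs sit in sub-percent sigmoid
  # tails, where the shallow leaf curve can minutely exceed the flower's
  expect_true(all(grid$plc_flower_end >= grid$plc_leaf_end - 0.1))
  expect_lt(mean(abs(grid$delta_psi_soil)), 0.1)
  one <- run_experiment_grid(p, -1.25, scenario = short_scenario())
  expect_equal(nrow(one), 1L)
  expect_error(run_experiment_grid(p, numeric(0)), "non-empty")
})
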