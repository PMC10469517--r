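# SurEau-style dynamics: dual time-stepping with a quasi-static apoplast
# (direct linear solve) and explicit, adaptively sub-stepped symplast
# storage. Cavitation, transpiration and the redistribution of water
# released by cavitation are updated at the outer step (default 60 s).

#' Climate scenario for a heat-wave run
#'
#' Piecewise-constant timeline of air temperature, relative humidity and
#' photosynthetic photon flux density. The default reproduces the published
#' protocol: a 25 degC ambient hour, a 180-min episode at 40 degC / 12 % RH
#' (VPD 6.5 kPa), then an ambient hour.
#'
#' @param segments data.frame with columns `duration_s, t_air, rh, ppfd` in
#'   chronological order.
#' @param heat_start Start of the heat window, s from run start.
#' @param heat_duration Heat window length, s.
#' @return Object of class `climate_scenario`.
#' @export
climate_scenario <- function(segments, heat_start, heat_duration) {
  stopifnot(is.data.frame(segments),
            all(c("duration_s", "t_air", "rh", "ppfd") %in% names(segments)),
            all(segments$duration_s > 0))
  total <- sum(segments$duration_s)
  if (heat_start < 0 || heat_start + heat_duration > total)
    stop("heat window must lie within the scenario timeline")
  structure(list(segments = segments, heat_start = heat_start,
                 heat_duration = heat_duration, total_s = total),
            class = "climate_scenario")
}

#' @rdname climate_scenario
#' @param t_heat Heat-wave air temperature, degC (default 40).
#' @param rh_heat Heat-wave relative humidity, % (default 12).
#' @param heat_s Heat duration, s (default 3 h).
#' @param ambient_s Length of the ambient segments flanking the heat wave, s.
#' @export
default_scenario <- function(t_heat = 40, rh_heat = 12, heat_s = 180 * 60,
                             ambient_s = 3600) {
  seg <- data.frame(
    duration_s = c(ambient_s, heat_s, ambient_s),
    t_air = c(25, t_heat, 25),
    rh = c(50, rh_heat, 50),
    ppfd = c(500, 500, 500))
  climate_scenario(seg, heat_start = ambient_s, heat_duration = heat_s)
}

#' Climate at a time point
#' @param scenario A [climate_scenario()].
#' @param t Time from run start, s.
#' @return List with `t_air`, `rh`, `ppfd`, `in_heat`.
#' @export
climate_at <- function(scenario, t) {
  edges <- cumsum(scenario$segments$duration_s)
  i <- min(findInterval(t, c(0, edges), rightmost.closed = TRUE),
           nrow(scenario$segments))
  s <- scenario$segments[i, ]
  list(t_air = s$t_air, rh = s$rh, ppfd = s$ppfd,
       in_heat = t >= scenario$heat_start &&
         t < scenario$heat_start + scenario$heat_duration)
}

#' Initialise the plant at a given soil water potential
#'
#' Sets the soil bucket by the inverted retention curve, then equilibrates
#' the plant to the steady state under predawn ambient conditions (default
#' 15 degC, 90 % RH, dark): stomata are closed, only residual transpiration
#' flows, and every compartment potential solves the steady network.
#' Because residual demand cannot be shut off, a daytime steady state does
#' not exist in dry soil; the predawn state always does and mirrors how such
#' plants are actually sampled (predawn water potentials). PLC is
#' initialised from each organ's vulnerability curve at its steady-state
#' apoplast potential.
#'
#' @param plant A [build_plant()] result.
#' @param psi_soil Initial soil water potential, MPa (<= 0).
#' @param init_climate List with `t_air`, `rh`, `ppfd` for the equilibration
#'   climate. Default `list(t_air = 15, rh = 90, ppfd = 0)`.
#' @return The plant with soil theta, compartment states and PLC set.
#' @export
initialize_at_soil_psi <- function(plant, psi_soil,
                                   init_climate = list(t_air = 15, rh = 90,
                                                       ppfd = 0)) {
  stopifnot(inherits(plant, "plant_state"))
  if (psi_soil > 0) stop("psi_soil must be <= 0")
  plant$soil$theta <- vg_theta(plant$soil$vg, psi_soil)  # errors if below residual
  se <- (plant$soil$theta - plant$soil$vg$theta_r) /
    (plant$soil$vg$theta_s - plant$soil$vg$theta_r)
  if (se < 1e-6) stop("psi_soil below the residual-theta limit of the soil")

  t_air <- init_climate$t_air
  air <- air_state(t_air, init_climate$rh)
  ref_t <- plant$reference_temperature
  nms <- names(plant$organs)
  psi <- rep(psi_soil, length(nms)); names(psi) <- nms
  k_rz <- .k_rhizosphere(plant$soil)

  for (iter in 1:200) {
    # evaporative demand at current potentials
    e_abs <- sapply(nms, function(nm) {
      o <- plant$organs[[nm]]
      if (is.null(o$g_res)) return(0)
      g <- .organ_g_res(o, t_air)
      if (nm == "leaf")
        g <- g + .g_stomatal(plant$stomata, psi[[nm]], init_climate$ppfd)
      convert_flux(g, air, "g2E") * o$area
    })
    # conductances at current (iterated) PLC
    k_edges <- sapply(nms, function(nm) {
      o <- plant$organs[[nm]]
      o$plc <- cumulative_cavitation(.curve_at_t(o, ref_t, t_air), psi[[nm]])
      ke <- .k_edge(o, ref_t, t_air)
      if (o$parent == "soil") 1 / (1 / ke + 1 / max(k_rz, 1e-12)) else ke
    })
    # steady state: symplast potentials equal apoplast, no storage flux
    for (nm in nms) plant$organs[[nm]]$psi_sym <- psi[[nm]]
    zero <- stats::setNames(rep(0, length(nms)), nms)
    psi_new <- .solve_apoplast(plant, as.list(k_edges), psi_soil,
                               as.list(e_abs), as.list(zero), k_sym_on = FALSE)
    names(psi_new) <- nms
    if (max(abs(psi_new - psi)) < 1e-8) { psi <- psi_new; break }
    psi <- 0.5 * psi + 0.5 * psi_new
  }

  for (nm in nms) {
    o <- plant$organs[[nm]]
    o$psi_apo <- o$psi_sym <- psi[[nm]]
    o$plc <- cumulative_cavitation(.curve_at_t(o, ref_t, t_air), psi[[nm]])
    o$r_sym <- pv_r(o$pv, min(psi[[nm]], 0), pi0 = .pi0_at_t(o, ref_t, t_air))
    o$pending_release <- 0
    o$desiccated <- FALSE
    plant$organs[[nm]] <- o
  }
  plant$time <- 0
  plant
}

#' Advance the plant by one outer time step
#'
#' One 60-s (default) step of the dual-time-step integrator:
#' \enumerate{
#'   \item boundary fluxes from the climate: leaf transpiration uses
#'     stomatal + residual conductance at leaf temperature (energy budget),
#'     the flower loses water through residual conductance only;
#'   \item inner integration: quasi-static apoplast network solved by a
#'     direct linear solve, symplast storage advanced explicitly with
#'     adaptive sub-steps limited by the symplast time constant;
#'   \item cavitation update from the minimum apoplast potential over the
#'     step (PLC is a ratchet: the running maximum), with the released
#'     conduit water credited to the organ's apoplast node;
#'   \item soil bucket decremented by root uptake;
#'   \item temperature effects: viscosity on conductances, surface tension
#'     on P50, van't Hoff on osmotic potential.
#' }
#'
#' @param plant A `plant_state`.
#' @param climate List with `t_air`, `rh`, `ppfd` (see [climate_at()]).
#' @param dt_outer Outer step, s (default 60).
#' @param dt_inner Optional fixed inner step, s; `NULL` (default) selects
#'   adaptively from the symplast time constants. Small fixed values (e.g.
#'   0.001) reproduce the explicit reference integrator.
#' @return List `plant` (advanced state) and `fluxes` (named evaporation,
#'   uptake and release, mmol, plus `t_leaf`).
#' @export
step_plant <- function(plant, climate, dt_outer = 60, dt_inner = NULL) {
  stopifnot(inherits(plant, "plant_state"), dt_outer > 0)
  ref_t <- plant$reference_temperature
  t_air <- climate$t_air
  air <- air_state(t_air, climate$rh)
  nms <- names(plant$organs)

  # (i) boundary fluxes, fixed over the outer step
  e_leaf_area_prev <- plant$e_leaf_area %||% 0
  t_leaf <- .leaf_temperature(plant$energy_budget, t_air, climate$ppfd,
                              e_leaf_area_prev)
  e_abs <- stats::setNames(rep(0, length(nms)), nms)
  for (nm in nms) {
    o <- plant$organs[[nm]]
    if (is.null(o$g_res) || o$desiccated) next
    g <- .organ_g_res(o, t_air)
    org_air <- air
    if (nm == "leaf") {
      g <- g + .g_stomatal(plant$stomata, o$psi_sym, climate$ppfd)
      rh_leaf <- min(climate$rh * saturation_vapor_pressure(t_air) /
                       saturation_vapor_pressure(t_leaf), 100)
      org_air <- air_state(t_leaf, rh_leaf)
    }
    e_abs[[nm]] <- convert_flux(g, org_air, "g2E") * o$area
  }
  plant$e_leaf_area <- if (!is.null(plant$organs$leaf))
    e_abs[["leaf"]] / plant$organs$leaf$area else 0

  # cavitation-released water from the previous step enters as a source
  src <- sapply(nms, function(nm) plant$organs[[nm]]$pending_release / dt_outer)
  for (nm in nms) plant$organs[[nm]]$pending_release <- 0

  k_rz <- .k_rhizosphere(plant$soil)
  psi_soil <- vg_psi(plant$soil$vg, plant$soil$theta)
  k_edges <- sapply(nms, function(nm) {
    o <- plant$organs[[nm]]
    ke <- .k_edge(o, ref_t, t_air)
    if (o$parent == "soil") 1 / (1 / max(ke, 1e-12) + 1 / max(k_rz, 1e-12)) else ke
  })

  # (ii) inner integration
  elapsed <- 0
  uptake <- 0
  evap <- stats::setNames(rep(0, length(nms)), nms)
  psi_min <- sapply(nms, function(nm) plant$organs[[nm]]$psi_apo)
  pi0_t <- sapply(nms, function(nm)
    .pi0_at_t(plant$organs[[nm]], ref_t, t_air))

  while (elapsed < dt_outer) {
    if (is.null(dt_inner)) {
      tau <- sapply(nms, function(nm) {
        o <- plant$organs[[nm]]
        cap <- o$v_sym * abs(pv_capacitance(o$pv, o$r_sym,
                                            pi0 = pi0_t[[nm]]))
        cap / max(o$k_sym, 1e-9)
      })
      dt <- max(min(0.25 * min(tau), dt_outer - elapsed), 1e-3)
    } else {
      dt <- min(dt_inner, dt_outer - elapsed)
    }

    psi_apo <- .solve_apoplast(plant, as.list(k_edges), psi_soil,
                               as.list(e_abs), as.list(src))
    names(psi_apo) <- nms
    if (any(!is.finite(psi_apo)))
      stop(sprintf("integration diverged (non-finite potential) at t = %.0f s",
                   plant$time + elapsed))

    for (i in seq_along(nms)) {
      nm <- nms[i]
      o <- plant$organs[[nm]]
      j_sym <- o$k_sym * (psi_apo[[nm]] - o$psi_sym)    # into symplast
      w <- o$r_sym * o$v_sym + j_sym * dt
      r_floor <- 0.05
      if (w < r_floor * o$v_sym) {
        # tissue has desiccated: stop withdrawing below the floor and shut
        # the organ's evaporation off from the next solve onwards
        short <- r_floor * o$v_sym - w
        w <- r_floor * o$v_sym
        evap[[nm]] <- evap[[nm]] - short   # water never actually evaporated
        o$desiccated <- TRUE
        e_abs[[nm]] <- 0
      }
      o$r_sym <- w / o$v_sym
      o$psi_sym <- pv_psi(o$pv, o$r_sym, pi0 = pi0_t[[nm]])
      o$psi_apo <- psi_apo[[nm]]
      plant$organs[[nm]] <- o
      psi_min[[nm]] <- min(psi_min[[nm]], psi_apo[[nm]])
      evap[[nm]] <- evap[[nm]] + e_abs[[nm]] * dt
    }
    uptake <- uptake + k_edges[["root"]] * (psi_soil - psi_apo[["root"]]) * dt
    elapsed <- elapsed + dt
  }

  # (iii) cavitation ratchet + release of conduit water
  for (nm in nms) {
    o <- plant$organs[[nm]]
    plc_new <- max(o$plc,
                   cumulative_cavitation(.curve_at_t(o, ref_t, t_air),
                                         psi_min[[nm]]))
    released <- (plc_new - o$plc) / 100 * o$v_apo
    o$pending_release <- o$pending_release + released
    o$plc <- plc_new
    plant$organs[[nm]] <- o
  }

  # (iv) soil bucket
  plant$soil$theta <- plant$soil$theta - uptake * .MMOL_TO_M3 / plant$soil$volume

  plant$time <- plant$time + dt_outer
  list(plant = plant,
       fluxes = list(evaporation = evap, uptake = uptake,
                     release = sapply(nms, function(nm)
                       plant$organs[[nm]]$pending_release),
                     t_leaf = t_leaf, psi_soil = psi_soil))
}

#' Total water held in the plant (symplast + water-filled conduits), mmol
#' @param plant A `plant_state`.
#' @return mmol of water.
#' @export
plant_water <- function(plant) {
  sum(sapply(plant$organs, function(o)
    o$r_sym * o$v_sym + (1 - o$plc / 100) * o$v_apo + o$pending_release))
}

#' Simulate a heat-wave scenario
#'
#' Runs [step_plant()] over the full scenario timeline and records a trace
#' at outer-step resolution.
#'
#' @param plant An initialised `plant_state` (see [initialize_at_soil_psi()]).
#' @param scenario A [climate_scenario()].
#' @param dt_outer Outer step, s (default 60).
#' @param dt_inner Optional fixed inner step, s (see [step_plant()]).
#' @return Object of class `simulation_trace`: a data.frame with columns
#'   `t_s`, `psi_<organ>`, `plc_<organ>`, `psi_soil`, `E_leaf`, `E_flower`
#'   (mmol s-1), `T_leaf`, `in_heat`, with attributes `end_of_heat` (row
#'   summary at the last heat step) and `conservation_error` (relative mass
#'   balance error of the whole run).
#' @export
simulate_heatwave <- function(plant, scenario, dt_outer = 60, dt_inner = NULL) {
  stopifnot(inherits(plant, "plant_state"), inherits(scenario, "climate_scenario"))
  nms <- names(plant$organs)
  n_steps <- ceiling(scenario$total_s / dt_outer)
  rows <- vector("list", n_steps)
  w0 <- plant_water(plant) +
    plant$soil$theta * plant$soil$volume / .MMOL_TO_M3
  evap_total <- 0
  end_of_heat <- NULL

  for (i in seq_len(n_steps)) {
    cl <- climate_at(scenario, (i - 1) * dt_outer)
    res <- step_plant(plant, cl, dt_outer = dt_outer, dt_inner = dt_inner)
    plant <- res$plant
    fx <- res$fluxes
    evap_total <- evap_total + sum(fx$evaporation)
    row <- data.frame(t_s = plant$time)
    for (nm in nms) {
      row[[paste0("psi_", nm)]] <- plant$organs[[nm]]$psi_apo
      row[[paste0("plc_", nm)]] <- plant$organs[[nm]]$plc
    }
    row$psi_soil <- fx$psi_soil
    row$E_leaf <- fx$evaporation[["leaf"]] / dt_outer
    row$E_flower <- if ("flower" %in% nms)
      fx$evaporation[["flower"]] / dt_outer else NA_real_
    row$T_leaf <- fx$t_leaf
    row$in_heat <- cl$in_heat
    rows[[i]] <- row
    if (cl$in_heat) end_of_heat <- row
  }

  trace <- do.call(rbind, rows)
  w1 <- plant_water(plant) +
    plant$soil$theta * plant$soil$volume / .MMOL_TO_M3
  attr(trace, "conservation_error") <-
    abs((w0 - w1) - evap_total) / max(evap_total, 1e-9)
  attr(trace, "end_of_heat") <- end_of_heat
  attr(trace, "final_plant") <- plant
  class(trace) <- c("simulation_trace", "data.frame")
  trace
}

#' Heat-wave grid over initial soil water potentials
#'
#' Repeats [simulate_heatwave()] from each initial soil water potential
#' (default: the seven published levels 0 to -1.5 MPa) and summarises
#' end-of-heat organ PLC and the soil drawdown.
#'
#' @param plant A built (not necessarily initialised) `plant_state`.
#' @param psi_levels Initial soil water potentials, MPa (non-empty).
#' @param scenario A [climate_scenario()]; default [default_scenario()].
#' @param dt_outer Outer step, s.
#' @param keep_traces Keep full traces as an attribute? Default FALSE.
#' @return data.frame with one row per level: `psi_soil_init`,
#'   `plc_flower_end`, `plc_leaf_end`, `delta_psi_soil`, `psi_leaf_min`.
#' @export
run_experiment_grid <- function(plant,
                                psi_levels = c(0, -0.25, -0.5, -0.75, -1,
                                               -1.25, -1.5),
                                scenario = default_scenario(),
                                dt_outer = 60, keep_traces = FALSE) {
  if (length(psi_levels) == 0L) stop("psi_levels must be non-empty")
  traces <- list()
  rows <- lapply(psi_levels, function(ps) {
    p <- initialize_at_soil_psi(plant, ps)
    tr <- simulate_heatwave(p, scenario, dt_outer = dt_outer)
    if (keep_traces) traces[[as.character(ps)]] <<- tr
    eoh <- attr(tr, "end_of_heat")
    data.frame(psi_soil_init = ps,
               plc_flower_end = if ("plc_flower" %in% names(eoh))
                 eoh$plc_flower else NA_real_,
               plc_leaf_end = eoh$plc_leaf,
               delta_psi_soil = eoh$psi_soil - ps,
               psi_leaf_min = min(tr$psi_leaf))
  })
  out <- do.call(rbind, rows)
  if (keep_traces) attr(out, "traces") <- traces
  out
}

#' Write a simulation trace as CSV
#' @param trace A `simulation_trace`.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
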