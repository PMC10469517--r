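# Orchestration: reproduce the computational tables and simulation grid,
# and analyse an (optical) experiment end to end.

#' Reproduce the analytical threshold tables
#'
#' Recomputes, from the organ parameter table and the two stated conditions
#' (20 degC / 40 % RH and 40 degC / 12 % RH), the derived quantities E_res
#' and viscosity-corrected K_max plus the runaway threshold for every
#' organ x temperature cell, and flags any cell deviating from a supplied
#' reference by more than a tolerance.
#'
#' @param organs List of [organ_params()]; default [default_organ_params()].
#' @param conditions List of [air_state()]; default the two stated ones.
#' @param reference Optional data.frame with columns `organ`, `temp_C`,
#'   `plc_runaway` to compare against.
#' @param tolerance Flagging tolerance, percentage points. Default 0.2.
#' @return The [runaway_table()] data.frame, with `reference` and
#'   `within_tolerance` columns when a reference is given.
#' @export
reproduce_tables <- function(organs = default_organ_params(),
                             conditions = list(air_state(20, 40),
                                               air_state(40, 12)),
                             reference = NULL, tolerance = 0.2) {
  tab <- runaway_table(organs, conditions)
  if (!is.null(reference)) {
    key <- paste(tab$organ, tab$temp_C)
    ref <- reference$plc_runaway[match(key, paste(reference$organ,
                                                  reference$temp_C))]
    tab$reference <- ref
    tab$within_tolerance <- abs(tab$plc_runaway - ref) <= tolerance
  }
  tab
}

#' Reproduce the heat-wave simulation grid
#'
#' Runs the seven-level soil water potential grid through the simulator and
#' asserts the qualitative tipping behaviour: end-of-heat flower PLC is
#' monotone in drought severity, complete flower failure occurs at
#' -1.25 MPa, and leaf PLC stays bounded everywhere.
#'
#' @param plant A `plant_state`; default [build_plant()].
#' @param psi_levels Grid levels, MPa. Default the seven stated ones.
#' @param scenario A [climate_scenario()]; default [default_scenario()].
#' @param leaf_bound Leaf damage bound, percent. Default 7.5.
#' @param out_dir Optional directory for trace CSVs and the summary.
#' @return The grid summary data.frame, with attribute `checks` (named
#'   logical vector: `flower_monotone`, `flower_fails_at_-1.25`,
#'   `leaf_bounded`, `soil_drawdown_small`).
#' @export
reproduce_simulation_grid <- function(plant = build_plant(),
                                      psi_levels = c(0, -0.25, -0.5, -0.75,
                                                     -1, -1.25, -1.5),
                                      scenario = default_scenario(),
                                      leaf_bound = 7.5, out_dir = NULL) {
  keep <- !is.null(out_dir)
  grid <- run_experiment_grid(plant, psi_levels, scenario, keep_traces = keep)
  ord <- order(-grid$psi_soil_init)   # increasing drought severity
  flower <- grid$plc_flower_end[ord]
  checks <- c(
    flower_monotone = all(diff(flower) >= -1e-6),
    `flower_fails_at_-1.25` =
      !any(abs(psi_levels + 1.25) < 1e-9) ||
      grid$plc_flower_end[which.min(abs(grid$psi_soil_init + 1.25))] >= 99.5,
    leaf_bounded = all(grid$plc_leaf_end < leaf_bound),
    soil_drawdown_small = mean(abs(grid$delta_psi_soil)) < 0.1)
  if (keep) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(grid[setdiff(names(grid), "traces")],
                     file.path(out_dir, "grid_summary.csv"), row.names = FALSE)
    trs <- attr(grid, "traces")
    for (nm in names(trs))
      write_trace(trs[[nm]], file.path(out_dir, paste0("trace_", nm, ".csv")))
  }
  attr(grid, "checks") <- checks
  grid
}

#' Analyse one optical cavitation experiment
#'
#' Full per-stem report: cumulative embolism before and after the heat
#' window, cavitation rate during heat, thickness-derived water potential
#' before/after (when a shrinkage model and reference thickness are
#' available), and the tipping classification of the post-heat embolism
#' level against the runaway threshold at the heat temperature.
#'
#' @param stack An [image_stack()] (or directory readable by
#'   [read_stack()]).
#' @param heat_start,heat_end Heat window, s.
#' @param shrinkage_model Optional [fit_shrinkage()] model.
#' @param reference_thickness Optional maximum thickness (px) at field
#'   capacity, for percent-of-maximum conversion.
#' @param organ An [organ_params()] for the threshold; default the packaged
#'   flower.
#' @param heat_air [air_state()] of the heat treatment; default 40 degC /
#'   12 % RH.
#' @param ... Passed to [cumulative_embolism()].
#' @return List of class `experiment_report`: `curve`, `pre_heat_pct`,
#'   `post_heat_pct`, `rate_pct_per_h`, `psi_pre`, `psi_post`,
#'   `plc_runaway`, `classification`.
#' @export
analyze_experiment <- function(stack, heat_start, heat_end,
                               shrinkage_model = NULL,
                               reference_thickness = NULL,
                               organ = default_organ_params()[["flower"]],
                               heat_air = air_state(40, 12), ...) {
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "image_stack"), heat_start < heat_end)
  curve <- tryCatch(cumulative_embolism(stack, ...),
                    error = function(e) e)
  no_events <- inherits(curve, "error")
  if (no_events && !grepl("no cavitation detected", conditionMessage(curve)))
    stop(curve)
  pre <- if (no_events) 0 else embolism_at(curve, heat_start)
  post <- if (no_events) 0 else embolism_at(curve, heat_end)
  rate <- if (no_events) 0 else cavitation_rate(curve, heat_start, heat_end)
  thr <- plc_runaway(organ, heat_air)
  psi_pre <- psi_post <- NA_real_
  if (!is.null(shrinkage_model) && !is.null(reference_thickness)) {
    frame_at <- function(t) {
      i <- max(findInterval(t, stack$timestamps), 1L)
      stack$frames[[i]]
    }
    th_pre <- measure_thickness(frame_at(heat_start),
                                reference = reference_thickness)
    th_post <- measure_thickness(frame_at(heat_end),
                                 reference = reference_thickness)
    psi_pre <- predict_psi(shrinkage_model, th_pre$pct_of_max,
                           warn_outside = FALSE)
    psi_post <- predict_psi(shrinkage_model, th_post$pct_of_max,
                            warn_outside = FALSE)
  }
  structure(list(curve = if (no_events) NULL else curve,
                 pre_heat_pct = pre, post_heat_pct = post,
                 rate_pct_per_h = rate,
                 psi_pre = psi_pre, psi_post = psi_post,
                 plc_runaway = thr$plc_runaway,
                 classification = classify_tipping(post, thr)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(paste0("<experiment_report> pre-heat %.1f %%, post-heat %.1f %%",
                     " (rate %.2f %%/h)\n  threshold %.1f %% -> %s\n"),
              x$pre_heat_pct, x$post_heat_pct, x$rate_pct_per_h,
              x$plc_runaway, as.character(x$classification)))
  if (!is.na(x$psi_pre))
    cat(sprintf("  psi (thickness proxy): %.2f -> %.2f MPa\n",
                x$psi_pre, x$psi_post))
  invisible(x)
}
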