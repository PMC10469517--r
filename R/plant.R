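# Plant network construction and initialisation for the hydraulic simulator.
#
# Topology (fixed): soil -> root -> stem -> { branch -> leaf ; flower }.
# Each organ owns the conductance of its supply edge (the path from its
# parent node into the organ) and carries a symplast storage compartment
# (pressure-volume curve) plus an apoplast (xylem) compartment whose filled
# fraction is 1 - PLC/100.

.ML_TO_MMOL <- 1000 / 18.015      # 1 mL water = 55.51 mmol
.MMOL_TO_M3 <- 18.015e-9          # 1 mmol water = 1.8015e-8 m3

.ORGAN_ORDER <- c("root", "stem", "branch", "leaf", "flower")
.PARENT <- c(root = "soil", stem = "root", branch = "stem",
             leaf = "branch", flower = "stem")

#' Build a soil-plant hydraulic network
#'
#' Constructs the five-organ network (root, stem, branch, leaf, flower; a
#' flowerless four-organ plant is allowed) with symplast/apoplast
#' compartments and a finite soil bucket, from a configuration list or JSON
#' file. The packaged default parameterises a potted pyrethrum plant: 0.6 m2
#' leaf and 0.07 m2 flower projected area over 0.054 m3 of loam, with
#' fine-root surface area equal to total leaf area (root supply-edge
#' conductance is set accordingly from the rhizosphere model).
#'
#' @param config A configuration list matching the schema of
#'   `inst/extdata/plant_default.json`, a path to such a JSON file, or `NULL`
#'   for the packaged default.
#' @return Object of class `plant_state`.
#' @examples
#' p <- build_plant()
#' names(p$organs)
#' @export
build_plant <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "plant_default.json",
                          package = "floralhydra", mustWork = TRUE)
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  need <- c("organs", "areas", "soil")
  if (!all(need %in% names(config)))
    stop("plant config must contain fields: ", paste(need, collapse = ", "))
  organs_cfg <- config$organs
  wanted <- intersect(.ORGAN_ORDER, names(organs_cfg))
  if (!all(c("root", "stem", "branch", "leaf") %in% wanted))
    stop("config must define at least root, stem, branch and leaf")

  organs <- lapply(wanted, function(nm) {
    oc <- organs_cfg[[nm]]
    area <- if (nm %in% names(config$areas)) config$areas[[nm]] else NA_real_
    k_abs <- if (!is.null(oc$k_abs)) oc$k_abs else {
      if (is.null(oc$k_max_area) || is.na(area))
        stop("organ '", nm, "' needs k_abs, or k_max_area plus an area")
      oc$k_max_area * area
    }
    if (!is.finite(k_abs) || k_abs <= 0)
      stop("organ '", nm, "' has non-positive supply conductance")
    pv <- pv_params(oc$pi0, oc$epsilon)
    list(name = nm,
         parent = .PARENT[[nm]],
         area = area,
         k_abs = k_abs,                       # supply edge, mmol s-1 MPa-1 at ref T
         k_sym = oc$k_sym_abs,                # symplast exchange, mmol s-1 MPa-1
         g_res = if (!is.null(oc$g_res)) unlist(oc$g_res) else NULL,
         curve = vulnerability_curve(oc$a, oc$p50, label = nm),
         pv = pv,
         v_sym = oc$v_sym_ml * .ML_TO_MMOL,   # mmol at full hydration
         v_apo = oc$v_apo_ml * .ML_TO_MMOL,
         plc = 0,
         r_sym = 1,
         psi_sym = 0,
         psi_apo = 0,
         pending_release = 0,
         desiccated = FALSE)
  })
  names(organs) <- wanted

  sc <- config$soil
  vg <- vg_params(sc$theta_r, sc$theta_s, sc$alpha_MPa_inv, sc$n)
  soil <- list(volume = sc$volume_m3, vg = vg,
               theta = sc$theta_s,
               root_length = sc$root_length_m,
               k_rhiz_max = sc$k_rhizosphere_max)

  structure(list(organs = organs, soil = soil,
                 stomata = config$stomata,
                 energy_budget = config$energy_budget,
                 reference_temperature = config$reference_temperature %||% 20,
                 time = 0),
            class = "plant_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plant_state <- function(x, ...) {
  cat(sprintf("<plant_state> %d organs, soil %.3f m3 (theta = %.3f, psi = %.3f MPa)\n",
              length(x$organs), x$soil$volume, x$soil$theta,
              vg_psi(x$soil$vg, x$soil$theta)))
  for (o in x$organs)
    cat(sprintf("  %-7s psi_apo = %7.3f  psi_sym = %7.3f  PLC = %5.1f %%\n",
                o$name, o$psi_apo, o$psi_sym, o$plc))
  invisible(x)
}

# Residual conductance of an organ at temperature t: linear interpolation
# between printed 20/40 degC values, flat outside; scalar used as-is.
.organ_g_res <- function(organ, t) {
  g <- organ$g_res
  if (is.null(g)) return(0)
  if (length(g) == 1L) return(g)
  stats::approx(c(20, 40), g, xout = t, rule = 2)$y
}

# Rhizosphere (soil -> root surface) conductance at current soil moisture,
# mmol s-1 MPa-1: saturated value scaled by the Mualem relative conductivity.
.k_rhizosphere <- function(soil) {
  soil$k_rhiz_max * vg_k_rel(soil$vg, soil$theta)
}

# Stomatal conductance model, mmol m-2 s-1: sigmoidal down-regulation with
# leaf water potential (closing fraction set so conductance is reduced 90 %
# at -2.1 MPa with the default psi_gs50/k_gs pair) times a saturating light
# response (zero in the dark).
.g_stomatal <- function(stomata, psi_leaf, ppfd) {
  f_psi <- 1 / (1 + exp(-stomata$k_gs * (psi_leaf - stomata$psi_gs50)))
  f_light <- ppfd / (ppfd + stomata$light_half_ppfd)
  stomata$g_s_max * f_psi * f_light
}

# Leaf temperature from a one-line steady-state energy budget:
# T_leaf = T_air + (absorbed shortwave - latent) / sensible conductance.
.leaf_temperature <- function(eb, t_air, ppfd, e_leaf_area) {
  dT <- (eb$absorptance * ppfd * eb$k_rad_W_per_umol -
           eb$lambda_J_per_mmol * e_leaf_area) / eb$g_bH_W_m2_K
  t_air + max(min(dT, 8), -8)
}

# Effective supply-edge conductance of an organ at temperature t (viscosity
# corrected, cavitation reduced).
.k_edge <- function(organ, ref_t, t) {
  organ$k_abs * water_viscosity_ratio(ref_t, t) * (1 - organ$plc / 100)
}

# Temperature-adjusted vulnerability curve (P50 scales with surface tension).
.curve_at_t <- function(organ, ref_t, t) {
  vulnerability_curve(organ$curve$a,
                      organ$curve$p50 * surface_tension_ratio(ref_t, t),
                      label = organ$name)
}

# Temperature-adjusted osmotic potential (van't Hoff).
.pi0_at_t <- function(organ, ref_t, t) {
  organ$pv$pi0 * (t + 273.15) / (ref_t + 273.15)
}

# Quasi-static apoplast network solve. Unknowns: psi_apo of each organ.
# Node balance: sum_edges K_e (psi_parent - psi_i) - sum_children K_c (psi_i
# - psi_child) + k_sym (psi_sym - psi_i) - E_i + S_i = 0. Returns psi vector.
.solve_apoplast <- function(plant, k_edges, psi_soil, e_abs, src, k_sym_on = TRUE) {
  nms <- names(plant$organs)
  n <- length(nms)
  A <- matrix(0, n, n, dimnames = list(nms, nms))
  b <- numeric(n); names(b) <- nms
  for (i in seq_len(n)) {
    nm <- nms[i]
    o <- plant$organs[[nm]]
    ke <- k_edges[[nm]]
    A[i, i] <- A[i, i] + ke
    if (o$parent == "soil") b[i] <- b[i] + ke * psi_soil
    else {
      j <- match(o$parent, nms)
      A[i, j] <- A[i, j] - ke
      A[j, i] <- A[j, i] - ke
      A[j, j] <- A[j, j] + ke
    }
    ks <- if (k_sym_on) o$k_sym else 0
    A[i, i] <- A[i, i] + ks
    b[i] <- b[i] + ks * o$psi_sym - e_abs[[nm]] + src[[nm]]
  }
  # Guard: a fully cavitated, dark node can have a singular row; add a tiny
  # leak to soil potential for numerical stability.
  diag(A) <- diag(A) + 1e-12
  as.numeric(solve(A, b))
}
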