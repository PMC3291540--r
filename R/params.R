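#' Default model parameters
#'
#' Builds the full parameter set of the simulator: actin dynamics, Rho-family
#' GTPase kinetics, phosphoinositide (PI) dynamics, Cellular Potts mechanics
#' and numerical settings. Baseline activation/input rates that are not free
#' (the GTPase input rates and three PI rates) are solved so that the stated
#' basal concentrations are an exact homogeneous steady state; this guarantees
#' that the resting cell is identical for every value of the PI feedback
#' strength \code{eta}.
#'
#' Units: lengths in micrometres, time in seconds, concentrations in uM,
#' barbed-end densities in ends/um^2 (free) and ends/um (pushing).
#'
#' @param eta PI feedback strength in [0, 1]: 0 = Cdc42/Rac activation
#'   independent of PIP2, 1 = activation impossible without PIP2.
#' @param ... named overrides for any default entry (unknown names error).
#' @return A named list of class \code{polarcpm_params}.
#' @export
#' @examples
#' p <- default_params(eta = 0)
#' p$tot_cdc42
default_params <- function(eta = 0.5, ...) {
  p <- list(
    ## -- GTPase block --------------------------------------------------
    tot_cdc42 = 2.4, tot_rac = 7.5, tot_rho = 3.1,   # conserved totals (uM)
    bas_cdc42 = 1.0, bas_rac = 3.0, bas_rho = 1.25,  # basal active levels (uM)
    # half-max inhibition constants: basal Rho sits at 1.3x a_rho (sensitive),
    # basal Cdc42 at 0.9x a_cdc (below the knee -> attracting rest state)
    a_rho = 1.25 / 1.3,
    a_cdc = 1.0 / 0.9,
    n_gtp = 3,                 # Hill coefficient of the mutual inhibition
    alpha_rac = 0.5,           # Cdc42-dependent Rac activation (/uM/s)
    beta_rho = 0.5,            # Rac-dependent Rho activation (/uM/s)
    d_gtp = 1.0,               # decay rate of the activated forms (/s)
    D_act = 0.2,               # membrane-bound (active) diffusion (um^2/s)
    D_cyt = 20,                # cytosolic diffusion (um^2/s)
    frac_membrane = 0.25,      # time fraction an inactive molecule is membrane-bound
    ## -- PI feedback ---------------------------------------------------
    eta = eta,
    fb_hill = 4,               # Hill coefficient of the PIP2 feedback sigmoid
    fb_half_rel = 1.45,        # sigmoid half-max as multiple of basal PIP2
    fb_amp_weight = 0.5,       # PIP2-feedback weight on the Cdc42->Rac amplification term
    ## -- PI block ------------------------------------------------------
    bas_pip = 5, bas_pip2 = 5, bas_pip3 = 0.25,      # basal lipid levels (uM)
    d_pi = 0.15,               # PIP / PIP2 decay rate (/s)
    k_pip2_pip = 0.02,         # PIP2 -> PIP conversion (/s)
    k_pi3k = 0.005,            # baseline PIP2 -> PIP3 conversion by PI3K (/s)
    D_pi = 1.0,                # lipid diffusion (um^2/s)
    rac_2x = 3.0,              # Rac level doubling PI5K/PI3K activity (uM)
    rho_2x = 1.25,             # Rho level doubling PTEN activity (uM)
    ## -- actin / Arp2/3 block -------------------------------------------
    k_arp_act = 0.1,           # PIP2-dependent Arp2/3 activation rate (uM/s)
    k_arp_cdc42 = 0.4,         # Cdc42 acceleration of Arp2/3 activation (/s)
    n_arp = 4,                 # Hill coeff. of PIP2-mediated Arp2/3 activation
    P2_arp = 9,                # PIP2 threshold for Arp2/3 activation (uM)
    d_arp = 0.2,               # Arp2/3 inactivation rate (/s)
    D_arp = 3,                 # Arp2/3 diffusion coefficient (um^2/s)
    k_nuc = 350,               # Arp2/3 nucleation rate ceiling (ends/um^2/s)
    K_nuc = 100,               # saturation constant for nucleation (uM^2)
    sc_FtoC = 1,               # scale factor: filament density -> concentration
    sc_CtoB = 1,               # scale factor: concentration -> barbed ends
    v_poly = 0.5,              # free polymerization speed (um/s)
    d_F = 0.1,                 # filament turnover rate (/s)
    k_cap = 2.8,               # basal barbed-end capping rate (/s)
    cap_red_max = 0.9,         # max fractional reduction of capping by PIP2
    cap_le_fact = 0.05,        # capping multiplier at the leading edge
    le_pip2_rel = 1.15,        # PIP2 (x basal) marking a boundary site as leading edge
    P2_cap = 9,                # PIP2 half-max of capping reduction (uM)
    n_cap = 4,                 # Hill coeff. of capping reduction
    ## -- Cellular Potts block (reference resolution dx_ref) -------------
    J_coupling = 4,            # coupling energy per boundary neighbour pair
    lam_area = 0.02,           # cell inelasticity (per site^2, at dx_ref)
    target_area = 314.16,      # target cell area (um^2; 20 um diameter disk)
    lam_perim = 0.02,          # membrane inelasticity (per pair^2, at dx_ref)
    target_perim = 62.83,      # target perimeter (um)
    target_perim_pairs = NA,   # pair-count target (measured on the lattice)
    H_yield = 274.6,           # membrane yield H_y (force-velocity fit)
    temp_T = 108.9,            # simulation "temperature" (force-velocity fit)
    lam_contract = 300,        # Rho contraction coefficient (ends/um per uM)
    rho_thresh = 1.6,          # Rho contraction threshold (uM)
    nbr_order = 2,             # neighbour order of the boundary coupling sum
    w_force = 1,               # scale of the force bias in energy units
    phi_mem = 30,              # renormalized membrane resistance (ends/um)
    ## -- numerics --------------------------------------------------------
    dx = 0.125,                # grid mesh size (um)
    dx_ref = 0.125,            # reference resolution for the CPM block
    dt = 0.05,                 # timestep at dx_ref (s); one MCS per step
    dt_scale_with_dx = TRUE,   # keep dx/dt (max edge speed) fixed across dx
    renorm_guard = 0.001,      # allowed per-MCS mass correction (fraction)
    edge_scheme = "copy",      # copy | heap | split (protrusion bookkeeping)
    arp_volumetric = TRUE,     # Arp2/3 activation everywhere vs edge-only
    min_front_frac = 0.01      # min front component size (fraction of area)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p <- solve_basal_rates(p)
  validate_params(p)
  class(p) <- c("polarcpm_params", "list")
  p
}

#' Solve derived baseline rates from the basal steady state
#'
#' GTPase input rates \code{I_cdc42, I_rac, I_rho} and the PI rates
#' \code{k_pi5k, k_pten, I_pip} are determined by requiring the basal
#' concentrations to be an exact steady state of the reaction terms.
#'
#' @param p parameter list (see [default_params()]).
#' @return The list with derived entries filled in.
#' @keywords internal
solve_basal_rates <- function(p) {
  xr <- p$bas_rho / p$a_rho; xc <- p$bas_cdc42 / p$a_cdc
  p$I_cdc42 <- p$d_gtp * p$bas_cdc42 / (p$tot_cdc42 - p$bas_cdc42) * (1 + xr^p$n_gtp)
  p$I_rac <- p$d_gtp * p$bas_rac / (p$tot_rac - p$bas_rac) - p$alpha_rac * p$bas_cdc42
  p$I_rho <- p$d_gtp * p$bas_rho / (p$tot_rho - p$bas_rho) * (1 + xc^p$n_gtp) -
    p$beta_rho * p$bas_rac
  fRb <- 1 + p$bas_rac / p$rac_2x
  fHb <- 1 + p$bas_rho / p$rho_2x
  p$k_pten <- p$k_pi3k * fRb * p$bas_pip2 / (fHb * p$bas_pip3)
  p$k_pi5k <- ((p$d_pi + p$k_pip2_pip + p$k_pi3k * fRb) * p$bas_pip2 -
    p$k_pten * fHb * p$bas_pip3) / (fRb * p$bas_pip)
  p$I_pip <- p$d_pi * p$bas_pip + p$k_pi5k * fRb * p$bas_pip - p$k_pip2_pip * p$bas_pip2
  p$D_inact <- effective_inactive_diffusion(p$frac_membrane, p)
  p
}

#' Validate a parameter set
#'
#' @param p parameter list.
#' @return \code{p}, invisibly; errors describe every violated constraint.
#' @keywords internal
validate_params <- function(p) {
  errs <- character()
  nonneg <- c("tot_cdc42", "tot_rac", "tot_rho", "bas_cdc42", "bas_rac",
    "bas_rho", "alpha_rac", "beta_rho", "d_gtp", "D_act", "D_cyt", "D_pi",
    "D_arp", "d_pi", "k_pip2_pip", "k_pi3k", "k_arp_act", "k_arp_cdc42",
    "d_arp", "k_nuc", "K_nuc", "v_poly", "d_F", "k_cap", "lam_area",
    "lam_perim", "lam_contract", "rho_thresh", "I_cdc42",
    "k_pi5k", "k_pten", "I_pip")
  for (nm in nonneg) if (is.null(p[[nm]]) || p[[nm]] < 0)
    errs <- c(errs, paste0(nm, " must be >= 0"))
  for (nm in c("n_gtp", "n_arp", "n_cap", "fb_hill"))
    if (p[[nm]] < 1) errs <- c(errs, paste0(nm, " must be >= 1"))
  if (p$eta < 0 || p$eta > 1) errs <- c(errs, "eta must be in [0, 1]")
  if (p$fb_amp_weight < 0 || p$fb_amp_weight > 1)
    errs <- c(errs, "fb_amp_weight must be in [0, 1]")
  if (p$dt <= 0) errs <- c(errs, "dt must be > 0")
  if (p$dx <= 0) errs <- c(errs, "dx must be > 0")
  if (p$frac_membrane < 0 || p$frac_membrane > 1)
    errs <- c(errs, "frac_membrane must be in [0, 1]")
  if (p$temp_T <= 0) errs <- c(errs, "temp_T must be > 0")
  if (p$target_area <= 0 || p$target_perim <= 0)
    errs <- c(errs, "target area/perimeter must be > 0")
  if (!p$nbr_order %in% c(1, 2)) errs <- c(errs, "nbr_order must be 1 or 2")
  if (!p$edge_scheme %in% c("copy", "heap", "split"))
    errs <- c(errs, "edge_scheme must be copy, heap or split")
  if (length(errs)) stop("invalid parameters:\n  ", paste(errs, collapse = "\n  "))
  invisible(p)
}

#' Effective diffusion coefficient of the inactive GTPase forms
#'
#' Inactive GTPases exchange between membrane and cytosol (GDI-regulated);
#' the effective coefficient is the time-fraction-weighted mean of the
#' membrane-bound and cytosolic coefficients.
#'
#' @param fraction_membrane fraction of time spent membrane-bound, in [0,1].
#' @param p parameter list.
#' @return Effective diffusion coefficient (um^2/s).
#' @export
effective_inactive_diffusion <- function(fraction_membrane, p) {
  if (fraction_membrane < 0 || fraction_membrane > 1)
    stop("fraction_membrane must be in [0, 1]")
  fraction_membrane * p$D_act + (1 - fraction_membrane) * p$D_cyt
}

#' Timestep at a given resolution
#'
#' With \code{dt_scale_with_dx} the Monte-Carlo/PDE timestep scales
#' proportionally to the mesh size, keeping the maximum edge speed
#' \code{dx/dt} - and therefore the calibrated force-velocity relation -
#' independent of the resolution.
#'
#' @param p parameter list.
#' @return Timestep in seconds at resolution \code{p$dx}.
#' @export
timestep <- function(p) {
  if (isTRUE(p$dt_scale_with_dx)) p$dt * p$dx / p$dx_ref else p$dt
}

# CPM constants rescaled from the reference resolution to p$dx.
# lam_area scales with site area (restoring bias per move constant for a
# given relative area deviation); lam_perim and the pair-count targets scale
# with 1/dx. J, temp_T, H_yield and the force terms are per-move quantities
# and stay fixed.
cpm_scaled <- function(p) {
  asite <- sqrt(3) / 2 * p$dx^2
  asite_ref <- sqrt(3) / 2 * p$dx_ref^2
  list(
    J = p$J_coupling,
    lam_area = p$lam_area * (asite / asite_ref)^2 * (asite_ref / asite), # = lam*asite/asite_ref
    A0 = p$target_area / asite,                     # target area in sites
    lam_perim = p$lam_perim * (p$dx / p$dx_ref)^2 * (p$dx_ref / p$dx),   # = lam*dx/dx_ref
    # pair-count target: measured on the lattice for the target disk, with a
    # naive geometric conversion as fallback
    P0 = if (is.finite(p$target_perim_pairs)) p$target_perim_pairs
         else 2 * p$target_perim / p$dx,
    H_y = p$H_yield, temp = p$temp_T,
    lam_contract = p$lam_contract, rho_thresh = p$rho_thresh,
    w_force = p$w_force, nbr_order = p$nbr_order
  )
}

#' Read a parameter configuration file
#'
#' Reads a YAML file of parameter overrides on top of [default_params()].
#' Unknown keys are rejected with the offending names.
#'
#' @param path YAML file path.
#' @return Validated parameter list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  drv <- c("I_cdc42", "I_rac", "I_rho", "k_pi5k", "k_pten", "I_pip", "D_inact")
  cfg <- cfg[setdiff(names(cfg), drv)]
  do.call(default_params, cfg)
}

#' Write a parameter configuration template
#'
#' @param p parameter list.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(p, path) {
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

# fixed order in which parameters are handed to the compiled stepper
.param_order <- c(
  "tot_cdc42", "tot_rac", "tot_rho", "bas_cdc42", "bas_rac", "bas_rho",
  "a_rho", "a_cdc", "n_gtp", "alpha_rac", "beta_rho", "d_gtp",
  "I_cdc42", "I_rac", "I_rho",
  "D_act", "D_inact", "D_pi", "D_arp",
  "eta", "fb_hill", "fb_half_rel", "fb_amp_weight",
  "bas_pip", "bas_pip2", "bas_pip3", "d_pi", "k_pip2_pip", "k_pi3k",
  "k_pi5k", "k_pten", "I_pip", "rac_2x", "rho_2x",
  "k_arp_act", "k_arp_cdc42", "n_arp", "P2_arp", "d_arp",
  "k_nuc", "K_nuc", "sc_FtoC", "sc_CtoB", "v_poly", "d_F",
  "k_cap", "cap_red_max", "cap_le_fact", "le_pip2_rel", "P2_cap", "n_cap")

.param_vec <- function(p) {
  v <- vapply(.param_order, function(nm) as.numeric(p[[nm]]), 0)
  names(v) <- .param_order
  v
}

.cpm_vec <- function(p) {
  s <- cpm_scaled(p)
  c(J = s$J, lam_area = s$lam_area, A0 = s$A0, lam_perim = s$lam_perim,
    P0 = s$P0, H_y = s$H_y, temp = s$temp, lam_contract = s$lam_contract,
    rho_thresh = s$rho_thresh, w_force = s$w_force, nbr_order = s$nbr_order)
}
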