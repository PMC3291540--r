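# Pointwise reaction terms for the signalling network. These pure functions
# are the reference implementation: the compiled stepper mirrors them and is
# tested against them on random states.

#' PIP2 feedback factor on Cdc42/Rac activation
#'
#' Sigmoidal (Hill) function of PIP2, normalized to 1 at the basal PIP2 level
#' and 0 at PIP2 = 0, blended with strength \code{eta}:
#' \code{(1 - eta) + eta * S(PIP2)}. With \code{eta = 0} the factor is
#' identically 1 (no feedback); with \code{eta = 1} activation vanishes
#' without PIP2. Because the factor is 1 at basal PIP2 for every eta, the
#' homogeneous rest state is independent of the feedback strength.
#'
#' @param pip2 PIP2 concentration (uM), scalar or vector.
#' @param p parameter list (uses \code{eta}, \code{fb_hill},
#'   \code{fb_half_rel}, \code{bas_pip2}).
#' @return Dimensionless factor, same length as \code{pip2}.
#' @export
pi_feedback_factor <- function(pip2, p) {
  if (any(pip2 < 0)) stop("pip2 must be >= 0")
  if (p$eta == 0) return(rep(1, length(pip2)))
  K <- p$fb_half_rel * p$bas_pip2
  m <- p$fb_hill
  S <- (pip2^m / (K^m + pip2^m)) * (K^m + p$bas_pip2^m) / p$bas_pip2^m
  (1 - p$eta) + p$eta * S
}

#' GEF-mediated Cdc42 activation rate
#'
#' Baseline rate inhibited by Rho (Hill form) and modulated by the PIP2
#' feedback factor. Applied per unit inactive Cdc42.
#'
#' @param rho_a active Rho concentration (uM).
#' @param pip2 PIP2 concentration (uM).
#' @param p parameter list.
#' @return Activation propensity (1/s).
#' @export
cdc42_activation_rate <- function(rho_a, pip2, p) {
  if (any(rho_a < 0) || any(pip2 < 0)) stop("inputs must be >= 0")
  p$I_cdc42 / (1 + (rho_a / p$a_rho)^p$n_gtp) * pi_feedback_factor(pip2, p)
}

#' Rac activation rate
#'
#' Sum of a baseline term and a Cdc42-proportional amplification term. The
#' PIP2 feedback factor revises the baseline input rate fully; its weight on
#' the Cdc42-dependent term is \code{fb_amp_weight} in [0, 1]. Full weight
#' closes a Rac - PI5K - PIP2 - Rac self-amplification loop that can
#' destabilize the polarized state into pole-to-pole oscillations; zero
#' weight leaves the amplification term PIP2-independent.
#'
#' @param cdc42_a active Cdc42 concentration (uM).
#' @param pip2 PIP2 concentration (uM).
#' @param p parameter list.
#' @return Activation propensity (1/s).
#' @export
rac_activation_rate <- function(cdc42_a, pip2, p) {
  if (any(cdc42_a < 0) || any(pip2 < 0)) stop("inputs must be >= 0")
  g <- pi_feedback_factor(pip2, p)
  ga <- 1 + p$fb_amp_weight * (g - 1)
  p$I_rac * g + p$alpha_rac * cdc42_a * ga
}

#' Rho activation rate
#'
#' Baseline plus Rac-enhanced activation, inhibited by Cdc42 (Hill form)
#' and floored at zero (the solved baseline input can be negative, making
#' Rho activation effectively Rac-driven). Independent of the PIs and of
#' \code{eta}.
#'
#' @param cdc42_a active Cdc42 concentration (uM).
#' @param rac_a active Rac concentration (uM).
#' @param p parameter list.
#' @return Activation propensity (1/s).
#' @export
rho_activation_rate <- function(cdc42_a, rac_a, p) {
  if (any(cdc42_a < 0) || any(rac_a < 0)) stop("inputs must be >= 0")
  pmax(0, p$I_rho + p$beta_rho * rac_a) / (1 + (cdc42_a / p$a_cdc)^p$n_gtp)
}

#' GTPase reaction terms at one site
#'
#' For each GTPase, d(active)/dt = activation x inactive - decay x active and
#' d(inactive)/dt is its exact negative: interconversion conserves each total
#' pointwise (diffusion is handled by the solver, not here).
#'
#' @param f named list/vector with \code{cdc42_a, rac_a, rho_a, cdc42_i,
#'   rac_i, rho_i, pip2} (uM).
#' @param p parameter list.
#' @param stim multiplicative stimulus on the Cdc42 activation rate.
#' @return Named numeric vector of six time derivatives (uM/s).
#' @export
gtpase_reaction <- function(f, p, stim = 1) {
  aC <- stim * cdc42_activation_rate(f$rho_a, f$pip2, p)
  aR <- rac_activation_rate(f$cdc42_a, f$pip2, p)
  aH <- rho_activation_rate(f$cdc42_a, f$rac_a, p)
  dC <- aC * f$cdc42_i - p$d_gtp * f$cdc42_a
  dR <- aR * f$rac_i - p$d_gtp * f$rac_a
  dH <- aH * f$rho_i - p$d_gtp * f$rho_a
  c(cdc42_a = dC, rac_a = dR, rho_a = dH,
    cdc42_i = -dC, rac_i = -dR, rho_i = -dH)
}

#' Phosphoinositide reaction terms at one site
#'
#' PIP gains a constant input and the PIP2 back-conversion flux, loses decay
#' and PI5K conversion; PIP2 gains PI5K conversion and PTEN back-conversion
#' from PIP3, loses decay, back-conversion and PI3K conversion; PIP3 gains
#' PI3K conversion and loses PTEN conversion. Kinase activities scale
#' linearly with Rac (PI5K, PI3K) and PTEN with Rho, doubling at the
#' respective \code{rac_2x} / \code{rho_2x} levels.
#'
#' @param f named list/vector with \code{pip, pip2, pip3, rac_a, rho_a} (uM).
#' @param p parameter list.
#' @return Named numeric vector of three time derivatives (uM/s).
#' @export
pi_reaction <- function(f, p) {
  if (any(unlist(f[c("pip", "pip2", "pip3", "rac_a", "rho_a")]) < 0))
    stop("inputs must be >= 0")
  fR <- 1 + f$rac_a / p$rac_2x
  fH <- 1 + f$rho_a / p$rho_2x
  dP1 <- p$I_pip - p$d_pi * f$pip - p$k_pi5k * fR * f$pip + p$k_pip2_pip * f$pip2
  dP2 <- p$k_pi5k * fR * f$pip - (p$d_pi + p$k_pip2_pip) * f$pip2 -
    p$k_pi3k * fR * f$pip2 + p$k_pten * fH * f$pip3
  dP3 <- p$k_pi3k * fR * f$pip2 - p$k_pten * fH * f$pip3
  c(pip = dP1, pip2 = dP2, pip3 = dP3)
}

#' Arp2/3 activation rate
#'
#' Hill function of PIP2 with a Cdc42-dependent acceleration (synergy):
#' \code{(k_arp_act + k_arp_cdc42 * cdc42_a) * Hill(PIP2)}. Zero at
#' PIP2 = 0, monotone non-decreasing in both arguments.
#'
#' @param cdc42_a active Cdc42 (uM).
#' @param pip2 PIP2 (uM).
#' @param p parameter list.
#' @return Activation rate (uM/s).
#' @export
arp23_activation <- function(cdc42_a, pip2, p) {
  if (any(cdc42_a < 0) || any(pip2 < 0)) stop("inputs must be >= 0")
  hill <- pip2^p$n_arp / (p$P2_arp^p$n_arp + pip2^p$n_arp)
  (p$k_arp_act + p$k_arp_cdc42 * cdc42_a) * hill
}

#' Arp2/3-mediated barbed-end nucleation rate
#'
#' Saturating in the product of active Arp2/3 and total filament density:
#' zero when either vanishes, plateauing at the nucleation ceiling
#' \code{k_nuc} as Arp2/3 (or F-actin) grows.
#'
#' @param arp23 active Arp2/3 (uM).
#' @param F_total total filament density over orientations (uM-equivalent).
#' @param p parameter list.
#' @return Nucleation rate (ends/um^2/s) summed over daughter classes.
#' @export
branching_rate <- function(arp23, F_total, p) {
  if (any(arp23 < 0) || any(F_total < 0)) stop("inputs must be >= 0")
  x <- arp23 * p$sc_FtoC * F_total
  p$k_nuc * p$sc_CtoB * x / (p$K_nuc + x)
}

#' PIP2-regulated barbed-end capping rate
#'
#' Basal rate reduced sigmoidally by PIP2 (half-max \code{P2_cap}, Hill
#' \code{n_cap}, maximal fractional reduction \code{cap_red_max}), with an
#' additional multiplicative reduction at the leading edge. A boundary site
#' counts as leading edge when its PIP2 exceeds \code{le_pip2_rel} times the
#' basal level (the membrane marker of the cell front).
#'
#' @param pip2 PIP2 (uM).
#' @param at_leading_edge logical flag.
#' @param p parameter list.
#' @return Capping rate (1/s).
#' @export
capping_rate <- function(pip2, at_leading_edge, p) {
  if (any(pip2 < 0)) stop("pip2 must be >= 0")
  red <- p$cap_red_max * pip2^p$n_cap / (p$P2_cap^p$n_cap + pip2^p$n_cap)
  k <- p$k_cap * (1 - red)
  ifelse(at_leading_edge, p$cap_le_fact * k, k)
}

#' Homogeneous basal state of all fields
#'
#' @param p parameter list.
#' @return Named numeric vector of the ten concentration species at rest.
#' @export
basal_levels <- function(p) {
  arp0 <- arp23_activation(p$bas_cdc42, p$bas_pip2, p) / p$d_arp
  c(cdc42_a = p$bas_cdc42, rac_a = p$bas_rac, rho_a = p$bas_rho,
    cdc42_i = p$tot_cdc42 - p$bas_cdc42, rac_i = p$tot_rac - p$bas_rac,
    rho_i = p$tot_rho - p$bas_rho,
    pip = p$bas_pip, pip2 = p$bas_pip2, pip3 = p$bas_pip3, arp = arp0)
}

#' Basal actin fixed point
#'
#' Self-consistent resting totals of free barbed ends and filaments under
#' basal signalling: nucleation balances capping with
#' \code{F = sc_FtoC v / d_F x B}. Returns zero when branching at vanishing
#' density cannot outrun capping (actin extinct at rest).
#'
#' @param p parameter list.
#' @return List with \code{B_tot} (ends/um^2) and \code{F_tot}
#'   (uM-equivalent), totals over the six orientation classes.
#' @export
basal_actin <- function(p) {
  arp0 <- arp23_activation(p$bas_cdc42, p$bas_pip2, p) / p$d_arp
  kcap <- capping_rate(p$bas_pip2, FALSE, p)
  fpb <- p$sc_FtoC * p$v_poly / p$d_F    # filaments per barbed end at balance
  g <- function(B) branching_rate(arp0, fpb * B, p) - kcap * B
  if (p$k_nuc * p$sc_CtoB * arp0 * p$sc_FtoC * fpb / p$K_nuc <= kcap)
    return(list(B_tot = 0, F_tot = 0))
  hi <- p$k_nuc * p$sc_CtoB / kcap      # nucleation ceiling / capping bound
  B <- stats::uniroot(g, c(1e-9, hi * 1.01), tol = 1e-12)$root
  list(B_tot = B, F_tot = fpb * B)
}

#' All signalling reaction derivatives at one site
#'
#' Combines the GTPase, PI and Arp2/3 reaction terms (no diffusion, no actin
#' transport). The basal state returned by [basal_levels()] has residuals at
#' machine precision by construction.
#'
#' @param f named list/vector of the ten species.
#' @param p parameter list.
#' @param stim multiplicative stimulus on the Cdc42 activation rate.
#' @return Named vector of ten derivatives.
#' @export
signalling_reaction <- function(f, p, stim = 1) {
  f <- as.list(f)
  dg <- gtpase_reaction(f, p, stim)
  dpi <- pi_reaction(f, p)
  darp <- arp23_activation(f$cdc42_a, f$pip2, p) - p$d_arp * f$arp
  c(dg, dpi, arp = darp)
}
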