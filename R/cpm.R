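# Cellular Potts shape engine: Hamiltonian, acceptance rule and the
# force-velocity calibration that fixes the temperature and yield.

#' Potts Hamiltonian of a cell mask
#'
#' \code{J x (occupied-unoccupied neighbour pairs up to the configured
#' order) + lam_area (a - A0)^2 + lam_perim (p - P0)^2}, with the area in
#' sites and the perimeter as the first-order mismatch pair count; the
#' targets derive from \code{target_area} (um^2) and \code{target_perim}
#' (um) at the grid resolution.
#'
#' @param cell a [cell_state()] (or list with \code{grid} and \code{mask}).
#' @param p parameter list.
#' @return Energy (scalar, barbed-ends-per-um-equivalent units).
#' @export
hamiltonian <- function(cell, p) {
  g <- cell$grid
  p$dx <- g$dx
  hamiltonian_cpp(as.integer(cell$mask), g$nbr, g$nbr2, .cpm_vec(p))
}

#' Metropolis acceptance probability
#'
#' Changes that decrease the total energy by at least the yield \code{H_y}
#' are accepted with probability 1; all others with Boltzmann probability
#' \code{exp(-(dH + H_y) / T)}.
#'
#' @param dH total energy change including the force bias.
#' @param p parameter list (uses \code{H_yield}, \code{temp_T}).
#' @return Acceptance probability in (0, 1].
#' @export
metropolis_probability <- function(dH, p) {
  ifelse(dH <= -p$H_yield, 1, exp(-(dH + p$H_yield) / p$temp_T))
}

#' Metropolis acceptance draw
#'
#' @param dH total energy change.
#' @param p parameter list.
#' @param rng_u optional uniform deviate (drawn from the session RNG if
#'   missing).
#' @return Logical accept flag.
#' @export
metropolis_accept <- function(dH, p, rng_u = stats::runif(1)) {
  rng_u < metropolis_probability(dH, p)
}

#' Force bias of a proposed edge move
#'
#' For a protrusion from occupied \code{from} into empty \code{to}: the sum
#' over orientation classes of pushing ends at \code{from} projected onto
#' the move direction, minus the Rho contraction force at \code{from}
#' (\code{lam_contract * max(0, rho - rho_thresh)}). For a retraction the
#' sign convention is mirrored: contraction favours, pushing ends resist.
#' The returned value is subtracted from the Hamiltonian change.
#'
#' @param sim simulation state.
#' @param from,to adjacent site indices (1-based); exactly one occupied.
#' @return Energy-equivalent bias (positive favours the move).
#' @export
force_bias <- function(sim, from, to) {
  g <- sim$grid
  k <- which(g$nbr[from, ] == to)
  if (!length(k)) stop("force_bias: sites are not first-order neighbours")
  if (sim$mask[from] + sim$mask[to] != 1L)
    stop("force_bias: proposal must be a protrusion or retraction at the edge")
  u <- g$ev[, k]
  proj <- pmax(0, colSums(g$ev * u))
  if (sim$mask[from] == 1L) {
    # protrusion into `to`: pushing ends at the source favour, Rho opposes
    push <- sum(sim$Bp[from, ] * proj)
    con <- sim$p$lam_contract * max(0, sim$conc[from, "rho_a"] - sim$p$rho_thresh)
    push - con
  } else {
    # retraction of `to` toward empty `from`: Rho contraction favours,
    # ends pushing toward the vacated side resist
    proj <- pmax(0, colSums(g$ev * -u))
    push <- sum(sim$Bp[to, ] * proj)
    con <- sim$p$lam_contract * max(0, sim$conc[to, "rho_a"] - sim$p$rho_thresh)
    con - push
  }
}

#' Mean protrusion speed of a straight edge
#'
#' Closed-form mean speed of a flat cell edge under the acceptance rule, as
#' a function of the pushing barbed-end density: each sweep the edge site
#' attempts one extension (bias \code{-Bp}) and one retraction (bias
#' \code{+Bp}), so \code{v = dx/dt (P_acc(-Bp) - P_acc(+Bp))}. Used for the
#' calibration against the polymerization-ratchet force-velocity relation,
#' not inside the simulation loop.
#'
#' @param Bp pushing barbed ends per unit edge length (scalar or vector).
#' @param p parameter list.
#' @return Speed (um/s).
#' @export
mean_protrusion_speed <- function(Bp, p) {
  v_mcs <- p$dx / timestep(p)
  v_mcs * (metropolis_probability(-p$w_force * Bp, p) -
           metropolis_probability(p$w_force * Bp, p))
}

#' Thermal-ratchet force-velocity relation
#'
#' Protrusion speed of a membrane pushed by \code{Bp} barbed ends per unit
#' edge length against a renormalized membrane resistance \code{phi_mem}
#' (ends/um): \code{v_poly * exp(-phi_mem / Bp)}. The free polymerization
#' speed is the load-free limit.
#'
#' @param Bp pushing barbed ends per unit edge length.
#' @param p parameter list (uses \code{v_poly}, \code{phi_mem}).
#' @return Speed (um/s).
#' @export
ratchet_velocity <- function(Bp, p) {
  ifelse(Bp > 0, p$v_poly * exp(-p$phi_mem / Bp), 0)
}

#' Calibrate temperature and yield against the ratchet relation
#'
#' Least-squares fit of the shape engine's mean protrusion speed
#' ([mean_protrusion_speed()]) to the thermal-ratchet relation
#' ([ratchet_velocity()]) over the biologically relevant range of
#' barbed-end densities, by adjusting the simulation temperature and the
#' membrane yield. The fitted values are the package defaults.
#'
#' The speed curve alone only constrains the difference of the extension and
#' retraction acceptance probabilities, leaving a degenerate direction along
#' which the zero-load fluctuation rate grows without bound. The temperature
#' is therefore additionally anchored through the resting-edge fluctuation
#' level \code{base_accept} (the acceptance probability of a neutral edge
#' move, \code{exp(-H_y / T)}), the quantity the temperature is interpreted
#' to control.
#'
#' @param p parameter list.
#' @param Bp_range range of pushing-end densities (ends/um) to fit over.
#' @param n_pts number of fit points (log-spaced).
#' @param base_accept target zero-load acceptance probability.
#' @param anchor_weight weight of the fluctuation anchor in the objective.
#' @return List with \code{temp_T}, \code{H_yield}, \code{rms} (speed
#'   residual, um/s) and the fit table (\code{Bp}, \code{v_ratchet},
#'   \code{v_cpm}).
#' @export
calibrate_force_velocity <- function(p, Bp_range = c(10, 120), n_pts = 40,
                                     base_accept = 0.05, anchor_weight = 0.5) {
  Bp <- exp(seq(log(Bp_range[1]), log(Bp_range[2]), length.out = n_pts))
  target <- ratchet_velocity(Bp, p)
  obj <- function(th) {
    q <- p; q$temp_T <- exp(th[1]); q$H_yield <- exp(th[2])
    mean((mean_protrusion_speed(Bp, q) - target)^2) +
      anchor_weight * (exp(-q$H_yield / q$temp_T) - base_accept)^2
  }
  fit <- stats::optim(log(c(p$temp_T, p$H_yield)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  q <- p; q$temp_T <- exp(fit$par[1]); q$H_yield <- exp(fit$par[2])
  list(temp_T = q$temp_T, H_yield = q$H_yield,
       rms = sqrt(mean((mean_protrusion_speed(Bp, q) - target)^2)),
       table = data.frame(Bp = Bp, v_ratchet = target,
                          v_cpm = mean_protrusion_speed(Bp, q)))
}
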