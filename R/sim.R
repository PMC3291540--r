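#' Create a simulation state
#'
#' Assembles the full multiscale state: occupancy mask, the ten concentration
#' fields (three active + three inactive GTPases, three PIs, active Arp2/3),
#' and the 18 orientation-resolved actin fields (6 orientation classes for
#' each of filaments, free barbed ends and pushing barbed ends). All fields
#' start at the homogeneous basal steady state inside the mask (actin at its
#' basal fixed point, pushing ends at zero).
#'
#' @param grid a [hex_grid()].
#' @param p parameter list from [default_params()]; \code{p$dx} is taken from
#'   the grid.
#' @param mask 0/1 occupancy vector (e.g. [disk_mask()]).
#' @param obstacle optional 0/1 vector of permanently excluded sites.
#' @param frozen logical: if TRUE the Monte-Carlo shape updates are disabled
#'   (immobilized cell); the PDEs still run on the static mask.
#' @return An environment of class \code{polarcpm_sim}.
#' @export
new_simulation <- function(grid, p, mask, obstacle = NULL, frozen = FALSE) {
  if (!inherits(grid, "hexgrid")) stop("grid must be a hex_grid()")
  mask <- as.integer(as.logical(mask))
  if (length(mask) != grid$n) stop("mask length must equal grid$n")
  if (sum(mask) == 0) stop("empty cell mask")
  if (is.null(obstacle)) obstacle <- integer(grid$n)
  obstacle <- as.integer(as.logical(obstacle))
  if (any(mask == 1L & obstacle == 1L))
    stop("obstacle overlaps the initial cell mask")
  p$dx <- grid$dx
  p <- solve_basal_rates(p)
  if (!is.finite(p$target_perim_pairs)) {
    # measure the boundary pair count of the target-area disk on this lattice
    # (the naive edge-length conversion underestimates the staircase count)
    r0 <- sqrt(p$target_area / pi)
    ref <- disk_mask(grid, r0)
    p$target_perim_pairs <- perimeter_measure(grid, ref) *
      p$target_perim / (2 * pi * r0)
  }
  lam <- p$v_poly * timestep(p) / grid$dx
  if (lam > 1)
    stop(sprintf("advection CFL violated: v*dt/dx = %.2f > 1", lam))
  n <- grid$n
  b0 <- basal_levels(p)
  conc <- matrix(0, n, 10,
    dimnames = list(NULL, c("cdc42_a", "rac_a", "rho_a", "cdc42_i", "rac_i",
                            "rho_i", "pip", "pip2", "pip3", "arp")))
  inside <- mask == 1L
  for (j in seq_len(10)) conc[inside, j] <- b0[[j]]
  sim <- new.env(parent = emptyenv())
  sim$grid <- grid
  sim$p <- p
  sim$mask <- mask
  sim$obstacle <- obstacle
  sim$conc <- conc
  # resting actin starts at its basal fixed point, isotropic over classes
  act0 <- basal_actin(p)
  sim$F <- matrix(0, n, 6); sim$F[inside, ] <- act0$F_tot / 6
  sim$B <- matrix(0, n, 6); sim$B[inside, ] <- act0$B_tot / 6
  sim$Bp <- matrix(0, n, 6)
  sim$t <- 0
  sim$frozen <- frozen
  sim$stimulus <- NULL
  sim$log <- list(renorm_max = numeric(), acc_prot = integer(),
                  acc_retr = integer(), frag_events = 0L,
                  worst_renorm = 0)
  class(sim) <- "polarcpm_sim"
  sim
}

#' @export
print.polarcpm_sim <- function(x, ...) {
  cat(sprintf(
    "polarcpm simulation: t = %.1f s, area = %d sites (%.0f um^2), %s\n",
    x$t, sum(x$mask), sum(x$mask) * x$grid$site_area,
    if (x$frozen) "frozen shape" else "dynamic shape"))
  invisible(x)
}

#' Attach a stimulus to a simulation
#'
#' The stimulus multiplies the baseline Cdc42 activation rate site-wise
#' during its time window. See [linear_gradient()] and [v_gradient()].
#'
#' @param sim a [new_simulation()] state.
#' @param stim a stimulus specification, or NULL to clear.
#' @return \code{sim}, invisibly.
#' @export
set_stimulus <- function(sim, stim) {
  sim$stimulus <- stim
  invisible(sim)
}

#' Advance the simulation
#'
#' Runs \code{n_steps} full timesteps. Each step is: explicit reaction update
#' of the signalling network, actin branching/capping/transport with edge
#' flux feeding the pushing barbed ends, three-direction ADI diffusion of all
#' ten concentration species on the current mask, and (unless frozen) one
#' Monte-Carlo sweep of the shape engine followed by the mass-conservation
#' renormalization of every concentration species.
#'
#' @param sim simulation state.
#' @param n_steps number of timesteps (each of [timestep()] seconds).
#' @param strict_guard error if a renormalization correction exceeds
#'   \code{p$renorm_guard} (default: record only).
#' @param do_reaction,do_diffusion,do_actin switches used by unit tests to
#'   isolate operators; all TRUE in normal use.
#' @return \code{sim}, invisibly; per-step logs are appended to
#'   \code{sim$log}.
#' @export
step_simulation <- function(sim, n_steps = 1, strict_guard = FALSE,
                            do_reaction = TRUE, do_diffusion = TRUE,
                            do_actin = TRUE) {
  p <- sim$p
  dt <- timestep(p)
  stim <- sim$stimulus
  if (is.null(stim)) {
    stim_field <- numeric(sim$grid$n)
    stim_t0 <- Inf; stim_t1 <- Inf
  } else {
    stim_field <- stim$field
    stim_t0 <- stim$t_on; stim_t1 <- stim$t_off
  }
  scheme <- match(p$edge_scheme, c("copy", "heap", "split")) - 1L
  ctrl <- list(nsteps = as.integer(n_steps), dt = dt, dx = sim$grid$dx,
               t0 = sim$t, frozen = sim$frozen,
               do_reaction = do_reaction, do_diffusion = do_diffusion,
               do_actin = do_actin,
               stim_field = stim_field, stim_t0 = stim_t0, stim_t1 = stim_t1,
               renorm_guard = p$renorm_guard, strict_guard = strict_guard,
               edge_scheme = scheme)
  state <- list(conc = sim$conc, F = sim$F, B = sim$B, Bp = sim$Bp,
                mask = sim$mask, obstacle = sim$obstacle)
  out <- advance_cpp(state, sim$grid$geom, .param_vec(p), .cpm_vec(p), ctrl)
  sim$t <- out$t
  sim$log$renorm_max <- c(sim$log$renorm_max, out$renorm_max)
  sim$log$acc_prot <- c(sim$log$acc_prot, out$acc_prot)
  sim$log$acc_retr <- c(sim$log$acc_retr, out$acc_retr)
  sim$log$frag_events <- sim$log$frag_events + out$frag_events
  sim$log$worst_renorm <- max(sim$log$worst_renorm, out$worst_renorm)
  invisible(sim)
}

#' Run for a simulated duration with periodic snapshots
#'
#' @param sim simulation state.
#' @param duration simulated seconds to run.
#' @param snapshot_every seconds between snapshot callbacks (0 = none).
#' @param callback function(sim) invoked at each snapshot time; its return
#'   values are collected in a list.
#' @param ... passed to [step_simulation()].
#' @return List of callback results (invisibly if no callback).
#' @export
run_for <- function(sim, duration, snapshot_every = 0, callback = NULL, ...) {
  dt <- timestep(sim$p)
  n_total <- max(1L, round(duration / dt))
  if (snapshot_every <= 0 || is.null(callback)) {
    step_simulation(sim, n_total, ...)
    return(invisible(list()))
  }
  chunk <- max(1L, round(snapshot_every / dt))
  out <- list()
  done <- 0L
  while (done < n_total) {
    k <- min(chunk, n_total - done)
    step_simulation(sim, k, ...)
    done <- done + k
    out[[length(out) + 1L]] <- callback(sim)
  }
  out
}

#' Totals of the conserved GTPase pools
#'
#' @param sim simulation state.
#' @return Named vector: active + inactive totals (site sums) for Cdc42,
#'   Rac and Rho.
#' @export
gtpase_totals <- function(sim) {
  m <- sim$mask == 1L
  c(cdc42 = sum(sim$conc[m, "cdc42_a"]) + sum(sim$conc[m, "cdc42_i"]),
    rac = sum(sim$conc[m, "rac_a"]) + sum(sim$conc[m, "rac_i"]),
    rho = sum(sim$conc[m, "rho_a"]) + sum(sim$conc[m, "rho_i"]))
}

#' Total barbed-end count (free + pushing)
#'
#' Free ends are a per-area density and pushing ends a per-edge-length
#' density; both are converted to absolute end counts before summing, so the
#' value changes only through nucleation and capping, never through
#' shape-engine bookkeeping.
#'
#' @param sim simulation state.
#' @return Total end count.
#' @export
barbed_end_total <- function(sim) {
  g <- sim$grid
  sum(sim$B) * g$site_area + sum(sim$Bp) * g$dx
}

#' Extract one concentration field
#'
#' @param sim simulation state.
#' @param species column name of \code{sim$conc} (e.g. "cdc42_a").
#' @return Numeric vector of length \code{grid$n} (0 outside the cell).
#' @export
get_field <- function(sim, species) {
  if (!species %in% colnames(sim$conc)) stop("unknown species: ", species)
  sim$conc[, species]
}
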