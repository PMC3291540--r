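# Orientation-resolved actin bookkeeping at the moving edge. The same rules
# run inside the compiled Monte-Carlo sweep; these R implementations perform
# single scripted events for audits and tests.

# unit-conversion factors between free ends (per area) and pushing ends
# (per edge length): one boundary pixel exposes an edge segment of length dx
.bp_to_b <- function(grid) grid$dx / grid$site_area
.b_to_bp <- function(grid) grid$site_area / grid$dx

#' One explicit actin update step
#'
#' Filaments grow by polymerization at barbed ends and turn over; free
#' barbed ends are nucleated by Arp2/3-dependent branching into the two
#' orientation classes adjacent to each mother class, capped at the
#' PIP2-regulated rate, and advected along their orientation; flux through
#' the cell edge feeds the pushing barbed ends, which cap at the
#' leading-edge-reduced rate and have no transport term.
#'
#' @param sim simulation state.
#' @param dt timestep (s); must satisfy the advection CFL bound.
#' @return \code{sim}, invisibly.
#' @export
actin_step <- function(sim, dt = timestep(sim$p)) {
  g <- sim$grid
  if (sim$p$v_poly * dt / g$dx > 1)
    stop("actin_step: advection CFL bound violated")
  actin_step_cpp(sim$F, sim$B, sim$Bp, sim$conc, sim$mask, g$nbr,
                 .param_vec(sim$p), .cpm_vec(sim$p), dt, g$dx,
                 g$ev[1, ], g$ev[2, ])
  invisible(sim)
}

#' Demote pushing ends when the edge protrudes
#'
#' After a pixel extension covers part of the old edge, pushing barbed ends
#' whose outlet was covered lose membrane contact and become free barbed
#' ends at the old edge site (unit-converted); the total end count is
#' conserved.
#'
#' @param sim simulation state (mask already updated).
#' @param new_site the just-occupied site.
#' @return \code{sim}, invisibly.
#' @export
demote_on_protrusion <- function(sim, new_site) {
  g <- sim$grid
  if (sim$mask[new_site] != 1L)
    stop("demote_on_protrusion: site is not newly occupied")
  sim$F[new_site, ] <- 0; sim$B[new_site, ] <- 0; sim$Bp[new_site, ] <- 0
  for (k in 1:6) {
    j <- g$nbr[new_site, k]
    if (sim$mask[j] != 1L) next
    kjs <- (k + 2L) %% 6L + 1L   # direction j -> new_site (k + 3 in 0-based)
    if (sim$Bp[j, kjs] > 0) {
      sim$B[j, kjs] <- sim$B[j, kjs] + sim$Bp[j, kjs] * .bp_to_b(g)
      sim$Bp[j, kjs] <- 0
    }
  }
  invisible(sim)
}

#' Promote barbed ends when the edge retracts
#'
#' Filaments and barbed ends of the removed pixel are pushed back with the
#' edge and pile up equally on the occupied neighbours with their original
#' orientations; piled ends whose orientation outlet at the receiving site
#' is open immediately push against the new edge (promotion to pushing
#' ends). No filament or end mass is created or destroyed.
#'
#' @param sim simulation state (mask already updated: site unoccupied).
#' @param removed_site the just-vacated site.
#' @return \code{sim}, invisibly.
#' @export
promote_on_retraction <- function(sim, removed_site) {
  g <- sim$grid
  if (sim$mask[removed_site] != 0L)
    stop("promote_on_retraction: site is still occupied")
  recv <- g$nbr[removed_site, ][sim$mask[g$nbr[removed_site, ]] == 1L]
  if (length(recv)) {
    share <- 1 / length(recv)
    for (k in 1:6) {
      fmass <- sim$F[removed_site, k] * share
      bmass <- (sim$B[removed_site, k] +
                  sim$Bp[removed_site, k] * .bp_to_b(g)) * share
      for (j in recv) {
        sim$F[j, k] <- sim$F[j, k] + fmass
        if (sim$mask[g$nbr[j, k]] == 0L)
          sim$Bp[j, k] <- sim$Bp[j, k] + bmass * .b_to_bp(g)
        else
          sim$B[j, k] <- sim$B[j, k] + bmass
      }
    }
  }
  sim$F[removed_site, ] <- 0
  sim$B[removed_site, ] <- 0
  sim$Bp[removed_site, ] <- 0
  invisible(sim)
}

#' Pushing-end gain at a boundary site over one step
#'
#' The discrete edge flux: free ends advected along orientation class k
#' whose outlet neighbour is unoccupied are blocked by the membrane and
#' converted to pushing ends per unit edge length. Returns the updated
#' simulation; for a flat edge with ends oriented along the outward normal
#' the gain rate is \code{v * B * site_area / dx^2} per unit edge length.
#'
#' @param sim simulation state.
#' @param site boundary site index.
#' @param dt timestep (s).
#' @return \code{sim}, invisibly.
#' @export
pushing_ends_step <- function(sim, site, dt = timestep(sim$p)) {
  g <- sim$grid
  if (sim$mask[site] != 1L || all(sim$mask[g$nbr[site, ]] == 1L))
    stop("pushing_ends_step: not a boundary site")
  lam <- sim$p$v_poly * dt / g$dx
  for (k in 1:6) {
    j <- g$nbr[site, k]
    if (sim$mask[j] == 0L) {
      out <- lam * sim$B[site, k]
      sim$B[site, k] <- sim$B[site, k] - out
      sim$Bp[site, k] <- sim$Bp[site, k] + out * .b_to_bp(g)
    }
  }
  invisible(sim)
}
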