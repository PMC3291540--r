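# Diffusion and moving-boundary bookkeeping exposed at the R level. The
# compiled stepper uses the same routines internally; these entry points
# exist for analysis and for the test suite's operator-level checks.

#' One ADI diffusion step of a single field
#'
#' Three sequential implicit 1D solves, one along each principal hex axis,
#' each over a third of the timestep, on ring segments clipped to the mask
#' with no-flux ends (full rings are solved periodically). The directional
#' coefficient is scaled so the three-pass composite reproduces the
#' isotropic hexagonal Laplacian; the scheme is unconditionally stable and
#' conserves the masked total to solver tolerance.
#'
#' @param grid a [hex_grid()].
#' @param field numeric vector of length \code{grid$n}.
#' @param mask 0/1 occupancy vector.
#' @param D diffusion coefficient (um^2/s).
#' @param dt timestep (s).
#' @return Updated field (unchanged outside the mask).
#' @export
adi_diffusion_step <- function(grid, field, mask, D, dt) {
  mask <- as.integer(as.logical(mask))
  if (sum(mask) == 0) stop("adi_diffusion_step: empty mask")
  if (D < 0) stop("D must be >= 0")
  adi_step_cpp(as.numeric(field), mask, D, dt, grid$dx, grid$chains)
}

#' Explicit reaction step over all sites
#'
#' Applies the pointwise signalling reaction terms ([signalling_reaction()])
#' with an explicit Euler update; GTPase interconversion preserves each
#' pointwise total exactly.
#'
#' @param sim simulation state.
#' @param dt timestep (s); defaults to the model timestep.
#' @return \code{sim}, invisibly.
#' @export
reaction_step <- function(sim, dt = timestep(sim$p)) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(invisible(sim))
  stim_field <- numeric(sim$grid$n)
  reaction_step_cpp(sim$conc, sim$mask, .param_vec(sim$p), dt, stim_field, 0)
  if (any(!is.finite(sim$conc)))
    stop("numerical instability: non-finite concentration after reaction step")
  invisible(sim)
}

#' Renormalize conserved pools after a Monte-Carlo sweep
#'
#' Multiplies each concentration species by the scalar restoring its
#' pre-sweep masked total, exactly compensating the mass gained or lost by
#' edge copy events. Returns the per-species correction factors; with no
#' boundary change all factors are exactly 1.
#'
#' @param sim simulation state.
#' @param totals_before named vector of pre-sweep site-sum totals (one per
#'   column of \code{sim$conc}).
#' @param guard error if any |factor - 1| exceeds this fraction (default:
#'   the configured \code{renorm_guard}; NULL disables).
#' @return Named vector of correction factors.
#' @export
renormalize_conserved <- function(sim, totals_before,
                                  guard = sim$p$renorm_guard) {
  m <- sim$mask == 1L
  f <- rep(1, ncol(sim$conc))
  names(f) <- colnames(sim$conc)
  for (j in seq_len(ncol(sim$conc))) {
    tot <- sum(sim$conc[m, j])
    nm <- colnames(sim$conc)[j]
    if (tot > 0 && totals_before[[nm]] > 0) {
      f[j] <- totals_before[[nm]] / tot
      sim$conc[m, j] <- sim$conc[m, j] * f[j]
    }
  }
  if (!is.null(guard) && any(abs(f - 1) > guard))
    stop(sprintf(
      "renormalization correction %.3g exceeds the %.3g guard; use a smaller timestep or finer grid",
      max(abs(f - 1)), guard))
  f
}

#' Copy concentrations into a newly occupied site
#'
#' Implements the locally flat profile at a protruding edge: every
#' concentration species at the new site receives the source pixel's value.
#' Actin fields are handled by [demote_on_protrusion()] instead.
#'
#' @param sim simulation state.
#' @param source occupied site that won the copy.
#' @param new_site newly occupied neighbour of \code{source}.
#' @return \code{sim}, invisibly.
#' @export
copy_concentrations_on_protrusion <- function(sim, source, new_site) {
  if (!new_site %in% sim$grid$nbr[source, ])
    stop("copy_concentrations_on_protrusion: sites are not adjacent")
  sim$conc[new_site, ] <- sim$conc[source, ]
  invisible(sim)
}
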