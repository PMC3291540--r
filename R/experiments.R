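# High-level measurement routines for the standard in-silico experiments.
# The acceptance script and the test suite both call these, so the reported
# quantities are always recomputed from scratch by the same code path.

#' Shape-induced repolarization time of the frozen ellipse
#'
#' Polarizes an immobilized 2:1 ellipse along its short axis with the
#' standard transient gradient and measures the first sustained entry of
#' the polarity axis into the long-axis direction (plus/minus 15 degrees,
#' sustained 60 s). Deterministic up to the seeded onset perturbation.
#'
#' @param eta PI feedback strength.
#' @param seed RNG seed.
#' @param max_minutes give up after this many simulated minutes.
#' @param sample_every polarity sampling cadence (s).
#' @param ... overrides passed to [build_preset()].
#' @return List with \code{time_min} (simulated minutes; the censoring cap
#'   if never), \code{resolved} flag and the angle series.
#' @export
measure_ellipse_repolarization <- function(eta, seed = 1, max_minutes = 100,
                                           sample_every = 30, ...) {
  set.seed(seed)
  pre <- build_preset("frozen_ellipse", eta = eta, ...)
  sim <- pre$sim
  .apply_event(sim, pre$schedule[[1]])
  ts <- c(); devs <- c()
  while (sim$t < max_minutes * 60) {
    run_for(sim, sample_every)
    pa <- polarity_axis(sim)
    a <- if (pa$defined) pa$angle else NA_real_
    # deviation from the long axis (a direction, not an orientation)
    devs <- c(devs, abs(((a + pi / 2) %% pi) - pi / 2))
    ts <- c(ts, sim$t)
  }
  tr <- suppressWarnings(
    repolarization_time(ts, devs, 0, tol = 15 * pi / 180, sustain = 60))
  list(time_min = ifelse(is.finite(tr), tr / 60, max_minutes),
       resolved = is.finite(tr), t = ts, deviation = devs)
}

#' Resolution time of the V-shaped-gradient front conflict
#'
#' Applies the transient symmetric V-gradient (7.5% difference, 10 s) to a
#' disk cell and measures when the front count reaches and sustains one
#' (30 s window), counted from stimulus offset.
#'
#' @param eta PI feedback strength.
#' @param frozen immobilized (TRUE) or motile (FALSE) cell.
#' @param seed RNG seed.
#' @param max_seconds censoring cap (simulated s).
#' @param sample_every front-count cadence (s).
#' @param early_stop stop as soon as the resolution is sustained.
#' @param ... overrides passed to [build_preset()].
#' @return List with \code{time_s} (the cap if never), \code{resolved},
#'   and the count series.
#' @export
measure_v_resolution <- function(eta, frozen = TRUE, seed = 1,
                                 max_seconds = 2000, sample_every = 10,
                                 early_stop = TRUE, ...) {
  set.seed(seed)
  pre <- build_preset(if (frozen) "vgrad_static" else "vgrad_motile",
                      eta = eta, frozen = frozen, ...)
  sim <- pre$sim
  .apply_event(sim, pre$schedule[[1]])
  ts <- c(); nf <- c()
  while (sim$t < max_seconds) {
    run_for(sim, sample_every)
    ts <- c(ts, sim$t); nf <- c(nf, count_fronts(sim))
    n <- length(nf)
    if (early_stop && n > 8 && all(nf[(n - 5):n] == 1) && sim$t > 100) break
  }
  tr <- resolution_time(ts - 10, nf, sustain = 30)
  list(time_s = ifelse(is.finite(tr), tr, max_seconds),
       resolved = is.finite(tr), t = ts, fronts = nf)
}

#' Angular progress toward a second, rotated gradient
#'
#' Polarizes a cell with the standard gradient, applies a shallower (3%)
#' sustained gradient rotated by \code{angle} after 5 simulated minutes,
#' and reports how far the polarity axis has rotated toward the new cue by
#' the end of the observation window.
#'
#' @param frozen immobilized or motile cell.
#' @param angle second-gradient direction (radians).
#' @param seed RNG seed.
#' @param observe observation window after the second stimulus (s).
#' @param ... overrides passed to [build_preset()].
#' @return List with \code{progress_deg} (degrees rotated toward the cue,
#'   mean over the final quarter of the window) and the angle series.
#' @export
measure_turning <- function(frozen, angle = pi / 2, seed = 1, observe = 600,
                            ...) {
  set.seed(seed)
  pre <- build_preset("turn90", frozen = frozen, ...)
  sim <- pre$sim
  .apply_event(sim, pre$schedule[[1]])
  run_for(sim, 300)
  set_stimulus(sim, linear_gradient(sim, 0.03, angle, onset = sim$t,
                                    duration = observe))
  ts <- c(); devs <- c()
  while (sim$t < 300 + observe) {
    run_for(sim, 20)
    pa <- polarity_axis(sim)
    a <- if (pa$defined) pa$angle else NA_real_
    devs <- c(devs, abs(((a - angle + pi) %% (2 * pi)) - pi))
    ts <- c(ts, sim$t)
  }
  last <- devs[seq(ceiling(3 * length(devs) / 4), length(devs))]
  start_dev <- abs(((0 - angle + pi) %% (2 * pi)) - pi)
  list(progress_deg = (start_dev - mean(last, na.rm = TRUE)) * 180 / pi,
       t = ts, deviation = devs)
}

#' Mass-conservation correction of the standard motile run
#'
#' Runs the basic-motility protocol at the reference resolution and
#' reports the largest per-sweep, per-species renormalization correction.
#'
#' @param seed RNG seed.
#' @param minutes simulated minutes.
#' @param dx grid spacing (um); reference resolution by default.
#' @param grid_n lattice size.
#' @param ... overrides passed to [build_preset()].
#' @return List with \code{max_correction_pct} and the per-step series.
#' @export
measure_renorm_guard <- function(seed = 1, minutes = 8, dx = 0.125,
                                 grid_n = 256, ...) {
  set.seed(seed)
  pre <- build_preset("basic_motility", eta = 0.5, dx = dx, grid_n = grid_n,
                      ...)
  sim <- pre$sim
  .apply_event(sim, pre$schedule[[1]])
  run_for(sim, minutes * 60)
  list(max_correction_pct = 100 * max(sim$log$renorm_max),
       series = sim$log$renorm_max)
}
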