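# Named in-silico experiments. Each preset builds a ready-to-run simulation
# (grid, cell, parameters, stimulus schedule) for one of the standard
# protocols; run_experiment() executes it and collects the metric series.
#
# Desk-scale defaults resolve the standard 20 um cell with ~50 sites across
# its diameter (dx = 0.4 um); the reference resolution is dx = 0.125 um.

#' Available experiment presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() {
  c("basic_motility", "resting", "frozen_ellipse", "wavy_interface",
    "injection", "vgrad_static", "vgrad_motile", "noise_ic",
    "turn90", "turn180", "wall", "obstacle")
}

#' Build a preset experiment
#'
#' @param name preset name (see [preset_names()]).
#' @param eta PI feedback strength.
#' @param dx grid spacing (um); desk scale 0.4, reference 0.125.
#' @param grid_n lattice size (grid_n x grid_n); default scales with dx.
#' @param cell_radius cell radius (um).
#' @param frozen override the preset's shape mode.
#' @param stim_noise_std std of the small correlated perturbation applied at
#'   stimulus onset in the gradient presets (fraction of basal; gives the
#'   seed-to-seed variability of otherwise deterministic frozen runs).
#' @param ... parameter overrides passed to [default_params()].
#' @return List with the simulation, the stimulus schedule and metadata.
#' @export
build_preset <- function(name, eta = 0.5, dx = 0.4, grid_n = NULL,
                         cell_radius = 10, frozen = NULL,
                         stim_noise_std = 0.01, ...) {
  name <- match.arg(name, preset_names())
  if (is.null(grid_n)) {
    need <- switch(name,
      frozen_ellipse = ceiling(3.4 * cell_radius / dx),
      wall = ,
      obstacle = ceiling(7 * cell_radius / dx),
      ceiling(5 * cell_radius / dx))
    grid_n <- max(64, 2^ceiling(log2(need)))
  }
  p <- default_params(eta = eta, dx = dx, ...)
  p$target_area <- pi * cell_radius^2
  p$target_perim <- 2 * pi * cell_radius
  g <- hex_grid(grid_n, grid_n, dx)
  frozen_default <- name %in% c("frozen_ellipse", "wavy_interface",
                                "injection", "vgrad_static")
  if (is.null(frozen)) frozen <- frozen_default
  ctr <- c(mean(range(g$x)), mean(range(g$y)))
  obstacle <- NULL
  if (name == "wall") {
    x0 <- ctr[1] + 2.2 * cell_radius
    obstacle <- place_obstacle(g, "wall", x0 = x0, x1 = x0 + 2)
  } else if (name == "obstacle") {
    obstacle <- place_obstacle(g, "disk",
      center = c(ctr[1] + 2.5 * cell_radius, ctr[2]), radius = cell_radius / 2)
  }
  if (name %in% c("wall", "obstacle")) {
    # polarized cell starts left of the barrier, moving +x
    ctr[1] <- ctr[1] - 1.2 * cell_radius
  }
  mask <- if (name == "frozen_ellipse") {
    ellipse_mask(g, a = cell_radius * sqrt(2), b = cell_radius / sqrt(2),
                 center = ctr)
  } else {
    disk_mask(g, cell_radius, center = ctr)
  }
  sim <- new_simulation(g, p, mask, obstacle = obstacle, frozen = frozen)
  sched <- switch(name,
    basic_motility = ,
    wall = ,
    obstacle = list(list(t = 0, what = "gradient", magnitude = 0.15,
                         direction = 0, duration = 10)),
    resting = list(),
    frozen_ellipse = list(list(t = 0, what = "gradient", magnitude = 0.15,
                               direction = pi / 2, duration = 10,
                               noise_std = stim_noise_std)),
    wavy_interface = list(list(t = 0, what = "polarize_template"),
                          list(t = 300, what = "sinusoidal", n_peaks = 3)),
    injection = list(list(t = 0, what = "polarize_template"),
                     list(t = 300, what = "inject")),
    vgrad_static = ,
    vgrad_motile = list(list(t = 0, what = "vgradient", magnitude = 0.075,
                             direction = 0, duration = 10,
                             noise_std = stim_noise_std)),
    noise_ic = list(list(t = 0, what = "noise", std = 0.25, corr = 2)),
    turn90 = list(list(t = 0, what = "gradient", magnitude = 0.15,
                       direction = 0, duration = 10),
                  list(t = 300, what = "gradient", magnitude = 0.03,
                       direction = pi / 2, duration = 10)),
    turn180 = list(list(t = 0, what = "gradient", magnitude = 0.15,
                        direction = 0, duration = 10),
                   list(t = 300, what = "gradient", magnitude = 0.03,
                        direction = pi, duration = 10)))
  list(name = name, sim = sim, schedule = sched, eta = eta, dx = dx,
       cell_radius = cell_radius, grid_n = grid_n)
}

# apply one scheduled event to the simulation
.apply_event <- function(sim, ev) {
  switch(ev$what,
    gradient = {
      if (!is.null(ev$noise_std) && ev$noise_std > 0)
        noisy_initial_condition(sim, std = ev$noise_std, corr_length = 2)
      set_stimulus(sim, linear_gradient(sim, magnitude = ev$magnitude,
        direction = ev$direction, onset = sim$t, duration = ev$duration))
    },
    vgradient = {
      if (!is.null(ev$noise_std) && ev$noise_std > 0)
        noisy_initial_condition(sim, std = ev$noise_std, corr_length = 2)
      set_stimulus(sim, v_gradient(sim, magnitude = ev$magnitude,
        direction = ev$direction, onset = sim$t, duration = ev$duration))
    },
    noise = noisy_initial_condition(sim, std = ev$std, corr_length = ev$corr),
    polarize_template = {
      set_stimulus(sim, linear_gradient(sim, magnitude = 0.15, direction = 0,
                                        onset = sim$t, duration = 10))
    },
    sinusoidal = sinusoidal_pattern_ic(sim, n_peaks = ev$n_peaks),
    inject = {
      ctr_site <- which(sim$mask == 1L)[which.min(
        (sim$grid$x[sim$mask == 1L] - mean(range(sim$grid$x[sim$mask == 1L])))^2 +
        (sim$grid$y[sim$mask == 1L] - mean(range(sim$grid$y[sim$mask == 1L])))^2)]
      inject_cdc42(sim, ctr_site, radius = 2)
    },
    stop("unknown scheduled event: ", ev$what))
  invisible(sim)
}

#' Run a preset experiment and collect metric series
#'
#' Executes the preset's stimulus schedule for the requested duration,
#' sampling polarity, front count, centroid, area and the renormalization
#' log at a fixed cadence. Deterministic given (configuration, seed).
#'
#' @param preset name or a [build_preset()] result.
#' @param seed RNG seed for the run.
#' @param duration simulated seconds.
#' @param sample_every metric sampling cadence (s).
#' @param out_dir optional directory: writes \code{metrics.csv},
#'   \code{manifest.json} and the final mask/fields as delimited text.
#' @param keep_masks logical: retain the mask at every sample (needed for
#'   velocity analysis; memory scales with samples x grid).
#' @param quiet suppress progress output.
#' @param ... passed to [build_preset()] when \code{preset} is a name.
#' @return List with \code{series} (data frame), \code{sim}, \code{masks}
#'   (if kept), and run metadata.
#' @export
run_experiment <- function(preset, seed = 1, duration = 300,
                           sample_every = 5, out_dir = NULL,
                           keep_masks = FALSE, quiet = TRUE, ...) {
  set.seed(seed)
  if (is.character(preset)) preset <- build_preset(preset, ...)
  sim <- preset$sim
  sched <- preset$schedule
  dt <- timestep(sim$p)
  times <- seq(0, duration, by = sample_every)[-1]
  ev_times <- vapply(sched, function(e) e$t, 0)
  # event times and sample times define the chunk boundaries
  bounds <- sort(unique(c(times, ev_times, duration)))
  bounds <- bounds[bounds > 0 & bounds <= duration]
  done <- vapply(sched, function(e) e$t <= 0, TRUE)
  for (i in which(done)) .apply_event(sim, sched[[i]])
  rows <- list()
  masks <- list()
  sample_row <- function(sim) {
    pa <- polarity_axis(sim)
    data.frame(t = sim$t,
               area = sum(sim$mask),
               cx = NA_real_, cy = NA_real_,
               angle = if (pa$defined) pa$angle else NA_real_,
               magnitude = pa$magnitude,
               fronts = count_fronts(sim),
               cdc42_max = max(sim$conc[, "cdc42_a"]),
               renorm_max = if (length(sim$log$renorm_max))
                 max(tail(sim$log$renorm_max, 1)) else 0)
  }
  t_prev <- 0
  for (tb in bounds) {
    n_steps <- round((tb - t_prev) / dt)
    if (n_steps > 0) step_simulation(sim, n_steps)
    t_prev <- tb
    for (i in seq_along(sched)) {
      if (!done[i] && abs(sched[[i]]$t - tb) < dt / 2) {
        .apply_event(sim, sched[[i]])
        done[i] <- TRUE
      }
    }
    if (any(abs(times - tb) < dt / 2)) {
      rows[[length(rows) + 1]] <- sample_row(sim)
      if (keep_masks) masks[[length(masks) + 1]] <- sim$mask + 0L  # copy: engine mutates in place
      if (!quiet) message(sprintf("t = %.0f s", sim$t))
    }
  }
  series <- do.call(rbind, rows)
  if (keep_masks && length(masks) > 1) {
    pos <- centroid_track(sim$grid, masks)
    series$cx <- pos[, 1]; series$cy <- pos[, 2]
  }
  res <- list(name = preset$name, seed = seed, series = series, sim = sim,
              masks = if (keep_masks) masks else NULL,
              eta = preset$eta, dx = preset$dx,
              worst_renorm = sim$log$worst_renorm,
              frag_events = sim$log$frag_events)
  if (!is.null(out_dir)) .write_bundle(res, out_dir)
  res
}

.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$series, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  man <- list(preset = res$name, seed = res$seed, eta = res$eta, dx = res$dx,
              package_version = as.character(utils::packageVersion("polarcpm")),
              worst_renorm = res$worst_renorm, frag_events = res$frag_events)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(data.frame(site = seq_along(res$sim$mask),
                              mask = res$sim$mask),
                   file.path(out_dir, "final_mask.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$sim$conc),
                   file.path(out_dir, "final_fields.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Deterministic small test states
#'
#' @param kind one of "disk-cell", "ellipse-cell", "half-plane",
#'   "toy-3-site", "random-fields".
#' @param size grid side length (sites).
#' @param seed RNG seed (used by "random-fields").
#' @param dx grid spacing (um).
#' @param eta PI feedback strength.
#' @return A [new_simulation()] state.
#' @export
fixture_generator <- function(kind = c("disk-cell", "ellipse-cell",
                                       "half-plane", "toy-3-site",
                                       "random-fields"),
                              size = 32, seed = 1, dx = 0.4, eta = 0) {
  kind <- match.arg(kind)
  p <- default_params(eta = eta, dx = dx)
  g <- hex_grid(size, size, dx)
  r_cell <- size * dx / 5
  p$target_area <- pi * r_cell^2
  p$target_perim <- 2 * pi * r_cell
  mask <- switch(kind,
    "disk-cell" = ,
    "random-fields" = disk_mask(g, r_cell),
    "ellipse-cell" = ellipse_mask(g, r_cell * sqrt(2), r_cell / sqrt(2)),
    "half-plane" = half_plane_mask(g, mean(range(g$x))),
    "toy-3-site" = {
      m <- integer(g$n)
      c0 <- (size %/% 2) * size + size %/% 2 + 1L   # 1-based centre site
      m[c(c0, c0 + 1L, c0 + 2L)] <- 1L
      m
    })
  sim <- new_simulation(g, p, mask, frozen = TRUE)
  if (kind == "random-fields") {
    set.seed(seed)
    m <- sim$mask == 1L
    for (j in seq_len(ncol(sim$conc)))
      sim$conc[m, j] <- sim$conc[m, j] * stats::runif(sum(m), 0.5, 1.5)
    sim$B[m, ] <- matrix(stats::runif(sum(m) * 6, 0, 10), ncol = 6)
    sim$F[m, ] <- matrix(stats::runif(sum(m) * 6, 0, 50), ncol = 6)
  }
  sim
}
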