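# Stimulation protocols: graded and V-shaped transient stimuli on the Cdc42
# activation rate, correlated-noise initial conditions, local injection,
# predetermined sinusoidal patterns, and static obstacles.

# bounding extent of the current cell along a direction (um)
.cell_extent <- function(sim, direction) {
  m <- sim$mask == 1L
  u <- c(cos(direction), sin(direction))
  proj <- sim$grid$x[m] * u[1] + sim$grid$y[m] * u[2]
  range(proj)
}

#' Transient linear gradient stimulus
#'
#' Multiplies the baseline Cdc42 activation rate by a linear ramp along the
#' stimulus direction, with the stated total relative variation across the
#' cell's bounding extent at onset (e.g. 0.15 for a 15% variation). Identity
#' outside the time window.
#'
#' @param sim simulation state (used for the cell extent at onset).
#' @param magnitude total relative variation across the cell.
#' @param direction stimulus direction (radians; 0 = +x).
#' @param onset,duration window start and length (s).
#' @return Stimulus specification to pass to [set_stimulus()].
#' @export
linear_gradient <- function(sim, magnitude = 0.15, direction = 0,
                            onset = 0, duration = 10) {
  if (magnitude < 0 || duration < 0) stop("magnitude and duration must be >= 0")
  u <- c(cos(direction), sin(direction))
  proj <- sim$grid$x * u[1] + sim$grid$y * u[2]
  ext <- .cell_extent(sim, direction)
  mid <- mean(ext); span <- diff(ext)
  field <- 1 + magnitude * (proj - mid) / span
  list(kind = "linear-gradient", field = pmax(0, field),
       t_on = onset, t_off = onset + duration,
       magnitude = magnitude, direction = direction)
}

#' Transient V-shaped gradient stimulus
#'
#' Two superimposed, simultaneous, diametrically opposed gradients along the
#' chosen axis: the activation rate rises from the cell centre toward both
#' extremities, with the stated end-to-centre relative difference.
#'
#' @param sim simulation state.
#' @param magnitude relative difference between the extremities and the
#'   centre (default 0.075, i.e. 7.5%).
#' @param direction axis direction (radians).
#' @param onset,duration window (s).
#' @return Stimulus specification.
#' @export
v_gradient <- function(sim, magnitude = 0.075, direction = 0,
                       onset = 0, duration = 10) {
  if (magnitude < 0 || duration < 0) stop("magnitude and duration must be >= 0")
  u <- c(cos(direction), sin(direction))
  proj <- sim$grid$x * u[1] + sim$grid$y * u[2]
  ext <- .cell_extent(sim, direction)
  mid <- mean(ext); half <- diff(ext) / 2
  field <- 1 + magnitude * abs(proj - mid) / half
  list(kind = "v-gradient", field = field,
       t_on = onset, t_off = onset + duration,
       magnitude = magnitude, direction = direction)
}

#' Correlated-noise initial condition
#'
#' Adds a Gaussian random field with the given standard deviation (as a
#' fraction of the basal level) and spatial autocorrelation length to the
#' active Cdc42 and Rac fields at t = 0 only, debiting the inactive pools
#' pointwise so each total is conserved; negative results are clamped after
#' compensation.
#'
#' @param sim simulation state.
#' @param std noise standard deviation as a fraction of the basal active
#'   level.
#' @param corr_length spatial autocorrelation length (um).
#' @return \code{sim}, invisibly.
#' @export
noisy_initial_condition <- function(sim, std = 0.25, corr_length = 2) {
  if (std < 0) stop("std must be >= 0")
  if (corr_length <= 0) stop("corr_length must be > 0")
  if (std == 0) return(invisible(sim))
  for (sp in c("cdc42", "rac")) {
    z <- gaussian_random_field(sim$grid, sim$mask, corr_length)
    act <- paste0(sp, "_a"); inact <- paste0(sp, "_i")
    bas <- sim$p[[paste0("bas_", sp)]]
    m <- sim$mask == 1L
    dz <- std * bas * z[m]
    a <- sim$conc[m, act] + dz
    i <- sim$conc[m, inact] - dz
    neg <- a < 0; dz[neg] <- -sim$conc[m, act][neg]
    a <- pmax(0, sim$conc[m, act] + dz)
    i <- sim$conc[m, inact] - dz
    negi <- i < 0
    a[negi] <- a[negi] + i[negi]; i[negi] <- 0
    sim$conc[m, act] <- a
    sim$conc[m, inact] <- i
  }
  invisible(sim)
}

#' Unit-variance Gaussian random field on the masked lattice
#'
#' White noise smoothed by iterated neighbour averaging until the effective
#' kernel width matches the requested autocorrelation length, then
#' standardized to unit variance over the mask.
#'
#' @param grid a [hex_grid()].
#' @param mask 0/1 vector.
#' @param corr_length autocorrelation length (um).
#' @return Numeric vector (0 outside the mask).
#' @export
gaussian_random_field <- function(grid, mask, corr_length) {
  n <- grid$n
  z <- stats::rnorm(n)
  # pass count calibrated so the realized field autocorrelation length
  # (Gaussian decay scale) matches corr_length
  n_pass <- max(1L, ceiling(1.6 * (corr_length / grid$dx)^2))
  n_pass <- min(n_pass, 2000L)
  for (i in seq_len(n_pass)) {
    zn <- matrix(z[grid$nbr], nrow = n)
    z <- 0.5 * z + 0.5 * rowMeans(zn)
  }
  m <- mask == 1L
  z[m] <- (z[m] - mean(z[m])) / stats::sd(z[m])
  z[!m] <- 0
  z
}

#' Local injection of active Cdc42
#'
#' Sets active Cdc42 in a patch to the current cell-wide maximum and debits
#' the added amount from the inactive pool: first locally (clamped at zero),
#' the remainder uniformly across the cell, so the total is conserved
#' exactly.
#'
#' @param sim simulation state.
#' @param site centre site (must be inside the cell).
#' @param radius patch radius (um).
#' @return \code{sim}, invisibly.
#' @export
inject_cdc42 <- function(sim, site, radius) {
  g <- sim$grid
  if (sim$mask[site] != 1L) stop("inject_cdc42: site is outside the cell")
  m <- sim$mask == 1L
  dxv <- wrap_delta(g$x - g$x[site], g$n_cols * g$dx)
  dyv <- wrap_delta(g$y - g$y[site], g$n_rows * g$dx * sqrt(3) / 2)
  patch <- which(m & dxv^2 + dyv^2 <= radius^2)
  peak <- max(sim$conc[m, "cdc42_a"])
  add <- pmax(0, peak - sim$conc[patch, "cdc42_a"])
  sim$conc[patch, "cdc42_a"] <- sim$conc[patch, "cdc42_a"] + add
  # debit locally, then spread any remaining deficit uniformly
  avail <- sim$conc[patch, "cdc42_i"]
  local_debit <- pmin(add, avail)
  sim$conc[patch, "cdc42_i"] <- avail - local_debit
  rest <- sum(add) - sum(local_debit)
  if (rest > 0) {
    cells <- which(m)
    pool <- sim$conc[cells, "cdc42_i"]
    if (sum(pool) < rest)
      stop("inject_cdc42: inactive pool too small to compensate")
    sim$conc[cells, "cdc42_i"] <- pool - rest * pool / sum(pool)
  }
  invisible(sim)
}

#' Predetermined sinusoidal pattern initial condition
#'
#' Re-maps a stabilized polarized profile so that every species repeats
#' sinusoidally along the horizontal axis with \code{n_peaks} maxima:
#' site values are taken from the template profile at a phase-folded
#' position, giving corresponding lower and higher levels; totals are then
#' rescaled to the template's exactly.
#'
#' @param sim simulation state holding a stabilized polarized profile.
#' @param n_peaks number of sinusoidal repetitions.
#' @return \code{sim}, invisibly.
#' @export
sinusoidal_pattern_ic <- function(sim, n_peaks = 3) {
  m <- sim$mask == 1L
  if (!any(m)) stop("sinusoidal_pattern_ic: no template available")
  xr <- range(sim$grid$x[m])
  xi <- (sim$grid$x[m] - xr[1]) / diff(xr)          # position in [0, 1]
  # fold so the pattern sweeps the template n_peaks times (triangle wave)
  ph <- abs((xi * n_peaks) %% 2 - 1)
  for (j in seq_len(ncol(sim$conc))) {
    v <- sim$conc[m, j]
    tot <- sum(v)
    if (tot == 0) next
    o <- order(xi)
    # map each site through the template's x-profile at the folded phase
    prof <- stats::approx(xi[o], v[o], xout = ph, rule = 2, ties = mean)$y
    prof <- prof * tot / sum(prof)
    sim$conc[m, j] <- prof
  }
  invisible(sim)
}

#' Static obstacle: wall or disk
#'
#' Builds a set of permanently excluded sites. Copy proposals into obstacle
#' sites are always rejected; the no-flux condition at the cell-obstacle
#' contact holds automatically because flux is only defined on the cell
#' mask.
#'
#' @param grid a [hex_grid()].
#' @param kind "wall" (half-plane band) or "disk".
#' @param x0,x1 wall band x-range (um), for kind = "wall".
#' @param center,radius disk geometry (um), for kind = "disk".
#' @return 0/1 obstacle vector.
#' @export
place_obstacle <- function(grid, kind = c("wall", "disk"), x0 = NULL,
                           x1 = NULL, center = NULL, radius = NULL) {
  kind <- match.arg(kind)
  if (kind == "wall") {
    if (is.null(x0) || is.null(x1)) stop("wall needs x0 and x1")
    as.integer(grid$x >= x0 & grid$x <= x1)
  } else {
    if (is.null(center) || is.null(radius)) stop("disk needs center and radius")
    if (radius <= 0) return(integer(grid$n))
    disk_mask(grid, radius, center)
  }
}
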