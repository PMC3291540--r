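# Quantitative readouts: front-back interface extraction, polarity axis,
# front counting, resolution/repolarization timing and centroid velocity.

# resample a hex field onto a Cartesian matrix by nearest-site lookup
.hex_to_cart <- function(grid, field, mask, factor = 2) {
  m <- mask == 1L
  xr <- range(grid$x[m]); yr <- range(grid$y[m])
  pad <- grid$dx
  nx <- max(8L, ceiling((diff(xr) + 2 * pad) / grid$dx * factor))
  ny <- max(8L, ceiling((diff(yr) + 2 * pad) / grid$dx * factor))
  xs <- seq(xr[1] - pad, xr[2] + pad, length.out = nx)
  ys <- seq(yr[1] - pad, yr[2] + pad, length.out = ny)
  # inverse of the axial embedding: r = y / (dx*sqrt(3)/2), q = x/dx - r/2
  rr <- outer(rep(1, nx), ys) / (grid$dx * sqrt(3) / 2)
  qq <- outer(xs, rep(1, ny)) / grid$dx - rr / 2
  ri <- ((round(rr)) %% grid$n_rows)
  qi <- ((round(qq)) %% grid$n_cols)
  idx <- ri * grid$n_cols + qi + 1
  z <- matrix(field[idx], nx, ny)
  inmask <- matrix(mask[idx] == 1L, nx, ny)
  z[!inmask] <- NA
  list(x = xs, y = ys, z = z)
}

#' Extract the front-back interface
#'
#' Level-set contour of a concentration field at the rest-state mean (or a
#' chosen level), clipped to the cell mask. The field is resampled onto a
#' Cartesian grid; contour polylines are returned with total length and
#' three-point circumcircle curvature estimates.
#'
#' @param sim simulation state.
#' @param species field name (default active Cdc42).
#' @param level contour level; defaults to the basal (rest-state) value.
#' @param factor Cartesian resampling factor.
#' @return List with \code{length} (um), \code{segments} (list of polyline
#'   data frames), and \code{curvature} (per-vertex estimates, 1/um).
#'   A field entirely above or below the level yields length 0.
#' @export
extract_interface <- function(sim, species = "cdc42_a", level = NULL,
                              factor = 2) {
  if (is.null(level)) level <- basal_levels(sim$p)[[species]]
  fld <- get_field(sim, species)
  cz <- .hex_to_cart(sim$grid, fld, sim$mask, factor)
  # NA outside the mask: contours break at the cell edge instead of
  # tracing it
  segs <- suppressWarnings(
    grDevices::contourLines(cz$x, cz$y, cz$z, levels = level))
  total <- 0
  curv <- numeric()
  keep <- list()
  for (s in segs) {
    if (length(s$x) < 2) next
    dl <- sqrt(diff(s$x)^2 + diff(s$y)^2)
    if (sum(dl) < 2 * sim$grid$dx) next  # discard mask-hugging slivers
    total <- total + sum(dl)
    keep[[length(keep) + 1]] <- data.frame(x = s$x, y = s$y)
    if (length(s$x) >= 3)
      curv <- c(curv, .polyline_curvature(s$x, s$y))
  }
  list(length = total, segments = keep, curvature = curv)
}

# curvature by circumcircle through consecutive vertex triples
.polyline_curvature <- function(x, y) {
  n <- length(x)
  k <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    ax <- x[i - 1] - x[i]; ay <- y[i - 1] - y[i]
    bx <- x[i + 1] - x[i]; by <- y[i + 1] - y[i]
    cross <- ax * by - ay * bx
    a <- sqrt(ax^2 + ay^2); b <- sqrt(bx^2 + by^2)
    cc <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2)
    k[i - 1] <- if (a * b * cc < 1e-12) 0 else 2 * abs(cross) / (a * b * cc)
  }
  k
}

#' Polarity axis of a field
#'
#' Direction and magnitude of the concentration-weighted centroid offset
#' from the geometric centroid of the cell, computed with periodic
#' unwrapping. The angle is flagged undefined for near-uniform fields.
#'
#' @param sim simulation state.
#' @param species field name.
#' @param tol minimum normalized offset for a defined angle.
#' @return List with \code{angle} (radians, NA if undefined),
#'   \code{magnitude} (offset / cell radius-equivalent) and \code{defined}.
#' @export
polarity_axis <- function(sim, species = "cdc42_a", tol = 1e-3) {
  g <- sim$grid
  m <- sim$mask == 1L
  w <- get_field(sim, species)[m]
  cx <- .circular_centroid(g$x[m], g$n_cols * g$dx)
  cy <- .circular_centroid(g$y[m], g$n_rows * g$dx * sqrt(3) / 2)
  if (sum(w) <= 0) return(list(angle = NA_real_, magnitude = 0, defined = FALSE))
  dxv <- wrap_delta(g$x[m] - cx, g$n_cols * g$dx)
  dyv <- wrap_delta(g$y[m] - cy, g$n_rows * g$dx * sqrt(3) / 2)
  ox <- sum(w * dxv) / sum(w)
  oy <- sum(w * dyv) / sum(w)
  scale <- sqrt(sum(m) * g$site_area / pi)   # radius of the equal-area disk
  mag <- sqrt(ox^2 + oy^2) / scale
  if (mag < tol) return(list(angle = NA_real_, magnitude = mag, defined = FALSE))
  list(angle = atan2(oy, ox), magnitude = mag, defined = TRUE)
}

# centroid of positions on a periodic interval (circular mean)
.circular_centroid <- function(v, L) {
  th <- v / L * 2 * pi
  (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * L) %% L
}

#' Count front regions
#'
#' Number of connected components (hex adjacency) of the super-level set
#' \{field > level\} inside the cell, ignoring components smaller than the
#' configured fraction of the cell area.
#'
#' @param sim simulation state.
#' @param species field name.
#' @param level threshold; defaults to the rest-state value.
#' @param min_frac minimum component size as a fraction of cell area
#'   (default \code{p$min_front_frac}).
#' @return Integer count.
#' @export
count_fronts <- function(sim, species = "cdc42_a", level = NULL,
                         min_frac = sim$p$min_front_frac) {
  if (is.null(level)) level <- basal_levels(sim$p)[[species]]
  fld <- get_field(sim, species)
  sel <- as.integer(sim$mask == 1L & fld > level)
  if (!sum(sel)) return(0L)
  lab <- hex_components(sim$grid, sel)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= max(1, min_frac * sum(sim$mask)))
}

#' Resolution time of a front-count series
#'
#' First time (from the series start) at which the front count reaches 1
#' and stays 1 for the sustain window; \code{Inf} if never.
#'
#' @param times sample times (s).
#' @param counts front counts at those times.
#' @param sustain required sustained window (s).
#' @return Time (s) or \code{Inf}.
#' @export
resolution_time <- function(times, counts, sustain = 30) {
  stopifnot(length(times) == length(counts))
  n <- length(counts)
  for (i in seq_len(n)) {
    if (counts[i] != 1) next
    horizon <- times[i] + sustain
    window <- which(times >= times[i] & times <= horizon)
    if (all(counts[window] == 1)) {
      if (times[n] >= horizon || i == n) return(times[i])
    }
  }
  Inf
}

#' Repolarization time of a polarity-angle series
#'
#' First sustained entry of the polarity angle into the target direction
#' plus/minus the tolerance; \code{Inf} if never.
#'
#' @param times sample times (s).
#' @param angles polarity angles (radians; NA = undefined).
#' @param target target direction (radians).
#' @param tol half-width of the acceptance band (radians, default 15 deg).
#' @param sustain required sustained window (s).
#' @return Time (s) or \code{Inf}.
#' @export
repolarization_time <- function(times, angles, target, tol = 15 * pi / 180,
                                sustain = 30) {
  stopifnot(length(times) == length(angles))
  dev <- abs(.angle_diff(angles, target))
  inside <- !is.na(dev) & dev <= tol
  n <- length(times)
  for (i in seq_len(n)) {
    if (!inside[i]) next
    horizon <- times[i] + sustain
    window <- which(times >= times[i] & times <= horizon)
    if (all(inside[window])) {
      if (times[n] >= horizon || i == n) return(times[i])
    }
  }
  Inf
}

# signed smallest difference between angles, with axis-symmetric option
.angle_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  d
}

#' Centroid track of a mask time series
#'
#' Positions are unwrapped across the periodic boundaries by accumulating
#' shortest displacements between consecutive samples.
#'
#' @param grid a [hex_grid()].
#' @param masks list of 0/1 mask vectors.
#' @return Matrix (length(masks) x 2) of unwrapped centroid coordinates.
#' @export
centroid_track <- function(grid, masks) {
  Lx <- grid$n_cols * grid$dx
  Ly <- grid$n_rows * grid$dx * sqrt(3) / 2
  pos <- matrix(0, length(masks), 2)
  raw <- t(vapply(masks, function(m) {
    mm <- m == 1L
    c(.circular_centroid(grid$x[mm], Lx), .circular_centroid(grid$y[mm], Ly))
  }, numeric(2)))
  pos[1, ] <- raw[1, ]
  if (nrow(raw) > 1)
    for (i in 2:nrow(raw)) {
      pos[i, 1] <- pos[i - 1, 1] + wrap_delta(raw[i, 1] - raw[i - 1, 1], Lx)
      pos[i, 2] <- pos[i - 1, 2] + wrap_delta(raw[i, 2] - raw[i - 1, 2], Ly)
    }
  pos
}

#' Centroid speed series
#'
#' Finite-difference speed of the unwrapped centroid track with an optional
#' moving-average smoothing window.
#'
#' @param grid a [hex_grid()].
#' @param masks list of masks sampled at fixed cadence.
#' @param dt_sample sampling interval (s).
#' @param smooth smoothing window in samples (1 = none).
#' @return Numeric vector of speeds (um/s), length \code{length(masks) - 1}.
#' @export
centroid_velocity <- function(grid, masks, dt_sample, smooth = 1) {
  if (length(masks) < 2) stop("need at least two samples")
  pos <- centroid_track(grid, masks)
  v <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2) / dt_sample
  if (smooth > 1) {
    v <- stats::filter(v, rep(1 / smooth, smooth), sides = 2)
    v <- as.numeric(v)
  }
  v
}

#' Angle between the concentration gradient and the cell edge
#'
#' No-flux boundaries force concentration isoclines to meet the cell edge
#' orthogonally, i.e. the in-plane gradient at a boundary site is tangent to
#' the edge. For every boundary site with an appreciable gradient this
#' returns the angle between the least-squares local gradient (fitted over
#' the in-mask first and second neighbour rings) and the boundary tangent.
#'
#' @param sim simulation state.
#' @param species field name.
#' @param min_grad_frac ignore sites whose gradient magnitude is below this
#'   fraction of the maximum boundary gradient.
#' @return Vector of angles (radians, in [0, pi/2]); mean near 0 indicates
#'   orthogonal isoclines.
#' @export
isocline_boundary_angles <- function(sim, species = "cdc42_a",
                                     min_grad_frac = 0.2) {
  g <- sim$grid
  f <- get_field(sim, species)
  cs <- cell_state(g, sim$mask)
  nm <- boundary_normals(cs)
  grads <- matrix(NA_real_, length(cs$boundary), 2)
  for (i in seq_along(cs$boundary)) {
    s <- cs$boundary[i]
    nbs <- unique(c(g$nbr[s, ], g$nbr2[s, ]))
    nbs <- nbs[sim$mask[nbs] == 1L]
    if (length(nbs) < 3) next
    dxv <- wrap_delta(g$x[nbs] - g$x[s], g$n_cols * g$dx)
    dyv <- wrap_delta(g$y[nbs] - g$y[s], g$n_rows * g$dx * sqrt(3) / 2)
    df <- f[nbs] - f[s]
    fit <- stats::lm.fit(cbind(1, dxv, dyv), df)   # intercept absorbs site noise
    grads[i, ] <- fit$coefficients[2:3]
  }
  mag <- sqrt(rowSums(grads^2))
  keep <- !is.na(mag) & mag >= min_grad_frac * max(mag, na.rm = TRUE)
  gv <- grads[keep, , drop = FALSE] / mag[keep]
  nv <- nm[keep, , drop = FALSE]
  dotn <- abs(rowSums(gv * nv))
  asin(pmin(1, dotn))
}
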