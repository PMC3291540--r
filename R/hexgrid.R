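#' Periodic hexagonal lattice
#'
#' Builds a toroidal hexagonal grid in axial coordinates (q, r). Site
#' \code{s = (r - 1) * n_cols + q} (1-based) is embedded in the plane at
#' \code{x = dx (q + r/2)}, \code{y = dx (sqrt(3)/2) r}. Every site has six
#' first-order neighbours at angles 0, 60, ..., 300 degrees; the three
#' principal axes (0, 60, 120 degrees) each partition the lattice into
#' parallel rings that cover all sites exactly once, which is what the
#' three-direction ADI diffusion solver and the orientation-resolved actin
#' transport rely on.
#'
#' @param n_rows,n_cols lattice dimensions (>= 8).
#' @param spacing distance between adjacent site centres (um).
#' @return An object of class \code{hexgrid}: list with \code{n_rows},
#'   \code{n_cols}, \code{n}, \code{dx}, \code{nbr} (n x 6 neighbour indices,
#'   1-based, column k+1 = neighbour at angle 60k), \code{nbr2} (n x 12
#'   second-ring indices), \code{x}, \code{y} (embedding), \code{chains}
#'   (compiled ring decomposition) and \code{ev} (2 x 6 orientation unit
#'   vectors).
#' @export
#' @examples
#' g <- hex_grid(8, 8, 1)
#' all(rowSums(matrix(g$nbr %in% seq_len(g$n), g$n)) == 6)
hex_grid <- function(n_rows, n_cols, spacing = 0.125) {
  if (n_rows < 8 || n_cols < 8) stop("grid must be at least 8 x 8")
  if (spacing <= 0) stop("spacing must be > 0")
  geom <- make_geometry_cpp(as.integer(n_rows), as.integer(n_cols))
  q <- rep(0:(n_cols - 1), n_rows)
  r <- rep(0:(n_rows - 1), each = n_cols)
  ang <- (0:5) * pi / 3
  g <- list(
    n_rows = n_rows, n_cols = n_cols, n = n_rows * n_cols, dx = spacing,
    nbr = geom$nbr + 1L, nbr2 = geom$nbr2 + 1L,
    geom = geom,            # 0-based geometry handed to the compiled stepper
    chains = geom$chains,
    x = spacing * (q + r / 2), y = spacing * (sqrt(3) / 2) * r,
    ev = rbind(cos(ang), sin(ang)),
    site_area = sqrt(3) / 2 * spacing^2
  )
  class(g) <- "hexgrid"
  g
}

#' @export
print.hexgrid <- function(x, ...) {
  cat(sprintf("hexgrid: %d x %d (toroidal), dx = %g um\n", x$n_rows, x$n_cols, x$dx))
  invisible(x)
}

#' Cell occupancy state
#'
#' Wraps an occupancy mask on a hexagonal grid together with the derived
#' quantities the shape engine needs: area (site count), boundary sites
#' (occupied with at least one unoccupied neighbour) and the perimeter
#' measure (count of occupied-unoccupied first-order neighbour pairs, the
#' quantity penalized by the Potts Hamiltonian).
#'
#' @param grid a [hex_grid()].
#' @param mask logical or 0/1 integer vector of length \code{grid$n}.
#' @return Object of class \code{cellstate}.
#' @export
cell_state <- function(grid, mask) {
  mask <- as.integer(as.logical(mask))
  if (length(mask) != grid$n) stop("mask length must equal grid$n")
  s <- list(grid = grid, mask = mask,
            area = sum(mask),
            boundary = boundary_sites(grid, mask),
            perimeter = perimeter_measure(grid, mask))
  class(s) <- "cellstate"
  s
}

#' @export
print.cellstate <- function(x, ...) {
  cat(sprintf("cellstate: %d sites (%.1f um^2), %d boundary sites, perimeter measure %d\n",
              x$area, x$area * x$grid$site_area, length(x$boundary), x$perimeter))
  invisible(x)
}

#' Boundary sites of a mask
#'
#' @param grid a [hex_grid()].
#' @param mask occupancy vector.
#' @return Integer site indices (1-based) of occupied sites having at least
#'   one unoccupied first-order neighbour.
#' @export
boundary_sites <- function(grid, mask) {
  mask <- as.integer(as.logical(mask))
  which(mask == 1L & .has_empty_nbr(grid, mask))
}

# any unoccupied neighbour, vectorized over sites
.has_empty_nbr <- function(grid, mask) {
  nb <- matrix(mask[grid$nbr], nrow = grid$n)
  rowSums(nb) < 6L
}

#' Perimeter measure of a mask
#'
#' Number of occupied-unoccupied first-order neighbour pairs; additive over
#' disconnected components, zero for the fully occupied torus.
#'
#' @param grid a [hex_grid()].
#' @param mask occupancy vector.
#' @return Integer pair count.
#' @export
perimeter_measure <- function(grid, mask) {
  mask <- as.integer(as.logical(mask))
  if (sum(mask) == 0) stop("perimeter_measure: empty mask")
  occ <- which(mask == 1L)
  nb <- matrix(mask[grid$nbr[occ, , drop = FALSE]], nrow = length(occ))
  sum(6L - rowSums(nb))
}

#' Outward boundary normal at a site
#'
#' Estimated from the local occupancy pattern: mean of the unit vectors from
#' the site toward each unoccupied first-order neighbour, normalized; if the
#' first-order pattern cancels (ambiguous), the second-ring pattern is used;
#' a fully isolated site is degenerate and returns the +x direction with
#' attribute \code{degenerate = TRUE}.
#'
#' @param cell a [cell_state()] (or list with \code{grid} and \code{mask}).
#' @param site site index (1-based); must be a boundary site.
#' @return Unit 2-vector (x, y components).
#' @export
boundary_normal <- function(cell, site) {
  g <- cell$grid; mask <- cell$mask
  if (mask[site] != 1L) stop("boundary_normal: site is not occupied")
  nb <- g$nbr[site, ]
  empty <- which(mask[nb] == 0L)
  if (!length(empty)) stop("boundary_normal: interior site")
  if (length(empty) == 6L) {
    v <- c(1, 0); attr(v, "degenerate") <- TRUE; return(v)
  }
  v <- rowSums(g$ev[, empty, drop = FALSE])
  if (sqrt(sum(v^2)) < 1e-9) {
    # opposite-neighbour cancellation: fall back to 2nd-order patch average
    nb2 <- c(nb, g$nbr2[site, ])
    dxv <- wrap_delta(g$x[nb2] - g$x[site], g$n_cols * g$dx)
    dyv <- wrap_delta(g$y[nb2] - g$y[site], g$n_rows * g$dx * sqrt(3) / 2)
    w <- 1 - mask[nb2]
    v <- c(sum(w * dxv), sum(w * dyv))
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) {
    v <- c(1, 0); attr(v, "degenerate") <- TRUE; return(v)
  }
  v / nv
}

# shortest displacement on a periodic interval
wrap_delta <- function(d, L) d - L * round(d / L)

#' Outward normals for all boundary sites
#'
#' @param cell a [cell_state()].
#' @return Matrix (length(boundary) x 2) of unit normals, rows aligned with
#'   \code{cell$boundary}.
#' @export
boundary_normals <- function(cell) {
  t(vapply(cell$boundary, function(s) as.numeric(boundary_normal(cell, s)),
           numeric(2)))
}

#' Disk-shaped cell mask
#'
#' @param grid a [hex_grid()].
#' @param center site coordinates (x, y) in um; defaults to the grid centre.
#' @param radius disk radius in um.
#' @return 0/1 integer mask vector.
#' @export
disk_mask <- function(grid, radius, center = NULL) {
  if (is.null(center))
    center <- c(mean(range(grid$x)), mean(range(grid$y)))
  dxv <- wrap_delta(grid$x - center[1], grid$n_cols * grid$dx)
  dyv <- wrap_delta(grid$y - center[2], grid$n_rows * grid$dx * sqrt(3) / 2)
  as.integer(dxv^2 + dyv^2 <= radius^2)
}

#' Ellipse-shaped cell mask
#'
#' @param grid a [hex_grid()].
#' @param a,b semi-axes (um) along x and y.
#' @param center centre (x, y) in um; defaults to the grid centre.
#' @param angle rotation of the a-axis from +x (radians).
#' @return 0/1 integer mask vector.
#' @export
ellipse_mask <- function(grid, a, b, center = NULL, angle = 0) {
  if (is.null(center))
    center <- c(mean(range(grid$x)), mean(range(grid$y)))
  dxv <- wrap_delta(grid$x - center[1], grid$n_cols * grid$dx)
  dyv <- wrap_delta(grid$y - center[2], grid$n_rows * grid$dx * sqrt(3) / 2)
  u <- cos(angle) * dxv + sin(angle) * dyv
  v <- -sin(angle) * dxv + cos(angle) * dyv
  as.integer((u / a)^2 + (v / b)^2 <= 1)
}

#' Half-plane mask
#'
#' All sites with x-coordinate below a threshold; used for flat-edge tests.
#'
#' @param grid a [hex_grid()].
#' @param x0 threshold (um).
#' @return 0/1 integer mask vector.
#' @export
half_plane_mask <- function(grid, x0) as.integer(grid$x < x0)

#' Connected components of a site set under hex adjacency
#'
#' @param grid a [hex_grid()].
#' @param mask 0/1 vector.
#' @return Integer vector of length \code{grid$n}: 0 outside the mask,
#'   component label (1 = largest) inside.
#' @export
hex_components <- function(grid, mask) {
  components_cpp(as.integer(as.logical(mask)), grid$nbr - 1L)
}
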