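# Shared fixtures: everything is generated in code; no data files.

small_grid <- function(n = 16, dx = 0.5) hex_grid(n, n, dx)

# brute-force occupied-unoccupied pair count over all site pairs (oracle)
brute_perimeter <- function(grid, mask) {
  cnt <- 0L
  for (s in which(mask == 1L))
    cnt <- cnt + sum(mask[grid$nbr[s, ]] == 0L)
  cnt
}

# brute-force Hamiltonian oracle: per-pair double loop
brute_hamiltonian <- function(grid, mask, p) {
  s <- cpm_scaled_public(p, grid$dx)
  pairs <- 0L
  for (i in which(mask == 1L)) {
    pairs <- pairs + sum(mask[grid$nbr[i, ]] == 0L)
    if (s$nbr_order >= 2) pairs <- pairs + sum(mask[grid$nbr2[i, ]] == 0L)
  }
  area <- sum(mask)
  perim <- brute_perimeter(grid, mask)
  s$J * pairs + s$lam_area * (area - s$A0)^2 + s$lam_perim * (perim - s$P0)^2
}

# re-derive the scaled CPM constants the way the package does
cpm_scaled_public <- function(p, dx) {
  p$dx <- dx
  v <- polarcpm:::.cpm_vec(p)
  list(J = v[["J"]], lam_area = v[["lam_area"]], A0 = v[["A0"]],
       lam_perim = v[["lam_perim"]], P0 = v[["P0"]],
       nbr_order = v[["nbr_order"]])
}

# tiny frozen simulation with a disk cell
disk_sim <- function(n = 40, dx = 0.5, r = 4, eta = 0, frozen = TRUE, ...) {
  p <- default_params(eta = eta, dx = dx, ...)
  g <- hex_grid(n, n, dx)
  p$target_area <- pi * r^2
  p$target_perim <- 2 * pi * r
  new_simulation(g, p, disk_mask(g, r), frozen = frozen)
}

# explicit-Euler diffusion oracle on the full hex Laplacian (masked, no-flux)
explicit_diffuse <- function(grid, f, mask, D, t_total, dt) {
  coef <- 2 / 3 * D / grid$dx^2
  inm <- mask == 1L
  for (i in seq_len(round(t_total / dt))) {
    nb <- matrix(f[grid$nbr], nrow = grid$n)
    nbm <- matrix(inm[grid$nbr], nrow = grid$n)
    lap <- rowSums((nb - f) * nbm)
    f <- f + dt * coef * lap * inm
  }
  f
}

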