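test_that("Hamiltonian matches the brute-force per-pair oracle", {
  g <- small_grid()
  p <- default_params()
  p$target_area <- 20 * g$site_area
  p$target_perim <- 5
  p$target_perim_pairs <- 40
  set.seed(5)
  for (i in 1:5) {
    m <- as.integer(runif(g$n) < 0.3)
    cell <- list(grid = g, mask = m)
    expect_equal(hamiltonian(cell, p), brute_hamiltonian(g, m, p))
  }
  # empty mask has zero energy; at both targets only the coupling term remains
  expect_equal(hamiltonian(list(grid = g, mask = integer(g$n)), p), 0)
  m7 <- integer(g$n); m7[100] <- 1L; m7[g$nbr[100, ]] <- 1L
  p2 <- p
  p2$target_area <- 7 * g$site_area
  p2$target_perim_pairs <- perimeter_measure(g, m7)
  s <- cpm_scaled_public(p2, g$dx)
  pairs_only <- brute_hamiltonian(g, m7, p2)
  expect_equal(hamiltonian(list(grid = g, mask = m7), p2), pairs_only)
  expect_equal(pairs_only %% s$J, 0)   # pure pair count times J
})

test_that("Metropolis rule: yield threshold, Boltzmann tail, zero-temperature limit", {
  p <- default_params()
  expect_equal(metropolis_probability(-p$H_yield, p), 1)
  expect_equal(metropolis_probability(-p$H_yield - 5, p), 1)
  expect_equal(metropolis_probability(-p$H_yield + p$temp_T * log(2), p), 0.5)
  pT <- p; pT$temp_T <- 1e-9
  expect_equal(metropolis_probability(-p$H_yield + 0.01, pT), 0)
  expect_equal(metropolis_probability(-p$H_yield - 0.01, pT), 1)
})

test_that("empirical acceptance frequencies reproduce the closed form", {
  p <- default_params()
  set.seed(21)
  for (dH in c(-300, -150, 0, 100)) {
    n <- 2e4
    acc <- mean(vapply(seq_len(n), function(i) metropolis_accept(dH, p), TRUE))
    pr <- metropolis_probability(dH, p)
    se <- sqrt(pr * (1 - pr) / n)
    expect_lt(abs(acc - pr), max(4 * se, 1e-6))
  }
})

test_that("force bias vanishes without pushing ends or above-threshold Rho", {
  sim <- disk_sim()
  g <- sim$grid
  bd <- boundary_sites(g, sim$mask)
  s <- bd[1]
  t_new <- g$nbr[s, which(sim$mask[g$nbr[s, ]] == 0L)[1]]
  sim$Bp[s, ] <- 0
  sim$conc[s, "rho_a"] <- sim$p$rho_thresh   # exactly at threshold
  expect_equal(force_bias(sim, s, t_new), 0)
  # contraction is linear just above threshold
  sim$conc[s, "rho_a"] <- sim$p$rho_thresh + 0.1
  expect_equal(force_bias(sim, s, t_new), -sim$p$lam_contract * 0.1)
  expect_equal(force_bias(sim, t_new, s), sim$p$lam_contract * 0.1)
  # pushing ends toward the target favour the protrusion
  k <- which(g$nbr[s, ] == t_new)
  sim$conc[s, "rho_a"] <- 0
  sim$Bp[s, k] <- 10
  expect_equal(force_bias(sim, s, t_new), 10)
  expect_error(force_bias(sim, s, s), "neighbours")
})

test_that("mean protrusion speed is non-positive without drive and saturates", {
  p <- default_params()
  p$dx <- 0.125
  expect_lte(mean_protrusion_speed(0, p), 0)
  v <- mean_protrusion_speed(c(1, 10, 100, 1000, 1e5), p)
  expect_true(all(diff(v) >= 0))
  expect_lt(abs(v[5] - p$dx / timestep(p)), 1e-6)   # ratchet limit of the rule
})

test_that("force-velocity calibration reproduces the stored temperature and yield", {
  p <- default_params()
  p$dx <- 0.125
  p$temp_T <- 150; p$H_yield <- 350       # start away from the answer
  fit <- calibrate_force_velocity(p)
  expect_equal(fit$temp_T, 108.9, tolerance = 0.05)
  expect_equal(fit$H_yield, 274.6, tolerance = 0.05)
  # the two force-velocity relations agree over the fitted range
  expect_lt(fit$rms, 0.12)
  expect_lt(max(abs(fit$table$v_cpm - fit$table$v_ratchet)), 0.2)
})

test_that("Monte-Carlo sweeps conserve GTPase totals and barbed-end counts", {
  # cooler membrane keeps the audit window fragmentation-free (a shed
  # fragment legitimately removes its densities with it)
  set.seed(8)
  sim <- disk_sim(n = 32, dx = 0.5, r = 4, eta = 0.5, frozen = FALSE,
                  temp_T = 60)
  bd <- boundary_sites(sim$grid, sim$mask)
  sim$Bp[bd, ] <- matrix(runif(length(bd) * 6, 0, 30), ncol = 6)
  sim$B[sim$mask == 1, ] <- matrix(runif(sum(sim$mask) * 6, 0, 20), ncol = 6)
  tot0 <- gtpase_totals(sim)
  ends0 <- barbed_end_total(sim)
  # shape updates only: reactions, diffusion and actin kinetics off
  step_simulation(sim, 50, do_reaction = FALSE, do_diffusion = FALSE,
                  do_actin = FALSE)
  expect_gt(sum(sim$log$acc_prot) + sum(sim$log$acc_retr), 0)
  expect_equal(sim$log$frag_events, 0L)
  tot1 <- gtpase_totals(sim)
  expect_equal(unname(tot1), unname(tot0), tolerance = 1e-12)
  expect_equal(barbed_end_total(sim), ends0, tolerance = 1e-9)
})

test_that("with forces disabled the cell fluctuates about the target-area disk", {
  set.seed(9)
  sim <- disk_sim(n = 80, dx = 0.4, r = 10, frozen = FALSE,
                  lam_contract = 0)
  sim$B[] <- 0; sim$Bp[] <- 0
  sim$p$k_arp_act <- 0; sim$p$k_arp_cdc42 <- 0
  areas <- numeric(30)
  for (i in 1:30) {
    step_simulation(sim, 10)
    areas[i] <- sum(sim$mask)
  }
  A0 <- sim$p$target_area / sim$grid$site_area
  expect_lt(abs(mean(areas[10:30]) - A0) / A0, 0.02)
})

test_that("proposals into obstacle sites are always rejected", {
  g <- hex_grid(32, 32, 0.5)
  p <- default_params()
  p$target_area <- pi * 4^2
  p$target_perim <- 2 * pi * 4
  obst <- place_obstacle(g, "disk", center = c(mean(range(g$x)) + 5,
                                               mean(range(g$y))), radius = 2)
  mask <- disk_mask(g, 4, center = c(mean(range(g$x)) - 2, mean(range(g$y))))
  mask[obst == 1L] <- 0L
  set.seed(10)
  sim <- new_simulation(g, p, mask, obstacle = obst, frozen = FALSE)
  step_simulation(sim, 200)
  expect_equal(sum(sim$mask[obst == 1L]), 0L)
  expect_equal(sum(place_obstacle(g, "disk", center = c(1, 1), radius = 0)), 0)
})
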