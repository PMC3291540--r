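test_that("the actin module comprises 18 orientation-resolved fields", {
  sim <- disk_sim()
  expect_equal(ncol(sim$F), 6)
  expect_equal(ncol(sim$B), 6)
  expect_equal(ncol(sim$Bp), 6)
})

test_that("filaments decay exponentially without barbed ends", {
  sim <- disk_sim()
  m <- sim$mask == 1
  sim$B[] <- 0
  # suppress nucleation entirely so no new ends appear
  sim$p$k_nuc <- 0
  f0 <- sim$F[m, 1][1]
  dt <- timestep(sim$p)
  for (i in 1:20) actin_step(sim)
  expect_equal(sim$F[m, 1][1], f0 * (1 - sim$p$d_F * dt)^20, tolerance = 1e-10)
})

test_that("interior barbed-end transport matches a 1D upwind oracle and conserves mass", {
  sim <- disk_sim(n = 40, dx = 0.5, r = 6)
  m <- which(sim$mask == 1)
  # silence reactions: pure advection
  sim$p$k_arp_act <- 0; sim$p$k_arp_cdc42 <- 0; sim$p$k_cap <- 0
  sim$p$cap_red_max <- 0; sim$p$d_F <- 0; sim$p$sc_FtoC <- 0
  sim$F[] <- 0; sim$B[] <- 0; sim$Bp[] <- 0
  g <- sim$grid
  ctr <- m[which.min((g$x[m] - mean(g$x[m]))^2 + (g$y[m] - mean(g$y[m]))^2)]
  sim$B[ctr, 1] <- 10           # one interior pulse in the +x class
  dt <- timestep(sim$p)
  lam <- sim$p$v_poly * dt / g$dx
  k_steps <- 6
  # oracle: 1D explicit upwind along the +x ring through ctr
  chain <- ctr
  for (i in 1:12) chain <- c(chain, g$nbr[tail(chain, 1), 1])
  b_or <- c(10, numeric(12))
  for (s in 1:k_steps) b_or <- b_or - lam * b_or + lam * c(0, head(b_or, -1))
  tot0 <- barbed_end_total(sim)
  for (s in 1:k_steps) actin_step(sim)
  expect_equal(sim$B[chain, 1], b_or, tolerance = 1e-10)
  expect_equal(barbed_end_total(sim), tot0, tolerance = 1e-10)
})

test_that("uniform fields with branching balancing capping stay unchanged", {
  sim <- disk_sim()
  m <- sim$mask == 1
  b0 <- sim$B[m, 1][1]
  interior <- setdiff(which(m), boundary_sites(sim$grid, sim$mask))
  before <- sim$B[interior, ] + 0
  actin_step(sim)
  # interior sites away from the edge see zero net flux and balanced reactions
  deep <- interior[vapply(interior, function(s)
    all(sim$grid$nbr[s, ] %in% interior), TRUE)]
  expect_lt(max(abs(sim$B[deep, ] - b0)), 1e-8 * b0)
})

test_that("edge flux feeds pushing ends at the blocked-outlet rate", {
  sim <- disk_sim(n = 24, dx = 0.5, r = 3)
  g <- sim$grid
  # flat-edge configuration: half-plane cell
  p <- sim$p
  mask <- half_plane_mask(g, mean(range(g$x)))
  sim2 <- new_simulation(g, p, mask, frozen = TRUE)
  sim2$B[] <- 0; sim2$Bp[] <- 0
  bd <- boundary_sites(g, mask)
  # pick a right-edge site whose +x outlet is open (the torus also has a left edge)
  s <- bd[which(mask[g$nbr[bd, 1]] == 0L)[3]]
  expect_true(sim2$mask[g$nbr[s, 1]] == 0L)
  sim2$B[s, 1] <- 8
  dt <- timestep(p)
  pushing_ends_step(sim2, s, dt)
  lam <- p$v_poly * dt / g$dx
  expect_equal(sim2$Bp[s, 1], lam * 8 * g$site_area / g$dx)
  expect_equal(sim2$B[s, 1], 8 * (1 - lam))
  # ends parallel to the edge gain nothing
  sim2$B[s, 2] <- 5
  before <- sim2$Bp[s, 2]
  pushing_ends_step(sim2, s, dt)
  if (sim2$mask[g$nbr[s, 2]] == 1L) expect_equal(sim2$Bp[s, 2], before)
  interior <- which(mask == 1 & apply(matrix(mask[g$nbr], ncol = 6), 1, min) == 1)
  expect_error(pushing_ends_step(sim2, interior[1], dt), "boundary")
})

test_that("demotion on protrusion conserves total end count", {
  sim <- disk_sim()
  g <- sim$grid
  bd <- boundary_sites(g, sim$mask)
  s <- bd[1]
  open_k <- which(sim$mask[g$nbr[s, ]] == 0L)[1]
  new_site <- g$nbr[s, open_k]
  sim$Bp[s, open_k] <- 12
  tot0 <- barbed_end_total(sim)
  sim$mask[new_site] <- 1L
  demote_on_protrusion(sim, new_site)
  expect_equal(sim$Bp[s, open_k], 0)
  expect_equal(barbed_end_total(sim), tot0, tolerance = 1e-12)
  expect_error(demote_on_protrusion(sim, which(sim$mask == 0L)[1]),
               "newly occupied")
})

test_that("promotion on retraction redistributes mass with orientations preserved", {
  sim <- disk_sim()
  g <- sim$grid
  bd <- boundary_sites(g, sim$mask)
  s <- bd[1]
  sim$F[] <- 0; sim$B[] <- 0; sim$Bp[] <- 0
  sim$F[s, ] <- c(7, 0, 0, 0, 0, 0)
  sim$B[s, ] <- c(3, 0, 0, 1, 0, 0)
  totF <- sum(sim$F); tot0 <- barbed_end_total(sim)
  sim$mask[s] <- 0L
  promote_on_retraction(sim, s)
  expect_equal(sum(sim$F), totF, tolerance = 1e-12)       # same class: column 1 only
  expect_equal(sum(sim$F[, 1]), totF, tolerance = 1e-12)
  expect_equal(barbed_end_total(sim), tot0, tolerance = 1e-12)
  expect_true(all(sim$F[s, ] == 0) && all(sim$B[s, ] == 0))
  expect_error(promote_on_retraction(sim, which(sim$mask == 1L)[1]), "occupied")
  # retraction of an empty-density site changes nothing
  sim3 <- disk_sim()
  bd3 <- boundary_sites(sim3$grid, sim3$mask)
  s3 <- bd3[2]
  sim3$F[s3, ] <- 0; sim3$B[s3, ] <- 0; sim3$Bp[s3, ] <- 0
  snap <- list(F = sim3$F + 0, B = sim3$B + 0)
  sim3$mask[s3] <- 0L
  promote_on_retraction(sim3, s3)
  expect_equal(sim3$F, snap$F)
  expect_equal(sim3$B, snap$B)
})

test_that("all 18 fields stay non-negative over randomized short runs", {
  set.seed(11)
  for (rep in 1:3) {
    sim <- disk_sim(n = 24, dx = 0.5, r = 3, eta = 0.5, frozen = FALSE)
    m <- sim$mask == 1
    sim$conc[m, ] <- sim$conc[m, ] * runif(sum(m), 0.6, 1.4)
    sim$B[m, ] <- sim$B[m, ] * runif(sum(m), 0, 2)
    step_simulation(sim, 100)
    expect_true(all(sim$F >= 0))
    expect_true(all(sim$B >= 0))
    expect_true(all(sim$Bp >= 0))
    expect_true(all(sim$conc >= 0))
  }
})

test_that("actin goes extinct when Arp2/3 activation is silenced", {
  sim <- disk_sim(n = 24, dx = 0.5, r = 3)
  sim$p$k_arp_act <- 0; sim$p$k_arp_cdc42 <- 0
  m <- sim$mask == 1
  sim$conc[m, "arp"] <- 0
  ends0 <- barbed_end_total(sim); f0 <- sum(sim$F)
  run_for(sim, 150)
  expect_lt(barbed_end_total(sim), 1e-4 * ends0)
  expect_lt(sum(sim$F), 1e-3 * f0)
})
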