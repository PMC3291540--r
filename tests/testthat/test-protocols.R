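test_that("linear gradient has the stated relative variation across the cell", {
  sim <- disk_sim(n = 40, dx = 0.5, r = 6)
  st <- linear_gradient(sim, magnitude = 0.15, direction = 0, duration = 10)
  m <- sim$mask == 1
  expect_equal(diff(range(st$field[m])), 0.15, tolerance = 0.01)
  expect_equal(mean(range(st$field[m])), 1, tolerance = 0.005)
  st0 <- linear_gradient(sim, magnitude = 0, direction = 0)
  expect_true(all(st0$field == 1))
  # the ramp follows the requested direction
  st90 <- linear_gradient(sim, magnitude = 0.1, direction = pi / 2)
  expect_gt(cor(st90$field[m], sim$grid$y[m]), 0.999)
})

test_that("V gradient is symmetric about the cell midline with the stated difference", {
  sim <- disk_sim(n = 40, dx = 0.5, r = 6)
  st <- v_gradient(sim, magnitude = 0.075, direction = 0, duration = 10)
  m <- sim$mask == 1
  xs <- sim$grid$x[m]
  mid <- mean(range(xs)); half <- diff(range(xs)) / 2
  expected <- 1 + 0.075 * abs(xs - mid) / half
  expect_lt(max(abs(st$field[m] - expected)), 1e-12)
  # exact mirror symmetry of the profile function
  d <- seq(0, half, length.out = 11)
  left <- 1 + 0.075 * abs(-d) / half
  right <- 1 + 0.075 * abs(d) / half
  expect_equal(left, right)
  expect_true(all(v_gradient(sim, magnitude = 0)$field[m] == 1))
})

test_that("noise IC conserves totals and matches the requested statistics", {
  set.seed(2)
  sim <- disk_sim(n = 64, dx = 0.5, r = 12)
  tot0 <- gtpase_totals(sim)
  noisy_initial_condition(sim, std = 0, corr_length = 2)
  expect_equal(max(abs(sim$conc[sim$mask == 1, "cdc42_a"] - 1)), 0)
  # empirical std over seeds
  sds <- replicate(20, {
    s2 <- disk_sim(n = 64, dx = 0.5, r = 12)
    noisy_initial_condition(s2, std = 0.1, corr_length = 2)
    sd(s2$conc[s2$mask == 1, "cdc42_a"])
  })
  expect_lt(abs(mean(sds) - 0.1) / 0.1, 0.1)
  noisy_initial_condition(sim, std = 0.2, corr_length = 2)
  expect_equal(unname(gtpase_totals(sim)), unname(tot0), tolerance = 1e-9)
  expect_true(all(sim$conc >= 0))
})

test_that("noise field has the requested autocorrelation length", {
  g <- hex_grid(96, 96, 0.4)
  mask <- disk_mask(g, 15)
  m <- mask == 1
  set.seed(4)
  L <- 2
  cors <- replicate(5, {
    z <- gaussian_random_field(g, mask, L)
    s0 <- which(m); nb <- s0
    for (i in seq_len(round(L / g$dx))) nb <- g$nbr[nb, 1]
    ok <- m[nb]
    cor(z[s0[ok]], z[nb[ok]])
  })
  # Gaussian autocorrelation: corr at lag L is exp(-1/2)
  expect_lt(abs(mean(cors) - exp(-0.5)), 0.2 * exp(-0.5))
})

test_that("Cdc42 injection raises the patch to the peak and conserves the total", {
  set.seed(3)
  sim <- disk_sim(n = 40, dx = 0.5, r = 6)
  m <- sim$mask == 1
  sim$conc[m, "cdc42_a"] <- sim$conc[m, "cdc42_a"] * runif(sum(m), 0.8, 1.6)
  tot0 <- sum(sim$conc[m, "cdc42_a"]) + sum(sim$conc[m, "cdc42_i"])
  peak <- max(sim$conc[m, "cdc42_a"])
  ctr <- which(m)[1]
  inject_cdc42(sim, ctr, radius = 1.2)
  expect_equal(unname(sim$conc[ctr, "cdc42_a"]), unname(peak))
  expect_equal(sum(sim$conc[m, "cdc42_a"]) + sum(sim$conc[m, "cdc42_i"]),
               tot0, tolerance = 1e-9)
  # injecting at the current maximum changes nothing
  s_max <- which(m)[which.max(sim$conc[m, "cdc42_a"])]
  before <- sim$conc + 0
  inject_cdc42(sim, s_max, radius = 0.1)
  expect_equal(sim$conc, before)
  expect_error(inject_cdc42(sim, which(sim$mask == 0L)[1], 1), "outside")
})

test_that("toy three-site injection audit matches hand bookkeeping", {
  sim <- fixture_generator("toy-3-site", size = 12)
  sites <- which(sim$mask == 1L)
  sim$conc[sites, "cdc42_a"] <- c(1, 2, 0.5)
  sim$conc[sites, "cdc42_i"] <- c(1.4, 0.4, 1.9)
  inject_cdc42(sim, sites[3], radius = 1e-6)  # patch = that site only
  # site 3 raised from 0.5 to the max (2): +1.5 debited from its inactive 1.9
  expect_equal(unname(sim$conc[sites[3], "cdc42_a"]), 2)
  expect_equal(unname(sim$conc[sites[3], "cdc42_i"]), 0.4)
  expect_equal(sum(sim$conc[sites, c("cdc42_a", "cdc42_i")]), 1 + 2 + 0.5 + 1.4 + 0.4 + 1.9)
})

test_that("sinusoidal pattern remap makes the requested number of peaks", {
  set.seed(1)
  pre <- build_preset("wavy_interface", eta = 0.5, dx = 0.5, grid_n = 64,
                      cell_radius = 6)
  sim <- pre$sim
  set_stimulus(sim, linear_gradient(sim, 0.15, 0, onset = 0, duration = 10))
  run_for(sim, 200)
  tot0 <- colSums(sim$conc[sim$mask == 1, ])
  sinusoidal_pattern_ic(sim, 3)
  expect_equal(colSums(sim$conc[sim$mask == 1, ]), tot0, tolerance = 1e-9)
  # count maxima of the binned x-profile
  m <- sim$mask == 1
  xb <- cut(sim$grid$x[m], 24)
  prof <- tapply(sim$conc[m, "cdc42_a"], xb, mean)
  prof <- prof[!is.na(prof)]
  sm <- stats::filter(prof, rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  peaks <- sum(diff(sign(diff(sm))) == -2)
  expect_gte(peaks, 2)
  expect_lte(peaks, 4)
})

test_that("wall obstacles exclude sites and reject overlapping cells", {
  g <- hex_grid(32, 32, 0.5)
  wall <- place_obstacle(g, "wall", x0 = 10, x1 = 11)
  expect_true(all(g$x[wall == 1L] >= 10 & g$x[wall == 1L] <= 11))
  p <- default_params()
  mask <- disk_mask(g, 3, center = c(10.5, 8))
  expect_error(new_simulation(g, p, mask, obstacle = wall), "overlaps")
})
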