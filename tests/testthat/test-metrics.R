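test_that("interface of a linear ramp crossing at the diameter has chord length", {
  sim <- disk_sim(n = 48, dx = 0.5, r = 8)
  g <- sim$grid
  m <- sim$mask == 1
  mid <- mean(range(g$x[m]))
  sim$conc[, "cdc42_a"] <- ifelse(m, 1 + 0.5 * (g$x - mid), 0)
  res <- extract_interface(sim, "cdc42_a", level = 1)
  expect_equal(res$length, 16, tolerance = 0.1 * 16)
  # uniform field at the level: no interface
  sim$conc[m, "cdc42_a"] <- 1
  expect_equal(extract_interface(sim, "cdc42_a", level = 1)$length, 0)
})

test_that("a wavy interface is longer than the straight chord", {
  sim <- disk_sim(n = 48, dx = 0.5, r = 8)
  g <- sim$grid
  m <- sim$mask == 1
  mid <- mean(range(g$x[m])); midy <- mean(range(g$y[m]))
  sim$conc[, "cdc42_a"] <- ifelse(m, 1 + 0.4 * (g$x - mid - 2 * sin(g$y - midy)), 0)
  wavy <- extract_interface(sim, "cdc42_a", level = 1)
  expect_gt(wavy$length, 16)
  expect_true(length(wavy$curvature) > 0)
})

test_that("polarity axis points along a ramp and is equivariant under rotation", {
  sim <- disk_sim(n = 48, dx = 0.5, r = 8)
  g <- sim$grid
  m <- sim$mask == 1
  mid <- mean(range(g$x[m])); midy <- mean(range(g$y[m]))
  sim$conc[, "cdc42_a"] <- ifelse(m, 2 + 0.1 * (g$x - mid), 0)
  pa <- polarity_axis(sim)
  expect_true(pa$defined)
  expect_lt(abs(pa$angle), 2 * pi / 180)
  sim$conc[, "cdc42_a"] <- ifelse(m, 2 + 0.1 * (g$y - midy), 0)
  pa90 <- polarity_axis(sim)
  expect_lt(abs(pa90$angle - pi / 2), 2 * pi / 180)
  expect_equal(pa$magnitude, pa90$magnitude, tolerance = 0.05)
  sim$conc[m, "cdc42_a"] <- 1.7
  expect_false(polarity_axis(sim)$defined)
})

test_that("front counting respects hex adjacency and the minimum size", {
  sim <- disk_sim(n = 48, dx = 0.5, r = 8)
  g <- sim$grid
  m <- which(sim$mask == 1)
  sim$conc[m, "cdc42_a"] <- 0.5            # all below basal
  expect_equal(count_fronts(sim), 0L)
  # two well-separated patches
  left <- m[g$x[m] < quantile(g$x[m], 0.2)]
  right <- m[g$x[m] > quantile(g$x[m], 0.8)]
  sim$conc[left, "cdc42_a"] <- 2
  sim$conc[right, "cdc42_a"] <- 2
  expect_equal(count_fronts(sim), 2L)
  # a single-site blip is ignored at the configured minimum size
  sim$conc[m, "cdc42_a"] <- 0.5
  sim$conc[m[1], "cdc42_a"] <- 3
  expect_equal(count_fronts(sim), 0L)
})

test_that("resolution time scans match a brute-force oracle", {
  brute <- function(times, counts, sustain) {
    for (i in seq_along(times)) {
      w <- which(times >= times[i] & times <= times[i] + sustain)
      if (counts[i] == 1 && all(counts[w] == 1) &&
          (tail(times, 1) >= times[i] + sustain || i == length(times)))
        return(times[i])
    }
    Inf
  }
  t5 <- seq(0, 100, by = 10)
  c1 <- c(2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(resolution_time(t5, c1, sustain = 20), 20)
  expect_equal(resolution_time(t5, rep(2, 11), sustain = 20), Inf)
  c2 <- c(2, 1, 2, 1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(resolution_time(t5, c2, sustain = 30), brute(t5, c2, 30))
  set.seed(6)
  for (i in 1:10) {
    cc <- sample(1:3, 11, replace = TRUE)
    expect_equal(resolution_time(t5, cc, sustain = 30), brute(t5, cc, 30))
  }
})

test_that("repolarization time detects sustained entry into the target band", {
  t5 <- seq(0, 200, by = 20)
  a_in <- rep(0.1, 11)
  expect_equal(repolarization_time(t5, a_in, 0, tol = 0.3, sustain = 40), 0)
  a_rot <- seq(pi, 0, length.out = 11)   # monotone rotation into the band
  tr <- repolarization_time(t5, a_rot, 0, tol = 15 * pi / 180, sustain = 40)
  expect_equal(tr, t5[which(abs(a_rot) <= 15 * pi / 180)[1]])
  expect_equal(repolarization_time(t5, rep(pi, 11), 0, tol = 0.2, sustain = 40), Inf)
  expect_equal(repolarization_time(t5, rep(NA_real_, 11), 0, tol = 0.2, sustain = 40), Inf)
})

test_that("centroid velocity handles static masks, rigid translation and wrap", {
  g <- hex_grid(24, 24, 0.5)
  m0 <- disk_mask(g, 2.5)
  expect_equal(centroid_velocity(g, list(m0, m0, m0), 1), c(0, 0))
  # rigid translation by one site per sample along +x (wraps the torus)
  shift_x <- function(m) {
    out <- integer(g$n)
    for (s in which(m == 1L)) out[g$nbr[s, 1]] <- 1L
    out
  }
  masks <- list(m0)
  for (i in 1:40) masks[[i + 1]] <- shift_x(masks[[i]])
  v <- centroid_velocity(g, masks, dt_sample = 2)
  expect_equal(v, rep(g$dx / 2, 40), tolerance = 1e-6)
  pos <- centroid_track(g, masks)
  expect_equal(pos[41, 1] - pos[1, 1], 40 * g$dx, tolerance = 1e-6)
  expect_error(centroid_velocity(g, list(m0), 1), "two samples")
})
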