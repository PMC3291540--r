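test_that("mutual-inhibition rates drop to half at the half-max constants", {
  p <- default_params(eta = 0)
  expect_equal(cdc42_activation_rate(p$a_rho, p$bas_pip2, p),
               cdc42_activation_rate(0, p$bas_pip2, p) / 2)
  r0 <- rho_activation_rate(0, p$bas_rac, p)
  expect_equal(rho_activation_rate(p$a_cdc, p$bas_rac, p), r0 / 2)
  # monotonicity
  rho <- seq(0, 4, by = 0.25)
  expect_true(all(diff(cdc42_activation_rate(rho, p$bas_pip2, p)) < 0))
  expect_error(cdc42_activation_rate(-1, 1, p), ">= 0")
})

test_that("PIP2 feedback factor anchors at basal, vanishes at zero, saturates", {
  p5 <- default_params(eta = 0.5)
  expect_equal(pi_feedback_factor(p5$bas_pip2, p5), 1)
  expect_equal(pi_feedback_factor(0, p5), 1 - p5$eta)
  p1 <- default_params(eta = 1)
  expect_equal(pi_feedback_factor(0, p1), 0)
  expect_equal(cdc42_activation_rate(1, 0, p1), 0)
  # saturation level approached from below
  hi <- pi_feedback_factor(1e4, p5)
  expect_true(all(diff(pi_feedback_factor(seq(1, 50, by = 1), p5)) >= 0))
  expect_lt(pi_feedback_factor(50, p5), hi + 1e-9)
  # equal rates at basal PIP2 for any eta, across a Rho sweep
  p0 <- default_params(eta = 0)
  for (rho in c(0, 0.5, 1.25, 3))
    expect_equal(cdc42_activation_rate(rho, p0$bas_pip2, p0),
                 cdc42_activation_rate(rho, p5$bas_pip2, p5))
  # continuity in eta at fixed inputs
  etas <- seq(0, 1, by = 0.05)
  vals <- vapply(etas, function(e)
    cdc42_activation_rate(1, 6, default_params(eta = e)), 0)
  expect_lt(max(abs(diff(vals))), 0.1 * max(vals))
})

test_that("Rac rate is linear in Cdc42 and Rho rate is eta-independent", {
  p <- default_params(eta = 0)
  base <- rac_activation_rate(0, p$bas_pip2, p)
  expect_equal(base, p$I_rac)
  r1 <- rac_activation_rate(1, p$bas_pip2, p)
  r2 <- rac_activation_rate(2, p$bas_pip2, p)
  expect_equal(r2 - r1, r1 - base)    # linear increments
  p5 <- default_params(eta = 0.5)
  for (cd in c(0, 1, 3)) for (ra in c(0, 2, 6))
    expect_equal(rho_activation_rate(cd, ra, p),
                 rho_activation_rate(cd, ra, p5))
})

test_that("GTPase interconversion conserves each pointwise total", {
  p <- default_params(eta = 0.5)
  set.seed(7)
  for (i in 1:20) {
    f <- list(cdc42_a = runif(1, 0, 3), rac_a = runif(1, 0, 8),
              rho_a = runif(1, 0, 3), cdc42_i = runif(1, 0, 2),
              rac_i = runif(1, 0, 5), rho_i = runif(1, 0, 2),
              pip2 = runif(1, 0, 10))
    d <- gtpase_reaction(f, p)
    expect_equal(d[["cdc42_a"]] + d[["cdc42_i"]], 0)
    expect_equal(d[["rac_a"]] + d[["rac_i"]], 0)
    expect_equal(d[["rho_a"]] + d[["rho_i"]], 0)
  }
  # nothing to activate: active pool only decays
  f0 <- list(cdc42_a = 1, rac_a = 1, rho_a = 1, cdc42_i = 0, rac_i = 0,
             rho_i = 0, pip2 = 5)
  d0 <- gtpase_reaction(f0, p)
  expect_equal(d0[["cdc42_a"]], -p$d_gtp)
})

test_that("PI kinase/phosphatase activities double at the stated GTPase levels", {
  p <- default_params()
  b <- as.list(basal_levels(p))
  # at rac_a = rac_2x the PI5K and PI3K factors are exactly (1 + rac_2x/rac_2x) = 2
  f <- b; f$rac_a <- p$rac_2x; f$rho_a <- 0; f$pip3 <- 0; f$pip2 <- 0
  d <- pi_reaction(f, p)
  # PIP loss to PI5K at doubled rate: I - d*pip - 2*k5*pip
  expect_equal(d[["pip"]], p$I_pip - p$d_pi * f$pip - 2 * p$k_pi5k * f$pip)
  # only PIP grows when all lipids are absent
  f2 <- b; f2$pip <- 0; f2$pip2 <- 0; f2$pip3 <- 0
  d2 <- pi_reaction(f2, p)
  expect_gt(d2[["pip"]], 0)
  expect_equal(d2[["pip2"]], 0)
  expect_equal(d2[["pip3"]], 0)
  # basal state is a fixed point of the lipid subsystem
  expect_lt(max(abs(pi_reaction(b, p))), 1e-12)
})

test_that("homogeneous rest state is linearly stable with diffusion damping", {
  for (eta in c(0, 0.5)) {
    p <- default_params(eta = eta)
    b <- basal_levels(p)[1:9]
    nms <- names(b)
    f0 <- signalling_reaction(c(b, arp = basal_levels(p)[["arp"]]), p)[nms]
    J <- matrix(0, 9, 9)
    for (j in 1:9) {
      bb <- b; h <- 1e-6 * max(1, abs(b[j])); bb[j] <- bb[j] + h
      fj <- signalling_reaction(c(bb, arp = basal_levels(p)[["arp"]]), p)[nms]
      J[, j] <- (unlist(fj) - unlist(f0)) / h
    }
    D <- c(rep(p$D_act, 3), rep(p$D_inact, 3), rep(p$D_pi, 3))
    ks <- c(seq(0.05, 2, by = 0.05), 3, 5, 8)
    growth <- vapply(ks, function(k)
      max(Re(eigen(J - diag(D * k^2), only.values = TRUE)$values)), 0)
    expect_lt(max(growth), 1e-8)
  }
})

test_that("branching saturates and vanishes without nucleator or mothers", {
  p <- default_params()
  expect_equal(branching_rate(0, 100, p), 0)
  expect_equal(branching_rate(5, 0, p), 0)
  expect_equal(branching_rate(1e9, 50, p), p$k_nuc * p$sc_CtoB,
               tolerance = 1e-4)
  x <- branching_rate(seq(0.1, 10, by = 0.1), 100, p)
  expect_true(all(diff(x) > 0))
  expect_error(branching_rate(-1, 1, p), ">= 0")
})

test_that("capping drops sigmoidally with PIP2 between basal and floor rates", {
  p <- default_params()
  expect_equal(capping_rate(0, FALSE, p), p$k_cap)
  floor_rate <- p$k_cap * (1 - p$cap_red_max)
  expect_equal(capping_rate(1e6, FALSE, p), floor_rate, tolerance = 1e-6)
  expect_equal(capping_rate(p$P2_cap, FALSE, p), (p$k_cap + floor_rate) / 2)
  expect_equal(capping_rate(p$P2_cap, TRUE, p),
               p$cap_le_fact * (p$k_cap + floor_rate) / 2)
})

test_that("Arp2/3 activation needs PIP2 and is accelerated by Cdc42", {
  p <- default_params()
  expect_equal(arp23_activation(5, 0, p), 0)
  base <- arp23_activation(0, seq(0.5, 20, by = 0.5), p)
  syn <- arp23_activation(2, seq(0.5, 20, by = 0.5), p)
  expect_true(all(syn >= base))
  grid_c <- seq(0, 5, length.out = 20)
  grid_p <- seq(0, 20, length.out = 20)
  vals <- outer(grid_c, grid_p, function(cc, pp) arp23_activation(cc, pp, p))
  expect_true(all(apply(vals, 2, function(col) all(diff(col) >= 0))))
  expect_true(all(apply(vals, 1, function(row) all(diff(row) >= 0))))
})

test_that("basal actin fixed point balances nucleation and capping", {
  p <- default_params()
  a0 <- basal_actin(p)
  expect_gt(a0$B_tot, 0)
  arp0 <- basal_levels(p)[["arp"]]
  resid <- branching_rate(arp0, a0$F_tot, p) -
    capping_rate(p$bas_pip2, FALSE, p) * a0$B_tot
  expect_lt(abs(resid), 1e-8 * a0$B_tot)
  # extinct when branching cannot outrun capping
  q <- default_params(k_arp_act = 0, k_arp_cdc42 = 0)
  expect_equal(basal_actin(q)$B_tot, 0)
})
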