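test_that("drift rate is k * (coherence + me)", {
  expect_equal(drift_rate(ddm_params(1, 10, 0.3, 0.3), 0.1), 1.0)
  expect_equal(drift_rate(ddm_params(1, 10, 0.3, 0.3, me = 0.1), -0.1), 0)
  expect_equal(drift_rate(params_c_left(), 0.512), 2.44776)
})

test_that("choice probability has the right limits and symmetries", {
  p0 <- ddm_params(1.5, 8, 0.3, 0.3, z = 0.5, me = 0)
  expect_equal(choice_probability(p0, 0), 0.5)
  # zero drift (coherence cancelling me) gives P = z for any z
  for (z in c(0.2, 0.5, 0.83)) {
    pz <- ddm_params(1.5, 8, 0.3, 0.3, z = z, me = 0.1)
    expect_equal(choice_probability(pz, -0.1), z, tolerance = 1e-9)
  }
  # extreme drift saturates without overflow
  pbig <- ddm_params(3, 40, 0.3, 0.3)
  expect_equal(choice_probability(pbig, 1), 1, tolerance = 1e-10)
  expect_equal(choice_probability(pbig, -1), 0, tolerance = 1e-10)
  # bias symmetry: P_right(coh; me, z) = 1 - P_right(-coh; -me, 1-z)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.5, 3); k <- runif(1, 1, 20)
    z <- runif(1, 0.1, 0.9); me <- runif(1, -0.4, 0.4)
    coh <- runif(1, -0.6, 0.6)
    p1 <- choice_probability(ddm_params(a, k, .3, .3, z, me), coh)
    p2 <- choice_probability(ddm_params(a, k, .3, .3, 1 - z, -me), -coh)
    expect_equal(p1, 1 - p2, tolerance = 1e-10)
  }
})

test_that("choice probability is monotone in coherence, me and z", {
  base <- list(a = 1.6, k = 7, t0 = .3, t1 = .3, z = 0.45, me = -0.05)
  coh <- seq(-0.5, 0.5, length.out = 21)
  p <- choice_probability(do.call(ddm_params, base), coh)
  expect_true(all(diff(p) > 0))
  mes <- seq(-0.4, 0.4, length.out = 17)
  pm <- vapply(mes, function(m) choice_probability(
    ddm_params(base$a, base$k, .3, .3, base$z, m), 0.1), 0)
  expect_true(all(diff(pm) > 0))
  zs <- seq(0.1, 0.9, length.out = 17)
  pz <- vapply(zs, function(z) choice_probability(
    ddm_params(base$a, base$k, .3, .3, z, base$me), 0.1), 0)
  expect_true(all(diff(pz) > 0))
})

test_that("mean decision time has the diffusive limits", {
  # zero drift, central start: E[T] = (a/2)^2 for unit-variance diffusion
  for (a in c(0.8, 1.77, 3)) {
    p <- ddm_params(a, 5, 0.3, 0.3, z = 0.5, me = 0)
    expect_equal(mean_decision_time(p, 0)$mean, (a / 2)^2,
                 tolerance = 1e-8)
  }
  # doubling a quadruples the zero-drift mean
  m1 <- mean_decision_time(ddm_params(1, 5, .3, .3), 0)$mean
  m2 <- mean_decision_time(ddm_params(2, 5, .3, .3), 0)$mean
  expect_equal(m2 / m1, 4, tolerance = 1e-8)
  # decreasing in |drift| at fixed a, z = 0.5
  p <- ddm_params(1.6, 8, .3, .3)
  ms <- mean_decision_time(p, seq(0, 0.5, by = 0.05))$mean
  expect_true(all(diff(ms) < 0))
})

test_that("analytic choice probability and decision times match Monte-Carlo", {
  set.seed(101)
  n <- 2e4
  for (i in 1:6) {
    a <- runif(1, 0.8, 2.5); k <- runif(1, 2, 15)
    z <- runif(1, 0.25, 0.75); me <- runif(1, -0.3, 0.3)
    coh <- sample(c(-COH_SET, COH_SET), 1)
    p <- ddm_params(a, k, 0.3, 0.35, z, me)
    sim <- simulate_trials(p, coh, n, dt = 1e-3)
    expect_lt(mean(sim$censored), 0.001)
    pa <- choice_probability(p, coh)
    pm <- mean(sim$choice == "right")
    expect_lt(abs(pm - pa), 3 * sqrt(pa * (1 - pa) / n) + 1e-6)
    td <- sim$rt - ifelse(sim$choice == "right", p$t1, p$t0)
    ma <- mean_decision_time(p, coh)$mean
    expect_lt(abs(mean(td) - ma), 3 * sd(td) / sqrt(n))
  }
})

test_that("simulated RTs never undercut the choice's non-decision time", {
  p <- ddm_params(1.2, 6, t0 = 0.25, t1 = 0.4, z = 0.6, me = 0)
  set.seed(2)
  sim <- simulate_trials(p, 0.064, 2000, dt = 1e-3)
  expect_true(all(sim$rt[sim$choice == "left"] > p$t0))
  expect_true(all(sim$rt[sim$choice == "right"] > p$t1))
})

test_that("first-passage density normalises and matches the analytic choice probability", {
  tt <- seq(1e-4, 40, length.out = 40000)
  dtg <- diff(tt[1:2])
  for (pars in list(params_c_left(), params_c_right(),
                    ddm_params(1.1, 3, .2, .25, .3, .3))) {
    for (coh in c(-0.256, 0.032, 0.512)) {
      fr <- exp(fpt_log_density(pars, coh, "right", tt + pars$t1))
      fl <- exp(fpt_log_density(pars, coh, "left", tt + pars$t0))
      expect_equal(sum(fr + fl) * dtg, 1, tolerance = 1e-3)
      expect_equal(sum(fr) * dtg, choice_probability(pars, coh),
                   tolerance = 1e-3)
      # conditional mean from the density matches the closed form
      expect_equal(sum(tt * fr) * dtg / (sum(fr) * dtg),
                   mean_decision_time(pars, coh)$upper, tolerance = 1e-3)
    }
  }
})

test_that("density agrees with the Monte-Carlo RT distribution", {
  p <- params_c_left()
  coh <- 0.128
  set.seed(5)
  n <- 4e4
  sim <- simulate_trials(p, coh, n, dt = 1e-3)
  # total-variation distance between binned MC histogram and the density
  breaks <- seq(0, 5, by = 0.05)
  for (side in c("left", "right")) {
    rts <- pmin(sim$rt[sim$choice == side], 4.99)
    h <- hist(rts, breaks = breaks, plot = FALSE)$counts / n
    mid <- breaks[-1] - 0.025
    dens <- exp(fpt_log_density(p, coh, side, mid)) * 0.05
    expect_lt(sum(abs(h - dens)) / 2, 0.02)
  }
  expect_equal(fpt_log_density(p, coh, "right", p$t1 - 0.01), -Inf)
})

test_that("collapsing bounds reduce to a fixed-bound model when beta = 0", {
  p <- ddm_params(1.6, 6, 0.3, 0.3, z = 0.55, me = 0.05)
  cb <- collapsing_bound(0, d = 1)
  a_eff <- p$a / (1 + exp(-1))
  z_eff <- (p$a * p$z - (p$a - a_eff) / 2) / a_eff
  p_eff <- ddm_params(a_eff, p$k, p$t0, p$t1, z_eff, p$me)
  set.seed(11)
  n <- 3e4
  sim <- simulate_trials_collapsing(p, cb, 0.064, n, dt = 5e-4)
  pa <- choice_probability(p_eff, 0.064)
  expect_lt(abs(mean(sim$choice == "right") - pa),
            3 * sqrt(pa * (1 - pa) / n))
  td <- sim$rt - ifelse(sim$choice == "right", p$t1, p$t0)
  expect_lt(abs(mean(td) - mean_decision_time(p_eff, 0.064)$mean),
            3 * sd(td) / sqrt(n))
})

test_that("strong collapse shortens decisions; strong evidence still wins", {
  p <- ddm_params(1.6, 6, 0.3, 0.3)
  set.seed(12)
  fix <- simulate_trials(p, 0, 5000, dt = 1e-3)
  col <- simulate_trials_collapsing(p, collapsing_bound(5, 0), 0, 5000,
                                    dt = 1e-3)
  expect_lt(mean(col$rt), mean(fix$rt))
  hi <- simulate_trials_collapsing(p, collapsing_bound(2, 1), 0.9, 2000,
                                   dt = 1e-3)
  expect_gt(mean(hi$choice == "right"), 0.95)
})
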