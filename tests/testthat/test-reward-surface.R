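sym_econ <- function(context = "LR-Left", iti = 2, timeout = 3)
  task_economics(1, 1, iti = iti, timeout_error = timeout,
                 coherence_levels = COH_SET, context = context)

test_that("equal rewards give a symmetric surface peaked at (0, 0.5)", {
  g <- grid_spec(n_me = 41, n_z = 41)
  s <- compute_surface(params_c_left(), sym_econ(), g)
  f <- surface_features(s)
  expect_equal(unname(f$argmax["me"]), 0, tolerance = 1e-9)
  expect_equal(unname(f$argmax["z"]), 0.5, tolerance = 1e-9)
  # symmetry under (me, z) -> (-me, 1-z)
  expect_equal(s$values, s$values[rev(seq_along(s$me)),
                                  rev(seq_along(s$z))],
               tolerance = 1e-8)
})

test_that("asymmetric reward shifts the optimum toward the large-reward side", {
  sL <- compute_surface(params_c_left(),
                        task_economics(1.91, 1, context = "LR-Left",
                                       coherence_levels = COH_SET))
  fL <- surface_features(sL)
  expect_lt(fL$argmax["me"], 0)
  expect_lt(fL$argmax["z"], 0.5)
  sR <- compute_surface(params_c_right(),
                        task_economics(1.91, 1, context = "LR-Right",
                                       coherence_levels = COH_SET))
  fR <- surface_features(sR)
  expect_gt(fR$argmax["me"], 0)
  expect_gt(fR$argmax["z"], 0.5)
})

test_that("analytic and Monte-Carlo engines agree at probe nodes", {
  g <- grid_spec(me_lim = c(-0.3, 0.3), z_lim = c(0.25, 0.75),
                 n_me = 3, n_z = 3)
  econ <- task_economics(1.91, 1, context = "LR-Left",
                         coherence_levels = c(0.064, 0.256))
  sa <- compute_surface(params_c_left(), econ, g)
  sm <- compute_surface(params_c_left(), econ, g, method = "mc",
                        n_mc = 8000, seed = 3)
  # MC standard error of RTrial per node is roughly reward_sd/sqrt(cells*n)
  expect_lt(max(abs(sa$values - sm$values)), 0.03)
})

test_that("RTrial ignores timing; RR falls with longer inter-trial intervals", {
  g <- grid_spec(n_me = 21, n_z = 21)
  s1 <- compute_surface(params_c_left(), sym_econ(iti = 1, timeout = 0), g)
  s2 <- compute_surface(params_c_left(), sym_econ(iti = 9, timeout = 5), g)
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
  r1 <- compute_surface(params_c_left(), sym_econ(iti = 1), g,
                        objective = "RR")
  r2 <- compute_surface(params_c_left(), sym_econ(iti = 9), g,
                        objective = "RR")
  expect_true(all(r2$values < r1$values))
})

test_that("surface features report the argmax and a known patch tilt", {
  # synthetic anisotropic Gaussian bump with principal axis 30 deg from
  # vertical (grid spacing equal on both axes so angles are unambiguous)
  g <- grid_spec(me_lim = c(-0.5, 0.5), z_lim = c(0, 1), n_me = 101,
                 n_z = 101)
  th <- 30 * pi / 180
  mk <- function(me, z) {
    u <- sin(th) * me + cos(th) * (z - 0.5)   # along-axis coordinate
    w <- cos(th) * me - sin(th) * (z - 0.5)
    exp(-(u^2 / (2 * 0.09) + w^2 / (2 * 0.0025)))
  }
  vals <- outer(g$me, g$z, mk)
  s <- structure(list(me = g$me, z = g$z, values = vals,
                      objective = "RTrial", method = "analytic"),
                 class = "reward_surface")
  f <- surface_features(s)
  expect_equal(unname(f$orientation), 30, tolerance = 2)
  expect_equal(f$max_value, max(vals))
  expect_true(f$patch_area > 0 && f$patch_area <= length(vals))
  # circularly symmetric bump: isotropy flag, orientation reported as 0
  iso <- s
  iso$values <- outer(g$me, g$z,
                      function(me, z) exp(-(me^2 + (z - 0.5)^2) / 0.02))
  fi <- surface_features(iso)
  expect_true(fi$isotropic)
  expect_equal(fi$orientation, 0)
})

test_that("argmax is stable under grid refinement", {
  econ <- task_economics(1.91, 1, context = "LR-Left",
                         coherence_levels = COH_SET)
  f1 <- surface_features(compute_surface(params_c_left(), econ,
                                         grid_spec(n_me = 31, n_z = 26)))
  f2 <- surface_features(compute_surface(params_c_left(), econ,
                                         grid_spec(n_me = 61, n_z = 51)))
  cell <- c(1.2 / 30, 1 / 25)   # coarse spacing
  expect_lt(abs(f1$argmax["me"] - f2$argmax["me"]), cell[1])
  expect_lt(abs(f1$argmax["z"] - f2$argmax["z"]), cell[2])
})

test_that("reward summaries interpolate and never beat the maximum", {
  s <- compute_surface(params_c_left(),
                       task_economics(1.91, 1, context = "LR-Left",
                                      coherence_levels = COH_SET))
  f <- surface_features(s)
  at_max <- reward_summary(s, f$argmax["me"], f$argmax["z"])
  expect_equal(at_max$ratio_predicted_to_max, 1, tolerance = 1e-9)
  set.seed(7)
  for (i in 1:25) {
    rs <- reward_summary(s, runif(1, -0.6, 0.6), runif(1, 0, 1))
    expect_lte(rs$ratio_predicted_to_max, 1 + 1e-12)
    expect_gt(rs$ratio_predicted_to_max, 0)
  }
  expect_warning(reward_summary(s, 0.9, 0.5), "clipped")
})

test_that("conditional optima match a brute-force slice scan", {
  s <- compute_surface(params_c_left(),
                       task_economics(1.91, 1, context = "LR-Left",
                                      coherence_levels = COH_SET))
  co <- conditional_optima(s, fixed_z = 0.5)
  vals <- interp_surface(s, s$me, rep(0.5, length(s$me)))
  expect_equal(co$optimum, s$me[which.max(vals)])
  expect_lte(co$slice_max, max(s$values))
  expect_true(co$band[1] <= co$optimum && co$optimum <= co$band[2])
  # symmetric surface: conditional me* at z = 0.5 is 0
  ssym <- compute_surface(params_c_left(), sym_econ(),
                          grid_spec(n_me = 41, n_z = 41))
  expect_equal(conditional_optima(ssym, fixed_z = 0.5)$optimum, 0)
  expect_error(conditional_optima(s), "exactly one")
})

test_that("near-peak gradient is steeper on the under-biased side", {
  # along me at the optimal z: moving toward zero bias (under-biased) loses
  # reward faster than over-biasing by the same amount
  s <- compute_surface(params_c_left(),
                       task_economics(1.91, 1, context = "LR-Left",
                                      coherence_levels = COH_SET))
  f <- surface_features(s)
  me_star <- f$argmax["me"]; z_star <- f$argmax["z"]
  d <- 0.1
  under <- interp_surface(s, me_star + d, z_star)   # toward 0 (me* < 0)
  over <- interp_surface(s, me_star - d, z_star)
  expect_lt(under, over)
})
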