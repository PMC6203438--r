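test_that("starting points implement the four overshoot assumptions", {
  expect_equal(starting_point("over_me", "LR-Left", 0.512,
                              baseline_z = 0.51),
               c(me = -0.4608, z = 0.51))
  expect_equal(starting_point("over_me", "LR-Right", 0.512,
                              baseline_z = 0.51)[["me"]], 0.4608)
  expect_equal(starting_point("over_z", "LR-Right", 0.512,
                              baseline_me = 0.035)[["z"]], 0.9)
  expect_equal(starting_point("over_z", "LR-Left", 0.512)[["z"]], 0.1)
  expect_equal(starting_point("neutral", "LR-Left", 0.512, 0.035, 0.51),
               c(me = 0.035, z = 0.51))
  expect_equal(starting_point("over_both", "LR-Left", 0.4),
               c(me = -0.36, z = 0.1))
  expect_error(starting_point("bogus", "LR-Left", 0.5), "unknown variant")
})

quad_surface <- function() {
  g <- grid_spec(me_lim = c(-0.5, 0.5), z_lim = c(0, 1), n_me = 81,
                 n_z = 81)
  vals <- outer(g$me, g$z, function(me, z)
    2 - (me^2 + (z - 0.5)^2))   # radially symmetric bowl, peak 2 at centre
  structure(list(me = g$me, z = g$z, values = vals, objective = "RTrial",
                 method = "analytic"), class = "reward_surface")
}

test_that("gradient ascent climbs monotonically to the required level set", {
  s <- quad_surface()
  thr <- 2 - 0.04   # level set: circle of radius 0.2
  tr <- gradient_ascent(s, c(me = -0.45, z = 0.15), thr)
  expect_true(tr$terminated)
  expect_false(tr$stationary)
  expect_true(all(diff(tr$objective_values) >= 0))
  r_end <- sqrt(tr$endpoint["me"]^2 + (tr$endpoint["z"] - 0.5)^2)
  expect_lt(abs(r_end - 0.2), 0.02)   # within ~2 step lengths of the set
  expect_gte(tail(tr$objective_values, 1), thr - 1e-6)
  # starting at the peak terminates immediately
  tr0 <- gradient_ascent(s, c(me = 0, z = 0.5), thr)
  expect_equal(tr0$n_steps, 0)
  expect_equal(unname(tr0$endpoint), c(0, 0.5))
  # threshold above the max is clipped with a warning
  expect_warning(gradient_ascent(s, c(0, 0.5), 5), "clipped")
  expect_error(gradient_ascent(s, c(2, 0.5), 1), "inside the grid")
})

test_that("halving the step does not move endpoints materially", {
  surf <- surfaces_c()[["LR-Left"]]
  st <- starting_point("over_me", "LR-Left", 0.512, 0.035, 0.51)
  thr <- 0.97 * max(surf$values)
  e1 <- gradient_ascent(surf, st, thr)$endpoint
  e2 <- gradient_ascent(surf, st, thr,
                        step_length = sqrt(1.2^2 + 1) / 400)$endpoint
  cell <- c(diff(surf$me[1:2]), diff(surf$z[1:2]))
  expect_lt(abs(e1["me"] - e2["me"]), cell[1])
  expect_lt(abs(e1["z"] - e2["z"]), cell[2])
})

test_that("endpoints at the 97% threshold land on the 97% contour", {
  surf <- surfaces_c()[["LR-Left"]]
  f <- surface_features(surf)
  thr <- 0.97 * f$max_value
  for (v in c("over_me", "over_z", "neutral")) {
    st <- starting_point(v, "LR-Left", 0.512, 0.035, 0.51)
    tr <- gradient_ascent(surf, st, thr)
    expect_true(tr$terminated)
    # value at the endpoint within one step of the contour level
    expect_gte(tail(tr$objective_values, 1), thr - 1e-9)
    expect_lt(tail(tr$objective_values, 1), thr + 0.02 * f$max_value)
  }
})

test_that("endpoint classes follow the large-reward sign convention", {
  mk_traj <- function(me, z) structure(
    list(points = matrix(c(me, z), 1), objective_values = 1,
         terminated = TRUE, stationary = FALSE, termination_value = 1,
         endpoint = c(me = me, z = z), n_steps = 0, flagged = FALSE),
    class = "gradient_trajectory")
  expect_equal(classify_endpoint(mk_traj(-0.1, 0.6), "LR-Left")$class,
               "me_adaptive_z_nonadaptive")
  expect_equal(classify_endpoint(mk_traj(0.1, 0.6), "LR-Right")$class,
               "both_adaptive")
  expect_equal(classify_endpoint(mk_traj(-0.1, 0.4), "LR-Right")$class,
               "both_nonadaptive")
  expect_equal(classify_endpoint(mk_traj(0.05, 0.3), "LR-Left")$class,
               "z_adaptive_me_nonadaptive")
  b <- classify_endpoint(mk_traj(0, 0.5), "LR-Left")
  expect_true(b$boundary)
  expect_equal(b$class, "both_adaptive")   # ties break adaptive
})

test_that("only over-me starts reproduce the adaptive-me/non-adaptive-z pattern", {
  surfs <- surfaces_c()
  fit <- fake_session_fit(params_c_left(), params_c_right())
  pattern <- list()
  for (v in c("over_me", "over_z", "over_both", "neutral")) {
    pd <- predict_deltas(list(fit), list(surfs), v)
    d <- pd$deltas
    pattern[[v]] <- c(me = d$pred_delta_me, z = d$pred_delta_z)
  }
  expect_gt(pattern$over_me["me"], 0)
  expect_lt(pattern$over_me["z"], 0)
  for (v in c("over_z", "over_both", "neutral")) {
    expect_false(pattern[[v]]["me"] > 0 && pattern[[v]]["z"] < 0)
  }
})

test_that("satisficing predictions track the generating pattern across a cohort", {
  # three synthetic sessions with over-adjusted me and counter-adaptive z,
  # session-specific sensitivity: predictions and actuals should align
  surfs <- list(); fits <- list()
  for (i in 1:3) {
    kmul <- c(0.8, 1, 1.25)[i]
    pl <- ddm_params(1.77, 6.58 * kmul, 0.33, 0.35,
                     z = 0.60 + 0.02 * i, me = -0.1 - 0.03 * i)
    pr <- ddm_params(1.53, 5.08 * kmul, 0.31, 0.33,
                     z = 0.44 - 0.02 * i, me = 0.15 + 0.03 * i)
    fits[[i]] <- fake_session_fit(pl, pr)
    surfs[[i]] <- list(
      "LR-Left" = compute_surface(pl, task_economics(
        1.91, 1, context = "LR-Left", coherence_levels = COH_SET)),
      "LR-Right" = compute_surface(pr, task_economics(
        1.91, 1, context = "LR-Right", coherence_levels = COH_SET)))
  }
  pd <- predict_deltas(fits, surfs, "over_me")
  expect_equal(nrow(pd$deltas), 3)
  expect_true(all(pd$deltas$pred_delta_me > 0))
  expect_true(all(pd$deltas$pred_delta_z < 0))
  expect_true(is.finite(pd$regression["me"]))
  # deterministic under identical config
  pd2 <- predict_deltas(fits, surfs, "over_me")
  expect_identical(pd$deltas, pd2$deltas)
})
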