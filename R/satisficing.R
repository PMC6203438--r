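# Satisficing, gradient-following adjustment of the two bias parameters on
# a reward surface: over-biased starting points, ascent along the local
# reward gradient, termination once the session's achieved reward level is
# reached.

.START_VARIANTS <- c("over_me", "over_z", "over_both", "neutral")

#' Starting point for the satisficing learner
#'
#' Four starting-point assumptions: `over_me` overshoots the
#' momentary-evidence bias in the adaptive direction (90% of the session's
#' highest coherence, negative for LR-Left) with `z` at baseline; `over_z`
#' overshoots the decision-rule bias (`z = 0.1` for LR-Left, `0.9` for
#' LR-Right) with `me` at baseline; `over_both` overshoots both; `neutral`
#' starts at the baselines.  Baselines are the midpoints of the fitted
#' values across the two reward contexts.
#'
#' @param variant One of `"over_me"`, `"over_z"`, `"over_both"`,
#'   `"neutral"`.
#' @param context `"LR-Left"` or `"LR-Right"`.
#' @param max_coherence Highest unsigned coherence used in the session.
#' @param baseline_me,baseline_z Midpoints of the fitted `me` and `z`
#'   across contexts.
#' @return Named numeric vector `c(me, z)`.
#' @export
starting_point <- function(variant, context, max_coherence,
                           baseline_me = 0, baseline_z = 0.5) {
  if (!variant %in% .START_VARIANTS)
    stop("unknown variant: ", variant)
  stopifnot(context %in% c("LR-Left", "LR-Right"))
  sgn <- if (context == "LR-Left") -1 else 1
  me_over <- sgn * 0.9 * max_coherence
  z_over <- if (context == "LR-Left") 0.1 else 0.9
  switch(variant,
         over_me = c(me = me_over, z = baseline_z),
         over_z = c(me = baseline_me, z = z_over),
         over_both = c(me = me_over, z = z_over),
         neutral = c(me = baseline_me, z = baseline_z))
}

# bilinearly interpolated gradient at a point (from the node-wise
# finite-difference field)
.interp_gradient <- function(surface, grad, me, z) {
  gs <- function(m) {
    tmp <- surface; tmp$values <- m
    interp_surface(tmp, me, z)
  }
  c(dme = gs(grad$dme), dz = gs(grad$dz))
}

#' Gradient ascent on a reward surface
#'
#' Follows the interpolated finite-difference gradient of the surface from a
#' starting point in small normalised steps (default 1/200 of the grid
#' diagonal) until the surface value reaches `threshold` (the satisficing
#' termination) or the gradient vanishes.  If a step would decrease the
#' value (possible near ridges) the step is halved; the recorded objective
#' values are non-decreasing.
#'
#' @param surface A `reward_surface`.
#' @param start Numeric `c(me, z)` inside the grid.
#' @param threshold Termination value; clipped to `0.999 * max` with a
#'   warning if above the surface maximum.
#' @param step_length Step size in surface units; default grid diagonal /
#'   200.
#' @param max_steps Step budget; exceeded trajectories are flagged.
#' @param grad_tol Gradient-norm tolerance for declaring a stationary
#'   point (relative to max |gradient| on the grid).
#' @return An object of class `gradient_trajectory`: `points` (matrix of
#'   (me, z) states), `objective_values`, `terminated`, `stationary`,
#'   `termination_value`, `endpoint`.
#' @export
gradient_ascent <- function(surface, start, threshold, step_length = NULL,
                            max_steps = 1e5, grad_tol = 1e-6) {
  stopifnot(inherits(surface, "reward_surface"), length(start) == 2)
  me_rng <- range(surface$me); z_rng <- range(surface$z)
  if (start[1] < me_rng[1] || start[1] > me_rng[2] ||
      start[2] < z_rng[1] || start[2] > z_rng[2])
    stop("start must lie inside the grid")
  mx <- max(surface$values)
  if (threshold > mx) {
    warning("threshold above surface maximum; clipped to 0.999 * max")
    threshold <- 0.999 * mx
  }
  if (is.null(step_length))
    step_length <- sqrt(diff(me_rng)^2 + diff(z_rng)^2) / 200
  grad <- .surface_gradient(surface)
  gmax <- max(sqrt(grad$dme^2 + grad$dz^2))
  pt <- c(me = unname(start[1]), z = unname(start[2]))
  val <- interp_surface(surface, pt[1], pt[2])
  pts <- matrix(pt, 1, 2, dimnames = list(NULL, c("me", "z")))
  vals <- val
  terminated <- val >= threshold
  stationary <- FALSE
  steps <- 0L
  while (!terminated && steps < max_steps) {
    g <- .interp_gradient(surface, grad, pt[1], pt[2])
    gn <- sqrt(sum(g^2))
    if (gn < grad_tol * gmax) { stationary <- TRUE; terminated <- TRUE; break }
    h <- step_length
    repeat {
      cand <- pt + h * g / gn
      cand[1] <- min(max(cand[1], me_rng[1]), me_rng[2])
      cand[2] <- min(max(cand[2], z_rng[1]), z_rng[2])
      cval <- interp_surface(surface, cand[1], cand[2])
      if (cval >= val || h < step_length / 1024) break
      h <- h / 2
    }
    if (cval < val || all(cand == pt)) {  # stuck (ridge or grid corner)
      stationary <- TRUE; terminated <- TRUE; break
    }
    pt <- cand; val <- cval
    pts <- rbind(pts, pt); vals <- c(vals, val)
    steps <- steps + 1L
    if (val >= threshold) terminated <- TRUE
  }
  structure(list(points = pts, objective_values = vals,
                 terminated = terminated, stationary = stationary,
                 termination_value = threshold,
                 endpoint = c(me = unname(pt[1]), z = unname(pt[2])),
                 n_steps = steps, flagged = steps >= max_steps),
            class = "gradient_trajectory")
}

#' Classify a trajectory endpoint as adaptive or non-adaptive per bias
#'
#' A bias is adaptive when directed toward the large-reward choice of the
#' context: in LR-Left, `me < 0` and `z < 0.5` are adaptive; in LR-Right,
#' `me > 0` and `z > 0.5`.  Endpoints exactly on a boundary are tie-broken
#' to adaptive and flagged.
#'
#' @param trajectory A `gradient_trajectory` (terminated).
#' @param context `"LR-Left"` or `"LR-Right"`.
#' @return A list: `class` in `{me_adaptive_z_nonadaptive,
#'   z_adaptive_me_nonadaptive, both_adaptive, both_nonadaptive}`,
#'   `me_adaptive`, `z_adaptive`, `boundary` flag.
#' @export
classify_endpoint <- function(trajectory, context) {
  stopifnot(inherits(trajectory, "gradient_trajectory"),
            context %in% c("LR-Left", "LR-Right"))
  if (!trajectory$terminated) stop("trajectory did not terminate")
  ep <- trajectory$endpoint
  sgn <- if (context == "LR-Left") -1 else 1
  me_rel <- sgn * ep["me"]          # > 0 toward large reward
  z_rel <- sgn * (ep["z"] - 0.5)
  boundary <- me_rel == 0 || z_rel == 0
  me_ad <- me_rel >= 0              # ties -> adaptive
  z_ad <- z_rel >= 0
  cls <- if (me_ad && z_ad) "both_adaptive"
         else if (me_ad && !z_ad) "me_adaptive_z_nonadaptive"
         else if (!me_ad && z_ad) "z_adaptive_me_nonadaptive"
         else "both_nonadaptive"
  list(class = cls, me_adaptive = unname(me_ad), z_adaptive = unname(z_ad),
       boundary = unname(boundary))
}

#' Satisficing predictions of context bias differences
#'
#' For each session and reward context, runs the gradient ascent from the
#' chosen starting-point variant on that context's surface, terminating at
#' the context's predicted reward at the fitted point (the satisficing
#' level); predicted context deltas come from the two endpoints
#' (`LR-Right` minus `LR-Left`, as in [bias_summary()]), and the actual
#' deltas are regressed on the predicted ones across sessions.
#'
#' @param fits List of `session_fit` objects (full model), one per session.
#' @param surfaces List (one element per session) of named lists
#'   `list("LR-Left" = surface, "LR-Right" = surface)`.
#' @param variant Starting-point variant (see [starting_point()]).
#' @param max_coherence Highest unsigned coherence (for the `over_me`
#'   start); defaults to the max of the surfaces' coherence sets.
#' @param step_length Passed to [gradient_ascent()].
#' @return An object of class `satisficing_prediction`: per-session
#'   data.frame `deltas` (predicted and actual `delta_me`, `delta_z`) and
#'   `regression` (slopes of actual on predicted; NA with fewer than 3
#'   sessions).
#' @export
predict_deltas <- function(fits, surfaces, variant, max_coherence = NULL,
                           step_length = NULL) {
  stopifnot(length(fits) == length(surfaces), length(fits) >= 1)
  rows <- vector("list", length(fits))
  for (s in seq_along(fits)) {
    fit <- fits[[s]]
    surf <- surfaces[[s]]
    if (!all(c("LR-Left", "LR-Right") %in% names(surf)))
      stop("missing context surface for session ", s)
    base_me <- (fit$params_lrleft$me + fit$params_lrright$me) / 2
    base_z <- (fit$params_lrleft$z + fit$params_lrright$z) / 2
    ep <- list()
    for (cx in c("LR-Left", "LR-Right")) {
      p <- if (cx == "LR-Left") fit$params_lrleft else fit$params_lrright
      mc <- if (is.null(max_coherence))
        max(surf[[cx]]$econ$coherence_levels) else max_coherence
      st <- starting_point(variant, cx, mc, base_me, base_z)
      thr <- reward_summary(surf[[cx]], p$me, p$z)$predicted
      traj <- gradient_ascent(surf[[cx]], st, thr,
                              step_length = step_length)
      ep[[cx]] <- traj$endpoint
    }
    rows[[s]] <- data.frame(
      session = s,
      pred_delta_me = ep[["LR-Right"]]["me"] - ep[["LR-Left"]]["me"],
      pred_delta_z = ep[["LR-Right"]]["z"] - ep[["LR-Left"]]["z"],
      actual_delta_me = fit$params_lrright$me - fit$params_lrleft$me,
      actual_delta_z = fit$params_lrright$z - fit$params_lrleft$z,
      row.names = NULL)
  }
  deltas <- do.call(rbind, rows)
  reg <- c(me = NA_real_, z = NA_real_)
  if (nrow(deltas) >= 3) {
    if (sd(deltas$pred_delta_me) > 1e-12)
      reg["me"] <- coef(lm(actual_delta_me ~ pred_delta_me,
                           data = deltas))[2]
    if (sd(deltas$pred_delta_z) > 1e-12)
      reg["z"] <- coef(lm(actual_delta_z ~ pred_delta_z,
                          data = deltas))[2]
  }
  structure(list(variant = variant, deltas = deltas, regression = reg),
            class = "satisficing_prediction")
}

#' @export
print.satisficing_prediction <- function(x, ...) {
  cat(sprintf("Satisficing predictions [start variant: %s], %d session(s)\n",
              x$variant, nrow(x$deltas)))
  cat(sprintf("  mean predicted delta_me %+.3f, delta_z %+.3f\n",
              mean(x$deltas$pred_delta_me), mean(x$deltas$pred_delta_z)))
  cat(sprintf("  regression (actual ~ predicted): me %.3f, z %.3f\n",
              x$regression["me"], x$regression["z"]))
  invisible(x)
}
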