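# Expected-reward surfaces over the (me, z) bias plane for fixed non-bias
# DDM parameters and task economics, with optimality benchmarks: argmax,
# 97%-of-max contour, patch area and orientation, gradient field.

#' Task economics for reward-surface computation
#'
#' @param reward_large,reward_small Reward volumes,
#'   `reward_large >= reward_small > 0`.
#' @param iti Inter-trial interval (s).
#' @param timeout_error Error timeout (s), added to the inter-trial time on
#'   error trials.
#' @param coherence_levels Unsigned coherence set; the design is the full
#'   coherence-by-direction cross with equal weights.
#' @param context `"LR-Left"` (large reward for correct leftward choices) or
#'   `"LR-Right"`.
#' @return An object of class `task_economics`.
#' @export
task_economics <- function(reward_large, reward_small, iti = 2,
                           timeout_error = 3,
                           coherence_levels = c(0.032, 0.064, 0.128,
                                                0.256, 0.512),
                           context = c("LR-Left", "LR-Right")) {
  context <- match.arg(context)
  if (!(reward_large >= reward_small && reward_small > 0))
    stop("need reward_large >= reward_small > 0")
  if (iti < 0 || timeout_error < 0) stop("times must be >= 0")
  structure(list(reward_large = reward_large, reward_small = reward_small,
                 iti = iti, timeout_error = timeout_error,
                 coherence_levels = coherence_levels, context = context),
            class = "task_economics")
}

#' Grid specification for reward surfaces
#'
#' @param me_lim,z_lim Grid limits for the momentary-evidence bias (signed
#'   coherence units) and the relative start point.
#' @param n_me,n_z Number of grid nodes per axis (each `>= 21` recommended).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(me_lim = c(-0.6, 0.6), z_lim = c(0, 1),
                      n_me = 61, n_z = 51) {
  stopifnot(me_lim[1] < me_lim[2], z_lim[1] < z_lim[2],
            z_lim[1] >= 0, z_lim[2] <= 1, n_me >= 2, n_z >= 2)
  structure(list(me = seq(me_lim[1], me_lim[2], length.out = n_me),
                 z = seq(z_lim[1], z_lim[2], length.out = n_z)),
            class = "grid_spec")
}

# expected reward and trial time at a set of (me, z) nodes; analytic engine.
# Returns list(reward, time) matrices [n_me x n_z].
.surface_analytic <- function(a, k, t0, t1, econ, me, z) {
  zc <- pmin(pmax(z, 1e-3), 1 - 1e-3)  # interior evaluation at grid edges
  coh <- c(-econ$coherence_levels, econ$coherence_levels)
  large_side <- if (econ$context == "LR-Left") "left" else "right"
  rew_right <- ifelse(coh > 0,
                      ifelse(large_side == "right", econ$reward_large,
                             econ$reward_small), 0)
  rew_left <- ifelse(coh < 0,
                     ifelse(large_side == "left", econ$reward_large,
                            econ$reward_small), 0)
  nodes <- expand.grid(me = me, z = zc, KEEP.OUT.ATTRS = FALSE)
  R <- matrix(0, nrow(nodes), 1)
  Tm <- matrix(0, nrow(nodes), 1)
  for (ci in seq_along(coh)) {
    v <- k * (coh[ci] + nodes$me)
    p <- .p_upper(v, a, nodes$z)
    e <- .et_cond(v, a, nodes$z)
    rew <- p * rew_right[ci] + (1 - p) * rew_left[ci]
    p_err <- if (coh[ci] > 0) 1 - p else p
    rt <- p * (e$upper + t1) + (1 - p) * (e$lower + t0)
    R <- R + rew
    Tm <- Tm + rt + econ$iti + p_err * econ$timeout_error
  }
  list(reward = matrix(R / length(coh), length(me), length(z)),
       time = matrix(Tm / length(coh), length(me), length(z)))
}

.surface_mc <- function(a, k, t0, t1, econ, me, z, n_mc, dt, seed) {
  set.seed(seed)
  zc <- pmin(pmax(z, 1e-3), 1 - 1e-3)
  coh <- c(-econ$coherence_levels, econ$coherence_levels)
  large_side <- if (econ$context == "LR-Left") "left" else "right"
  R <- matrix(0, length(me), length(z))
  Tm <- matrix(0, length(me), length(z))
  for (i in seq_along(me)) for (j in seq_along(z)) {
    rtot <- 0; ttot <- 0
    for (ci in seq_along(coh)) {
      sim <- ddm_simulate_cpp(n_mc, k * (coh[ci] + me[i]), a, zc[j], dt,
                              30, TRUE)
      ch <- ifelse(sim$choice == 1L, "right", "left")
      corr <- (coh[ci] > 0) == (sim$choice == 1L)
      rew <- ifelse(corr, ifelse(ch == large_side, econ$reward_large,
                                 econ$reward_small), 0)
      rt <- sim$tdec + ifelse(sim$choice == 1L, t1, t0)
      rtot <- rtot + mean(rew)
      ttot <- ttot + mean(rt) + econ$iti + mean(!corr) * econ$timeout_error
    }
    R[i, j] <- rtot / length(coh)
    Tm[i, j] <- ttot / length(coh)
  }
  list(reward = R, time = Tm)
}

#' Compute a reward surface over the (me, z) plane
#'
#' At each grid node the bias parameters are set to the node's `(me, z)` and
#' expected accuracy and decision times are computed per signed coherence
#' (analytically, or by Monte-Carlo to mirror the simulation-based
#' procedure).  `RTrial` is the expected reward per trial averaged over the
#' equal-weight coherence-by-direction design; `RR` divides total expected
#' reward by total expected time, where each trial costs its mean RT plus
#' the inter-trial interval plus the error probability times the timeout.
#'
#' @param params A [ddm_params()]; its `me` and `z` fields are ignored
#'   (replaced by the grid node).
#' @param econ A [task_economics()].
#' @param grid A [grid_spec()].
#' @param objective `"RTrial"` (volume per trial) or `"RR"` (volume per s).
#' @param method `"analytic"` (exact, default) or `"mc"`.
#' @param n_mc Monte-Carlo trials per coherence-by-direction cell per node.
#' @param dt,seed Monte-Carlo step and seed.
#' @return An object of class `reward_surface`: `me`, `z` grids and a
#'   `values` matrix (`length(me)` rows by `length(z)` columns).
#' @export
compute_surface <- function(params, econ, grid = grid_spec(),
                            objective = c("RTrial", "RR"),
                            method = c("analytic", "mc"), n_mc = 1000,
                            dt = 1e-3, seed = 1) {
  stopifnot(inherits(params, "ddm_params"), inherits(econ, "task_economics"),
            inherits(grid, "grid_spec"))
  objective <- match.arg(objective)
  method <- match.arg(method)
  s <- if (method == "analytic")
    .surface_analytic(params$a, params$k, params$t0, params$t1, econ,
                      grid$me, grid$z)
  else
    .surface_mc(params$a, params$k, params$t0, params$t1, econ,
                grid$me, grid$z, n_mc, dt, seed)
  values <- if (objective == "RTrial") s$reward else {
    if (all(s$time <= 0)) stop("reward rate undefined: all-zero trial times")
    s$reward / s$time
  }
  structure(list(me = grid$me, z = grid$z, values = values,
                 objective = objective, method = method, econ = econ,
                 params = params),
            class = "reward_surface")
}

#' @export
print.reward_surface <- function(x, ...) {
  f <- surface_features(x)
  cat(sprintf("Reward surface [%s, %s] %dx%d grid\n", x$objective,
              x$method, length(x$me), length(x$z)))
  cat(sprintf("  max %.4f at me* = %+.3f, z* = %.3f\n",
              f$max_value, f$argmax[1], f$argmax[2]))
  invisible(x)
}

#' Bilinear interpolation of a reward surface
#'
#' @param surface A `reward_surface`.
#' @param me,z Query point(s); clipped to the grid with a warning if
#'   outside.
#' @return Interpolated surface value(s).
#' @export
interp_surface <- function(surface, me, z) {
  n <- max(length(me), length(z))
  me <- rep_len(me, n); z <- rep_len(z, n)
  if (any(me < min(surface$me) | me > max(surface$me) |
          z < min(surface$z) | z > max(surface$z)))
    warning("query point outside grid; clipped")
  me <- pmin(pmax(me, min(surface$me)), max(surface$me))
  z <- pmin(pmax(z, min(surface$z)), max(surface$z))
  gi <- findInterval(me, surface$me, rightmost.closed = TRUE)
  gj <- findInterval(z, surface$z, rightmost.closed = TRUE)
  gi <- pmin(pmax(gi, 1L), length(surface$me) - 1L)
  gj <- pmin(pmax(gj, 1L), length(surface$z) - 1L)
  x1 <- surface$me[gi]; x2 <- surface$me[gi + 1L]
  y1 <- surface$z[gj]; y2 <- surface$z[gj + 1L]
  tx <- (me - x1) / (x2 - x1); ty <- (z - y1) / (y2 - y1)
  v11 <- surface$values[cbind(gi, gj)]
  v21 <- surface$values[cbind(gi + 1L, gj)]
  v12 <- surface$values[cbind(gi, gj + 1L)]
  v22 <- surface$values[cbind(gi + 1L, gj + 1L)]
  (1 - tx) * (1 - ty) * v11 + tx * (1 - ty) * v21 +
    (1 - tx) * ty * v12 + tx * ty * v22
}

# central finite-difference gradient field; one-sided at the edges
.surface_gradient <- function(surface) {
  v <- surface$values
  dme <- matrix(0, nrow(v), ncol(v)); dz <- dme
  nm <- nrow(v); nz <- ncol(v)
  hm <- diff(surface$me[1:2]); hz <- diff(surface$z[1:2])
  dme[2:(nm - 1), ] <- (v[3:nm, ] - v[1:(nm - 2), ]) / (2 * hm)
  dme[1, ] <- (v[2, ] - v[1, ]) / hm
  dme[nm, ] <- (v[nm, ] - v[nm - 1, ]) / hm
  dz[, 2:(nz - 1)] <- (v[, 3:nz] - v[, 1:(nz - 2)]) / (2 * hz)
  dz[, 1] <- (v[, 2] - v[, 1]) / hz
  dz[, nz] <- (v[, nz] - v[, nz - 1]) / hz
  list(dme = dme, dz = dz)
}

#' Derived features of a reward surface
#'
#' Locates the grid argmax, the set of nodes at or above `level` (default
#' 97%) of the maximum ("patch"), its area in grid-node units, its
#' orientation, and the finite-difference gradient field.  Orientation is
#' the angle (degrees) between the patch's principal axis and the vertical
#' (z) axis, measured in grid-index units to mirror pixel-based measurement;
#' positive angles mean the patch top tilts toward positive `me`.
#'
#' @param surface A `reward_surface`.
#' @param level Contour level as a fraction of the maximum.
#' @return An object of class `surface_features`: `argmax` (me*, z*),
#'   `max_value`, `contour_mask`, `patch_area`, `orientation`, `isotropic`
#'   flag and `gradient` (`dme`, `dz` matrices).
#' @export
surface_features <- function(surface, level = 0.97) {
  stopifnot(inherits(surface, "reward_surface"))
  v <- surface$values
  mx <- max(v)
  if (mx <= 0) stop("degenerate surface: maximum is not positive")
  am <- which(v == mx, arr.ind = TRUE)[1, ]
  mask <- v >= level * mx
  idx <- which(mask, arr.ind = TRUE)
  # principal axis of the patch in grid-index coordinates
  orientation <- 0; isotropic <- FALSE
  if (nrow(idx) > 2) {
    xy <- scale(idx, scale = FALSE)
    cv <- crossprod(xy) / nrow(xy)
    eg <- eigen(cv, symmetric = TRUE)
    if (eg$values[1] < 1e-12 || eg$values[2] / eg$values[1] > 0.95) {
      isotropic <- TRUE
    } else {
      ax <- eg$vectors[, 1]  # (row = me index, col = z index)
      ang <- atan2(ax[1], ax[2]) * 180 / pi
      if (ang > 90) ang <- ang - 180
      if (ang <= -90) ang <- ang + 180
      orientation <- ang
    }
  } else isotropic <- TRUE
  structure(list(argmax = c(me = surface$me[am[1]], z = surface$z[am[2]]),
                 max_value = mx, contour_mask = mask,
                 patch_area = sum(mask), orientation = orientation,
                 isotropic = isotropic,
                 gradient = .surface_gradient(surface), level = level),
            class = "surface_features")
}

#' Predicted and maximal reward for a fitted session
#'
#' Interpolates the surface at the fitted `(me, z)` and reports the ratio to
#' the surface maximum (the predicted-to-max reward ratio, at most 1).
#'
#' @param surface A `reward_surface`.
#' @param fitted_me,fitted_z Fitted bias parameters.
#' @return An object of class `reward_summary`: `predicted`, `max_value`,
#'   `ratio_predicted_to_max`.
#' @export
reward_summary <- function(surface, fitted_me, fitted_z) {
  mx <- max(surface$values)
  pred <- interp_surface(surface, fitted_me, fitted_z)
  structure(list(predicted = pred, max_value = mx,
                 ratio_predicted_to_max = pred / mx),
            class = "reward_summary")
}

#' Conditionally optimal bias along one surface slice
#'
#' Given a fixed value of one bias parameter, finds the value of the other
#' that maximises the surface along that slice, together with the interval
#' of values reaching at least `level` of the slice maximum.
#'
#' @param surface A `reward_surface`.
#' @param fixed_me,fixed_z Exactly one must be given.
#' @param level Band level as a fraction of the slice maximum.
#' @return A list: `optimum` (the conditionally optimal me or z),
#'   `band` (range attaining `level` of the slice max), `slice_max`.
#' @export
conditional_optima <- function(surface, fixed_me = NULL, fixed_z = NULL,
                               level = 0.97) {
  if (is.null(fixed_me) == is.null(fixed_z))
    stop("give exactly one of 'fixed_me' or 'fixed_z'")
  if (!is.null(fixed_z)) {
    grid <- surface$me
    vals <- interp_surface(surface, grid, rep(fixed_z, length(grid)))
  } else {
    grid <- surface$z
    vals <- interp_surface(surface, rep(fixed_me, length(grid)), grid)
  }
  mx <- max(vals)
  band <- range(grid[vals >= level * mx])
  list(optimum = grid[which.max(vals)], band = band, slice_max = mx)
}
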