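#' Biased drift-diffusion model parameters
#'
#' Bundle the six decision parameters of the reward-biased DDM for one reward
#' context.  The accumulator starts at `a * z`, drifts at rate
#' `k * (coherence + me)` with unit-variance diffusion noise, and terminates
#' at bounds 0 (leftward choice) or `a` (rightward choice).  Response time is
#' decision time plus the choice-specific non-decision time (`t0` left, `t1`
#' right).
#'
#' @param a Total bound height (evidence units), `> 0`.
#' @param k Drift scaling factor (evidence units per second per unit
#'   coherence), `> 0`.
#' @param t0,t1 Non-decision times (s) for leftward / rightward choices.
#' @param z Relative start point in (0, 1); values above 0.5 favour rightward
#'   choices.
#' @param me Momentary-evidence bias in signed-coherence units; positive
#'   favours rightward choices.
#'
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(a = 1.77, k = 6.58, t0 = 0.33, t1 = 0.35, z = 0.62, me = -0.14)
#' @export
ddm_params <- function(a, k, t0, t1, z = 0.5, me = 0) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(z), length(z) == 1L, is.finite(z),
            is.numeric(me), length(me) == 1L, is.finite(me),
            is.numeric(t0), length(t0) == 1L, is.finite(t0),
            is.numeric(t1), length(t1) == 1L, is.finite(t1))
  if (a <= 0) stop("'a' must be > 0")
  if (k <= 0) stop("'k' must be > 0")
  if (z <= 0 || z >= 1) stop("'z' must lie strictly between 0 and 1")
  if (t0 < 0 || t1 < 0) stop("non-decision times must be >= 0")
  structure(list(a = a, k = k, t0 = t0, t1 = t1, z = z, me = me),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Biased DDM parameters\n")
  cat(sprintf("  a = %.3f  k = %.3f  t0 = %.3f s  t1 = %.3f s\n",
              x$a, x$k, x$t0, x$t1))
  cat(sprintf("  z = %.3f  me = %+.3f\n", x$z, x$me))
  invisible(x)
}

#' Collapsing-bound specification
#'
#' Time-varying bound geometry in which the distance between the two choice
#' bounds shrinks as `a / (1 + exp(beta * t - d))`.  Both bounds collapse
#' symmetrically toward the midpoint of the initial interval; the start point
#' `a * z` is held fixed.
#'
#' @param beta Collapse rate (1/s); `beta = 0` gives a constant effective
#'   bound distance `a / (1 + exp(-d))`.
#' @param d Collapse onset parameter (dimensionless).
#' @return An object of class `collapsing_bound`.
#' @export
collapsing_bound <- function(beta, d) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(d), length(d) == 1L, is.finite(d))
  structure(list(beta = beta, d = d), class = "collapsing_bound")
}
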