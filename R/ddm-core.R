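# Analytic first-passage results for the biased DDM (unit-variance noise,
# bounds 0 and a, start a*z) plus Monte-Carlo simulation wrappers.

# coth with series fallback near 0
.coth <- function(y) ifelse(abs(y) < 1e-4, 1 / y + y / 3, 1 / tanh(y))

#' Drift rate of the biased DDM
#'
#' The effective evidence is the signed coherence plus the momentary-evidence
#' bias, scaled by `k`: drift `= k * (coherence + me)`.  The diffusion noise
#' has unit variance per second by convention, so all parameters are on that
#' scale.
#'
#' @param params A [ddm_params()] object.
#' @param signed_coherence Signed motion coherence (negative = leftward),
#'   vectorised.
#' @return Drift rate(s) in evidence units per second.
#' @examples
#' drift_rate(ddm_params(1.77, 6.58, 0.33, 0.35, me = -0.14), 0.512)
#' @export
drift_rate <- function(params, signed_coherence) {
  stopifnot(inherits(params, "ddm_params"))
  params$k * (signed_coherence + params$me)
}

# stable P(absorb at upper bound) for drift v, bound a, relative start z;
# vectorised over v
.p_upper <- function(v, a, z) {
  c2 <- 2 * v * a
  p <- ifelse(abs(c2) < 1e-6,
              z + c2 * z * (1 - z) / 2,
              ifelse(c2 > 0,
                     expm1(-c2 * z) / expm1(-c2),
                     # reflect for numerical stability at large negative drift
                     1 - expm1(c2 * (1 - z)) / expm1(c2)))
  pmin(pmax(p, 0), 1)
}

#' Probability of a rightward (upper-bound) choice
#'
#' Analytic first-passage probability of the biased DDM.  In the zero-drift
#' limit (coherence exactly cancelling `me`) the probability equals `z`.
#'
#' @inheritParams drift_rate
#' @return Probability in (0, 1), vectorised over `signed_coherence`.
#' @export
choice_probability <- function(params, signed_coherence) {
  v <- drift_rate(params, signed_coherence)
  .p_upper(v, params$a, params$z)
}

# conditional mean decision times, vectorised over v
.et_cond <- function(v, a, z) {
  x0 <- a * z
  small <- abs(a * v) < 1e-3
  e_up <- ifelse(small,
                 (a^2 - x0^2) / 3 - v^2 * (a^4 - x0^4) / 45,
                 (a / v) * .coth(a * v) - (x0 / v) * .coth(x0 * v))
  x1 <- a - x0
  e_lo <- ifelse(small,
                 (a^2 - x1^2) / 3 - v^2 * (a^4 - x1^4) / 45,
                 (a / v) * .coth(a * v) - (x1 / v) * .coth(x1 * v))
  list(upper = e_up, lower = e_lo)
}

#' Mean decision time of the biased DDM
#'
#' Expected first-passage (decision) time, both unconditioned and conditioned
#' on each bound.  Non-decision times are not included.  In the zero-drift
#' limit with `z = 0.5` the unconditional mean is `(a/2)^2` (unit-variance
#' diffusion between bounds 0 and `a`).
#'
#' @inheritParams drift_rate
#' @return A data.frame with columns `mean`, `upper` (rightward) and `lower`
#'   (leftward) conditional mean decision times in seconds.
#' @export
mean_decision_time <- function(params, signed_coherence) {
  v <- drift_rate(params, signed_coherence)
  a <- params$a
  x0 <- a * params$z
  p <- .p_upper(v, a, params$z)
  e <- .et_cond(v, a, params$z)
  m <- ifelse(abs(v) < 1e-6, x0 * (a - x0), (a * p - x0) / v)
  data.frame(mean = m, upper = e$upper, lower = e$lower)
}

#' Log first-passage density of (choice, RT)
#'
#' Log density of observing a given choice at a given response time under the
#' biased DDM, using small/large-time series expansions of the Wiener
#' first-passage density with automatic switching (truncation tolerance
#' `tol`).  The response time includes the choice-specific non-decision time;
#' observations at or below it are impossible and return `-Inf`.
#'
#' @inheritParams drift_rate
#' @param choice `"left"` or `"right"` (vectorised, recycled against `rt`).
#' @param rt Response time(s) in seconds.
#' @param tol Series truncation tolerance.
#' @return Log densities, same length as `rt`.
#' @export
fpt_log_density <- function(params, signed_coherence, choice, rt,
                            tol = 1e-7) {
  stopifnot(inherits(params, "ddm_params"))
  n <- max(length(rt), length(choice), length(signed_coherence))
  rt <- rep_len(rt, n)
  choice <- rep_len(choice, n)
  coh <- rep_len(signed_coherence, n)
  if (!all(choice %in% c("left", "right")))
    stop("'choice' must be 'left' or 'right'")
  right <- as.integer(choice == "right")
  td <- rt - ifelse(right == 1L, params$t1, params$t0)
  v <- params$k * (coh + params$me)
  out <- rep(-Inf, n)
  ok <- td > 0
  if (any(ok)) {
    out[ok] <- wfpt_log_density_cpp(td[ok], right[ok], v[ok],
                                    params$a, params$z, tol)
  }
  out
}

#' Simulate trials from the biased DDM
#'
#' Euler–Maruyama simulation of the accumulation process (step
#' `drift * dt + sqrt(dt) * N(0, 1)`), with an optional Brownian-bridge
#' within-step crossing test (`bridge = TRUE`, the default) that removes the
#' `O(sqrt(dt))` boundary bias of the plain scheme so that simulated choice
#' frequencies and decision times are unbiased estimates of the analytic
#' values.  Walks that have not terminated by `max_t` are flagged censored.
#'
#' @inheritParams drift_rate
#' @param n Number of trials.
#' @param dt Time step (s); default 0.5 ms.
#' @param max_t Censoring horizon (s).
#' @param bridge Apply the Brownian-bridge crossing correction.
#' @return A data.frame with columns `choice` (`"left"`/`"right"`), `rt`
#'   (decision time plus the choice-specific non-decision time, s) and
#'   `censored`.  Uses the R random number stream (`set.seed()` applies).
#' @export
simulate_trials <- function(params, signed_coherence, n, dt = 5e-4,
                            max_t = 30, bridge = TRUE) {
  stopifnot(inherits(params, "ddm_params"), n >= 1, dt > 0, max_t > dt)
  stopifnot(length(signed_coherence) == 1L)
  v <- drift_rate(params, signed_coherence)
  sim <- ddm_simulate_cpp(as.integer(n), v, params$a, params$z, dt, max_t,
                          bridge)
  ch <- ifelse(sim$choice == 1L, "right", "left")
  data.frame(choice = ch,
             rt = sim$tdec + ifelse(sim$choice == 1L, params$t1, params$t0),
             censored = sim$censored)
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(params, signed_coherence, dt = 5e-4, max_t = 30,
                           bridge = TRUE) {
  simulate_trials(params, signed_coherence, 1L, dt, max_t, bridge)
}

#' Simulate trials from the collapsing-bound DDM
#'
#' As [simulate_trials()], but the distance between the two bounds decreases
#' with time as `a / (1 + exp(beta * t - d))`, both bounds collapsing
#' symmetrically toward the midpoint of the initial interval while the start
#' point `a * z` stays fixed.  With `beta = 0` the process is
#' (distributionally) a fixed-bound DDM with effective bound distance
#' `a / (1 + exp(-d))`.
#'
#' @inheritParams simulate_trials
#' @param collapse A [collapsing_bound()] object.
#' @return As [simulate_trials()].
#' @export
simulate_trials_collapsing <- function(params, collapse, signed_coherence,
                                       n, dt = 5e-4, max_t = 30) {
  stopifnot(inherits(params, "ddm_params"),
            inherits(collapse, "collapsing_bound"),
            n >= 1, dt > 0, length(signed_coherence) == 1L)
  v <- drift_rate(params, signed_coherence)
  sim <- ddm_simulate_collapse_cpp(as.integer(n), v, params$a, params$z,
                                   collapse$beta, collapse$d, dt, max_t)
  ch <- ifelse(sim$choice == 1L, "right", "left")
  data.frame(choice = ch,
             rt = sim$tdec + ifelse(sim$choice == 1L, params$t1, params$t0),
             censored = sim$censored)
}
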