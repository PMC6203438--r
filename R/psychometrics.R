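# Logistic characterisation of choice behaviour: lapse-bounded psychometric
# function with context-specific bias and sensitivity, a sequential-bias
# extension, and the optimal context-difference-in-bias benchmark.

#' Lapse-bounded logistic psychometric function
#'
#' `P(rightward) = lambda + (1 - 2*lambda) / (1 + exp(-sens * (coh - bias)))`.
#'
#' @param coh Signed coherence (vectorised).
#' @param lambda Lapse rate in `[0, 0.5)`.
#' @param bias Bias (coherence at which performance is at chance).
#' @param sens Sensitivity (1/coherence), `> 0`.
#' @return Probability of a rightward choice.
#' @export
logistic_psychometric <- function(coh, lambda, bias, sens) {
  lambda + (1 - 2 * lambda) * plogis(sens * (coh - bias))
}

.psy_prepare <- function(trials) {
  stopifnot(is.data.frame(trials))
  t <- trials[!trials$excluded, , drop = FALSE]
  if (!all(t$context %in% c("LR-Left", "LR-Right")))
    stop("unknown context label in trials")
  if (length(unique(t$context)) < 2L)
    stop("both reward contexts must be present")
  if (length(unique(t$choice)) < 2L)
    stop("degenerate fit: all trials share one choice")
  t$right <- as.integer(t$choice == "right")
  t$is_left_ctx <- as.integer(t$context == "LR-Left")
  t
}

# theta = (lambda, alpha0, alpha_rew, beta0, beta_rew); bias_seq optional
.psy_nll <- function(theta, t, seq_term = NULL) {
  lambda <- theta[1]
  bias <- theta[2] + theta[3] * t$is_left_ctx
  sens <- theta[4] + theta[5] * t$is_left_ctx
  if (any(sens <= 0.05)) return(1e10)
  if (!is.null(seq_term)) bias <- bias + theta[6] * seq_term
  p <- logistic_psychometric(t$signed_coherence, lambda, bias, sens)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(ifelse(t$right == 1L, log(p), log1p(-p)))
}

.psy_starts <- function(t, n_starts) {
  # moment-based start from a plain logistic GLM, plus jittered copies
  g <- try(suppressWarnings(glm(right ~ signed_coherence * is_left_ctx,
                                data = t, family = binomial())),
           silent = TRUE)
  if (!inherits(g, "try-error") && all(is.finite(coef(g)))) {
    cf <- coef(g)
    b0 <- max(cf[["signed_coherence"]], 0.5)
    b1 <- cf[["signed_coherence"]] +
      ifelse(is.na(cf[["signed_coherence:is_left_ctx"]]), 0,
             cf[["signed_coherence:is_left_ctx"]])
    b1 <- max(b1, 0.5)
    a0 <- -cf[["(Intercept)"]] / b0
    a1 <- -(cf[["(Intercept)"]] +
              ifelse(is.na(cf[["is_left_ctx"]]), 0, cf[["is_left_ctx"]])) / b1
    start <- c(0.01, a0, a1 - a0, b0, b1 - b0)
  } else {
    start <- c(0.01, 0, 0, 10, 0)
  }
  starts <- list(start)
  for (i in seq_len(n_starts - 1L)) {
    starts[[i + 1L]] <- start * runif(5, 0.7, 1.3) + c(0, runif(2, -0.05,
                                                                0.05), 0, 0)
  }
  starts
}

.psy_optim <- function(t, n_starts, seq_term = NULL, seed = 1,
                       extra_starts = list()) {
  set.seed(seed)
  npar <- if (is.null(seq_term)) 5L else 6L
  lower <- c(0, -0.9, -1.8, 0.1, -199)
  upper <- c(0.45, 0.9, 1.8, 200, 199)
  if (npar == 6L) { lower <- c(lower, -0.9); upper <- c(upper, 0.9) }
  best <- NULL
  for (s in c(extra_starts, .psy_starts(t, n_starts))) {
    if (length(s) < npar) s <- c(s, rep(0, npar - length(s)))
    s <- pmin(pmax(s, lower + 1e-6), upper - 1e-6)
    fit <- try(optim(s, .psy_nll, t = t, seq_term = seq_term,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("degenerate fit: psychometric optimisation failed")
  best
}

#' Fit the context-dependent logistic psychometric function
#'
#' Maximum-likelihood fit of the lapse-bounded logistic to all non-excluded
#' trials, with one shared lapse and context-specific bias and sensitivity:
#' bias is `alpha0` in LR-Right and `alpha0 + alpha_rew` in LR-Left,
#' sensitivity `beta0` and `beta0 + beta_rew` likewise.  Multi-start
#' (default 5) bounded optimisation with the lapse constrained to
#' `[0, 0.45]`.
#'
#' @param trials A trial data.frame (see [generate_session()]).
#' @param n_starts Number of optimisation starts.
#' @return An object of class `psychometric_fit` with elements `lapse`,
#'   `bias_lrright`, `bias_delta`, `sens_lrright`, `sens_delta`, `loglik`,
#'   `n`.
#' @export
fit_logistic <- function(trials, n_starts = 5) {
  t <- .psy_prepare(trials)
  best <- .psy_optim(t, n_starts)
  th <- best$par
  structure(list(lapse = th[1], bias_lrright = th[2], bias_delta = th[3],
                 sens_lrright = th[4], sens_delta = th[5],
                 loglik = -best$value, n = nrow(t)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit (logistic with lapse)\n")
  cat(sprintf("  lapse          %.4f\n", x$lapse))
  cat(sprintf("  bias  LR-Right %+.4f   LR-Left %+.4f\n",
              x$bias_lrright, x$bias_lrright + x$bias_delta))
  cat(sprintf("  sens  LR-Right %.2f    LR-Left %.2f\n",
              x$sens_lrright, x$sens_lrright + x$sens_delta))
  cat(sprintf("  loglik %.2f on %d trials\n", x$loglik, x$n))
  invisible(x)
}

.SEQ_TYPES <- c("prevLR-prevCorrect", "prevLR-prevError",
                "prevSR-prevCorrect", "prevSR-prevError")

# indicator of the sequential event on the PREVIOUS trial, aligned to the
# current trial; first trial of the session gets 0
.seq_indicator <- function(t, effect_type) {
  prev_choice <- c(NA, head(t$choice, -1))
  prev_correct <- c(NA, head(t$correct, -1))
  prev_ctx <- c(NA, head(t$context, -1))
  prev_large_side <- ifelse(prev_ctx == "LR-Left", "left", "right")
  to_lr <- prev_choice == prev_large_side
  ind <- switch(effect_type,
                "prevLR-prevCorrect" = to_lr & prev_correct,
                "prevLR-prevError"   = to_lr & !prev_correct,
                "prevSR-prevCorrect" = !to_lr & prev_correct,
                "prevSR-prevError"   = !to_lr & !prev_correct,
                stop("unknown effect type"))
  ind[is.na(ind)] <- FALSE
  as.integer(ind)
}

#' Fit the sequential-bias extension of the psychometric function
#'
#' Adds a sequential bias `I_seq * I_rew * alpha_seq` to the bias term,
#' where `I_seq` indicates the previous-trial event (previous choice to the
#' large- or small-reward target, previous trial correct or error) and
#' `I_rew = +1/-1` for the LR-Right/LR-Left context of the current trial.
#' `alpha_seq = 0` is tested against the base model with a 1-df
#' likelihood-ratio test.
#'
#' @inheritParams fit_logistic
#' @param effect_types Character vector of sequential-effect types to fit
#'   (default all four).
#' @param min_trials Minimum qualifying trials; below it the effect is
#'   flagged `insufficient_data` and not fitted.
#' @return A list of `sequential_fit` objects (one per effect type), each
#'   with the base fit, `alpha_seq`, `loglik` and `lr_test_p`.
#' @export
fit_sequential <- function(trials, effect_types = .SEQ_TYPES,
                           n_starts = 5, min_trials = 10) {
  t <- .psy_prepare(trials)
  base <- fit_logistic(trials, n_starts)
  i_rew <- ifelse(t$context == "LR-Right", 1, -1)
  out <- list()
  for (et in effect_types) {
    i_seq <- .seq_indicator(t, et)
    if (sum(i_seq) < min_trials) {
      out[[et]] <- structure(list(base = base, effect_type = et,
                                  alpha_seq = NA_real_, loglik = NA_real_,
                                  lr_test_p = NA_real_,
                                  insufficient_data = TRUE,
                                  n_qualifying = sum(i_seq)),
                             class = "sequential_fit")
      next
    }
    base_par <- c(base$lapse, base$bias_lrright, base$bias_delta,
                  base$sens_lrright, base$sens_delta)
    # warm-start at the base optimum (alpha_seq = 0) so the LR statistic
    # cannot be inflated by optimiser noise in the nested fit
    fit <- .psy_optim(t, n_starts, seq_term = i_seq * i_rew,
                      extra_starts = list(base_par))
    ll <- -fit$value
    lr <- max(0, 2 * (ll - base$loglik))
    out[[et]] <- structure(list(base = base, effect_type = et,
                                alpha_seq = fit$par[6], loglik = ll,
                                lr_test_p = pchisq(lr, df = 1,
                                                   lower.tail = FALSE),
                                insufficient_data = FALSE,
                                n_qualifying = sum(i_seq)),
                           class = "sequential_fit")
  }
  out
}

#' Optimal difference in psychometric bias between reward contexts
#'
#' Finds the difference in horizontal shift between the two contexts'
#' psychometric curves that would maximise expected reward per trial, given
#' the fitted sensitivities and lapse, the session's coherence set and the
#' reward ratio.  The shift is decomposed as equal-and-opposite offsets of
#' the two context curves; positive values bias each context toward its
#' large-reward side.
#'
#' @param fit A `psychometric_fit`.
#' @param reward_ratio Large:small reward ratio (`>= 1` typical).
#' @param coherence_levels Unsigned coherence set of the session.
#' @param delta_lim Search interval for the bias difference.
#' @return The optimal bias difference (coherence units; positive =
#'   adaptive, i.e. LR-Left curve shifted right and LR-Right curve left).
#' @export
optimal_delta_bias <- function(fit, reward_ratio, coherence_levels,
                               delta_lim = c(-0.6, 0.6)) {
  stopifnot(inherits(fit, "psychometric_fit"), reward_ratio > 0)
  sens_r <- fit$sens_lrright
  sens_l <- fit$sens_lrright + fit$sens_delta
  stopifnot(sens_r > 0, sens_l > 0)
  lam <- fit$lapse
  coh <- c(-coherence_levels, coherence_levels)
  expected_reward <- function(delta) {
    # LR-Left curve shifted by +delta/2 (more leftward choices), LR-Right
    # by -delta/2; large reward = reward_ratio, small = 1
    rew_ctx <- function(bias, sens, large_side) {
      p_right <- logistic_psychometric(coh, lam, bias, sens)
      p_corr <- ifelse(coh > 0, p_right, 1 - p_right)
      rew <- ifelse((coh < 0) == (large_side == "left"), reward_ratio, 1)
      mean(p_corr * rew)
    }
    (rew_ctx(delta / 2, sens_l, "left") +
       rew_ctx(-delta / 2, sens_r, "right")) / 2
  }
  opt <- optimize(expected_reward, interval = delta_lim, maximum = TRUE,
                  tol = 1e-6)
  opt$maximum
}
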