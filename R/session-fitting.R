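# Per-session maximum-likelihood fitting of the biased DDM (full, me-only,
# z-only; fixed or collapsing bounds) and simulate-and-refit model
# comparison.  Each reward context gets its own parameter set.

.FIT_BOUNDS <- list(a = c(0.3, 5), k = c(0.5, 40), t = c(0.02, 0.6),
                    z = c(0.05, 0.95), me = c(-0.6, 0.6))

# free-parameter layout per model variant
.variant_layout <- function(variant) {
  switch(variant,
         full    = c("a", "k", "t0", "t1", "z", "me"),
         me_only = c("a", "k", "t0", "t1", "me"),
         z_only  = c("a", "k", "t0", "t1", "z"),
         stop("unknown variant: ", variant))
}

.theta_to_params <- function(theta, variant) {
  nm <- .variant_layout(variant)
  p <- as.list(setNames(theta, nm))
  if (is.null(p$z)) p$z <- 0.5
  if (is.null(p$me)) p$me <- 0
  p
}

.context_nll <- function(theta, variant, rt, right, coh, tol = 1e-6) {
  p <- .theta_to_params(theta, variant)
  nll <- ddm_negloglik_cpp(rt, right, coh, p$a, p$k, p$t0, p$t1, p$z, p$me,
                           tol)
  if (!is.finite(nll)) 1e10 else nll  # L-BFGS-B needs finite values
}

# crude moment-based start: non-decision near the fastest RTs, k from
# accuracy at the highest coherence, a from mean decision time
.heuristic_start <- function(rt, right, coh, variant) {
  tnd <- max(.FIT_BOUNDS$t[1], min(0.9 * min(rt), .FIT_BOUNDS$t[2] - 0.01))
  maxc <- max(abs(coh))
  hi <- abs(coh) == maxc
  acc <- mean((coh[hi] > 0) == (right[hi] == 1L))
  acc <- min(max(acc, 0.55), 0.99)
  a0 <- 1.5
  k0 <- min(max(qlogis(acc) / (a0 * maxc) * 2, 1), 30)
  mdt <- max(mean(rt) - tnd, 0.05)
  a0 <- min(max(2 * sqrt(mdt), .FIT_BOUNDS$a[1] + 0.05), .FIT_BOUNDS$a[2] - 0.1)
  full <- c(a = a0, k = k0, t0 = tnd, t1 = tnd, z = 0.5, me = 0)
  full[.variant_layout(variant)]
}

.lhs_starts <- function(n, variant) {
  nm <- .variant_layout(variant)
  lo <- vapply(nm, function(x) switch(x, a = .FIT_BOUNDS$a[1],
                                      k = .FIT_BOUNDS$k[1],
                                      t0 = , t1 = .FIT_BOUNDS$t[1],
                                      z = 0.3, me = -0.3), 0)
  hi <- vapply(nm, function(x) switch(x, a = 3, k = 20,
                                      t0 = , t1 = 0.45,
                                      z = 0.7, me = 0.3), 0)
  # Latin-hypercube: stratified uniform draws, one stratum per start
  lapply(seq_len(n), function(i) {
    u <- (sample(n)[seq_along(nm)] - runif(length(nm))) / n
    setNames(lo + u * (hi - lo), nm)
  })
}

.fit_context <- function(rt, right, coh, variant, n_starts, seed) {
  set.seed(seed)
  nm <- .variant_layout(variant)
  lower <- vapply(nm, function(x) switch(x, a = .FIT_BOUNDS$a[1],
                                         k = .FIT_BOUNDS$k[1],
                                         t0 = , t1 = .FIT_BOUNDS$t[1],
                                         z = .FIT_BOUNDS$z[1],
                                         me = .FIT_BOUNDS$me[1]), 0)
  upper <- vapply(nm, function(x) switch(x, a = .FIT_BOUNDS$a[2],
                                         k = .FIT_BOUNDS$k[2],
                                         t0 = , t1 = .FIT_BOUNDS$t[2],
                                         z = .FIT_BOUNDS$z[2],
                                         me = .FIT_BOUNDS$me[2]), 0)
  # RTs at or below the smallest admissible non-decision time cannot be
  # produced by any admissible parameter set; pre-screen with a warning
  bad <- rt <= .FIT_BOUNDS$t[1] + 1e-6
  if (any(bad)) {
    warning(sprintf("%d trial(s) with rt <= %.3f s dropped before fitting",
                    sum(bad), .FIT_BOUNDS$t[1]))
    rt <- rt[!bad]; right <- right[!bad]; coh <- coh[!bad]
  }
  # non-decision upper bound must stay below the fastest RT of that choice
  for (ch in 0:1) {
    tn <- if (ch == 1) "t1" else "t0"
    if (any(right == ch))
      upper[nm == tn] <- min(upper[nm == tn],
                             min(rt[right == ch]) - 1e-3)
  }
  starts <- c(list(.heuristic_start(rt, right, coh, variant)),
              .lhs_starts(max(n_starts - 1L, 0L), variant))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-4), upper - 1e-4)
    fit <- try(optim(s, .context_nll, variant = variant, rt = rt,
                     right = right, coh = coh, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 400)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("non-convergence: all optimisation starts failed")
  p <- .theta_to_params(best$par, variant)
  list(params = ddm_params(p$a, p$k, p$t0, p$t1, p$z, p$me),
       loglik = -best$value, n = length(rt),
       converged = best$convergence == 0)
}

#' Fit the biased DDM to one session
#'
#' Maximum-likelihood fit of the first-passage-time likelihood to all
#' non-excluded, non-censored trials, separately for each reward context
#' (six free parameters per context for the full model).  Reduced variants
#' fix `z = 0.5` (`me_only`) or `me = 0` (`z_only`).  Bounded quasi-Newton
#' optimisation from a moment-based start plus Latin-hypercube restarts.
#'
#' @param trials A trial data.frame (see [generate_session()]).
#' @param variant `"full"`, `"me_only"` or `"z_only"`.
#' @param bound_type `"fixed"` (analytic likelihood) or `"collapsing"`
#'   (Monte-Carlo kernel likelihood; slow, see Details).
#' @param n_starts Optimisation starts per context.
#' @param seed Seed for the Latin-hypercube starts (and the Monte-Carlo
#'   likelihood when `bound_type = "collapsing"`).
#' @param collapse A [collapsing_bound()] start value, only for
#'   `bound_type = "collapsing"`.
#' @param n_mc Simulated trials per condition for the collapsing-bound
#'   kernel likelihood.
#' @param collapse_maxit Iteration cap for the collapsing-bound optimiser.
#'
#' @details For collapsing bounds no closed-form first-passage density
#'   exists; the likelihood is estimated from simulated RT distributions
#'   with common random numbers (a kernel-density estimate per
#'   choice-by-coherence cell), so fits are slower and noisier than the
#'   fixed-bound path.
#'
#' @return An object of class `session_fit`: per-context parameters,
#'   total log-likelihood, parameter count, AIC and BIC.
#' @export
fit_session <- function(trials, variant = c("full", "me_only", "z_only"),
                        bound_type = c("fixed", "collapsing"),
                        n_starts = 4, seed = 1, collapse = NULL,
                        n_mc = 500, collapse_maxit = 50) {
  variant <- match.arg(variant)
  bound_type <- match.arg(bound_type)
  t <- trials[!trials$excluded, , drop = FALSE]
  stopifnot(nrow(t) > 0, all(t$context %in% c("LR-Left", "LR-Right")))
  fits <- list()
  for (cx in c("LR-Left", "LR-Right")) {
    ti <- t[t$context == cx, , drop = FALSE]
    if (!nrow(ti)) stop("missing context: ", cx)
    right <- as.integer(ti$choice == "right")
    if (bound_type == "fixed") {
      fits[[cx]] <- .fit_context(ti$rt, right, ti$signed_coherence,
                                 variant, n_starts, seed)
    } else {
      fits[[cx]] <- .fit_context_collapsing(ti$rt, right,
                                            ti$signed_coherence, variant,
                                            seed, collapse, n_mc,
                                            collapse_maxit)
    }
  }
  n_par_ctx <- length(.variant_layout(variant)) +
    if (bound_type == "collapsing") 2L else 0L
  ll <- fits[["LR-Left"]]$loglik + fits[["LR-Right"]]$loglik
  n <- fits[["LR-Left"]]$n + fits[["LR-Right"]]$n
  n_params <- 2L * n_par_ctx
  structure(list(params_lrleft = fits[["LR-Left"]]$params,
                 params_lrright = fits[["LR-Right"]]$params,
                 collapse_lrleft = fits[["LR-Left"]]$collapse,
                 collapse_lrright = fits[["LR-Right"]]$collapse,
                 variant = variant, bound_type = bound_type,
                 loglik = ll, n_params = n_params, n_trials = n,
                 aic = -2 * ll + 2 * n_params,
                 bic = -2 * ll + n_params * log(n),
                 converged = fits[["LR-Left"]]$converged &&
                   fits[["LR-Right"]]$converged),
            class = "session_fit")
}

#' @export
print.session_fit <- function(x, ...) {
  cat(sprintf("Session DDM fit  [variant: %s, bounds: %s]\n",
              x$variant, x$bound_type))
  for (cx in c("params_lrleft", "params_lrright")) {
    p <- x[[cx]]
    cat(sprintf("  %-9s a=%.2f k=%.2f t0=%.3f t1=%.3f z=%.3f me=%+.3f\n",
                if (cx == "params_lrleft") "LR-Left" else "LR-Right",
                p$a, p$k, p$t0, p$t1, p$z, p$me))
  }
  cat(sprintf("  loglik %.1f  n=%d  params=%d  BIC=%.1f\n",
              x$loglik, x$n_trials, x$n_params, x$bic))
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

# Monte-Carlo kernel likelihood for the collapsing-bound variant: simulate
# n_mc trials per signed coherence with common random numbers, estimate
# P(choice) and a Gaussian KDE of the decision-time distribution per choice.
.collapse_nll <- function(theta, variant, rt, right, coh, n_mc, seed) {
  nm <- c(.variant_layout(variant), "beta", "d")
  p <- .theta_to_params(theta[seq_len(length(nm) - 2L)], variant)
  beta <- theta[length(nm) - 1L]; d <- theta[length(nm)]
  nll <- 0
  for (sc in unique(coh)) {
    idx <- which(coh == sc)
    set.seed(seed)  # common random numbers across evaluations
    sim <- ddm_simulate_collapse_cpp(n_mc, p$k * (sc + p$me), p$a, p$z,
                                     beta, d, 2e-3, 10)
    for (ch in 0:1) {
      oi <- idx[right[idx] == ch]
      if (!length(oi)) next
      si <- sim$choice == ch & !sim$censored
      pch <- max(mean(sim$choice == ch), 1 / n_mc)
      td <- rt[oi] - (if (ch == 1) p$t1 else p$t0)
      if (any(td <= 0)) return(1e10)
      if (sum(si) < 5) { nll <- nll + length(oi) * 20; next }
      ts <- sim$tdec[si]
      bw <- max(stats::bw.nrd0(ts), 1e-3)
      dens <- vapply(td, function(x)
        mean(stats::dnorm((x - ts) / bw)) / bw, 0)
      dens <- pmax(dens, 1e-10)
      nll <- nll - sum(log(pch * dens))
    }
  }
  nll
}

.fit_context_collapsing <- function(rt, right, coh, variant, seed,
                                    collapse, n_mc, maxit = 50) {
  if (is.null(collapse)) collapse <- collapsing_bound(1, 2)
  start_fix <- .fit_context(rt, right, coh, variant, 2L, seed)
  sp <- start_fix$params
  nm <- .variant_layout(variant)
  th0 <- c(unlist(sp[nm]), beta = collapse$beta, d = collapse$d)
  lower <- c(vapply(nm, function(x) switch(x, a = .FIT_BOUNDS$a[1],
                                           k = .FIT_BOUNDS$k[1],
                                           t0 = , t1 = .FIT_BOUNDS$t[1],
                                           z = .FIT_BOUNDS$z[1],
                                           me = .FIT_BOUNDS$me[1]), 0),
             0, -5)
  upper <- c(vapply(nm, function(x) switch(x, a = .FIT_BOUNDS$a[2],
                                           k = .FIT_BOUNDS$k[2],
                                           t0 = , t1 = .FIT_BOUNDS$t[2],
                                           z = .FIT_BOUNDS$z[2],
                                           me = .FIT_BOUNDS$me[2]), 0),
             10, 8)
  th0 <- pmin(pmax(th0, lower + 1e-3), upper - 1e-3)
  fit <- optim(th0, .collapse_nll, variant = variant, rt = rt,
               right = right, coh = coh, n_mc = n_mc, seed = seed,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = maxit))
  p <- .theta_to_params(fit$par[seq_along(nm)], variant)
  list(params = ddm_params(p$a, p$k, p$t0, p$t1, p$z, p$me),
       collapse = collapsing_bound(fit$par[length(nm) + 1L],
                                   fit$par[length(nm) + 2L]),
       loglik = -fit$value, n = length(rt), converged = TRUE)
}

#' Compare full and reduced bias models on one session
#'
#' Fits the full, `me_only` and `z_only` variants, reports the information-
#' criterion difference (BIC by default) full minus reduced, and calibrates
#' it by simulate-and-refit: assuming each reduced model's fit is the ground
#' truth, trial-matched datasets are simulated and all variants refitted,
#' giving the expected criterion difference when the reduced model is true
#' (positive values indicate the complexity penalty is doing its job).
#'
#' @inheritParams fit_session
#' @param n_boot Simulate-refit replicates per reduced model (`>= 2`).
#' @param criterion `"bic"` or `"aic"`.
#' @param dt Simulation step for the trial-matched simulations.
#' @return An object of class `model_comparison`.
#' @export
compare_models <- function(trials, n_boot = 10, seed = 1,
                           criterion = c("bic", "aic"), n_starts = 3,
                           dt = 1e-3) {
  criterion <- match.arg(criterion)
  if (n_boot < 2) stop("'n_boot' must be >= 2")
  fits <- lapply(c(full = "full", me_only = "me_only", z_only = "z_only"),
                 function(v) fit_session(trials, v, n_starts = n_starts,
                                         seed = seed))
  ic <- vapply(fits, `[[`, 0, criterion)
  delta_data <- c(me_only = unname(ic["full"] - ic["me_only"]),
                  z_only = unname(ic["full"] - ic["z_only"]))
  t <- trials[!trials$excluded, , drop = FALSE]
  boot <- list()
  set.seed(seed)
  boot_seeds <- sample.int(2^31 - 2, n_boot)
  for (red in c("me_only", "z_only")) {
    deltas <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      sim <- .simulate_trial_matched(t, fits[[red]], boot_seeds[b] + b, dt)
      refit <- lapply(c(full = "full", red = red), function(v)
        fit_session(sim, v, n_starts = n_starts, seed = seed))
      deltas[b] <- refit$full[[criterion]] - refit$red[[criterion]]
    }
    boot[[red]] <- c(mean = mean(deltas), sd = sd(deltas))
  }
  structure(list(fits = fits, criterion = criterion,
                 delta_ic_full_minus_reduced = delta_data,
                 bootstrap_expected_delta = boot, n_boot = n_boot),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%s), full minus reduced\n",
              toupper(x$criterion)))
  for (red in names(x$delta_ic_full_minus_reduced)) {
    b <- x$bootstrap_expected_delta[[red]]
    cat(sprintf("  vs %-8s data: %+8.1f   expected if %s true: %+.1f (sd %.1f, %d reps)\n",
                red, x$delta_ic_full_minus_reduced[[red]], red,
                b["mean"], b["sd"], x$n_boot))
  }
  invisible(x)
}

# simulate a dataset matched trial-for-trial (context x signed coherence) to
# the observed table, from a fitted model
.simulate_trial_matched <- function(t, fit, seed, dt = 1e-3) {
  set.seed(seed)
  out <- t
  for (cx in c("LR-Left", "LR-Right")) {
    p <- if (cx == "LR-Left") fit$params_lrleft else fit$params_lrright
    idx <- which(t$context == cx)
    sim <- .simulate_block_trials(t$signed_coherence[idx], p, dt, 30)
    out$choice[idx] <- sim$choice
    out$rt[idx] <- sim$rt
  }
  out$correct <- (out$signed_coherence > 0 & out$choice == "right") |
                 (out$signed_coherence < 0 & out$choice == "left")
  out
}

#' Context differences in fitted biases
#'
#' Signed differences of the fitted bias parameters between the two reward
#' contexts, oriented so that positive values mean the bias favours the
#' large-reward choice in each context: `delta_me = me(LR-Right) -
#' me(LR-Left)` and `delta_z = z(LR-Right) - z(LR-Left)`.
#'
#' @param fit A `session_fit` (full model).
#' @return An object of class `context_deltas` with `delta_me`, `delta_z`.
#' @export
bias_summary <- function(fit) {
  stopifnot(inherits(fit, "session_fit"))
  structure(list(delta_me = fit$params_lrright$me - fit$params_lrleft$me,
                 delta_z = fit$params_lrright$z - fit$params_lrleft$z),
            class = "context_deltas")
}

#' @export
print.context_deltas <- function(x, ...) {
  cat(sprintf("Context deltas: delta_me = %+.3f, delta_z = %+.3f\n",
              x$delta_me, x$delta_z))
  cat("  (positive = bias toward the large-reward choice)\n")
  invisible(x)
}
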