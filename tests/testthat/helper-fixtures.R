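# Shared fixtures: published-scale parameter sets and small generators.

# mean fitted parameters for the mid-sensitivity animal, per reward context
params_c_left <- function(z = 0.62, me = -0.14)
  ddm_params(a = 1.77, k = 6.58, t0 = 0.33, t1 = 0.35, z = z, me = me)

params_c_right <- function(z = 0.40, me = 0.21)
  ddm_params(a = 1.53, k = 5.08, t0 = 0.31, t1 = 0.33, z = z, me = me)

truth_c <- function() ground_truth(params_c_left(), params_c_right())

COH_SET <- c(0.032, 0.064, 0.128, 0.256, 0.512)

# small trial table drawn directly from the lapse-bounded logistic (fast;
# no diffusion simulation), for psychometric tests
logistic_trials <- function(n, lambda, a0, arew, b0, brew, seed,
                            lev = COH_SET, alpha_seq = 0) {
  set.seed(seed)
  ctx <- sample(c("LR-Left", "LR-Right"), n, TRUE)
  coh <- sample(c(-lev, lev), n, TRUE)
  bias <- a0 + arew * (ctx == "LR-Left")
  sens <- b0 + brew * (ctx == "LR-Left")
  ch <- character(n)
  correct <- logical(n)
  for (i in seq_len(n)) {
    b <- bias[i]
    if (alpha_seq != 0 && i > 1) {
      prev_large <- ifelse(ctx[i - 1] == "LR-Left", "left", "right")
      i_seq <- as.integer(ch[i - 1] == prev_large & correct[i - 1])
      i_rew <- ifelse(ctx[i] == "LR-Right", 1, -1)
      b <- b + i_seq * i_rew * alpha_seq
    }
    p <- logistic_psychometric(coh[i], lambda, b, sens[i])
    ch[i] <- if (runif(1) < p) "right" else "left"
    correct[i] <- (coh[i] > 0) == (ch[i] == "right")
  }
  data.frame(session_id = "S", trial_index = seq_len(n), block_index = 1L,
             context = ctx, signed_coherence = coh, choice = ch, rt = 0.5,
             correct = correct,
             reward = ifelse(correct, 1, 0), excluded = FALSE,
             stringsAsFactors = FALSE)
}

# surfaces for the two contexts from the published-scale non-bias parameters
surfaces_c <- function(grid = grid_spec(), reward_ratio = 1.91,
                       objective = "RTrial") {
  list(
    "LR-Left" = compute_surface(
      params_c_left(), task_economics(reward_ratio, 1, context = "LR-Left",
                                      coherence_levels = COH_SET),
      grid, objective),
    "LR-Right" = compute_surface(
      params_c_right(), task_economics(reward_ratio, 1,
                                       context = "LR-Right",
                                       coherence_levels = COH_SET),
      grid, objective))
}

# minimal session_fit-shaped object for satisficing tests
fake_session_fit <- function(pl, pr) {
  structure(list(params_lrleft = pl, params_lrright = pr,
                 variant = "full", bound_type = "fixed",
                 loglik = 0, n_params = 12, n_trials = 0,
                 aic = 0, bic = 0, converged = TRUE),
            class = "session_fit")
}
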