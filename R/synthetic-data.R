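# Synthetic sessions with the statistical structure of the blocked
# asymmetric-reward random-dot task: two reward contexts alternating in
# blocks, interleaved signed coherences, choices/RTs from a biased DDM.

#' Session configuration
#'
#' Task parameters for one synthetic session.  Defaults follow the task as
#' run: coherence set \{0.032, 0.064, 0.128, 0.256, 0.512\}, blocks of 30–50
#' trials, large:small reward ratio 1.91.  The inter-trial interval and
#' error timeout only enter reward-rate (not reward-per-trial) accounting.
#'
#' @param coherence_levels Unsigned coherences, each in (0, 1].
#' @param block_length_range Integer pair (min, max) block length in trials.
#' @param n_trials Total trials in the session.
#' @param reward_large,reward_small Reward volumes (arbitrary units);
#'   `reward_large >= reward_small > 0`.
#' @param timeout_error Error timeout (s).
#' @param iti Inter-trial interval (s).
#' @param seed Optional integer seed recorded with the config.
#' @return An object of class `session_config`.
#' @export
session_config <- function(coherence_levels = c(0.032, 0.064, 0.128,
                                                0.256, 0.512),
                           block_length_range = c(30L, 50L),
                           n_trials = 1000L,
                           reward_large = 1.91, reward_small = 1,
                           timeout_error = 3, iti = 2, seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials <= 0)
    stop("invalid config: 'n_trials' must be a positive integer")
  n_trials <- as.integer(n_trials)
  if (any(coherence_levels <= 0) || any(coherence_levels > 1))
    stop("invalid config: coherence levels must lie in (0, 1]")
  block_length_range <- as.integer(round(block_length_range))
  if (length(block_length_range) != 2L ||
      block_length_range[1] > block_length_range[2] ||
      block_length_range[1] < 1L || block_length_range[2] > n_trials)
    stop("invalid config: 'block_length_range' must be within [1, n_trials]")
  if (!(reward_large >= reward_small && reward_small > 0))
    stop("invalid config: need reward_large >= reward_small > 0")
  if (timeout_error < 0 || iti < 0)
    stop("invalid config: times must be >= 0")
  structure(list(coherence_levels = sort(coherence_levels),
                 block_length_range = block_length_range,
                 n_trials = n_trials,
                 reward_large = reward_large, reward_small = reward_small,
                 timeout_error = timeout_error, iti = iti, seed = seed),
            class = "session_config")
}

#' Ground-truth parameters for a synthetic session
#'
#' The generating DDM parameters for the two reward contexts (`LR-Left`:
#' large reward for correct leftward choices; `LR-Right`: for rightward).
#'
#' @param params_lrleft,params_lrright [ddm_params()] for each context.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(params_lrleft, params_lrright) {
  stopifnot(inherits(params_lrleft, "ddm_params"),
            inherits(params_lrright, "ddm_params"))
  structure(list(`LR-Left` = params_lrleft, `LR-Right` = params_lrright),
            class = "ground_truth")
}

# minimum RT floor (s): simulated trials below it are resampled, not
# truncated, so densities stay proper
.RT_FLOOR <- 0.05

# vectorised simulation of a set of trials grouped by (context, signed coh)
.simulate_block_trials <- function(signed_coh, params, dt, max_t) {
  n <- length(signed_coh)
  choice <- character(n)
  rt <- numeric(n)
  for (sc in unique(signed_coh)) {
    idx <- which(signed_coh == sc)
    need <- idx
    while (length(need) > 0) {
      sim <- simulate_trials(params, sc, length(need), dt = dt,
                             max_t = max_t)
      ok <- !sim$censored & sim$rt >= .RT_FLOOR
      take <- which(ok)
      nuse <- min(length(take), length(need))
      if (nuse > 0) {
        use <- take[seq_len(nuse)]
        choice[need[seq_len(nuse)]] <- sim$choice[use]
        rt[need[seq_len(nuse)]] <- sim$rt[use]
        need <- need[-seq_len(nuse)]
      }
    }
  }
  list(choice = choice, rt = rt)
}

#' Generate one synthetic session
#'
#' Builds a trial table with the blocked structure of the task: reward
#' context alternates between `LR-Left` and `LR-Right` in blocks whose
#' lengths are drawn uniformly from `block_length_range`; within a block,
#' motion direction and coherence are drawn uniformly at random; the first
#' two trials of every block use the highest coherence (mimicking the
#' signalled block change) and are flagged `excluded` so analyses can drop
#' them.  Choices and response times come from the context's ground-truth
#' DDM; correct choices earn the context-appropriate reward volume.
#'
#' @param config A [session_config()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed (overrides `config$seed` if given).
#' @param session_id Identifier stored with each trial.
#' @param dt,max_t Simulation step and censoring horizon (s).
#' @return A data.frame of trials with columns `session_id`, `trial_index`,
#'   `block_index`, `context`, `signed_coherence`, `choice`, `rt`, `correct`,
#'   `reward`, `excluded`.
#' @export
generate_session <- function(config, truth, seed = config$seed,
                             session_id = "S1", dt = 1e-3, max_t = 30) {
  stopifnot(inherits(config, "session_config"),
            inherits(truth, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  lev <- config$coherence_levels
  max_coh <- max(lev)

  # block skeleton
  block_index <- integer(n); context <- character(n); excluded <- logical(n)
  ctx <- "LR-Left"; i <- 1L; b <- 0L
  while (i <= n) {
    b <- b + 1L
    len <- sample(seq(config$block_length_range[1],
                      config$block_length_range[2]), 1L)
    j <- min(i + len - 1L, n)
    block_index[i:j] <- b
    context[i:j] <- ctx
    excluded[i:min(i + 1L, j)] <- TRUE
    ctx <- if (ctx == "LR-Left") "LR-Right" else "LR-Left"
    i <- j + 1L
  }

  # stimulus draws: uniform direction x coherence; block-change trials use
  # the highest coherence
  coh <- sample(lev, n, replace = TRUE)
  coh[excluded] <- max_coh
  dir <- sample(c(-1, 1), n, replace = TRUE)
  signed_coh <- dir * coh

  choice <- character(n); rt <- numeric(n)
  for (cx in c("LR-Left", "LR-Right")) {
    idx <- which(context == cx)
    if (!length(idx)) next
    sim <- .simulate_block_trials(signed_coh[idx], truth[[cx]], dt, max_t)
    choice[idx] <- sim$choice
    rt[idx] <- sim$rt
  }

  correct <- (signed_coh > 0 & choice == "right") |
             (signed_coh < 0 & choice == "left")
  large_side <- ifelse(context == "LR-Left", "left", "right")
  reward <- ifelse(correct,
                   ifelse(choice == large_side, config$reward_large,
                          config$reward_small),
                   0)
  data.frame(session_id = session_id, trial_index = seq_len(n),
             block_index = block_index, context = context,
             signed_coherence = signed_coh, choice = choice, rt = rt,
             correct = correct, reward = reward, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Generate a cohort of synthetic sessions
#'
#' Repeats [generate_session()] over `n_sessions`, scaling the ground-truth
#' sensitivity `k` by a per-session multiplier (emulating across-session
#' sensitivity changes) and optionally jittering the remaining parameters by
#' a uniform fraction.
#'
#' @inheritParams generate_session
#' @param n_sessions Number of sessions, `>= 1`.
#' @param base_config A [session_config()] shared by all sessions.
#' @param sensitivity_trend Numeric vector of length `n_sessions` (or 1) of
#'   positive multipliers applied to both contexts' `k`.
#' @param jitter_frac Half-width, as a fraction of each parameter value, of
#'   uniform session-to-session jitter on `a`, `t0`, `t1` (0 = none).
#' @return A list with one element per session: `list(trials, truth)`.
#' @export
generate_cohort <- function(n_sessions, base_config, truth,
                            sensitivity_trend = 1, jitter_frac = 0,
                            seed = 1) {
  stopifnot(n_sessions >= 1)
  mult <- rep_len(sensitivity_trend, n_sessions)
  if (any(mult <= 0))
    stop("invalid config: sensitivity multipliers must be positive")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    set.seed(seeds[s])
    jit <- function(x) x * (1 + runif(1, -jitter_frac, jitter_frac))
    tr <- ground_truth(
      do.call(ddm_params, within(unclass(truth[["LR-Left"]]), {
        a <- jit(a); t0 <- jit(t0); t1 <- jit(t1); k <- k * mult[s]
      })),
      do.call(ddm_params, within(unclass(truth[["LR-Right"]]), {
        a <- jit(a); t0 <- jit(t0); t1 <- jit(t1); k <- k * mult[s]
      })))
    out[[s]] <- list(
      trials = generate_session(base_config, tr, seed = seeds[s],
                                session_id = sprintf("S%02d", s)),
      truth = tr)
  }
  out
}
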