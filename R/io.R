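# Delimited-text formats for trial tables and reward surfaces, and the
# end-to-end pipeline runner.

.TRIAL_COLUMNS <- c("session_id", "trial_index", "block_index", "context",
                    "signed_coherence", "choice", "rt", "correct",
                    "reward", "excluded")

#' Write / read a trial table
#'
#' Trial tables are plain CSV with the documented header
#' `session_id, trial_index, block_index, context, signed_coherence,
#' choice, rt, correct, reward, excluded`.  `read_trials()` validates the
#' schema (missing columns and unknown context or choice labels are
#' errors) and reports row and exclusion counts.
#'
#' @param trials A trial data.frame (see [generate_session()]).
#' @param path File path.
#' @param quiet Suppress the row-count message.
#' @return `read_trials()` returns the typed trial data.frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(.TRIAL_COLUMNS %in% names(trials)))
  write.csv(trials[, .TRIAL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  t <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRIAL_COLUMNS, names(t))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  t <- t[, .TRIAL_COLUMNS]
  if (!all(t$context %in% c("LR-Left", "LR-Right")))
    stop("schema error: unknown context label in column 'context'")
  if (!all(t$choice %in% c("left", "right")))
    stop("schema error: unknown choice label in column 'choice'")
  num <- c("trial_index", "block_index", "signed_coherence", "rt", "reward")
  for (cl in num) {
    t[[cl]] <- suppressWarnings(as.numeric(t[[cl]]))
    if (anyNA(t[[cl]])) {
      stop(sprintf("schema error: unparsable value in column '%s', row %d",
                   cl, which(is.na(t[[cl]]))[1]))
    }
  }
  t$correct <- as.logical(t$correct)
  t$excluded <- as.logical(t$excluded)
  if (anyNA(t$correct) || anyNA(t$excluded))
    stop("schema error: unparsable logical in 'correct' or 'excluded'")
  if (!quiet)
    message(sprintf("read %d trials (%d excluded)", nrow(t),
                    sum(t$excluded)))
  t
}

#' Write / read a reward surface as a delimited grid
#'
#' The surface is stored as CSV (rows = `me` grid, columns = `z` grid) with
#' `#`-prefixed header metadata lines recording the objective, method and
#' grid axes.
#'
#' @param surface A `reward_surface`.
#' @param path File path.
#' @return `read_surface()` returns a `reward_surface` (without the
#'   generating parameters); `write_surface()` returns `path` invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "reward_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# objective: %s", surface$objective),
               sprintf("# method: %s", surface$method),
               sprintf("# me: %s", paste(surface$me, collapse = ",")),
               sprintf("# z: %s", paste(surface$z, collapse = ","))), con)
  write.table(surface$values, con, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    x <- sub(sprintf("^# %s: ", key), "", grep(sprintf("^# %s:", key),
                                               hdr, value = TRUE)[1])
    x
  }
  me <- as.numeric(strsplit(get("me"), ",")[[1]])
  z <- as.numeric(strsplit(get("z"), ",")[[1]])
  vals <- as.matrix(read.csv(textConnection(lines[!grepl("^#", lines)]),
                             header = FALSE))
  dimnames(vals) <- NULL
  stopifnot(nrow(vals) == length(me), ncol(vals) == length(z))
  structure(list(me = me, z = z, values = vals, objective = get("objective"),
                 method = get("method"), econ = NULL, params = NULL),
            class = "reward_surface")
}

#' Run the full analysis pipeline on a cohort of sessions
#'
#' For each session: fit the full biased DDM per context, build the
#' context-specific reward surfaces from the fitted non-bias parameters and
#' the session's economics, summarise predicted-vs-max reward and surface
#' features, and run the satisficing predictions across sessions for the
#' requested starting-point variants.  All randomness is governed by
#' `seed`.
#'
#' @param sessions A list of trial data.frames (or file paths readable by
#'   [read_trials()]).
#' @param iti,timeout_error Task timing (s) used in the surface economics.
#' @param grid A [grid_spec()] for the surfaces.
#' @param objective `"RTrial"` or `"RR"`.
#' @param variants Starting-point variants to evaluate.
#' @param n_starts,seed Fitting options (see [fit_session()]).
#' @return A list: `fits`, `surfaces`, `cohort` (one row per session per
#'   context: fitted biases, predicted-to-max ratio, patch area and
#'   orientation), `satisficing` (one `satisficing_prediction` per
#'   variant), and the `seed`.
#' @export
run_pipeline <- function(sessions, iti = 2, timeout_error = 3,
                         grid = grid_spec(), objective = "RTrial",
                         variants = .START_VARIANTS, n_starts = 3,
                         seed = 1) {
  sessions <- lapply(sessions, function(s)
    if (is.character(s)) read_trials(s, quiet = TRUE) else s)
  fits <- list(); surfaces <- list(); rows <- list()
  for (i in seq_along(sessions)) {
    tr <- sessions[[i]]
    fit <- fit_session(tr, "full", n_starts = n_starts, seed = seed + i)
    fits[[i]] <- fit
    rewards <- sort(unique(tr$reward[tr$reward > 0]))
    r_small <- rewards[1]
    r_large <- rewards[length(rewards)]
    lev <- sort(unique(abs(tr$signed_coherence[!tr$excluded])))
    surf <- list()
    for (cx in c("LR-Left", "LR-Right")) {
      p <- if (cx == "LR-Left") fit$params_lrleft else fit$params_lrright
      econ <- task_economics(r_large, r_small, iti, timeout_error, lev, cx)
      surf[[cx]] <- compute_surface(p, econ, grid, objective)
      feat <- surface_features(surf[[cx]])
      rs <- reward_summary(surf[[cx]], p$me, p$z)
      rows[[length(rows) + 1L]] <- data.frame(
        session = i, context = cx, me = p$me, z = p$z,
        predicted = rs$predicted, max_value = rs$max_value,
        ratio_predicted_to_max = rs$ratio_predicted_to_max,
        opt_me = feat$argmax[1], opt_z = feat$argmax[2],
        patch_area = feat$patch_area, orientation = feat$orientation,
        row.names = NULL)
    }
    surfaces[[i]] <- surf
  }
  satisficing <- lapply(setNames(variants, variants), function(v)
    predict_deltas(fits, surfaces, v))
  list(fits = fits, surfaces = surfaces, cohort = do.call(rbind, rows),
       satisficing = satisficing, seed = seed)
}
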