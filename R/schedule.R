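# Experiment schedules and trial-skeleton generation. A schedule is an
# ordered list of blocks (condition, number of sessions, trials per session).
# Potential rewards are pre-drawn per trial -- reward availability is a
# property of the trial, which is what makes within-condition shuffling of
# (stimulus, potential reward) pairs meaningful.

#' Build an experiment schedule
#'
#' @param condition Character vector of condition names, one per block, in
#'   presentation order.
#' @param n_sessions Sessions per block (recycled).
#' @param trials_per_session Trials per session (recycled).
#' @return A data frame of class `experiment_schedule` with columns
#'   `condition`, `n_sessions`, `trials_per_session`.
#' @export
experiment_schedule <- function(condition, n_sessions, trials_per_session) {
  if (any(n_sessions < 1) || any(trials_per_session < 1))
    stop2("`n_sessions` and `trials_per_session` must be >= 1")
  out <- data.frame(condition = as.character(condition),
                    n_sessions = as.integer(rep_len(n_sessions, length(condition))),
                    trials_per_session =
                      as.integer(rep_len(trials_per_session, length(condition))))
  class(out) <- c("experiment_schedule", "data.frame")
  out
}

#' Default species protocols
#'
#' The default rat protocol interleaves baseline blocks with the L/R pairs of
#' each manipulation (pairs run in succession): Baseline, Rich L, Rich R,
#' Baseline, Lean L, Lean R, Baseline, Confuse L, Confuse R; 10 sessions of
#' 500 trials per experimental condition and 3 x 500 per baseline block. The
#' pigeon protocol is identical in structure with 280-trial sessions.
#'
#' @param sessions_per_condition Sessions per experimental condition.
#' @param baseline_sessions Sessions per baseline block.
#' @param trials_per_session Trials per session.
#' @param order Condition order (defaults to the standard interleaving).
#' @return An [experiment_schedule()].
#' @export
rat_protocol <- function(sessions_per_condition = 10, baseline_sessions = 3,
                         trials_per_session = 500,
                         order = c("Baseline", "Rich L", "Rich R",
                                   "Baseline", "Lean L", "Lean R",
                                   "Baseline", "Confuse L", "Confuse R")) {
  experiment_schedule(order,
                      ifelse(order == "Baseline", baseline_sessions,
                             sessions_per_condition),
                      trials_per_session)
}

#' @rdname rat_protocol
#' @export
pigeon_protocol <- function(sessions_per_condition = 10, baseline_sessions = 3,
                            trials_per_session = 280,
                            order = c("Baseline", "Rich L", "Rich R",
                                      "Baseline", "Lean L", "Lean R",
                                      "Baseline", "Confuse L", "Confuse R")) {
  rat_protocol(sessions_per_condition, baseline_sessions, trials_per_session,
               order)
}

#' Generate trial skeletons for a schedule
#'
#' Draws, per trial, the stimulus (per its presentation probability) and the
#' potential reward (per the stimulus's reward probability given a correct
#' response). Responses and realized rewards are left unset; they are filled
#' in by [simulate_agent()] or by real data. Sessions are numbered
#' consecutively across the whole schedule.
#'
#' @param schedule An [experiment_schedule()].
#' @param conditions Named list of [condition_spec()] covering every
#'   condition in the schedule.
#' @param seed Integer seed; the output is fully reproducible from it.
#' @param subject Subject label stored in the records.
#' @param abort_p Optional independent per-trial abort probability
#'   (default 0). Aborted trials carry no response or outcome but occupy a
#'   position in the sequence.
#' @return A trial-record data frame (see [read_trials()] for the schema).
#' @export
generate_schedule <- function(schedule, conditions = builtin_conditions(),
                              seed = 1L, subject = "sim", abort_p = 0) {
  if (!inherits(schedule, "experiment_schedule"))
    stop2("`schedule` must be an experiment_schedule")
  assert_prob(abort_p, "abort_p")
  miss <- setdiff(unique(schedule$condition), names(conditions))
  if (length(miss)) stop2("conditions missing from `conditions`: ",
                          paste(miss, collapse = ", "))
  with_seed(seed, {
    pieces <- list()
    sess0 <- 0L
    for (b in seq_len(nrow(schedule))) {
      cnd <- conditions[[schedule$condition[b]]]
      st <- cnd$stimuli
      for (s in seq_len(schedule$n_sessions[b])) {
        n <- schedule$trials_per_session[b]
        idx <- sample.int(nrow(st), n, replace = TRUE, prob = st$p_present)
        pot <- stats::rbinom(n, 1L, st$p_reward_correct[idx]) == 1L
        ab <- if (abort_p > 0) stats::runif(n) < abort_p else rep(FALSE, n)
        pieces[[length(pieces) + 1L]] <- data.frame(
          subject = subject, condition = cnd$name, session = sess0 + s,
          trial = seq_len(n), stimulus_id = st$id[idx],
          observation = NA_real_, response = NA_character_,
          potential_reward = pot, rewarded = NA, aborted = ab)
      }
      sess0 <- sess0 + schedule$n_sessions[b]
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out$rewarded <- as.logical(out$rewarded)
    out
  })
}

#' Shuffle trials within condition blocks
#'
#' Permutes the (stimulus, potential reward, abort flag) triplets within each
#' contiguous run of a condition, preserving session boundary positions and
#' lengths so session-wise summaries stay comparable. Responses, outcomes and
#' observations are cleared: the result is a fresh skeleton carrying the same
#' per-block multiset of trial types.
#'
#' @param records Trial records.
#' @param seed Integer seed.
#' @return Shuffled skeleton records.
#' @export
shuffle_within_condition <- function(records, seed = 1L) {
  check_trial_order(records)
  with_seed(seed, {
    out <- records
    runs <- rle(records$condition)
    stops <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (b in seq_along(starts)) {
      i <- starts[b]:stops[b]
      perm <- sample(i)
      out$stimulus_id[i] <- records$stimulus_id[perm]
      out$potential_reward[i] <- records$potential_reward[perm]
      out$aborted[i] <- records$aborted[perm]
    }
    out$observation <- NA_real_
    out$response <- NA_character_
    out$rewarded <- NA
    out
  })
}
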