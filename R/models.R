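# Criterion-learning model families and single-trial updates.
#
# All families share the skeleton c(t+1) = gamma * c(t) + step(outcome):
#   IR      — step = delta * (RewR1 - RewR2): shifts only after rewards.
#   IRO     — step = upsilon * (NoRewR2 - NoRewR1): shifts only after omissions.
#   IR&RO   — both channels.
#   -SLR    — delta varies with the presented stimulus (one rate per stimulus,
#             or two groups easy = {1,5} / difficult = {2,3,4} for SLR(red)).
#   -RD     — the whole update (including the leak) happens only on rewarded
#             trials; unrewarded trials leave c untouched, which makes the
#             steady state depend on relative rather than absolute reward rates.
# The leak pulls c towards 0. Aborted trials deliver no outcome and produce
# no update and no leak.

CRIT_FAMILIES <- c("IR", "IRO", "IR&RO", "IR-RD", "IR-SLR", "IR-SLR-RD",
                   "IR-SLR(red)", "IR-SLR(red)-RD")

# Dispatch table: what a family name implies.
family_info <- function(family) {
  if (length(family) != 1L || !family %in% CRIT_FAMILIES)
    stop2("unknown model family: ", paste(family, collapse = ", "),
          " (known: ", paste(CRIT_FAMILIES, collapse = ", "), ")")
  list(family = family,
       rew = family != "IRO",
       omi = family %in% c("IRO", "IR&RO"),
       rd  = grepl("-RD$", family),
       slr = if (grepl("SLR\\(red\\)", family)) "red"
             else if (grepl("SLR", family)) "full" else "none")
}

slr_group_map <- function(slr) {
  switch(slr,
         none = c(`1` = "all", `2` = "all", `3` = "all", `4` = "all", `5` = "all"),
         full = c(`1` = "s1", `2` = "s2", `3` = "s3", `4` = "s4", `5` = "s5"),
         red  = c(`1` = "easy", `2` = "difficult", `3` = "difficult",
                  `4` = "difficult", `5` = "easy"))
}

#' Construct a criterion-learning model specification
#'
#' @param family One of `"IR"`, `"IRO"`, `"IR&RO"`, `"IR-RD"`, `"IR-SLR"`,
#'   `"IR-SLR-RD"`, `"IR-SLR(red)"`, `"IR-SLR(red)-RD"`.
#' @param gamma Leak factor in `[0, 1]`; multiplies the criterion on update
#'   trials, pulling it towards 0.
#' @param delta Reward learning rate(s). A scalar is shared by all learning-
#'   rate groups of the family; alternatively a named vector over the
#'   family's groups (`"all"`; `"s1"`..`"s5"`; or `"easy"`/`"difficult"`).
#'   Signs are unconstrained. Ignored (must be `NULL` or scalar) for `IRO`,
#'   which has no reward channel.
#' @param upsilon Reward-omission learning rate; required for `IRO` and
#'   `IR&RO`, disallowed otherwise.
#'
#' @return Object of class `model_spec`: list with `family`, `gamma`,
#'   `delta` (named by group, or `NULL`), `upsilon` (or `NULL`),
#'   `slr_groups` (stimulus id -> group label) and the parsed `info`.
#' @examples
#' model_spec("IR", gamma = 0.99, delta = 0.04)
#' model_spec("IR-SLR-RD", gamma = 0.99,
#'            delta = c(s1 = 0.01, s2 = 0.05, s3 = 0.08, s4 = 0.05, s5 = 0.01))
#' @export
model_spec <- function(family, gamma, delta = NULL, upsilon = NULL) {
  info <- family_info(family)
  assert_finite(gamma, "gamma")
  if (length(gamma) != 1L || gamma < 0 || gamma > 1)
    stop2("`gamma` must be a single value in [0, 1]")
  groups <- unique(unname(slr_group_map(info$slr)))
  if (info$rew) {
    if (is.null(delta)) stop2("family ", family, " requires `delta`")
    assert_finite(delta, "delta")
    if (is.null(names(delta))) {
      if (length(delta) == 1L) delta <- stats::setNames(rep(delta, length(groups)), groups)
      else if (length(delta) == length(groups)) names(delta) <- groups
      else stop2("`delta` must be scalar or named by group: ",
                 paste(groups, collapse = ", "))
    } else {
      if (!all(groups %in% names(delta)))
        stop2("`delta` must define every group: ", paste(groups, collapse = ", "))
      delta <- delta[groups]
    }
  } else {
    delta <- NULL
  }
  if (info$omi) {
    if (is.null(upsilon)) stop2("family ", family, " requires `upsilon`")
    assert_finite(upsilon, "upsilon")
    if (length(upsilon) != 1L) stop2("`upsilon` must be a single value")
  } else if (!is.null(upsilon)) {
    stop2("family ", family, " has no omission channel; `upsilon` must be NULL")
  }
  structure(list(family = family, gamma = gamma, delta = delta,
                 upsilon = upsilon, slr_groups = slr_group_map(info$slr),
                 info = info),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Criterion-learning model:", x$family, "\n")
  cat("  gamma =", format(x$gamma), "\n")
  if (!is.null(x$delta))
    cat("  delta =", paste(sprintf("%s: %g", names(x$delta), x$delta),
                           collapse = ", "), "\n")
  if (!is.null(x$upsilon)) cat("  upsilon =", format(x$upsilon), "\n")
  invisible(x)
}

# delta of the group that stimulus `id` belongs to.
delta_for_stimulus <- function(model, id) {
  g <- model$slr_groups[as.character(id)]
  if (anyNA(g)) stop2("stimulus id ", paste(id[is.na(g)], collapse = ","),
                      " has no learning-rate group")
  unname(model$delta[g])
}

#' Single-trial criterion update
#'
#' Applies the model's update rule to the current criterion given one trial's
#' outcome. Aborted trials return `c` unchanged (no outcome, no leak). For RD
#' families, unrewarded trials also return `c` unchanged.
#'
#' @param model A [model_spec()].
#' @param c Current criterion.
#' @param trial A list or one-row data frame with `stimulus_id`,
#'   `response` (`"R1"`/`"R2"`), `rewarded` (logical), `aborted` (logical).
#' @return The criterion before the next trial, `c(t+1)`.
#' @examples
#' m <- model_spec("IR", gamma = 0.99, delta = 0.04)
#' update_criterion(m, 0.2, list(stimulus_id = 1, response = "R1",
#'                               rewarded = TRUE, aborted = FALSE))  # 0.238
#' @export
update_criterion <- function(model, c, trial) {
  if (!inherits(model, "model_spec")) stop2("`model` must be a model_spec")
  assert_finite(c, "c")
  aborted <- isTRUE(as.logical(trial$aborted))
  if (aborted) return(c)
  rewarded <- isTRUE(as.logical(trial$rewarded))
  info <- model$info
  if (info$rd && !rewarded) return(c)
  resp <- as.character(trial$response)
  if (!resp %in% c("R1", "R2"))
    stop2("non-aborted trial must carry response 'R1' or 'R2'")
  r1 <- resp == "R1"
  u <- if (rewarded) (if (r1) 1 else -1) else 0      # RewR1 - RewR2
  v <- if (!rewarded) (if (r1) -1 else 1) else 0     # NoRewR2 - NoRewR1
  out <- model$gamma * c
  if (info$rew) out <- out + delta_for_stimulus(model, trial$stimulus_id) * u
  if (info$omi) out <- out + model$upsilon * v
  out
}

#' Replay a criterion trajectory over recorded trials
#'
#' Deterministically applies [update_criterion()] across an ordered trial
#' sequence, returning the criterion in effect *before* each trial (length
#' `nrow(trials) + 1`; the last element is the criterion after the final
#' trial). The criterion carries over across session and condition boundaries
#' by default, matching fitting over a subject's whole sequence; set
#' `reset_per_session = TRUE` to restart at `initial_c` at each new session.
#'
#' @param model A [model_spec()].
#' @param trials Trial records ordered by (session, trial); a data frame with
#'   columns `session`, `trial`, `stimulus_id`, `response`, `rewarded`,
#'   `aborted`.
#' @param initial_c Criterion before the first trial (default 0).
#' @param reset_per_session Reset the criterion at session starts?
#' @return Object of class `criterion_trajectory`: list with numeric `c`
#'   (length `n + 1`) and `initial_c`.
#' @export
replay_trajectory <- function(model, trials, initial_c = 0,
                              reset_per_session = FALSE) {
  check_trial_order(trials)
  assert_finite(initial_c, "initial_c")
  n <- nrow(trials)
  cc <- numeric(n + 1)
  cc[1] <- initial_c
  cur <- initial_c
  sess <- trials$session
  for (t in seq_len(n)) {
    if (reset_per_session && t > 1L && sess[t] != sess[t - 1L]) cur <- initial_c
    cur <- update_criterion(model, cur, trials[t, ])
    cc[t + 1] <- cur
  }
  structure(list(c = cc, initial_c = initial_c), class = "criterion_trajectory")
}

# Trials must be sorted by (session, trial index).
check_trial_order <- function(trials) {
  if (!is.data.frame(trials)) stop2("`trials` must be a data frame")
  needed <- c("session", "trial")
  miss <- setdiff(needed, names(trials))
  if (length(miss)) stop2("trials missing column(s): ", paste(miss, collapse = ", "))
  o <- order(trials$session, trials$trial)
  if (!identical(o, seq_len(nrow(trials))))
    stop2("trials must be ordered by (session, trial)")
  invisible(trials)
}

#' @export
print.criterion_trajectory <- function(x, ...) {
  n <- length(x$c) - 1L
  cat("Criterion trajectory over", n, "trials\n")
  cat("  initial:", format(x$initial_c),
      " final:", format(x$c[n + 1L]),
      " range: [", format(min(x$c)), ",", format(max(x$c)), "]\n")
  invisible(x)
}

#' Reference synthetic subject
#'
#' The package's default generating model for synthetic experiments: an
#' IR-SLR-RD learner with leak `gamma = 0.98` and inverted-U
#' stimulus-specific learning rates (0.0075, 0.03, 0.045, 0.03, 0.0075 for
#' stimuli 1..5; median 0.03). Under the built-in conditions this agent
#' settles at moderate steady-state criterion shifts (about +/-0.34 in
#' Rich/Lean, +/-0.53 in Confuse) with a stable baseline -- the behavioral
#' regime the update rules are meant to capture.
#'
#' @return A [model_spec()].
#' @export
reference_agent <- function() {
  model_spec("IR-SLR-RD", gamma = 0.98,
             delta = c(s1 = 0.0075, s2 = 0.03, s3 = 0.045, s4 = 0.03,
                       s5 = 0.0075))
}
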