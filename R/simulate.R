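# Forward simulation: a learning agent playing through a trial skeleton, and
# ensembles of such simulations on shuffled schedules.

#' Simulate a learning agent through a trial skeleton
#'
#' Per non-aborted trial the agent draws evidence `x ~ Normal(mu_stim, 1)`,
#' responds R2 iff `x >= c(t)`, is rewarded iff the response is correct and
#' the trial's pre-drawn potential reward is available, and updates the
#' criterion per the model's rule. Aborted trials leave the criterion
#' untouched. The drawn evidence is recorded in `observation` for
#' testability (empirical data leave it absent).
#'
#' @param model A [model_spec()].
#' @param trials Skeleton records from [generate_schedule()] or
#'   [shuffle_within_condition()].
#' @param conditions Named list of [condition_spec()] resolving every
#'   condition label in `trials` (supplies stimulus means and categories).
#' @param seed Integer seed for the evidence draws.
#' @param initial_c Criterion before the first trial.
#' @return List with `records` (completed trial records) and `trajectory`
#'   (a `criterion_trajectory`).
#' @examples
#' conds <- builtin_conditions()
#' sched <- experiment_schedule("Rich L", n_sessions = 2, trials_per_session = 100)
#' skel <- generate_schedule(sched, conds, seed = 7)
#' m <- model_spec("IR", gamma = 0.99, delta = 0.04)
#' sim <- simulate_agent(m, skel, conds, seed = 8)
#' mean(sim$records$response == "R2")
#' @export
simulate_agent <- function(model, trials, conditions = builtin_conditions(),
                           seed = 1L, initial_c = 0) {
  if (!inherits(model, "model_spec")) stop2("`model` must be a model_spec")
  check_trial_order(trials)
  assert_finite(initial_c, "initial_c")
  n <- nrow(trials)
  info <- model$info
  # Per-trial lookups resolved up front so the sequential loop stays lean.
  mu <- cat2 <- numeric(n)
  for (nm in unique(trials$condition)) {
    cnd <- conditions[[nm]]
    if (is.null(cnd)) stop2("condition not found: ", nm)
    st <- cnd$stimuli
    rows <- which(trials$condition == nm)
    m_idx <- match(trials$stimulus_id[rows], st$id)
    if (anyNA(m_idx)) stop2("stimulus id absent from condition ", nm)
    mu[rows] <- st$mean[m_idx]
    cat2[rows] <- st$category[m_idx] == 2
  }
  dstim <- if (info$rew) delta_for_stimulus(model, trials$stimulus_id) else numeric(n)
  pot <- as.logical(trials$potential_reward)
  ab <- as.logical(trials$aborted)
  gamma <- model$gamma
  ups <- if (info$omi) model$upsilon else 0
  use_rew <- info$rew; use_omi <- info$omi; rd <- info$rd
  with_seed(seed, {
    xs <- stats::rnorm(n)
    cc <- numeric(n + 1)
    resp2 <- logical(n)
    rew <- logical(n)
    cur <- initial_c
    cc[1] <- cur
    for (t in seq_len(n)) {
      if (!ab[t]) {
        x <- xs[t] + mu[t]
        xs[t] <- x
        r2 <- x >= cur
        resp2[t] <- r2
        correct <- r2 == cat2[t]
        rw <- correct && pot[t]
        rew[t] <- rw
        if (!rd || rw) {
          u <- if (rw) (if (r2) -1 else 1) else 0
          v <- if (!rw) (if (r2) 1 else -1) else 0
          cur <- gamma * cur +
            (if (use_rew) dstim[t] * u else 0) +
            (if (use_omi) ups * v else 0)
        }
      }
      cc[t + 1] <- cur
    }
    records <- trials
    records$observation <- ifelse(ab, NA_real_, xs)
    records$response <- ifelse(ab, NA_character_, ifelse(resp2, "R2", "R1"))
    records$rewarded <- ifelse(ab, NA, rew)
    list(records = records,
         trajectory = structure(list(c = cc, initial_c = initial_c),
                                class = "criterion_trajectory"))
  })
}

#' Forward-simulation ensemble
#'
#' Repeats (shuffle within condition, then simulate) `n_sims` times with the
#' given model and aggregates session-wise behavior: the mean and standard
#' deviation across simulations of the fraction of R2 responses and of the
#' mean criterion per session.
#'
#' @param model A [model_spec()].
#' @param records Trial records for one subject (typically observed data or
#'   a generated protocol); supplies the per-condition trial multisets.
#' @param conditions Named list of [condition_spec()].
#' @param n_sims Number of simulations (default 1000).
#' @param seed Base seed; each simulation derives its own child seeds.
#' @param initial_c Criterion before each simulated sequence.
#' @return Data frame with one row per session: `session`, `condition`,
#'   `p_r2_mean`, `p_r2_sd`, `criterion_mean`, `criterion_sd`.
#' @export
forward_ensemble <- function(model, records, conditions = builtin_conditions(),
                             n_sims = 1000, seed = 1L, initial_c = 0) {
  if (n_sims < 2) stop2("`n_sims` must be >= 2 for a standard deviation")
  check_trial_order(records)
  sess <- sort(unique(records$session))
  sess_of <- match(records$session, sess)
  cond_of <- vapply(sess, function(s)
    records$condition[match(s, records$session)], character(1))
  p_mat <- matrix(NA_real_, n_sims, length(sess))
  c_mat <- matrix(NA_real_, n_sims, length(sess))
  for (k in seq_len(n_sims)) {
    skel <- shuffle_within_condition(records, seed = child_seed(seed, 2L * k))
    sim <- simulate_agent(model, skel, conditions,
                          seed = child_seed(seed, 2L * k + 1L),
                          initial_c = initial_c)
    ok <- !sim$records$aborted
    r2 <- sim$records$response == "R2"
    p_mat[k, ] <- vapply(seq_along(sess), function(j)
      mean(r2[ok & sess_of == j]), numeric(1))
    traj <- sim$trajectory$c[seq_len(nrow(records))]  # criterion before each trial
    c_mat[k, ] <- vapply(seq_along(sess), function(j)
      mean(traj[sess_of == j]), numeric(1))
  }
  data.frame(session = sess, condition = cond_of,
             p_r2_mean = colMeans(p_mat), p_r2_sd = apply(p_mat, 2, stats::sd),
             criterion_mean = colMeans(c_mat),
             criterion_sd = apply(c_mat, 2, stats::sd))
}
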