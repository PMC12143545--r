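# Shared fixtures built in code.

# Symmetric two-stimulus condition with d' = 2 (the worked-example setting).
two_stim_condition <- function() {
  condition_spec("d2", id = c(1, 5), mean = c(-1, 1), category = c(1, 2),
                 p_present = c(0.5, 0.5))
}

# Small hand-built trial-record data frame.
make_trials <- function(stimulus_id, response, rewarded,
                        aborted = rep(FALSE, length(stimulus_id)),
                        session = rep(1L, length(stimulus_id)),
                        condition = "Baseline", subject = "t",
                        potential_reward = rewarded | !aborted) {
  n <- length(stimulus_id)
  data.frame(subject = subject, condition = condition, session = session,
             trial = stats::ave(seq_len(n), session, FUN = seq_along),
             stimulus_id = as.integer(stimulus_id),
             observation = NA_real_,
             response = ifelse(aborted, NA_character_, response),
             potential_reward = potential_reward,
             rewarded = ifelse(aborted, NA, rewarded),
             aborted = aborted)
}

# A compact synthetic subject: reduced protocol + simulated agent.
small_protocol <- function(n_sessions = 2, trials = 200) {
  experiment_schedule(c("Baseline", "Rich L", "Lean R"),
                      n_sessions, trials)
}

simulate_subject <- function(model, schedule = small_protocol(), seed = 100,
                             conditions = builtin_conditions(), abort_p = 0) {
  skel <- generate_schedule(schedule, conditions, seed = seed,
                            abort_p = abort_p)
  simulate_agent(model, skel, conditions, seed = seed + 1L)
}

# Independent one-step oracle for trajectory replay: a literal transcription
# of the update equations, separate from update_criterion()'s code path.
oracle_trajectory <- function(family, gamma, delta, upsilon, trials,
                              initial_c = 0) {
  groups <- switch(
    if (grepl("red", family)) "red" else if (grepl("SLR", family)) "full" else "none",
    none = function(id) "all",
    full = function(id) paste0("s", id),
    red = function(id) ifelse(id %in% c(1, 5), "easy", "difficult"))
  rd <- grepl("-RD$", family)
  cc <- numeric(nrow(trials) + 1)
  cur <- initial_c
  cc[1] <- cur
  for (t in seq_len(nrow(trials))) {
    ab <- isTRUE(trials$aborted[t])
    rw <- isTRUE(trials$rewarded[t])
    if (!ab && (!rd || rw)) {
      rew_r1 <- as.numeric(rw && trials$response[t] == "R1")
      rew_r2 <- as.numeric(rw && trials$response[t] == "R2")
      norew_r1 <- as.numeric(!rw && trials$response[t] == "R1")
      norew_r2 <- as.numeric(!rw && trials$response[t] == "R2")
      step <- 0
      if (family != "IRO")
        step <- step + delta[groups(trials$stimulus_id[t])] * (rew_r1 - rew_r2)
      if (family %in% c("IRO", "IR&RO"))
        step <- step + upsilon * (norew_r2 - norew_r1)
      cur <- gamma * cur + step
    }
    cc[t + 1] <- cur
  }
  cc
}

# Mirror a trial set: swap R1/R2 labels and category-consistent fields.
mirror_trials <- function(trials) {
  out <- trials
  out$response <- ifelse(is.na(trials$response), NA_character_,
                         ifelse(trials$response == "R1", "R2", "R1"))
  out
}
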