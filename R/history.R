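# Discounted outcome-history regressors. For a fixed leak gamma every
# criterion-learning family is linear in its parameters: the criterion
# before trial t is
#   c(t) = sum_g delta_g * H_g(t) + upsilon * Homi(t)
# with, for families whose leak applies every trial,
#   H_g(t) = sum_{k < t, stim(k) in g} gamma^{(t-1)-k} u(k),
#   u(k) = RewR1(k) - RewR2(k)
# (omission channel analogous with v(k) = NoRewR2(k) - NoRewR1(k)); for RD
# families the exponent counts only rewarded trials between k and t, and
# unrewarded trials neither decay nor contribute. Aborted trials contribute
# u = v = 0; for non-RD families they still advance the decay clock (time
# passes), for RD families the clock is outcome-driven by definition.

#' Discounted outcome-history design for a trial sequence
#'
#' Builds, per trial, stimulus indicator columns and the discounted history
#' regressors that make each model family a probit GLM at fixed `gamma`
#' (see [fit_criterion_model()]).
#'
#' @param records Ordered trial records.
#' @param family Model family name (see [model_spec()]).
#' @param gamma Leak factor in `[0, 1]`.
#' @return List of class `history_design`: `stimulus` (indicator matrix, one
#'   column per stimulus id present), `H` (reward-channel matrix, one column
#'   per learning-rate group; `NULL` for IRO), `H_omi` (omission channel or
#'   `NULL`), `keep` (logical: non-aborted rows, the likelihood rows),
#'   `response2` (logical response vector), `gamma`, `family`.
#' @export
history_regressors <- function(records, family, gamma) {
  info <- family_info(family)
  check_trial_order(records)
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    stop2("`gamma` must be a single value in [0, 1]")
  n <- nrow(records)
  ab <- as.logical(records$aborted)
  resp <- as.character(records$response)
  r2 <- !ab & resp == "R2"
  r1 <- !ab & resp == "R1"
  rew <- !ab & as.logical(records$rewarded) %in% TRUE
  u <- ifelse(rew & r1, 1, ifelse(rew & r2, -1, 0))
  norew <- !ab & !rew
  v <- ifelse(norew & r2, 1, ifelse(norew & r1, -1, 0))

  ids <- sort(unique(records$stimulus_id))
  stim <- matrix(0, n, length(ids),
                 dimnames = list(NULL, paste0("mu", ids)))
  stim[cbind(seq_len(n), match(records$stimulus_id, ids))] <- 1

  groups <- unique(unname(slr_group_map(info$slr)))
  gmap <- slr_group_map(info$slr)
  gi <- match(gmap[as.character(records$stimulus_id)], groups)

  H <- NULL
  if (info$rew) {
    H <- matrix(0, n, length(groups), dimnames = list(NULL, paste0("H_", groups)))
    h <- numeric(length(groups))
    for (t in seq_len(n)) {
      H[t, ] <- h
      if (info$rd) {
        if (rew[t]) { h <- gamma * h; h[gi[t]] <- h[gi[t]] + u[t] }
        # unrewarded / aborted: clock frozen, no contribution
      } else {
        h <- gamma * h                      # leak advances every trial
        if (u[t] != 0) h[gi[t]] <- h[gi[t]] + u[t]
      }
    }
  }
  H_omi <- NULL
  if (info$omi) {
    H_omi <- numeric(n)
    h <- 0
    for (t in seq_len(n)) {
      H_omi[t] <- h
      h <- gamma * h + v[t]
    }
  }
  structure(list(stimulus = stim, H = H, H_omi = H_omi, keep = !ab,
                 response2 = r2, gamma = gamma, family = family),
            class = "history_design")
}

# Assemble the GLM design matrix (likelihood rows only).
design_matrix <- function(hd) {
  X <- hd$stimulus
  if (!is.null(hd$H)) X <- cbind(X, hd$H)
  if (!is.null(hd$H_omi)) X <- cbind(X, Homi = hd$H_omi)
  X[hd$keep, , drop = FALSE]
}
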