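# Session-level descriptive inference: the outcome-history logistic
# regression, steady-state summaries, and hit/false-alarm rates.

# Per-trial outcome codes for the lagged regressors: propensity towards R2 is
# coded +1, towards R1 is -1. Reward for R1 and no-reward for R2 are -1 in
# their respective channels; reward for R2 and no-reward for R1 are +1;
# aborted trials are 0 in both channels.
outcome_codes <- function(records) {
  ab <- as.logical(records$aborted)
  resp <- as.character(records$response)
  rew <- !ab & as.logical(records$rewarded) %in% TRUE
  r1 <- !ab & resp == "R1"
  r2 <- !ab & resp == "R2"
  list(rew = ifelse(rew & r2, 1, ifelse(rew & r1, -1, 0)),
       norew = ifelse(!ab & !rew & r1, 1, ifelse(!ab & !rew & r2, -1, 0)))
}

lag_matrix <- function(x, n_back) {
  n <- length(x)
  out <- matrix(0, n, n_back)
  for (j in seq_len(n_back)) out[(j + 1):n, j] <- x[1:(n - j)]
  out
}

#' Outcome-history logistic regression
#'
#' Logistic (binomial, logit link) regression of the response on trial `t`
#' (R1 = 0, R2 = 1) on the current stimulus, the rewards and reward
#' omissions of the preceding `n_back` trials, and session indicators
#' (excluding the first session to avoid collinearity). The regressor table
#' is built on *all* trials; aborted trials are then removed from the
#' response rows only, so an aborted trial at lag `j` contributes zeros to
#' the history regressors rather than shifting the lag structure.
#'
#' @param records Ordered trial records.
#' @param n_back Number of outcome lags (default 4).
#' @return Object of class `history_glm`: coefficient groups `beta0`,
#'   `beta_stim`, `beta_rew` (lags 1..`n_back`), `beta_norew`, `beta_sess`,
#'   their standard errors, and the underlying `glm` fit.
#' @export
history_logit <- function(records, n_back = 4L) {
  check_trial_order(records)
  n <- nrow(records)
  if (n < n_back + 1L) stop2("need more than `n_back` trials")
  codes <- outcome_codes(records)
  rew_l <- lag_matrix(codes$rew, n_back)
  norew_l <- lag_matrix(codes$norew, n_back)
  colnames(rew_l) <- paste0("rew_lag", seq_len(n_back))
  colnames(norew_l) <- paste0("norew_lag", seq_len(n_back))
  stim <- factor(records$stimulus_id)
  sess <- factor(records$session)
  dat <- data.frame(y = as.numeric(records$response == "R2"),
                    stim = stim, sess = sess)
  dat <- cbind(dat, rew_l, norew_l)
  keep <- !as.logical(records$aborted)
  dat <- dat[keep, , drop = FALSE]
  dat$stim <- droplevels(dat$stim)
  dat$sess <- droplevels(dat$sess)
  form <- stats::as.formula(paste(
    "y ~ stim +", paste(colnames(rew_l), collapse = " + "), "+",
    paste(colnames(norew_l), collapse = " + "),
    if (nlevels(dat$sess) > 1) "+ sess" else ""))
  fit <- suppressWarnings(stats::glm(form, data = dat,
                                     family = stats::binomial("logit")))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  big <- !is.na(cf) & abs(cf) > 15
  if (any(big))
    warning("possible separation: extreme coefficient(s) ",
            paste(names(cf)[big], collapse = ", "))
  pick <- function(prefix) {
    i <- grep(prefix, names(cf))
    stats::setNames(cf[i], names(cf)[i])
  }
  structure(list(beta0 = unname(cf["(Intercept)"]),
                 beta_stim = pick("^stim"),
                 beta_rew = pick("^rew_lag"),
                 beta_norew = pick("^norew_lag"),
                 beta_sess = pick("^sess"),
                 se = se, n_back = n_back, glm = fit),
            class = "history_glm")
}

#' @export
print.history_glm <- function(x, ...) {
  cat("Outcome-history logistic regression (", x$n_back, "lags )\n")
  cat("  reward lags:   ", paste(sprintf("%+.3f", x$beta_rew), collapse = "  "), "\n")
  cat("  omission lags: ", paste(sprintf("%+.3f", x$beta_norew), collapse = "  "), "\n")
  invisible(x)
}

#' Hit and false-alarm rates per session
#'
#' Hit rate is the fraction of R1 responses to the clearest category-1
#' stimulus (id 1); false-alarm rate the fraction of R1 responses to the
#' clearest category-2 stimulus (id 5); both among non-aborted trials.
#'
#' @param records Trial records.
#' @return Data frame with `session`, `hr`, `fa`, `n_s1`, `n_s5` (missing
#'   values where a session has no S1 or S5 trials).
#' @export
hit_fa_rates <- function(records) {
  ok <- !as.logical(records$aborted)
  rr <- records[ok, , drop = FALSE]
  if (!any(rr$stimulus_id == 1) || !any(rr$stimulus_id == 5))
    stop2("records must contain stimuli 1 and 5")
  sess <- sort(unique(records$session))
  one <- function(s, id) {
    i <- rr$session == s & rr$stimulus_id == id
    c(rate = if (any(i)) mean(rr$response[i] == "R1") else NA_real_,
      n = sum(i))
  }
  hr <- t(vapply(sess, one, numeric(2), id = 1))
  fa <- t(vapply(sess, one, numeric(2), id = 5))
  data.frame(session = sess, hr = hr[, 1], fa = fa[, 1],
             n_s1 = hr[, 2], n_s5 = fa[, 2])
}

#' Steady-state summary per condition
#'
#' Combines OCPS session criteria with fitted-model equilibrium predictions:
#' for each condition, the observed steady-state criterion (mean over the
#' last `last_n` sessions of the condition, baseline-referenced), the
#' predicted steady state of each fitted model family (its fixed point minus
#' its Baseline fixed point, computed with the fitted stimulus means), the
#' reward-maximizing criterion (likewise Baseline-referenced), and the
#' distances to the optimum of the first and last `last_n` sessions.
#' Pearson `r` and `r^2` between predicted and observed values across the
#' non-baseline conditions are attached per family.
#'
#' @param ocps An [fit_ocps()] result.
#' @param fits List of `crit_fit` objects (possibly of different families).
#' @param conditions Named list of [condition_spec()] covering the conditions
#'   in the records.
#' @param records The trial records the OCPS fit was computed from (supplies
#'   the session-to-condition mapping).
#' @param last_n Number of steady-state sessions (default 3).
#' @param use_fitted_means Replace condition stimulus means by each fit's
#'   estimated means when solving for equilibria (default `TRUE`).
#' @return Object of class `steady_state_summary`: a data frame with one row
#'   per condition run and attributes `correlations` (per family: r, r2)
#'   and `baseline` (the baseline condition name).
#' @export
steady_state_summary <- function(ocps, fits, conditions, records,
                                 last_n = 3L, use_fitted_means = TRUE) {
  if (!inherits(ocps, "ocps_fit")) stop2("`ocps` must be an ocps_fit")
  if (inherits(fits, "crit_fit")) fits <- list(fits)
  if (!length(fits)) stop2("`fits` must contain at least one crit_fit")
  sess_tab <- ocps$sessions
  runs <- rle(sess_tab$condition)
  stops <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  baseline <- ocps$baseline

  fam_names <- vapply(fits, `[[`, character(1), "family")
  names(fits) <- make.unique(fam_names)

  cond_with_means <- function(cnd, fit) {
    if (!use_fitted_means || is.null(fit)) return(cnd)
    st <- cnd$stimuli
    mu_fit <- fit$mu[paste0("mu", st$id)]
    st$mean <- ifelse(is.na(mu_fit), st$mean, unname(mu_fit))
    condition_spec(cnd$name, st$id, st$mean, st$category, st$p_present,
                   st$p_reward_correct)
  }
  # Baseline references per family (fixed point and optimum of Baseline).
  base_cnd <- conditions[[baseline]]
  refs <- lapply(fits, function(f) {
    if (is.null(base_cnd)) return(list(fp = 0, opt = 0))
    bc <- cond_with_means(base_cnd, f)
    list(fp = solve_steady_state(as_model_spec(f), bc)$selected,
         opt = optimal_criterion(bc))
  })

  rows <- list()
  for (b in seq_along(starts)) {
    nm <- runs$values[b]
    cnd <- conditions[[nm]]
    if (is.null(cnd)) stop2("condition not found: ", nm)
    idx <- starts[b]:stops[b]
    if (length(idx) < last_n)
      warning("condition run ", nm, " has fewer than ", last_n,
              " sessions; using all ", length(idx))
    k <- min(last_n, length(idx))
    c_sess <- ocps$c[as.character(sess_tab$session[idx])]
    observed <- mean(utils::tail(c_sess, k))
    first_obs <- mean(utils::head(c_sess, k))
    row <- data.frame(condition = nm, run = b,
                      n_sessions = length(idx), observed = observed)
    for (fn in names(fits)) {
      f <- fits[[fn]]
      cw <- cond_with_means(cnd, f)
      fp <- solve_steady_state(as_model_spec(f), cw)$selected
      opt <- optimal_criterion(cw)
      row[[paste0("predicted_", fn)]] <- fp - refs[[fn]]$fp
      if (fn == names(fits)[1]) {
        opt_rel <- opt - refs[[fn]]$opt
        row$optimal <- opt_rel
        row$dist_first <- abs(first_obs - opt_rel)
        row$dist_last <- abs(observed - opt_rel)
      }
    }
    rows[[b]] <- row
  }
  out <- do.call(rbind, rows)
  non_base <- out$condition != baseline
  correl <- lapply(names(fits), function(fn) {
    pred <- out[[paste0("predicted_", fn)]][non_base]
    obs <- out$observed[non_base]
    if (length(obs) >= 3 && stats::sd(pred) > 0 && stats::sd(obs) > 0) {
      r <- stats::cor(pred, obs)
      c(r = r, r2 = r^2)
    } else c(r = NA_real_, r2 = NA_real_)
  })
  names(correl) <- names(fits)
  structure(out, correlations = correl, baseline = baseline,
            class = c("steady_state_summary", "data.frame"))
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat("Steady-state summary (baseline-referenced criteria)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  cr <- attr(x, "correlations")
  for (fn in names(cr))
    cat(sprintf("  %s: predicted-vs-observed r = %.3f (r2 = %.3f)\n",
                fn, cr[[fn]]["r"], cr[[fn]]["r2"]))
  invisible(x)
}
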