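# Analytic expected outcome rates, fixed-point (steady-state) criteria for
# every model family, the objective reward function, and the
# reward-maximizing criterion.

# Per-stimulus expected reward rate at criterion c, with the sign of its
# contribution to the criterion step (+1 if the rewarded response is R1).
# Returns list(rate = matrix [length(c) x n_stim], sign, id).
stimulus_reward_rates <- function(condition, c) {
  st <- condition$stimuli
  rate <- vapply(seq_len(nrow(st)), function(i) {
    p_r_correct <- if (st$category[i] == 1) stats::pnorm(c - st$mean[i])
                   else stats::pnorm(st$mean[i] - c)
    st$p_present[i] * st$p_reward_correct[i] * p_r_correct
  }, numeric(length(c)))
  rate <- matrix(rate, nrow = length(c))
  list(rate = rate, sign = ifelse(st$category == 1, 1, -1), id = st$id)
}

#' Expected per-trial outcome rates at a fixed criterion
#'
#' The four mutually exclusive per-trial outcome probabilities: rewarded R1,
#' rewarded R2, unrewarded R1, unrewarded R2. Rewards require a correct
#' response and an available reward (probability `p_reward_correct`).
#'
#' @param condition A [condition_spec()].
#' @param c Decision criterion (may be a vector; each component is returned
#'   as a vector of the same length).
#' @return List with components `e_rew_r1`, `e_rew_r2`, `e_norew_r1`,
#'   `e_norew_r2`; the four sum to 1.
#' @export
outcome_rates <- function(condition, c) {
  assert_finite(c, "c")
  st <- condition$stimuli
  rr <- stimulus_reward_rates(condition, c)
  e_rew_r1 <- rowSums(rr$rate[, rr$sign == 1, drop = FALSE])
  e_rew_r2 <- rowSums(rr$rate[, rr$sign == -1, drop = FALSE])
  p_r1 <- 0
  for (i in seq_len(nrow(st))) p_r1 <- p_r1 + st$p_present[i] * stats::pnorm(c - st$mean[i])
  list(e_rew_r1 = e_rew_r1, e_rew_r2 = e_rew_r2,
       e_norew_r1 = p_r1 - e_rew_r1,
       e_norew_r2 = (1 - p_r1) - e_rew_r2)
}

#' Expected next criterion given the current one
#'
#' Averages the model's single-trial update over all possible trial outcomes
#' at criterion `c`. For the RD families the leak applies only on rewarded
#' trials, so `E[c(t+1)] = c (1 - (1-gamma) R) + step`, with `R` the total
#' reward rate. For SLR families the reward step decomposes per stimulus and
#' is weighted by that stimulus group's `delta`.
#'
#' @param model A [model_spec()].
#' @param condition A [condition_spec()].
#' @param c Criterion (vectorized).
#' @return `E[c(t+1) | c]`.
#' @export
expected_next_criterion <- function(model, condition, c) {
  if (!inherits(model, "model_spec")) stop2("`model` must be a model_spec")
  assert_finite(c, "c")
  info <- model$info
  rr <- stimulus_reward_rates(condition, c)
  r_tot <- rowSums(rr$rate)
  step <- 0
  if (info$rew) {
    d <- delta_for_stimulus(model, rr$id)
    step <- step + as.numeric(rr$rate %*% (d * rr$sign))
  }
  if (info$omi) {
    orates <- outcome_rates(condition, c)
    step <- step + model$upsilon * (orates$e_norew_r2 - orates$e_norew_r1)
  }
  if (info$rd) c * (1 - (1 - model$gamma) * r_tot) + step
  else model$gamma * c + step
}

#' Solve for the steady-state criterion
#'
#' Finds all fixed points of `c = E[c(t+1) | c]` by scanning
#' `g(c) = E[c(t+1)|c] - c` on a uniform grid over the bracketing interval
#' and bisecting every sign change, then classifies each root's stability
#' via the numerical derivative (`|dE/dc| < 1`). When several stable roots
#' exist (possible in Confuse-type conditions), the one closest to 0 -- the
#' baseline criterion learning starts from -- is selected.
#'
#' @param model A [model_spec()]; `gamma < 1` is required for families whose
#'   leak applies on every trial (with `gamma = 1` the criterion drifts
#'   without bound).
#' @param condition A [condition_spec()].
#' @param interval Bracketing interval on the decision axis.
#' @param step Grid step for the sign-change scan.
#' @param tol Bisection tolerance.
#' @return Object of class `fixed_point`: list with `roots`, `stable`
#'   (logical per root), `selected`, `derivative` (of `E[c(t+1)]` at each
#'   root), and `diagnostics` (scan grid summary).
#' @examples
#' m <- model_spec("IR", gamma = 0.99, delta = 0.04)
#' solve_steady_state(m, builtin_conditions()[["Rich L"]])
#' @export
solve_steady_state <- function(model, condition, interval = c(-5, 5),
                               step = 0.01, tol = 1e-8) {
  if (!inherits(model, "model_spec")) stop2("`model` must be a model_spec")
  if (model$gamma >= 1)
    stop2("gamma = 1: the criterion has no finite steady state (diverges)")
  grid <- seq(interval[1], interval[2], by = step)
  g <- expected_next_criterion(model, condition, grid) - grid
  roots <- numeric(0)
  zero <- which(g == 0)
  if (length(zero)) roots <- grid[zero]
  flips <- which(g[-1] * g[-length(g)] < 0)
  for (i in flips) {
    r <- stats::uniroot(function(cc) expected_next_criterion(model, condition, cc) - cc,
                        lower = grid[i], upper = grid[i + 1], tol = tol)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (!length(roots))
    stop2("no fixed point found in [", interval[1], ", ", interval[2],
          "]; g ranges over [", format(min(g)), ", ", format(max(g)), "]")
  h <- 1e-5
  deriv <- vapply(roots, function(r) {
    (expected_next_criterion(model, condition, r + h) -
       expected_next_criterion(model, condition, r - h)) / (2 * h)
  }, numeric(1))
  stable <- abs(deriv) < 1
  # Selection: learning starts from baseline-adapted behavior (c = 0), so the
  # relevant equilibrium is the one the mean dynamics reach from 0 -- the root
  # bounding the basin of attraction that contains 0. Falls back to the stable
  # root nearest 0 when 0 is itself an (unstable) fixed point.
  g0 <- expected_next_criterion(model, condition, 0)
  selected <- NA_real_
  if (abs(g0) < tol && any(abs(roots) < 1e-6 & stable)) {
    selected <- roots[which.min(abs(roots))]
  } else if (g0 > 0 && any(roots > 0)) {
    selected <- min(roots[roots > 0])
  } else if (g0 < 0 && any(roots < 0)) {
    selected <- max(roots[roots < 0])
  }
  if (is.na(selected)) {
    cand <- if (any(stable)) roots[stable] else roots
    cand <- cand[order(abs(cand), -cand)]
    selected <- cand[1]
  }
  structure(list(roots = roots, stable = stable, selected = selected,
                 derivative = deriv,
                 diagnostics = list(interval = interval, step = step,
                                    tol = tol, n_sign_changes = length(flips))),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("Steady-state fixed point(s):\n")
  for (i in seq_along(x$roots))
    cat(sprintf("  c* = %+.6f  (|dE/dc| = %.4f, %s)\n", x$roots[i],
                abs(x$derivative[i]), if (x$stable[i]) "stable" else "unstable"))
  cat("Selected:", format(x$selected), "\n")
  invisible(x)
}

#' Analytic standard error of a time-averaged criterion at equilibrium
#'
#' Linearizes the stochastic criterion process at a fixed point: the
#' per-trial update variance is obtained by enumerating every trial outcome
#' (stimulus, response, reward) with its probability and criterion step, and
#' the relaxation rate is the derivative of the expected-update map at the
#' root. The stationary variance is `v / (1 - rho^2)` and the variance of an
#' `n`-trial time average is approximately
#' `v_stat * (1 + rho) / ((1 - rho) * n)` (AR(1) spectral formula). This is
#' the yardstick for comparing simulated long-run criteria against
#' [solve_steady_state()] roots: near-unit-root dynamics can leave only a
#' handful of effective samples even in very long runs.
#'
#' @param model A [model_spec()].
#' @param condition A [condition_spec()].
#' @param root A fixed point of the expected-update map (a stable root from
#'   [solve_steady_state()]).
#' @param n Number of trials in the time average.
#' @return List with `se` (standard error of the time average), `sd_stat`
#'   (stationary criterion standard deviation), `rho` (per-trial relaxation),
#'   `step_var` (per-trial update variance).
#' @export
equilibrium_se <- function(model, condition, root, n) {
  if (!inherits(model, "model_spec")) stop2("`model` must be a model_spec")
  assert_finite(root, "root")
  if (n < 2) stop2("`n` must be >= 2")
  info <- model$info
  st <- condition$stimuli
  gamma <- model$gamma
  probs <- steps <- numeric(0)
  for (i in seq_len(nrow(st))) {
    p_i <- st$p_present[i]
    p_r1 <- stats::pnorm(root - st$mean[i])
    q <- st$p_reward_correct[i]
    rew_r1 <- if (st$category[i] == 1) p_r1 * q else 0
    rew_r2 <- if (st$category[i] == 2) (1 - p_r1) * q else 0
    d_i <- if (info$rew) delta_for_stimulus(model, st$id[i]) else 0
    leak <- (gamma - 1) * root
    # four outcome branches for this stimulus
    probs <- c(probs, p_i * c(rew_r1, p_r1 - rew_r1, rew_r2,
                              (1 - p_r1) - rew_r2))
    steps <- c(steps,
               leak + d_i,                                       # rewarded R1
               if (info$rd) 0 else
                 leak + (if (info$omi) -model$upsilon else 0),   # unrew. R1
               leak - d_i,                                       # rewarded R2
               if (info$rd) 0 else
                 leak + (if (info$omi) model$upsilon else 0))    # unrew. R2
  }
  m1 <- sum(probs * steps)
  v <- sum(probs * steps^2) - m1^2
  h <- 1e-2
  E <- function(cc) expected_next_criterion(model, condition, cc)
  rho <- (E(root + h) - E(root - h)) / (2 * h)
  curv <- (E(root + h) - 2 * E(root) + E(root - h)) / h^2
  rho <- min(abs(rho), 1 - 1e-8)
  sd_stat <- sqrt(v / (1 - rho^2))
  se <- sd_stat * sqrt((1 + rho) / ((1 - rho) * n))
  # second-order stationary-mean shift: the fluctuating process averages the
  # curved update map, displacing its mean from the deterministic fixed point
  bias <- 0.5 * sd_stat^2 * curv / (1 - rho)
  list(se = se, sd_stat = sd_stat, rho = rho, step_var = v, bias = bias)
}

#' Objective reward function
#'
#' Expected per-trial reward probability as a function of the criterion:
#' the sum of the two rewarded-outcome rates.
#'
#' @param condition A [condition_spec()].
#' @param c Criterion (vectorized).
#' @return `P(Rew | c)`.
#' @export
objective_reward_function <- function(condition, c) {
  orates <- outcome_rates(condition, c)
  orates$e_rew_r1 + orates$e_rew_r2
}

#' Reward-maximizing criterion
#'
#' Global maximizer of [objective_reward_function()] over the decision axis,
#' found by a dense grid argmax refined by golden-section search. (The
#' stationarity condition -- intersection of the two decision distributions --
#' can also be satisfied at local minima in interleaved-category conditions,
#' so the argmax route is used rather than direct root-finding.)
#'
#' @param condition A [condition_spec()].
#' @param interval Search interval.
#' @param step Grid step for the initial argmax.
#' @return The optimal criterion (scalar).
#' @examples
#' optimal_criterion(builtin_conditions()[["Rich L"]])
#' @export
optimal_criterion <- function(condition, interval = c(-5, 5), step = 1e-3) {
  st <- condition$stimuli
  if (all(st$p_present * st$p_reward_correct == 0))
    stop2("degenerate condition: no reward is ever attainable, objective is flat")
  grid <- seq(interval[1], interval[2], by = step)
  vals <- objective_reward_function(condition, grid)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(cc) objective_reward_function(condition, cc),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  opt$maximum
}

#' Decision distribution of one category
#'
#' The category's stimulus mixture density scaled by presentation and reward
#' probabilities: `sum_i dnorm(x - mu_i) * p_present_i * p_reward_correct_i`
#' over the stimuli of the category. The crossing point of the two decision
#' distributions nearest the optimum equals the reward-maximizing criterion.
#'
#' @param condition A [condition_spec()].
#' @param category 1 or 2.
#' @param x Evaluation point(s) on the decision axis.
#' @return Scaled density values.
#' @export
decision_distribution <- function(condition, category, x) {
  if (!category %in% c(1, 2)) stop2("`category` must be 1 or 2")
  assert_finite(x, "x")
  st <- condition$stimuli[condition$stimuli$category == category, , drop = FALSE]
  out <- 0
  for (i in seq_len(nrow(st)))
    out <- out + st$p_present[i] * st$p_reward_correct[i] * stats::dnorm(x - st$mean[i])
  out
}

#' Export equilibrium curves for plotting
#'
#' Tabulates, over a criterion grid, the objective reward function, the two
#' decision distributions, and `E[c(t+1)]` for each supplied model.
#'
#' @param condition A [condition_spec()].
#' @param models Optional named list of [model_spec()] objects.
#' @param grid Criterion grid.
#' @return A long-format data frame with columns `c`, `series`, `value`.
#' @export
equilibrium_curves <- function(condition, models = list(),
                               grid = seq(-5, 5, by = 0.01)) {
  out <- list(
    data.frame(c = grid, series = "objective_reward",
               value = objective_reward_function(condition, grid)),
    data.frame(c = grid, series = "decision_distribution_c1",
               value = decision_distribution(condition, 1, grid)),
    data.frame(c = grid, series = "decision_distribution_c2",
               value = decision_distribution(condition, 2, grid)))
  for (nm in names(models))
    out <- c(out, list(data.frame(
      c = grid, series = paste0("expected_next_", nm),
      value = expected_next_criterion(models[[nm]], condition, grid))))
  do.call(rbind, out)
}
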