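conds <- builtin_conditions()

test_that("noise-free probabilities invert exactly up to the constraint", {
  mu_true <- c(`1` = -1.4, `3` = 0.2, `5` = 1.6)
  c_true <- c(0.1, -0.3, 0.5, 0.8)
  p <- outer(mu_true, c_true, function(m, cc) pnorm(m - cc))
  rownames(p) <- names(mu_true)
  colnames(p) <- seq_along(c_true)
  sol <- ocps_solve(p)
  # c_1 = 0 constraint: everything shifts by c_true[1]
  expect_equal(unname(sol$c), unname(c_true - c_true[1]), tolerance = 1e-10)
  expect_equal(unname(sol$mu), unname(mu_true - c_true[1]), tolerance = 1e-10)
  expect_lt(sol$residual_sse, 1e-20)
  # shift invariance: adding a constant to all mu and c changes nothing
  p2 <- outer(mu_true + 0.7, c_true + 0.7, function(m, cc) pnorm(m - cc))
  dimnames(p2) <- dimnames(p)
  sol2 <- ocps_solve(p2)
  expect_equal(sol$c, sol2$c, tolerance = 1e-10)
  expect_equal(sol$mu, sol2$mu, tolerance = 1e-10)
})

test_that("OCPS recovers session criteria from large-sample counts", {
  set.seed(2718)
  mu <- c(`1` = -1.5, `3` = 0, `5` = 1.5)
  c_true <- c(0, 0.4, -0.3, 0.2, 0.6, -0.5)
  rows <- list()
  n_cell <- 10000
  for (j in seq_along(c_true)) for (id in c(1, 3, 5)) {
    n_r2 <- rbinom(1, n_cell, pnorm(mu[as.character(id)] - c_true[j]))
    resp <- c(rep("R2", n_r2), rep("R1", n_cell - n_r2))
    rows[[length(rows) + 1]] <- make_trials(
      rep(id, n_cell), resp, rep(TRUE, n_cell),
      session = rep(j, n_cell),
      condition = if (j == 1) "Baseline" else "Rich L")
  }
  rec <- do.call(rbind, rows)
  rec <- rec[order(rec$session, rec$trial), ]
  rec$trial <- with(rec, ave(trial, session, FUN = seq_along))
  oc <- fit_ocps(rec)
  # criteria are identified up to a constant; compare in the mean-centred gauge
  # so the single reference session's own noise is not counted six times over
  err_c <- (oc$c - mean(oc$c)) - (c_true - mean(c_true))
  expect_lt(max(abs(err_c)), 0.02)
  err_mu <- (oc$mu - mean(oc$mu)) - (mu - mean(mu))
  expect_lt(max(abs(err_mu)), 0.02)
})

test_that("extreme cells stay finite through proportion clipping", {
  rec <- make_trials(rep(c(1, 5), 60), rep(c("R1", "R2"), 60), rep(TRUE, 120),
                     session = rep(1:2, each = 60))
  # stimulus 5 answered R2 on every trial: p-hat = 1 without clipping
  oc <- fit_ocps(rec)
  expect_true(all(is.finite(oc$d)))
  expect_true(all(is.finite(oc$c)))
  expect_equal(unname(oc$d["5", 1]), qnorm((30 + 0.5) / 31))
})

test_that("OCPS validates its inputs", {
  rec <- make_trials(rep(1, 10), rep(c("R1", "R2"), 5), rep(TRUE, 10))
  expect_error(fit_ocps(rec), "2 sessions")
})

test_that("lagged outcome regressors use the documented coding", {
  rec <- make_trials(c(1, 5, 5, 1, 5), c("R1", "R2", "R2", "R1", "R2"),
                     c(TRUE, FALSE, TRUE, FALSE, NA),
                     aborted = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  codes <- critlearn:::outcome_codes(rec)
  # rewarded R1 -> -1; rewarded R2 -> +1 in the reward channel
  expect_equal(codes$rew, c(-1, 0, 1, 0, 0))
  # unrewarded R2 -> -1; unrewarded R1 -> +1; aborted -> 0
  expect_equal(codes$norew, c(0, -1, 0, 1, 0))
  lm1 <- critlearn:::lag_matrix(codes$rew, 2)
  expect_equal(lm1[, 1], c(0, -1, 0, 1, 0))
  expect_equal(lm1[, 2], c(0, 0, -1, 0, 1))
})

test_that("history regression finds reward influence for an IR agent and none for a null agent", {
  sched <- experiment_schedule(c("Baseline", "Rich L"), c(2, 3), 400)
  null_rec <- simulate_subject(model_spec("IR", 0.99, 0),
                               sched, seed = 3001)$records
  h0 <- history_logit(null_rec)
  z0 <- abs(c(h0$beta_rew, h0$beta_norew)) /
    h0$se[c(names(h0$beta_rew), names(h0$beta_norew))]
  expect_lt(mean(z0 > 2), 0.5)  # no systematic outcome dependence
  # a faster-forgetting agent so the four-lag window spans visible decay
  sched2 <- experiment_schedule(c("Baseline", "Rich L"), c(2, 4), 800)
  ir_rec <- simulate_subject(model_spec("IR", 0.7, 0.15),
                             sched2, seed = 3002)$records
  h1 <- history_logit(ir_rec)
  expect_gt(h1$beta_rew["rew_lag1"], 0)
  expect_gt(h1$beta_rew["rew_lag1"], h1$beta_rew["rew_lag4"])
  # omission weights stay small relative to reward weights
  expect_gt(abs(h1$beta_rew["rew_lag1"]), abs(h1$beta_norew["norew_lag1"]))
})

test_that("permuting outcomes within sessions nulls the lag coefficients", {
  set.seed(662)
  rec <- simulate_subject(model_spec("IR", 0.97, 0.05),
                          experiment_schedule("Rich L", 3, 400),
                          seed = 4001)$records
  perm <- rec
  for (s in unique(perm$session)) {
    i <- which(perm$session == s)
    j <- sample(i)
    perm$response[i] <- rec$response[j]
    perm$rewarded[i] <- rec$rewarded[j]
    perm$stimulus_id[i] <- rec$stimulus_id[j]
  }
  hp <- history_logit(perm)
  zs <- abs(c(hp$beta_rew, hp$beta_norew)) /
    hp$se[c(names(hp$beta_rew), names(hp$beta_norew))]
  expect_lt(max(zs), 4)
  expect_lt(mean(zs > 2), 0.5)
})

test_that("hit and false-alarm rates follow the analytic null", {
  rec <- simulate_subject(model_spec("IR", 0.99, 0),
                          experiment_schedule("Baseline", 3, 2000),
                          seed = 5001)$records
  hf <- hit_fa_rates(rec)
  expect_equal(nrow(hf), 3)
  expect_true(all(hf$hr >= 0 & hf$hr <= 1 & hf$fa >= 0 & hf$fa <= 1))
  for (j in 1:3) {
    expect_lt(abs(hf$hr[j] - pnorm(1.5)), 3 * sqrt(0.07 * 0.93 / hf$n_s1[j]))
    expect_lt(abs(hf$fa[j] - (1 - pnorm(1.5))),
              3 * sqrt(0.07 * 0.93 / hf$n_s5[j]))
  }
  # a perfect responder has HR = 1 and FA = 0
  perfect <- make_trials(rep(c(1, 5), 50),
                         rep(c("R1", "R2"), 50), rep(TRUE, 100))
  pf <- hit_fa_rates(perfect)
  expect_equal(pf$hr, 1)
  expect_equal(pf$fa, 0)
})

test_that("steady-state summary tracks the generating model and mirrors", {
  # same equilibria as reference_agent() but a 4x slower time constant, so the
  # first three sessions of each condition still contain the transient
  gen <- model_spec("IR-SLR-RD", 0.995,
                    delta = c(s1 = 0.001875, s2 = 0.0075, s3 = 0.01125,
                              s4 = 0.0075, s5 = 0.001875))
  sched <- experiment_schedule(c("Baseline", "Rich L", "Rich R", "Lean L",
                                 "Lean R", "Confuse L", "Confuse R"),
                               c(3, rep(6, 6)), 400)
  skel <- generate_schedule(sched, conds, seed = 6001)
  sim <- simulate_agent(gen, skel, conds, seed = 6002)
  oc <- fit_ocps(sim$records)
  fit <- fit_criterion_model(sim$records, "IR-SLR-RD",
                             gamma_grid = default_gamma_grid(12, c(2e-3, 0.2)),
                             conditions = conds)
  ss <- steady_state_summary(oc, fit, conds, sim$records)
  expect_equal(nrow(ss), 7)
  expect_equal(ss$observed[ss$condition == "Baseline"], 0, tolerance = 1e-10)
  cr <- attr(ss, "correlations")[[1]]
  expect_gt(cr["r"], 0.9)
  # an agent that converges towards the optimum gets closer over a condition
  rich <- ss[ss$condition %in% c("Rich L", "Rich R", "Lean L", "Lean R"), ]
  expect_lt(mean(rich$dist_last), mean(rich$dist_first))
  # L/R mirror equivariance: mirroring the whole dataset negates the summary
  mir_conds <- lapply(conds, mirror_condition)
  for (nm in names(mir_conds)) mir_conds[[nm]]$name <- nm
  mir_rec <- mirror_trials(sim$records)
  oc_m <- fit_ocps(mir_rec)
  expect_equal(unname(oc_m$c), -unname(oc$c), tolerance = 1e-10)
  fit_m <- fit_criterion_model(mir_rec, "IR-SLR-RD",
                               gamma_grid = fit$gamma, refine = FALSE,
                               conditions = mir_conds)
  ss_m <- steady_state_summary(oc_m, fit_m, mir_conds, mir_rec)
  expect_equal(ss_m$observed, -ss$observed, tolerance = 1e-8)
  expect_equal(ss_m$optimal, -ss$optimal, tolerance = 0.05)
})
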