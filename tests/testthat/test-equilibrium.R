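conds <- builtin_conditions()

test_that("outcome rates partition probability and respect baseline symmetry", {
  grid <- seq(-3, 3, by = 0.25)
  for (nm in names(conds)) {
    o <- outcome_rates(conds[[nm]], grid)
    tot <- o$e_rew_r1 + o$e_rew_r2 + o$e_norew_r1 + o$e_norew_r2
    expect_equal(tot, rep(1, length(grid)), tolerance = 1e-12)
    expect_true(all(unlist(o) >= 0 & unlist(o) <= 1))
  }
  b0 <- outcome_rates(conds[["Baseline"]], 0)
  expect_equal(b0$e_rew_r1, b0$e_rew_r2, tolerance = 1e-14)
})

test_that("Lean reward rates are exactly half the Rich reward rates", {
  # independent term-by-term mixture oracle, written out from the condition
  # tables rather than via outcome_rates()
  grid <- seq(-4, 4, length.out = 100)
  rich_r1 <- 0.5 * pnorm(grid + 1.5)
  rich_r2 <- 0.25 * (1 - pnorm(grid)) + 0.25 * (1 - pnorm(grid - 1.5))
  o_rich <- outcome_rates(conds[["Rich L"]], grid)
  o_lean <- outcome_rates(conds[["Lean L"]], grid)
  expect_equal(o_rich$e_rew_r1, rich_r1, tolerance = 1e-12)
  expect_equal(o_rich$e_rew_r2, rich_r2, tolerance = 1e-12)
  expect_equal(o_lean$e_rew_r1, 0.5 * o_rich$e_rew_r1, tolerance = 1e-12)
  expect_equal(o_lean$e_rew_r2, 0.5 * o_rich$e_rew_r2, tolerance = 1e-12)
  o_rr <- outcome_rates(conds[["Rich R"]], grid)
  o_lr <- outcome_rates(conds[["Lean R"]], grid)
  expect_equal(o_lr$e_rew_r1, 0.5 * o_rr$e_rew_r1, tolerance = 1e-12)
  expect_equal(o_lr$e_rew_r2, 0.5 * o_rr$e_rew_r2, tolerance = 1e-12)
})

test_that("expected next criterion reduces to the leak with zero step sizes", {
  cc <- c(-1, 0, 0.7)
  for (family in c("IR", "IRO", "IR&RO")) {
    m <- model_spec(family, 0.95,
                    delta = if (family != "IRO") 0,
                    upsilon = if (family %in% c("IRO", "IR&RO")) 0 else NULL)
    expect_equal(expected_next_criterion(m, conds[["Confuse L"]], cc),
                 0.95 * cc, tolerance = 1e-14)
  }
  # symmetric rates cancel at the baseline midpoint
  for (family in c("IR", "IR-RD", "IR&RO"))
    expect_equal(expected_next_criterion(
      model_spec(family, 0.99, delta = 0.04,
                 upsilon = if (family == "IR&RO") 0.04 else NULL),
      conds[["Baseline"]], 0), 0, tolerance = 1e-14)
})

test_that("fixed points match a damped iteration oracle and are stable", {
  m <- model_spec("IR", 0.99, 0.04)
  fp <- solve_steady_state(m, conds[["Rich L"]])
  expect_gt(fp$selected, 0)  # reward integration pushes rightward in Rich L
  # independent oracle: damped fixed-point iteration to 1e-10
  cc <- 0.5
  for (i in 1:20000)
    cc <- cc + 0.5 * (expected_next_criterion(m, conds[["Rich L"]], cc) - cc)
  expect_equal(fp$selected, cc, tolerance = 1e-7)
  expect_true(all(abs(fp$derivative[fp$stable]) < 1))
  # expected_next_criterion at the root returns the root
  expect_equal(expected_next_criterion(m, conds[["Rich L"]], fp$selected),
               fp$selected, tolerance = 1e-7)
  # baseline symmetry gives a zero root for all families
  for (family in c("IR", "IRO", "IR&RO")) {
    ms <- model_spec(family, 0.99,
                     delta = if (family != "IRO") 0.04,
                     upsilon = if (family %in% c("IRO", "IR&RO")) 0.04 else NULL)
    expect_equal(solve_steady_state(ms, conds[["Baseline"]])$selected, 0,
                 tolerance = 1e-6)
  }
  expect_error(solve_steady_state(model_spec("IR", 1, 0.04),
                                  conds[["Rich L"]]), "diverge")
})

test_that("RD fixed points are reward-density invariant", {
  ird <- model_spec("IR-RD", 0.99, 0.04)
  slr_rd <- model_spec("IR-SLR-RD", 0.98,
                       delta = c(s1 = 0.0075, s2 = 0.03, s3 = 0.045,
                                 s4 = 0.03, s5 = 0.0075))
  for (m in list(ird, slr_rd)) {
    fr <- solve_steady_state(m, conds[["Rich L"]])$selected
    fl <- solve_steady_state(m, conds[["Lean L"]])$selected
    expect_equal(fr, fl, tolerance = 1e-6)
    expect_equal(solve_steady_state(m, conds[["Rich R"]])$selected,
                 solve_steady_state(m, conds[["Lean R"]])$selected,
                 tolerance = 1e-6)
  }
  # scaling every reward probability by alpha leaves the RD root unchanged
  st <- conds[["Rich L"]]$stimuli
  for (alpha in c(0.3, 0.7)) {
    scaled <- condition_spec("scaled", st$id, st$mean, st$category,
                             st$p_present, st$p_reward_correct * alpha)
    expect_equal(solve_steady_state(ird, scaled)$selected,
                 solve_steady_state(ird, conds[["Rich L"]])$selected,
                 tolerance = 1e-6)
    # ... while the IR (absolute-difference) root shrinks
    ir <- model_spec("IR", 0.99, 0.04)
    expect_lt(abs(solve_steady_state(ir, scaled)$selected),
              abs(solve_steady_state(ir, conds[["Rich L"]])$selected))
  }
  # Lean fixed point smaller in magnitude than Rich for plain IR
  ir <- model_spec("IR", 0.99, 0.04)
  expect_lt(abs(solve_steady_state(ir, conds[["Lean L"]])$selected),
            abs(solve_steady_state(ir, conds[["Rich L"]])$selected))
})

test_that("objective reward function has the expected limits and values", {
  b <- conds[["Baseline"]]
  expect_equal(objective_reward_function(b, -8), 0.5, tolerance = 1e-9)
  expect_equal(objective_reward_function(b, 8), 0.5, tolerance = 1e-9)
  expect_equal(objective_reward_function(b, 0), 0.5 * (pnorm(1.5) + pnorm(0.5)),
               tolerance = 1e-12)
  # Monte-Carlo trial-sampling oracle at c = 0
  set.seed(5150)
  n <- 1e6
  st <- b$stimuli
  stim <- sample(nrow(st), n, replace = TRUE, prob = st$p_present)
  x <- rnorm(n, st$mean[stim])
  resp2 <- x >= 0
  correct <- resp2 == (st$category[stim] == 2)
  rew <- correct & (runif(n) < st$p_reward_correct[stim])
  expect_equal(objective_reward_function(b, 0), mean(rew), tolerance = 2e-3)
  # evenness under mirror symmetry
  expect_equal(objective_reward_function(b, 0.7),
               objective_reward_function(b, -0.7), tolerance = 1e-12)
})

test_that("optimal criterion matches closed forms and grid argmax", {
  # two-stimulus asymmetric condition with the closed-form optimum ln(2)/2
  cnd <- condition_spec("asym", id = c(1, 5), mean = c(-1, 1),
                        category = c(1, 2), p_present = c(2 / 3, 1 / 3))
  expect_equal(optimal_criterion(cnd), log(2) / 2, tolerance = 1e-6)
  expect_equal(optimal_criterion(conds[["Baseline"]]), 0, tolerance = 1e-6)
  # mirrored conditions have mirrored optima
  for (p in list(c("Rich L", "Rich R"), c("Lean L", "Lean R"),
                 c("Confuse L", "Confuse R")))
    expect_equal(optimal_criterion(conds[[p[1]]]),
                 -optimal_criterion(conds[[p[2]]]), tolerance = 1e-6)
  degenerate <- condition_spec("deg", id = c(1, 5), mean = c(-1, 1),
                               category = c(1, 2), p_present = c(0.5, 0.5),
                               p_reward_correct = c(0, 0))
  expect_error(optimal_criterion(degenerate), "degenerate")
})

test_that("decision distributions integrate to 1 and cross at the optimum", {
  b <- conds[["Baseline"]]
  x <- seq(-12, 12, by = 1e-3)
  total <- decision_distribution(b, 1, x) + decision_distribution(b, 2, x)
  expect_equal(sum(total) * 1e-3, 1, tolerance = 1e-5)
  s <- condition_spec("one", id = c(1, 5), mean = c(-1.5, 3),
                      category = c(1, 2), p_present = c(0.25, 0.75))
  expect_equal(decision_distribution(s, 1, -1.5), 0.25 * dnorm(0),
               tolerance = 1e-14)
  for (nm in c("Rich L", "Lean R", "Confuse L")) {
    cnd <- conds[[nm]]
    opt <- optimal_criterion(cnd)
    expect_equal(decision_distribution(cnd, 1, opt),
                 decision_distribution(cnd, 2, opt), tolerance = 1e-6)
  }
})

test_that("equilibrium curves export all requested series", {
  tab <- equilibrium_curves(conds[["Rich L"]],
                            models = list(ir = model_spec("IR", 0.99, 0.04)),
                            grid = seq(-2, 2, by = 0.5))
  expect_setequal(unique(tab$series),
                  c("objective_reward", "decision_distribution_c1",
                    "decision_distribution_c2", "expected_next_ir"))
  expect_equal(nrow(tab), 4 * 9)
})
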