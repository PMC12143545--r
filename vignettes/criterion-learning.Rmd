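---
title: "Trial-by-trial criterion learning: models, equilibria, and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-by-trial criterion learning: models, equilibria, and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critlearn)
```

## The model

In a single-interval forced-choice task, each trial presents one stimulus
from a small set; the subject emits one of two responses (R1 or R2). Under
equal-variance signal detection theory, stimulus $i$ generates evidence
$x \sim \mathcal N(\mu_i, 1)$ on a one-dimensional decision axis, and the
subject responds R2 iff $x \ge c$, where $c$ is the decision criterion. The
tie $x = c$ is a measure-zero event assigned to R2 for determinism.
Sensitivity between two stimuli is $d' = |\mu_j - \mu_i|$.

Classical SDT treats $c$ as fixed. This package implements learning rules
that update $c$ after every trial as a function of the outcome:

* **IR** (integrate rewards): $c_{t+1} = \gamma c_t + \delta(\mathrm{Rew}_{R1} - \mathrm{Rew}_{R2})$.
  Only rewards move the criterion (towards repeating the rewarded response);
  the leak $\gamma \in [0,1]$ pulls $c$ towards 0 and prevents unbounded
  drift ($\gamma = 1$ diverges in asymmetric conditions).
* **IRO** (integrate reward omissions): $c_{t+1} = \gamma c_t + \upsilon(\mathrm{NoRew}_{R2} - \mathrm{NoRew}_{R1})$.
  Only omissions move the criterion (away from the unsuccessful response).
* **IR&RO**: both channels.
* **SLR** variants give each stimulus its own learning rate $\delta_i$
  (five rates), capturing larger updates after rewards on perceptually
  uncertain, near-boundary stimuli; **SLR(red)** uses two groups, easy
  stimuli $\{1, 5\}$ and difficult stimuli $\{2, 3, 4\}$.
* **RD** variants apply the whole update — including the leak — only on
  rewarded trials. Unrewarded trials leave $c$ untouched. This makes the
  steady state depend on *relative* rather than absolute reward rates
  (see below), a matching-law-like property.

Aborted trials deliver no outcome: no update and no leak. Learning-rate
signs are never constrained; fits can and do return negative rates, and
that sign is itself diagnostic (see the fitting section).

## Conditions

`builtin_conditions()` returns seven stimulus/reward designs on canonical
means $(-1.5, -0.5, 0, 0.5, 1.5)$: a symmetric **Baseline**; **Rich L/R**
(one flank presented on half the trials); **Lean L/R** (identical relative
reward ratios to Rich, but probabilistic reinforcement roughly halves the
overall reward density); and **Confuse L/R** (one central stimulus assigned
against the sign of its mean). L and R varieties are mirror images, which
gives the suite a family of exact symmetry checks. A key algebraic property
of the design: at every criterion, the two *rewarded*-outcome rates in Lean
are exactly half the corresponding Rich rates; the unrewarded rates are not
halved (Lean converts rewarded-correct mass into unrewarded-correct mass).
The RD fixed-point equation depends only on the ratio of reward rates, so
RD equilibria coincide in Rich and Lean — the mechanism behind
density-independent steady-state biases.

```{r}
conds <- builtin_conditions()
conds[["Lean L"]]
```

## Equilibria

`expected_next_criterion()` averages a model's update over all trial
outcomes at a given criterion; `solve_steady_state()` finds all fixed
points of that map by scanning $[-5, 5]$ at step 0.01 and bisecting every
sign change to $10^{-8}$, classifying stability via $|dE[c_{t+1}]/dc| < 1$.
The bracketing interval is deliberately generous: means span $\pm 1.5$ and
attainable equilibria are bounded by $\delta/(1-\gamma)$ at the defaults.

**Root selection.** Confuse-type conditions, and all RD families at
moderate-to-large $\delta/(1-\gamma)$, can have several fixed points.
Learning in these experiments starts from baseline-adapted behavior
($c \approx 0$), so the reported `selected` root is the stable root whose
basin of attraction contains 0, i.e. the first root encountered when
following the sign of the mean update away from 0. When the flow at 0
vanishes and 0 itself is unstable (a symmetric bistable case — the RD
families at $\gamma = 0.99$, $\delta = 0.04$ in Baseline are an example),
no root is dynamically preferred; the solver then reports the stable root
nearest 0, ties towards the positive side, and the full root list should be
consulted. A plain "stable root nearest 0" rule was rejected because it can
pick a root on the wrong side of zero when exclusive-choice equilibria sit
at nearly symmetric positions.

**Comparing simulations to equilibria.** The criterion process is a
stochastic recursion, so a long run's time average differs from the
deterministic fixed point in two quantifiable ways. `equilibrium_se()`
linearizes the process at a root and returns (i) the standard error of an
$n$-trial time average from the AR(1) spectral formula — essential because
near-unit-root cells (e.g. IR in Baseline has relaxation
$\rho \approx 0.9996$) retain only a handful of effective samples even in
50,000 trials — and (ii) a second-order estimate of the stationary-mean
shift, $\tfrac12 \sigma^2_{\mathrm{stat}} E''/(1-\rho)$, which is visible
where the expected-update map is strongly curved (Confuse conditions, and
the saturated exclusive-choice equilibria of RD families). The equilibrium
tests use $3\,\mathrm{SE} + |\mathrm{bias}|$ as their yardstick.

`objective_reward_function()` is the expected per-trial reward probability
as a function of $c$; `optimal_criterion()` maximizes it by a dense grid
argmax (step $10^{-3}$) refined by golden-section search. The stationarity
condition — equality of the two `decision_distribution()` curves (category
mixtures scaled by presentation and reward probabilities) — is also
satisfied at local minima in interleaved-category conditions, which is why
the argmax route is used rather than root-finding on the derivative.

```{r}
m <- model_spec("IR", gamma = 0.99, delta = 0.04)
solve_steady_state(m, conds[["Rich L"]])
optimal_criterion(conds[["Rich L"]])
```

## The synthetic experiment generator

`generate_schedule()` draws, per trial, the stimulus (by presentation
probability) and a *potential reward* (by the stimulus's reward
probability). Pre-drawing reward availability makes it a property of the
trial, so `shuffle_within_condition()` — which permutes the
(stimulus, potential reward, abort) triplets within each contiguous
condition run while preserving session boundaries — conserves the reward
schedule exactly. `simulate_agent()` then plays a model through the
skeleton: draw $x$, respond by the criterion rule, collect the reward if
the response is correct and the potential reward is available, update $c$.
The drawn evidence is recorded for testability; empirical data leave it
absent.

The default rat protocol is Baseline, Rich L, Rich R, Baseline, Lean L,
Lean R, Baseline, Confuse L, Confuse R with 10 sessions of 500 trials per
experimental condition and 3 per baseline block (pigeons: 280-trial
sessions). L/R pairs stay adjacent, as in the animal experiments; order is
configurable. Aborts are off by default and available as an independent
per-trial probability.

`reference_agent()` is the package's default generating model: IR-SLR-RD
with $\gamma = 0.98$ and inverted-U rates
$\delta = (0.0075, 0.03, 0.045, 0.03, 0.0075)$ (median 0.03). These values
were chosen once, to land in the empirically documented regime — moderate
steady-state shifts of about $\pm 0.34$ (Rich/Lean) and $\pm 0.53$
(Confuse) with a stable baseline and near-optimal reward harvesting
(about 99.8% of the attainable rate). Larger rates on easy stimuli push RD
dynamics into bistable exclusive-choice equilibria near
$\pm\delta_{\mathrm{eff}}/(1-\gamma)$, a regime inconsistent with the
moderate biases the models are meant to emulate.

What the generator does *not* emulate: lapses and disengaged states,
slow drifts of sensitivity, reaction times, satiety or motivation effects,
and session-level non-stationarities other than those the learning rule
itself produces. Passing tests therefore certify the internal consistency
of the machinery (generator, equilibria, fitting), not that real animals
follow these rules.

## Fitting

For fixed $\gamma$, every family is a probit GLM. The criterion implied by
the history is linear in the parameters,
$c(t) = \sum_g \delta_g H_g(t) + \upsilon H^{\mathrm{omi}}(t)$, with
discounted history regressors
$H_g(t) = \sum_{k<t,\ \mathrm{stim}(k)\in g} \gamma^{(t-1)-k} u(k)$,
$u(k) = \mathrm{Rew}_{R1}(k) - \mathrm{Rew}_{R2}(k)$ (omission channel
analogous). For RD families the exponent counts only rewarded trials
between $k$ and $t$: unrewarded trials neither decay nor contribute. So
$P(\mathrm{R2}_t \mid S_i) = \Phi(\mu_i - c(t))$: a probit regression of
the response on stimulus indicators (coefficients $\mu_i$) and history
columns (coefficients $-\delta_g$, $-\upsilon$). The likelihood at fixed
$\gamma$ has a unique maximum; `fit_criterion_model()` profiles $\gamma$
on a grid — $1-\gamma$ log-spaced over $[5\times10^{-4}, 0.3]$ at 40
points — and refines around the grid minimum by golden-section search in
$\log(1-\gamma)$. $k$ for the BIC ($2\,\mathrm{NLL} + k \ln N$) counts
$\gamma$, all estimated GLM coefficients ($\mu_i$, $\delta$ groups,
$\upsilon$).

Conventions decided here (the data sources are silent on them):

* The criterion carries over across session and condition boundaries
  (fits run over a subject's whole sequence); `replay_trajectory()` offers
  a per-session reset switch for sensitivity analyses.
* Aborted trials are excluded from the likelihood. For families whose leak
  runs every trial, the decay clock still advances across them (time
  passes); for RD families the clock is outcome-driven by definition. Note
  the single-trial replay applies *no* leak on aborted trials — the two
  conventions coincide exactly on abort-free data, which is how the
  likelihood-equivalence test is posed.
* Stimulus means are free coefficients shared across all conditions of a
  subject, estimated jointly; no separate intercept (a constant offset is
  absorbed into the $\hat\mu_i$).
* The probit link is the only one offered for model fitting (the
  generative model is $\Phi$-based); the logit link appears only in the
  descriptive outcome-history regression.

A diagnostic signature worth knowing: fitting an omission-learning family
to reward-driven data from a biased condition yields $\hat\upsilon < 0$ —
steady-state response autocorrelation masquerades as "approach the
unrewarded response". The acceptance suite reproduces this sign flip.

```{r, eval = FALSE}
rec <- simulate_agent(reference_agent(),
                      generate_schedule(rat_protocol(), conds, seed = 1),
                      conds, seed = 2)$records
fits <- lapply(c("IR", "IR-SLR", "IR-SLR-RD"), fit_criterion_model,
               records = rec, conditions = conds)
compare_models(fits)
```

## Session-level analyses

**OCPS.** With a fixed within-session criterion,
$P_j(\mathrm{R2} \mid S_i) = \Phi(\mu_i - c_j)$, so the z-scored response
proportions satisfy $d_{ij} = \mu_i - c_j$ — a linear model in stimulus and
session dummies solved by (optionally count-weighted, default unweighted)
least squares. Proportions are clipped as $(n_{R2} + 0.5)/(n + 1)$ before
$\Phi^{-1}$ so all-R1/all-R2 cells stay finite. The model is identified
only up to a constant; `fit_ocps()` solves with $c_1 = 0$ and then
re-references everything to the mean criterion of the subject's initial
baseline block, so baseline steady states sit at 0 by construction. Tests
compare recovered criteria in the mean-centred gauge, which does not charge
the reference session's own sampling noise to every other session.

**Outcome-history regression.** A logistic regression of the response on
the current stimulus, session indicators (first session excluded to avoid
collinearity), and the outcomes of the previous four trials, coded
directionally: reward-for-R1 and omission-after-R2 are $-1$, reward-for-R2
and omission-after-R1 are $+1$, in their respective channels. The regressor
table is built on all trials first; aborted trials are then dropped from
the response rows only, so an abort at lag $j$ contributes zeros rather
than shifting the lag structure. Note that four lags resolve the *decay* of
reward influence only when $\gamma$ is well below 1; at $\gamma = 0.99$ the
first four lags are nearly equal by design of the learning rule.

**Steady-state summary.** Per condition run: the observed steady state
(mean OCPS criterion over the last three sessions, baseline-referenced),
each fitted family's predicted equilibrium, the reward-maximizing
criterion, and the distances to the optimum of the first versus last three
sessions. Because fitted stimulus means need not be symmetric, the model's
Baseline fixed point is not exactly 0; predictions are therefore
re-expressed relative to the same model's Baseline fixed point (and the
optimum relative to the Baseline optimum). Equilibria are solved with the
fitted means substituted into the condition (`use_fitted_means = TRUE`).

**Hit/false-alarm rates.** Per session, HR is the fraction of R1 responses
to stimulus 1 (the clearest category-1 stimulus) and FA the fraction of R1
responses to stimulus 5. The "yes"-response assignment is a convention; it
reproduces the qualitative pattern (both rates track accuracy) and flips
trivially under the mirror transformation.

## Numerical choices and problem sizes

Probabilities go through `pnorm`/`qnorm` in double precision; no lapse
parameter exists anywhere in the core. Root finding: grid step 0.01,
bisection to $10^{-8}$; optimum: grid step $10^{-3}$ plus golden-section
refinement; stability margin $|dE/dc| < 1$ with a central difference.
The test suite simulates 50,000-trial runs for equilibrium checks, one
full ~34,500-trial protocol for parameter recovery, ten replicate
protocols for model recovery, and $10^6$-draw Monte-Carlo oracles for the
static probabilities; these sizes hold the whole suite to a few minutes
while keeping every stochastic check at 3-standard-error resolution.

## Known limitations

* The equilibrium analysis characterizes means, not the full stationary
  distribution; `equilibrium_se()` is a linearization and its bias term a
  second-order truncation, adequate at the parameter scales used here but
  not for $\delta/(1-\gamma)$ far beyond the stimulus range.
* In symmetric bistable regimes the committed equilibrium side of a
  simulated agent is a property of the noise realization; only the root
  *set* is predictable.
* The fitting GLM conditions on the recorded outcome sequence; it does not
  marginalize over latent criterion noise beyond the model's own dynamics.
* No hierarchical pooling across subjects, cross-validation, or Bayesian
  inference; one subject's sequence is one fit.
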