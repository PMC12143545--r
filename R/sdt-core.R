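# Equal-variance normal signal-detection primitives. Evidence x on a trial is
# drawn from Normal(mu, 1); the subject responds R2 iff x >= c and R1
# otherwise (the tie x == c is a measure-zero event, assigned to R2 for
# determinism). Sensitivity d' between two stimuli is the difference of their
# means on this axis.

#' Probability of an R2 response
#'
#' Under the equal-variance normal model with decision rule "R2 iff x >= c",
#' the probability of responding R2 to a stimulus with mean `mu` is
#' `pnorm(mu - c)`.
#'
#' @param mu Stimulus mean(s) on the decision axis.
#' @param c Decision criterion (recycled against `mu`).
#' @return `P(R2 | mu, c)`, strictly increasing in `mu` and strictly
#'   decreasing in `c`.
#' @examples
#' prob_r2(mu = 1, c = 0.25)   # ~0.773
#' prob_r2(mu = -1, c = 0.25)  # ~0.106, so P(R1) ~0.894
#' @export
prob_r2 <- function(mu, c) {
  assert_finite(mu, "mu")
  assert_finite(c, "c")
  stats::pnorm(mu - c)
}

#' Probability of a correct response to one stimulus
#'
#' Correct means R1 for a category-1 stimulus (evidence below criterion) and
#' R2 for a category-2 stimulus.
#'
#' @param stimulus A single stimulus: any list/one-row data frame with fields
#'   `mean` and `category`, e.g. a row of `condition$stimuli`.
#' @param c Decision criterion (may be a vector).
#' @return `P(correct | stimulus, c)`.
#' @export
prob_correct <- function(stimulus, c) {
  mu <- stimulus$mean
  cat <- stimulus$category
  if (length(mu) != 1L || length(cat) != 1L)
    stop2("`stimulus` must describe a single stimulus")
  if (!cat %in% c(1, 2)) stop2("stimulus `category` must be 1 or 2")
  assert_finite(mu, "stimulus$mean")
  assert_finite(c, "c")
  if (cat == 1) stats::pnorm(c - mu) else stats::pnorm(mu - c)
}

#' Expected accuracy of a fixed criterion in a condition
#'
#' Presentation-probability-weighted fraction of correct responses; reward
#' probabilities play no role here (accuracy, not reward).
#'
#' @param condition A [condition_spec()].
#' @param c Decision criterion (may be a vector).
#' @return Expected fraction correct.
#' @examples
#' # d' = 2 two-stimulus condition at c = 0.25: accuracy ~0.83
#' cnd <- condition_spec("d2", id = c(1, 5), mean = c(-1, 1),
#'                       category = c(1, 2), p_present = c(0.5, 0.5))
#' expected_accuracy(cnd, 0.25)
#' @export
expected_accuracy <- function(condition, c) {
  st <- condition$stimuli
  assert_finite(c, "c")
  acc <- 0
  for (i in seq_len(nrow(st))) {
    pc <- if (st$category[i] == 1) stats::pnorm(c - st$mean[i])
          else stats::pnorm(st$mean[i] - c)
    acc <- acc + st$p_present[i] * pc
  }
  acc
}
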