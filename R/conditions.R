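# Experimental condition containers: a condition is a small set of stimuli on
# a common decision axis (unit-variance normal evidence distributions), each
# with a category assignment, a presentation probability, and a probability of
# reward given a correct response.

#' Construct a condition specification
#'
#' A condition bundles 3-5 stimuli living on the decision axis. Each stimulus
#' has a mean (in units of the common, unit standard deviation), a response
#' category (1 = respond R1 correct, 2 = respond R2 correct), a presentation
#' probability and a reward probability given a correct response.
#'
#' @param name Condition label (e.g. `"Rich L"`).
#' @param id Integer stimulus labels in 1..5.
#' @param mean Stimulus means on the decision axis.
#' @param category Category assignment, 1 or 2, per stimulus.
#' @param p_present Presentation probabilities; must sum to 1.
#' @param p_reward_correct Reward probability given a correct response,
#'   per stimulus. Defaults to 1 (deterministic reinforcement of correct
#'   responses).
#'
#' @return An object of class `condition_spec`: a list with `name` and a
#'   `stimuli` data frame (columns `id`, `mean`, `category`, `p_present`,
#'   `p_reward_correct`).
#' @examples
#' cnd <- condition_spec("demo", id = c(1, 5), mean = c(-1, 1),
#'                       category = c(1, 2), p_present = c(0.5, 0.5))
#' expected_accuracy(cnd, c = 0.25)
#' @export
condition_spec <- function(name, id, mean, category, p_present,
                           p_reward_correct = rep(1, length(id))) {
  n <- length(id)
  if (!all(lengths(list(mean, category, p_present, p_reward_correct)) == n))
    stop2("stimulus fields must all have the same length")
  id <- as.integer(id)
  if (anyNA(id) || any(id < 1L | id > 5L)) stop2("stimulus `id` must be in 1..5")
  if (anyDuplicated(id)) stop2("stimulus ids must be unique")
  assert_finite(mean, "mean")
  if (!all(category %in% c(1, 2))) stop2("`category` must be 1 or 2")
  assert_prob(p_present, "p_present")
  assert_prob(p_reward_correct, "p_reward_correct")
  if (abs(sum(p_present) - 1) > 1e-12)
    stop2("presentation probabilities must sum to 1 (got ", sum(p_present), ")")
  if (!all(c(1, 2) %in% category))
    stop2("each category needs at least one stimulus")
  stimuli <- data.frame(id = id, mean = as.numeric(mean),
                        category = as.integer(category),
                        p_present = as.numeric(p_present),
                        p_reward_correct = as.numeric(p_reward_correct))
  structure(list(name = as.character(name), stimuli = stimuli),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("Condition:", x$name, "\n")
  print(x$stimuli, row.names = FALSE)
  invisible(x)
}

#' Built-in experimental conditions
#'
#' The seven standard conditions of the stimulus/reward-probability design:
#' a symmetric Baseline, Rich L/R (one flank presented twice as often),
#' Lean L/R (same relative reward ratios as Rich but roughly half the overall
#' reward density, via probabilistic reinforcement), and Confuse L/R (one
#' central stimulus assigned to the "wrong" side of the category boundary).
#' Canonical stimulus means are -1.5, -0.5, 0, 0.5, 1.5 for stimuli 1..5.
#'
#' @param species_profile `"rat"` or `"pigeon"`. The condition structure is
#'   identical for both; the profile is kept so callers can pair conditions
#'   with the matching session-length protocol (see [rat_protocol()]).
#' @param mean_overrides Optional named numeric vector mapping stimulus id
#'   (`"1"`..`"5"`) to a subject-specific mean on the decision axis, e.g. the
#'   means recovered by [fit_ocps()]. Must cover every stimulus id used.
#'
#' @return Named list of [condition_spec()] objects.
#' @examples
#' conds <- builtin_conditions()
#' names(conds)
#' conds[["Lean L"]]
#' @export
builtin_conditions <- function(species_profile = c("rat", "pigeon"),
                               mean_overrides = NULL) {
  species_profile <- match.arg(species_profile)
  mu <- c(`1` = -1.5, `2` = -0.5, `3` = 0, `4` = 0.5, `5` = 1.5)
  if (!is.null(mean_overrides)) {
    if (is.null(names(mean_overrides)))
      stop2("`mean_overrides` must be named by stimulus id")
    missing_ids <- setdiff(names(mu), names(mean_overrides))
    if (length(missing_ids))
      stop2("`mean_overrides` missing stimulus id(s): ",
            paste(missing_ids, collapse = ", "))
    mu[names(mean_overrides)] <- as.numeric(mean_overrides)
  }
  cs <- function(name, id, category, p_present, q = rep(1, length(id))) {
    condition_spec(name, id = id, mean = unname(mu[as.character(id)]),
                   category = category, p_present = p_present,
                   p_reward_correct = q)
  }
  list(
    "Baseline"  = cs("Baseline",  c(1, 2, 4, 5), c(1, 1, 2, 2), rep(0.25, 4)),
    "Rich L"    = cs("Rich L",    c(1, 3, 5), c(1, 2, 2), c(0.50, 0.25, 0.25)),
    "Rich R"    = cs("Rich R",    c(1, 3, 5), c(1, 1, 2), c(0.25, 0.25, 0.50)),
    "Lean L"    = cs("Lean L",    c(1, 3, 5), c(1, 2, 2), c(0.25, 0.50, 0.25),
                     q = c(1, 0.25, 0.50)),
    "Lean R"    = cs("Lean R",    c(1, 3, 5), c(1, 1, 2), c(0.25, 0.50, 0.25),
                     q = c(0.50, 0.25, 1)),
    "Confuse L" = cs("Confuse L", c(1, 3, 4, 5), c(1, 2, 1, 2), rep(0.25, 4)),
    "Confuse R" = cs("Confuse R", c(1, 2, 3, 5), c(1, 2, 1, 2), rep(0.25, 4))
  )
}

#' Mirror a condition at the category boundary
#'
#' Negates all stimulus means and swaps the two categories. The L and R
#' varieties of each built-in condition are mirror images of one another in
#' this sense.
#'
#' @param condition A [condition_spec()].
#' @return The mirrored `condition_spec`.
#' @export
mirror_condition <- function(condition) {
  st <- condition$stimuli
  condition_spec(paste(condition$name, "(mirrored)"),
                 id = st$id, mean = -st$mean, category = 3L - st$category,
                 p_present = st$p_present,
                 p_reward_correct = st$p_reward_correct)
}

#' Write / read a condition specification as YAML
#'
#' Serializes the condition as a key-value document with a list of stimuli,
#' using exactly the field names `name`, `id`, `mean`, `category`,
#' `p_present`, `p_reward_correct`.
#'
#' @param condition A [condition_spec()].
#' @param path File path.
#' @return `read_condition()` returns a `condition_spec`;
#'   `write_condition()` returns `path` invisibly.
#' @export
write_condition <- function(condition, path) {
  st <- condition$stimuli
  doc <- list(name = condition$name,
              stimuli = lapply(seq_len(nrow(st)), function(i) as.list(st[i, ])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_condition
#' @export
read_condition <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$name) || is.null(doc$stimuli))
    stop2("condition file must contain `name` and `stimuli`")
  st <- do.call(rbind, lapply(doc$stimuli, as.data.frame))
  condition_spec(doc$name, id = st$id, mean = st$mean, category = st$category,
                 p_present = st$p_present,
                 p_reward_correct = st$p_reward_correct)
}
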