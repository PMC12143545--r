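# Maximum-likelihood fitting. At fixed gamma, every family is a probit GLM:
#   P(R2 at trial t | stimulus i) = Phi(mu_i - c(t)),
#   c(t) = sum_g delta_g H_g(t) + upsilon * Homi(t),
# so the GLM coefficients are mu_i on the stimulus indicators, -delta_g on
# the reward-channel history columns, and -upsilon on the omission channel.
# The likelihood has a unique maximum at fixed gamma; gamma itself is
# profiled over a grid (log-spaced in 1 - gamma) and refined by
# golden-section search around the grid minimum.

#' Default leak-parameter grid
#'
#' `1 - gamma` log-spaced over `[5e-4, 0.3]`.
#'
#' @param n Number of grid points.
#' @param range Range of `1 - gamma`.
#' @return Decreasing vector of `gamma` values.
#' @export
default_gamma_grid <- function(n = 40, range = c(5e-4, 0.3)) {
  1 - exp(seq(log(range[1]), log(range[2]), length.out = n))
}

# One probit GLM at fixed gamma. Returns nll and, optionally, the fit pieces.
probit_at_gamma <- function(records, family, gamma, details = FALSE) {
  hd <- history_regressors(records, family, gamma)
  X <- design_matrix(hd)
  y <- hd$response2[hd$keep]
  drop_cols <- which(apply(X, 2, function(col) all(col == 0)))
  if (length(drop_cols)) X <- X[, -drop_cols, drop = FALSE]
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(y), family = stats::binomial("probit")))
  if (!fit$converged)
    warning("probit IRLS did not converge at gamma = ", format(gamma))
  nll <- fit$deviance / 2
  if (!details) return(nll)
  w <- fit$weights
  covmat <- tryCatch(chol2inv(chol(crossprod(X, X * w))),
                     error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(covmat))
  names(se) <- colnames(X)
  list(nll = nll, coef = stats::setNames(fit$coefficients, colnames(X)),
       se = se, design = hd, n = length(y),
       dropped = colnames(design_matrix(hd))[drop_cols])
}

#' Fit a criterion-learning model to a trial sequence
#'
#' Maximum-likelihood fit of one model family to a subject's recorded choice
#' sequence, profiling the leak `gamma` over a grid and estimating the
#' stimulus means, learning rate(s) and (for omission-learning families) the
#' omission rate jointly by probit regression on discounted outcome-history
#' regressors. Coefficient signs are unconstrained (fits can and do return
#' negative learning rates). Aborted trials are excluded from the likelihood;
#' for families whose leak runs on every trial the decay clock still advances
#' across them.
#'
#' @param records Ordered trial records with at least one R1 and one R2
#'   response among non-aborted trials.
#' @param family Model family (see [model_spec()]).
#' @param gamma_grid Grid of `gamma` values to profile over.
#' @param refine Golden-section refinement of `gamma` around the grid
#'   minimum (default `TRUE`).
#' @param conditions Optional named list of [condition_spec()]; stored in the
#'   result so that [simulate.crit_fit()] and steady-state prediction can
#'   resolve condition structure later.
#'
#' @return Object of class `crit_fit` with components `family`, `gamma`,
#'   `mu` (fitted stimulus means), `delta` (named by learning-rate group, or
#'   `NULL` for IRO), `upsilon` (or `NULL`), `se` (standard errors on the
#'   GLM scale), `nll`, `k` (free parameters incl. `gamma`), `n` (analyzed
#'   trials), `bic`, `gamma_profile` (data frame of the profiled grid),
#'   `records`, `conditions`.
#' @seealso [compare_models()], [solve_steady_state()], [forward_ensemble()]
#' @export
fit_criterion_model <- function(records, family,
                                gamma_grid = default_gamma_grid(),
                                refine = TRUE, conditions = NULL) {
  info <- family_info(family)
  check_trial_order(records)
  if (!length(gamma_grid)) stop2("`gamma_grid` must be non-empty")
  ok <- !as.logical(records$aborted)
  resp <- as.character(records$response[ok])
  if (!any(resp == "R1") || !any(resp == "R2"))
    stop2("non-identifiable: need both R1 and R2 responses among ",
          "non-aborted trials (all responses identical)")
  gamma_grid <- sort(unique(gamma_grid), decreasing = TRUE)
  nlls <- vapply(gamma_grid, function(g) probit_at_gamma(records, family, g),
                 numeric(1))
  i <- which.min(nlls)
  gamma_hat <- gamma_grid[i]
  if (refine && length(gamma_grid) > 1L) {
    # bracket in log(1 - gamma); grid is decreasing in gamma
    lg <- log(1 - gamma_grid)
    lo <- if (i > 1L) lg[i - 1L] else lg[i]
    hi <- if (i < length(lg)) lg[i + 1L] else lg[i]
    if (lo != hi) {
      opt <- stats::optimize(function(l)
        probit_at_gamma(records, family, 1 - exp(l)), interval = sort(c(lo, hi)),
        tol = 1e-4)
      if (opt$objective < nlls[i]) gamma_hat <- 1 - exp(opt$minimum)
    }
  }
  best <- probit_at_gamma(records, family, gamma_hat, details = TRUE)
  if (best$nll > nlls[i]) {   # refinement never accepted if worse than grid
    gamma_hat <- gamma_grid[i]
    best <- probit_at_gamma(records, family, gamma_hat, details = TRUE)
  }
  if (length(gamma_grid) > 1L && i %in% c(1L, length(gamma_grid)))
    warning("gamma profile minimum lies on the grid boundary; ",
            "consider widening `gamma_grid`")
  cf <- best$coef
  mu_cols <- grep("^mu", names(cf), value = TRUE)
  h_cols <- grep("^H_", names(cf), value = TRUE)
  mu <- cf[mu_cols]
  delta <- if (info$rew) stats::setNames(-cf[h_cols], sub("^H_", "", h_cols)) else NULL
  upsilon <- if (info$omi) unname(-cf["Homi"]) else NULL
  k <- 1L + length(cf)   # gamma + every estimated GLM coefficient
  out <- structure(list(
    family = family, gamma = gamma_hat, mu = mu, delta = delta,
    upsilon = upsilon, se = best$se, nll = best$nll, k = k, n = best$n,
    bic = bic(best$nll, k, best$n),
    gamma_profile = data.frame(gamma = gamma_grid, nll = nlls),
    dropped = best$dropped, records = records, conditions = conditions,
    records_digest = records_digest(records)),
    class = "crit_fit")
  out
}

# Fingerprint used to refuse BIC comparisons across different record sets.
records_digest <- function(records) {
  ok <- !as.logical(records$aborted)
  hash32(c(nrow(records), records$stimulus_id[ok],
           as.character(records$response[ok])))
}

#' Bayesian Information Criterion
#'
#' `BIC = 2 * NLL + k * log(n)` with the natural logarithm.
#'
#' @param nll Negative log likelihood.
#' @param k Number of free parameters.
#' @param n Number of analyzed trials.
#' @return The BIC value.
#' @examples
#' bic(100, 2, 500)  # 212.429
#' @export
bic <- function(nll, k, n) {
  if (n < 1) stop2("`n` must be >= 1")
  if (k < 0) stop2("`k` must be >= 0")
  assert_finite(nll, "nll")
  2 * nll + k * log(n)
}

#' Evidence label for a BIC difference
#'
#' Conventional strength-of-evidence bands against the higher-BIC model:
#' differences of 2-6 are "positive", 6-10 "strong", above 10 "very strong";
#' below 2 the evidence is "weak".
#'
#' @param delta_bic Non-negative BIC difference(s).
#' @return Character vector of labels.
#' @export
bic_evidence <- function(delta_bic) {
  if (any(delta_bic < 0)) stop2("`delta_bic` must be >= 0")
  cut(delta_bic, breaks = c(-Inf, 2, 6, 10, Inf),
      labels = c("weak", "positive", "strong", "very strong"),
      right = FALSE) |> as.character()
}

#' Compare fitted models by BIC
#'
#' @param fits List of `crit_fit` objects fitted to the identical record set.
#' @return Data frame of class `crit_fit_comparison`, sorted by BIC, with
#'   `family`, `k`, `n`, `nll`, `bic`, `delta_bic` (relative to the best
#'   model) and `evidence` (band of the evidence against each model).
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "crit_fit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "crit_fit")))
    stop2("`fits` must be a list of crit_fit objects")
  digs <- vapply(fits, `[[`, character(1), "records_digest")
  if (length(unique(digs)) != 1L)
    stop2("fits were computed on different record sets; BICs are not comparable")
  tab <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    n = vapply(fits, `[[`, numeric(1), "n"),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    bic = vapply(fits, `[[`, numeric(1), "bic"))
  tab <- tab[order(tab$bic), ]
  tab$delta_bic <- tab$bic - tab$bic[1]
  tab$evidence <- bic_evidence(tab$delta_bic)
  rownames(tab) <- NULL
  class(tab) <- c("crit_fit_comparison", "data.frame")
  tab
}

#' Turn a fit into a model specification
#'
#' @param fit A `crit_fit`.
#' @return A [model_spec()] carrying the fitted `gamma`, `delta` and
#'   `upsilon`, usable with [solve_steady_state()] and [simulate_agent()].
#' @export
as_model_spec <- function(fit) {
  stopifnot(inherits(fit, "crit_fit"))
  model_spec(fit$family, gamma = fit$gamma, delta = fit$delta,
             upsilon = fit$upsilon)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.crit_fit <- function(x, ...) {
  cat("Criterion-learning model fit (probit ML)\n")
  cat("  family:", x$family, "   trials:", x$n, "\n")
  cat(sprintf("  gamma = %.5f   NLL = %.2f   k = %d   BIC = %.2f\n",
              x$gamma, x$nll, x$k, x$bic))
  cat("  stimulus means:",
      paste(sprintf("%s=%.3f", names(x$mu), x$mu), collapse = "  "), "\n")
  if (!is.null(x$delta))
    cat("  delta:", paste(sprintf("%s=%.4f", names(x$delta), x$delta),
                          collapse = "  "), "\n")
  if (!is.null(x$upsilon)) cat(sprintf("  upsilon = %.4f\n", x$upsilon))
  invisible(x)
}

#' @export
summary.crit_fit <- function(object, ...) {
  cf <- c(object$mu,
          if (!is.null(object$delta))
            stats::setNames(object$delta, paste0("delta_", names(object$delta))),
          if (!is.null(object$upsilon)) c(upsilon = object$upsilon))
  # SEs: delta/upsilon SEs equal the GLM-column SEs (sign flip is immaterial)
  se <- object$se
  names(se) <- sub("^H_", "delta_", names(se))
  names(se)[names(se) == "Homi"] <- "upsilon"
  names(se) <- sub("^mu", "mu", names(se))
  se <- se[names(cf)]
  tab <- data.frame(estimate = cf, std_error = se, z = cf / se)
  out <- list(family = object$family, gamma = object$gamma,
              coefficients = tab, nll = object$nll, k = object$k,
              n = object$n, bic = object$bic)
  class(out) <- "summary.crit_fit"
  out
}

#' @export
print.summary.crit_fit <- function(x, ...) {
  cat("Family:", x$family, "  gamma:", format(x$gamma), "\n")
  printCoefmat(as.matrix(x$coefficients))
  cat(sprintf("NLL = %.2f on %d trials; k = %d; BIC = %.2f\n",
              x$nll, x$n, x$k, x$bic))
  invisible(x)
}

#' @export
coef.crit_fit <- function(object, ...) {
  c(object$mu,
    if (!is.null(object$delta))
      stats::setNames(object$delta, paste0("delta_", names(object$delta))),
    if (!is.null(object$upsilon)) c(upsilon = object$upsilon),
    gamma = object$gamma)
}

#' @export
logLik.crit_fit <- function(object, ...) {
  structure(-object$nll, df = object$k, nobs = object$n, class = "logLik")
}

#' Predicted response probabilities or criterion trajectory
#'
#' @param object A `crit_fit`.
#' @param newdata Optional trial records (defaults to the fitted records).
#' @param type `"response"` for fitted `P(R2)` per non-aborted trial, or
#'   `"criterion"` for the implied criterion before every trial.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.crit_fit <- function(object, newdata = NULL,
                             type = c("response", "criterion"), ...) {
  type <- match.arg(type)
  records <- if (is.null(newdata)) object$records else newdata
  hd <- history_regressors(records, object$family, object$gamma)
  crit <- numeric(nrow(records))
  if (!is.null(hd$H)) {
    d <- object$delta[sub("^H_", "", colnames(hd$H))]
    d[is.na(d)] <- 0
    crit <- crit + as.numeric(hd$H %*% d)
  }
  if (!is.null(hd$H_omi)) crit <- crit + object$upsilon * hd$H_omi
  if (type == "criterion") return(crit)
  mu <- object$mu[paste0("mu", records$stimulus_id)]
  p <- stats::pnorm(mu - crit)
  p[!hd$keep] <- NA_real_
  unname(p)
}

#' @export
residuals.crit_fit <- function(object, ...) {
  p <- predict(object, type = "response")
  ok <- !is.na(p)
  y <- as.numeric(object$records$response[ok] == "R2")
  sign(y - p[ok]) * sqrt(-2 * (y * log(p[ok]) + (1 - y) * log(1 - p[ok])))
}

#' Forward-simulate from a fitted model
#'
#' Runs [forward_ensemble()] with the fitted parameters on the fitted record
#' set (shuffled within condition).
#'
#' @param object A `crit_fit` fitted with `conditions` supplied.
#' @param nsim Number of simulations.
#' @param seed Base seed.
#' @param ... Passed on to [forward_ensemble()].
#' @return See [forward_ensemble()].
#' @export
simulate.crit_fit <- function(object, nsim = 1000, seed = 1L, ...) {
  if (is.null(object$conditions))
    stop2("fit was created without `conditions`; pass them to fit_criterion_model()")
  forward_ensemble(as_model_spec(object), object$records, object$conditions,
                   n_sims = nsim, seed = seed, ...)
}

#' @export
plot.crit_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(log10(1 - x$gamma_profile$gamma), x$gamma_profile$nll,
                 type = "b", xlab = "log10(1 - gamma)", ylab = "NLL",
                 main = paste(x$family, "gamma profile"))
  graphics::abline(v = log10(1 - x$gamma), col = 2)
  p <- predict(x, type = "response")
  sess <- x$records$session
  obs <- tapply(x$records$response == "R2", sess, mean, na.rm = TRUE)
  fit <- tapply(p, sess, mean, na.rm = TRUE)
  graphics::plot(as.numeric(names(obs)), obs, pch = 16, cex = 0.6,
                 xlab = "session", ylab = "P(R2)", main = "observed vs fitted")
  graphics::lines(as.numeric(names(fit)), fit, col = 2)
  invisible(x)
}
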