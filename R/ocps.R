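# One-criterion-per-session (OCPS) estimation. Under a fixed within-session
# criterion, P_j(R2 | S_i) = Phi(mu_i - c_j); z-scoring the observed response
# proportions gives d_ij = qnorm(P_j(R2|S_i)) = mu_i - c_j, a linear model in
# stimulus and session dummies, fitted by least squares. The constant
# ambiguity (adding a to all mu and all c leaves d unchanged) is resolved by
# c_1 = 0 during solving and re-referencing afterwards.

#' One-criterion-per-session fit from z-scored response matrices
#'
#' Workhorse taking a stimulus-by-session matrix of R2 probabilities (or
#' z-scores) directly; [fit_ocps()] builds that matrix from trial records.
#'
#' @param p Matrix of `P(R2)` values, rows = stimuli (rownames = stimulus
#'   ids), columns = sessions (colnames = session indices); `NA` cells are
#'   dropped.
#' @param weights Optional matrix of cell weights (same shape).
#' @param z Set `TRUE` if `p` already holds z-scores `d_ij`.
#' @return List with `mu` (per stimulus), `c` (per session, `c[1] = 0`),
#'   `d` (the z-score matrix), `residual_sse`.
#' @export
ocps_solve <- function(p, weights = NULL, z = FALSE) {
  if (!is.matrix(p)) stop2("`p` must be a matrix (stimuli x sessions)")
  d <- if (z) p else stats::qnorm(p)
  cells <- which(!is.na(d), arr.ind = TRUE)
  if (!nrow(cells)) stop2("no usable cells")
  stim <- factor(rownames(d)[cells[, 1]], levels = rownames(d))
  sess <- factor(colnames(d)[cells[, 2]], levels = colnames(d))
  stim <- droplevels(stim)
  sess <- droplevels(sess)
  if (nlevels(sess) < 2) stop2("OCPS needs at least 2 sessions")
  y <- d[cells]
  w <- if (is.null(weights)) rep(1, length(y)) else weights[cells]
  X <- stats::model.matrix(~ 0 + stim + sess)   # sess level 1 absorbed
  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  if (anyNA(beta))
    stop2("OCPS design is rank deficient after dropping empty cells")
  mu <- beta[seq_len(nlevels(stim))]
  names(mu) <- levels(stim)
  c_hat <- c(0, -beta[-seq_len(nlevels(stim))])
  names(c_hat) <- levels(sess)
  list(mu = mu, c = c_hat, d = d,
       residual_sse = sum(w * fit$residuals^2))
}

#' One-criterion-per-session criterion estimation
#'
#' Estimates fixed per-stimulus means and one criterion per session from a
#' subject's trial records by least squares on z-scored R2 proportions.
#' Before z-scoring, cell proportions are clipped as
#' `p = (n_R2 + 0.5) / (n + 1)` so that all-R1 or all-R2 cells stay finite.
#' After solving with the constraint `c_1 = 0`, all criteria (and means) are
#' re-expressed relative to the mean criterion of the subject's initial
#' baseline sessions, so baseline steady-state values sit at 0 by
#' construction.
#'
#' @param records Trial records for one subject (>= 2 sessions).
#' @param baseline Condition name used as the reference block (default
#'   `"Baseline"`); if absent from the records, the `c_1 = 0` constraint is
#'   kept as the reference.
#' @param weighted Weight cells by trial counts (off by default: plain
#'   least squares).
#' @param min_trials Cells with fewer non-aborted trials are dropped.
#' @return Object of class `ocps_fit`: `mu` (per stimulus), `c` (per
#'   session), `sessions` (data frame session/condition/n), `d` (z-score
#'   matrix), `reference` (subtracted constant), `residual_sse`.
#' @export
fit_ocps <- function(records, baseline = "Baseline", weighted = FALSE,
                     min_trials = 1L) {
  check_trial_order(records)
  ok <- !as.logical(records$aborted)
  rr <- records[ok, , drop = FALSE]
  if (!nrow(rr)) stop2("no non-aborted trials")
  sess_levels <- sort(unique(records$session))
  stim_levels <- sort(unique(rr$stimulus_id))
  n_tab <- table(factor(rr$stimulus_id, stim_levels),
                 factor(rr$session, sess_levels))
  r2_tab <- table(factor(rr$stimulus_id[rr$response == "R2"], stim_levels),
                  factor(rr$session[rr$response == "R2"], sess_levels))
  never <- rowSums(n_tab) == 0
  if (any(never)) {
    warning("dropping never-presented stimulus id(s): ",
            paste(stim_levels[never], collapse = ", "))
    n_tab <- n_tab[!never, , drop = FALSE]
    r2_tab <- r2_tab[!never, , drop = FALSE]
    stim_levels <- stim_levels[!never]
  }
  p <- (unclass(r2_tab) + 0.5) / (unclass(n_tab) + 1)
  p[unclass(n_tab) < min_trials] <- NA
  dimnames(p) <- list(stim_levels, sess_levels)
  w <- if (weighted) unclass(n_tab) else NULL
  sol <- ocps_solve(p, weights = w)
  # Re-reference to the initial baseline block.
  sess_cond <- vapply(sess_levels, function(s)
    records$condition[match(s, records$session)], character(1))
  ref <- 0
  if (baseline %in% sess_cond) {
    runs <- rle(sess_cond)
    first_b <- which(runs$values == baseline)[1]
    idx <- seq(sum(utils::head(runs$lengths, first_b - 1L)) + 1L,
               length.out = runs$lengths[first_b])
    ref <- mean(sol$c[as.character(sess_levels[idx])], na.rm = TRUE)
  }
  structure(list(mu = sol$mu - ref, c = sol$c - ref,
                 sessions = data.frame(session = sess_levels,
                                       condition = sess_cond,
                                       n = colSums(unclass(n_tab))),
                 d = sol$d, reference = ref,
                 residual_sse = sol$residual_sse,
                 baseline = baseline),
            class = "ocps_fit")
}

#' @export
print.ocps_fit <- function(x, ...) {
  cat("One-criterion-per-session fit\n")
  cat("  stimuli:", length(x$mu), "  sessions:", length(x$c),
      "  residual SSE:", format(x$residual_sse, digits = 4), "\n")
  cat("  mu:", paste(sprintf("%s=%.3f", names(x$mu), x$mu), collapse = "  "),
      "\n")
  cat("  criterion range: [", format(min(x$c), digits = 3), ",",
      format(max(x$c), digits = 3), "]  (baseline-referenced)\n")
  invisible(x)
}

#' @export
coef.ocps_fit <- function(object, ...) {
  c(stats::setNames(object$mu, paste0("mu", names(object$mu))),
    stats::setNames(object$c, paste0("c", names(object$c))))
}

#' @export
fitted.ocps_fit <- function(object, ...) {
  outer(object$mu, object$c, `-`)
}

#' @export
residuals.ocps_fit <- function(object, ...) {
  object$d - fitted(object)   # mu - c is invariant to the re-referencing
}

#' @export
plot.ocps_fit <- function(x, ...) {
  graphics::plot(x$sessions$session, x$c, type = "b", pch = 16, cex = 0.7,
                 xlab = "session", ylab = "criterion (baseline-referenced)",
                 main = "OCPS session criteria")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
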