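# Trial-table I/O. One row per trial; exact column set below. Booleans are
# written as 0/1, absent values as empty fields. Lines starting with `#` are
# provenance headers and are ignored on read.

TRIAL_COLUMNS <- c("subject", "condition", "session", "trial", "stimulus_id",
                   "observation", "response", "potential_reward", "rewarded",
                   "aborted")

#' Write trial records to a delimited table
#'
#' @param records Trial-record data frame (see [read_trials()] for schema).
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @param header Optional character vector of provenance lines, written as
#'   `#`-prefixed comments before the column header.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path, sep = "\t", header = NULL) {
  miss <- setdiff(TRIAL_COLUMNS, names(records))
  if (length(miss)) stop2("records missing column(s): ", paste(miss, collapse = ", "))
  out <- records[TRIAL_COLUMNS]
  for (col in c("potential_reward", "rewarded", "aborted"))
    out[[col]] <- ifelse(is.na(out[[col]]), NA_integer_, as.integer(out[[col]]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read trial records from a delimited table
#'
#' The file must contain exactly the columns `subject`, `condition`,
#' `session`, `trial`, `stimulus_id`, `observation`, `response`,
#' `potential_reward`, `rewarded`, `aborted`. Booleans are 0/1; absent
#' values are empty fields. `#`-prefixed lines are skipped.
#'
#' @param path Input path.
#' @param sep Field separator (default tab).
#' @return Trial-record data frame with R types (logical flags, character
#'   response, numeric observation).
#' @export
read_trials <- function(path, sep = "\t") {
  if (!file.exists(path)) stop2("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           na.strings = "", quote = "")
  unknown <- setdiff(names(raw), TRIAL_COLUMNS)
  if (length(unknown)) stop2("unknown column(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(miss)) stop2("missing column(s): ", paste(miss, collapse = ", "))
  parse_num <- function(col, what, integer = FALSE) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop2("malformed ", what, " in column `", col, "` at data line ", bad[1])
    if (integer) as.integer(out) else out
  }
  parse_flag <- function(col) {
    x <- raw[[col]]
    bad <- which(!is.na(x) & !x %in% c("0", "1", "TRUE", "FALSE"))
    if (length(bad))
      stop2("malformed boolean in column `", col, "` at data line ", bad[1])
    ifelse(is.na(x), NA, x %in% c("1", "TRUE"))
  }
  resp <- raw$response
  bad <- which(!is.na(resp) & !resp %in% c("R1", "R2"))
  if (length(bad))
    stop2("malformed response (must be R1/R2/empty) at data line ", bad[1])
  out <- data.frame(subject = raw$subject, condition = raw$condition,
                    session = parse_num("session", "session", TRUE),
                    trial = parse_num("trial", "trial index", TRUE),
                    stimulus_id = parse_num("stimulus_id", "stimulus id", TRUE),
                    observation = parse_num("observation", "observation"),
                    response = resp,
                    potential_reward = parse_flag("potential_reward"),
                    rewarded = parse_flag("rewarded"),
                    aborted = parse_flag("aborted"))
  if (nrow(out)) {
    viol <- which(out$rewarded %in% TRUE & out$aborted %in% TRUE)
    if (length(viol)) stop2("rewarded aborted trial at data line ", viol[1])
  }
  out
}

#' Write / read a model specification as YAML
#'
#' @param model A [model_spec()].
#' @param path File path.
#' @return `read_model()` returns a `model_spec`; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(family = model$family, gamma = model$gamma)
  if (!is.null(model$delta)) doc$delta <- as.list(model$delta)
  if (!is.null(model$upsilon)) doc$upsilon <- model$upsilon
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  model_spec(doc$family, gamma = doc$gamma,
             delta = if (!is.null(doc$delta)) unlist(doc$delta),
             upsilon = doc$upsilon)
}

#' Serialize a fit as a JSON report
#'
#' @param fit A `crit_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "crit_fit"))
  doc <- list(family = fit$family, gamma = fit$gamma,
              mu = as.list(fit$mu),
              delta = if (!is.null(fit$delta)) as.list(fit$delta),
              upsilon = fit$upsilon,
              se = as.list(fit$se), nll = fit$nll, k = fit$k, n = fit$n,
              bic = fit$bic,
              gamma_profile = fit$gamma_profile)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Export a criterion trajectory as a two-column table
#'
#' @param trajectory A `criterion_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "criterion_trajectory"))
  utils::write.table(
    data.frame(trial = seq_along(trajectory$c) - 1L, criterion = trajectory$c),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
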