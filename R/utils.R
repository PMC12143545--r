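# Internal helpers shared across modules.

stop2 <- function(...) stop(..., call. = FALSE)

assert_finite <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop2("`", name, "` must be finite numeric, got: ", paste(utils::head(x), collapse = ", "))
  invisible(x)
}

assert_prob <- function(x, name = deparse(substitute(x))) {
  assert_finite(x, name)
  if (any(x < 0 | x > 1)) stop2("`", name, "` must lie in [0, 1]")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's random-number stream is left untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop2("`seed` must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1009) %% 2147483647)
}

# Cheap 32-bit polynomial hash of a character vector; provenance stamps only.
hash32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%010.0f", h)
}
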