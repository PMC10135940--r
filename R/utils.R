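# Internal validation and seeding helpers.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (strict_min && x <= min) abort_field(field, sprintf("must be > %g", min))
  if (!strict_min && x < min) abort_field(field, sprintf("must be >= %g", min))
  if (x > max) abort_field(field, sprintf("must be <= %g", max))
  invisible(x)
}

#' Derive a stream-specific sub-seed from a global seed
#'
#' Deterministically maps a `(seed, tag)` pair to an integer in
#' `[0, 2^31 - 2]`, so that pipeline stages (simulation, splitting, weight
#' initialization, batching) draw from independent, reproducible streams that
#' all fan out from one user-facing seed.
#'
#' @param seed Integer global seed.
#' @param tag Character stream label, e.g. `"simulate"` or `"record003"`.
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  check_number(seed, "seed")
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (k in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + k) %% 2147483629
  }
  as.integer(h %% 2147483646)
}

# Evaluate fn with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
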