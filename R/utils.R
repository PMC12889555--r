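# Internal helpers shared across modules.

#' Derive a reproducible child seed
#'
#' Mixes a base seed with integer stream identifiers (donor, condition,
#' cell index, ...) so that independent simulation units get independent,
#' reproducible RNG streams. Kept below 2^31 so the result is a valid R
#' integer seed.
#'
#' @param seed base integer seed
#' @param ... integer stream identifiers
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 69069 + as.numeric(k) * 9973 + 1) %% 2147483647
  }
  as.integer(x)
}

# Evaluate code with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Format a proportion the way counts are reported: one decimal place.
format_percent <- function(k, n) {
  if (n <= 0) return(NA_character_)
  sprintf("%.1f%%", 100 * k / n)
}

condition_code <- function(condition) {
  match(condition, c("acute", "chronic"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
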