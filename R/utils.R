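# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators are pure functions of (spec, seed) via this helper.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (base round() rounds half to even).
# Matches reporting conventions like 89.15 -> 89.2.
round_half_away <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

stop_if_not_finite <- function(x, what) {
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite %s at row(s) %s", what,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
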