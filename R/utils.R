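# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible per-specimen seed from a cohort seed and an id string.
# Uses a 31-ary rolling hash over the id bytes combined with the cohort seed,
# all modulo 2^31 - 1 so the result is a valid set.seed() argument and every
# intermediate product stays well below 2^53 (exact in doubles).
derive_seed <- function(seed, id) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% m
  as.integer((h * 48271 + (as.numeric(seed) %% m)) %% m)
}

# with_seed: run code under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero at `digits` decimals (report-style rounding;
# base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
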