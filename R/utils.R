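# Internal helpers shared across modules.

# Run code under a local RNG seed without touching the caller's RNG state.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

# Expand one global seed into per-stage seeds (documented counter scheme:
# stage i gets seed*97 + i, folded into the 32-bit integer range).
stageSeed <- function(seed, stage) {
  as.integer((as.double(seed) * 97 + stage) %% .Machine$integer.max)
}

# Validate a scalar, erroring with the offending field name.
checkScalar <- function(x, field, lower = -Inf, upper = Inf,
                        integer = FALSE, strict = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("invalid config: '", field, "' must be a finite scalar",
         call. = FALSE)
  bad <- if (strict) (x <= lower || x >= upper) else (x < lower || x > upper)
  if (bad)
    stop("invalid config: '", field, "' out of range", call. = FALSE)
  if (integer && x != round(x))
    stop("invalid config: '", field, "' must be an integer", call. = FALSE)
  invisible(x)
}

# Expression assay accessor tolerant of plain matrices.
exprsOf <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x) else as.matrix(x)
}
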