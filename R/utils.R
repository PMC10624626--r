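#' @keywords internal
"_PACKAGE"

## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "fc_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fc_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## round-half-up (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)

## deterministic child seed derivation; keeps results < 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}

## quantile with fixed type so envelopes are reproducible across R versions
q_lo <- function(x) unname(stats::quantile(x, 0.025, type = 7, names = FALSE))
q_hi <- function(x) unname(stats::quantile(x, 0.975, type = 7, names = FALSE))
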