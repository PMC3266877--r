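#' Round half away from zero
#'
#' Converts printed allele frequencies back to integer allele counts. Base R's
#' `round()` rounds half to even; published tables are produced with ordinary
#' half-away-from-zero rounding, and reconstructed odds ratios depend on the
#' convention, so it is fixed here.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a per-component seed from a master seed
#'
#' Each stochastic pipeline component draws from its own stream so that adding
#' a component never perturbs the draws of another. Streams are derived
#' deterministically from the master seed and a component label; the result is
#' always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param stream character label of the component.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- digest::digest(list(as.integer(seed), as.character(stream)), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483647L)
}

## Upper-tail 1-df chi-square p-value, guarded so p is in (0, 1].
chisq_p <- function(chi2, df = 1L) {
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

## Internal: stop with a configuration error naming the offending field.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

## Internal: %||%
`%||%` <- function(a, b) if (is.null(a)) b else a
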