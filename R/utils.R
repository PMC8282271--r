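#' Round half away from zero
#'
#' Bridges printed allele frequencies back to integer allele counts. R's
#' `round()` rounds half to even; published tables are assumed to round half
#' up, so 10.8 -> 11 and 1.0 -> 1 but also 0.5 -> 1.
#'
#' @param x numeric vector, non-negative in all pipeline uses.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Canonical variant key
#'
#' Variants are keyed by `chrom:pos:ref:alt`; rs identifiers are unstable for
#' novel variants (printed as a dot in the source tables), so the key never
#' depends on them.
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Derive named substream seeds from one master seed so cohort genotypes,
# pooling and annotations can be regenerated independently. Offsets are fixed
# constants; all results stay below 2^31.
substream_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  base <- as.integer(seed %% 2147480000L)
  c(
    genotypes   = (base + 1000L) %% 2147483647L,
    pooling     = (base + 2000L) %% 2147483647L,
    annotations = (base + 3000L) %% 2147483647L
  )
}

#' Closed vocabulary of genomic region classes
#' @return character vector of admissible region labels.
#' @export
region_classes <- function() {
  c("upstream", "exonic-synonymous", "exonic-nonsynonymous", "stopgain",
    "stoploss", "frameshift", "splicing", "intronic", "utr3", "utr5")
}

# abort() with a class so tests can assert on the error family
stop_config <- function(msg, field = NULL) {
  abort(msg, class = "centiskat_config_error", field = field)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "centiskat_validation_error", ...)
}

# check a probability table sums to one
check_prob_sum <- function(p, field, tol = 1e-9) {
  if (any(p < 0)) {
    stop_config(sprintf("`%s` has negative entries", field), field = field)
  }
  if (abs(sum(p) - 1) > tol) {
    stop_config(
      sprintf("`%s` must sum to 1 (got %.12f)", field, sum(p)),
      field = field
    )
  }
  invisible(TRUE)
}
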