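# Shared constants, condition classes and small helpers.

#' Variant effect vocabulary
#'
#' The controlled vocabulary used in the `effect` column of variant tables,
#' and the subset regarded as loss-of-function for the predisposition screen
#' (truncating and canonical splice-site classes only; splice-region variants
#' are deliberately excluded).
#'
#' @return Character vector of effect labels.
#' @export
variant_effects <- function() {
  c("stopgain", "stoploss", "frameshift_indel", "inframe_indel", "missense",
    "splice_donor", "splice_acceptor", "synonymous", "other")
}

#' @rdname variant_effects
#' @export
lof_effects <- function() {
  c("stopgain", "stoploss", "frameshift_indel", "splice_donor", "splice_acceptor")
}

TIMEPOINTS <- c("INI", "REM", "REL")

# Classed conditions: validation -> exit 1, configuration -> exit 2 in the CLI.
rt_abort <- function(msg, class = "rt_validation_error") {
  stop(errorCondition(msg, class = c(class, "rt_error", "error", "condition")))
}

rt_config_error <- function(msg) rt_abort(msg, "rt_config_error")
rt_format_error <- function(msg) rt_abort(msg, "rt_format_error")
rt_integrity_error <- function(msg) rt_abort(msg, "rt_integrity_error")

#' Round half away from zero
#'
#' Printed-percent convention: 90.5 -> 91, not banker's rounding.
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Variant identity key
#'
#' Canonical `(chrom, pos, ref, alt)` key used for matching variants across
#' timepoints; timepoint and read counts are deliberately not part of the key.
#'
#' @param variants variant table (data.frame), see [variant_table()].
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Effective allele frequency: purity-adjusted when available.
effective_af <- function(variants) {
  af <- variants$af
  if (!is.null(variants$af_adjusted)) {
    adj <- !is.na(variants$af_adjusted)
    af[adj] <- variants$af_adjusted[adj]
  }
  af
}
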