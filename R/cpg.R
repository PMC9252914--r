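# Constitutional cancer-predisposition gene (CPG) screen on remission
# variants, and the carrier-enrichment contingency table.

#' Filter remission variants for constitutional CPG loss-of-function
#'
#' Retains exactly the remission variants that are (1) constitutional by AF
#' (`af >= af_min`, the heterozygous-germline convention), (2) of a
#' loss-of-function class — stopgain, stoploss, frameshift indel, splice
#' donor or splice acceptor (splice-region and missense variants are
#' excluded), and (3) in a listed predisposition gene. Order is preserved;
#' the filter is a pure predicate.
#'
#' @param rem_variants variant table of REM-timepoint records.
#' @param gene_list character vector of predisposition gene symbols.
#' @param af_min constitutional AF threshold.
#' @return subset of `rem_variants`.
#' @export
filter_cpg_variants <- function(rem_variants, gene_list, af_min = 0.30) {
  if (length(gene_list) == 0) rt_config_error("empty predisposition gene list")
  v <- rem_variants
  keep <- !is.na(v$af) & v$af >= af_min &
    v$effect %in% lof_effects() &
    v$gene %in% gene_list
  v[keep, , drop = FALSE]
}

#' Carrier contingency table by relapse type
#'
#' A patient is a carrier when at least one variant survived the CPG filter.
#' Returns the 2x2 table with rows TYPE1 / TYPE2 and columns
#' carrier / non-carrier; marginals reconstruct the cohort sizes.
#' UNEVALUABLE cases are rejected.
#'
#' @param cases data.frame with columns `patient_id`, `relapse_type`
#'   (TYPE1/TYPE2) and `n_retained_variants`.
#' @return 2x2 integer matrix.
#' @export
carrier_table <- function(cases) {
  need <- c("patient_id", "relapse_type", "n_retained_variants")
  if (!all(need %in% names(cases)))
    rt_format_error("cases need patient_id, relapse_type, n_retained_variants")
  bad <- !cases$relapse_type %in% c("TYPE1", "TYPE2")
  if (any(bad))
    rt_abort(paste("UNEVALUABLE or unknown relapse type for:",
                   paste(cases$patient_id[bad], collapse = ", ")))
  carrier <- cases$n_retained_variants >= 1
  m <- matrix(0L, 2, 2, dimnames = list(c("TYPE1", "TYPE2"),
                                        c("carrier", "non_carrier")))
  for (ty in c("TYPE1", "TYPE2")) {
    sel <- cases$relapse_type == ty
    m[ty, "carrier"] <- sum(sel & carrier)
    m[ty, "non_carrier"] <- sum(sel & !carrier)
  }
  m
}
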