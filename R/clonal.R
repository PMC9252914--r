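# Type-1 / type-2 relapse classification from matched diagnosis-relapse
# allele frequencies.
#
# Type-1: all clonal (AF >= 30%) somatic diagnosis mutations are preserved at
# relapse (relapse derives from the major diagnostic clone). Type-2: a subset
# of clonal diagnosis mutations is lost (relapse derives from a minor
# ancestral clone that expanded after the major clone was eradicated).

#' Partition variants into clonal and subclonal
#'
#' Clonal iff effective allele frequency (purity-adjusted when available) is
#' at or above `threshold`; the 30% boundary is inclusive.
#'
#' @param variants variant table.
#' @param threshold clonality AF threshold, in (0, 1).
#' @return list of key vectors `clonal` and `subclonal` (disjoint,
#'   exhaustive over rows with defined AF).
#' @export
partition_clonality <- function(variants, threshold = 0.30) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    rt_abort("clonality threshold must lie in (0, 1)")
  af <- effective_af(variants)
  keys <- variant_key(variants)
  list(clonal = keys[!is.na(af) & af >= threshold],
       subclonal = keys[!is.na(af) & af < threshold])
}

#' Call the fate of a diagnosis variant at relapse
#'
#' Given the relapse pileup at the diagnosis variant's locus: LOST when the
#' relapse AF is below `absent_af` with at least `min_depth` reads (absence
#' is only trusted at adequate coverage); PRESERVED when the relapse AF
#' reaches `absent_af`; UNEVALUABLE below `min_depth`.
#'
#' @param alt_count,depth relapse-sample pileup counts at the locus.
#' @param absent_af AF below which the variant counts as absent.
#' @param min_depth minimum relapse depth required to call a loss.
#' @return one of `"PRESERVED"`, `"LOST"`, `"UNEVALUABLE"`.
#' @export
call_site_fate <- function(alt_count, depth, absent_af = 0.02, min_depth = 20) {
  if (any(c(alt_count, depth) < 0)) rt_abort("negative pileup counts")
  if (depth < min_depth) return("UNEVALUABLE")
  af <- if (depth > 0) alt_count / depth else 0
  if (af < absent_af) "LOST" else "PRESERVED"
}

new_classification_result <- function(patient_id) {
  structure(list(patient_id = patient_id, relapse_type = "UNEVALUABLE",
                 preserved = character(), lost = character(),
                 gained = character(), unevaluable_sites = character(),
                 n_clonal_ini = 0L, n_subclonal_ini = 0L,
                 n_clonal_rel = 0L, n_subclonal_rel = 0L,
                 n_lost_clonal = 0L, n_rel_coding = 0L,
                 n_acquired = 0L, n_acquired_coding = 0L,
                 flags = character(), detail = NULL),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification %s> %s | preserved %d, lost %d, gained %d | flags: %s\n",
              x$patient_id, x$relapse_type, length(x$preserved), length(x$lost),
              length(x$gained),
              if (length(x$flags)) paste(x$flags, collapse = ",") else "-"))
  invisible(x)
}

#' Classify a relapse as type-1 or type-2
#'
#' Runs the full per-patient decision: somatic/constitutional partition
#' against the remission sample, purity correction of low-blast timepoints,
#' clonality partition of the diagnosis variants, per-site fate calls at
#' relapse, and the type decision — TYPE2 when at least `min_lost` clonal
#' somatic diagnosis variants are confidently lost, TYPE1 when none are lost
#' and at least one clonal diagnosis variant was evaluable, UNEVALUABLE when
#' no clonal diagnosis variant could be evaluated. Gained variants are
#' relapse somatic variants absent at diagnosis (computed with the symmetric
#' absence rule).
#'
#' @param case a [patient_case()] with all three timepoints.
#' @param clonal_threshold AF threshold for clonality (boundary inclusive).
#' @param min_lost number of confidently lost clonal diagnosis variants
#'   required for a TYPE2 call.
#' @param absent_af,min_depth absence rule at the other timepoint, see
#'   [call_site_fate()].
#' @param purity_trigger blast fraction below which AFs are purity-corrected
#'   before thresholding.
#' @param low_blast_flag blast fraction below which the case is additionally
#'   flagged `low_blast`.
#' @param rem_af_const,rem_af_absent,min_rem_depth forwarded to
#'   [partition_somatic_constitutional()].
#' @return object of class `classification_result` with the
#'   preserved/lost/gained key partitions, the four clonality-cell counts, a
#'   per-variant `detail` data.frame and flags (`purity_corrected`,
#'   `low_coverage_losses`, `low_blast`, later `cna_confirmed_type2`,
#'   `hypermutator`).
#' @export
classify_relapse <- function(case, clonal_threshold = 0.30, min_lost = 1L,
                             absent_af = 0.02, min_depth = 20L,
                             purity_trigger = 0.8, low_blast_flag = 0.2,
                             rem_af_const = 0.30, rem_af_absent = 0.05,
                             min_rem_depth = 10L) {
  stopifnot(inherits(case, "patient_case"))
  if (nrow(case_timepoint(case, "REL")) == 0)
    rt_config_error(paste0(case$patient_id, ": relapse (REL) timepoint required"))
  res <- new_classification_result(case$patient_id)

  part <- partition_somatic_constitutional(case, rem_af_const, rem_af_absent,
                                           min_rem_depth)
  ini <- case_timepoint(case, "INI")
  rel <- case_timepoint(case, "REL")
  for (tp in c("INI", "REL")) {
    bf <- case$blast_fraction[[tp]]
    if (!is.na(bf) && bf < purity_trigger) {
      if (tp == "INI") ini <- correct_af_for_purity(ini, bf, purity_trigger)
      else rel <- correct_af_for_purity(rel, bf, purity_trigger)
      res$flags <- union(res$flags, "purity_corrected")
      if (bf < low_blast_flag) res$flags <- union(res$flags, "low_blast")
    }
  }
  ini_key <- variant_key(ini)
  rel_key <- variant_key(rel)

  # clonality of detected somatic variants at each timepoint
  ini_som <- ini[ini_key %in% part$somatic_ini, , drop = FALSE]
  rel_som <- rel[rel_key %in% part$somatic_rel, , drop = FALSE]
  clon_ini <- partition_clonality(ini_som, clonal_threshold)
  clon_rel <- partition_clonality(rel_som, clonal_threshold)
  res$n_clonal_ini <- length(clon_ini$clonal)
  res$n_subclonal_ini <- length(clon_ini$subclonal)
  res$n_clonal_rel <- length(clon_rel$clonal)
  res$n_subclonal_rel <- length(clon_rel$subclonal)

  # fate of every somatic diagnosis variant at relapse
  idx_rel <- match(variant_key(ini_som), rel_key)
  fates <- vapply(seq_len(nrow(ini_som)), function(i) {
    j <- idx_rel[i]
    if (is.na(j)) return("UNEVALUABLE")  # no relapse pileup at this locus
    call_site_fate(rel$alt_count[j], rel$depth[j], absent_af, min_depth)
  }, character(1))
  keys_som <- variant_key(ini_som)
  res$preserved <- keys_som[fates == "PRESERVED"]
  res$lost <- keys_som[fates == "LOST"]
  res$unevaluable_sites <- keys_som[fates == "UNEVALUABLE"]

  # gained: relapse somatic variants absent at diagnosis (symmetric rule)
  idx_ini <- match(variant_key(rel_som), ini_key)
  ini_fate <- vapply(seq_len(nrow(rel_som)), function(i) {
    j <- idx_ini[i]
    if (is.na(j)) return("UNEVALUABLE")
    call_site_fate(ini$alt_count[j], ini$depth[j], absent_af, min_depth)
  }, character(1))
  res$gained <- variant_key(rel_som)[ini_fate == "LOST"]

  is_clonal <- keys_som %in% clon_ini$clonal
  lost_clonal <- sum(fates == "LOST" & is_clonal)
  uneval_clonal <- sum(fates == "UNEVALUABLE" & is_clonal)
  eval_clonal <- sum(fates != "UNEVALUABLE" & is_clonal)
  res$n_lost_clonal <- lost_clonal
  if (uneval_clonal > 0) res$flags <- union(res$flags, "low_coverage_losses")
  res$relapse_type <-
    if (lost_clonal >= min_lost) "TYPE2"
    else if (eval_clonal >= 1 && lost_clonal == 0) "TYPE1"
    else "UNEVALUABLE"

  # relapse mutational load (coding): preserved + gained coding variants
  rel_coding_keys <- variant_key(rel_som)[rel_som$coding]
  res$n_rel_coding <- sum(rel_coding_keys %in% c(res$preserved, res$gained))
  res$n_acquired <- length(res$gained)
  res$n_acquired_coding <- sum(res$gained %in% rel_coding_keys)

  res$detail <- data.frame(
    key = keys_som,
    fate = fates,
    clonal_ini = is_clonal,
    coding = ini_som$coding,
    af_ini = effective_af(ini_som),
    af_rel = rel$af[idx_rel],
    stringsAsFactors = FALSE
  )
  res <- flag_hypermutator(res)
  res
}

#' Flag hypermutator relapses
#'
#' A relapse is a hypermutator when it carries more than `threshold` coding
#' somatic mutations (preserved plus gained; strict inequality, so exactly
#' `threshold` does not qualify).
#'
#' @param result a `classification_result`.
#' @param threshold coding-mutation count that must be exceeded.
#' @return the result with the `hypermutator` flag set or cleared.
#' @export
flag_hypermutator <- function(result, threshold = 85L) {
  stopifnot(inherits(result, "classification_result"))
  if (result$n_rel_coding > threshold) {
    result$flags <- union(result$flags, "hypermutator")
  } else {
    result$flags <- setdiff(result$flags, "hypermutator")
  }
  result
}

#' Is a classification flagged as hypermutator?
#' @param result a `classification_result`.
#' @return logical.
#' @export
is_hypermutator <- function(result) "hypermutator" %in% result$flags

#' Tabulate a per-patient classification report
#'
#' One row per somatic diagnosis variant with its fate, clonality and AF at
#' both timepoints — the per-patient TSV payload.
#'
#' @param result a `classification_result`.
#' @return data.frame.
#' @export
classification_report <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  cbind(patient_id = result$patient_id, relapse_type = result$relapse_type,
        result$detail)
}
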