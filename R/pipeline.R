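# End-to-end orchestration: per-patient classification runs, cohort
# aggregation, and the command-line entry point. The CLI is a thin shell —
# every reported number is reproducible by direct module calls.

#' Default pipeline configuration
#'
#' Every threshold used anywhere in the pipeline, with its package default;
#' all values can be overridden (and a run's report records the effective
#' configuration).
#'
#' @return named list.
#' @export
pipeline_config <- function() {
  list(clonal_threshold = 0.30, min_lost = 1L,
       absent_af = 0.02, min_depth = 20L,
       rem_af_const = 0.30, rem_af_absent = 0.05, min_rem_depth = 10L,
       purity_trigger = 0.8, low_blast_flag = 0.2,
       hypermutator_threshold = 85L,
       cna_min_ro = 0.5,
       cpg_af_min = 0.30,
       dominant_min_share = 0.4)
}

merge_config <- function(overrides = list()) {
  cfg <- pipeline_config()
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0)
    rt_config_error(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the per-patient pipeline
#'
#' Classifies one matched trio: somatic partition, purity correction,
#' type-1/type-2 call, CNA concordance (when both profiles are present) and
#' hypermutator flag. Writes a per-variant TSV and a JSON summary when `out`
#' is given.
#'
#' @param case a [patient_case()].
#' @param config named list of overrides for [pipeline_config()].
#' @param out optional output directory.
#' @return list with `classification`, `cna` (or `NULL`) and `config`.
#' @export
run_patient <- function(case, config = list(), out = NULL) {
  cfg <- merge_config(config)
  cls <- classify_relapse(case,
                          clonal_threshold = cfg$clonal_threshold,
                          min_lost = cfg$min_lost,
                          absent_af = cfg$absent_af, min_depth = cfg$min_depth,
                          purity_trigger = cfg$purity_trigger,
                          low_blast_flag = cfg$low_blast_flag,
                          rem_af_const = cfg$rem_af_const,
                          rem_af_absent = cfg$rem_af_absent,
                          min_rem_depth = cfg$min_rem_depth)
  cls <- flag_hypermutator(cls, cfg$hypermutator_threshold)
  cna_cmp <- NULL
  if (!is.null(case$cna$INI) && !is.null(case$cna$REL)) {
    cna_cmp <- compare_cna_profiles(case$cna$INI, case$cna$REL,
                                    min_ro = cfg$cna_min_ro)
    cls <- confirm_type2(cls, cna_cmp)
  }
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(classification_report(cls),
                       file.path(out, paste0(case$patient_id, ".variants.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(patient_id = cls$patient_id, relapse_type = cls$relapse_type,
           n_preserved = length(cls$preserved), n_lost = length(cls$lost),
           n_gained = length(cls$gained), n_lost_clonal = cls$n_lost_clonal,
           n_clonal_ini = cls$n_clonal_ini, n_subclonal_ini = cls$n_subclonal_ini,
           n_clonal_rel = cls$n_clonal_rel, n_subclonal_rel = cls$n_subclonal_rel,
           n_rel_coding = cls$n_rel_coding, flags = cls$flags,
           cna_profile_loss = if (is.null(cna_cmp)) NA else cna_cmp$profile_loss,
           config = cfg),
      file.path(out, paste0(case$patient_id, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(classification = cls, cna = cna_cmp, config = cfg)
}

#' Load a fixture directory into patient cases
#'
#' Reads the per-patient files written by [simulate_cohort()] (variant TSVs,
#' CNA BEDs, blast fractions, outcomes) back into [patient_case()] objects.
#'
#' @param dir fixture directory.
#' @return list of cases.
#' @export
load_cohort_dir <- function(dir) {
  vfiles <- list.files(dir, pattern = "\\.variants\\.tsv$", full.names = TRUE)
  if (length(vfiles) == 0)
    rt_config_error(paste("no *.variants.tsv files under", dir))
  blast <- outcomes <- NULL
  if (file.exists(file.path(dir, "blast.tsv")))
    blast <- utils::read.table(file.path(dir, "blast.tsv"), header = TRUE, sep = "\t")
  if (file.exists(file.path(dir, "outcomes.tsv")))
    outcomes <- utils::read.table(file.path(dir, "outcomes.tsv"), header = TRUE, sep = "\t")
  lapply(vfiles, function(vf) {
    pid <- sub("\\.variants\\.tsv$", "", basename(vf))
    variants <- read_variant_table(vf, "tsv")
    cna <- list()
    for (tp in c("INI", "REL")) {
      bed <- file.path(dir, paste0(pid, ".cna_", tp, ".bed"))
      if (file.exists(bed)) cna[[tp]] <- read_cna_segments(bed)
    }
    bf <- NULL
    if (!is.null(blast)) {
      b <- blast[blast$patient_id == pid, ]
      if (nrow(b)) bf <- stats::setNames(b$blast_fraction, b$timepoint)
    }
    ttr <- NA_integer_; ev <- NA
    if (!is.null(outcomes)) {
      o <- outcomes[outcomes$patient_id == pid, ]
      if (nrow(o)) { ttr <- o$time_to_relapse_days[1]; ev <- o$event_after_relapse[1] == 1 }
    }
    patient_case(pid, variants, blast_fraction = bf, cna = cna,
                 time_to_relapse_days = ttr, event_after_relapse = ev)
  })
}

#' Run the cohort-level pipeline
#'
#' Classifies every case, aggregates the per-type mutation bookkeeping, and
#' reproduces the cohort statistics: Fisher exact tests on the
#' clonal/subclonal tables at diagnosis and relapse, the unpaired Welch t on
#' acquired-mutation counts, the log-rank test on time to relapse, and —
#' when a predisposition gene list is available — the carrier-enrichment
#' Fisher test. Writes a JSON + TSV bundle when `out` is given.
#'
#' @param cases list of [patient_case()] objects (e.g. [load_cohort_dir()]).
#' @param cpg_genes optional character vector of predisposition gene symbols.
#' @param config overrides for [pipeline_config()].
#' @param out optional output directory.
#' @return list with `classifications`, `summary`, `stats`, `cpg`, `config`.
#' @export
run_cohort <- function(cases, cpg_genes = NULL, config = list(), out = NULL) {
  cfg <- merge_config(config)
  if (length(cases) < 2) rt_config_error("cohort run needs at least 2 cases")
  runs <- lapply(cases, run_patient, config = config)
  cls <- lapply(runs, `[[`, "classification")
  evaluable <- vapply(cls, function(r) r$relapse_type != "UNEVALUABLE", logical(1))
  if (sum(evaluable) < 2)
    rt_config_error("fewer than 2 evaluable cases: cannot aggregate")
  summ <- cohort_summary(cls[evaluable])

  stats_out <- list()
  stats_out$fisher_clonality_ini <- fisher_exact_two_sided(summ$clonality_ini)
  stats_out$fisher_clonality_rel <- fisher_exact_two_sided(summ$clonality_rel)
  type <- vapply(cls, `[[`, character(1), "relapse_type")
  acq1 <- vapply(cls[type == "TYPE1"], `[[`, numeric(1), "n_acquired")
  acq2 <- vapply(cls[type == "TYPE2"], `[[`, numeric(1), "n_acquired")
  if (length(acq1) >= 2 && length(acq2) >= 2) {
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    stats_out$welch_acquired <- welch_t_from_summary(
      mean(acq1), sem(acq1), length(acq1), mean(acq2), sem(acq2), length(acq2))
  }
  ttr <- vapply(cases, function(cs) as.numeric(cs$time_to_relapse_days %||% NA),
                numeric(1))
  has_ttr <- !is.na(ttr) & type %in% c("TYPE1", "TYPE2")
  if (length(unique(type[has_ttr])) == 2) {
    # time-to-relapse comparison: relapse occurred in everyone (no censoring)
    stats_out$logrank_ttr <- logrank_two_groups(
      ttr[has_ttr & type == "TYPE1"], rep(1, sum(has_ttr & type == "TYPE1")),
      ttr[has_ttr & type == "TYPE2"], rep(1, sum(has_ttr & type == "TYPE2")))
  }

  cpg_out <- NULL
  if (!is.null(cpg_genes)) {
    if (!all(type[evaluable] %in% c("TYPE1", "TYPE2")) ||
        length(unique(type[evaluable])) < 2) {
      message("CPG enrichment skipped: need both TYPE1 and TYPE2 cases")
    } else {
      carriers <- do.call(rbind, lapply(which(evaluable), function(i) {
        rem <- case_timepoint(cases[[i]], "REM")
        hits <- filter_cpg_variants(rem, cpg_genes, af_min = cfg$cpg_af_min)
        data.frame(patient_id = cases[[i]]$patient_id, relapse_type = type[i],
                   n_retained_variants = nrow(hits), stringsAsFactors = FALSE)
      }))
      tab <- carrier_table(carriers)
      cpg_out <- list(carriers = carriers, table = tab,
                      fisher_p = fisher_exact_two_sided(tab))
    }
  }

  report <- list(
    n_cases = length(cases), per_type = summ$per_type,
    clonality_ini = summ$clonality_ini, clonality_rel = summ$clonality_rel,
    stats = stats_out,
    cpg_table = if (!is.null(cpg_out)) cpg_out$table,
    cpg_fisher_p = if (!is.null(cpg_out)) cpg_out$fisher_p,
    config = cfg)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    per_patient <- do.call(rbind, lapply(cls, function(r) data.frame(
      patient_id = r$patient_id, relapse_type = r$relapse_type,
      n_preserved = length(r$preserved), n_lost = length(r$lost),
      n_gained = length(r$gained), n_lost_clonal = r$n_lost_clonal,
      n_clonal_ini = r$n_clonal_ini, n_subclonal_ini = r$n_subclonal_ini,
      n_clonal_rel = r$n_clonal_rel, n_subclonal_rel = r$n_subclonal_rel,
      n_rel_coding = r$n_rel_coding,
      flags = paste(r$flags, collapse = ","), stringsAsFactors = FALSE)))
    utils::write.table(per_patient, file.path(out, "cohort_patients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out, "cohort_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  list(classifications = cls, summary = summ, stats = stats_out,
       cpg = cpg_out, config = cfg, report = report)
}
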