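# Variant and CNA segment I/O: TSV and minimal-VCF dialects, patient cases,
# somatic/constitutional partition, purity correction and variant matching.

VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "alt_count", "depth", "af",
                  "effect", "gene", "coding", "timepoint", "patient_id")

#' Construct and validate a variant table
#'
#' Variants are kept in a plain data.frame, one row per
#' `(chrom, pos, ref, alt, timepoint)` record, with read support
#' (`alt_count`, `depth`), allele frequency `af` (`alt_count / depth`, `NA`
#' at zero depth), functional `effect` (see [variant_effects()]), `gene`
#' symbol (possibly empty), a `coding` flag and the `timepoint`
#' (INI / REM / REL). Positions are 1-based (VCF convention).
#'
#' @param df data.frame carrying at least the columns named above (`af` is
#'   recomputed from the counts).
#' @return validated data.frame with canonical column order.
#' @export
variant_table <- function(df) {
  missing_cols <- setdiff(setdiff(VARIANT_COLS, "af"), names(df))
  if (length(missing_cols) > 0)
    rt_format_error(paste("variant table lacks columns:",
                          paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$pos <- as.integer(df$pos)
  df$alt_count <- as.integer(df$alt_count)
  df$depth <- as.integer(df$depth)
  df$coding <- as.logical(df$coding)
  df$gene[is.na(df$gene)] <- ""
  df$af <- ifelse(df$depth > 0, df$alt_count / df$depth, NA_real_)

  if (any(df$pos < 1)) rt_abort("variant pos must be >= 1")
  if (any(df$alt_count < 0) || any(df$depth < 0))
    rt_abort("negative read counts in variant table")
  if (any(df$alt_count > df$depth)) {
    bad <- which(df$alt_count > df$depth)[1]
    rt_abort(sprintf("alt_count > depth at %s:%d", df$chrom[bad], df$pos[bad]))
  }
  if (any(df$depth == 0 & df$alt_count > 0))
    rt_abort("record with depth 0 but alt_count > 0")
  if (any(df$ref == df$alt)) rt_abort("ref equal to alt in variant table")
  if (!all(df$effect %in% variant_effects()))
    rt_format_error(paste("unknown effect label(s):",
                          paste(setdiff(unique(df$effect), variant_effects()),
                                collapse = ", ")))
  if (!all(df$timepoint %in% TIMEPOINTS))
    rt_format_error("timepoint must be one of INI, REM, REL")
  extra <- setdiff(names(df), VARIANT_COLS)
  df[, c(VARIANT_COLS, extra), drop = FALSE]
}

#' Read a variant table
#'
#' Two dialects are supported. `"tsv"` is a header-bearing tab-separated file
#' with columns `chrom pos ref alt alt_count depth effect gene coding
#' timepoint patient_id`. `"vcf"` is a VCF 4.2 subset with per-alt `EFF`,
#' `GENE`, `CODING`, `TP` INFO tags and a FORMAT `AD` (ref,alt depths) field
#' for one sample whose name is the patient id; multi-allelic rows are split
#' into one record per alternate allele and `depth` is the sum of the AD
#' entries.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return variant table (see [variant_table()]).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) rt_config_error(paste("no such file:", path))
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "",
                            comment.char = "")
    need <- setdiff(VARIANT_COLS, "af")
    if (!all(need %in% names(df)))
      rt_format_error(paste("TSV header must contain:", paste(need, collapse = " ")))
    return(variant_table(df))
  }
  read_variant_vcf(path)
}

read_variant_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  hdr_fmt <- rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))
  if (!"AD" %in% hdr_fmt)
    rt_format_error("VCF dialect requires a FORMAT/AD (allelic depths) field")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) rt_format_error("VCF has no AD genotype data")
  sample_id <- colnames(vcf)[1]
  # after expand(): AD holds (ref, alt) depth pairs per record, either as a
  # records x samples x 2 array or as a list-matrix
  pairs <- if (is.array(ad) && length(dim(ad)) == 3) {
    lapply(seq_len(dim(ad)[1]), function(i) ad[i, 1, ])
  } else {
    ad[, 1]
  }
  ad_mat <- t(vapply(pairs, function(x) {
    if (length(x) < 2 || anyNA(x)) rt_format_error("missing AD depths in VCF record")
    c(x[1], sum(x) - x[1], sum(x))
  }, numeric(3)))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    alt_count = as.integer(round(ad_mat[, 2])),
    depth = as.integer(round(ad_mat[, 3])),
    effect = as.character(info$EFF %||% rep("other", nrow(ad_mat))),
    gene = as.character(info$GENE %||% rep("", nrow(ad_mat))),
    coding = as.logical(info$CODING %||% rep(FALSE, nrow(ad_mat))),
    timepoint = as.character(info$TP %||% rep("INI", nrow(ad_mat))),
    patient_id = sample_id,
    stringsAsFactors = FALSE
  )
  variant_table(df)
}

#' Write a variant table (TSV dialect)
#'
#' Stable column order; reading the file back with
#' `read_variant_table(dialect = "tsv")` reproduces all fields.
#'
#' @param variants variant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  variants <- variant_table(variants)
  utils::write.table(variants[, setdiff(VARIANT_COLS, "af")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a patient's variants as a minimal VCF
#'
#' One sample column (the patient id), FORMAT `AD` with ref/alt depths and
#' INFO tags `EFF`, `GENE`, `CODING`, `TP` carrying annotation and timepoint.
#'
#' @param variants variant table for a single patient.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  variants <- variant_table(variants)
  pid <- unique(variants$patient_id)
  if (length(pid) != 1) rt_abort("VCF writer takes a single patient's variants")
  ord <- order(variants$chrom, variants$pos, variants$alt, variants$timepoint)
  v <- variants[ord, ]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Functional effect\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CODING,Number=0,Type=Flag,Description=\"Coding variant\">",
    "##INFO=<ID=TP,Number=1,Type=String,Description=\"Timepoint INI/REM/REL\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", pid, sep = "\t")
  )
  info <- sprintf("EFF=%s;GENE=%s%s;TP=%s", v$effect,
                  ifelse(v$gene == "", ".", v$gene),
                  ifelse(v$coding, ";CODING", ""), v$timepoint)
  ad <- sprintf("%d,%d", v$depth - v$alt_count, v$alt_count)
  rows <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "AD", ad,
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Construct a patient case
#'
#' Bundles the matched trio for one patient: variant records for the INI
#' (initial diagnosis), REM (remission, day 33) and REL (relapse) timepoints,
#' optional blast-content fractions per timepoint, optional CNA/CN-LOH segment
#' profiles per timepoint, and optional outcome data.
#'
#' @param patient_id patient identifier.
#' @param variants variant table with a `timepoint` column.
#' @param blast_fraction named numeric vector, names in INI/REM/REL, values in
#'   (0, 1]; `NA` or missing names mean unknown.
#' @param cna named list of CNA segment tables (see [cna_segments()]).
#' @param time_to_relapse_days non-negative integer or `NA`.
#' @param event_after_relapse logical (`TRUE` = death/second relapse observed,
#'   `FALSE` = censored) or `NA`.
#' @return object of class `patient_case`.
#' @export
patient_case <- function(patient_id, variants, blast_fraction = NULL,
                         cna = list(), time_to_relapse_days = NA_integer_,
                         event_after_relapse = NA) {
  variants <- variant_table(variants)
  bf <- c(INI = NA_real_, REM = NA_real_, REL = NA_real_)
  if (!is.null(blast_fraction)) {
    if (is.null(names(blast_fraction)) ||
        !all(names(blast_fraction) %in% TIMEPOINTS))
      rt_config_error("blast_fraction must be named with INI/REM/REL")
    if (any(!is.na(blast_fraction) & (blast_fraction <= 0 | blast_fraction > 1)))
      rt_abort("blast_fraction must lie in (0, 1]")
    bf[names(blast_fraction)] <- blast_fraction
  }
  structure(list(patient_id = patient_id, variants = variants,
                 blast_fraction = bf, cna = cna,
                 time_to_relapse_days = time_to_relapse_days,
                 event_after_relapse = event_after_relapse),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  tp <- table(factor(x$variants$timepoint, TIMEPOINTS))
  cat(sprintf("<patient_case %s> variants INI/REM/REL: %d/%d/%d\n",
              x$patient_id, tp["INI"], tp["REM"], tp["REL"]))
  invisible(x)
}

case_timepoint <- function(case, tp) {
  case$variants[case$variants$timepoint == tp, , drop = FALSE]
}

#' Partition variants into somatic and constitutional sets
#'
#' Uses the remission (REM) sample as the constitutional reference: a variant
#' observed at diagnosis or relapse is called constitutional when its
#' remission allele frequency is at least `rem_af_const` (the AF >= 30%
#' convention for heterozygous germline variants), somatic when it is
#' essentially absent in remission (`af < rem_af_absent` at depth
#' `>= min_rem_depth`), and unevaluable otherwise (including sites without a
#' remission record). Only the constitutional AF cutoff is a field
#' convention; the absence thresholds are declared package defaults.
#'
#' @param case a [patient_case()]; the REM timepoint must be present.
#' @param rem_af_const remission AF at/above which a variant is constitutional.
#' @param rem_af_absent remission AF below which a variant is somatic.
#' @param min_rem_depth minimum remission depth to trust absence.
#' @return list with character-key vectors `somatic_ini`, `somatic_rel`,
#'   `constitutional`, `unevaluable`, and a `status` data.frame (one row per
#'   distinct detected variant). The three statuses partition the distinct
#'   input keys.
#' @export
partition_somatic_constitutional <- function(case, rem_af_const = 0.30,
                                             rem_af_absent = 0.05,
                                             min_rem_depth = 10) {
  stopifnot(inherits(case, "patient_case"))
  rem <- case_timepoint(case, "REM")
  if (nrow(rem) == 0)
    rt_config_error(paste0(case$patient_id,
                           ": remission (REM) timepoint required for somatic/constitutional partition"))
  ini <- case_timepoint(case, "INI")
  rel <- case_timepoint(case, "REL")
  ini_keys <- variant_key(ini)[ini$alt_count > 0]
  rel_keys <- variant_key(rel)[rel$alt_count > 0]
  keys <- unique(c(ini_keys, rel_keys))
  rem_key <- variant_key(rem)
  idx <- match(keys, rem_key)
  rem_af <- rem$af[idx]
  rem_depth <- rem$depth[idx]
  status <- rep("unevaluable", length(keys))
  known <- !is.na(idx) & !is.na(rem_af)
  status[known & rem_af >= rem_af_const] <- "constitutional"
  status[known & rem_af < rem_af_absent & rem_depth >= min_rem_depth] <- "somatic"
  somatic <- keys[status == "somatic"]
  list(somatic_ini = intersect(ini_keys, somatic),
       somatic_rel = intersect(rel_keys, somatic),
       constitutional = keys[status == "constitutional"],
       unevaluable = keys[status == "unevaluable"],
       status = data.frame(key = keys, status = status,
                           stringsAsFactors = FALSE))
}

#' Correct allele frequencies for blast content (tumor purity)
#'
#' Observed AF is diluted by normal-cell contamination. When the blast
#' fraction of a sample falls below `trigger_below`, adjusted frequencies
#' `af / blast_fraction` (capped at 1) are stored in an `af_adjusted` column
#' and a `purity_corrected` flag is set; otherwise records are returned
#' unchanged, mirroring the convention of correcting only clearly contaminated
#' samples.
#'
#' @param variants variant table (one timepoint of one sample).
#' @param blast_fraction fraction of leukemic blasts in the sample, in (0, 1].
#' @param trigger_below correction is applied only below this blast fraction.
#' @return variant table, possibly with `af_adjusted` and `purity_corrected`
#'   columns.
#' @export
correct_af_for_purity <- function(variants, blast_fraction, trigger_below = 0.8) {
  if (is.na(blast_fraction) || blast_fraction <= 0 || blast_fraction > 1)
    rt_abort("blast_fraction must lie in (0, 1]")
  variants <- variant_table(variants)
  if (blast_fraction >= trigger_below) return(variants)
  variants$af_adjusted <- pmin(variants$af / blast_fraction, 1.0)
  variants$purity_corrected <- TRUE
  variants
}

#' Match two variant lists by identity key
#'
#' Buckets variants into shared / only-a / only-b on the
#' `(chrom, pos, ref, alt)` key; timepoint and read counts are ignored.
#' Indels are matched on verbatim alleles — normalize (left-align) upstream.
#'
#' @param a,b variant tables.
#' @return list of key character vectors `shared`, `only_a`, `only_b`.
#' @export
match_variants <- function(a, b) {
  ka <- variant_key(a)
  kb <- variant_key(b)
  for (side in list(c("a", "ka"), c("b", "kb"))) {
    k <- get(side[2])
    if (anyDuplicated(k))
      rt_abort(sprintf("duplicate variant key in list %s: %s", side[1],
                       k[duplicated(k)][1]))
  }
  list(shared = intersect(ka, kb),
       only_a = setdiff(ka, kb),
       only_b = setdiff(kb, ka))
}

#' Read a cancer-predisposition gene list
#'
#' Plain text, one gene symbol per line; `#` starts a comment.
#'
#' @param path file path.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) rt_config_error(paste("no such file:", path))
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines[nzchar(lines)]
}
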