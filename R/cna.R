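# CNA / CN-LOH segment handling and INI-vs-REL profile concordance.

CNA_STATES <- c("gain", "loss", "cnloh")

#' Construct and validate a CNA segment table
#'
#' Segments use BED convention: 0-based half-open `[start, end)` intervals
#' with an aberrant `state` in `gain` / `loss` / `cnloh` and an optional
#' `logratio`. Copy-neutral diploid segments are not stored.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `state` and
#'   optionally `logratio`.
#' @return validated data.frame.
#' @export
cna_segments <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "state")
  if (!all(need %in% names(df)))
    rt_format_error("CNA segments need columns chrom, start, end, state")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (is.null(df$logratio)) df$logratio <- rep(NA_real_, nrow(df))
  if (any(df$start >= df$end)) rt_abort("CNA segment with start >= end (zero length)")
  if (!all(df$state %in% CNA_STATES))
    rt_format_error("CNA state must be gain, loss or cnloh")
  df[, c("chrom", "start", "end", "state", "logratio")]
}

#' Read CNA segments from a BED4+ file
#'
#' Columns: `chrom start end state [logratio]`, tab-separated, no header.
#'
#' @param path file path.
#' @return CNA segment table.
#' @export
read_cna_segments <- function(path) {
  if (!file.exists(path)) rt_config_error(paste("no such file:", path))
  if (length(readLines(path, n = 1)) == 0) {  # empty profile (no aberrations)
    return(cna_segments(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), state = character())))
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  names(df)[1:4] <- c("chrom", "start", "end", "state")
  if (ncol(df) >= 5) names(df)[5] <- "logratio"
  if (!is.null(df$logratio)) df$logratio <- as.numeric(df$logratio)
  cna_segments(df)
}

#' Write CNA segments as BED4+
#' @param segments CNA segment table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cna_segments <- function(segments, path) {
  segments <- cna_segments(segments)
  out <- segments
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reciprocal overlap of two segments
#'
#' `min(overlap / len(a), overlap / len(b))`; 0 for disjoint segments or
#' different chromosomes. Symmetric, in `[0, 1]`.
#'
#' @param a,b single-row CNA segment tables (or lists with `chrom`, `start`,
#'   `end`).
#' @return fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  la <- a$end - a$start
  lb <- b$end - b$start
  if (la <= 0 || lb <= 0) rt_abort("zero-length CNA segment")
  if (a$chrom != b$chrom) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  if (ov <= 0) return(0)
  min(ov / la, ov / lb)
}

# Pairwise reciprocal-overlap matrix between two segment tables (same state
# and chromosome enforced by the caller); IRanges does the interval algebra.
ro_matrix <- function(a, b) {
  ra <- IRanges::IRanges(start = a$start + 1, end = a$end)
  rb <- IRanges::IRanges(start = b$start + 1, end = b$end)
  ov <- matrix(0, nrow(a), nrow(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(ov)
  hits <- IRanges::findOverlaps(ra, rb)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same_chr <- a$chrom[qi] == b$chrom[si]
  qi <- qi[same_chr]; si <- si[same_chr]
  w <- IRanges::width(IRanges::pintersect(ra[qi], rb[si]))
  ov[cbind(qi, si)] <- pmin(w / IRanges::width(ra)[qi], w / IRanges::width(rb)[si])
  ov
}

#' Compare CNA profiles between diagnosis and relapse
#'
#' An INI segment is retained when some REL segment of the same state
#' reciprocally overlaps it by at least `min_ro`, otherwise lost; REL segments
#' with no such INI partner are gained. `profile_loss` is `TRUE` as soon as
#' one INI segment is lost — the declared operationalization of "loss of the
#' CNA/CN-LOH profile". `cnloh` never matches `gain`/`loss` regardless of
#' overlap.
#'
#' @param ini,rel CNA segment tables for the two timepoints; segments of one
#'   timepoint must not overlap each other on the same chromosome.
#' @param min_ro reciprocal-overlap threshold defining "same segment".
#' @return list with data.frames `retained`, `lost`, `gained` and logical
#'   `profile_loss`.
#' @export
compare_cna_profiles <- function(ini, rel, min_ro = 0.5) {
  ini <- cna_segments(ini)
  rel <- cna_segments(rel)
  for (tp in list(c("INI"), c("REL"))) {
    seg <- if (tp == "INI") ini else rel
    if (nrow(seg) > 1) {
      r <- IRanges::IRanges(start = seg$start + 1, end = seg$end)
      hits <- IRanges::findOverlaps(r, r)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      clash <- qi < si & seg$chrom[qi] == seg$chrom[si]
      if (any(clash))
        rt_abort(sprintf("overlapping %s segments within one timepoint", tp))
    }
  }
  retained_idx <- logical(nrow(ini))
  gained_idx <- rep(TRUE, nrow(rel))
  for (st in CNA_STATES) {
    ai <- which(ini$state == st)
    bi <- which(rel$state == st)
    if (length(ai) == 0 || length(bi) == 0) next
    ro <- ro_matrix(ini[ai, , drop = FALSE], rel[bi, , drop = FALSE])
    retained_idx[ai] <- apply(ro >= min_ro, 1, any)
    gained_idx[bi] <- gained_idx[bi] & !apply(ro >= min_ro, 2, any)
  }
  list(retained = ini[retained_idx, , drop = FALSE],
       lost = ini[!retained_idx, , drop = FALSE],
       gained = rel[gained_idx, , drop = FALSE],
       profile_loss = any(!retained_idx))
}

#' Use CNA concordance to confirm a type-2 call
#'
#' Sets the `cna_confirmed_type2` flag when an SNV-based TYPE2 classification
#' is accompanied by loss of the initial CNA/CN-LOH profile. A TYPE1 call with
#' profile loss is discordant (the expectation is that type-1 relapses never
#' lose the initial profile) and raises a warning without altering the call.
#'
#' @param classification a [classify_relapse()] result.
#' @param comparison a [compare_cna_profiles()] result for the same patient.
#' @param patient_id optional patient id carried by the comparison, checked
#'   against the classification when supplied.
#' @return the classification with flags updated.
#' @export
confirm_type2 <- function(classification, comparison, patient_id = NULL) {
  stopifnot(inherits(classification, "classification_result"))
  if (!is.null(patient_id) && !identical(patient_id, classification$patient_id))
    rt_abort(sprintf("patient id mismatch: %s vs %s", patient_id,
                     classification$patient_id))
  if (classification$relapse_type == "TYPE2" && isTRUE(comparison$profile_loss)) {
    classification$flags <- union(classification$flags, "cna_confirmed_type2")
  } else if (classification$relapse_type == "TYPE1" &&
             isTRUE(comparison$profile_loss)) {
    warning(sprintf("%s: TYPE1 call but initial CNA profile lost (discordant)",
                    classification$patient_id))
  }
  classification
}
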