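# 96-channel trinucleotide mutation spectra and signature refitting.
#
# Channels follow the COSMIC-v2 convention: six pyrimidine substitution
# classes (C>A, C>G, C>T, T>A, T>C, T>G), each in 16 flanking contexts
# ordered alphabetically by (5' base, 3' base). Purine-reference SNVs are
# reverse-complemented so the mutated base is always C or T.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 trinucleotide context labels
#'
#' Labels of the form `A[C>A]A`, in canonical order: substitution class major,
#' flanking context (5' base then 3' base, alphabetical) minor.
#'
#' @return character vector of length 96.
#' @export
sbs96_contexts <- function() {
  unlist(lapply(SUB_CLASSES, function(cl)
    as.vector(t(outer(BASES, BASES, function(p5, p3)
      sprintf("%s[%s]%s", p5, cl, p3))))))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Map an SNV to its 96-channel index
#'
#' Looks up the trinucleotide context around the variant in the reference
#' genome, checks that the reference base matches the record, and
#' reverse-complements purine-reference variants (alleles and flanks) so the
#' central base is a pyrimidine. Returns the 1-based channel index (1..96,
#' the R convention; subtract 1 for the 0-based convention) with the context
#' label attached as an attribute.
#'
#' @param chrom,pos,ref,alt the SNV (single bases in ACGT).
#' @param genome a named [Biostrings::DNAStringSet] (or object coercible to
#'   one) holding the reference sequences.
#' @return integer channel index in 1..96 with attribute `label`.
#' @export
extract_context <- function(chrom, pos, ref, alt, genome) {
  if (!ref %in% BASES || !alt %in% BASES || ref == alt)
    rt_abort(sprintf("not an SNV: %s>%s at %s:%s", ref, alt, chrom, pos))
  if (!chrom %in% names(genome))
    rt_integrity_error(paste("chromosome not in genome:", chrom))
  chr_seq <- genome[[chrom]]
  if (pos < 2 || pos > length(chr_seq) - 1)
    rt_integrity_error(sprintf("position %s:%d too close to contig end", chrom, pos))
  tri <- strsplit(as.character(Biostrings::subseq(chr_seq, pos - 1, pos + 1)), "")[[1]]
  if (tri[2] != ref)
    rt_integrity_error(sprintf(
      "reference mismatch at %s:%d: genome has %s, record says %s",
      chrom, pos, tri[2], ref))
  if (ref %in% c("A", "G")) {  # purine strand: flip to pyrimidine convention
    tri <- rev(unname(REVCOMP[tri]))
    ref <- REVCOMP[[ref]]
    alt <- REVCOMP[[alt]]
  }
  cl <- match(paste0(ref, ">", alt), SUB_CLASSES)
  idx <- (cl - 1L) * 16L + (match(tri[1], BASES) - 1L) * 4L + match(tri[3], BASES)
  structure(as.integer(idx), label = sprintf("%s[%s>%s]%s", tri[1], ref, alt, tri[3]))
}

#' Build a 96-channel mutation spectrum
#'
#' Counts SNVs per trinucleotide channel; non-SNV records (indels) are
#' skipped.
#'
#' @param variants variant table.
#' @param genome reference sequences, as in [extract_context()].
#' @return named integer vector of length 96 (class `mutation_spectrum`).
#' @export
mutation_spectrum <- function(variants, genome) {
  counts <- integer(96)
  is_snv <- variants$ref %in% BASES & variants$alt %in% BASES
  for (i in which(is_snv)) {
    idx <- extract_context(variants$chrom[i], variants$pos[i],
                           variants$ref[i], variants$alt[i], genome)
    counts[idx] <- counts[idx] + 1L
  }
  structure(stats::setNames(counts, sbs96_contexts()), class = "mutation_spectrum")
}

#' Read / write a signature matrix
#'
#' TSV with a `signature` key column and the 96 context labels (`A[C>A]A`,
#' ...) as remaining columns; one row per signature, rows sum to 1.
#'
#' @param path file path.
#' @return numeric matrix, signatures x 96 channels.
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) rt_config_error(paste("no such file:", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  key <- names(df)[1]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[key]]
  validate_signature_matrix(m)
}

#' @rdname read_signature_matrix
#' @param sigs signature matrix.
#' @export
write_signature_matrix <- function(sigs, path) {
  sigs <- validate_signature_matrix(sigs)
  df <- data.frame(signature = rownames(sigs), sigs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_signature_matrix <- function(sigs) {
  if (is.null(dim(sigs)) || ncol(sigs) != 96)
    rt_format_error("signature matrix must have 96 channel columns")
  if (any(sigs < 0)) rt_abort("signature matrix entries must be non-negative")
  if (any(abs(rowSums(sigs) - 1) > 1e-6))
    rt_abort("signature matrix rows must each sum to 1 (+- 1e-6)")
  colnames(sigs) <- sbs96_contexts()
  if (is.null(rownames(sigs)))
    rownames(sigs) <- paste0("Signature.", seq_len(nrow(sigs)))
  sigs
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
# Deterministic; A is small (<= a few thousand rows x tens of columns) in all
# package uses. No NNLS solver ships with the environment, so it is built here
# and cross-checked against grid-search oracles in the tests.
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive & w > tol) && iter < max_iter) {
    j <- which.max(replace(w, passive, -Inf))
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- drop(qr.coef(qr(Ap), b))
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
      if (iter >= max_iter) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Refit signature exposures by non-negative least squares
#'
#' Normalizes the spectrum to frequencies, solves
#' `min || t(sigs) x - spectrum ||_2` subject to `x >= 0` (Lawson-Hanson
#' active set, deterministic), and renormalizes the exposures to sum to 1.
#'
#' @param spectrum 96-channel counts (see [mutation_spectrum()]).
#' @param sigs signature matrix, signatures x 96, rows summing to 1.
#' @return object of class `exposure_vector`: list with `shares` (named,
#'   summing to 1) and `residual_norm` (L2 residual of the frequency fit).
#' @export
fit_exposures <- function(spectrum, sigs) {
  sigs <- validate_signature_matrix(sigs)
  counts <- as.numeric(spectrum)
  if (length(counts) != 96) rt_format_error("spectrum must have 96 channels")
  total <- sum(counts)
  if (total <= 0) rt_abort("all-zero mutation spectrum: nothing to fit")
  b <- counts / total
  A <- t(sigs)                      # 96 x S
  x <- nnls_solve(A, b)
  resid <- sqrt(sum((b - A %*% x)^2))
  if (sum(x) <= 0) x <- rep(1 / length(x), length(x))  # degenerate: flat
  shares <- x / sum(x)
  structure(list(shares = stats::setNames(shares, rownames(sigs)),
                 residual_norm = resid),
            class = "exposure_vector")
}

#' @export
print.exposure_vector <- function(x, ...) {
  top <- sort(x$shares, decreasing = TRUE)[1:min(3, length(x$shares))]
  cat(sprintf("<exposures> %s (residual %.4f)\n",
              paste(sprintf("%s=%.2f", names(top), top), collapse = ", "),
              x$residual_norm))
  invisible(x)
}

#' Dominant signature of an exposure vector
#'
#' The argmax signature, reported only when its share reaches `min_share`;
#' ties are broken by signature order (first wins).
#'
#' @param exposures an `exposure_vector`.
#' @param min_share minimum share to call a signature dominant.
#' @return signature name, or `NA_character_` when no share reaches
#'   `min_share`.
#' @export
dominant_signature <- function(exposures, min_share = 0.4) {
  stopifnot(inherits(exposures, "exposure_vector"))
  i <- which.max(exposures$shares)  # which.max is first-wins on ties
  if (exposures$shares[i] >= min_share) names(exposures$shares)[i]
  else NA_character_
}
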