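# Reference-based deconvolution of bulk chromatin-accessibility profiles
# into T-cell precursor stage mixtures, in the spirit of CIBERSORT but with
# a deterministic NNLS solver on CPM-scaled linear values.

T_STAGES <- c("DN2", "DN3/ISP", "DPCD3-/DPCD3+", "CD4+", "CD8+")

#' Construct a reference accessibility atlas
#'
#' Regions x stages non-negative accessibility matrix with region ids as
#' row names; default stage set is the five thymic T-cell precursor stages
#' DN2, DN3/ISP, DPCD3-/DPCD3+, CD4+, CD8+.
#'
#' @param values numeric matrix, regions x stages.
#' @param region_ids optional row names.
#' @param stages optional column names.
#' @return validated matrix of class `reference_atlas`.
#' @export
reference_atlas <- function(values, region_ids = rownames(values),
                            stages = colnames(values)) {
  values <- as.matrix(values)
  if (any(values < 0)) rt_abort("atlas values must be non-negative")
  if (is.null(stages)) stages <- T_STAGES[seq_len(ncol(values))]
  if (is.null(region_ids)) region_ids <- sprintf("region_%05d", seq_len(nrow(values)))
  dimnames(values) <- list(region_ids, stages)
  keep <- rowSums(values) > 0
  values <- values[keep, , drop = FALSE]
  structure(values, class = c("reference_atlas", "matrix", "array"))
}

#' Read / write an accessibility matrix (atlas or sample profiles)
#'
#' TSV with a `region_id` key column; remaining columns are stages (atlas)
#' or samples (profiles).
#'
#' @param path file path.
#' @return numeric matrix with region ids as row names.
#' @export
read_accessibility_matrix <- function(path) {
  if (!file.exists(path)) rt_config_error(paste("no such file:", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_accessibility_matrix
#' @param m matrix to write.
#' @export
write_accessibility_matrix <- function(m, path) {
  df <- data.frame(region_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cpm_scale <- function(m) {
  totals <- colSums(m)
  if (any(totals <= 0)) rt_abort("all-zero profile column: cannot CPM-scale")
  sweep(m, 2, totals, "/") * 1e6
}

#' Select stage-discriminating signature regions
#'
#' After counts-per-million column scaling, each region is scored per stage
#' by the fold-change of that stage's accessibility over the mean of the
#' other stages; for every stage the top `per_stage_k` regions with fold
#' `>= min_fold` are taken and the union (deduplicated) forms the reduced
#' signature matrix. The default `per_stage_k = 565` sizes the union near the
#' conventional ~2,800-region five-stage signature.
#'
#' @param atlas a [reference_atlas()] (or regions x stages matrix).
#' @param per_stage_k regions to take per stage.
#' @param min_fold minimum fold-change over the mean of the other stages.
#' @return list with `regions` (selected ids), `signature` (reduced CPM
#'   matrix) and `per_stage` (list of ids selected per stage).
#' @export
build_signature_regions <- function(atlas, per_stage_k = 565, min_fold = 2.0) {
  m <- cpm_scale(unclass(atlas))
  if (per_stage_k > nrow(m))
    rt_abort(sprintf("per_stage_k (%d) exceeds region count (%d)",
                     per_stage_k, nrow(m)))
  per_stage <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    others <- rowMeans(m[, -j, drop = FALSE])
    fold <- ifelse(others > 0, v / others, ifelse(v > 0, Inf, 1))
    ok <- which(fold >= min_fold)
    ok[order(fold[ok], decreasing = TRUE)][seq_len(min(per_stage_k, length(ok)))]
  })
  names(per_stage) <- colnames(m)
  sel <- sort(unique(unlist(per_stage)))
  list(regions = rownames(m)[sel],
       signature = m[sel, , drop = FALSE],
       per_stage = lapply(per_stage, function(i) rownames(m)[i]))
}

#' Estimate the stage mixture of one bulk profile
#'
#' CPM-scales the profile, restricts it to the signature regions, solves a
#' non-negative least squares fit against the stage columns and renormalizes
#' to mixture proportions. Scale-invariant in the input profile.
#'
#' @param profile named numeric vector (region ids) or single-column matrix.
#' @param signature reduced signature matrix from [build_signature_regions()]
#'   (or any regions x stages reference).
#' @return object of class `stage_mixture`: `proportions` (named, sum 1),
#'   `dominant_stage`, `dominant_fraction`, `residual_norm`.
#' @export
estimate_mixture <- function(profile, signature) {
  if (is.matrix(profile)) profile <- profile[, 1]
  if (is.null(names(profile)))
    rt_integrity_error("profile must carry region ids as names")
  if (sum(profile) <= 0) rt_abort("all-zero sample profile")
  missing_regions <- setdiff(rownames(signature), names(profile))
  if (length(missing_regions) > 0)
    rt_integrity_error(paste("profile lacks signature regions, e.g.",
                             missing_regions[1]))
  p <- profile / sum(profile) * 1e6
  b <- p[rownames(signature)]
  x <- nnls_solve(signature, b)
  resid <- sqrt(sum((b - signature %*% x)^2))
  if (sum(x) <= 0) x <- rep(1 / length(x), length(x))
  prop <- stats::setNames(x / sum(x), colnames(signature))
  i <- which.max(prop)
  structure(list(proportions = prop,
                 dominant_stage = names(prop)[i],
                 dominant_fraction = unname(prop[i]),
                 residual_norm = resid),
            class = "stage_mixture")
}

#' @export
print.stage_mixture <- function(x, ...) {
  cat(sprintf("<stage_mixture> dominant %s (%.2f); %s\n", x$dominant_stage,
              x$dominant_fraction,
              paste(sprintf("%s=%.2f", names(x$proportions), x$proportions),
                    collapse = " ")))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation enumeration over all group splits (midranks for ties)
#' when `n1 + n2 <= exact_max`; otherwise the normal approximation with tie
#' correction and continuity correction. The reported `U` counts the wins of
#' group 1 over group 2. Two-sided exact p is `2 * min(P(U <= u), P(U >= u))`
#' capped at 1.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max maximum total size for exact enumeration.
#' @return list with `U`, `p` and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  if (length(x) == 0 || length(y) == 0)
    rt_abort("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    splits <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
    return(list(U = u_obs, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  list(U = u_obs, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Compare dominant deconvolution fractions between relapse types
#'
#' Two-sided Mann-Whitney test of the per-sample dominant stage fractions of
#' type-1 versus type-2 cases (type-1 leukemias are expected to resemble a
#' single precursor population, i.e. higher dominant fractions).
#'
#' @param type1,type2 numeric vectors of dominant fractions.
#' @return list with `U`, `p` and `method` (see [mann_whitney_u()]).
#' @export
compare_dominant_fractions <- function(type1, type2) {
  mann_whitney_u(type1, type2)
}
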