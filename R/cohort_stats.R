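# Cohort-level statistics: exact 2x2 tests, Welch t from summary statistics,
# printed-percent reproduction, log-rank, and the per-type mutation
# bookkeeping that feeds them.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the observed margins, sums the hypergeometric probability
#' of every table at most as probable as the observed one (with a
#' `1 + 1e-7` relative tolerance on the comparison, the standard convention).
#'
#' @param tab 2x2 matrix or the four counts `a, b, c, d` given as
#'   `matrix(c(a, c, b, d), 2)`; rows are groups, columns outcomes.
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) rt_format_error("need a 2x2 table")
  if (any(tab < 0)) rt_abort("negative entries in contingency table")
  if (sum(tab) == 0) rt_abort("empty contingency table")
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[1, 2]   # row 1 margin
  n <- tab[2, 1] + tab[2, 2]   # row 2 margin
  k <- tab[1, 1] + tab[2, 1]   # column 1 margin
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Welch's t-test from summary statistics
#'
#' Unpaired two-sided t-test computed directly from group means, standard
#' errors of the mean and sizes:
#' `t = (mean2 - mean1) / sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param mean1,sem1,n1 first group summary (SEM, not SD).
#' @param mean2,sem2,n2 second group summary.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (n1 < 2 || n2 < 2) rt_abort("group sizes must be at least 2")
  if (sem1 <= 0 || sem2 <= 0) rt_abort("SEMs must be positive")
  se2 <- sem1^2 + sem2^2
  t <- (mean2 - mean1) / sqrt(se2)
  df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Preserved-mutation percentage, printed convention
#'
#' `round(100 * n_preserved / n_total)` with halves away from zero, matching
#' printed percentages such as 306/337 -> 91.
#'
#' @param n_preserved,n_total non-negative counts, `n_total > 0`.
#' @return integer percent.
#' @export
preserved_fraction <- function(n_preserved, n_total) {
  if (n_total <= 0) rt_abort("n_total must be positive")
  if (n_preserved < 0 || n_preserved > n_total)
    rt_abort("need 0 <= n_preserved <= n_total")
  as.integer(round_half_away(100 * n_preserved / n_total))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Standard log-rank statistic on 1 degree of freedom, delegated to
#' [survival::survdiff()].
#'
#' @param times1,events1 first group: follow-up times and event indicators
#'   (`TRUE`/1 = event observed, `FALSE`/0 = censored).
#' @param times2,events2 second group.
#' @return list with `chi2` and `p`.
#' @export
logrank_two_groups <- function(times1, events1, times2, events2) {
  if (length(times1) == 0 || length(times2) == 0)
    rt_abort("both groups must be non-empty")
  if (any(c(times1, times2) < 0)) rt_abort("negative follow-up times")
  ev <- c(as.integer(events1), as.integer(events2))
  if (sum(ev) == 0) rt_abort("all observations censored: log-rank undefined")
  df <- data.frame(time = c(times1, times2), event = ev,
                   group = rep(c(1L, 2L), c(length(times1), length(times2))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Summarize a cohort of classifications
#'
#' Per relapse type: case counts and cohort percentage, totals of preserved /
#' lost / gained mutations, the four clonality cells at each timepoint, mean
#' acquired-mutation count, and the 2x2 clonality tables (type x
#' clonal/subclonal at INI and at REL) that feed the Fisher tests.
#'
#' @param results list of `classification_result` objects.
#' @return list with `per_type` data.frame, `clonality_ini` and
#'   `clonality_rel` 2x2 matrices, and `n_cases`.
#' @export
cohort_summary <- function(results) {
  if (length(results) == 0) rt_abort("no classified cases")
  stopifnot(all(vapply(results, inherits, logical(1), "classification_result")))
  type <- vapply(results, `[[`, character(1), "relapse_type")
  grab <- function(field) vapply(results, function(r) as.numeric(r[[field]]),
                                 numeric(1))
  n_pres <- vapply(results, function(r) length(r$preserved), numeric(1))
  n_lost <- vapply(results, function(r) length(r$lost), numeric(1))
  n_gain <- vapply(results, function(r) length(r$gained), numeric(1))
  per_type <- do.call(rbind, lapply(c("TYPE1", "TYPE2", "UNEVALUABLE"), function(ty) {
    sel <- type == ty
    if (!any(sel)) return(NULL)
    data.frame(
      relapse_type = ty,
      n_cases = sum(sel),
      pct_cases = preserved_fraction(sum(sel), length(results)),
      preserved = sum(n_pres[sel]), lost = sum(n_lost[sel]),
      gained = sum(n_gain[sel]),
      pct_preserved = preserved_fraction(sum(n_pres[sel]),
                                         max(1, sum(n_pres[sel]) + sum(n_lost[sel]))),
      clonal_ini = sum(grab("n_clonal_ini")[sel]),
      subclonal_ini = sum(grab("n_subclonal_ini")[sel]),
      clonal_rel = sum(grab("n_clonal_rel")[sel]),
      subclonal_rel = sum(grab("n_subclonal_rel")[sel]),
      mean_acquired = mean(grab("n_acquired")[sel]),
      n_hypermutator = sum(vapply(results[sel], is_hypermutator, logical(1))),
      stringsAsFactors = FALSE
    )
  }))
  mk_tab <- function(clon, subc) {
    m <- matrix(0, 2, 2, dimnames = list(c("TYPE1", "TYPE2"),
                                         c("subclonal", "clonal")))
    for (ty in c("TYPE1", "TYPE2")) {
      row <- per_type[per_type$relapse_type == ty, , drop = FALSE]
      if (nrow(row)) m[ty, ] <- c(row[[subc]], row[[clon]])
    }
    m
  }
  list(per_type = per_type,
       clonality_ini = mk_tab("clonal_ini", "subclonal_ini"),
       clonality_rel = mk_tab("clonal_rel", "subclonal_rel"),
       n_cases = length(results))
}
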