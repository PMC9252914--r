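# Shared in-code fixtures for the suite; everything is generated at test time.

# A minimal hand-built variant row.
vrow <- function(chrom = "chr1", pos = 100L, ref = "G", alt = "T",
                 alt_count = 45L, depth = 100L, effect = "missense",
                 gene = "JAK2", coding = TRUE, timepoint = "INI",
                 patient_id = "P1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             alt_count = alt_count, depth = depth, effect = effect,
             gene = gene, coding = coding, timepoint = timepoint,
             patient_id = patient_id, stringsAsFactors = FALSE)
}

# A small hand-built trio: n_clonal clonal + n_sub subclonal somatic INI
# variants, n_lost of the clonal ones absent at REL, n_gained REL-private,
# plus one germline variant. Deterministic counts (no sampling).
toy_case <- function(n_clonal = 5, n_sub = 3, n_lost = 0, n_gained = 2,
                     depth = 100L, rel_depth_lost = 100L, patient_id = "T1") {
  mk <- function(i, af, tp) vrow(pos = 1000L + i, alt_count = as.integer(round(af * depth)),
                                 depth = depth, timepoint = tp,
                                 gene = sprintf("G%03d", i), patient_id = patient_id)
  rows <- list()
  for (i in seq_len(n_clonal + n_sub)) {
    af_ini <- if (i <= n_clonal) 0.45 else 0.12
    lost <- i <= n_lost  # losses taken from the clonal block first
    rows <- c(rows, list(
      mk(i, af_ini, "INI"),
      { r <- mk(i, if (lost) 0 else af_ini, "REL"); r$depth <- rel_depth_lost
        r$alt_count <- as.integer(round(if (lost) 0 else af_ini * rel_depth_lost)); r },
      { r <- mk(i, 0, "REM"); r }))
  }
  for (j in seq_len(n_gained)) {
    i <- 500L + j
    rows <- c(rows, list(mk(i, 0, "INI"), mk(i, 0.40, "REL"), mk(i, 0, "REM")))
  }
  g <- 900L
  rows <- c(rows, list(mk(g, 0.5, "INI"), mk(g, 0.5, "REL"), mk(g, 0.5, "REM")))
  patient_case(patient_id, do.call(rbind, rows))
}

small_cfg <- function(...) {
  simulation_config(n_type1 = 3L, n_type2 = 3L, atlas_regions = 300L, ...)
}

# Independent brute-force two-sided Fisher p: enumerate every table with the
# observed margins and sum the probabilities of those at most as likely.
fisher_bruteforce <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]; n <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(a) {
    choose(m, a) * choose(n, k - a) / choose(m + n, k)
  }, numeric(1))
  p_obs <- probs[match(tab[1, 1], support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent exact Mann-Whitney p via full enumeration of label assignments.
mw_bruteforce <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}
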