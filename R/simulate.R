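# Fully labeled synthetic cohorts: matched INI/REM/REL variant trios under
# type-1/type-2 clonal evolution, CNA profiles, germline predisposition
# variants, signature-biased mutation spectra and stage-mixture
# accessibility profiles. Every generator records its ground truth so each
# pipeline stage can be checked against the planted labels.

#' Simulation configuration
#'
#' Defaults encode the cohort the package emulates: 18 type-1 and 20 type-2
#' matched trios at ~100x mean depth, high blast content, a ~15% hypermutator
#' rate among type-2 cases bursting >85 coding mutations, a 35% type-2 (and
#' zero type-1) constitutional-predisposition carrier rate, and longer times
#' to relapse for type-2. Clone cancer-cell fractions translate to allele
#' frequencies as `af = CCF / 2` (diploid heterozygous sites).
#'
#' @param seed integer seed (drives [simulate_cohort()]).
#' @param n_type1,n_type2 cohort composition.
#' @param depth mean per-site sequencing depth (Poisson).
#' @param n_truncal,n_major,n_minor ranges (length-2 integer vectors) of
#'   mutations per clone.
#' @param major_ccf_ini,minor_ccf_ini,minor_ccf_rel CCF ranges of the major
#'   clone at diagnosis and the minor ancestral clone at diagnosis/relapse.
#' @param acquired_mean named mean acquired-mutation counts per type.
#' @param blast_range named list of per-timepoint blast-fraction ranges.
#' @param hypermutator_prob named per-type probability of a hypermutator
#'   relapse.
#' @param hypermutator_burst coding mutations added in a hypermutator burst.
#' @param cpg_carrier_prob named per-type probability of carrying a
#'   constitutional predisposition loss-of-function variant.
#' @param n_cpg_genes,n_decoy_genes sizes of the predisposition gene list and
#'   the background gene pool.
#' @param cna_segments range of aberrant segments per case at diagnosis.
#' @param cna_loss_prob probability that a type-2 relapse loses part of the
#'   initial CNA profile.
#' @param ttr_meanlog named log-mean of the lognormal time-to-relapse (days).
#' @param atlas_regions,noise_sigma accessibility-atlas size and
#'   multiplicative log-normal noise sd.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_type1 = 18L, n_type2 = 20L,
                              depth = 100,
                              n_truncal = c(8L, 16L),
                              n_major = c(4L, 10L),
                              n_minor = c(2L, 6L),
                              major_ccf_ini = c(0.85, 1.0),
                              minor_ccf_ini = c(0.05, 0.25),
                              minor_ccf_rel = c(0.8, 1.0),
                              acquired_mean = c(TYPE1 = 11, TYPE2 = 20),
                              blast_range = list(INI = c(0.9, 1.0),
                                                 REL = c(0.9, 1.0)),
                              hypermutator_prob = c(TYPE1 = 0, TYPE2 = 0.15),
                              hypermutator_burst = 100L,
                              cpg_carrier_prob = c(TYPE1 = 0, TYPE2 = 0.35),
                              n_cpg_genes = 40L, n_decoy_genes = 200L,
                              cna_segments = c(1L, 5L),
                              cna_loss_prob = 0.45,
                              ttr_meanlog = c(TYPE1 = log(250), TYPE2 = log(330)),
                              atlas_regions = 3000L,
                              noise_sigma = 0.1) {
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

EFFECT_PROBS <- c(missense = 0.50, synonymous = 0.18, other = 0.15,
                  stopgain = 0.04, frameshift_indel = 0.04, inframe_indel = 0.03,
                  splice_donor = 0.02, splice_acceptor = 0.02, stoploss = 0.02)
CODING_EFFECTS <- c("stopgain", "stoploss", "frameshift_indel", "inframe_indel",
                    "missense", "synonymous")

cpg_gene_names <- function(n) sprintf("CPG%03d", seq_len(n))
decoy_gene_names <- function(n) sprintf("GENE%03d", seq_len(n))

runif1 <- function(range) stats::runif(1, range[1], range[2])
rint <- function(range) sample(seq(range[1], range[2]), 1)

# Draw reads for one site: depth ~ Poisson(mean), alt ~ Binomial(depth, af).
draw_reads <- function(true_af, mean_depth) {
  depth <- stats::rpois(1, mean_depth)
  alt <- if (depth > 0) stats::rbinom(1, depth, min(true_af, 1)) else 0L
  c(alt = alt, depth = depth)
}

sample_effects <- function(n, coding_only = FALSE, lof_only = FALSE) {
  pool <- EFFECT_PROBS
  if (lof_only) pool <- pool[names(pool) %in% lof_effects()]
  else if (coding_only) pool <- pool[names(pool) %in% CODING_EFFECTS]
  sample(names(pool), n, replace = TRUE, prob = pool)
}

make_alleles <- function(n, effects) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(seq_len(n), function(i) {
    if (effects[i] %in% c("frameshift_indel", "inframe_indel")) {
      paste0(ref[i], paste(sample(BASES, if (effects[i] == "inframe_indel") 3 else 1,
                                  replace = TRUE), collapse = ""))
    } else sample(setdiff(BASES, ref[i]), 1)
  }, character(1))
  list(ref = ref, alt = alt)
}

#' Simulate one matched diagnosis/remission/relapse case
#'
#' Builds a small clone tree (truncal clone, major subclone, optional minor
#' subclone) and realizes it at both tumor timepoints. Type-1 path: truncal
#' and major clones persist to relapse and a relapse-private clone acquires
#' new mutations. Type-2 path: the major clone's private mutations drop to
#' CCF 0 at relapse while a minor ancestral subclone (subclonal at diagnosis)
#' expands to dominance, with more acquired mutations on average. Germline
#' variants (AF 0.5 at every timepoint) include benign background variants
#' and, for carriers, loss-of-function variants in listed predisposition
#' genes. Read counts are binomial at Poisson depth; remission records are
#' force-called at every site.
#'
#' @param type_label `"TYPE1"` or `"TYPE2"`.
#' @param cfg a [simulation_config()]; the caller controls the RNG state.
#' @param patient_id identifier for the case.
#' @param cpg_genes,decoy_genes gene name pools (defaults derived from `cfg`).
#' @return list with `case` (a [patient_case()]) and `truth` (planted labels:
#'   type, clone CCFs, per-variant clone/germline assignment and true AFs,
#'   carrier status, hypermutator status, CNA profile-loss indicator).
#' @export
simulate_case <- function(type_label, cfg = simulation_config(),
                          patient_id = "P1",
                          cpg_genes = cpg_gene_names(cfg$n_cpg_genes),
                          decoy_genes = decoy_gene_names(cfg$n_decoy_genes)) {
  stopifnot(type_label %in% c("TYPE1", "TYPE2"))
  blast <- c(INI = runif1(cfg$blast_range$INI), REM = 1,
             REL = runif1(cfg$blast_range$REL))

  # --- clone tree ----------------------------------------------------------
  major_ini <- runif1(cfg$major_ccf_ini)
  clones <- data.frame(
    clone = c("truncal", "major", "minor", "relprivate"),
    ccf_ini = c(1, major_ini,
                if (type_label == "TYPE2") runif1(cfg$minor_ccf_ini) else
                  sample(c(0, runif1(cfg$minor_ccf_ini)), 1),
                0),
    ccf_rel = c(1,
                if (type_label == "TYPE2") 0 else runif1(cfg$major_ccf_ini),
                if (type_label == "TYPE2") runif1(cfg$minor_ccf_rel) else 0,
                stats::runif(1, 0.35, 1)),
    stringsAsFactors = FALSE
  )
  if (clones$ccf_ini[3] > 0 && clones$ccf_ini[2] + clones$ccf_ini[3] > 1)
    clones$ccf_ini[3] <- 1 - clones$ccf_ini[2]  # sibling branches: CCFs sum <= 1

  hyper <- stats::runif(1) < cfg$hypermutator_prob[[type_label]]
  n_acq <- stats::rpois(1, cfg$acquired_mean[[type_label]]) +
    if (hyper) cfg$hypermutator_burst else 0L
  n_mut <- c(truncal = rint(cfg$n_truncal), major = rint(cfg$n_major),
             minor = if (clones$ccf_ini[3] > 0) rint(cfg$n_minor) else 0L,
             relprivate = n_acq)

  clone_of <- rep(clones$clone, n_mut)
  n_som <- length(clone_of)
  effects <- sample_effects(n_som)
  if (hyper) {  # burst mutations are coding (mismatch-repair-style SNVs)
    burst_idx <- which(clone_of == "relprivate")[seq_len(cfg$hypermutator_burst)]
    effects[burst_idx] <- sample_effects(cfg$hypermutator_burst, coding_only = TRUE)
  }

  # --- germline variants ---------------------------------------------------
  carrier <- stats::runif(1) < cfg$cpg_carrier_prob[[type_label]]
  n_cpg <- if (carrier) rint(c(1L, 2L)) else 0L
  n_benign <- rint(c(3L, 6L))
  n_near_miss <- 2L  # LoF outside the list + missense inside it
  g_eff <- c(sample_effects(n_cpg, lof_only = TRUE),
             rep("missense", n_benign),
             sample_effects(1, lof_only = TRUE), "missense")
  g_gene <- c(sample(cpg_genes, n_cpg, replace = TRUE),
              sample(decoy_genes, n_benign, replace = TRUE),
              sample(decoy_genes, 1), sample(cpg_genes, 1))
  n_germ <- n_cpg + n_benign + n_near_miss

  n_all <- n_som + n_germ
  pos <- sample(1e7L, n_all)
  alleles <- make_alleles(n_all, c(effects, g_eff))
  gene <- c(sample(decoy_genes, n_som, replace = TRUE), g_gene)
  effect <- c(effects, g_eff)
  germline <- c(rep(FALSE, n_som), rep(TRUE, n_germ))
  ccf_ini <- c(clones$ccf_ini[match(clone_of, clones$clone)], rep(NA, n_germ))
  ccf_rel <- c(clones$ccf_rel[match(clone_of, clones$clone)], rep(NA, n_germ))
  true_af <- function(ccf, tp) ifelse(is.na(ccf), 0.5, ccf / 2 * blast[[tp]])

  rows <- lapply(TIMEPOINTS, function(tp) {
    af <- switch(tp,
                 INI = true_af(ccf_ini, "INI"),
                 REM = ifelse(germline, 0.5, 0),
                 REL = true_af(ccf_rel, "REL"))
    reads <- t(vapply(af, draw_reads, numeric(2), mean_depth = cfg$depth))
    data.frame(chrom = "chr1", pos = pos, ref = alleles$ref, alt = alleles$alt,
               alt_count = as.integer(reads[, 1]), depth = as.integer(reads[, 2]),
               effect = effect, gene = gene,
               coding = effect %in% CODING_EFFECTS,
               timepoint = tp, patient_id = patient_id,
               stringsAsFactors = FALSE)
  })
  variants <- variant_table(do.call(rbind, rows))

  # --- CNA profiles --------------------------------------------------------
  n_seg <- rint(cfg$cna_segments)
  seg_chrom <- sample(sprintf("chr%d", 1:22), n_seg)
  seg_start <- sample(5e7L, n_seg)
  ini_cna <- cna_segments(data.frame(
    chrom = seg_chrom, start = seg_start,
    end = seg_start + sample(1e6:1e7, n_seg, replace = TRUE),
    state = sample(CNA_STATES, n_seg, replace = TRUE),
    logratio = stats::rnorm(n_seg, 0, 0.5)))
  cna_loss <- type_label == "TYPE2" && stats::runif(1) < cfg$cna_loss_prob
  keep <- if (cna_loss) {
    drop_n <- rint(c(1L, n_seg))
    seq_len(n_seg)[-sample(n_seg, drop_n)]
  } else seq_len(n_seg)
  rel_cna <- ini_cna[keep, , drop = FALSE]
  if (stats::runif(1) < 0.3) {  # relapse-acquired segment on a free chromosome
    free <- setdiff(sprintf("chr%d", 1:22), rel_cna$chrom)
    st <- sample(5e7L, 1)
    rel_cna <- rbind(rel_cna, cna_segments(data.frame(
      chrom = sample(free, 1), start = st, end = st + sample(1e6:1e7, 1),
      state = sample(CNA_STATES, 1), logratio = stats::rnorm(1, 0, 0.5))))
  }

  ttr <- round(stats::rlnorm(1, cfg$ttr_meanlog[[type_label]], 0.4))
  case <- patient_case(patient_id, variants, blast_fraction = blast,
                       cna = list(INI = ini_cna, REL = rel_cna),
                       time_to_relapse_days = as.integer(ttr),
                       event_after_relapse = stats::runif(1) < 0.6)
  truth <- list(patient_id = patient_id, type = type_label,
                clones = clones,
                variants = data.frame(
                  key = variant_key(variants[variants$timepoint == "INI", ]),
                  clone = c(clone_of, rep("germline", n_germ)),
                  germline = germline,
                  true_af_ini = true_af(ccf_ini, "INI"),
                  true_af_rel = true_af(ccf_rel, "REL"),
                  stringsAsFactors = FALSE),
                carrier = carrier, n_cpg_variants = n_cpg,
                hypermutator = hyper, n_acquired = n_acq,
                cna_profile_loss = cna_loss,
                blast = blast)
  list(case = case, truth = truth)
}

#' Simulate a full cohort (optionally writing fixtures to disk)
#'
#' Draws `n_type1 + n_type2` cases under `cfg` (seeded by `cfg$seed`, so a
#' fixed config yields byte-identical fixtures) and, when `dir` is given,
#' writes one variant TSV and two CNA BEDs per patient plus the
#' predisposition gene list, blast-fraction table, outcome table and the
#' ground-truth table.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created), or `NULL` for in-memory only.
#' @return list with `cases`, `truths`, `truth_table` (data.frame),
#'   `cpg_genes` and `dir`.
#' @export
simulate_cohort <- function(cfg = simulation_config(), dir = NULL) {
  set.seed(cfg$seed)
  cpg_genes <- cpg_gene_names(cfg$n_cpg_genes)
  decoy_genes <- decoy_gene_names(cfg$n_decoy_genes)
  labels <- rep(c("TYPE1", "TYPE2"), c(cfg$n_type1, cfg$n_type2))
  sims <- lapply(seq_along(labels), function(i)
    simulate_case(labels[i], cfg, sprintf("P%02d", i), cpg_genes, decoy_genes))
  cases <- lapply(sims, `[[`, "case")
  truths <- lapply(sims, `[[`, "truth")
  truth_table <- do.call(rbind, lapply(truths, function(tr) data.frame(
    patient_id = tr$patient_id, type = tr$type, carrier = tr$carrier,
    n_cpg_variants = tr$n_cpg_variants, hypermutator = tr$hypermutator,
    n_acquired = tr$n_acquired, cna_profile_loss = tr$cna_profile_loss,
    stringsAsFactors = FALSE)))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir, pattern = "\\.variants\\.tsv$")))
      rt_abort(paste("fixture files already present in", dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (case in cases) {
      pid <- case$patient_id
      write_variant_table(case$variants, file.path(dir, paste0(pid, ".variants.tsv")))
      write_cna_segments(case$cna$INI, file.path(dir, paste0(pid, ".cna_INI.bed")))
      write_cna_segments(case$cna$REL, file.path(dir, paste0(pid, ".cna_REL.bed")))
    }
    writeLines(c("# synthetic cancer predisposition gene list", cpg_genes),
               file.path(dir, "cpg_genes.txt"))
    blast <- do.call(rbind, lapply(cases, function(cs) data.frame(
      patient_id = cs$patient_id, timepoint = TIMEPOINTS,
      blast_fraction = unname(cs$blast_fraction[TIMEPOINTS]))))
    utils::write.table(blast, file.path(dir, "blast.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outcome <- do.call(rbind, lapply(cases, function(cs) data.frame(
      patient_id = cs$patient_id,
      time_to_relapse_days = cs$time_to_relapse_days,
      event_after_relapse = as.integer(cs$event_after_relapse))))
    utils::write.table(outcome, file.path(dir, "outcomes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth_table, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(cases = cases, truths = truths, truth_table = truth_table,
       cpg_genes = cpg_genes, dir = dir)
}

#' Simulate a random reference genome
#'
#' @param chrom_lengths named integer vector of contig lengths.
#' @return [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(chrom_lengths = c(chr1 = 20000L)) {
  seqs <- vapply(chrom_lengths, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate a well-separated signature matrix
#'
#' Each signature concentrates most of its mass on its own random subset of
#' channels (plus a flat background), keeping mixtures identifiable.
#'
#' @param n_sigs number of signatures.
#' @param peak_channels channels carrying the concentrated mass per signature.
#' @return signature matrix (n_sigs x 96), rows summing to 1.
#' @export
simulate_signature_matrix <- function(n_sigs = 3, peak_channels = 8) {
  m <- matrix(stats::runif(n_sigs * 96, 0, 0.2), n_sigs, 96)
  for (s in seq_len(n_sigs))
    m[s, sample(96, peak_channels)] <- stats::runif(peak_channels, 3, 8)
  m <- m / rowSums(m)
  rownames(m) <- paste0("Signature.", seq_len(n_sigs))
  validate_signature_matrix(m)
}

#' Simulate a mutation spectrum from known exposures
#'
#' Multinomial draw of `n` mutations from the channel distribution
#' `t(sigs) %*% exposures`.
#'
#' @param exposures non-negative weights, one per signature (normalized
#'   internally).
#' @param sigs signature matrix.
#' @param n number of mutations.
#' @return 96-channel count vector.
#' @export
simulate_spectrum <- function(exposures, sigs, n = 5000) {
  sigs <- validate_signature_matrix(sigs)
  p <- drop(t(sigs) %*% (exposures / sum(exposures)))
  stats::setNames(as.integer(stats::rmultinom(1, n, p)), sbs96_contexts())
}

#' Simulate SNV records drawn from a channel distribution
#'
#' Samples 96-channel contexts from `channel_probs`, then places each
#' mutation at a genome position whose trinucleotide matches the channel
#' (on either strand), recording the true channel as ground truth.
#'
#' @param n number of SNVs.
#' @param channel_probs length-96 probability vector.
#' @param genome [Biostrings::DNAStringSet] to place mutations on.
#' @param timepoint,patient_id record metadata.
#' @return list with `variants` (variant table) and `channels` (true 1-based
#'   channel per record).
#' @export
simulate_snvs_from_channels <- function(n, channel_probs, genome,
                                        timepoint = "REL", patient_id = "P1") {
  labels <- sbs96_contexts()
  # canonical (pyrimidine-centered) trinucleotide at every genome position
  canon <- lapply(names(genome), function(chr) {
    s <- as.character(genome[[chr]])
    tri <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
    center <- substring(s, 2:(nchar(s) - 1), 2:(nchar(s) - 1))
    flip <- center %in% c("A", "G")
    tri[flip] <- vapply(tri[flip], function(t3)
      paste(rev(unname(REVCOMP[strsplit(t3, "")[[1]]])), collapse = ""), character(1))
    data.frame(chrom = chr, pos = seq_along(tri) + 1L, tri = tri, flip = flip,
               stringsAsFactors = FALSE)
  })
  canon <- do.call(rbind, canon)
  ch <- sample(96, n, replace = TRUE, prob = channel_probs)
  cl <- (ch - 1) %/% 16 + 1
  p5 <- BASES[((ch - 1) %% 16) %/% 4 + 1]
  p3 <- BASES[(ch - 1) %% 4 + 1]
  center <- ifelse(cl <= 3, "C", "T")
  target <- substring(SUB_CLASSES[cl], 3, 3)
  want_tri <- paste0(p5, center, p3)
  rows <- lapply(seq_len(n), function(i) {
    hit <- canon[canon$tri == want_tri[i], , drop = FALSE]
    if (nrow(hit) == 0)
      rt_abort(paste("genome lacks context", want_tri[i], "- enlarge it"))
    j <- hit[sample(nrow(hit), 1), ]
    if (j$flip) data.frame(chrom = j$chrom, pos = j$pos,
                           ref = REVCOMP[[center[i]]], alt = REVCOMP[[target[i]]])
    else data.frame(chrom = j$chrom, pos = j$pos, ref = center[i], alt = target[i])
  })
  df <- do.call(rbind, rows)
  df$alt_count <- 50L; df$depth <- 100L
  df$effect <- "missense"; df$gene <- ""; df$coding <- TRUE
  df$timepoint <- timepoint; df$patient_id <- patient_id
  list(variants = variant_table(df), channels = ch)
}

#' Simulate an accessibility atlas and mixed bulk profiles
#'
#' Builds a five-stage reference with planted stage-specific
#' high-accessibility regions, then draws bulk samples as convex stage
#' mixtures with multiplicative log-normal noise. Type-1-style samples have
#' a dominant component >= 0.8; type-2-style samples are constrained to a
#' maximum component <= 0.5, mirroring the homogeneous-vs-mixed contrast the
#' deconvolution is meant to detect.
#'
#' @param cfg a [simulation_config()] (uses `atlas_regions`, `noise_sigma`).
#' @param n_type1,n_type2 samples per group.
#' @return list with `atlas` ([reference_atlas()]), `profiles` (regions x
#'   samples), `true_mixtures` (stages x samples), `groups`.
#' @export
simulate_atlas_and_mixtures <- function(cfg = simulation_config(),
                                        n_type1 = 8, n_type2 = 8) {
  R <- cfg$atlas_regions
  S <- 5L
  if (R < 10 * S) rt_abort("atlas_regions must be at least 10x the stage count")
  base <- matrix(stats::rlnorm(R * S, log(5), 0.5), R, S)
  spec_per_stage <- R %/% 10
  idx <- matrix(sample(R, spec_per_stage * S), ncol = S)
  for (s in seq_len(S)) base[idx[, s], s] <- base[idx[, s], s] * 8
  atlas <- reference_atlas(base, stages = T_STAGES)
  n <- n_type1 + n_type2
  mixes <- sapply(seq_len(n), function(i) {
    if (i <= n_type1) {
      dom <- sample(S, 1)
      u <- stats::runif(1, 0.82, 0.95)
      rest <- stats::rgamma(S - 1, 1)
      m <- numeric(S); m[dom] <- u; m[-dom] <- (1 - u) * rest / sum(rest)
      m
    } else {
      repeat {
        m <- stats::rgamma(S, 2); m <- m / sum(m)
        if (max(m) <= 0.5) return(m)
      }
    }
  })
  profiles <- unclass(atlas) %*% mixes *
    matrix(stats::rlnorm(nrow(atlas) * n, 0, cfg$noise_sigma), nrow(atlas), n)
  colnames(profiles) <- sprintf("S%02d", seq_len(n))
  rownames(mixes) <- T_STAGES
  colnames(mixes) <- colnames(profiles)
  list(atlas = atlas, profiles = profiles, true_mixtures = mixes,
       groups = rep(c("TYPE1", "TYPE2"), c(n_type1, n_type2)))
}
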