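test_that("context channel: strand symmetry, integrity checks, oracle agreement", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TACGT", chr2 = "ACGTA"))
  # chr1:2-4 = ACG (A[C>T]G); chr2 pos 3 has G with context CGT ->
  # reverse complement ACG, G>A -> C>T: the same channel
  fwd <- extract_context("chr1", 3, "C", "T", genome)
  revc <- extract_context("chr2", 3, "G", "A", genome)
  expect_equal(as.integer(fwd), as.integer(revc))
  expect_equal(attr(fwd, "label"), "A[C>T]G")
  expect_equal(sbs96_contexts()[as.integer(fwd)], "A[C>T]G")

  expect_error(extract_context("chr1", 3, "A", "T", genome),
               class = "rt_integrity_error")       # genome has C, not A
  expect_error(extract_context("chr1", 3, "CA", "T", genome), class = "rt_error")
  expect_error(extract_context("chr9", 3, "C", "T", genome),
               class = "rt_integrity_error")

  # independent oracle: a naive 192-row string lookup table
  oracle_table <- local({
    rows <- list()
    for (cl in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
      for (p5 in c("A", "C", "G", "T")) for (p3 in c("A", "C", "G", "T")) {
        lab <- sprintf("%s[%s]%s", p5, cl, p3)
        idx <- match(lab, sbs96_contexts())
        ref <- substr(cl, 1, 1); alt <- substr(cl, 3, 3)
        rc <- c(A = "T", C = "G", G = "C", T = "A")
        rows[[length(rows) + 1]] <- data.frame(
          tri = paste0(p5, ref, p3), ref = ref, alt = alt, idx = idx)
        rows[[length(rows) + 1]] <- data.frame(
          tri = paste0(rc[p3], rc[ref], rc[p5]), ref = rc[ref], alt = rc[alt],
          idx = idx)
      }
    do.call(rbind, rows)
  })
  set.seed(12)
  g <- simulate_genome(c(chr1 = 30000L))
  sim <- simulate_snvs_from_channels(1000, rep(1 / 96, 96), g)
  s <- as.character(g[[1]])
  for (i in seq_len(nrow(sim$variants))) {
    v <- sim$variants[i, ]
    tri <- substr(s, v$pos - 1, v$pos + 1)
    want <- oracle_table$idx[oracle_table$tri == tri & oracle_table$ref == v$ref &
                               oracle_table$alt == v$alt]
    expect_equal(as.integer(extract_context(v$chrom, v$pos, v$ref, v$alt, g)),
                 want)
  }
  # and the generator's own ground-truth channels agree
  got <- vapply(seq_len(nrow(sim$variants)), function(i)
    as.integer(extract_context(sim$variants$chrom[i], sim$variants$pos[i],
                               sim$variants$ref[i], sim$variants$alt[i], g)),
    integer(1))
  expect_equal(got, sim$channels)
})

test_that("spectrum is invariant under strand flip of every input SNV", {
  set.seed(13)
  g <- simulate_genome(c(chr1 = 20000L))
  sim <- simulate_snvs_from_channels(300, rep(1 / 96, 96), g)
  spec <- mutation_spectrum(sim$variants, g)
  expect_equal(sum(spec), 300)
  g_flip <- Biostrings::reverseComplement(g)
  names(g_flip) <- names(g)
  v_flip <- sim$variants
  L <- Biostrings::width(g)[1]
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  v_flip$pos <- L - v_flip$pos + 1L
  v_flip$ref <- unname(rc[v_flip$ref])
  v_flip$alt <- unname(rc[v_flip$alt])
  expect_equal(mutation_spectrum(variant_table(v_flip), g_flip), spec)
})

test_that("exposure fitting: identity, planted mixtures, grid-search oracle", {
  set.seed(14)
  sigs <- simulate_signature_matrix(3)
  # spectrum exactly proportional to one signature
  e1 <- fit_exposures(round(sigs[2, ] * 1e6), sigs)
  expect_equal(unname(e1$shares), c(0, 1, 0), tolerance = 1e-3)
  expect_lt(e1$residual_norm, 1e-4)

  # 0.7 / 0.3 planted mixture, 10,000 mutations
  spec <- simulate_spectrum(c(0.7, 0.3, 0), sigs, n = 10000)
  e2 <- fit_exposures(spec, sigs)
  expect_equal(unname(e2$shares), c(0.7, 0.3, 0), tolerance = 0.02)

  # brute-force simplex grid (step 0.01) agrees within 0.02 L1
  grid_fit <- function(spec, sigs) {
    b <- spec / sum(spec); A <- t(sigs)
    best <- NULL; best_r <- Inf
    for (x1 in seq(0, 1, 0.01)) for (x2 in seq(0, 1 - x1, 0.01)) {
      x <- c(x1, x2, 1 - x1 - x2)
      r <- sum((b - A %*% x)^2)
      if (r < best_r) { best_r <- r; best <- x }
    }
    best
  }
  for (w in list(c(0.5, 0.3, 0.2), c(0.9, 0.1, 0), c(1, 1, 1) / 3)) {
    spec <- simulate_spectrum(w, sigs, n = 8000)
    got <- unname(fit_exposures(spec, sigs)$shares)
    want <- grid_fit(spec, sigs)
    expect_lt(sum(abs(got - want)), 0.02)
  }

  expect_error(fit_exposures(rep(0, 96), sigs), class = "rt_error")
})

test_that("sparse-mixture recovery: mean L1 error <= 0.05 over seeds", {
  # scaled to 20 seeds here; the acceptance suite runs the full 50
  set.seed(15)
  sigs <- simulate_signature_matrix(3)
  l1 <- replicate(20, {
    w <- stats::rgamma(3, 0.8); w <- w / sum(w)
    spec <- simulate_spectrum(w, sigs, n = 5000)
    sum(abs(unname(fit_exposures(spec, sigs)$shares) - w))
  })
  expect_lte(mean(l1), 0.05)
})

test_that("dominant signature: threshold and deterministic tie-break", {
  ev <- function(x) structure(list(shares = stats::setNames(x, paste0("S", seq_along(x))),
                                   residual_norm = 0), class = "exposure_vector")
  expect_equal(dominant_signature(ev(c(0.8, 0.1, 0.1))), "S1")
  expect_true(is.na(dominant_signature(ev(c(0.35, 0.33, 0.32)))))
  expect_equal(dominant_signature(ev(rep(1 / 3, 3)), min_share = 0), "S1")
})

test_that("signature matrix TSV round-trips and is validated", {
  set.seed(16)
  sigs <- simulate_signature_matrix(4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature_matrix(sigs, f)
  back <- read_signature_matrix(f)
  expect_equal(back, sigs, tolerance = 1e-12)
  bad <- sigs; bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(read_signature_matrix({ f2 <- withr::local_tempfile();
    write.table(data.frame(signature = rownames(bad), bad, check.names = FALSE),
                f2, sep = "\t", quote = FALSE, row.names = FALSE); f2 }),
    class = "rt_error")
})
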