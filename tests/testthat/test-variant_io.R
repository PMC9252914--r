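test_that("TSV dialect computes AF from counts and round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(vrow(chrom = "chr9", pos = 5073770L, alt_count = 45L,
                           depth = 100L), f)
  v <- read_variant_table(f, "tsv")
  expect_equal(v$af, 0.45)
  expect_equal(v$gene, "JAK2")

  set.seed(11)
  sim <- simulate_case("TYPE2", small_cfg(), "P7")
  v50 <- sim$case$variants[1:50, ]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v50, f2)
  back <- read_variant_table(f2, "tsv")
  rownames(v50) <- rownames(back) <- NULL
  expect_equal(back, v50[, names(back)])
})

test_that("VCF dialect: AD-derived AF, multi-allelic split, annotation tags", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"effect\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##INFO=<ID=CODING,Number=0,Type=Flag,Description=\"coding\">",
    "##INFO=<ID=TP,Number=1,Type=String,Description=\"timepoint\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", sep = "\t"),
    paste("chr2", "500", ".", "G", "T", ".", "PASS",
          "EFF=missense;GENE=NRAS;CODING;TP=INI", "AD", "60,40", sep = "\t"),
    paste("chr2", "900", ".", "A", "C,G", ".", "PASS",
          "EFF=other;TP=REL", "AD", "80,15,5", sep = "\t")
  ), f)
  v <- read_variant_table(f, "vcf")
  expect_equal(nrow(v), 3)         # multi-allelic row split per alt
  expect_equal(v$af[1], 0.40)      # 40 / (60 + 40)
  expect_equal(v$gene[1], "NRAS")
  expect_true(v$coding[1])
  expect_equal(v$timepoint[1], "INI")
  expect_setequal(v$alt[2:3], c("C", "G"))

  # VCF writer -> reader reproduces the table
  set.seed(3)
  sim <- simulate_case("TYPE1", small_cfg(), "P2")
  vv <- sim$case$variants
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(vv, f2)
  back <- read_variant_table(f2, "vcf")
  key <- function(d) order(d$chrom, d$pos, d$alt, d$timepoint)
  a <- vv[key(vv), 1:12]; b <- back[key(back), 1:12]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a)
})

test_that("VCF without AD is a format error; invalid records are rejected", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", sep = "\t"),
    paste("chr1", "10", ".", "A", "T", ".", "PASS", ".", "GT", "0/1", sep = "\t")
  ), f)
  expect_error(read_variant_table(f, "vcf"), class = "rt_format_error")
  expect_error(variant_table(vrow(alt_count = 5L, depth = 0L)), class = "rt_error")
  expect_error(variant_table(vrow(ref = "G", alt = "G")), class = "rt_error")
  expect_error(read_variant_table("no/such/file.tsv", "tsv"),
               class = "rt_config_error")
})

test_that("somatic/constitutional partition follows the remission AF rule", {
  case <- toy_case(n_clonal = 4, n_sub = 2, n_lost = 0, n_gained = 1)
  part <- partition_somatic_constitutional(case)
  # the germline variant (REM af 0.5) is constitutional; all others somatic
  expect_length(part$constitutional, 1)
  expect_length(part$unevaluable, 0)
  expect_length(part$somatic_ini, 6)
  expect_length(part$somatic_rel, 7)
  # partition of distinct keys is exhaustive and disjoint
  n_distinct <- nrow(part$status)
  expect_equal(length(unique(c(part$somatic_ini, part$somatic_rel))) +
                 length(part$constitutional) + length(part$unevaluable),
               n_distinct)

  # simulated case with known germline labels: full recovery at depth 100
  set.seed(21)
  sim <- simulate_case("TYPE2", small_cfg(), "P5")
  part2 <- partition_somatic_constitutional(sim$case)
  truth <- sim$truth$variants
  st <- part2$status
  germ_truth <- truth$germline[match(st$key, truth$key)]
  expect_equal(st$status == "constitutional", germ_truth)

  no_rem <- patient_case("X", vrow())
  expect_error(partition_somatic_constitutional(no_rem),
               class = "rt_config_error")
})

test_that("purity correction triggers, caps, and is idempotent", {
  v <- variant_table(rbind(vrow(pos = 1L, alt_count = 15L, depth = 100L),
                           vrow(pos = 2L, alt_count = 90L, depth = 100L)))
  out <- correct_af_for_purity(v, 0.30)
  expect_equal(out$af_adjusted, c(0.50, 1.0))    # 0.15/0.30; capped
  expect_true(all(out$purity_corrected))
  # no trigger above threshold
  same <- correct_af_for_purity(v, 0.95)
  expect_null(same$af_adjusted)
  # idempotent: af column untouched, re-running reproduces the same result
  again <- correct_af_for_purity(out, 0.30)
  expect_equal(again$af_adjusted, out$af_adjusted)
  expect_equal(again$af, v$af)
  expect_error(correct_af_for_purity(v, 0), class = "rt_error")
})

test_that("variant matching buckets by identity key", {
  a <- variant_table(rbind(vrow(pos = 1L), vrow(pos = 2L), vrow(pos = 3L)))
  expect_equal(match_variants(a, a)$shared, variant_key(a))
  expect_length(match_variants(a, a)$only_a, 0)
  b <- variant_table(vrow(pos = 9L))
  m <- match_variants(a, b)
  expect_length(m$shared, 0)
  expect_length(m$only_a, 3)
  expect_length(m$only_b, 1)

  dup <- variant_table(rbind(vrow(pos = 1L), vrow(pos = 1L)))
  expect_error(match_variants(dup, b), "chr1:1:G:T")

  # 500 simulated variants with a planted 30% overlap
  set.seed(5)
  pos <- sample(1e6L, 650L)
  mk <- function(p) variant_table(do.call(rbind, lapply(p, function(i) vrow(pos = i))))
  va <- mk(pos[1:500])                    # 500 in a
  vb <- mk(pos[c(1:150, 501:650)])        # 150 shared + 150 b-only
  m2 <- match_variants(va, vb)
  expect_length(m2$shared, 150)
  expect_length(m2$only_a, 350)
  expect_length(m2$only_b, 150)
})
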