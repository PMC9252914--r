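# relapsetype

Typing of leukemia relapses from matched diagnosis–remission–relapse
sequencing trios.

Relapsed T-cell acute lymphoblastic leukemia (T-ALL) follows one of two
evolutionary routes: **type-1**, where the major diagnostic clone survives
therapy (every clonal diagnosis mutation — allele frequency AF ≥ 30% — is
preserved at relapse), or **type-2**, where the major clone is eradicated
and a minor ancestral subclone expands (a subset of clonal diagnosis
mutations is lost). `relapsetype` implements this threshold classifier and
the analyses that build on it, for anyone studying clonal evolution in
matched tumor pairs with a constitutional (remission) reference:

* variant/CNA I/O (TSV and a minimal VCF 4.2 dialect; BED4+ segments),
  somatic-vs-constitutional partitioning against the remission sample,
  blast-content (purity) AF correction;
* the type-1/type-2 classifier with per-site fate calls
  (`PRESERVED` / `LOST` / `UNEVALUABLE`, absence = AF < 0.02 at ≥ 20×),
  preserved/lost/gained accounting and hypermutator flagging
  (> 85 coding mutations at relapse);
* CNA/CN-LOH profile concordance (reciprocal overlap ≥ 0.5, state-matched)
  as independent confirmation of type-2 calls;
* 96-channel trinucleotide spectra and non-negative least squares (NNLS)
  refitting of mutational-signature exposures (e.g. a dominant
  mismatch-repair signature in hypermutators);
* a constitutional cancer-predisposition gene (CPG) screen
  (loss-of-function classes, AF ≥ 30%, user-supplied gene list) with
  carrier-enrichment testing;
* reference-based deconvolution of bulk chromatin-accessibility profiles
  into five T-cell precursor stages (DN2, DN3/ISP, DPCD3−/DPCD3+, CD4+,
  CD8+) by NNLS on a stage-discriminating region signature;
* exact cohort statistics: two-sided Fisher's exact test (hypergeometric
  summation), Welch's t from summary statistics, exact Mann-Whitney U,
  log-rank via the `survival` package;
* a fully labeled synthetic-cohort generator (clone trees, binomial reads
  at Poisson depth, germline CPG variants, CNA gain/loss, signature-biased
  mutation bursts, stage-mixture accessibility profiles) so the whole
  pipeline is testable without controlled-access data.

The classifier in one line: a case is **TYPE2** iff at least `min_lost`
(default 1) clonal (AF ≥ 0.30) somatic diagnosis variants are confidently
absent at relapse (AF < 0.02, depth ≥ 20), **TYPE1** iff none are lost and
at least one clonal variant was evaluable, **UNEVALUABLE** otherwise.

See `vignettes/relapse-typing.Rmd` for the model, every tunable threshold,
and the design decisions.

## Worked example

```r
library(relapsetype)

sim <- simulate_cohort(simulation_config(seed = 11))   # 18 TYPE1 + 20 TYPE2
res <- run_cohort(sim$cases, cpg_genes = sim$cpg_genes)

res$classifications[[20]]
#> <classification P20> TYPE2 | preserved 19, lost 5, gained 11 | flags: cna_confirmed_type2

res$summary$per_type[, c("relapse_type", "n_cases", "pct_cases",
                         "pct_preserved", "mean_acquired", "n_hypermutator")]
#>   relapse_type n_cases pct_cases pct_preserved mean_acquired n_hypermutator
#> 1        TYPE1      18        47            91      10.88889              0
#> 2        TYPE2      20        53            69      42.20000              4
```

Patient P20 is a type-2 relapse: 5 of its clonal diagnosis mutations are
confidently absent at relapse, and the loss of its diagnostic CNA profile
independently confirms the call (`cna_confirmed_type2`). At the cohort
level, 47% of cases are type-1; type-1 relapses preserve 91% of their
diagnosis mutations versus 69% for type-2, acquire far fewer mutations
(mean 10.9 vs 42.2, Welch p = 0.0031), and contain none of the 4
hypermutators.

```r
res$summary$clonality_ini                     # clonal/subclonal cells at diagnosis
#>       subclonal clonal
#> TYPE1        35    350
#> TYPE2        65    371
res$stats$fisher_clonality_ini                # higher subclonal fraction in future TYPE2
#> [1] 0.01362923
res$cpg$table                                 # constitutional CPG carriers by type
#>       carrier non_carrier
#> TYPE1       0          18
#> TYPE2      10          10
res$cpg$fisher_p
#> [1] 0.0004833884
res$stats$logrank_ttr$p                       # longer time to relapse in TYPE2
#> [1] 0.02771452
```

Published-statistic reproductions are direct calls:

```r
fisher_exact_two_sided(matrix(c(0, 7, 18, 13), 2))   # 0/18 vs 7/20 carriers
#> [1] 0.008664167                                     # prints as 0.0087
welch_t_from_summary(10.94, 1.677, 18, 33.05, 7.636, 20)$p
#> [1] 0.01012721                                      # prints as 0.01
preserved_fraction(306, 337)
#> [1] 91
```

## Command line

```sh
Rscript inst/cli/relapsetype.R fixtures generate --out fixtures/ --seed 1
Rscript inst/cli/relapsetype.R cohort --dir fixtures/ --out results/
Rscript inst/cli/relapsetype.R classify --variants P01.variants.tsv \
    --cna-ini P01.cna_INI.bed --cna-rel P01.cna_REL.bed --out results/
```

Subcommands: `fixtures generate`, `classify`, `cohort`, `cpg`,
`signatures`, `deconv`. Shared flags: `--config` (key=value overrides of
`pipeline_config()`), `--seed`, `--out`, `--log-level`. Exit codes:
0 ok, 1 validation error, 2 configuration error.

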