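test_that("Fisher exact: reference tables, invariances, degenerate input", {
  expect_equal(round(fisher_exact_two_sided(matrix(c(0, 7, 18, 13), 2)), 4),
               0.0087)
  # hand-verifiable: the only tables at most as probable are a=0 and a=7
  expect_equal(fisher_exact_two_sided(matrix(c(0, 7, 18, 13), 2)),
               dhyper(0, 18, 20, 7) + dhyper(7, 18, 20, 7), tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_lt(fisher_exact_two_sided(matrix(c(153, 431, 351, 411), 2)), 1e-4)

  t0 <- matrix(c(3, 1, 2, 9), 2)
  p <- fisher_exact_two_sided(t0)
  expect_equal(p, fisher_exact_two_sided(t0[2:1, 2:1]))  # swap rows + cols
  expect_equal(p, fisher_exact_two_sided(t(t0)))
  expect_error(fisher_exact_two_sided(matrix(c(-1, 2, 3, 4), 2)),
               class = "rt_error")
})

test_that("Fisher exact equals brute-force enumeration for all margins <= 15", {
  n_checked <- 0
  for (r1 in 0:15) for (r2 in 0:15) for (a in 0:r1) for (c1 in 0:r2) {
    if (r1 + r2 == 0) next
    tab <- matrix(c(a, c1, r1 - a, r2 - c1), 2)
    if (identical(fisher_exact_two_sided(tab), fisher_bruteforce(tab)) ||
        abs(fisher_exact_two_sided(tab) - fisher_bruteforce(tab)) < 1e-12) {
      n_checked <- n_checked + 1
    } else {
      expect_equal(fisher_exact_two_sided(tab), fisher_bruteforce(tab),
                   tolerance = 1e-12,
                   label = paste("table", paste(tab, collapse = ",")))
    }
  }
  expect_gt(n_checked, 18000)  # every table with both row margins <= 15
  # spot agreement with the stock implementation on random tables
  set.seed(33)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20), 2)
    expect_equal(fisher_exact_two_sided(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Welch t from summary stats: reference case, symmetry, simulation oracle", {
  ref <- welch_t_from_summary(10.94, 1.677, 18, 33.05, 7.636, 20)
  expect_equal(round(ref$p, 2), 0.01)
  expect_equal(welch_t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_equal(welch_t_from_summary(5, 1, 10, 5, 1, 10)$p, 1)
  # antisymmetric in group order for t, invariant for p
  rev <- welch_t_from_summary(33.05, 7.636, 20, 10.94, 1.677, 18)
  expect_equal(rev$t, -ref$t)
  expect_equal(rev$p, ref$p)
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 10), class = "rt_error")

  # Monte-Carlo oracle: normal groups with matching moments
  set.seed(34)
  n1 <- 18; n2 <- 20; sem1 <- 1.677; sem2 <- 7.636
  reps <- 2e5
  t_null <- replicate(reps, {
    x <- rnorm(n1, 0, sem1 * sqrt(n1)); y <- rnorm(n2, 0, sem2 * sqrt(n2))
    (mean(y) - mean(x)) / sqrt(var(x) / n1 + var(y) / n2)
  })
  p_mc <- mean(abs(t_null) >= abs(ref$t))
  se_mc <- sqrt(p_mc * (1 - p_mc) / reps)
  expect_lt(abs(p_mc - ref$p), 3 * se_mc + 1e-4)
})

test_that("printed-percent convention rounds half away from zero", {
  expect_identical(preserved_fraction(306, 337), 91L)
  expect_identical(preserved_fraction(181, 356), 51L)
  expect_identical(preserved_fraction(18, 38), 47L)
  expect_identical(preserved_fraction(0, 10), 0L)
  expect_identical(preserved_fraction(181, 360), 50L)  # 50.28 -> 50
  expect_identical(preserved_fraction(1, 200), 1L)     # 0.5 -> 1 (away from 0)
  expect_error(preserved_fraction(1, 0), class = "rt_error")
  expect_error(preserved_fraction(5, 3), class = "rt_error")
})

test_that("log-rank: identical groups, planted hazard, permutation null", {
  g <- c(5, 10, 15, 20, 30)
  same <- logrank_two_groups(g, rep(1, 5), g, rep(1, 5))
  expect_equal(same$chi2, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-9)

  set.seed(35)
  t1 <- rexp(50, 1); t2 <- rexp(50, 0.5)   # group 2 lives twice as long
  res <- logrank_two_groups(t1, rep(1, 50), t2, rep(1, 50))
  expect_lt(res$p, 0.05)

  # permutation oracle on a small mixed sample
  set.seed(36)
  times <- c(rexp(12, 1), rexp(12, 0.6))
  ev <- rbinom(24, 1, 0.8)
  obs <- logrank_two_groups(times[1:12], ev[1:12], times[13:24], ev[13:24])$chi2
  perm <- replicate(2000, {
    i <- sample(24, 12)
    logrank_two_groups(times[i], ev[i], times[-i], ev[-i])$chi2
  })
  p_perm <- mean(perm >= obs)
  p_asym <- pchisq(obs, 1, lower.tail = FALSE)
  expect_lt(abs(p_perm - p_asym), 3 * sqrt(p_asym * (1 - p_asym) / 2000) + 0.02)

  expect_error(logrank_two_groups(g, rep(0, 5), g, rep(0, 5)), class = "rt_error")
})

test_that("cohort summary recounts a simulated cohort and feeds the tests", {
  sim <- simulate_cohort(simulation_config(n_type1 = 5L, n_type2 = 5L, seed = 77L))
  cls <- lapply(sim$cases, classify_relapse)
  summ <- cohort_summary(cls)
  expect_equal(summ$n_cases, 10)
  pt <- summ$per_type
  expect_equal(pt$n_cases[pt$relapse_type == "TYPE1"], 5)
  expect_equal(pt$pct_cases[pt$relapse_type == "TYPE1"], 50)
  # direct recount from the classification objects
  lost_direct <- sum(vapply(cls, function(r)
    if (r$relapse_type == "TYPE2") length(r$lost) else 0L, integer(1)))
  expect_equal(pt$lost[pt$relapse_type == "TYPE2"], lost_direct)
  expect_equal(sum(summ$clonality_ini["TYPE1", ]),
               pt$clonal_ini[pt$relapse_type == "TYPE1"] +
                 pt$subclonal_ini[pt$relapse_type == "TYPE1"])

  # single all-preserved case
  one <- classify_relapse(toy_case(n_clonal = 4, n_lost = 0, n_gained = 0))
  s1 <- cohort_summary(list(one))
  expect_equal(s1$per_type$lost, 0)
  expect_equal(s1$per_type$gained, 0)
  expect_equal(s1$per_type$pct_cases, 100)

  # 18 of 38 -> 47%
  set.seed(78)
  many <- c(replicate(18, classify_relapse(toy_case(n_clonal = 3)), simplify = FALSE),
            replicate(20, classify_relapse(toy_case(n_clonal = 3, n_lost = 1)),
                      simplify = FALSE))
  expect_equal(cohort_summary(many)$per_type$pct_cases[1], 47)
})
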