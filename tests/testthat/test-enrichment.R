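test_that("carrier counts expand to allele counts", {
  expect_equal(alleles_from_individuals(247, 1, 0),
               c(affected = 1L, unaffected = 493L))
  expect_equal(alleles_from_individuals(125748, 1, 0),
               c(affected = 1L, unaffected = 251495L))
  expect_equal(alleles_from_individuals(10, 0, 0),
               c(affected = 0L, unaffected = 20L))
  # homozygotes contribute ploidy alleles
  expect_equal(alleles_from_individuals(10, 2, 3),
               c(affected = 8L, unaffected = 12L))
  expect_error(alleles_from_individuals(5, 4, 2), "exceed")
})

test_that("two-sided exact test reproduces enumerable and published tables", {
  # brute-force enumerable: margins (5,5)/(6,4) -> 132/252
  expect_equal(fisher_two_sided(2, 3, 4, 1), 132 / 252, tolerance = 1e-12)
  # empty affected margin is degenerate
  p0 <- fisher_two_sided(0, 5, 0, 7)
  expect_equal(as.numeric(p0), 1)
  expect_true(isTRUE(attr(p0, "degenerate")))
  # the two cohort-versus-population allele tables
  expect_equal(round(as.numeric(fisher_two_sided(1, 493, 1, 251495)), 3),
               0.004)
  expect_equal(round(as.numeric(fisher_two_sided(1, 1815, 1, 251495)), 2),
               0.01)
})

test_that("exact test agrees with independent oracles on random tables", {
  set.seed(42)
  for (i in 1:200) {
    cells <- as.integer(rpois(4, sample(c(2, 5, 20), 1)))
    p_mine <- as.numeric(fisher_two_sided(cells[1], cells[2], cells[3], cells[4]))
    p_orc <- oracle_fisher_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_mine, p_orc, tolerance = 1e-12)
    if (sum(cells[1:2]) > 0 && sum(cells[3:4]) > 0 &&
        (cells[1] + cells[3]) > 0 && (cells[2] + cells[4]) > 0) {
      p_ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
      expect_equal(p_mine, p_ft, tolerance = 1e-7)
    }
  }
})

test_that("exact test is invariant under simultaneous row and column swap", {
  set.seed(7)
  for (i in 1:50) {
    cells <- as.integer(rpois(4, 8))
    expect_equal(
      as.numeric(fisher_two_sided(cells[1], cells[2], cells[3], cells[4])),
      as.numeric(fisher_two_sided(cells[4], cells[3], cells[2], cells[1])),
      tolerance = 1e-12
    )
  }
})

test_that("p decreases as the cohort-affected cell grows with fixed margins", {
  # enumerated family: margins (10, 200), k varies with a
  p_at <- function(a) as.numeric(fisher_two_sided(a, 10 - a, 2, 198))
  ps <- vapply(2:8, p_at, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("Woolf logit interval matches closed forms and Haldane rule", {
  w <- woolf_logit_interval(10, 10, 10, 10)
  z <- qnorm(0.975)
  expect_equal(w$odds_ratio, 1)
  expect_false(w$correction_applied)
  expect_equal(w$ci_low, exp(-z * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(w$ci_high, exp(z * sqrt(0.4)), tolerance = 1e-12)

  w0 <- woolf_logit_interval(0, 10, 5, 5)
  expect_true(w0$correction_applied)
  expect_equal(w0$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)

  # correction applied iff a zero cell exists
  expect_false(woolf_logit_interval(1, 2, 3, 4)$correction_applied)
  expect_error(woolf_logit_interval(0, 0, 0, 0), "all-zero")

  # log-symmetry around the odds ratio and widening with confidence
  w1 <- woolf_logit_interval(7, 13, 4, 26)
  expect_equal(log(w1$ci_high) - log(w1$odds_ratio),
               log(w1$odds_ratio) - log(w1$ci_low), tolerance = 1e-12)
  w99 <- woolf_logit_interval(7, 13, 4, 26, conf_level = 0.99)
  expect_true(w99$ci_low < w1$ci_low && w99$ci_high > w1$ci_high)
})

test_that("burden test combines allele expansion, exact test and interval", {
  sco <- lof_burden_test(247, 1, 0, 125748, 1, 0)
  expect_equal(sco$table["cohort", ], c(affected = 1, unaffected = 493))
  expect_equal(round(sco$p_two_sided, 3), 0.004)
  expect_true(sco$ci_low <= sco$odds_ratio && sco$odds_ratio <= sco$ci_high)

  merge <- lof_burden_test(908, 1, 0, 125748, 1, 0)
  expect_equal(round(merge$p_two_sided, 2), 0.01)

  null <- lof_burden_test(100, 0, 0, 1000, 0, 0)
  expect_equal(null$p_two_sided, 1)
  expect_true(null$degenerate)

  # a smaller reported reference allele number shrinks cell d
  capped <- lof_burden_test(247, 1, 0, 125748, 1, 0,
                            ref_allele_number = 250000)
  expect_equal(capped$table["reference", "unaffected"], 249999)
})

test_that("individual-based tables change the published p by less than 5e-5", {
  p_allele_sco <- as.numeric(fisher_two_sided(1, 493, 1, 251495))
  p_indiv_sco <- as.numeric(fisher_two_sided(1, 246, 1, 125747))
  expect_lt(abs(p_allele_sco - p_indiv_sco), 5e-5)
  p_allele_merge <- as.numeric(fisher_two_sided(1, 1815, 1, 251495))
  p_indiv_merge <- as.numeric(fisher_two_sided(1, 907, 1, 125747))
  expect_lt(abs(p_allele_merge - p_indiv_merge), 5e-5)
})
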