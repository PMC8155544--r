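# Shared in-code fixtures and independent oracles.

# Independent two-sided Fisher oracle: hypergeometric point masses from
# stats::dhyper, minimum-likelihood summation. Used only to check the
# package's own lchoose-based implementation.
oracle_fisher_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  pp <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  min(sum(pp[pp <= p_obs * (1 + rel_tol)]), 1)
}

# A tiny hand-built cohort: three genes on chromosomes 1, 2 and X, one
# variant each, two case samples.
tiny_cohort <- function() {
  v <- variant_table(
    chrom = c("1", "2", "X"),
    pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"),
    alt = c("T", "G", "A"),
    gene = c("ALPHA", "BETA", "GAMMA"),
    consequence = c("stop_gained", "missense_variant", "frameshift_variant"),
    cadd = c(NA, 25, NA)
  )
  calls <- call_table(
    variant_id = c(v$variant_id[1], v$variant_id[2], v$variant_id[3]),
    sample_id = c("S1", "S1", "S2"),
    dosage = c(1L, 2L, 1L),
    dp = c(50L, 40L, 30L),
    ad = c(25L, 38L, 15L)
  )
  variant_cohort(v, calls, samples = c("S1", "S2"))
}

# Wide expression table where every listed gene is testis-dominant.
flat_expression <- function(genes, testis = 100, other = 10) {
  tibble::tibble(gene = genes, testis = testis, brain = other, liver = other)
}

expected_stage_counts <- function(truth, cfg) {
  n_planted <- sum(truth$role == "planted")
  dec <- function(k) sum(truth$role == paste0("decoy_", k))
  g1 <- n_planted + dec("low_quality") + dec("het_maf_fail") +
    dec("low_testis") + dec("control_hit")
  tibble::tibble(
    stage = c("effect_and_rarity", "quality", "genotype_maf", "expression",
              "control_exclusion"),
    genes_in = c(cfg$n_genes, g1, g1 - dec("low_quality"),
                 g1 - dec("low_quality") - dec("het_maf_fail"),
                 g1 - dec("low_quality") - dec("het_maf_fail") -
                   dec("low_testis")),
    genes_out = c(g1, g1 - dec("low_quality"),
                  g1 - dec("low_quality") - dec("het_maf_fail"),
                  g1 - dec("low_quality") - dec("het_maf_fail") -
                    dec("low_testis"),
                  n_planted)
  )
}
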