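cfg <- filter_config()

test_that("filter defaults are the published thresholds", {
  expect_equal(cfg$lof_maf_max, 0.01)
  expect_equal(cfg$het_maf_max, 0.001)
  expect_equal(cfg$x_linked_maf_max, 0.001)
  expect_equal(cfg$min_read_depth, 10)
  expect_equal(cfg$min_alt_depth, 4)
  expect_equal(cfg$min_vaf, 0.40)
  expect_equal(cfg$testis_fraction_min, 0.5)
})

test_that("testis fraction is testis over the max across tissues", {
  expr <- tibble::tibble(gene = c("A", "B", "C"),
                         testis = c(80, 30, 0),
                         brain = c(40, 60, 0),
                         liver = c(10, 20, 0))
  tf <- testis_fraction(expr)
  expect_equal(tf$testis_fraction, c(1, 0.5, 0))
  expect_error(testis_fraction(expr[, c("gene", "brain", "liver")]),
               "testis")
})

make_work <- function(class = "lof", eff_maf = 0, dp = 50L, ad = 25L,
                      dosage = 1L, chrom = "1", gene = "G1",
                      sample_id = "S1", variant_id = "v1") {
  tibble::tibble(variant_id = variant_id, sample_id = sample_id,
                 dosage = dosage, dp = dp, ad = ad, chrom = chrom,
                 pos = 1L, ref = "A", alt = "T", gene = gene,
                 consequence = NA_character_, class = class,
                 cadd = NA_real_, maf = NA_real_, eff_maf = eff_maf)
}

test_that("stage 1 keeps rare LoF variants, treating absent MAF as zero", {
  w <- dplyr::bind_rows(
    make_work(class = "lof", eff_maf = 0, variant_id = "novel_fs"),
    make_work(class = "lof", eff_maf = 0.02, variant_id = "common_fs"),
    make_work(class = "missense", eff_maf = 0, variant_id = "rare_mis"),
    make_work(class = "lof", eff_maf = 0.01, variant_id = "boundary_fs")
  )
  kept <- stage1_effect_and_rarity(w, cfg)$variant_id
  expect_setequal(kept, c("novel_fs", "boundary_fs"))
})

test_that("stage 2 applies inclusive DP/AD/VAF thresholds per call", {
  w <- dplyr::bind_rows(
    make_work(dp = 10L, ad = 4L, variant_id = "boundary"),    # 0.40 exactly
    make_work(dp = 9L, ad = 4L, variant_id = "low_dp"),       # VAF 0.44
    make_work(dp = 100L, ad = 30L, variant_id = "low_vaf"),   # 0.30
    make_work(dp = 50L, ad = 3L, variant_id = "low_ad"),
    make_work(dp = NA_integer_, ad = NA_integer_, variant_id = "no_depth")
  )
  expect_equal(stage2_quality(w, cfg)$variant_id, "boundary")
})

test_that("stage 3 stratifies the MAF cutoff by genotype and X linkage", {
  w <- dplyr::bind_rows(
    make_work(dosage = 1L, eff_maf = 0.0047, variant_id = "het_common"),
    make_work(dosage = 1L, eff_maf = 0, variant_id = "het_novel"),
    make_work(dosage = 2L, eff_maf = 0.009, variant_id = "hom_rare"),
    make_work(dosage = 2L, eff_maf = 0.009, chrom = "X", variant_id = "hom_x"),
    make_work(dosage = 1L, eff_maf = 0.001, variant_id = "het_boundary")
  )
  kept <- stage3_genotype_maf(w, cfg)$variant_id
  expect_setequal(kept, c("het_novel", "hom_rare", "het_boundary"))
})

test_that("stage 4 enforces the strict expression gate and logs unprofiled genes", {
  expr <- tibble::tibble(gene = c("HI", "HALF"), testis = c(100, 30),
                         brain = c(20, 60))
  s4 <- stage4_expression(c("HI", "HALF", "UNKNOWN"), expr, cfg)
  expect_equal(s4$kept, "HI")
  expect_setequal(s4$removed$gene, c("HALF", "UNKNOWN"))
  expect_equal(s4$removed$reason[s4$removed$gene == "UNKNOWN"], "no profile")
  # threshold disabled: only unprofiled genes are removed
  s4b <- stage4_expression(c("HI", "HALF", "UNKNOWN"), expr,
                           filter_config(testis_fraction_min = 0))
  expect_setequal(s4b$kept, c("HI", "HALF"))
})

test_that("stage 5 removes genes with quality-passing control LoF, no MAF gate", {
  v <- variant_table(chrom = c("1", "1", "2"), pos = c(10L, 20L, 30L),
                     ref = "A", alt = "T",
                     gene = c("HIT", "NOISY", "BENIGN"),
                     consequence = c("stop_gained", "stop_gained",
                                     "missense_variant"))
  ctrl_calls <- call_table(v$variant_id, "CTRL1", c(1L, 1L, 1L),
                           dp = c(60L, 5L, 60L), ad = c(30L, 3L, 30L))
  controls <- variant_cohort(v, ctrl_calls, samples = "CTRL1")
  s5 <- stage5_control_exclusion(c("HIT", "NOISY", "BENIGN"), controls, cfg)
  # HIT: quality-passing control LoF -> removed; NOISY: DP 5 control call
  # is noise, kept; BENIGN: controls carry only missense, kept
  expect_setequal(s5$kept, c("NOISY", "BENIGN"))
  expect_equal(s5$removed$gene, "HIT")
})

test_that("the full cascade recovers planted genes and audits every stage", {
  sim <- simulate_prioritization_cohort(cohort_sim_config(
    seed = 11, n_cases = 40, n_controls = 15, n_genes = 60))
  res <- run_cascade(sim$cases, sim$controls, sim$frequency, sim$expression)
  planted <- sort(sim$truth$gene[sim$truth$role == "planted"])
  expect_identical(sort(res$candidates$gene), planted)

  st <- res$audit$stages
  expect_equal(st$stage, c("effect_and_rarity", "quality", "genotype_maf",
                           "expression", "control_exclusion"))
  # chaining and monotonicity
  expect_true(all(st$genes_out <= st$genes_in))
  expect_equal(st$genes_in[-1], st$genes_out[-nrow(st)])

  # each decoy is removed at exactly its designed stage, with a reason
  dec <- sim$truth[grepl("^decoy_", sim$truth$role), ]
  rem <- merge(dec, res$audit$removed, by = "gene")
  expect_equal(nrow(rem), nrow(dec))
  expect_equal(rem$stage, rem$designed_stage)
})

test_that("cascade output is invariant to input row order", {
  sim <- simulate_prioritization_cohort(cohort_sim_config(
    seed = 5, n_cases = 30, n_controls = 10, n_genes = 40))
  res1 <- run_cascade(sim$cases, sim$controls, sim$frequency, sim$expression)
  set.seed(99)
  shuf <- sim$cases
  shuf$variants <- shuf$variants[sample.int(nrow(shuf$variants)), ]
  shuf$calls <- shuf$calls[sample.int(nrow(shuf$calls)), ]
  res2 <- run_cascade(shuf, sim$controls,
                      sim$frequency[sample.int(nrow(sim$frequency)), ],
                      sim$expression)
  expect_identical(res1$candidates, res2$candidates)
  expect_identical(res1$audit$stages, res2$audit$stages)
})

test_that("degenerate cascades behave as declared", {
  sim <- simulate_prioritization_cohort(cohort_sim_config(
    seed = 2, n_cases = 10, n_controls = 4, n_genes = 20, n_planted = 0))
  res <- run_cascade(sim$cases, sim$controls, sim$frequency, sim$expression)
  expect_equal(nrow(res$candidates), 0)
  expect_equal(nrow(recurrence_histogram(res)), 0)

  # cases with zero LoF variants: stage 1 empties the cascade
  v <- variant_table("1", 10L, "A", "T", "G1", "missense_variant")
  cases <- variant_cohort(v, call_table(v$variant_id, "S1", 1L, 50L, 25L))
  res2 <- suppressWarnings(run_cascade(cases, NULL, NULL,
                                       flat_expression("G1")))
  expect_equal(res2$audit$stages$genes_out[1], 0)
  expect_equal(nrow(res2$candidates), 0)

  empty <- variant_cohort(v[0, ], call_table(character(), character(),
                                             integer()))
  expect_error(run_cascade(empty, NULL, NULL, flat_expression("G1")),
               "empty")
  expect_warning(run_cascade(cases, NULL, NULL, flat_expression("G1")),
                 "no-op")
})

test_that("recurrence histogram bins genes by distinct patient count", {
  cand <- tibble::tibble(gene = c("A", "B", "C", "D"),
                         patient_count = c(1L, 1L, 2L, 4L),
                         n_variants = 1L, variants = "v")
  h <- recurrence_histogram(cand)
  expect_equal(h$patient_count, c(1L, 2L, 4L))
  expect_equal(h$n_genes, c(2L, 1L, 1L))
  expect_equal(h$percent, c(50, 25, 25))
  expect_equal(sum(h$n_genes), nrow(cand))
  expect_equal(sum(h$percent), 100)

  one <- tibble::tibble(gene = letters[1:10], patient_count = 1L,
                        n_variants = 1L, variants = "v")
  h1 <- recurrence_histogram(one)
  expect_equal(h1$n_genes, 10L)
  expect_equal(h1$percent, 100)
})

test_that("planted recurrence structure is recovered exactly", {
  sim <- simulate_prioritization_cohort(cohort_sim_config(
    seed = 23, n_cases = 50, n_controls = 10, n_genes = 60, n_planted = 8,
    recurrence_probs = c(0.4, 0.3, 0.2, 0.1)))
  res <- run_cascade(sim$cases, sim$controls, sim$frequency, sim$expression)
  truth <- sim$truth[sim$truth$role == "planted", c("gene", "recurrence")]
  got <- res$candidates[, c("gene", "patient_count")]
  m <- merge(truth, got, by = "gene")
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$patient_count, m$recurrence)
  h <- recurrence_histogram(res)
  expect_equal(sum(h$n_genes), 8)
  expect_equal(h$n_genes,
               as.vector(table(factor(truth$recurrence,
                                      levels = sort(unique(truth$recurrence))))))
})
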