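test_that("cohort generator is a pure function of its config", {
  cfg <- cohort_sim_config(seed = 17, n_cases = 15, n_controls = 6,
                           n_genes = 30)
  s1 <- simulate_prioritization_cohort(cfg)
  s2 <- simulate_prioritization_cohort(cfg)
  expect_identical(s1$cases$variants, s2$cases$variants)
  expect_identical(s1$cases$calls, s2$cases$calls)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expression, s2$expression)
  # different seed, different draws
  s3 <- simulate_prioritization_cohort(cohort_sim_config(
    seed = 18, n_cases = 15, n_controls = 6, n_genes = 30))
  expect_false(identical(s1$cases$calls, s3$cases$calls))
})

test_that("emitted files are byte-identical across reruns and round-trip", {
  cfg <- cohort_sim_config(seed = 9, n_cases = 12, n_controls = 5,
                           n_genes = 25)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim <- simulate_prioritization_cohort(cfg, out_dir = d1)
  simulate_prioritization_cohort(cfg, out_dir = d2)
  for (f in c("cases.vcf", "controls.vcf", "annotations.tsv",
              "frequency.tsv", "expression.tsv", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # files validate against the package's own readers and reproduce the
  # in-memory cascade result
  cases <- read_cohort_vcf(file.path(d1, "cases.vcf"),
                           file.path(d1, "annotations.tsv"))
  controls <- read_cohort_vcf(file.path(d1, "controls.vcf"),
                              file.path(d1, "annotations.tsv"))
  freq <- read_frequency_table(file.path(d1, "frequency.tsv"))
  expr <- read_expression_table(file.path(d1, "expression.tsv"))
  r_file <- run_cascade(cases, controls, freq, expr)
  r_mem <- run_cascade(sim$cases, sim$controls, sim$frequency,
                       sim$expression)
  expect_identical(r_file$candidates, r_mem$candidates)
  expect_identical(r_file$audit$stages, r_mem$audit$stages)
})

test_that("infeasible cohort configs are rejected", {
  expect_error(cohort_sim_config(n_genes = 5, n_planted = 3,
                                 decoys = c(common_maf = 1, low_quality = 1,
                                            het_maf_fail = 1, low_testis = 1,
                                            control_hit = 1)),
               "more planted")
  expect_error(cohort_sim_config(decoys = c(common_maf = 1)), "decoys")
})

test_that("competition model frequencies follow the growth law", {
  # equal cycle times: neutral dynamics, frequencies constant
  cfg_eq <- competition_sim_config(cycle_hours = c(wild_type = 24,
                                                   in_frame = 24,
                                                   frameshift = 24))
  tr <- competition_model_frequencies(cfg_eq)
  expect_true(all(abs(tr$frameshift - tr$frameshift[1]) < 1e-12))
  # slower frameshift class: expected frequency strictly decreases
  cfg <- competition_sim_config()
  tr2 <- competition_model_frequencies(cfg)
  expect_true(all(diff(tr2$frameshift) < 0))
  expect_true(all(diff(tr2$wild_type) > 0))
  expect_equal(rowSums(as.matrix(tr2[, -1])), rep(1, nrow(tr2)),
               tolerance = 1e-12)
  # closed form at one point: n_x(t) = p_x * 2^(t/T_x)
  t1 <- cfg$timepoint_hours[2]
  ab <- cfg$initial_props * 2^(t1 / cfg$cycle_hours)
  expect_equal(as.numeric(tr2[2, -1]), as.numeric(ab / sum(ab)),
               tolerance = 1e-12)
})

test_that("sampled competition counts stay within binomial error of the model", {
  cfg <- competition_sim_config(seed = 4, depth = 50000)
  sim <- simulate_competition_series(cfg)
  obs <- as.matrix(sim$series[, -1]) / cfg$depth
  tru <- as.matrix(sim$truth[, -1])
  # 4 sigma binomial envelope per class and timepoint
  sd4 <- 4 * sqrt(tru * (1 - tru) / cfg$depth)
  expect_true(all(abs(obs - tru) <= sd4 + 1e-12))
  # determinism
  sim2 <- simulate_competition_series(cfg)
  expect_identical(sim$series, sim2$series)
})

test_that("noiseless dye dilution inverts exactly to the true cycle time", {
  m <- simulate_dye_dilution(seed = 1, true_cycle_hours = 24,
                             timepoint_hours = 96, noise_sd = 0)
  dn <- division_number(m$mfi_day0, m$mfi_final, m$mfi_unstained)
  expect_equal(dn, 4)
  expect_equal(mean_cycle_duration(m$elapsed_hours, dn), 24)
  # any T, machine precision
  for (T in c(17.3, 24, 31.9)) {
    m2 <- simulate_dye_dilution(seed = 1, true_cycle_hours = T,
                                timepoint_hours = 90, noise_sd = 0)
    dn2 <- division_number(m2$mfi_day0, m2$mfi_final, m2$mfi_unstained)
    expect_equal(mean_cycle_duration(m2$elapsed_hours, dn2), T,
                 tolerance = 1e-12)
  }
})
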