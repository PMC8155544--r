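#' Configuration for the synthetic prioritization cohort
#'
#' Defaults emulate the study conditions of the cohort the cascade was
#' designed for: 247 azoospermic cases with a Sertoli cell-only
#' phenotype and 89 men with intact spermatogenesis as controls. Planted
#' causal genes carry loss-of-function variants that pass every filter;
#' each decoy gene family violates exactly one designed filter; the
#' remaining background genes carry non-qualifying (missense or
#' synonymous) variants with a gnomAD-like allele-frequency spectrum.
#'
#' @param seed Root seed; the generator is a pure function of the
#'   config (identical config, identical output).
#' @param n_cases,n_controls Cohort sizes.
#' @param n_genes Size of the simulated gene universe.
#' @param n_planted Number of planted causal genes.
#' @param decoys Named counts per decoy class: `common_maf`,
#'   `low_quality`, `het_maf_fail`, `low_testis`, `control_hit`.
#' @param recurrence_probs Probabilities that a planted gene is hit in
#'   1, 2, 3 or 4 distinct patients (none beyond 4, matching the
#'   observed recurrence ceiling).
#' @param mean_depth Mean sequencing depth (Poisson).
#' @param bg_maf_shape1,bg_maf_shape2 Beta parameters of the background
#'   population allele-frequency spectrum.
#' @param tissues Tissue labels of the expression table (`testis`
#'   always included first).
#' @return A list with class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(seed = 1,
                              n_cases = 247,
                              n_controls = 89,
                              n_genes = 160,
                              n_planted = 5,
                              decoys = c(common_maf = 1, low_quality = 1,
                                         het_maf_fail = 1, low_testis = 1,
                                         control_hit = 1),
                              recurrence_probs = c(0.90, 0.06, 0.03, 0.01),
                              mean_depth = 40,
                              bg_maf_shape1 = 0.3,
                              bg_maf_shape2 = 30,
                              tissues = c("testis", "brain", "liver", "heart",
                                          "lung", "kidney", "muscle", "skin",
                                          "spleen", "thyroid")) {
  need <- c("common_maf", "low_quality", "het_maf_fail", "low_testis",
            "control_hit")
  miss <- setdiff(need, names(decoys))
  if (length(miss) > 0) {
    stop("decoys must name counts for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  decoys <- decoys[need]
  stopifnot(n_cases >= 1, n_controls >= 0, n_planted >= 0, all(decoys >= 0),
            mean_depth > 0, length(recurrence_probs) == 4,
            all(recurrence_probs >= 0), "testis" %in% tolower(tissues))
  if (n_planted + sum(decoys) > n_genes) {
    stop("more planted + decoy genes than genes in the universe",
         call. = FALSE)
  }
  structure(
    list(seed = seed, n_cases = n_cases, n_controls = n_controls,
         n_genes = n_genes, n_planted = n_planted, decoys = decoys,
         recurrence_probs = recurrence_probs / sum(recurrence_probs),
         mean_depth = mean_depth, bg_maf_shape1 = bg_maf_shape1,
         bg_maf_shape2 = bg_maf_shape2, tissues = tissues),
    class = "cohort_sim_config"
  )
}

.lof_pick <- c("stop_gained", "frameshift_variant",
               "splice_acceptor_variant", "splice_donor_variant")

# depth/alt-depth pair guaranteed to pass (or fail) the quality gate
.good_call <- function(n, mean_depth) {
  dp <- stats::rpois(n, mean_depth) + 12L
  ad <- stats::rbinom(n, dp, 0.5)
  ad <- pmax(ad, 4L, as.integer(ceiling(0.42 * dp)))
  list(dp = as.integer(dp), ad = pmin(ad, dp))
}
.bad_call <- function(n) {
  dp <- sample(5:8, n, replace = TRUE)      # fails DP >= 10
  ad <- pmin(3L, dp)                        # and AD >= 4; VAF is fine
  list(dp = as.integer(dp), ad = as.integer(ad))
}

#' Simulate a prioritization cohort with planted ground truth
#'
#' Emits case and control cohorts, the annotation sidecar implied by
#' their variant tables, a gnomAD-like frequency table, a GTEx-like
#' expression table, and a truth table recording each planted gene's
#' recurrence and each decoy's designed failing stage. Running
#' [run_cascade()] on the outputs recovers exactly the planted genes.
#'
#' @param cfg A [cohort_sim_config()].
#' @param out_dir Optional directory; when given, all artifacts are
#'   also written as plain-text files (`cases.vcf`, `controls.vcf`,
#'   `annotations.tsv`, `frequency.tsv`, `expression.tsv`,
#'   `truth.tsv`). Identical config produces byte-identical files.
#' @return A list: `cases`, `controls` ([variant_cohort()]s),
#'   `frequency`, `expression`, `truth`, `config`.
#' @export
#' @examples
#' sim <- simulate_prioritization_cohort(cohort_sim_config(seed = 7,
#'   n_cases = 30, n_controls = 10, n_genes = 40))
#' sim$truth[sim$truth$role == "planted", ]
simulate_prioritization_cohort <- function(cfg = cohort_sim_config(),
                                           out_dir = NULL) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)

  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  chroms <- rep(c(as.character(1:22), "X"), length.out = cfg$n_genes)
  roles <- rep("background", cfg$n_genes)
  idx <- seq_len(cfg$n_planted + sum(cfg$decoys))
  roles[idx] <- c(rep("planted", cfg$n_planted),
                  rep(paste0("decoy_", names(cfg$decoys)), cfg$decoys))
  # shuffle role assignment so planted genes are not clustered by locus
  perm <- sample.int(cfg$n_genes)
  roles <- roles[order(perm)]
  # heterozygous-MAF decoys must be autosomal or the X-linked cutoff
  # would coincide with the designed failure
  fix <- roles == "decoy_het_maf_fail" & chroms == "X"
  chroms[fix] <- "7"

  cases <- sprintf("CASE%03d", seq_len(cfg$n_cases))
  ctrls <- sprintf("CTRL%03d", seq_len(cfg$n_controls))

  vrows <- list(); crows <- list(); ctrl_crows <- list(); frows <- list()
  truth <- list()
  add_variant <- function(gene_i, consequence, cadd = NA_real_, af = NA_real_) {
    pos <- gene_i * 10000L + sample.int(5000L, 1)
    alleles <- sample(c("A", "C", "G", "T"), 2)
    vid <- paste(chroms[gene_i], pos, alleles[1], alleles[2], sep = ":")
    vrows[[length(vrows) + 1L]] <<- tibble::tibble(
      chrom = chroms[gene_i], pos = pos, ref = alleles[1], alt = alleles[2],
      gene = genes[gene_i], consequence = consequence, cadd = cadd
    )
    if (!is.na(af)) {
      frows[[length(frows) + 1L]] <<- tibble::tibble(
        chrom = chroms[gene_i], pos = pos, ref = alleles[1],
        alt = alleles[2], af = af
      )
    }
    vid
  }
  add_case_calls <- function(vid, carriers, q, dosage = 1L) {
    crows[[length(crows) + 1L]] <<- tibble::tibble(
      variant_id = vid, sample_id = carriers, dosage = dosage,
      dp = q$dp, ad = q$ad
    )
  }

  testis_frac_target <- stats::setNames(rep(NA_real_, cfg$n_genes), genes)

  for (i in seq_len(cfg$n_genes)) {
    role <- roles[i]
    if (role == "planted") {
      r <- sample(1:4, 1, prob = cfg$recurrence_probs)
      carriers <- sample(cases, r)
      vid <- add_variant(i, sample(.lof_pick, 1))           # absent from gnomAD
      add_case_calls(vid, carriers, .good_call(r, cfg$mean_depth))
      testis_frac_target[i] <- 1
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene = genes[i], role = role, designed_stage = NA_character_,
        recurrence = r)
    } else if (role == "decoy_common_maf") {
      vid <- add_variant(i, sample(.lof_pick, 1),
                         af = stats::runif(1, 0.02, 0.2))
      add_case_calls(vid, sample(cases, 1), .good_call(1, cfg$mean_depth))
      testis_frac_target[i] <- 1
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene = genes[i], role = role, designed_stage = "effect_and_rarity",
        recurrence = NA_integer_)
    } else if (role == "decoy_low_quality") {
      vid <- add_variant(i, sample(.lof_pick, 1))
      add_case_calls(vid, sample(cases, 1), .bad_call(1))
      testis_frac_target[i] <- 1
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene = genes[i], role = role, designed_stage = "quality",
        recurrence = NA_integer_)
    } else if (role == "decoy_het_maf_fail") {
      vid <- add_variant(i, sample(.lof_pick, 1),
                         af = stats::runif(1, 0.002, 0.009))
      add_case_calls(vid, sample(cases, 1), .good_call(1, cfg$mean_depth))
      testis_frac_target[i] <- 1
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene = genes[i], role = role, designed_stage = "genotype_maf",
        recurrence = NA_integer_)
    } else if (role == "decoy_low_testis") {
      vid <- add_variant(i, sample(.lof_pick, 1))
      add_case_calls(vid, sample(cases, 1), .good_call(1, cfg$mean_depth))
      testis_frac_target[i] <- stats::runif(1, 0.2, 0.45)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene = genes[i], role = role, designed_stage = "expression",
        recurrence = NA_integer_)
    } else if (role == "decoy_control_hit") {
      vid <- add_variant(i, sample(.lof_pick, 1))
      add_case_calls(vid, sample(cases, 1), .good_call(1, cfg$mean_depth))
      if (cfg$n_controls > 0) {
        q <- .good_call(1, cfg$mean_depth)
        ctrl_crows[[length(ctrl_crows) + 1L]] <- tibble::tibble(
          variant_id = vid, sample_id = sample(ctrls, 1), dosage = 1L,
          dp = q$dp, ad = q$ad)
      }
      testis_frac_target[i] <- 1
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene = genes[i], role = role, designed_stage = "control_exclusion",
        recurrence = NA_integer_)
    } else {
      # background gene: non-LoF variant, population-frequency spectrum
      cons <- sample(c("missense_variant", "synonymous_variant"), 1,
                     prob = c(0.7, 0.3))
      af <- stats::rbeta(1, cfg$bg_maf_shape1, cfg$bg_maf_shape2)
      vid <- add_variant(i, cons,
                         cadd = round(stats::runif(1, 0, 35), 1), af = af)
      k <- sample(1:3, 1)
      add_case_calls(vid, sample(cases, k), .good_call(k, cfg$mean_depth))
      testis_frac_target[i] <- stats::runif(1, 0.1, 1)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene = genes[i], role = role, designed_stage = "effect_and_rarity",
        recurrence = NA_integer_)
    }
  }

  variants <- dplyr::bind_rows(vrows)
  variants <- variant_table(variants$chrom, variants$pos, variants$ref,
                            variants$alt, variants$gene, variants$consequence,
                            cadd = variants$cadd)
  calls <- dplyr::bind_rows(crows)
  case_cohort <- variant_cohort(
    variants, call_table(calls$variant_id, calls$sample_id, calls$dosage,
                         calls$dp, calls$ad),
    samples = cases
  )

  # controls share the variant universe; a light sprinkling of benign
  # background carriers plus the designed control LoF hits
  if (cfg$n_controls > 0) {
    bg_ids <- variants$variant_id[variants$class != "lof"]
    n_bg <- min(length(bg_ids), 10L)
    if (n_bg > 0) {
      picked <- sample(bg_ids, n_bg)
      q <- .good_call(n_bg, cfg$mean_depth)
      ctrl_crows[[length(ctrl_crows) + 1L]] <- tibble::tibble(
        variant_id = picked, sample_id = sample(ctrls, n_bg, replace = TRUE),
        dosage = 1L, dp = q$dp, ad = q$ad)
    }
    cc <- dplyr::bind_rows(ctrl_crows)
    control_cohort <- variant_cohort(
      variants, call_table(cc$variant_id, cc$sample_id, cc$dosage, cc$dp,
                           cc$ad),
      samples = ctrls
    )
  } else {
    control_cohort <- variant_cohort(
      variants[0, , drop = FALSE],
      call_table(character(), character(), integer()),
      samples = character()
    )
  }

  frequency <- if (length(frows) > 0) {
    fr <- dplyr::bind_rows(frows)
    tibble::tibble(
      variant_id = paste(fr$chrom, fr$pos, fr$ref, fr$alt, sep = ":"),
      af = fr$af, chrom = fr$chrom, pos = fr$pos, ref = fr$ref, alt = fr$alt
    )
  } else {
    tibble::tibble(variant_id = character(), af = numeric(),
                   chrom = character(), pos = integer(), ref = character(),
                   alt = character())
  }

  # expression: testis value plus other tissues scaled to realise the
  # designed testis fraction exactly (testis included in the maximum)
  other <- setdiff(cfg$tissues, cfg$tissues[tolower(cfg$tissues) == "testis"])
  expression <- tibble::tibble(gene = genes)
  testis_val <- round(stats::runif(cfg$n_genes, 40, 150), 2)
  frac <- testis_frac_target[genes]
  max_val <- round(testis_val / frac, 2)
  expression$testis <- testis_val
  mat <- matrix(NA_real_, nrow = cfg$n_genes, ncol = length(other),
                dimnames = list(NULL, other))
  for (j in seq_along(other)) {
    mat[, j] <- round(stats::runif(cfg$n_genes, 0, 0.8) * testis_val, 2)
  }
  # the designated dominant tissue pins the maximum for low-testis genes
  dominant <- other[1]
  low <- frac < 1
  mat[low, dominant] <- max_val[low]
  for (j in seq_along(other)) {
    expression[[other[j]]] <- mat[, j]
  }

  truth <- dplyr::bind_rows(truth)
  out <- list(cases = case_cohort, controls = control_cohort,
              frequency = frequency, expression = expression,
              truth = truth, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_vcf(case_cohort, file.path(out_dir, "cases.vcf"))
    write_cohort_vcf(control_cohort, file.path(out_dir, "controls.vcf"))
    ann <- case_cohort$variants[, c("chrom", "pos", "ref", "alt", "gene",
                                    "consequence", "cadd")]
    write_tsv_plain(ann, file.path(out_dir, "annotations.tsv"))
    write_tsv_plain(frequency[, c("chrom", "pos", "ref", "alt", "af")],
                    file.path(out_dir, "frequency.tsv"))
    write_tsv_plain(expression, file.path(out_dir, "expression.tsv"))
    write_tsv_plain(truth, file.path(out_dir, "truth.tsv"))
    out$files <- file.path(out_dir, c("cases.vcf", "controls.vcf",
                                      "annotations.tsv", "frequency.tsv",
                                      "expression.tsv", "truth.tsv"))
  }
  out
}

#' Configuration for the growth-competition simulator
#'
#' Emulates a 1:1 mix of wild-type and CRISPR-edited cells whose edited
#' pool splits into in-frame and frameshift alleles, growing
#' exponentially with class-specific cycle times and sampled by
#' amplicon sequencing at fixed timepoints.
#'
#' @param seed Root seed.
#' @param initial_props Named initial allele proportions (sum to 1).
#' @param cycle_hours Named class-specific cell-cycle durations (hours).
#' @param timepoint_hours Sampling times in hours (default days 0, 3,
#'   7, 14, 21).
#' @param depth Reads sampled per timepoint.
#' @return A list with class `competition_sim_config`.
#' @export
competition_sim_config <- function(seed = 1,
                                   initial_props = c(wild_type = 0.5,
                                                     in_frame = 0.175,
                                                     frameshift = 0.325),
                                   cycle_hours = c(wild_type = 24,
                                                   in_frame = 25.7,
                                                   frameshift = 27.9),
                                   timepoint_hours = c(0, 3, 7, 14, 21) * 24,
                                   depth = 20000) {
  cls <- c("wild_type", "in_frame", "frameshift")
  stopifnot(setequal(names(initial_props), cls),
            setequal(names(cycle_hours), cls),
            abs(sum(initial_props) - 1) < 1e-9, all(initial_props >= 0),
            all(cycle_hours > 0), length(timepoint_hours) >= 2,
            !is.unsorted(timepoint_hours, strictly = TRUE), depth >= 1)
  structure(list(seed = seed, initial_props = initial_props[cls],
                 cycle_hours = cycle_hours[cls],
                 timepoint_hours = timepoint_hours, depth = depth),
            class = "competition_sim_config")
}

#' Model allele-class frequencies of exponential competition
#'
#' Closed form: class abundance `n_x(t) = p_x * 2^(t / T_x)`; the
#' expected read frequency of a class is its abundance share.
#'
#' @param cfg A [competition_sim_config()].
#' @return Tibble `time, wild_type, in_frame, frameshift` of model
#'   frequencies.
#' @export
competition_model_frequencies <- function(cfg) {
  ab <- sapply(c("wild_type", "in_frame", "frameshift"), function(k) {
    cfg$initial_props[[k]] * 2^(cfg$timepoint_hours / cfg$cycle_hours[[k]])
  })
  ab <- ab / rowSums(ab)
  tibble::tibble(time = cfg$timepoint_hours,
                 wild_type = ab[, "wild_type"],
                 in_frame = ab[, "in_frame"],
                 frameshift = ab[, "frameshift"])
}

#' Simulate a growth-competition sequencing series
#'
#' Read counts are drawn multinomially from the model frequencies of
#' [competition_model_frequencies()] at each timepoint.
#'
#' @param cfg A [competition_sim_config()].
#' @return A list: `series` (observed counts per timepoint), `truth`
#'   (model frequencies), `config`.
#' @export
simulate_competition_series <- function(cfg = competition_sim_config()) {
  stopifnot(inherits(cfg, "competition_sim_config"))
  set.seed(cfg$seed)
  truth <- competition_model_frequencies(cfg)
  counts <- t(apply(as.matrix(truth[, -1]), 1, function(p) {
    stats::rmultinom(1, cfg$depth, p)[, 1]
  }))
  series <- tibble::tibble(time = truth$time,
                           wild_type = as.integer(counts[, 1]),
                           in_frame = as.integer(counts[, 2]),
                           frameshift = as.integer(counts[, 3]))
  list(series = series, truth = truth, config = cfg)
}

#' Simulate dye-dilution proliferation measurements
#'
#' Model: `mfi(t) = background + (mfi0 - background) * 2^(-t / T)` with
#' multiplicative log-normal noise on the background-subtracted signal.
#' Noiseless output inverts exactly through [division_number()] and
#' [mean_cycle_duration()] to the true cycle time `T`.
#'
#' @param seed Root seed.
#' @param true_cycle_hours True cell-cycle duration `T` (hours).
#' @param mfi0 Day-0 median fluorescence intensity.
#' @param background Unstained-control MFI.
#' @param noise_sd Standard deviation of the log-normal noise (0 for a
#'   noiseless series).
#' @param timepoint_hours Assay duration (hours).
#' @param n_replicates Number of replicate measurements.
#' @return Tibble `replicate, mfi_day0, mfi_final, mfi_unstained,
#'   elapsed_hours, true_cycle_hours`.
#' @export
#' @examples
#' m <- simulate_dye_dilution(1, true_cycle_hours = 24, timepoint_hours = 96)
#' division_number(m$mfi_day0, m$mfi_final, m$mfi_unstained)   # exactly 4
simulate_dye_dilution <- function(seed = 1, true_cycle_hours = 24,
                                  mfi0 = 5000, background = 100,
                                  noise_sd = 0, timepoint_hours = 96,
                                  n_replicates = 1) {
  stopifnot(true_cycle_hours > 0, mfi0 > background, timepoint_hours > 0,
            noise_sd >= 0, n_replicates >= 1)
  set.seed(seed)
  signal <- (mfi0 - background) * 2^(-timepoint_hours / true_cycle_hours)
  noise <- if (noise_sd > 0) {
    exp(stats::rnorm(n_replicates, 0, noise_sd))
  } else rep(1, n_replicates)
  tibble::tibble(
    replicate = seq_len(n_replicates),
    mfi_day0 = mfi0,
    mfi_final = background + signal * noise,
    mfi_unstained = background,
    elapsed_hours = timepoint_hours,
    true_cycle_hours = true_cycle_hours
  )
}
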