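#' Filtering thresholds for the prioritization cascade
#'
#' Defaults are the published criteria: loss-of-function variants with
#' population MAF <= 0.01; call quality DP >= 10, AD >= 4, VAF >= 40%
#' (all inclusive); genotype-stratified MAF cutoffs of 0.01 for
#' autosomal homozygotes and 0.001 for heterozygous and X-linked
#' variants; testis expression strictly above 50% of the gene's maximum
#' across tissues. A variant absent from the frequency table is treated
#' as novel (MAF 0).
#'
#' @param lof_maf_max Rarity cutoff for the first stage.
#' @param hom_maf_max,het_maf_max,x_linked_maf_max Genotype-stratified
#'   cutoffs for the third stage.
#' @param min_read_depth,min_alt_depth,min_vaf Call-quality cutoffs
#'   (inclusive).
#' @param testis_fraction_min Expression gate; comparison is strict
#'   (`> testis_fraction_min`).
#' @param missing_maf_policy Only `"zero"` is implemented: absent MAF is
#'   treated as 0.
#' @return A list with class `filter_config`.
#' @export
#' @examples
#' filter_config()
#' filter_config(het_maf_max = 0.005)
filter_config <- function(lof_maf_max = 0.01,
                          hom_maf_max = 0.01,
                          het_maf_max = 0.001,
                          x_linked_maf_max = 0.001,
                          min_read_depth = 10,
                          min_alt_depth = 4,
                          min_vaf = 0.40,
                          testis_fraction_min = 0.5,
                          missing_maf_policy = c("zero")) {
  missing_maf_policy <- match.arg(missing_maf_policy)
  stopifnot(
    lof_maf_max >= 0, lof_maf_max <= 1,
    hom_maf_max >= 0, hom_maf_max <= 1,
    het_maf_max >= 0, het_maf_max <= 1,
    x_linked_maf_max >= 0, x_linked_maf_max <= 1,
    min_read_depth >= 0, min_alt_depth >= 0,
    min_vaf >= 0, min_vaf <= 1,
    testis_fraction_min >= 0, testis_fraction_min <= 1
  )
  structure(
    list(lof_maf_max = lof_maf_max, hom_maf_max = hom_maf_max,
         het_maf_max = het_maf_max, x_linked_maf_max = x_linked_maf_max,
         min_read_depth = min_read_depth, min_alt_depth = min_alt_depth,
         min_vaf = min_vaf, testis_fraction_min = testis_fraction_min,
         missing_maf_policy = missing_maf_policy),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", as.character(x[[nm]]), "\n", sep = "")
  invisible(x)
}

effective_maf <- function(maf) ifelse(is.na(maf), 0, maf)

#' Testis fraction of an expression profile
#'
#' Testis expression divided by the maximum over all tissues (testis
#' included in the maximum). Genes with all-zero profiles get 0.
#'
#' @param expression A wide gene-by-tissue table (first column `gene`),
#'   e.g. from [read_expression_table()]. A `testis` column
#'   (case-insensitive) is required.
#' @return A tibble `gene, testis_fraction`.
#' @export
#' @examples
#' expr <- tibble::tibble(gene = "A", testis = 30, brain = 60)
#' testis_fraction(expr)   # 0.5 -- fails the strict "above 50%" gate
testis_fraction <- function(expression) {
  tis <- which(tolower(names(expression)) == "testis")
  if (length(tis) != 1) {
    stop("expression table must contain exactly one 'testis' column",
         call. = FALSE)
  }
  vals <- as.matrix(expression[, -1, drop = FALSE])
  mx <- apply(vals, 1, max)
  frac <- ifelse(mx > 0, expression[[tis]] / mx, 0)
  tibble::tibble(gene = expression$gene, testis_fraction = as.numeric(frac))
}

# ---- Individual stages -----------------------------------------------------
# Each stage takes and returns a "worktable": carrier calls joined to
# variant annotations plus an `eff_maf` column. Gene-level summaries are
# taken by the audit, not by the stages themselves.

#' Stage 1: variant effect and population rarity
#'
#' Keeps loss-of-function variants whose effective population MAF
#' (missing treated as 0) is at most `cfg$lof_maf_max`.
#'
#' @param work A worktable from [cascade_worktable()].
#' @param cfg A [filter_config()].
#' @return The surviving worktable rows.
#' @export
stage1_effect_and_rarity <- function(work, cfg = filter_config()) {
  dplyr::filter(work, .data$class == "lof", .data$eff_maf <= cfg$lof_maf_max)
}

#' Stage 2: call quality
#'
#' A call survives iff DP, AD and VAF all meet their inclusive
#' thresholds; calls with missing DP or AD fail. A variant survives in
#' the cascade iff at least one case call survives.
#'
#' @inheritParams stage1_effect_and_rarity
#' @return The surviving worktable rows.
#' @export
stage2_quality <- function(work, cfg = filter_config()) {
  ok <- !is.na(work$dp) & !is.na(work$ad) & work$dp > 0 &
    work$dp >= cfg$min_read_depth & work$ad >= cfg$min_alt_depth &
    (work$ad / work$dp) >= cfg$min_vaf
  work[ok, , drop = FALSE]
}

#' Stage 3: genotype-stratified population frequency
#'
#' Autosomal homozygotes tolerate MAF up to `hom_maf_max`; heterozygous
#' and X-linked calls up to `het_maf_max` / `x_linked_maf_max`.
#'
#' @inheritParams stage1_effect_and_rarity
#' @return The surviving worktable rows.
#' @export
stage3_genotype_maf <- function(work, cfg = filter_config()) {
  zy <- zygosity(work$dosage)
  xl <- is_x_linked(work$chrom)
  lim <- ifelse(xl, cfg$x_linked_maf_max,
                ifelse(zy == "homozygous_alt", cfg$hom_maf_max, cfg$het_maf_max))
  work[work$eff_maf <= lim, , drop = FALSE]
}

#' Stage 4: testis-biased expression
#'
#' Keeps genes whose testis fraction is strictly above
#' `cfg$testis_fraction_min`; genes absent from the expression table are
#' removed with reason `"no profile"`.
#'
#' @param genes Character vector of gene symbols.
#' @param expression Wide expression table (see [testis_fraction()]).
#' @param cfg A [filter_config()].
#' @return A list: `kept` (character) and `removed`
#'   (tibble `gene, reason`).
#' @export
stage4_expression <- function(genes, expression, cfg = filter_config()) {
  tf <- testis_fraction(expression)
  frac <- tf$testis_fraction[match(genes, tf$gene)]
  unprofiled <- is.na(frac)
  pass <- !unprofiled & frac > cfg$testis_fraction_min
  removed <- tibble::tibble(
    gene = genes[!pass],
    reason = ifelse(unprofiled[!pass], "no profile",
                    sprintf("testis fraction %.3f <= %.2f",
                            frac[!pass], cfg$testis_fraction_min))
  )
  list(kept = genes[pass], removed = removed)
}

#' Stage 5: exclusion of genes hit in fertile controls
#'
#' Removes any gene in which at least one control individual carries a
#' quality-passing loss-of-function call. Control evidence must itself
#' pass the stage-2 quality gate, but no MAF gate is applied: any
#' loss-of-function allele in a man with intact spermatogenesis
#' disqualifies the gene.
#'
#' @param genes Character vector of candidate gene symbols.
#' @param controls A [variant_cohort()] of fertile controls (or `NULL` /
#'   empty for a no-op).
#' @param cfg A [filter_config()].
#' @return A list: `kept` and `removed` as in [stage4_expression()].
#' @export
stage5_control_exclusion <- function(genes, controls, cfg = filter_config()) {
  if (is.null(controls) || nrow(controls$variants) == 0) {
    return(list(kept = genes,
                removed = tibble::tibble(gene = character(), reason = character())))
  }
  cw <- carrier_table(controls)
  cw <- cw[cw$class == "lof", , drop = FALSE]
  cw <- stage2_quality(cw, cfg)
  hit <- intersect(genes, unique(cw$gene))
  list(
    kept = setdiff(genes, hit),
    removed = tibble::tibble(gene = hit, reason = "LoF in fertile control")
  )
}

#' Build the cascade worktable
#'
#' Carrier calls (alt dosage >= 1) joined to variant annotations with an
#' `eff_maf` column from the frequency table (absent entries treated as
#' MAF 0).
#'
#' @param cohort A [variant_cohort()].
#' @param frequency Frequency table from [read_frequency_table()], or
#'   `NULL` (all variants treated as novel).
#' @return A tibble.
#' @export
cascade_worktable <- function(cohort, frequency = NULL) {
  work <- carrier_table(cohort)
  if (!is.null(frequency)) {
    work <- dplyr::left_join(work,
                             frequency[, c("variant_id", "af")],
                             by = "variant_id")
    work$eff_maf <- effective_maf(work$af)
    work$af <- NULL
  } else {
    work$eff_maf <- effective_maf(work$maf)
  }
  work
}

#' Run the five-stage candidate-gene prioritization cascade
#'
#' Stages are applied in the fixed published order: (1) variant effect
#' and population rarity, (2) call quality, (3) genotype-stratified
#' population frequency, (4) testis-biased expression, (5) exclusion of
#' genes with loss-of-function alleles in fertile controls. Counts are
#' audited at gene level after every stage even when a filter acts per
#' call.
#'
#' @param cases A [variant_cohort()] of patients (must be non-empty).
#' @param controls A [variant_cohort()] of fertile controls, or `NULL`
#'   (stage 5 becomes a no-op, with a warning).
#' @param frequency Population frequency table
#'   ([read_frequency_table()]), or `NULL`.
#' @param expression Wide gene-by-tissue expression table.
#' @param cfg A [filter_config()].
#' @return A list of class `cascade_result`: `candidates` (tibble
#'   `gene, patient_count, n_variants, variants`), `audit` (a
#'   `stage_audit`), and `qualifying` (the surviving per-call worktable).
#' @export
run_cascade <- function(cases, controls, frequency, expression,
                        cfg = filter_config()) {
  stopifnot(inherits(cases, "variant_cohort"))
  if (nrow(cases$variants) == 0 || length(cases$samples) == 0) {
    stop("case cohort is empty", call. = FALSE)
  }
  if (is.null(controls) || length(controls$samples) == 0) {
    warning("no control cohort supplied; control-exclusion stage is a no-op",
            call. = FALSE)
    controls <- NULL
  }

  work <- cascade_worktable(cases, frequency)
  audit_rows <- list(); removed_rows <- list()
  genes_before <- sort(unique(work$gene))

  log_stage <- function(name, genes_in, genes_out, removed_reason) {
    gone <- setdiff(genes_in, genes_out)
    audit_rows[[length(audit_rows) + 1L]] <<- tibble::tibble(
      stage = name, genes_in = length(genes_in), genes_out = length(genes_out)
    )
    if (length(gone) > 0 && is.character(removed_reason)) {
      removed_rows[[length(removed_rows) + 1L]] <<- tibble::tibble(
        stage = name, gene = gone, reason = removed_reason
      )
    }
  }

  w1 <- stage1_effect_and_rarity(work, cfg)
  g1 <- sort(unique(w1$gene))
  log_stage("effect_and_rarity", genes_before, g1, "not a rare LoF variant")

  w2 <- stage2_quality(w1, cfg)
  g2 <- sort(unique(w2$gene))
  log_stage("quality", g1, g2, "no quality-passing call")

  w3 <- stage3_genotype_maf(w2, cfg)
  g3 <- sort(unique(w3$gene))
  log_stage("genotype_maf", g2, g3, "genotype-stratified MAF too high")

  s4 <- stage4_expression(g3, expression, cfg)
  g4 <- sort(s4$kept)
  log_stage("expression", g3, g4, NULL)
  if (nrow(s4$removed) > 0) {
    removed_rows[[length(removed_rows) + 1L]] <-
      tibble::tibble(stage = "expression", gene = s4$removed$gene,
                     reason = s4$removed$reason)
  }

  s5 <- stage5_control_exclusion(g4, controls, cfg)
  g5 <- sort(s5$kept)
  log_stage("control_exclusion", g4, g5, NULL)
  if (nrow(s5$removed) > 0) {
    removed_rows[[length(removed_rows) + 1L]] <-
      tibble::tibble(stage = "control_exclusion", gene = s5$removed$gene,
                     reason = s5$removed$reason)
  }

  qualifying <- w3[w3$gene %in% g5, , drop = FALSE]
  candidates <- qualifying |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      patient_count = dplyr::n_distinct(.data$sample_id),
      n_variants = dplyr::n_distinct(.data$variant_id),
      variants = paste(sort(unique(.data$variant_id)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$patient_count), .data$gene)

  audit <- structure(
    list(stages = dplyr::bind_rows(audit_rows),
         removed = if (length(removed_rows) > 0) dplyr::bind_rows(removed_rows)
                   else tibble::tibble(stage = character(), gene = character(),
                                       reason = character())),
    class = "stage_audit"
  )
  structure(list(candidates = candidates, audit = audit,
                 qualifying = tibble::as_tibble(qualifying)),
            class = "cascade_result")
}

#' @export
print.stage_audit <- function(x, ...) {
  cat("<stage_audit>\n")
  s <- x$stages
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s in %5d  out %5d\n",
                s$stage[i], s$genes_in[i], s$genes_out[i]))
  }
  invisible(x)
}

#' @export
print.cascade_result <- function(x, ...) {
  print(x$audit)
  cat(nrow(x$candidates), "candidate gene(s)\n")
  print(x$candidates, n = 10)
  invisible(x)
}

#' Recurrence histogram of candidate genes
#'
#' Bins candidate genes by the number of distinct patients carrying at
#' least one qualifying variant, with percentages of the candidate
#' total.
#'
#' @param candidates The `candidates` tibble of a [run_cascade()] result
#'   (or the result itself).
#' @return A tibble `patient_count, n_genes, percent` (empty for an
#'   empty candidate set).
#' @export
recurrence_histogram <- function(candidates) {
  if (inherits(candidates, "cascade_result")) candidates <- candidates$candidates
  if (nrow(candidates) == 0) {
    return(tibble::tibble(patient_count = integer(), n_genes = integer(),
                          percent = numeric()))
  }
  candidates |>
    dplyr::count(.data$patient_count, name = "n_genes") |>
    dplyr::mutate(percent = 100 * .data$n_genes / sum(.data$n_genes)) |>
    dplyr::arrange(.data$patient_count)
}

#' Write cascade outputs to a directory
#'
#' Candidates as TSV, the audit both as a readable text report and a
#' machine-readable key-value JSON document.
#'
#' @param result A `cascade_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cascade_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_plain(result$candidates, file.path(out_dir, "candidates.tsv"))
  s <- result$audit$stages
  writeLines(
    sprintf("%s\tin=%d\tout=%d", s$stage, s$genes_in, s$genes_out),
    file.path(out_dir, "audit.txt")
  )
  jsonlite::write_json(
    list(stages = s, removed = result$audit$removed),
    file.path(out_dir, "audit.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
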