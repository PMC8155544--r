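#' Does a variant qualify for the known-gene panel screen?
#'
#' A variant qualifies if it is loss-of-function, or missense with CADD
#' >= 20 (missense without a CADD score never qualifies), and is rare in
#' the population: MAF <= 0.01 for homozygous carriers, MAF <= 0.001 for
#' heterozygous carriers (missing MAF treated as 0).
#'
#' @param consequence Consequence term(s); classified with
#'   [classify_consequence()].
#' @param cadd CADD score(s), `NA` when absent.
#' @param maf Population MAF(s), `NA` when absent.
#' @param zyg Zygosity: `"homozygous_alt"` or `"heterozygous"`.
#' @param cadd_min CADD cutoff for missense variants.
#' @param hom_maf_max,het_maf_max Rarity cutoffs by zygosity.
#' @return Logical vector.
#' @export
#' @examples
#' variant_qualifies("frameshift_variant", NA, NA, "heterozygous")  # TRUE
#' variant_qualifies("missense_variant", 19.9, 0, "heterozygous")   # FALSE
variant_qualifies <- function(consequence, cadd, maf, zyg,
                              cadd_min = 20, hom_maf_max = 0.01,
                              het_maf_max = 0.001) {
  stopifnot(all(zyg %in% c("homozygous_alt", "heterozygous")))
  cls <- classify_consequence(consequence)
  effect_ok <- cls == "lof" |
    (cls == "missense" & !is.na(cadd) & cadd >= cadd_min)
  m <- effective_maf(maf)
  rare_ok <- ifelse(zyg == "homozygous_alt", m <= hom_maf_max, m <= het_maf_max)
  effect_ok & rare_ok
}

#' Screen one patient's variants against a gene panel
#'
#' Non-recessive panel genes are hit by any single qualifying variant.
#' Recessive genes require a homozygous qualifying variant or a likely
#' compound-heterozygous state: at least two distinct qualifying
#' variants in the same gene in the same patient (phase unknown).
#' Variants in genes absent from the panel are ignored.
#'
#' @param variants Tibble with one row per variant carried by the
#'   patient: columns `variant_id`, `gene`, `consequence`, `cadd`,
#'   `maf`, `zygosity` (values `homozygous_alt` / `heterozygous`).
#' @param panel Tibble `gene, inheritance` (see [read_panel()]).
#' @param ... Threshold overrides passed to [variant_qualifies()].
#' @return Tibble of hits: `gene, inheritance, rationale, n_variants,
#'   variants`; rationale is one of `lof`, `missense_cadd`,
#'   `homozygous`, `compound_het`.
#' @export
screen_patient <- function(variants, panel, ...) {
  stopifnot(all(c("variant_id", "gene", "consequence", "cadd", "maf",
                  "zygosity") %in% names(variants)))
  empty <- tibble::tibble(gene = character(), inheritance = character(),
                          rationale = character(), n_variants = integer(),
                          variants = character())
  v <- variants[variants$gene %in% panel$gene, , drop = FALSE]
  if (nrow(v) == 0) return(empty)
  q <- variant_qualifies(v$consequence, v$cadd, v$maf, v$zygosity, ...)
  v <- v[q, , drop = FALSE]
  if (nrow(v) == 0) return(empty)
  v$class <- classify_consequence(v$consequence)
  v <- dplyr::left_join(v, panel, by = "gene")

  one_gene <- function(g) {
    inh <- g$inheritance[1]
    collapse <- function(rows) paste(sort(unique(rows$variant_id)), collapse = ";")
    if (inh == "non_recessive") {
      # any qualifying variant hits; rationale from the strongest class
      rationale <- if (any(g$class == "lof")) "lof" else "missense_cadd"
      return(tibble::tibble(gene = g$gene[1], inheritance = inh,
                            rationale = rationale,
                            n_variants = dplyr::n_distinct(g$variant_id),
                            variants = collapse(g)))
    }
    hom <- g[g$zygosity == "homozygous_alt", , drop = FALSE]
    if (nrow(hom) > 0) {
      return(tibble::tibble(gene = g$gene[1], inheritance = inh,
                            rationale = "homozygous",
                            n_variants = dplyr::n_distinct(g$variant_id),
                            variants = collapse(g)))
    }
    if (dplyr::n_distinct(g$variant_id) >= 2) {
      return(tibble::tibble(gene = g$gene[1], inheritance = inh,
                            rationale = "compound_het",
                            n_variants = dplyr::n_distinct(g$variant_id),
                            variants = collapse(g)))
    }
    empty
  }
  out <- dplyr::bind_rows(lapply(split(v, v$gene), one_gene))
  dplyr::arrange(out, .data$gene)
}

#' Screen every patient of a cohort against a gene panel
#'
#' Convenience wrapper building the per-patient variant view (carrier
#' calls with zygosity and effective MAF) and calling [screen_patient()]
#' for each sample.
#'
#' @param cohort A [variant_cohort()].
#' @param panel Tibble `gene, inheritance`.
#' @param frequency Optional frequency table ([read_frequency_table()]).
#' @param ... Threshold overrides passed to [variant_qualifies()].
#' @return Tibble of hits with a leading `sample_id` column.
#' @export
screen_cohort <- function(cohort, panel, frequency = NULL, ...) {
  work <- cascade_worktable(cohort, frequency)
  work$zygosity <- zygosity(work$dosage)
  work$maf <- work$eff_maf
  hits <- lapply(split(work, work$sample_id), function(w) {
    h <- screen_patient(w, panel, ...)
    if (nrow(h) > 0) h$sample_id <- w$sample_id[1]
    h
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(sample_id = character(), gene = character(),
                          inheritance = character(), rationale = character(),
                          n_variants = integer(), variants = character()))
  }
  dplyr::select(out, "sample_id", dplyr::everything())
}
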