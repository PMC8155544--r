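#' Allele counts from carrier tallies
#'
#' Converts individual-level carrier counts into affected / unaffected
#' allele counts: heterozygotes contribute one affected allele,
#' homozygotes `ploidy`, and every individual contributes `ploidy`
#' alleles in total.
#'
#' @param n_individuals Cohort size.
#' @param het_carriers,hom_carriers Carrier counts.
#' @param ploidy Alleles per individual (2 for autosomes).
#' @return Named integer vector `c(affected, unaffected)`.
#' @export
#' @examples
#' alleles_from_individuals(247, 1, 0)      # c(affected = 1, unaffected = 493)
alleles_from_individuals <- function(n_individuals, het_carriers,
                                     hom_carriers = 0, ploidy = 2) {
  stopifnot(n_individuals >= 0, het_carriers >= 0, hom_carriers >= 0,
            ploidy >= 1)
  if (het_carriers + hom_carriers > n_individuals) {
    stop("carriers exceed cohort size", call. = FALSE)
  }
  affected <- het_carriers + ploidy * hom_carriers
  c(affected = as.integer(affected),
    unaffected = as.integer(ploidy * n_individuals - affected))
}

#' Exact conditional two-sided Fisher test for a 2x2 table
#'
#' Both margins fixed; the two-sided p-value is the sum of
#' hypergeometric point probabilities over all tables whose point
#' probability does not exceed that of the observed table
#' (minimum-likelihood rule), with a relative tolerance of `rel_tol` on
#' the comparison to guard floating-point ties. Degenerate margins
#' (an empty row or column) return p = 1 with attribute
#' `degenerate = TRUE`.
#'
#' @param a,b Cohort affected / unaffected allele counts.
#' @param c,d Reference affected / unaffected allele counts.
#' @param rel_tol Relative tolerance for the point-probability
#'   comparison.
#' @return The two-sided p-value (numeric scalar, clipped to <= 1).
#' @export
#' @examples
#' fisher_two_sided(2, 3, 4, 1)   # 132/252
fisher_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4, all(!is.na(cells)), all(cells >= 0),
            all(cells == floor(cells)))
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) {
    return(structure(1, degenerate = TRUE))
  }
  support <- max(0, k - m2):min(k, m1)
  # log point probabilities from first principles (binomial coefficients)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(n, k)
  logp_obs <- lchoose(m1, a) + lchoose(m2, k - a) - lchoose(n, k)
  keep <- logp <= logp_obs + log1p(rel_tol)
  min(sum(exp(logp[keep])), 1)
}

#' Woolf logit confidence interval for an odds ratio
#'
#' Normal-approximation interval on the log odds ratio with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. If any cell is zero, the
#' Haldane-Anscombe correction adds 0.5 to every cell first and
#' `correction_applied` is set.
#'
#' @inheritParams fisher_two_sided
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `odds_ratio`, `ci_low`, `ci_high`, `conf_level`,
#'   `correction_applied`.
#' @export
#' @examples
#' woolf_logit_interval(10, 10, 10, 10)
woolf_logit_interval <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  stopifnot(all(!is.na(cells)), all(cells >= 0),
            conf_level > 0, conf_level < 1)
  if (all(cells == 0)) stop("all-zero table has no odds ratio", call. = FALSE)
  correction <- any(cells == 0)
  if (correction) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    conf_level = conf_level,
    correction_applied = correction
  )
}

#' Allele-level loss-of-function burden test
#'
#' Compares the number of alleles affected by loss-of-function variants
#' in a gene between a patient cohort and a reference population.
#' Carrier counts are expanded to allele counts
#' ([alleles_from_individuals()]), then tested with the exact two-sided
#' Fisher test and summarized with the Woolf logit odds-ratio interval.
#'
#' @param cohort_n,cohort_het,cohort_hom Cohort size and carrier counts.
#' @param ref_n,ref_het,ref_hom Reference population size and carrier
#'   counts.
#' @param conf_level Confidence level for the Woolf interval.
#' @param ploidy Alleles per individual (2 for autosomal genes).
#' @param ref_allele_number Optional total reference allele number
#'   overriding `ploidy * ref_n` (population databases can report fewer
#'   called alleles than 2N at a site).
#' @return A list of class `lof_burden` with the 2x2 table, `p_two_sided`
#'   and the Woolf interval fields.
#' @export
#' @examples
#' lof_burden_test(247, 1, 0, 125748, 1, 0)
lof_burden_test <- function(cohort_n, cohort_het, cohort_hom = 0,
                            ref_n, ref_het, ref_hom = 0,
                            conf_level = 0.95, ploidy = 2,
                            ref_allele_number = NULL) {
  co <- alleles_from_individuals(cohort_n, cohort_het, cohort_hom, ploidy)
  re <- alleles_from_individuals(ref_n, ref_het, ref_hom, ploidy)
  if (!is.null(ref_allele_number)) {
    if (ref_allele_number < re[["affected"]]) {
      stop("reference allele number smaller than affected alleles",
           call. = FALSE)
    }
    re[["unaffected"]] <- as.integer(ref_allele_number - re[["affected"]])
  }
  a <- co[["affected"]]; b <- co[["unaffected"]]
  c_ <- re[["affected"]]; d <- re[["unaffected"]]
  p <- fisher_two_sided(a, b, c_, d)
  wi <- woolf_logit_interval(a, b, c_, d, conf_level)
  structure(
    list(table = matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                        dimnames = list(c("cohort", "reference"),
                                        c("affected", "unaffected"))),
         p_two_sided = as.numeric(p),
         degenerate = isTRUE(attr(p, "degenerate")),
         odds_ratio = wi$odds_ratio, ci_low = wi$ci_low,
         ci_high = wi$ci_high, conf_level = wi$conf_level,
         correction_applied = wi$correction_applied),
    class = "lof_burden"
  )
}

#' @export
print.lof_burden <- function(x, ...) {
  cat("Allele-level LoF burden test (two-sided Fisher, Woolf logit CI)\n")
  print(x$table)
  cat(sprintf("p = %.4g\nOR = %.4g  [%.4g, %.4g] at %.0f%%%s\n",
              x$p_two_sided, x$odds_ratio, x$ci_low, x$ci_high,
              100 * x$conf_level,
              if (x$correction_applied) "  (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}
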