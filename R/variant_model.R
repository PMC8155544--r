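#' Canonical consequence synonym map
#'
#' Annotation pipelines spell functional consequences differently
#' ("stop-gain", "stop_gained", "stopgain SNV", ...). This map normalizes
#' common dialects onto Sequence Ontology terms before classification.
#' Users may extend it and pass the result to [classify_consequence()].
#'
#' @return Named character vector mapping lower-cased input spellings to
#'   Sequence Ontology terms.
#' @export
#' @examples
#' consequence_synonyms()[["stop-gain"]]
consequence_synonyms <- function() {
  c(
    "stop-gain"               = "stop_gained",
    "stopgain"                = "stop_gained",
    "stop gained"             = "stop_gained",
    "nonsense"                = "stop_gained",
    "frameshift"              = "frameshift_variant",
    "frameshift deletion"     = "frameshift_variant",
    "frameshift insertion"    = "frameshift_variant",
    "splice donor"            = "splice_donor_variant",
    "splice-donor"            = "splice_donor_variant",
    "splice acceptor"         = "splice_acceptor_variant",
    "splice-acceptor"         = "splice_acceptor_variant",
    "missense"                = "missense_variant",
    "nonsynonymous"           = "missense_variant",
    "synonymous"              = "synonymous_variant"
  )
}

# The loss-of-function set: stop, frameshift, splice acceptor and splice
# donor. This set is closed; everything else is missense or other.
.lof_terms <- c(
  "stop_gained", "frameshift_variant",
  "splice_acceptor_variant", "splice_donor_variant"
)
.missense_terms <- "missense_variant"

#' Classify a consequence term into lof / missense / other
#'
#' Total, deterministic mapping. The loss-of-function class is exactly
#' \{stop gained, frameshift, splice acceptor, splice donor\}; missense
#' variants form their own class; every other (or unknown) term maps to
#' `other`.
#'
#' @param term Character vector of consequence terms (any common dialect;
#'   see [consequence_synonyms()]).
#' @param synonyms Named character vector of extra spellings.
#' @return Character vector with values in `c("lof", "missense", "other")`.
#' @export
#' @examples
#' classify_consequence(c("frameshift_variant", "stop-gain", "missense_variant"))
classify_consequence <- function(term, synonyms = consequence_synonyms()) {
  stopifnot(is.character(term))
  key <- tolower(trimws(term))
  hit <- !is.na(match(key, names(synonyms)))
  key[hit] <- unname(synonyms[key[hit]])
  out <- rep("other", length(key))
  out[key %in% .lof_terms] <- "lof"
  out[key %in% .missense_terms] <- "missense"
  out
}

#' Variant allele fraction of a genotype call
#'
#' `ad / dp`, the fraction of reads supporting the alternate allele.
#'
#' @param ad Alternate-allele read depth (non-negative integer vector).
#' @param dp Total read depth (positive integer vector).
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' variant_allele_fraction(4, 10)   # 0.40, the quality-filter boundary
variant_allele_fraction <- function(ad, dp) {
  stopifnot(length(ad) == length(dp))
  if (any(!is.na(dp) & dp <= 0)) {
    stop("variant allele fraction is undefined at read depth 0", call. = FALSE)
  }
  bad <- !is.na(ad) & !is.na(dp) & ad > dp
  if (any(bad)) stop("alt depth exceeds read depth", call. = FALSE)
  ad / dp
}

#' Zygosity of a genotype call
#'
#' @param dosage Integer copies of the alternate allele (0, 1, 2) or `NA`.
#' @return Character vector: `homozygous_alt`, `heterozygous`, `reference`
#'   or `missing`.
#' @export
zygosity <- function(dosage) {
  out <- rep("missing", length(dosage))
  out[!is.na(dosage) & dosage == 0] <- "reference"
  out[!is.na(dosage) & dosage == 1] <- "heterozygous"
  out[!is.na(dosage) & dosage == 2] <- "homozygous_alt"
  if (any(!is.na(dosage) & !dosage %in% 0:2)) {
    stop("alt dosage must be 0, 1, 2 or NA", call. = FALSE)
  }
  out
}

#' Is a chromosome label X-linked?
#'
#' Case-insensitive; an optional `chr` prefix is stripped before
#' comparison, so `"chrX"`, `"X"` and `"x"` all qualify.
#'
#' @param chromosome Character vector of chromosome labels.
#' @return Logical vector.
#' @export
is_x_linked <- function(chromosome) {
  lab <- sub("^chr", "", tolower(as.character(chromosome)))
  lab == "x"
}

#' Assemble an annotated variant table
#'
#' The atom of all filters: one row per (chromosome, position, ref, alt)
#' with gene symbol, consequence term, optional population MAF and CADD
#' score. A `variant_id` key column is added for joining against call
#' tables.
#'
#' @param chrom,pos,ref,alt Variant identity (single alternate allele per
#'   row; position 1-based).
#' @param gene Gene symbol (non-empty).
#' @param consequence Consequence term.
#' @param cadd Optional CADD score (`NA` when absent).
#' @param maf Optional population minor allele frequency in \[0, 1\]
#'   (`NA` when the variant is absent from the frequency table).
#' @return A tibble with class column `class` from [classify_consequence()].
#' @export
variant_table <- function(chrom, pos, ref, alt, gene, consequence,
                          cadd = NA_real_, maf = NA_real_) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  stopifnot(all(nzchar(chrom)), all(pos >= 1L),
            all(nzchar(ref)), all(nzchar(alt)), all(ref != alt),
            all(nzchar(gene)))
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop("population MAF must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = pos, ref = as.character(ref),
    alt = as.character(alt), gene = as.character(gene),
    consequence = as.character(consequence),
    class = classify_consequence(as.character(consequence)),
    cadd = as.numeric(cadd), maf = as.numeric(maf)
  )
}

#' Assemble a genotype call table
#'
#' Long format: one row per (variant, sample). Calls with missing dosage
#' are retained but excluded from every filter.
#'
#' @param variant_id Key matching [variant_table()] rows.
#' @param sample_id Sample identifier.
#' @param dosage Copies of the alternate allele (0/1/2 or `NA`).
#' @param dp,ad Read depth and alternate-allele depth (`NA` when the VCF
#'   omits them).
#' @return A tibble.
#' @export
call_table <- function(variant_id, sample_id, dosage, dp = NA_integer_,
                       ad = NA_integer_) {
  dosage <- as.integer(dosage)
  if (any(!is.na(dosage) & !dosage %in% 0:2)) {
    stop("alt dosage must be 0, 1, 2 or NA", call. = FALSE)
  }
  dp <- as.integer(dp); ad <- as.integer(ad)
  if (any(!is.na(dp) & dp < 0) || any(!is.na(ad) & ad < 0)) {
    stop("read depths must be non-negative", call. = FALSE)
  }
  if (any(!is.na(dp) & !is.na(ad) & ad > dp)) {
    stop("alt depth exceeds read depth", call. = FALSE)
  }
  tibble::tibble(
    variant_id = as.character(variant_id),
    sample_id = as.character(sample_id),
    dosage = dosage, dp = dp, ad = ad
  )
}

#' Bundle variants and calls into a cohort object
#'
#' @param variants A [variant_table()].
#' @param calls A [call_table()]; every `variant_id` must exist in
#'   `variants`.
#' @param samples Optional full sample roster (defaults to samples seen in
#'   `calls`); kept so that samples without a single alternate call still
#'   count toward cohort size.
#' @return A list with class `variant_cohort`.
#' @export
variant_cohort <- function(variants, calls, samples = NULL) {
  stopifnot(is.data.frame(variants), is.data.frame(calls))
  orphan <- setdiff(calls$variant_id, variants$variant_id)
  if (length(orphan) > 0) {
    stop("calls reference unknown variants: ", paste(utils::head(orphan, 3),
         collapse = ", "), call. = FALSE)
  }
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  structure(
    list(variants = tibble::as_tibble(variants),
         calls = tibble::as_tibble(calls),
         samples = as.character(samples)),
    class = "variant_cohort"
  )
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat("<variant_cohort> ", nrow(x$variants), " variants, ",
      length(x$samples), " samples, ", nrow(x$calls), " calls\n", sep = "")
  invisible(x)
}

# Carrier calls (dosage >= 1) joined to their variant annotations; the
# working table every cascade stage consumes.
carrier_table <- function(cohort) {
  calls <- dplyr::filter(cohort$calls, !is.na(.data$dosage), .data$dosage >= 1L)
  dplyr::inner_join(calls, cohort$variants, by = "variant_id")
}
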