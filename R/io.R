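#' Read a cohort from a VCF and an annotation sidecar
#'
#' Parses a VCF 4.2 file with FORMAT fields `GT`, `DP` and `AD`
#' (via \pkg{vcfR}), splits multi-allelic records into one row per
#' alternate allele (AD taken per allele), and joins the tab-separated
#' annotation sidecar (`chrom, pos, ref, alt, gene, consequence, cadd`).
#' Variants without a sidecar row are dropped with a warning: all filters
#' need a gene and consequence.
#'
#' @param vcf_path Path to an (uncompressed or gzipped) VCF.
#' @param annotation_path Path to the sidecar table.
#' @return A [variant_cohort()].
#' @export
read_cohort_vcf <- function(vcf_path, annotation_path) {
  for (p in c(vcf_path, annotation_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  adm <- vcfR::extract.gt(vcf, element = "AD")

  ann <- read_annotation_table(annotation_path)

  rows <- list(); crows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt[i, , drop = TRUE]
    ads <- adm[i, , drop = TRUE]
    dps <- dp[i, , drop = TRUE]
    alleles <- strsplit(gsub("\\|", "/", gts), "/", fixed = FALSE)
    ad_split <- strsplit(ads, ",", fixed = TRUE)
    for (j in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j], stringsAsFactors = FALSE
      )
      dosage <- vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
        sum(a == as.character(j))
      }, integer(1))
      ad_j <- vapply(ad_split, function(a) {
        if (length(a) < j + 1L || anyNA(a)) return(NA_integer_)
        suppressWarnings(as.integer(a[j + 1L]))
      }, integer(1))
      crows[[length(crows) + 1L]] <- data.frame(
        variant_id = paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[j], sep = ":"),
        sample_id = samples, dosage = dosage,
        dp = as.integer(dps), ad = ad_j, stringsAsFactors = FALSE
      )
    }
  }
  vtab <- dplyr::bind_rows(rows)
  vtab$variant_id <- paste(vtab$chrom, vtab$pos, vtab$ref, vtab$alt, sep = ":")
  merged <- dplyr::inner_join(
    vtab, ann,
    by = c("chrom", "pos", "ref", "alt")
  )
  missing_ann <- setdiff(vtab$variant_id, merged$variant_id)
  if (length(missing_ann) > 0) {
    warning(length(missing_ann), " variant(s) lacked sidecar annotation and were dropped",
            call. = FALSE)
  }
  variants <- variant_table(
    merged$chrom, merged$pos, merged$ref, merged$alt,
    merged$gene, merged$consequence, cadd = merged$cadd
  )
  calls <- dplyr::bind_rows(crows)
  calls <- calls[calls$variant_id %in% variants$variant_id, , drop = FALSE]
  variant_cohort(variants,
                 call_table(calls$variant_id, calls$sample_id, calls$dosage,
                            calls$dp, calls$ad),
                 samples = samples)
}

#' Read a variant annotation sidecar
#'
#' Tab-separated with header `chrom, pos, ref, alt, gene, consequence,
#' cadd` (missing CADD as `NA` or empty).
#' @param path File path.
#' @return A tibble.
#' @export
read_annotation_table <- function(path) {
  # "T" alleles must not be parsed as logicals
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "cadd")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann$pos <- as.integer(ann$pos)
  ann$cadd <- suppressWarnings(as.numeric(ann$cadd))
  tibble::as_tibble(ann[, need])
}

#' Read a population allele-frequency table
#'
#' Tab-separated with header `chrom, pos, ref, alt, af` (gnomAD-like).
#' @param path File path.
#' @return A tibble with a `variant_id` key column.
#' @export
read_frequency_table <- function(path) {
  fr <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "af")
  miss <- setdiff(need, names(fr))
  if (length(miss) > 0) {
    stop("frequency table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fr$af <- as.numeric(fr$af)
  if (any(!is.na(fr$af) & (fr$af < 0 | fr$af > 1))) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    variant_id = paste(fr$chrom, as.integer(fr$pos), fr$ref, fr$alt, sep = ":"),
    af = fr$af
  )
}

#' Read a gene-by-tissue expression table
#'
#' Tab-separated; first column `gene`, remaining header names are tissue
#' labels (TPM-like values). A `testis` column (case-insensitive) is
#' required by the expression filter.
#' @param path File path.
#' @return A tibble in wide format.
#' @export
read_expression_table <- function(path) {
  ex <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(ex)[1] != "gene") stop("expression table must start with a 'gene' column",
                                   call. = FALSE)
  vals <- as.matrix(ex[, -1, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  tibble::as_tibble(ex)
}

#' Read a gene panel table
#'
#' Tab-separated with header `gene, inheritance`; inheritance is
#' `recessive` or `non_recessive`.
#' @param path File path.
#' @return A tibble.
#' @export
read_panel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "inheritance"), names(p))
  if (length(miss) > 0) {
    stop("panel lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(p$gene)) stop("panel gene symbols must be unique", call. = FALSE)
  bad <- setdiff(unique(p$inheritance), c("recessive", "non_recessive"))
  if (length(bad) > 0) {
    stop("unknown inheritance mode(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(p[, c("gene", "inheritance")])
}

#' Write a cohort as a minimal VCF 4.2 file
#'
#' Emits `GT:DP:AD` per sample with contig headers for chromosomes 1-22
#' and X. Non-carrier samples are written as `0/0` with their recorded
#' depth. Deterministic: row order follows the variant table, sample
#' order the cohort roster.
#'
#' @param cohort A [variant_cohort()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  samples <- cohort$samples
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", c(as.character(1:22), "X"), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  calls <- cohort$calls
  key <- paste(calls$variant_id, calls$sample_id, sep = "\r")
  lut <- split(seq_len(nrow(calls)), key)
  gt_of <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
  }
  lines <- character(nrow(v))
  ord <- order(match(v$chrom, c(as.character(1:22), "X")), v$pos)
  v <- v[ord, , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    idx <- lut[paste(v$variant_id[i], samples, sep = "\r")]
    cells <- vapply(idx, function(j) {
      if (is.null(j) || length(j) == 0) return("0/0:30:30,0")
      j <- j[[1]]
      d <- calls$dosage[j]; dpv <- calls$dp[j]; adv <- calls$ad[j]
      if (is.na(dpv)) dpv <- "."
      refd <- if (is.na(adv) || identical(dpv, ".")) "." else max(as.integer(dpv) - adv, 0L)
      adf <- if (is.na(adv)) "." else paste(refd, adv, sep = ",")
      paste(gt_of(d), dpv, adf, sep = ":")
    }, character(1))
    lines[i] <- paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                        "PASS", ".", "GT:DP:AD", cells), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# Small writers for the sidecar tables the simulator emits.
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
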