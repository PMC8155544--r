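#' Naive global alignment of an amplicon read (fixture helper)
#'
#' Aligns a read globally against the amplicon reference (match 2,
#' mismatch -1, affine gaps costing 6 for the first gapped base and 1
#' for each further base) and extracts indel events in reference
#' coordinates, in the `signed-length@position` convention of
#' [parse_indel_events()]. Intended for generating and checking small
#' fixtures; production input is pre-called indel tables.
#'
#' @param read,reference DNA strings.
#' @return Tibble `length` (signed), `pos` (0-based reference offset).
#' @export
align_amplicon_read <- function(read, reference) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("align_amplicon_read needs the Biostrings package", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = read, subject = reference, type = "global",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 1
  )
  # insertions: gaps in the subject (reference); deletions: gaps in the read
  ins <- Biostrings::indel(Biostrings::subject(aln))[[1]]
  del <- Biostrings::indel(Biostrings::pattern(aln))[[1]]
  sub_start <- Biostrings::start(Biostrings::subject(aln))

  events <- tibble::tibble(length = integer(), pos = integer())
  if (length(del) > 0) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      length = -BiocGenerics::width(del),
      pos = BiocGenerics::start(del) + sub_start - 2L  # 0-based ref offset
    ))
  }
  if (length(ins) > 0) {
    # start() of a subject-side indel is the read position; map to the
    # reference offset by subtracting preceding inserted bases
    st <- BiocGenerics::start(ins); wd <- BiocGenerics::width(ins)
    ref_pos <- st - c(0L, cumsum(wd)[-length(wd)]) + sub_start - 2L
    events <- dplyr::bind_rows(events, tibble::tibble(
      length = as.integer(wd), pos = as.integer(ref_pos)
    ))
  }
  dplyr::arrange(events, .data$pos)
}

#' Call indel events for a set of raw amplicon reads
#'
#' Fixture-mode convenience: aligns each read with
#' [align_amplicon_read()] and encodes the events as strings accepted by
#' [classify_reads()].
#'
#' @param reads Character vector of read sequences (names used as read
#'   ids when present).
#' @param reference Amplicon reference sequence.
#' @return Tibble `read_id, events, substitution_only`.
#' @export
call_reads_from_sequences <- function(reads, reference) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    ev <- align_amplicon_read(reads[[i]], reference)
    tibble::tibble(
      read_id = ids[i],
      events = paste(sprintf("%+d@%d", ev$length, ev$pos), collapse = ";"),
      substitution_only = nrow(ev) == 0 && !identical(reads[[i]], reference)
    )
  })
  dplyr::bind_rows(rows)
}
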