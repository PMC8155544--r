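#' Parse semicolon-separated indel event strings
#'
#' Events are encoded `signed-length@position`, e.g. `"+17@52"` for a
#' 17-bp insertion at amplicon offset 52 or `"-3@40"` for a 3-bp
#' deletion. Positions are 0-based amplicon coordinates.
#'
#' @param events Character vector; empty string or `NA` means no events.
#' @return A list of tibbles (`length`, `pos`), one per input element.
#' @export
parse_indel_events <- function(events) {
  lapply(events, function(e) {
    if (is.na(e) || !nzchar(e)) {
      return(tibble::tibble(length = integer(), pos = integer()))
    }
    parts <- strsplit(e, ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([+-]?[0-9]+)@([0-9]+)$", parts))
    bad <- vapply(m, length, integer(1)) != 3
    if (any(bad)) stop("malformed indel event: ", parts[bad][1], call. = FALSE)
    len <- vapply(m, function(x) as.integer(x[2]), integer(1))
    if (any(len == 0)) stop("indel events must have non-zero length", call. = FALSE)
    tibble::tibble(length = len,
                   pos = vapply(m, function(x) as.integer(x[3]), integer(1)))
  })
}

# Does an indel event overlap a half-open window [start, end)?
# Deletions span [pos, pos + |len|); insertions are points at pos.
event_overlaps <- function(length, pos, window) {
  span_end <- ifelse(length < 0, pos - length, pos + 1L)
  pos < window[2] & span_end > window[1]
}

#' Net indel length of a read within a quantification window
#'
#' Sum of signed lengths (insertions positive, deletions negative) of
#' the events overlapping the window.
#'
#' @param events Tibble with columns `length` (signed, non-zero) and
#'   `pos` (0-based).
#' @param window Half-open interval `c(start, end)` in amplicon
#'   coordinates.
#' @return Integer.
#' @export
net_indel_length <- function(events, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (nrow(events) == 0) return(0L)
  keep <- event_overlaps(events$length, events$pos, window)
  as.integer(sum(events$length[keep]))
}

#' Classify a read as wild type, in-frame or frameshift
#'
#' No indel event in the window: wild type (substitution-only reads are
#' wild type, since reading frame is defined by indel length). At least
#' one indel with net length divisible by 3: in-frame. Otherwise:
#' frameshift.
#'
#' @inheritParams net_indel_length
#' @param substitution_only Logical; `TRUE` forces wild type and
#'   requires an empty event list.
#' @return One of `"wild_type"`, `"in_frame"`, `"frameshift"`.
#' @export
#' @examples
#' classify_read(tibble::tibble(length = 17L, pos = 50L), c(40, 60))  # frameshift
classify_read <- function(events, window, substitution_only = FALSE) {
  if (substitution_only && nrow(events) > 0) {
    stop("substitution-only reads cannot carry indel events", call. = FALSE)
  }
  if (nrow(events) == 0) return("wild_type")
  keep <- event_overlaps(events$length, events$pos, window)
  if (!any(keep)) return("wild_type")
  net <- sum(events$length[keep])
  if (net %% 3 == 0) "in_frame" else "frameshift"
}

#' Tally allele classes over a read set
#'
#' @param reads Tibble with columns `read_id`, `events`
#'   (semicolon-separated `signed-length@position` strings) and
#'   optionally `substitution_only`.
#' @param window Half-open quantification interval, or a cut site via
#'   [quantification_window()].
#' @return Tibble with one row: `wild_type, in_frame, frameshift,
#'   total_reads`.
#' @export
classify_reads <- function(reads, window) {
  stopifnot(all(c("read_id", "events") %in% names(reads)))
  subs <- if ("substitution_only" %in% names(reads)) {
    as.logical(reads$substitution_only)
  } else rep(FALSE, nrow(reads))
  evs <- parse_indel_events(reads$events)
  cls <- mapply(classify_read, evs, substitution_only = subs,
                MoreArgs = list(window = window))
  counts <- table(factor(cls, levels = c("wild_type", "in_frame", "frameshift")))
  tibble::tibble(
    wild_type = as.integer(counts[["wild_type"]]),
    in_frame = as.integer(counts[["in_frame"]]),
    frameshift = as.integer(counts[["frameshift"]]),
    total_reads = nrow(reads)
  )
}

#' Default quantification window around a cut site
#'
#' @param cut_site 0-based cut-site coordinate on the amplicon.
#' @param halfwidth Window half-width in bp (default 10).
#' @return Half-open interval `c(cut_site - halfwidth, cut_site + halfwidth)`.
#' @export
quantification_window <- function(cut_site, halfwidth = 10) {
  stopifnot(halfwidth > 0)
  c(cut_site - halfwidth, cut_site + halfwidth)
}

#' Per-class allele frequencies
#'
#' @param counts One-row tibble (or named vector) with `wild_type`,
#'   `in_frame`, `frameshift` counts.
#' @return Named numeric vector of fractions summing to 1.
#' @export
class_frequencies <- function(counts) {
  k <- c(wild_type = as.numeric(counts[["wild_type"]]),
         in_frame = as.numeric(counts[["in_frame"]]),
         frameshift = as.numeric(counts[["frameshift"]]))
  tot <- sum(k)
  if (tot <= 0) stop("no reads to compute frequencies from", call. = FALSE)
  k / tot
}

#' Fold change of an allele-class frequency between two timepoints
#'
#' Returns the ratio start/end and its nearest-integer fold, the way
#' competition outcomes are reported ("dropped ~13-fold").
#'
#' @param f_start,f_end Frequencies (fractions or percentages, as long
#'   as both use the same scale).
#' @return A list: `ratio`, `fold` (nearest integer), `infinite`
#'   (`TRUE` when `f_end` is 0, in which case `ratio` is `NA`).
#' @export
#' @examples
#' frequency_fold_change(32.46, 2.53)$fold   # 13
frequency_fold_change <- function(f_start, f_end) {
  stopifnot(f_start >= 0, f_end >= 0)
  if (f_end == 0) {
    return(list(ratio = NA_real_, fold = NA_integer_, infinite = TRUE))
  }
  r <- f_start / f_end
  list(ratio = r, fold = as.integer(round(r)), infinite = FALSE)
}

#' Allele-class frequency trajectory of a competition series
#'
#' @param series Tibble with one row per timepoint: `time` (hours or day
#'   labels convertible to numeric order), `wild_type`, `in_frame`,
#'   `frameshift`.
#' @return Tibble adding per-class frequency columns (`*_freq`) and the
#'   read total.
#' @export
competition_frequencies <- function(series) {
  stopifnot(all(c("time", "wild_type", "in_frame", "frameshift") %in%
                  names(series)))
  if (nrow(series) < 2) stop("need at least two timepoints", call. = FALSE)
  if (is.unsorted(series$time, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  tot <- series$wild_type + series$in_frame + series$frameshift
  if (any(tot <= 0)) stop("every timepoint needs reads", call. = FALSE)
  dplyr::mutate(series,
                total_reads = tot,
                wild_type_freq = .data$wild_type / tot,
                in_frame_freq = .data$in_frame / tot,
                frameshift_freq = .data$frameshift / tot)
}

#' Number of cell divisions from dye-dilution fluorescence
#'
#' Assumes the median fluorescence intensity of a dye-labelled
#' population halves with every division:
#' `log2((MFI_day0 - MFI_unstained) / (MFI_final - MFI_unstained))`.
#'
#' @param mfi_day0 MFI immediately after staining.
#' @param mfi_final MFI at the end of the experiment.
#' @param mfi_unstained Background MFI of an unstained control.
#' @return Number of divisions (non-negative real).
#' @export
#' @examples
#' division_number(1000, 250, 0)   # 2 divisions
division_number <- function(mfi_day0, mfi_final, mfi_unstained = 0) {
  if (any(mfi_day0 <= mfi_unstained) || any(mfi_final <= mfi_unstained)) {
    stop("background exceeds signal; check the unstained control",
         call. = FALSE)
  }
  log2((mfi_day0 - mfi_unstained) / (mfi_final - mfi_unstained))
}

#' Mean cell-cycle duration from a division count
#'
#' @param elapsed_hours Assay duration in hours.
#' @param divisions Number of divisions, e.g. from [division_number()].
#' @return Hours per division.
#' @export
#' @examples
#' mean_cycle_duration(96, 4)   # 24 h
mean_cycle_duration <- function(elapsed_hours, divisions) {
  stopifnot(elapsed_hours > 0)
  if (any(divisions <= 0)) {
    stop("cycle duration is undefined without divisions", call. = FALSE)
  }
  elapsed_hours / divisions
}
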