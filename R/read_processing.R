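#' Trim an adapter and all following bases from reads
#'
#' Mismatch-only sliding search: every start position (including 3'-end
#' partial occurrences with at least `min_overlap` bases) is scored by its
#' mismatch fraction; the lowest-fraction, then leftmost, occurrence with
#' mismatch fraction at or below `error_tolerance` is trimmed together with
#' everything downstream of it. Trimming repeats until no acceptable
#' occurrence remains, so the operation is idempotent. Reads without an
#' acceptable occurrence are returned unchanged.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (see
#'   [read_fastq()]).
#' @param adapter adapter sequence.
#' @param error_tolerance maximum mismatch fraction (default 0.2).
#' @param min_overlap minimum 3'-partial overlap considered.
#' @return the read table with trimmed `seq`/`qual`.
#' @export
trim_adapter <- function(reads, adapter, error_tolerance = 0.2,
                         min_overlap = 3) {
  stopifnot(error_tolerance >= 0, error_tolerance < 0.5, nchar(adapter) > 0)
  for (r in seq_len(nrow(reads))) {
    repeat {
      pos <- adapter_position(reads$seq[r], adapter, error_tolerance,
                              min_overlap)
      if (is.na(pos)) break
      reads$seq[r] <- substr(reads$seq[r], 1, pos - 1)
      reads$qual[r] <- substr(reads$qual[r], 1, pos - 1)
    }
  }
  reads
}

adapter_position <- function(seq, adapter, error_tolerance, min_overlap) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  if (n < min_overlap) return(NA_integer_)
  araw <- charToRaw(adapter)
  sraw <- charToRaw(seq)
  best_pos <- NA_integer_
  best_frac <- Inf
  last <- n - min_overlap + 1
  for (s in seq_len(last)) {
    ov <- min(alen, n - s + 1)
    mm <- sum(sraw[s:(s + ov - 1)] != araw[seq_len(ov)])
    frac <- mm / ov
    if (frac <= error_tolerance && frac < best_frac) {
      best_frac <- frac
      best_pos <- s
      if (frac == 0) break
    }
  }
  best_pos
}

phred_ints <- function(qual) utf8ToInt(qual) - 33L

#' Trim low-quality 3' ends and drop short reads
#'
#' Removes trailing bases with quality below `threshold` (3' trimming up to
#' the last base at or above the threshold), then rejects reads shorter than
#' `min_length`. Rejection is recorded in the returned `status`/`reason`
#' columns, never raised as an error.
#'
#' @param reads read table; a `status` column is added (or respected) so
#'   that already-rejected reads pass through untouched.
#' @param threshold Phred threshold (default 20).
#' @param min_length minimum retained length (default 25).
#' @return read table with updated `seq`, `qual`, `status`, `reason`.
#' @export
quality_trim <- function(reads, threshold = 20, min_length = 25) {
  stopifnot(threshold >= 0)
  reads <- ensure_status(reads)
  for (r in which(reads$status == "pass")) {
    q <- phred_ints(reads$qual[r])
    keep <- if (length(q)) max(c(0L, which(q >= threshold))) else 0L
    reads$seq[r] <- substr(reads$seq[r], 1, keep)
    reads$qual[r] <- substr(reads$qual[r], 1, keep)
    if (keep < min_length) {
      reads$status[r] <- "reject"
      reads$reason[r] <- "too_short"
    }
  }
  reads
}

#' Reject reads with too many low-quality bases
#'
#' A read passes when at least `min_fraction` of its bases have quality at
#' or above `min_quality` (boundary inclusive). Empty reads are rejected.
#'
#' @param reads read table.
#' @param min_quality Phred threshold (default 20).
#' @param min_fraction minimum passing-base fraction (default 0.8).
#' @return read table with updated `status`/`reason`.
#' @export
quality_filter <- function(reads, min_quality = 20, min_fraction = 0.8) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  reads <- ensure_status(reads)
  for (r in which(reads$status == "pass")) {
    q <- phred_ints(reads$qual[r])
    if (length(q) == 0 || mean(q >= min_quality) < min_fraction) {
      reads$status[r] <- "reject"
      reads$reason[r] <- "low_quality"
    }
  }
  reads
}

ensure_status <- function(reads) {
  if (is.null(reads$status)) {
    reads$status <- rep("pass", nrow(reads))
    reads$reason <- rep(NA_character_, nrow(reads))
  }
  reads
}

# leftmost lowest-mismatch occurrence of `flank` in seq at or after `from`;
# substitutions only, at most `max_mismatch` of them
find_flank <- function(seq, flank, from = 1, max_mismatch = 1) {
  n <- nchar(seq)
  fl <- nchar(flank)
  if (from > n - fl + 1) return(NA_integer_)
  exact <- regexpr(flank, substr(seq, from, n), fixed = TRUE)[1]
  if (exact > 0) return(from + exact - 1L)
  if (max_mismatch == 0) return(NA_integer_)
  fraw <- charToRaw(flank)
  sraw <- charToRaw(seq)
  best <- NA_integer_
  best_mm <- max_mismatch + 1L
  for (s in from:(n - fl + 1)) {
    mm <- sum(sraw[s:(s + fl - 1)] != fraw)
    if (mm < best_mm) {
      best_mm <- mm
      best <- s
    }
  }
  if (best_mm <= max_mismatch) best else NA_integer_
}

#' Extract barcodes (and stg sequences) from filtered reads
#'
#' Anchors on the amplicon flanks (tolerating one substitution per flank, no
#' indels) and returns the windows between them. Barcodes must be exactly 30
#' bases of unambiguous A/C/G/T; the stg window may have any length up to
#' `pattern$stg_max_length` since Cas9 indels are expected, but must also be
#' unambiguous. Every read receives a status and, when rejected, exactly one
#' reason code out of: `no_upstream_flank`, `no_internal_flank`,
#' `no_downstream_flank`, `bad_barcode_length`, `ambiguous_base`,
#' `stg_too_long`, plus any reason inherited from the quality filters.
#'
#' @param reads read table (after filtering; rejected rows pass through).
#' @param pattern an [amplicon_pattern()].
#' @return data.frame with columns `read_id`, `barcode`, `stg`, `status`,
#'   `reason`.
#' @export
extract_reads <- function(reads, pattern = amplicon_pattern("tumor")) {
  stopifnot(inherits(pattern, "extraction_pattern"))
  reads <- ensure_status(reads)
  n <- nrow(reads)
  out <- data.frame(read_id = reads$id,
                    barcode = rep(NA_character_, n),
                    stg = rep(NA_character_, n),
                    status = reads$status,
                    reason = reads$reason)
  recording <- pattern$layout == "recording"
  mid_flank <- if (recording) pattern$spacer else pattern$downstream_flank
  for (r in which(reads$status == "pass")) {
    seq <- reads$seq[r]
    up <- find_flank(seq, pattern$upstream_flank)
    if (is.na(up)) {
      out$status[r] <- "reject"; out$reason[r] <- "no_upstream_flank"; next
    }
    bc_start <- up + nchar(pattern$upstream_flank)
    mid <- find_flank(seq, mid_flank, from = bc_start)
    if (is.na(mid)) {
      out$status[r] <- "reject"
      out$reason[r] <- if (recording) "no_internal_flank" else "no_downstream_flank"
      next
    }
    barcode <- substr(seq, bc_start, mid - 1)
    if (nchar(barcode) != pattern$barcode_length) {
      out$status[r] <- "reject"; out$reason[r] <- "bad_barcode_length"; next
    }
    if (grepl("[^ACGT]", barcode)) {
      out$status[r] <- "reject"; out$reason[r] <- "ambiguous_base"; next
    }
    if (recording) {
      stg_start <- mid + nchar(mid_flank)
      down <- find_flank(seq, pattern$downstream_flank, from = stg_start)
      if (is.na(down)) {
        out$status[r] <- "reject"; out$reason[r] <- "no_downstream_flank"; next
      }
      stg <- substr(seq, stg_start, down - 1)
      if (nchar(stg) > pattern$stg_max_length) {
        out$status[r] <- "reject"; out$reason[r] <- "stg_too_long"; next
      }
      if (grepl("[^ACGT]", stg)) {
        out$status[r] <- "reject"; out$reason[r] <- "ambiguous_base"; next
      }
      out$stg[r] <- stg
    }
    out$barcode[r] <- barcode
  }
  out
}

#' Run the full read-processing stage
#'
#' Adapter trim, 3' quality trim, quality filter, then flank-anchored
#' extraction. The returned table has one row per input read; `pass` rows
#' carry the extracted barcode (and stg for the recording layout).
#'
#' @param reads read table from [read_fastq()] or [emit_fastq()].
#' @param pattern an [amplicon_pattern()].
#' @param adapter adapter sequence, or `NULL` to skip adapter trimming.
#' @param error_tolerance adapter mismatch tolerance.
#' @param quality_threshold,min_length 3' trim parameters.
#' @param min_quality,min_fraction quality-filter parameters.
#' @return extraction table as in [extract_reads()].
#' @export
process_reads <- function(reads, pattern = amplicon_pattern("tumor"),
                          adapter = NULL, error_tolerance = 0.2,
                          quality_threshold = 20, min_length = 25,
                          min_quality = 20, min_fraction = 0.8) {
  if (!is.null(adapter)) {
    reads <- trim_adapter(reads, adapter, error_tolerance)
  }
  reads <- quality_trim(reads, quality_threshold, min_length)
  reads <- quality_filter(reads, min_quality, min_fraction)
  extract_reads(reads, pattern)
}

#' Count extracted barcodes into a count table
#'
#' @param extracted extraction table from [extract_reads()].
#' @return named integer vector, barcode -> reads, the package's count-table
#'   representation (sorted by decreasing reads then barcode).
#' @export
count_barcodes <- function(extracted) {
  ok <- extracted$status == "pass"
  tab <- table(extracted$barcode[ok])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  sort_counts(counts)
}

#' Count (barcode, stg) pairs into a triplet table
#'
#' @param extracted extraction table from [extract_reads()] with stg calls.
#' @return data.frame with columns `barcode`, `stg`, `reads`.
#' @export
count_triplets <- function(extracted) {
  ok <- extracted$status == "pass" & !is.na(extracted$stg)
  if (!any(ok)) {
    return(data.frame(barcode = character(0), stg = character(0),
                      reads = integer(0)))
  }
  agg <- stats::aggregate(list(reads = rep(1L, sum(ok))),
                          by = list(barcode = extracted$barcode[ok],
                                    stg = extracted$stg[ok]),
                          FUN = sum)
  agg <- agg[order(-agg$reads, agg$barcode, agg$stg), ]
  rownames(agg) <- NULL
  agg
}

sort_counts <- function(counts) {
  counts[order(-counts, names(counts))]
}
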