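#' Hamming distance between equal-length sequences
#'
#' @param a,b character strings of equal length.
#' @return integer count of differing positions.
#' @examples
#' hamming("ACGT", "ACGA")
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("Hamming distance is undefined for sequences of unequal length")
  }
  sum(charToRaw(a) != charToRaw(b))
}

# barcodes as a bytes matrix (nchar x n) for vectorized distance scans
barcode_matrix <- function(barcodes) {
  if (length(barcodes) == 0) return(matrix(raw(0), nrow = 0, ncol = 0))
  vapply(barcodes, charToRaw, raw(nchar(barcodes[1])), USE.NAMES = FALSE)
}

hamming_to_set <- function(barcode, set_matrix) {
  b <- charToRaw(barcode)
  colSums(set_matrix != b)
}

#' Collapse sequencing-error barcode variants by Hamming distance
#'
#' Greedy absorption in decreasing read-count order (ties broken
#' lexicographically): each barcode becomes a new representative unless it
#' lies within `max_dist` of an existing representative, in which case its
#' reads are added to the closest representative (ties: lowest distance,
#' then highest current count, then lexicographic). Absorbed barcodes never
#' absorb others, so no transitive chaining occurs, and total reads are
#' conserved.
#'
#' @param counts named numeric vector, barcode -> reads.
#' @param max_dist maximum Hamming distance merged (default 2, the distance
#'   at which sequencing errors typically manifest).
#' @return list with `counts` (merged, sorted) and `map` (named character
#'   vector: every input barcode -> its representative).
#' @export
merge_barcodes <- function(counts, max_dist = 2) {
  stopifnot(max_dist >= 0)
  if (length(counts) == 0) {
    return(list(counts = counts, map = stats::setNames(character(0), character(0))))
  }
  stopifnot(!is.null(names(counts)), !anyDuplicated(names(counts)),
            all(counts > 0))
  ord <- order(-counts, names(counts))
  bcs <- names(counts)[ord]
  cnt <- unname(counts[ord])

  rep_names <- character(0)
  rep_counts <- numeric(0)
  rep_mat <- NULL
  map <- stats::setNames(character(length(bcs)), bcs)

  for (i in seq_along(bcs)) {
    b <- bcs[i]
    if (length(rep_names) > 0 && max_dist > 0) {
      d <- hamming_to_set(b, rep_mat)
      close <- which(d <= max_dist)
    } else {
      close <- integer(0)
    }
    if (length(close) == 0) {
      rep_names <- c(rep_names, b)
      rep_counts <- c(rep_counts, cnt[i])
      rep_mat <- cbind(rep_mat, charToRaw(b))
      map[b] <- b
    } else {
      # closest representative; ties by current count, then lexicographic
      dd <- d[close]
      best <- close[order(dd, -rep_counts[close], rep_names[close])[1]]
      rep_counts[best] <- rep_counts[best] + cnt[i]
      map[b] <- rep_names[best]
    }
  }
  merged <- stats::setNames(rep_counts, rep_names)
  list(counts = sort_counts(merged), map = map)
}

#' Select reference barcodes detected in every sample
#'
#' Intersection of barcode sets across count tables, mirroring the selection
#' of barcodes detected in the plasmid library and in all barcoded cell
#' lines.
#'
#' @param tables list of named count vectors.
#' @return character vector of barcodes present in every table.
#' @export
select_reference <- function(tables) {
  stopifnot(length(tables) >= 1)
  Reduce(intersect, lapply(tables, names))
}

#' Restrict a count table to a reference barcode set
#'
#' @param counts named count vector.
#' @param reference character vector of accepted barcodes (non-empty).
#' @return filtered count vector; `attr(, "discarded_reads")` tallies the
#'   reads removed.
#' @export
filter_to_reference <- function(counts, reference) {
  stopifnot(length(reference) > 0)
  keep <- names(counts) %in% reference
  out <- counts[keep]
  attr(out, "discarded_reads") <- sum(counts[!keep])
  out
}

#' Canonicalize (barcode, stg, reads) triplets against reference barcodes
#'
#' Each triplet's barcode is replaced by its representative: itself when
#' already a reference barcode, otherwise the closest reference barcode
#' within `max_dist` (ties: lowest distance, then highest reference count,
#' then lexicographic). Reads are summed only within identical
#' (representative, stg) pairs, so distinct stg variants stay separate under
#' one barcode: (A, X, M) + (A', X, N) becomes (A, X, M+N) while
#' (A, X, M) + (A', Y, N) stays as two rows (A, X, M) and (A, Y, N).
#' Triplets with no representative within `max_dist` are dropped and
#' tallied.
#'
#' @param triplets data.frame with columns `barcode`, `stg`, `reads`.
#' @param reference named count vector of reference (representative)
#'   barcodes, e.g. the merged plasmid table.
#' @param max_dist maximum Hamming distance to a representative (default 2).
#' @return data.frame (`barcode`, `stg`, `reads`) with
#'   `attr(, "dropped_reads")`.
#' @export
merge_triplets <- function(triplets, reference, max_dist = 2) {
  stopifnot(is.data.frame(triplets),
            all(c("barcode", "stg", "reads") %in% names(triplets)),
            length(reference) > 0)
  ref_names <- names(reference)
  ref_mat <- barcode_matrix(ref_names)
  ub <- unique(triplets$barcode)
  assign_rep <- vapply(ub, function(b) {
    if (b %in% ref_names) return(b)
    d <- hamming_to_set(b, ref_mat)
    ok <- which(d <= max_dist)
    if (length(ok) == 0) return(NA_character_)
    ref_names[ok[order(d[ok], -unname(reference)[ok], ref_names[ok])[1]]]
  }, character(1))
  reps <- assign_rep[triplets$barcode]
  dropped <- is.na(reps)
  kept <- triplets[!dropped, , drop = FALSE]
  kept$barcode <- reps[!dropped]
  if (nrow(kept) == 0) {
    out <- data.frame(barcode = character(0), stg = character(0),
                      reads = numeric(0))
  } else {
    out <- stats::aggregate(reads ~ barcode + stg, data = kept, FUN = sum)
    out <- out[order(-out$reads, out$barcode, out$stg), ]
    rownames(out) <- NULL
  }
  attr(out, "dropped_reads") <- sum(triplets$reads[dropped])
  out
}

#' Aggregate triplets into a barcode count table
#'
#' @param triplets data.frame (`barcode`, `stg`, `reads`).
#' @return named count vector barcode -> total reads.
#' @export
triplets_to_counts <- function(triplets) {
  if (nrow(triplets) == 0) return(stats::setNames(numeric(0), character(0)))
  agg <- tapply(triplets$reads, triplets$barcode, sum)
  sort_counts(stats::setNames(as.numeric(agg), names(agg)))
}
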