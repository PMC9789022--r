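#' Expression-abundance association for one sample
#'
#' Weighted Spearman correlation between each clone's mean stgRNA indel
#' score (the recorded cumulative expression) and its read count (clonal
#' abundance), weighted by the read count.
#'
#' @param summaries output of [clone_summaries()] (>= 3 clones).
#' @return correlation in `[-1, 1]` (or `NA` when degenerate).
#' @export
expression_abundance_cor <- function(summaries) {
  weighted_spearman(summaries$mean_indel_score, summaries$reads,
                    w = summaries$reads)
}

#' Mean-score matrix of the top mutated clones across samples
#'
#' Per sample, the top `n` clones by number of mutated reads (reads with a
#' positive indel score) are selected; rows are the deduplicated union of
#' those selections across samples, entries are each clone's read-weighted
#' mean indel score in each sample (0 where the clone is absent).
#'
#' @param sample_summaries named list of [clone_summaries()] tables.
#' @param n clones selected per sample (default 10).
#' @return numeric matrix, clones x samples; row order follows first
#'   appearance across samples.
#' @export
top_mutated_table <- function(sample_summaries, n = 10) {
  stopifnot(length(sample_summaries) >= 1, n >= 1)
  if (is.null(names(sample_summaries))) {
    names(sample_summaries) <- paste0("sample", seq_along(sample_summaries))
  }
  tops <- lapply(sample_summaries, function(s) {
    s <- s[order(-s$mutated_reads, s$barcode), , drop = FALSE]
    s$barcode[seq_len(min(n, nrow(s)))]
  })
  clones <- unique(unlist(tops))
  m <- matrix(0, length(clones), length(sample_summaries),
              dimnames = list(clones, names(sample_summaries)))
  for (s in names(sample_summaries)) {
    tab <- sample_summaries[[s]]
    hit <- tab$barcode %in% clones
    m[tab$barcode[hit], s] <- tab$mean_indel_score[hit]
  }
  m
}
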