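#' Build the wrong-template blacklist from the plasmid sample
#'
#' Plasmid stg variants whose total mutation score from the template is at
#' or above `params$blacklist_threshold` are treated as wrong-template
#' contaminants: reads closer to one of them than to the true template are
#' later discarded by [classify_stg()].
#'
#' @param plasmid_stg_counts named count vector, stg variant -> plasmid
#'   reads.
#' @param template stg template sequence.
#' @param params a [stg_scoring()] object.
#' @return character vector of blacklisted stg variants.
#' @export
build_blacklist <- function(plasmid_stg_counts, template,
                            params = stg_scoring()) {
  variants <- names(plasmid_stg_counts)
  if (length(variants) == 0) return(character(0))
  sc <- align_scores(variants, template, params)
  variants[sc$total >= params$blacklist_threshold]
}

#' Classify stg variants as valid or wrong-template
#'
#' A variant is `"wrong"` when its minimum mutation score to any blacklist
#' member is strictly smaller than its score to the template; ties keep the
#' variant `"valid"`.
#'
#' @param variants character vector of stg sequences.
#' @param template stg template.
#' @param blacklist character vector from [build_blacklist()].
#' @param params a [stg_scoring()] object.
#' @return character vector (`"valid"` / `"wrong"`) parallel to `variants`.
#' @export
classify_stg <- function(variants, template, blacklist,
                         params = stg_scoring()) {
  if (length(variants) == 0) return(character(0))
  t_score <- align_scores(variants, template, params)$total
  cls <- rep("valid", length(variants))
  if (length(blacklist) > 0) {
    uv <- unique(variants)
    min_b <- vapply(uv, function(v) {
      min(vapply(blacklist, function(b) align_score(v, b, params)$total,
                 numeric(1)))
    }, numeric(1))
    cls[min_b[match(variants, uv)] < t_score] <- "wrong"
  }
  cls
}

#' Score and classify a sample's (barcode, stg, reads) triplets
#'
#' @param triplets data.frame (`barcode`, `stg`, `reads`).
#' @param template stg template.
#' @param blacklist wrong-template variants (may be empty).
#' @param params a [stg_scoring()] object.
#' @return the triplet table with added columns `mismatch`, `insertion`,
#'   `deletion`, `indel`, `total`, `class`, `is_mutated` (indel score > 0).
#' @export
score_triplets <- function(triplets, template, blacklist = character(0),
                           params = stg_scoring()) {
  stopifnot(all(c("barcode", "stg", "reads") %in% names(triplets)))
  sc <- align_scores(triplets$stg, template, params)
  out <- cbind(triplets,
               sc[, c("mismatch", "insertion", "deletion", "indel", "total")])
  out$class <- classify_stg(triplets$stg, template, blacklist, params)
  out$is_mutated <- out$indel > 0
  out
}

#' Percent of valid reads carrying an stgRNA indel
#'
#' The expression-recording readout: the read-weighted percentage of valid
#' stg reads whose alignment to the template contains at least one insertion
#' or deletion (mismatches are excluded from the indicator as they arise
#' Cas9-independently). With `weight = "barcode"` each barcode contributes
#' its read-weighted mutated fraction equally instead.
#'
#' @param scored output of [score_triplets()].
#' @param weight `"read"` (default) or `"barcode"`.
#' @return percentage in `[0, 100]`.
#' @export
percent_mutation <- function(scored, weight = c("read", "barcode")) {
  weight <- match.arg(weight)
  v <- scored[scored$class == "valid", , drop = FALSE]
  if (nrow(v) == 0 || sum(v$reads) == 0) stop("no valid stg reads")
  if (weight == "read") {
    return(100 * sum(v$reads[v$is_mutated]) / sum(v$reads))
  }
  per_bc <- vapply(split(v, v$barcode), function(d) {
    sum(d$reads[d$is_mutated]) / sum(d$reads)
  }, numeric(1))
  100 * mean(per_bc)
}

#' Per-position mutation-rate profile along the stg template
#'
#' For each template position, the read-weighted fraction of valid reads
#' whose minimum-score alignment places a mismatch, insertion or deletion
#' there (an alignment contributes at most once per type and position;
#' insertions are assigned to the template position they precede, terminal
#' insertions to the last position).
#'
#' @param scored output of [score_triplets()].
#' @param template stg template.
#' @param params a [stg_scoring()] object.
#' @return matrix `3 x nchar(template)` with rows `mismatch`, `insertion`,
#'   `deletion`.
#' @export
position_profile <- function(scored, template, params = stg_scoring()) {
  m <- nchar(template)
  prof <- matrix(0, 3, m,
                 dimnames = list(c("mismatch", "insertion", "deletion"),
                                 seq_len(m)))
  v <- scored[scored$class == "valid", , drop = FALSE]
  total <- sum(v$reads)
  if (total == 0) return(prof)
  uv <- unique(v$stg)
  reads_by_variant <- tapply(v$reads, factor(v$stg, levels = uv), sum)
  for (idx in seq_along(uv)) {
    ev <- align_score(uv[idx], template, params)$events
    if (nrow(ev) == 0) next
    ev <- unique(ev)
    w <- reads_by_variant[[idx]]
    for (r in seq_len(nrow(ev))) {
      prof[ev$op[r], ev$tpos[r]] <- prof[ev$op[r], ev$tpos[r]] + w
    }
  }
  prof / total
}

#' Read-weighted empirical CDF of indel scores
#'
#' @param scored output of [score_triplets()].
#' @return data.frame with columns `indel_score` (ascending unique values)
#'   and `cum_fraction` (read-weighted cumulative fraction, ending at 1).
#' @export
score_cdf <- function(scored) {
  v <- scored[scored$class == "valid", , drop = FALSE]
  stopifnot(nrow(v) > 0)
  agg <- tapply(v$reads, v$indel, sum)
  s <- as.numeric(names(agg))
  ord <- order(s)
  data.frame(indel_score = s[ord],
             cum_fraction = cumsum(as.numeric(agg)[ord]) / sum(v$reads))
}

#' Per-clone summaries of recorded expression and abundance
#'
#' @param scored output of [score_triplets()] (valid reads only are used).
#' @return data.frame with one row per barcode: `barcode`, `reads` (total
#'   valid reads), `mutated_reads` (reads with indel score > 0) and
#'   `mean_indel_score` (read-weighted mean indel score).
#' @export
clone_summaries <- function(scored) {
  v <- scored[scored$class == "valid", , drop = FALSE]
  stopifnot(nrow(v) > 0)
  out <- do.call(rbind, lapply(split(v, v$barcode), function(d) {
    data.frame(barcode = d$barcode[1],
               reads = sum(d$reads),
               mutated_reads = sum(d$reads[d$is_mutated]),
               mean_indel_score = sum(d$reads * d$indel) / sum(d$reads))
  }))
  out <- out[order(-out$reads, out$barcode), ]
  rownames(out) <- NULL
  out
}
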