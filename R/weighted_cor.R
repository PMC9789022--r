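#' Weighted mid-ranks
#'
#' Cumulative-weight mid-rank convention: the rank of item i is the total
#' weight of items strictly below it, plus half the weight of its tie group
#' (itself included), plus 1/2. With unit weights this reduces to ordinary
#' mid-ranks, and ranking `-x` gives `sum(w) + 1 - rank(x)` exactly, so
#' perfect anti-concordance yields a correlation of -1.
#'
#' @param values numeric vector.
#' @param weights positive weights, same length.
#' @return numeric rank vector.
#' @export
weighted_rank <- function(values, weights) {
  stopifnot(length(values) >= 1, length(values) == length(weights),
            all(weights > 0))
  ord <- order(values)
  w_sorted <- weights[ord]
  v_sorted <- values[ord]
  below_sorted <- cumsum(w_sorted) - w_sorted
  ranks <- numeric(length(values))
  for (grp in split(seq_along(v_sorted), match(v_sorted, unique(v_sorted)))) {
    ranks[ord[grp]] <- below_sorted[grp[1]] + sum(w_sorted[grp]) / 2 + 0.5
  }
  ranks
}

#' Weighted Spearman correlation
#'
#' Weighted Pearson correlation of the weighted ranks of `x` and `y`, with
#' the same weights used for ranking and for the correlation. With unit
#' weights this equals the classical Spearman rank correlation. Used to
#' relate a clone's mean stgRNA indel score to its read abundance, weighting
#' clones by their reads.
#'
#' @param x,y numeric vectors (length >= 3).
#' @param w positive weights; default unit weights.
#' @return correlation in `[-1, 1]`, or `NA` when either weighted rank
#'   variance is zero.
#' @export
weighted_spearman <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(w), length(x) >= 3,
            all(w > 0))
  rx <- weighted_rank(x, w)
  ry <- weighted_rank(y, w)
  weighted_pearson(rx, ry, w)
}

weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  # guard against zero variance up to accumulated rounding in the means
  if (vx <= 1e-20 * (mx^2 + 1) || vy <= 1e-20 * (my^2 + 1)) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}
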