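#' Shannon entropy of a clonal profile (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over the clone proportions. Counts are
#' accepted and normalized.
#'
#' @param p numeric vector of proportions or counts (nonnegative, positive
#'   sum); zeros contribute nothing.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(p) {
  if (length(p) == 0) stop("empty profile")
  stopifnot(all(p >= 0), sum(p) > 0)
  p <- p[p > 0] / sum(p)
  -sum(p * log(p))
}

#' Corrected (effective) barcode number
#'
#' `exp(H)` of the sample's clone proportions — the Hill number of order 1,
#' i.e. the number of equally abundant clones giving the same Shannon
#' entropy. Removes skew from raw richness: it equals the richness for a
#' perfectly even sample and shrinks towards 1 as the sample is dominated by
#' few clones.
#'
#' @param counts named count vector (or proportions).
#' @return effective barcode number, between 1 and the richness.
#' @export
corrected_barcode_number <- function(counts) {
  exp(shannon_entropy(counts))
}

#' Top-N barcodes by read count
#'
#' @param counts named count vector.
#' @param n number of barcodes to return (default 10); fewer when the sample
#'   has fewer barcodes. Ties are broken lexicographically.
#' @return character vector of barcodes, highest count first.
#' @export
top_barcodes <- function(counts, n = 10) {
  stopifnot(n >= 1)
  ord <- order(-counts, names(counts))
  names(counts)[ord][seq_len(min(n, length(counts)))]
}

#' Jensen-Shannon divergence between two clonal profiles
#'
#' `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m = (p + q) / 2`, natural
#' log, computed over the union of supports (absent barcodes contribute
#' zero). Bounded by `log(2)`, attained on disjoint supports. In
#' `"top10_union"` mode the profiles are first restricted to the supplied
#' union of per-sample top-10 barcodes; `renormalize = TRUE` (default)
#' rescales the restricted vectors to sum to 1, `FALSE` keeps the raw
#' restricted proportions (implicit "other" mass).
#'
#' @param p,q named count or proportion vectors.
#' @param mode `"all"` or `"top10_union"`.
#' @param top_list character vector of barcodes (required for
#'   `"top10_union"`), normally the union of per-sample [top_barcodes()].
#' @param renormalize renormalize restricted profiles (default `TRUE`).
#' @return divergence in nats, in `[0, log(2)]`.
#' @export
js_divergence <- function(p, q, mode = c("all", "top10_union"),
                          top_list = NULL, renormalize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(p)), !is.null(names(q)))
  if (mode == "top10_union") {
    if (is.null(top_list)) stop("top10_union mode requires top_list")
    p <- p[names(p) %in% top_list]
    q <- q[names(q) %in% top_list]
  }
  if (sum(p) == 0 && sum(q) == 0) stop("both profiles empty on the support")
  support <- union(names(p), names(q))
  pv <- stats::setNames(numeric(length(support)), support)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  if (renormalize || mode == "all") {
    if (sum(pv) > 0) pv <- pv / sum(pv)
    if (sum(qv) > 0) qv <- qv / sum(qv)
  }
  m <- (pv + qv) / 2
  plogp <- function(x) sum(x[x > 0] * log(x[x > 0]))
  # generalized JSD; for unnormalized vectors this is the mixture-entropy
  # form evaluated on the raw masses
  h <- function(x) -plogp(x)
  h(m) - (h(pv) + h(qv)) / 2
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' For `"top10_union"` mode the union list is built once from the top
#' `top_n` barcodes of every sample, then shared across all pairs, matching
#' a single common barcode list per comparison set.
#'
#' @param tables named list of count vectors (>= 2 samples).
#' @param mode `"all"` or `"top10_union"`.
#' @param top_n list length used in `"top10_union"` mode (default 10).
#' @param renormalize see [js_divergence()].
#' @return symmetric matrix with zero diagonal.
#' @export
js_matrix <- function(tables, mode = c("all", "top10_union"), top_n = 10,
                      renormalize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(tables) >= 2)
  if (is.null(names(tables))) {
    names(tables) <- paste0("sample", seq_along(tables))
  }
  top_list <- NULL
  if (mode == "top10_union") {
    top_list <- unique(unlist(lapply(tables, top_barcodes, n = top_n)))
  }
  k <- length(tables)
  m <- matrix(0, k, k, dimnames = list(names(tables), names(tables)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v <- js_divergence(tables[[i]], tables[[j]], mode = mode,
                         top_list = top_list, renormalize = renormalize)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Pairwise Welch t-tests with Bonferroni correction
#'
#' All pairwise two-sample Welch t-tests (unequal variances,
#' Welch-Satterthwaite degrees of freedom) between groups, with p-values
#' multiplied by the number of comparisons and capped at 1. Degenerate pairs
#' where both groups are constant yield p = 1 for equal means and p = 0
#' otherwise.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return data.frame with columns `group1`, `group2`, `p`, `p_adjusted`.
#' @export
welch_bonferroni <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  pairs <- utils::combn(names(groups), 2)
  p <- apply(pairs, 2, function(gg) {
    x <- groups[[gg[1]]]
    y <- groups[[gg[2]]]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y, var.equal = FALSE)$p.value
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = p,
             p_adjusted = stats::p.adjust(p, method = "bonferroni"))
}
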