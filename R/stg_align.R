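#' Scoring parameters for stgRNA mutation-score alignment
#'
#' Costs used by the minimum-mutation-score aligner: 1 per mismatched base,
#' 2.5 for the first base of a deletion or insertion, and 0.5 for each base
#' extending it, with variants scoring 4.0 or more from the template
#' enrolled in the wrong-template blacklist.
#'
#' @param mismatch_cost cost per mismatched base (default 1).
#' @param gap_open_cost cost of the first base of a gap (default 2.5).
#' @param gap_extend_cost cost per additional gap base (default 0.5); must
#'   not exceed `gap_open_cost`.
#' @param blacklist_threshold minimum total score enrolling a plasmid stg
#'   variant in the blacklist (default 4).
#' @param open_includes_extension alternative gap-cost convention in which a
#'   k-base gap costs `gap_open + gap_extend * k` instead of the default
#'   `gap_open + gap_extend * (k - 1)`.
#' @return an object of class `scoring_params`.
#' @export
stg_scoring <- function(mismatch_cost = 1, gap_open_cost = 2.5,
                        gap_extend_cost = 0.5, blacklist_threshold = 4,
                        open_includes_extension = FALSE) {
  stopifnot(mismatch_cost > 0, gap_open_cost > 0, gap_extend_cost > 0,
            gap_extend_cost <= gap_open_cost)
  structure(list(mismatch_cost = mismatch_cost,
                 gap_open_cost = gap_open_cost,
                 gap_extend_cost = gap_extend_cost,
                 blacklist_threshold = blacklist_threshold,
                 open_includes_extension = open_includes_extension),
            class = "scoring_params")
}

gap_cost <- function(len, params) {
  if (len == 0) return(0)
  open1 <- params$gap_open_cost +
    if (params$open_includes_extension) params$gap_extend_cost else 0
  open1 + params$gap_extend_cost * (len - 1)
}

#' Minimum-mutation-score global alignment of an stg read to the template
#'
#' Global dynamic-programming alignment (end gaps charged) minimizing the
#' total mutation score under affine gap costs. Among equal-score
#' alignments, operations are preferred in the order match/mismatch,
#' insertion, deletion, applied left-to-right along the alignment, so the
#' reported decomposition is deterministic. Insertions are extra query
#' bases relative to the template; deletions are template bases absent from
#' the query.
#'
#' @param query stg read sequence (non-empty).
#' @param template stg template sequence (non-empty; 20 nt in the standard
#'   recorder design).
#' @param params a [stg_scoring()] object.
#' @return an object of class `mutation_score`: list with numeric `mismatch`,
#'   `insertion`, `deletion`, `indel` (= insertion + deletion), `total`, and
#'   `events`, a data.frame of alignment events (`op` in
#'   mismatch/insertion/deletion, `tpos` = template position; insertions take
#'   the template position they precede, clipped to the template for
#'   end-of-template insertions).
#' @examples
#' align_score("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGAACGT")$total
#' @export
align_score <- function(query, template, params = stg_scoring()) {
  if (nchar(query) == 0 || nchar(template) == 0) {
    stop("empty sequence in alignment")
  }
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  tt <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  n <- length(q)
  m <- length(tt)
  open1 <- params$gap_open_cost +
    if (params$open_includes_extension) params$gap_extend_cost else 0
  ext <- params$gap_extend_cost
  mis <- params$mismatch_cost

  # Backward DP over suffixes: B*[i+1, j+1] = minimum cost of completing the
  # alignment from (i, j) (i query bases and j template bases consumed),
  # conditioned on the state of the previous operation:
  #   BM after a match/mismatch, BI inside an insertion, BD inside a deletion.
  BM <- matrix(Inf, n + 1, m + 1)
  BI <- BM
  BD <- BM
  BM[n + 1, m + 1] <- BI[n + 1, m + 1] <- BD[n + 1, m + 1] <- 0
  for (i in (n + 1):1) {
    for (j in (m + 1):1) {
      if (i == n + 1 && j == m + 1) next
      cm <- if (i <= n && j <= m) {
        (if (q[i] == tt[j]) 0 else mis) + BM[i + 1, j + 1]
      } else Inf
      iM <- if (i <= n) BI[i + 1, j] else Inf
      dM <- if (j <= m) BD[i, j + 1] else Inf
      BM[i, j] <- min(cm, open1 + iM, open1 + dM)
      BI[i, j] <- min(cm, ext + iM, open1 + dM)
      BD[i, j] <- min(cm, open1 + iM, ext + dM)
    }
  }

  # forward greedy walk: at each step take the operation (priority
  # match/mismatch > insertion > deletion) that still achieves the optimal
  # completion cost
  i <- 0L
  j <- 0L
  state <- "M"
  total <- 0
  ops <- character(n + m)
  tpos <- integer(n + m)
  subs <- logical(n + m)
  k <- 0L
  while (i < n || j < m) {
    cM <- if (i < n && j < m) {
      (if (q[i + 1] == tt[j + 1]) 0 else mis) + BM[i + 2, j + 2]
    } else Inf
    cI <- if (i < n) {
      (if (state == "I") ext else open1) + BI[i + 2, j + 1]
    } else Inf
    cD <- if (j < m) {
      (if (state == "D") ext else open1) + BD[i + 1, j + 2]
    } else Inf
    best <- min(cM, cI, cD)
    k <- k + 1L
    if (cM <= best) {
      total <- total + (if (q[i + 1] == tt[j + 1]) 0 else mis)
      subs[k] <- q[i + 1] != tt[j + 1]
      ops[k] <- "M"
      tpos[k] <- j + 1L
      i <- i + 1L
      j <- j + 1L
      state <- "M"
    } else if (cI <= best) {
      total <- total + (if (state == "I") ext else open1)
      ops[k] <- "I"
      tpos[k] <- min(j + 1L, m)  # insertion precedes template position j+1
      i <- i + 1L
      state <- "I"
    } else {
      total <- total + (if (state == "D") ext else open1)
      ops[k] <- "D"
      tpos[k] <- j + 1L
      j <- j + 1L
      state <- "D"
    }
  }
  ops <- ops[seq_len(k)]
  tpos <- tpos[seq_len(k)]
  subs <- subs[seq_len(k)]

  # decompose the walked path into per-category scores
  mismatch_score <- mis * sum(subs)
  runs <- rle(ops)
  ins_score <- sum(vapply(runs$lengths[runs$values == "I"], gap_cost,
                          numeric(1), params = params))
  del_score <- sum(vapply(runs$lengths[runs$values == "D"], gap_cost,
                          numeric(1), params = params))

  events <- data.frame(
    op = c("mismatch", "insertion", "deletion")[match(ops, c("M", "I", "D"))],
    tpos = tpos)[subs | ops != "M", , drop = FALSE]
  rownames(events) <- NULL

  structure(list(mismatch = mismatch_score,
                 insertion = ins_score,
                 deletion = del_score,
                 indel = ins_score + del_score,
                 total = mismatch_score + ins_score + del_score,
                 events = events),
            class = "mutation_score")
}

#' @export
print.mutation_score <- function(x, ...) {
  cat(sprintf(
    "mutation_score: total %.1f (mismatch %.1f, insertion %.1f, deletion %.1f)\n",
    x$total, x$mismatch, x$insertion, x$deletion))
  invisible(x)
}

#' Score many stg variants against the template
#'
#' Vectorized wrapper over [align_score()]; duplicated variants are aligned
#' once.
#'
#' @param variants character vector of stg sequences.
#' @param template stg template.
#' @param params a [stg_scoring()] object.
#' @return data.frame with one row per input variant: `stg`, `mismatch`,
#'   `insertion`, `deletion`, `indel`, `total`.
#' @export
align_scores <- function(variants, template, params = stg_scoring()) {
  uv <- unique(variants)
  res <- lapply(uv, function(v) {
    a <- align_score(v, template, params)
    c(mismatch = a$mismatch, insertion = a$insertion, deletion = a$deletion,
      indel = a$indel, total = a$total)
  })
  mat <- do.call(rbind, res)[match(variants, uv), , drop = FALSE]
  out <- data.frame(stg = variants, mat)
  rownames(out) <- NULL
  out
}
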