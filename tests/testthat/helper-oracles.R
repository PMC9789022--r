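# Independent oracles used across the suite. These deliberately do not share
# code with the package implementation.

# --- alignment -------------------------------------------------------------

# minimum mutation score by memoized recursion over (i, j, last-op) states;
# written independently of the package's iterative matrix DP
oracle_align_cost <- function(query, template, mismatch = 1, open = 2.5,
                              ext = 0.5) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(template, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    if (i > length(q) && j > length(t)) return(0)
    key <- paste(i, j, last)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cands <- Inf
    if (i <= length(q) && j <= length(t)) {
      cands <- c(cands, (if (q[i] == t[j]) 0 else mismatch) +
                   rec(i + 1, j + 1, "M"))
    }
    if (i <= length(q)) {
      cands <- c(cands, (if (last == "I") ext else open) + rec(i + 1, j, "I"))
    }
    if (j <= length(t)) {
      cands <- c(cands, (if (last == "D") ext else open) + rec(i, j + 1, "D"))
    }
    memo[[key]] <- min(cands)
    min(cands)
  }
  rec(1, 1, "M")
}

# exhaustive enumeration of every edit path (op strings over M/I/D), scoring
# each path by scanning its runs; only feasible for tiny sequences — used to
# validate oracle_align_cost itself
oracle_align_enum <- function(query, template, mismatch = 1, open = 2.5,
                              ext = 0.5) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(template, "")[[1]]
  paths <- list()
  walk <- function(i, j, ops) {
    if (i > length(q) && j > length(t)) {
      paths[[length(paths) + 1]] <<- ops
      return(invisible(NULL))
    }
    if (i <= length(q) && j <= length(t)) {
      walk(i + 1, j + 1, c(ops, if (q[i] == t[j]) "=" else "X"))
    }
    if (i <= length(q)) walk(i + 1, j, c(ops, "I"))
    if (j <= length(t)) walk(i, j + 1, c(ops, "D"))
  }
  walk(1, 1, character(0))
  score_path <- function(ops) {
    s <- mismatch * sum(ops == "X")
    gap_ops <- ifelse(ops %in% c("=", "X"), "M", ops)
    runs <- rle(gap_ops)
    for (k in seq_along(runs$values)) {
      if (runs$values[k] %in% c("I", "D")) {
        s <- s + open + ext * (runs$lengths[k] - 1)
      }
    }
    s
  }
  min(vapply(paths, score_path, numeric(1)))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- hamming / merging -----------------------------------------------------

oracle_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  d <- 0L
  for (i in seq_len(nchar(a))) {
    if (substr(a, i, i) != substr(b, i, i)) d <- d + 1L
  }
  d
}

# exhaustive-pairs greedy collapse with the package's ordering rule, written
# as a plain double loop over barcodes
oracle_merge <- function(counts, max_dist = 2) {
  ord <- order(-counts, names(counts))
  bcs <- names(counts)[ord]
  cnt <- unname(counts[ord])
  reps <- character(0)
  rep_cnt <- numeric(0)
  for (i in seq_along(bcs)) {
    dists <- rep(NA_integer_, length(reps))
    for (k in seq_along(reps)) dists[k] <- oracle_hamming(bcs[i], reps[k])
    close <- which(dists <= max_dist)
    if (length(close) == 0) {
      reps <- c(reps, bcs[i])
      rep_cnt <- c(rep_cnt, cnt[i])
    } else {
      best <- close[order(dists[close], -rep_cnt[close], reps[close])[1]]
      rep_cnt[best] <- rep_cnt[best] + cnt[i]
    }
  }
  out <- stats::setNames(rep_cnt, reps)
  out[order(-out, names(out))]
}

# random count table of near-duplicate barcodes exercising the merge rules
random_count_table <- function(n, len = 30, mutate_prob = 0.6) {
  base <- replicate(ceiling(n / 3), random_dna(len))
  bcs <- character(0)
  while (length(bcs) < n) {
    b <- sample(base, 1)
    if (runif(1) < mutate_prob) {
      k <- sample(1:3, 1)
      pos <- sample(len, k)
      ch <- strsplit(b, "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      b <- paste(ch, collapse = "")
    }
    if (!b %in% bcs) bcs <- c(bcs, b)
  }
  stats::setNames(sample(1:500, n, replace = TRUE), bcs)
}

# --- weighted rank ---------------------------------------------------------

# direct-summation weighted mid-rank: total weight strictly below, plus half
# the tie-group weight (self included), plus one half
oracle_weighted_rank <- function(values, weights) {
  r <- numeric(length(values))
  for (i in seq_along(values)) {
    below <- 0
    ties <- 0
    for (j in seq_along(values)) {
      if (values[j] < values[i]) below <- below + weights[j]
      if (values[j] == values[i]) ties <- ties + weights[j]
    }
    r[i] <- below + ties / 2 + 0.5
  }
  r
}

# --- sequence fixtures -----------------------------------------------------

fixture_template <- function() "ACGTTGCAGATCGGAATCCT"

# substitute position `pos` with a base different from the original (and, to
# keep scores predictable, different from its neighbors)
with_sub <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[max(1, pos - 1):min(nchar(seq), pos + 1)])[1]
  paste(ch, collapse = "")
}

with_del <- function(seq, pos, len = 1) {
  paste0(substr(seq, 1, pos - 1), substr(seq, pos + len, nchar(seq)))
}

with_ins <- function(seq, pos, ins) {
  paste0(substr(seq, 1, pos - 1), ins, substr(seq, pos, nchar(seq)))
}
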