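#' Generate a WSN x 10 random barcode library
#'
#' Draws unique 30-base clone barcodes following the degenerate WSN repeat
#' design: ten repeats of W (weak base, A or T), S (strong base, G or C) and
#' N (any base). Real oligo synthesis is imperfect, so a configurable
#' fraction of barcodes is perturbed off-pattern by per-base substitutions,
#' emulating synthesis errors.
#'
#' @param n_barcodes number of unique barcodes to generate (>= 1).
#' @param off_pattern_rate fraction in `[0, 1]` of barcodes that must violate
#'   the strict WSN pattern in at least one position. Exactly
#'   `ceiling(off_pattern_rate * n_barcodes)` barcodes are perturbed.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param off_pattern_sub_rate per-base substitution probability used to
#'   perturb off-pattern barcodes (one violating substitution is always
#'   forced so the barcode is genuinely off-pattern).
#'
#' @return character vector of `n_barcodes` unique 30-base barcodes. The
#'   perturbed (off-pattern) barcodes carry `attr(, "off_pattern")`, a logical
#'   vector parallel to the result.
#' @examples
#' bc <- generate_library(100, off_pattern_rate = 0.1, seed = 1)
#' all(nchar(bc) == 30)
#' @export
generate_library <- function(n_barcodes, off_pattern_rate = 0, seed = NULL,
                             off_pattern_sub_rate = 0.1) {
  stopifnot(n_barcodes >= 1, off_pattern_rate >= 0, off_pattern_rate <= 1)
  if (n_barcodes > 16^10) {
    stop("n_barcodes exceeds the attainable WSNx10 diversity (16^10)")
  }
  if (!is.null(seed)) set.seed(seed)

  n_off <- ceiling(off_pattern_rate * n_barcodes)
  bc <- draw_wsn(n_barcodes)
  # enforce uniqueness by redrawing clashes
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- draw_wsn(sum(dup))
  }
  off <- rep(FALSE, n_barcodes)
  if (n_off > 0) {
    idx <- seq_len(n_off)
    bc[idx] <- vapply(bc[idx], perturb_off_pattern, character(1),
                      sub_rate = off_pattern_sub_rate)
    off[idx] <- TRUE
    while (anyDuplicated(bc)) {
      dup <- which(duplicated(bc))
      fresh <- draw_wsn(length(dup))
      redo <- off[dup]
      fresh[redo] <- vapply(fresh[redo], perturb_off_pattern, character(1),
                            sub_rate = off_pattern_sub_rate)
      bc[dup] <- fresh
    }
  }
  structure(bc, off_pattern = off)
}

WSN_W <- c("A", "T")
WSN_S <- c("G", "C")
WSN_N <- c("A", "C", "G", "T")

draw_wsn <- function(n) {
  if (n == 0) return(character(0))
  # 30 x n character matrix, rows cycle W, S, N
  m <- matrix("", nrow = 30, ncol = n)
  w_rows <- seq(1, 30, by = 3)
  s_rows <- seq(2, 30, by = 3)
  n_rows <- seq(3, 30, by = 3)
  m[w_rows, ] <- sample(WSN_W, 10 * n, replace = TRUE)
  m[s_rows, ] <- sample(WSN_S, 10 * n, replace = TRUE)
  m[n_rows, ] <- sample(WSN_N, 10 * n, replace = TRUE)
  apply(m, 2, paste, collapse = "")
}

# Substitute bases at Binomial(30, sub_rate) positions; force at least one
# substitution that breaks the WSN pattern (at a W or S position, where a
# violation is possible).
perturb_off_pattern <- function(barcode, sub_rate = 0.1) {
  chars <- strsplit(barcode, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(30) < sub_rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(WSN_N, chars[i]), 1)
  }
  pos_type <- rep(c("W", "S", "N"), 10)
  if (is_wsn(paste(chars, collapse = ""))) {
    i <- sample(which(pos_type != "N"), 1)
    bad <- if (pos_type[i] == "W") WSN_S else WSN_W
    chars[i] <- sample(bad, 1)
  }
  paste(chars, collapse = "")
}

#' Test barcodes against the strict WSN x 10 pattern
#'
#' @param barcodes character vector of sequences.
#' @return logical vector; `TRUE` where the sequence is exactly ten repeats
#'   of W (A/T), S (G/C), N (any base).
#' @export
is_wsn <- function(barcodes) {
  grepl("^([AT][GC][ACGT]){10}$", barcodes)
}
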