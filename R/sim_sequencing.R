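#' Sequencing error model
#'
#' Per-base substitution and indel error rates plus a per-position Phred
#' quality profile used when emitting synthetic reads.
#'
#' @param substitution_rate per-base substitution probability.
#' @param indel_rate per-base probability of a 1-base insertion or deletion
#'   (split evenly).
#' @param quality baseline Phred score (2-41); emitted for every base.
#' @param quality_decay per-position linear drop in expected quality towards
#'   the 3' end (Phred units per base); floors at Q2.
#' @param adapter adapter sequence appended after the amplicon (trimmed by
#'   [trim_adapter()] downstream).
#' @return an object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0, indel_rate = 0, quality = 37,
                        quality_decay = 0, adapter = "AGATCGGAAGAGC") {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            quality >= 2, quality <= 41, quality_decay >= 0)
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 quality = quality,
                 quality_decay = quality_decay,
                 adapter = adapter),
            class = "error_model")
}

#' Amplicon architecture shared by the simulator and the extractor
#'
#' The flank sequences anchoring the 30-base barcode (and, in the recording
#' layout, the stgRNA cassette) within a read. Fixing one definition here
#' guarantees that [emit_fastq()] and [extract_reads()] agree.
#'
#' @param layout `"tumor"` (flank + barcode + flank) or `"recording"`
#'   (flank + barcode + spacer + stg + flank).
#' @param barcode_length barcode length, fixed at 30.
#' @param stg_max_length maximum accepted stg window (indels expected).
#' @return an object of class `extraction_pattern` with elements
#'   `upstream_flank`, `spacer` (recording only), `downstream_flank`,
#'   `barcode_length`, `stg_max_length`, `layout`.
#' @export
amplicon_pattern <- function(layout = c("tumor", "recording"),
                             barcode_length = 30, stg_max_length = 40) {
  layout <- match.arg(layout)
  stopifnot(barcode_length == 30)
  structure(list(upstream_flank = "TGTGGAAAGG",
                 spacer = if (layout == "recording") "GTTTAAGAGC" else NULL,
                 downstream_flank = "ACGCGTAGCA",
                 barcode_length = barcode_length,
                 stg_max_length = stg_max_length,
                 layout = layout),
            class = "extraction_pattern")
}

#' Emit synthetic FASTQ reads from a simulated population
#'
#' Samples `depth` reads from the clone frequencies (and, for the recording
#' layout, each clone's stg variant pool), wraps barcode and stg in the
#' amplicon flanks, applies substitution and 1-base indel sequencing errors,
#' and attaches Phred+33 qualities. A truth table mapping each read to its
#' source clone (and true stg variant) is returned alongside; when `dir` is
#' given, `<prefix>.fastq` and `<prefix>_truth.tsv` are also written.
#'
#' @param state a [clone_state()].
#' @param depth number of reads (>= 1).
#' @param model an [error_model()].
#' @param layout `"tumor"` or `"recording"`.
#' @param seed integer seed or `NULL`.
#' @param dir optional output directory.
#' @param prefix file prefix used under `dir`.
#' @return list with `reads` (data.frame: id, seq, qual), `truth`
#'   (data.frame: read_id, barcode, stg) and, if written, `fastq` / `truth_file`
#'   paths.
#' @export
emit_fastq <- function(state, depth, model = error_model(),
                       layout = c("tumor", "recording"), seed = NULL,
                       dir = NULL, prefix = "sample") {
  validate_state(state)
  layout <- match.arg(layout)
  stopifnot(depth >= 1)
  if (layout == "recording" && is.null(state$stg_pool)) {
    stop("recording layout requires a state with stg pools")
  }
  if (!is.null(seed)) set.seed(seed)
  pat <- amplicon_pattern(layout)

  clone <- sample.int(length(state$barcodes), depth, replace = TRUE,
                      prob = state$frequencies)
  barcode <- state$barcodes[clone]
  stg <- rep(NA_character_, depth)
  if (layout == "recording") {
    stg <- vapply(clone, function(ci) {
      pool <- state$stg_pool[[ci]]
      sample(names(pool), 1, prob = pool)
    }, character(1))
    amplicon <- paste0(pat$upstream_flank, barcode, pat$spacer, stg,
                       pat$downstream_flank)
  } else {
    amplicon <- paste0(pat$upstream_flank, barcode, pat$downstream_flank)
  }
  if (!is.null(model$adapter) && nchar(model$adapter) > 0) {
    amplicon <- paste0(amplicon, model$adapter)
  }

  seqs <- vapply(amplicon, apply_seq_errors, character(1),
                 sub_rate = model$substitution_rate,
                 indel_rate = model$indel_rate, USE.NAMES = FALSE)
  quals <- vapply(nchar(seqs), phred_string, character(1),
                  q0 = model$quality, decay = model$quality_decay)

  ids <- sprintf("read%06d", seq_len(depth))
  reads <- data.frame(id = ids, seq = seqs, qual = quals)
  truth <- data.frame(read_id = ids, barcode = barcode, stg = stg)
  out <- list(reads = reads, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$fastq <- file.path(dir, paste0(prefix, ".fastq"))
    out$truth_file <- file.path(dir, paste0(prefix, "_truth.tsv"))
    write_fastq(reads, out$fastq)
    utils::write.table(truth, out$truth_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

apply_seq_errors <- function(seq, sub_rate, indel_rate) {
  if (sub_rate == 0 && indel_rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (sub_rate > 0) {
    hit <- which(stats::runif(length(chars)) < sub_rate)
    for (i in hit) chars[i] <- sample(setdiff(WSN_N, chars[i]), 1)
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(length(chars)) < indel_rate)
    for (i in rev(hit)) {
      if (stats::runif(1) < 0.5) {
        chars <- chars[-i]                                # deletion
      } else {
        chars <- append(chars, sample(WSN_N, 1), after = i) # insertion
      }
    }
  }
  paste(chars, collapse = "")
}

phred_string <- function(len, q0 = 37, decay = 0) {
  if (len == 0) return("")
  q <- pmax(2, pmin(41, round(q0 - decay * (seq_len(len) - 1))))
  intToUtf8(q + 33, multiple = FALSE)
}

#' Write reads to a 4-line FASTQ file (Phred+33)
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into the package's read table
#'
#' Thin wrapper over [Biostrings::readQualityScaledDNAStringSet()].
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)))
}
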