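#' Default 20-nt stgRNA template used by the scenario presets
#' @export
STG_TEMPLATE <- "ACGTTGCAGATCGGAATCCT"

#' Build a pipeline configuration
#'
#' Bundles a scenario preset, a seed and parameter overrides. Defaults
#' follow the analysis parameters used throughout the package: adapter
#' mismatch tolerance 0.2, quality trim Q20 / minimum length 25, quality
#' filter Q20 at 80% of bases, 30-base barcodes, Hamming merge distance 2,
#' alignment costs 1 / 2.5 / 0.5, blacklist threshold 4.0, top-10 lists.
#'
#' @param scenario one of `"growth"`, `"treatment"`, `"metastasis"`,
#'   `"recording"`.
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir optional directory for FASTQ/TSV/manifest output; `NULL`
#'   keeps everything in memory.
#' @param params named list of scenario parameter overrides (see
#'   [run_pipeline()] for the per-scenario defaults).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = c("growth", "treatment", "metastasis",
                                         "recording"),
                            seed = 1, out_dir = NULL, params = list()) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    growth = list(n_barcodes = 400, off_pattern_rate = 0.5, depth = 2000,
                  n_replicates = 3, folds = c(200, 5), dispersion = 0.05,
                  substitution_rate = 0.003, indel_rate = 3e-4),
    treatment = list(n_barcodes = 400, off_pattern_rate = 0.5, depth = 2000,
                     n_replicates = 3, fold = 200, dispersion = 0.05,
                     survival = 0.3, substitution_rate = 0.003,
                     indel_rate = 3e-4),
    metastasis = list(n_barcodes = 400, off_pattern_rate = 0.5, depth = 2000,
                      fold = 200, dispersion = 0.05, founders = c(1, 2, 2, 5, 50),
                      substitution_rate = 0.003, indel_rate = 3e-4),
    recording = list(n_barcodes = 150, off_pattern_rate = 0.5, depth = 2500,
                     gene_rate = 0.05, days = c(0, 7, 14), cut_position = 16,
                     expression_high = 1, expression_frac = 0.3,
                     coupling = 1, wrong_templates = 3,
                     substitution_rate = 0.002, indel_rate = 2e-4))
  defaults[names(params)] <- params
  structure(list(scenario = scenario, seed = as.integer(seed),
                 out_dir = out_dir, params = defaults,
                 max_dist = 2, top_n = 10,
                 scoring = stg_scoring(),
                 template = STG_TEMPLATE),
            class = "pipeline_config")
}

#' Run a scenario end-to-end
#'
#' Simulates a scenario (library, clonal dynamics, sequencing), runs the
#' read-processing / merging / statistics stages of the pipeline on the
#' simulated reads, and returns the result bundle together with the latent
#' truth. Deterministic under a fixed seed. When the config has an
#' `out_dir`, count tables and statistics are written as TSV and a YAML run
#' manifest is produced.
#'
#' Scenarios:
#' \describe{
#'   \item{growth}{in-vitro sample plus tumor replicates grown through the
#'     configured fold expansions; reports effective barcode numbers and JS
#'     divergence matrices (all barcodes and top-10 union).}
#'   \item{treatment}{untreated vs drug-treated tumors (binomial survival
#'     thinning); reports effective barcode numbers and Welch/Bonferroni
#'     comparisons.}
#'   \item{metastasis}{primary tumor plus lesions founded by small
#'     bottlenecks; reports per-lesion effective barcode numbers.}
#'   \item{recording}{expression-recording experiment: stgRNA editing
#'     coupled to expression, plasmid blacklist, percent mutation per day,
#'     clone summaries and the expression-abundance weighted Spearman.}
#' }
#'
#' @param config a [pipeline_config()].
#' @return a result bundle (list); common elements are `samples` (merged
#'   count tables), `stats` (per-sample statistics data.frame), `truth`
#'   (latent states) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  bundle <- switch(config$scenario,
                   growth = scenario_growth(config),
                   treatment = scenario_treatment(config),
                   metastasis = scenario_metastasis(config),
                   recording = scenario_recording(config))
  bundle$manifest <- list(
    package = "clonescribe",
    version = as.character(utils::packageVersion("clonescribe")),
    scenario = config$scenario,
    seed = config$seed,
    params = config$params)
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config)
  }
  bundle
}

pipeline_error_model <- function(p) {
  error_model(substitution_rate = p$substitution_rate,
              indel_rate = p$indel_rate)
}

# emit + process + count one barcode-only sample
sample_tumor_counts <- function(state, depth, model, config) {
  fq <- emit_fastq(state, depth, model, layout = "tumor")
  extracted <- process_reads(fq$reads, amplicon_pattern("tumor"),
                             adapter = model$adapter)
  count_barcodes(extracted)
}

scenario_growth <- function(config) {
  p <- config$params
  model <- pipeline_error_model(p)
  lib <- generate_library(p$n_barcodes, p$off_pattern_rate)
  cells <- clone_state(lib, n_cells = 200 * p$n_barcodes)
  plasmid <- sample_tumor_counts(cells, p$depth, model, config)
  states <- list(in_vitro = cells)
  for (r in seq_len(p$n_replicates)) {
    s <- cells
    for (fold in p$folds) {
      s <- simulate_growth(s, fold, p$dispersion)
    }
    states[[paste0("tumor", r)]] <- s
  }
  finish_barcode_scenario(states, plasmid, model, p$depth, config)
}

scenario_treatment <- function(config) {
  p <- config$params
  model <- pipeline_error_model(p)
  lib <- generate_library(p$n_barcodes, p$off_pattern_rate)
  cells <- clone_state(lib, n_cells = 200 * p$n_barcodes)
  plasmid <- sample_tumor_counts(cells, p$depth, model, config)
  states <- list(in_vitro = cells)
  for (r in seq_len(p$n_replicates)) {
    s <- simulate_growth(cells, p$fold, p$dispersion)
    states[[paste0("control", r)]] <- s
    states[[paste0("treated", r)]] <- simulate_selection(s, p$survival)
  }
  bundle <- finish_barcode_scenario(states, plasmid, model, p$depth, config)
  ecn <- bundle$stats$corrected_barcode_number
  grp <- list(
    control = ecn[grepl("^control", bundle$stats$sample)],
    treated = ecn[grepl("^treated", bundle$stats$sample)])
  bundle$comparison <- welch_bonferroni(grp)
  bundle
}

scenario_metastasis <- function(config) {
  p <- config$params
  model <- pipeline_error_model(p)
  lib <- generate_library(p$n_barcodes, p$off_pattern_rate)
  cells <- clone_state(lib, n_cells = 200 * p$n_barcodes)
  plasmid <- sample_tumor_counts(cells, p$depth, model, config)
  primary <- simulate_growth(cells, p$fold, p$dispersion)
  states <- list(in_vitro = cells, primary = primary)
  for (i in seq_along(p$founders)) {
    met <- simulate_bottleneck(primary, p$founders[i])
    met <- simulate_growth(met, max(2, 1e4 / met$n_cells), p$dispersion)
    states[[paste0("metastasis", i, "_k", p$founders[i])]] <- met
  }
  finish_barcode_scenario(states, plasmid, model, p$depth, config)
}

# shared tail of the barcode-only scenarios: sequence each state, merge
# against the plasmid-derived representatives, compute diversity statistics
finish_barcode_scenario <- function(states, plasmid, model, depth, config) {
  raw <- lapply(states, sample_tumor_counts, depth = depth, model = model,
                config = config)
  plasmid_merged <- merge_barcodes(plasmid, config$max_dist)$counts
  reference_tables <- c(list(plasmid = plasmid_merged), raw["in_vitro"])
  reference <- select_reference(reference_tables)
  samples <- lapply(raw, function(counts) {
    merged <- merge_barcodes(counts, config$max_dist)$counts
    filter_to_reference(merged, reference)
  })
  stats <- data.frame(
    sample = names(samples),
    reads = vapply(samples, sum, numeric(1)),
    barcodes = vapply(samples, length, numeric(1)),
    shannon_entropy = vapply(samples, shannon_entropy, numeric(1)),
    corrected_barcode_number = vapply(samples, corrected_barcode_number,
                                      numeric(1)))
  rownames(stats) <- NULL
  list(samples = samples,
       stats = stats,
       js_all = js_matrix(samples, "all"),
       js_top10 = js_matrix(samples, "top10_union", top_n = config$top_n),
       truth = states)
}

scenario_recording <- function(config) {
  p <- config$params
  model <- pipeline_error_model(p)
  template <- config$template
  lib <- generate_library(p$n_barcodes, p$off_pattern_rate)
  n_high <- max(1, round(p$expression_frac * p$n_barcodes))
  expr <- c(rep(p$expression_high, n_high),
            rep(0, p$n_barcodes - n_high))
  cells <- clone_state(lib, n_cells = 500 * p$n_barcodes, expression = expr,
                       stg_template = template)

  # plasmid stg pool: mostly the true template plus a few wrong templates
  wrong <- replicate(p$wrong_templates,
                     mutate_stg(mutate_stg(template, 8), 14))
  plasmid_stg <- stats::setNames(c(0.95, rep(0.05 / max(1, length(wrong)),
                                             length(wrong))),
                                 c(template, wrong))
  plasmid_stg <- plasmid_stg[!duplicated(names(plasmid_stg))]
  plasmid_state <- cells
  plasmid_state$stg_pool <- rep(list(plasmid_stg / sum(plasmid_stg)),
                                length(lib))

  sample_recording <- function(state) {
    fq <- emit_fastq(state, p$depth, model, layout = "recording")
    extracted <- process_reads(fq$reads, amplicon_pattern("recording"),
                               adapter = model$adapter)
    count_triplets(extracted)
  }

  plasmid_triplets <- sample_recording(plasmid_state)
  plasmid_counts <- merge_barcodes(triplets_to_counts(plasmid_triplets),
                                   config$max_dist)$counts
  plasmid_stg_counts <- tapply(plasmid_triplets$reads, plasmid_triplets$stg, sum)
  plasmid_stg_counts <- stats::setNames(as.numeric(plasmid_stg_counts),
                                        names(plasmid_stg_counts))
  blacklist <- build_blacklist(plasmid_stg_counts, template, config$scoring)

  # expression-coupled proliferation + recording through the day series
  states <- list()
  s <- cells
  prev_day <- 0
  for (d in p$days) {
    if (d > prev_day) {
      s <- simulate_recording(s, p$gene_rate, d - prev_day,
                              cut_position = p$cut_position)
      s <- simulate_growth(s, fold = 2,
                           fitness = exp(p$coupling * s$expression),
                           dispersion = 0.01)
      prev_day <- d
    }
    states[[paste0("day", d)]] <- s
  }

  samples <- list()
  stats <- NULL
  summaries <- list()
  for (nm in names(states)) {
    trip <- sample_recording(states[[nm]])
    trip <- merge_triplets(trip, plasmid_counts, config$max_dist)
    scored <- score_triplets(trip, template, blacklist, config$scoring)
    samples[[nm]] <- scored
    summaries[[nm]] <- clone_summaries(scored)
    stats <- rbind(stats, data.frame(
      sample = nm,
      valid_reads = sum(scored$reads[scored$class == "valid"]),
      wrong_reads = sum(scored$reads[scored$class == "wrong"]),
      percent_mutation = percent_mutation(scored),
      corrected_barcode_number =
        corrected_barcode_number(triplets_to_counts(scored)),
      expression_abundance_cor =
        if (nrow(summaries[[nm]]) >= 3) expression_abundance_cor(summaries[[nm]])
        else NA_real_))
  }
  rownames(stats) <- NULL
  list(samples = samples,
       stats = stats,
       blacklist = blacklist,
       summaries = summaries,
       top_mutated = top_mutated_table(summaries, n = config$top_n),
       truth = states)
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(bundle$stats, "stats.tsv")
  if (!is.null(bundle$samples) && !is.data.frame(bundle$samples[[1]])) {
    counts_long <- do.call(rbind, lapply(names(bundle$samples), function(nm) {
      data.frame(sample = nm, barcode = names(bundle$samples[[nm]]),
                 reads = unname(bundle$samples[[nm]]))
    }))
    tsv(counts_long, "counts.tsv")
  }
  if (!is.null(bundle$js_all)) {
    utils::write.table(bundle$js_all, file.path(config$out_dir, "js_all.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(bundle$js_top10,
                       file.path(config$out_dir, "js_top10.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(bundle$comparison)) tsv(bundle$comparison, "comparison.tsv")
  yaml::write_yaml(bundle$manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(NULL)
}
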