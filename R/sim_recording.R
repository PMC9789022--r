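#' Record gene expression as Cas9/stgRNA edits
#'
#' Advances the per-clone stgRNA variant pools by `days` of expression-coupled
#' Cas9 editing. Each clone's un-edited stg molecules acquire an indel with
#' probability `1 - exp(-gene_rate * expression * days)` (a Poisson editing
#' process at rate proportional to the clone's expression of the recorded
#' gene); the pool is propagated as variant proportions, i.e. the
#' infinite-population limit of per-molecule Bernoulli editing. Indel lengths
#' follow a truncated geometric distribution (mean 2, maximum 10) with a
#' deletion:insertion ratio of 3:1, centered on the Cas9 cut site. A molecule
#' whose cut-site +/- 3 window is already disrupted has lost its protospacer
#' and cannot be edited again.
#'
#' @param state a [clone_state()] carrying an `stg_template`.
#' @param gene_rate edits per expression-unit per day (>= 0).
#' @param days duration of recording.
#' @param cut_position Cas9 cut site within the 20-nt stg sequence
#'   (default 16).
#' @param indel_geom_p success parameter of the geometric indel-length
#'   distribution (`mean = 1/p`); default 0.5 (mean 2).
#' @param indel_max maximum indel length (default 10).
#' @param deletion_prob probability that an edit is a deletion (default 0.75,
#'   i.e. 3:1 deletion:insertion).
#' @param n_outcomes number of distinct edit outcomes sampled per editable
#'   variant per call; the edited mass is split equally among them.
#' @param seed integer seed or `NULL`.
#' @return updated `clone_state` with advanced `stg_pool` and `time`.
#' @export
simulate_recording <- function(state, gene_rate, days, cut_position = 16,
                               indel_geom_p = 0.5, indel_max = 10,
                               deletion_prob = 0.75, n_outcomes = 3,
                               seed = NULL) {
  validate_state(state)
  stopifnot(!is.null(state$stg_pool), gene_rate >= 0, days >= 0,
            cut_position >= 1, cut_position <= 20)
  if (!is.null(seed)) set.seed(seed)
  template <- state$stg_template
  for (ci in seq_along(state$stg_pool)) {
    p_edit <- 1 - exp(-gene_rate * state$expression[ci] * days)
    if (p_edit <= 0) next
    pool <- state$stg_pool[[ci]]
    new_pool <- pool
    for (v in names(pool)) {
      if (!stg_editable(v, template, cut_position)) next
      moved <- pool[[v]] * p_edit
      if (moved <= 0) next
      new_pool[[v]] <- new_pool[[v]] - moved
      outs <- replicate(n_outcomes,
                        mutate_stg(v, cut_position, indel_geom_p, indel_max,
                                   deletion_prob))
      share <- moved / length(outs)
      for (o in outs) {
        if (o %in% names(new_pool)) {
          new_pool[[o]] <- new_pool[[o]] + share
        } else {
          new_pool[o] <- share
        }
      }
    }
    new_pool <- new_pool[new_pool > 0]
    state$stg_pool[[ci]] <- new_pool / sum(new_pool)
  }
  state$time <- state$time + days
  state
}

# a molecule is editable while its protospacer cut window is intact:
# same length as the template and identical bases at cut_position +/- 3
stg_editable <- function(variant, template, cut_position) {
  if (nchar(variant) != nchar(template)) return(FALSE)
  lo <- max(1, cut_position - 3)
  hi <- min(nchar(template), cut_position + 3)
  substr(variant, lo, hi) == substr(template, lo, hi)
}

# draw one Cas9 indel outcome centred at the cut site
mutate_stg <- function(seq, cut_position, indel_geom_p = 0.5, indel_max = 10,
                       deletion_prob = 0.75) {
  len <- rtrunc_geom(indel_geom_p, indel_max)
  n <- nchar(seq)
  if (stats::runif(1) < deletion_prob) {
    start <- cut_position - len %/% 2
    start <- max(1, min(start, n - len + 1))
    paste0(substr(seq, 1, start - 1), substr(seq, start + len, n))
  } else {
    ins <- paste(sample(WSN_N, len, replace = TRUE), collapse = "")
    at <- min(cut_position, n)
    paste0(substr(seq, 1, at - 1), ins, substr(seq, at, n))
  }
}

# geometric on 1..max with P(k) proportional to (1-p)^(k-1) * p
rtrunc_geom <- function(p, max_len) {
  probs <- p * (1 - p)^(seq_len(max_len) - 1)
  sample.int(max_len, 1, prob = probs)
}

#' Read-weighted summaries of a clone's latent stg pool
#'
#' The latent edited fraction (mass on variants differing from the template)
#' per clone; used by round-trip tests.
#'
#' @param state a [clone_state()] with stg pools.
#' @return numeric vector, per-clone edited mass fraction.
#' @export
latent_edited_fraction <- function(state) {
  stopifnot(!is.null(state$stg_pool))
  template <- state$stg_template
  vapply(state$stg_pool, function(pool) {
    sum(pool[names(pool) != template])
  }, numeric(1))
}
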