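#' Latent state of a simulated barcoded clonal population
#'
#' Holds the ground truth behind a simulated experiment: clone barcodes,
#' their frequencies, the total cell count, a per-clone expression intensity
#' for the recorded gene, the per-clone pool of stgRNA sequence variants, and
#' elapsed time in days. All downstream parameter-recovery tests compare
#' pipeline output against this state.
#'
#' @param barcodes character vector of unique 30-base clone barcodes.
#' @param frequencies nonnegative clone frequencies; normalized to sum to 1.
#'   Default uniform.
#' @param n_cells total number of cells in the population.
#' @param expression per-clone nonnegative expression intensity of the
#'   recorded gene (arbitrary units); recycled to the number of clones.
#' @param stg_template the 20-nt stgRNA template sequence, or `NULL` for a
#'   barcode-only (tumor) experiment.
#' @param time elapsed days.
#'
#' @return an object of class `clone_state`: a list with elements
#'   `barcodes`, `frequencies`, `n_cells`, `expression`, `stg_template`,
#'   `stg_pool` (per-clone named proportion vectors over stg variants) and
#'   `time`.
#' @export
clone_state <- function(barcodes, frequencies = NULL, n_cells = 1e5,
                        expression = 0, stg_template = NULL, time = 0) {
  k <- length(barcodes)
  stopifnot(k >= 1, !anyDuplicated(barcodes))
  if (is.null(frequencies)) frequencies <- rep(1 / k, k)
  stopifnot(length(frequencies) == k, all(frequencies >= 0),
            sum(frequencies) > 0)
  frequencies <- frequencies / sum(frequencies)
  expression <- rep_len(expression, k)
  stopifnot(all(expression >= 0))
  stg_pool <- NULL
  if (!is.null(stg_template)) {
    stopifnot(nchar(stg_template) == 20)
    stg_pool <- rep(list(stats::setNames(1, stg_template)), k)
  }
  structure(list(barcodes = as.character(barcodes),
                 frequencies = unname(frequencies),
                 n_cells = n_cells,
                 expression = unname(expression),
                 stg_template = stg_template,
                 stg_pool = stg_pool,
                 time = time),
            class = "clone_state")
}

#' @export
print.clone_state <- function(x, ...) {
  cat(sprintf("clone_state: %d clones, %g cells, day %g\n",
              length(x$barcodes), x$n_cells, x$time))
  cat(sprintf("  effective clone number: %.1f\n",
              exp(shannon_entropy(x$frequencies))))
  invisible(x)
}

validate_state <- function(state) {
  stopifnot(inherits(state, "clone_state"),
            length(state$barcodes) >= 1,
            abs(sum(state$frequencies) - 1) < 1e-9,
            all(state$expression >= 0))
  if (!is.null(state$stg_pool)) {
    ok <- vapply(state$stg_pool, function(p) abs(sum(p) - 1) < 1e-9, logical(1))
    stopifnot(all(ok))
  }
  invisible(state)
}

keep_clones <- function(state, keep) {
  state$barcodes <- state$barcodes[keep]
  state$frequencies <- state$frequencies[keep]
  state$frequencies <- state$frequencies / sum(state$frequencies)
  state$expression <- state$expression[keep]
  if (!is.null(state$stg_pool)) state$stg_pool <- state$stg_pool[keep]
  state
}

state_counts <- function(state) {
  counts <- round(state$frequencies * state$n_cells)
  # rounding may zero very rare clones; keep at least one cell for clones
  # that are present in the latent frequencies
  counts[counts == 0 & state$frequencies > 0] <- 1
  counts
}

#' Grow a simulated clonal population
#'
#' Expands the population `fold`-fold with clone-level stochasticity modeled
#' by Dirichlet-multinomial resampling: per-clone growth rates are jittered
#' with a Dirichlet draw of concentration `frequencies / dispersion`, then
#' cells are resampled multinomially. `dispersion = 0` is deterministic
#' exponential growth (frequencies unchanged). An optional per-clone
#' `fitness` vector biases expected growth, modeling selection-coupled
#' proliferation.
#'
#' @param state a [clone_state()].
#' @param fold fold-expansion of the cell count (>= 1).
#' @param dispersion nonnegative growth-noise parameter; larger values give
#'   noisier clone trajectories.
#' @param fitness optional positive per-clone relative fitness; expected
#'   offspring frequencies are proportional to `frequencies * fitness`.
#' @param seed integer seed or `NULL`.
#' @return updated `clone_state` (extinct clones dropped).
#' @export
simulate_growth <- function(state, fold, dispersion = 0, fitness = NULL,
                            seed = NULL) {
  validate_state(state)
  stopifnot(fold >= 1, dispersion >= 0)
  if (!is.null(seed)) set.seed(seed)
  f <- state$frequencies
  if (!is.null(fitness)) {
    stopifnot(length(fitness) == length(f), all(fitness > 0))
    f <- f * fitness
    f <- f / sum(f)
  }
  new_n <- round(state$n_cells * fold)
  if (dispersion == 0) {
    state$frequencies <- f
    state$n_cells <- new_n
    return(state)
  }
  alpha <- f / dispersion
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(f)] <- 1
  p <- g / sum(g)
  counts <- stats::rmultinom(1, size = min(new_n, .Machine$integer.max %/% 2),
                             prob = p)[, 1]
  keep <- counts > 0
  if (!any(keep)) stop("population went extinct during growth resampling")
  state <- keep_clones(state, keep)
  state$frequencies <- counts[keep] / sum(counts[keep])
  state$n_cells <- new_n
  state
}

#' Found a new lesion from a small number of cells
#'
#' Samples `founders` cells without replacement (multivariate
#' hypergeometric over the per-clone cell counts), modeling metastasis
#' founding. The surviving clone support has size at most `founders`.
#'
#' @param state a [clone_state()].
#' @param founders number of founding cells (>= 1, at most the cell count).
#' @param seed integer seed or `NULL`.
#' @return updated `clone_state` with `n_cells = founders`.
#' @export
simulate_bottleneck <- function(state, founders, seed = NULL) {
  validate_state(state)
  stopifnot(founders >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- state_counts(state)
  if (founders > sum(counts)) {
    stop("founders exceeds the number of simulated cells")
  }
  taken <- rmvhyper(counts, founders)
  keep <- taken > 0
  state <- keep_clones(state, keep)
  state$frequencies <- taken[keep] / sum(taken[keep])
  state$n_cells <- founders
  state
}

# multivariate hypergeometric draw: k items from urns sized `counts`
rmvhyper <- function(counts, k) {
  out <- integer(length(counts))
  total <- sum(counts)
  for (i in seq_along(counts)) {
    if (k <= 0) break
    out[i] <- stats::rhyper(1, counts[i], total - counts[i], k)
    k <- k - out[i]
    total <- total - counts[i]
  }
  out
}

#' Apply selective pressure (e.g. drug treatment) to a population
#'
#' Thins each clone binomially by its survival probability. A scalar
#' `survival` models stochastic, clone-independent killing (no pre-existing
#' resistance); a per-clone vector models heritable resistance.
#'
#' @param state a [clone_state()].
#' @param survival survival probability in `[0, 1]`, scalar or per-clone.
#' @param seed integer seed or `NULL`.
#' @return updated `clone_state` (extinct clones dropped).
#' @export
simulate_selection <- function(state, survival, seed = NULL) {
  validate_state(state)
  survival <- rep_len(survival, length(state$barcodes))
  stopifnot(all(survival >= 0), all(survival <= 1))
  if (!is.null(seed)) set.seed(seed)
  if (all(survival == 1)) return(state)
  counts <- state_counts(state)
  kept <- stats::rbinom(length(counts), counts, survival)
  keep <- kept > 0
  if (!any(keep)) stop("no cells survived selection")
  state <- keep_clones(state, keep)
  state$frequencies <- kept[keep] / sum(kept[keep])
  state$n_cells <- sum(kept)
  state
}
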