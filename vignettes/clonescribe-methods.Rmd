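---
title: "Models and methods behind clonescribe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonescribe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonescribe)
```

# Overview

`clonescribe` analyzes two intertwined readouts of tumor evolution
experiments:

* **Clonal tracing** — each cell is marked once with a random 30-base DNA
  barcode delivered by lentivirus at low multiplicity of infection; the
  barcode census of a sample (a tumor, a metastasis, a treated culture) is a
  snapshot of its clonal composition.
* **Expression recording** — a Cas9 cassette knocked into a gene of interest
  expresses Cas9 proportionally to that gene; a self-targeting guide RNA
  (stgRNA) directs Cas9 to cut its own 20-nt encoding locus, so expression
  accumulates as indels in the stgRNA sequence. Sequencing the stgRNA next
  to the clone barcode reads out each clone's cumulative expression history.

The package provides the full desk-side analysis: read filtering, barcode
and stgRNA extraction, sequencing-error collapsing, diversity statistics,
mutation-score alignment and expression–abundance association — plus a
synthetic-data generator that emulates the experiments and exports the
latent truth, so every stage can be tested by parameter recovery.

# The synthetic-data generator

## Barcode libraries

Barcodes follow the WSN×10 degenerate design: ten repeats of W (A/T),
S (G/C), N (any base), 30 bases in all, giving $16^{10}$ possible barcodes.
Real libraries deviate substantially from the strict pattern because of
oligonucleotide synthesis errors — in libraries of this design only a small
minority of reads match WSN×10 exactly — so `generate_library()` perturbs a
configurable fraction of barcodes (`off_pattern_rate`) by substituting
uniformly random bases at `Binomial(30, p)` positions, forcing at least one
pattern violation. A per-base process is used because synthesis errors act
per base. The downstream pipeline deliberately imposes **no** WSN
restriction when accepting barcodes, only length 30 and unambiguous bases;
restricting to pattern-true reads would discard most of the signal.

## Clonal dynamics

A `clone_state` carries clone frequencies, a total cell count, per-clone
expression of the recorded gene and per-clone stgRNA variant pools. Three
operations move it forward:

* `simulate_growth(fold, dispersion, fitness)` — Dirichlet-multinomial
  resampling. Per-clone growth rates are jittered by a Dirichlet draw with
  concentration `frequencies / dispersion`; `dispersion = 0` is
  deterministic exponential growth. The optional `fitness` vector scales
  expected offspring frequencies, which is how expression–proliferation
  coupling is modeled. Growth noise can only lower the expected effective
  clone number, matching the intuition that stochastic proliferation skews
  compositions.
* `simulate_bottleneck(founders)` — a multivariate hypergeometric draw of
  `founders` cells without replacement, modeling metastasis founding. The
  surviving support is at most `founders`, which is what makes
  few-founder metastases recognizable by their tiny effective barcode
  number.
* `simulate_selection(survival)` — binomial thinning. A scalar survival
  models purely stochastic killing (no heritable resistance); a per-clone
  vector models pre-existing resistant subclones. The key qualitative
  contrast the package reproduces: scalar survival leaves the effective
  clone number statistically unchanged, a fully resistant subclone sweeps
  the population.

## Expression recording

Recording follows a Poisson editing process: over `days` of recording, an
un-edited molecule in a clone with expression $e$ acquires an indel with
probability $1 - \exp(-r \cdot e \cdot t)$ where $r$ is `gene_rate` (edits
per expression-unit per day). Pools are propagated as variant *proportions*
— the infinite-population limit of per-molecule Bernoulli editing — which
keeps the generator deterministic in its edited mass (the closed form is
testable exactly) while read sampling at `emit_fastq()` time restores
per-molecule stochasticity.

The indel spectrum is not prescribed by the recording design, so the
generator uses a configurable default: lengths from a geometric
distribution with mean 2 truncated at 10, deletions:insertions 3:1,
centered on the cut site (position 16 of 20 by default, where such
recorders typically accumulate their first edits). A molecule whose
cut-site ±3 window is disrupted has destroyed its own protospacer and is
never re-edited; this keeps "percent of molecules mutated" interpretable as
cumulative recorded expression. Whether multi-edit molecules occur in real
data is unknown; under this model a molecule is edited at most once per
window, and further edits require an intact window elsewhere in the pool.

## Sequencing

`emit_fastq()` samples reads from clone frequencies (and stg pools), wraps
them in fixed flank sequences shared with the extractor, appends the
adapter, applies per-base substitution and 1-base indel errors, and writes
Phred+33 FASTQ plus a read-level truth table. Qualities default to a flat
Q37 with an optional linear 3' decay so the quality filters can be
exercised; real instrument profiles are not modeled. The amplicon flanks
are configuration, defined once in `amplicon_pattern()` — their particular
sequences are arbitrary but shared by simulator and extractor.

# Read processing

The stages mirror a standard amplicon pipeline with fixed defaults:
adapter trimming at mismatch tolerance 0.2; 3' quality trimming at Q20
with minimum length 25; a quality filter requiring 80% of bases at Q20 or
better; then flank-anchored extraction accepting only 30-base unambiguous
barcodes (and an stg window of any length up to 40, since indels are
expected).

Numerical/design choices:

* Adapter search is a mismatch-only sliding comparison (no indels in the
  adapter), lowest mismatch fraction first, then leftmost, repeated to a
  fixpoint so the operation is idempotent. This reproduces the dominant
  behavior of full adapter trimmers without their linked/anywhere adapter
  machinery.
* Flank anchoring tolerates one substitution per flank and no indels:
  enough to rescue typical substitution errors without creating ambiguous
  matches.
* Rejection reasons are exhaustive and mutually exclusive (`too_short`,
  `low_quality`, missing flanks, `bad_barcode_length`, `ambiguous_base`,
  `stg_too_long`); pass + reject always equals input reads.

# Barcode error collapsing

Sequencing errors make each true barcode appear as a cloud of variants at
Hamming distance 1–2. `merge_barcodes()` collapses them greedily: barcodes
are visited in decreasing read count (ties lexicographic); each becomes a
new representative unless within distance 2 of an existing one, in which
case its reads are absorbed by the closest (lowest distance, then highest
count, then lexicographic) representative. Absorbed barcodes never absorb
others — no transitive chaining — so the representative set is pairwise
more than 2 apart and the procedure is order-deterministic on any
platform. Reads are conserved exactly.

Reference selection intersects the barcode sets of the plasmid library and
all barcoded cell lines; other samples are then restricted to that
reference set, removing barcodes that exist only as sequencing errors.
For recording data, `(barcode, stg, reads)` triplets are canonicalized
against the merged plasmid representatives: reads sum only within identical
`(representative, stg)` pairs, so distinct stg variants survive under one
barcode. Triplets with no representative within distance 2 are dropped and
tallied — the data give no principled home for them. Merging is performed
per sample against the shared plasmid-derived representative set.

# Diversity statistics

All logarithms are natural. The corrected (effective) barcode number is
$\exp(H)$ of the clone proportions, the Hill number of order 1: the number
of equally abundant clones with the same Shannon entropy. It equals the
richness only for perfectly even samples, and a `k`-founder bottleneck can
never exceed `k`.

Jensen–Shannon divergence compares compositions:
$JSD(p, q) = H(m) - \tfrac{1}{2}(H(p) + H(q))$, $m = (p+q)/2$, bounded by
$\ln 2$ on disjoint supports. The top-10 mode restricts both profiles to
the union of per-sample top-10 barcode lists before comparison. Whether the
restricted vectors should be renormalized is genuinely open — the
alternative keeps an implicit "other" mass — so both are implemented
(`renormalize`, default `TRUE`: JSD is defined between distributions).

Group comparisons use pairwise Welch t-tests (unequal variances,
Welch–Satterthwaite degrees of freedom) with Bonferroni multiplication,
capped at 1.

# The mutation-score aligner

The recording core scores each observed stg variant against the 20-nt
template with a global dynamic-programming alignment minimizing the total
mutation score: mismatch 1, gap opening 2.5, each gap extension base 0.5.
The total decomposes into mismatch, insertion and deletion components, and
**only insertion + deletion** is used as the expression indicator —
mismatches arise Cas9-independently (synthesis and sequencing errors) and
are too noisy to carry signal.

Design choices that required a decision:

* **End gaps are charged.** The stg window is flank-anchored and
  fixed-length in the template; free end gaps would hide terminal
  deletions that the recorder must count.
* **"Extension 0.5"** is read as each base beyond the first (a k-base gap
  costs $2.5 + 0.5(k-1)$); the alternative reading ($2.5 + 0.5k$) is a
  configuration switch (`open_includes_extension`).
* **Tie-breaking.** Among minimum-score alignments, operations are
  preferred in the order mismatch, insertion, deletion, applied
  left-to-right along the alignment. This is realized by a backward DP
  over suffix completion costs followed by a greedy forward walk that takes
  the highest-priority operation still achieving the optimum — an exactly
  lexicographic rule, so decompositions and positional profiles are
  deterministic.
* **Insertion positions** are assigned to the template position they
  precede (terminal insertions to the last position); the choice is a
  convention needed for deterministic positional profiles.

Wrong-template filtering: plasmid stg variants scoring ≥ 4.0 from the
template form a blacklist; an observed variant strictly closer to a
blacklist member than to the template is discarded as originating from a
wrong-template plasmid, ties retained as valid. The threshold score
includes the mismatch component — it is the same total the aligner reports.

Percent mutation is read-weighted by default (the fraction of valid reads
with a positive indel score); a barcode-weighted switch averages per-clone
mutated fractions instead, for analyses where clone identity should count
equally.

# Expression–abundance association

Per clone, the read-weighted mean indel score summarizes recorded
expression and total reads summarize abundance. Their association is the
weighted Spearman correlation with read-count weights: weighted Pearson of
weighted mid-ranks, where the rank of item $i$ is the total weight strictly
below it plus half its tie-group weight plus $\tfrac12$. With unit weights
this is the classical mid-rank, and ranks of $-x$ mirror ranks of $x$
exactly, so perfect anti-concordance gives $-1$. Whether abundance should
be log-transformed before correlation is immaterial: Spearman is invariant
to strictly increasing transforms. The top-mutated-clone heatmap table
selects each sample's top 10 clones by mutated-read count and reports mean
indel scores over the deduplicated cross-sample union, zero where absent.

# Problem sizes and what the tests show

The scenario presets and test suites run at desk scale, chosen so the whole
suite completes in minutes while keeping every statistical contrast
comfortably powered: libraries of 60–2000 barcodes, populations of
10^4–10^6 cells, sequencing depths of 500–3000 reads, and 50 independent
seeds for each stochastic claim. The qualitative findings these scenarios
reproduce — growth noise lowering effective clone numbers, uniform-survival
drug treatment leaving them statistically unchanged, few-founder metastases
collapsing them to the founder count, and expression–proliferation coupling
producing positive, increasing weighted correlations — do not depend on
scale. What passing tests do *not* show: behavior under real instrument
error profiles (quality decay here is linear and configurable, not
empirical), PCR chimeras and jackpots (not modeled), paired-end merging
(inputs are pre-merged by construction), or immune/spatial effects on
clonal dynamics.

# Known limitations

* The greedy count-descending merge is a heuristic; pathological tables
  (long chains of equal counts at distance 2) depend on the documented
  tie-break rather than on a global optimum.
* The recording model edits each molecule at most once per cut window; a
  recorder with substantial re-cutting of shifted protospacers would need a
  different editability rule.
* `classify_stg` compares against every blacklist member; with very large
  blacklists this is the dominant cost (alignments are cached per unique
  variant within a call).
* Sequencing indel errors inside the barcode shift the flank anchor and the
  read is rejected rather than rescued; at realistic indel rates this loses
  well under a percent of reads.

# A worked example

```{r example, eval = FALSE}
library(clonescribe)
cfg <- pipeline_config("recording", seed = 1, out_dir = "recording_run")
bundle <- run_pipeline(cfg)
bundle$stats
bundle$top_mutated
```
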