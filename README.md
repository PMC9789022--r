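# clonescribe

Clonal barcode tracing and stgRNA expression-recording analysis.

## What this is for

Tumor evolution experiments increasingly combine two DNA readouts:

* **Clonal tracing.** Every cell is marked once with a random 30-base
  lentiviral barcode built as ten repeats of W–S–N (W = A/T, S = G/C,
  N = any base). The barcode census of a sample — primary tumor,
  metastasis, drug-treated culture — is a snapshot of its clonal
  composition.
* **Gene expression recording.** A Cas9 cassette knocked into a gene of
  interest expresses Cas9 with that gene; a self-targeting guide RNA
  (stgRNA) makes Cas9 cut its own 20-nt encoding sequence, so cumulative
  expression is written into the stgRNA as indels and read out by
  sequencing the stgRNA next to the clone barcode.

`clonescribe` implements the complete desk-side analysis for both readouts,
plus a synthetic-data generator that emulates the experiments (barcode
libraries with synthesis errors, clonal growth/bottlenecks/selection,
expression-coupled stgRNA editing, sequencing errors) and exports the
latent truth so every stage is testable by parameter recovery.

## The statistics at the core

* **Hamming-distance barcode collapsing.** Sequencing errors surround each
  true barcode with variants at distance 1–2. Barcodes are merged greedily
  in decreasing read order when the Hamming distance is ≤ 2; reference
  barcodes are the intersection of the plasmid library and all barcoded
  cell lines. For recording data, triplets merge as
  (A, X, M) + (A′, X, N) → (A, X, M+N) while distinct stg variants stay
  separate under one barcode.
* **Corrected barcode number.** exp(H) of the clone proportions, with
  H = −Σ pᵢ ln pᵢ — the effective number of equally abundant clones (Hill
  number of order 1), removing skew from raw richness.
* **Jensen–Shannon divergence.** JSD(p, q) = H(m) − (H(p) + H(q))/2,
  m = (p + q)/2, natural log, bounded by ln 2; computed over all barcodes
  or over the union of per-sample top-10 lists.
* **Minimum mutation score.** Each stg read is globally aligned to the
  template with costs: mismatch 1, gap opening 2.5, gap extension 0.5 per
  additional base; ties resolved preferring mismatch, then insertion, then
  deletion, left to right. Insertion + deletion is the expression
  indicator (mismatches are Cas9-independent noise). Plasmid stg variants
  scoring ≥ 4.0 form a wrong-template blacklist; reads strictly closer to
  a blacklist member than to the template are discarded.
* **Weighted Spearman correlation** between each clone's mean indel score
  and its read count, weighted by reads — the association between recorded
  expression and clonal abundance.

## Worked example

```r
library(clonescribe)
cfg <- pipeline_config("recording", seed = 1,
                       params = list(n_barcodes = 40, depth = 800,
                                     gene_rate = 0.12))
bundle <- run_pipeline(cfg)
bundle$stats
```

```
  sample valid_reads wrong_reads percent_mutation corrected_barcode_number
1   day0         793           0            0.504                     39.0
2   day7         781           1           29.065                     31.8
3  day14         771           0           61.219                     20.8
  expression_abundance_cor
1                   0.0721
2                   0.6848
3                   0.5620
```

Forty barcoded clones carry an expression recorder; 30% of clones express
the recorded gene and expressing clones proliferate faster. At day 0 the
percent of stg reads with indels is background only (0.5%, sequencing
errors); by day 14 editing has accumulated to 61% of reads. The corrected
barcode number falls from 39 (nearly even, 40 clones) to 21 as the
expressing clones take over, and the weighted Spearman correlation between
mean indel score and read abundance turns strongly positive — clones that
recorded expression are the ones expanding. `bundle$top_mutated` holds the
clone × sample matrix of mean indel scores behind the top-mutated-clone
heatmap, and `bundle$blacklist` the wrong-template variants removed.

The same interface drives the barcode-only scenarios
(`"growth"`, `"treatment"`, `"metastasis"`), and
`exec/clonescribe run --scenario growth --seed 1 --out DIR` is a thin
command-line wrapper over the identical functions.

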