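---
title: "Two-arm pathway signatures: model, derivation and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-arm pathway signatures: model, derivation and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rassig)
```

## The score model

A two-arm signature summarizes pathway output as a single per-sample
number. Expression is first put on the *log10-ratio-to-mean* scale:
within a dataset, each gene's log10 values are centered on their mean
across samples (`mean_normalize()`). The composite score is then the
mean log10 ratio of the up-arm genes minus the mean of the down-arm
genes. Two properties follow directly from linearity and are the
backbone of the package's verification:

* **Population centering.** On row-centered data the score averages to
  zero over the samples of a dataset, which is what makes zero a
  meaningful activation threshold: "active" means above the cohort
  mean contrast. `classify_active()` therefore defaults to a strict
  `score > 0` rule; the strictness only matters on an event of measure
  zero and keeps a sample exactly at the population mean from being
  called active.

* **Scale invariance.** Multiplying any gene's raw intensities by a
  positive constant shifts its log10 values additively and is removed
  by centering; scores are unchanged. Platform-wide gain differences
  therefore cannot move the score, though they say nothing about
  nonlinear distortions.

Signature genes absent from a platform are skipped with a warning, not
imputed: the score is a mean over whatever arm members are measured,
which keeps it well-defined on any platform at the cost of comparing
slightly different gene sets across platforms. `missing_signature_genes()`
makes the skipped set explicit. Gene matching is case-sensitive exact
string matching — silent case-folding hides annotation mismatches.

Degenerate inputs are errors rather than silent repairs: matrices with
a single sample cannot be mean-normalized (the ratio to the mean is
identically zero), all-missing gene rows are reported by name, and
nonpositive raw intensities are rejected instead of clamped because
they indicate corrupted upstream processing.

## Coherence: does a signature transfer?

A signature carries information in a new dataset only if its internal
structure survives transfer. For every arm gene, `arm_correlations()`
computes the Pearson correlation with the average profile of each arm;
a gene is excluded from its own arm's average (leave-one-out), because
for an arm of size *k* the inclusion of the gene itself biases the
correlation upward by roughly 1/*k* even under the null, enough to
distort small arms badly.

The test then reduces each gene to one bit — the sign of its
correlation with the **up-arm** average — and forms the 2×2 table of
arm membership against that sign. A single axis captures both halves
of the coherence idea: up genes should sit on the positive side and
down genes (anticorrelated with the up arm) on the nonpositive side.
The table is tested with a Fisher exact test, one-sided by default
because coherence is a directional hypothesis; the two-sided variant
is available via `sided = "two"`. Zero-variance genes have no defined
correlation and are excluded from the table but reported per gene.

The Fisher test itself (`fisher_exact_2x2()`) is implemented once, as
fixed-margin hypergeometric tail sums, and shared with the clinical
response analysis; the test suite checks it against a full
enumeration over every 2×2 table with total at most 40 and against
`stats::fisher.test()`.

One statistical point deserves emphasis: an exact conditional test is
*discrete and conservative*. Its null p-values satisfy
P(p ≤ α) ≤ α but are not uniformly distributed — the attainable
p-values form a finite set and the null CDF lies below the diagonal.
For signature-sized tables (~150 genes) the deviation from uniformity
is small but reliably detectable by a Kolmogorov–Smirnov test at
realistic simulation sizes. The package's calibration tests therefore
assert validity (the empirical rejection rate never exceeds the
nominal level, up to Monte-Carlo slack) rather than exact uniformity;
a distribution-shape test of uniformity against U(0,1) is expected to
reject for any exact test and says nothing about its correctness.

## Module discovery

Signature derivation distills a coherent module from a candidate
superset across several cohorts:

1. Per cohort, the Pearson correlation matrix of the superset genes is
   clustered hierarchically — rows of the correlation matrix as
   feature vectors, Euclidean distance, complete linkage. This is the
   standard two-way correlation-heatmap workflow; since the matrix is
   symmetric, row and column clustering coincide.
2. Cut heights are scanned over 100 evenly spaced dendrogram levels.
   Every cluster of at least `min_module_size` (default 10) genes
   whose mean off-diagonal pairwise correlation reaches
   `min_mean_pairwise_r` (default 0.40) is a candidate; the largest
   wins, with ties resolved by higher mean correlation and then by
   lexicographic member order so that discovery is deterministic and
   invariant to input order. The original derivation states only the
   resulting 0.40 criterion, not the cluster-selection rule, so the
   scan-and-largest rule is this package's concretization and is fully
   configurable (`module_discovery_config()`); a median criterion is
   available alongside the default mean. The 0.40 criterion is applied
   per dataset, before intersection, matching the description of each
   cohort's module.
3. The up arm is the intersection of the per-cohort modules — genes
   whose co-expression replicates everywhere.
4. The down arm collects reference-panel genes with correlation at
   most −0.4 (inclusive) against the *average* up-arm profile; the
   average, not all pairwise correlations, because a single coherent
   axis is exactly what the up arm was built to represent.

## Drug response

Rather than fitting EC50 curves, sensitivity is read out at the tested
concentration where the panel's viabilities have maximal across-line
variance — the dose with the most power to discriminate lines. The
sample variance (n−1) is used; the argmax is invariant to that choice
whenever no column is excluded. Ties resolve to the lowest dose, and
columns containing missing viabilities are excluded from the argmax
with a warning rather than imputed. Growth-rate correction of the
viabilities is assumed already applied upstream; no growth model is
fitted here. Score–sensitivity association is a plain Pearson
correlation with its t-transform p-value; response-category
association reuses the shared Fisher test on the response ×
score-sign table.

## The synthetic generator

`generate_dataset()` draws, per dataset and sample, a latent
activation *a* ~ N(0, 1); an up gene takes value *b·a* + ε, a down
gene −*b·a* + ε, a background gene ε, with ε ~ N(0, σ) independent per
gene and sample, and rows centered exactly afterwards. Under this
single-factor model the within-arm pairwise correlation converges to
*b*²/(*b*² + σ²) and the up-versus-down correlation to its negative —
a closed form the tests check empirically at n = 2000 within ±0.02.

Defaults are chosen once to mirror the published setting: 105 up and
42 down planted genes (the packaged signature's geometry), 300
background genes, 50 samples per dataset (cohorts in this field run
~50–90 samples), 4 datasets (one per intersected cohort), *b* = 1 and
σ = 0.5, i.e. planted within-arm correlation 0.8. Each dataset draws
its own latent factor, mirroring cohorts normalized internally;
nothing ties activation across datasets. Derivation-scale checks use a
30-gene module inside a 300-gene superset, the regime the procedure is
meant for.

All randomness flows from one master seed through named substreams
(a counter-style hash of seed, dataset, block and gene), so enlarging
one gene block never perturbs the draws of another — a property the
tests assert bit-for-bit.

What the generator does *not* emulate: probe-level effects, batch
structure, heavy-tailed or platform-specific noise, correlated
background modules, and any nonlinearity between pathway activity and
expression. Passing tests on this generator therefore demonstrate that
the algorithms do what they claim under the model the method itself
assumes — not that the packaged signature is biologically optimal on
real cohorts.

Companion generators cover the rest of the pipeline:
`generate_scored_cohort()` draws binary response labels with log-odds
proportional to the latent activation (independence at effect 0), and
`generate_dose_response()` produces four-parameter logistic viability
curves whose log10 EC50 decreases with activation, so the max-variance
dose falls strictly inside the tested range whenever EC50s are
heterogeneous.

## Contrasts and open choices

`contrast_signature()` summarizes a two-condition comparison as
10^(mean up-arm log10 fold − mean down-arm log10 fold) with a
two-sided one-sample t test of the up-arm folds against zero. The test
behind the published acquired-resistance p-value is not stated in the
source; the t test on up-arm folds is this package's documented
choice, and with zero-variance folds the limiting p-value (0 or 1) is
returned. Similarly, the exact 2×2 construction and sidedness of the
published coherence test are unstated; the construction above is a
documented design choice, not a claimed reproduction.

The packaged 147-gene signature preserves the published arm sizes
(105 up, 42 down) and the pathway genes named in the source text, but
the complete original gene table is not redistributable here; the
remaining membership is a labelled synthetic reconstruction
(`ras_signature()`, `inst/extdata/ras_signature_synthetic.tsv`).
Analyses that depend on exact membership should substitute the
original table via `read_signature()`.

## Verification scale

The test suite and `scripts/acceptance.R` run entirely on generated
data at these problem sizes: 100 random 500×40 matrices for score
exactness; every 2×2 table with total ≤ 40 for Fisher enumeration
(~136,000 tables); 1000 null and 200 planted simulations for
coherence calibration and power; 20 derivation replicates (4 cohorts
of 330×50 plus a reference) for planted-signature recovery; n = 2000
samples for the factor-model closed form. These sizes give Monte-Carlo
error comfortably below the margins being checked while keeping a full
run in minutes on one core.
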