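---
title: "Methods: miRNA resistance profiling, signature selection, and target integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA resistance profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsig)
```

## The problem and the model

Drug resistance in ovarian cancer is studied with panels of resistant
sublines derived from one sensitive parental line — here A2780 with two
cisplatin-resistant (A2780CR1/2) and two paclitaxel-resistant
(A2780PR1/2) derivatives, four array replicates per group. The scientific
question has two halves: which miRNAs change expression consistently with
resistance to a given drug, and which of their target genes move in the
opposite direction, as expected if the miRNA represses them.

`mirsig` answers both with a fixed pipeline whose statistical core is the
standard microarray linear-model machinery, and whose selection and
integration stages encode the panel-specific decision rules.

### Normalization (RMA core)

Quantile normalization replaces each sample column's order statistics
with the across-sample mean of order statistics, mapped back by
within-column rank; tied values receive the mean of the order-statistic
means of the tied ranks, making the result independent of tie order. The
operation is idempotent and preserves within-column ranks — both are
tested properties. Probe-level values are summarized per feature by Tukey
median polish (additive probe + sample decomposition by alternating
median sweeps; tolerance 1e-6, at most 10 cycles — conventional defaults,
both configurable), reporting overall + sample effect as the feature's
expression.

Full RMA also includes a normal-exponential background deconvolution. Its
parameters are not recoverable from the data this package targets, so
background handling is reduced to a documented optional floor shift
(`background_floor`: subtract a low-quantile per-sample floor on the
intensity scale, clamp, return to log2), off by default; the pipeline
assumes already-log2 matrices and may bypass normalization entirely for
pre-normalized inputs.

### Differential expression

Each resistant line is contrasted independently against the parental
reference (four two-group comparisons rather than one joint five-group
fit; with per-contrast pooled variances the pairwise effects are the
same, and the per-contrast form matches how panel results are reported).
For feature *g*: effect `b_g = mean(A) − mean(B)`, pooled variance
`s²_g` on `d = n_A + n_B − 2` df. The empirical-Bayes step models the
true variances as scaled inverse chi-square with prior df `d₀` and scale
`s₀²`, estimated by moment matching of `log s²`: the excess of the
empirical variance of log variances over `trigamma(d/2)` determines `d₀`
through the inverse-trigamma relation (Newton iteration, tolerance 1e-8),
and the mean determines `s₀²`. When the observed spread of log variances
does not exceed what sampling alone produces, the variances are treated
as homogeneous: `d₀ = ∞`, every posterior variance equals `s₀²` (the mean
variance), and the reference distribution is normal. Posterior variances
are the convex combination `(d₀ s₀² + d s²)/(d₀ + d)` — a tested
invariant — and the moderated t gets `d₀ + d` df. Two-sided p-values are
adjusted by the Benjamini–Hochberg step-up rule, implemented directly
from its definition and tested against a hand-applied formula.

Fold changes use the signed convention of miRNA array reports:
`+2^b` for `b ≥ 0`, `−2^(−b)` otherwise, so values lie outside (−1, 1)
and a repression by half prints as −2. `signed_fold(0) = +1`: the sign
ambiguity at zero is resolved to positive, which never matters in
practice because no reported value sits in (−1, 1).

### Two-tier selection

Directional calls require |fold| strictly greater than 5 **and** adjusted
p strictly below 0.05. The signature rule retains a miRNA when (tier 1)
both lines resistant to the same drug carry a directional call, or
(tier 2) at least one line changes at least 10-fold ("at least" — the
single-line comparison is non-strict) with significance. Strictness
conventions are configurable in `thresholds()`; on the packaged fixture
no row sits on a boundary, so the counts are insensitive to them. Tier 1
deliberately requires per-line significance in both lines: this is the
reading under which every panel count we can re-derive from the fixture
(46 retained; 34/9/3 up/down/mixed; 3 miRNAs changed in all four lines; 5
in exactly three) is reproduced exactly. One narrative inconsistency in
the source material — a miRNA listed in a drug signature whose second
line's adjusted p is 0.09 — is resolved in favor of the call-table
arithmetic.

"Changed in k lines" counts non-`none` calls, i.e. requires both the fold
and the significance criterion, per line.

### Target integration

Target edges from the four prediction databases and two validated
collections are combined by **union** with per-edge source provenance and
a validated flag (any validated source). Union rather than intersection
is a deliberate choice: the source enumeration mixes predicted and
validated collections, and recording provenance per edge lets an
intersection be recovered downstream, while the reverse is impossible.
"Inverse correlation" is sign opposition of the two point fold changes
within one cell line — not a correlation coefficient across samples — with
both members required to pass the same |fold| > 5, adjusted p < 0.05
cut-offs; a target whose own fold is below cut-off is "not significant"
and the pair is suppressed. GO subsetting matches annotation term
*names*, case-insensitively and exactly, against a keyword list whose
default is the superset of the two keyword lists used in the source
workflow (they differ by "drug transport"; the superset is configurable).
Identifier-based GO matching is an extension point, not implemented.
Networks are exported per cell line (directed miRNA → gene) as SIF,
GraphML with node-type and fold/source/GO attributes, or a TSV that
round-trips exactly through the package's reader.

## The synthetic world

The generator emulates the panel design: 5 groups × 4 replicates,
feature universes up to the chip's 2578 mature miRNAs (tests use 200–500
for speed), baseline 7 log2 units, and i.i.d. Gaussian noise on the log2
scale. Defaults are chosen once, as the stated world of the tests:

* `noise_sd = 0.25` log2 units — the source arrays report no dispersion
  estimates, so this is a package choice of a typical replicate-level sd
  for single-channel arrays; the null-control property is additionally
  exercised at 0.5.
* planted effects: `plant_signature_effects()` perturbs each planted
  miRNA in **both** lines resistant to one drug (alternating drug pairs
  and signs) — the biology the two-tier rule is designed to detect. A
  miRNA planted at |fold| 10 in two lines is recovered through tier 1
  with near-certainty at n = 4 and sd 0.25 (the observed fold only needs
  to exceed 5), which is why the 50-seed sensitivity criterion is met
  with margin; planting in a single line instead would put the observed
  fold exactly at the tier-2 boundary and sensitivity near 0.5 — a
  statement about that design, not about the implementation.
* target resources: one true target gene per planted miRNA with an
  inverse-sign mRNA fold drawn above the cut-off (uniform in log2 between
  1.2× and 8× the cut-off) in the miRNA's planted lines and a null fold
  elsewhere; decoy edges at a configurable rate, split between same-sign
  decoys (rejected only by the inverse filter) and sub-threshold decoys
  (rejected only by the fold cut-off), so the two filters are separately
  falsifiable; decoy genes also receive GO keywords so the GO stage
  cannot mask a filter defect.

What a green synthetic test does **not** establish: probe-level
chemistry (cross-hybridization, GC effects), intensity-dependent
variance, correlated replicates, or the realism of any specific database
snapshot — the generator's noise is exchangeable Gaussian and its truth
is planted, so these tests verify the decision logic and its statistics,
not array physics.

## Numerical and degenerate-input choices

* Median polish: tolerance 1e-6 on the residual sweep, max 10 cycles.
* Trigamma inversion: Newton with relative tolerance 1e-8; non-positive
  moment estimates fall back to `d₀ = ∞`.
* Zero-variance features are flagged in `fit_contrast`, excluded from
  prior estimation, and receive `NA` statistics when unshrunk.
* Missing values in matrices are an error everywhere (arrays are
  complete); no silent imputation.
* Quantile normalization of a single column warns and returns the input.
* `t` with `d₀ = ∞` uses the normal tail.
* JSON is the configuration and summary format because it round-trips
  the config losslessly and is diff-stable for determinism checks
  (identical config ⇒ byte-identical summary).

## Known limitations

* No bit-level reproduction of any specific RMA software build is
  attempted (different tie and background conventions exist).
* The moderated test's feature universe is caller-supplied; the package
  takes no position on probe-set vs mature-miRNA filtering.
* Live target-database clients are out of scope; edge tables are
  consumed as static TSVs, so results inherit whatever snapshot produced
  them.
* Per-drug signatures require exactly the both-lines-consistent pattern;
  panels with more than two lines per drug would need a generalized rule
  (the code requires `>= 2` and checks all of them).
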