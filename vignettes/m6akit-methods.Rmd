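---
title: "Models and methods behind m6akit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind m6akit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6akit)
```

m6akit implements the desk-side half of an m6A regulation study: peak
calling from MeRIP-seq coverage, mRNA half-life estimation from
actinomycin-D (ActD) chases, time-course expression analysis, gene-set
over-representation, and ELISA quantification. This vignette explains each
model, its assumptions, the tunable parameters, and the design choices made
where the underlying procedures are commonly described only operationally.

## Sliding-window peak calling

MeRIP-seq compares an anti-m6A immunoprecipitated library (IP) against its
input. The caller scans each transcript with `window_nt = 100` nt windows
every `step_nt = 50` nt, computes RPKM per window in each library, and calls
a window enriched when the pseudocounted ratio
`(RPKM_IP + 0.5) / (RPKM_input + 0.5)` reaches `min_fold = 4`. The threshold
is inclusive: a window at exactly fourfold is enriched. Enriched windows that
overlap or are book-ended merge into final peaks spanning their union; with a
50-nt step, consecutive enriched windows always overlap, so "adjacent" and
"overlapping-or-book-ended" coincide on the default grid.

Numerical choices worth stating:

* **RPKM of per-nt depth.** Depth is treated as read-equivalents:
  `rpkm = mean_depth × 1e9 / library_total`, where the library total defaults
  to the summed depth over the whole file. Uniform depth 1 at a library of
  10^6 gives RPKM 1000 for any window; doubling the library halves it.
* **Pseudocount α = 0.5 RPKM on both sides of the ratio.** Zero-coverage
  behaviour is otherwise undefined; a symmetric pseudocount bounds the fold
  and leaves well-covered windows essentially untouched.
* **Coverage gate `min_window_reads = 10`.** A window whose raw IP+input
  depth sum is below 10 can never be called, whatever its ratio; this
  suppresses spurious ≥4-fold calls produced by one or two reads.
* **Terminal windows.** A truncated final window is emitted only when at
  least `step_nt` long, so sub-step fragments cannot dominate the fold
  estimate. This is configurable via the window geometry.
* **Composition.** Because each library is normalized by its own total, a
  5×-enriched region scores slightly below 5 when planted signal inflates
  the IP library; callers of the simulator should keep planted signal a
  small fraction of the library, as real m6A peaks are.

Window enrichment can in principle be computed on raw counts instead of
RPKM; m6akit uses RPKM windows and states this as an assumption. With equal
library totals the two are identical, and the pseudocount is the only scale
left in the ratio.

## Decay kinetics with spike-in anchoring

In an ActD chase, transcription stops and remaining mRNA decays, so total
cellular mRNA shrinks over the course — any per-library normalization would
erase the very signal of interest. ERCC spike-ins added per microgram of RNA
provide the anchor: their expected counts are constant across samples up to
library-scale distortion. `spike_in_size_factors()` takes each sample's
spike total over the geometric mean of spike totals (geometric mean 1,
idempotent); `ruv_factor_removal()` can additionally project out `ruv_k`
singular directions of the centred spike submatrix, a RUV-style correction
implemented here directly as a least-squares projection, which is why
applying it twice equals applying it once.

The kinetic model is first-order decay — the standard ActD-chase model —
fit by OLS of `ln(count + 0.5)` on time: `k = max(0, −slope)`,
`t½ = ln 2 / k` (infinite at k = 0). The pseudocount 0.5 handles zeros at
late timepoints; clipping encodes that synthesis is impossible under ActD,
so apparent gains are noise. Replicates are averaged per timepoint after
normalization. On the default 0/4/8 h design with Poisson noise at baseline
1000, the 3-point fit recovers half-lives between 1 and 16 h with a pooled
median relative error of about 5%; the 16-h stratum is intrinsically
hardest (the decrement over 8 h is only 30%), sitting near 9–10% by the
variance of a 3-point log-linear slope.

Stabilization calls between conditions use
`t½(trt)/t½(ctrl) = k_ctrl/k_trt ≥ ratio_cut` (default 1.5) with a quality
gate `r² ≥ 0.5`; flat profiles (k = 0) pass the gate since r² is undefined
on a constant. The published analyses mark "degradation-inhibited" genes
without printing their criterion, so this cut is a declared, configurable
stand-in. Note that a symmetric distortion such as (1, 2, 1) across
(0, 4, 8) h cannot bias the slope — the design is balanced — which is why
the normalization-necessity checks plant a monotone halving distortion
(4, 2, 1): unanchored, it masquerades exactly as k = ln 2 / 4 per hour.

## Time-course expression

The expression stages deliberately use simple, fully specified stand-ins
rather than re-implementing a negative-binomial GLM framework:

* **Filter**: keep genes with row sum > 1, applied literally.
* **Normalization**: median-of-ratios size factors (median over genes
  positive in all samples of count over geometric mean).
* **Transform**: `log2(norm + 1)` in place of a regularized log; it is
  monotone, variance-flattening at high counts, and exactly reproducible.
* **Testing**: two-sided Welch t on the transformed scale with BH
  adjustment. With n = 2 replicates per condition — the design these
  experiments usually have — such p-values are severely underpowered, and
  the DEG table carries a header note saying so. Classification supports
  both published rules side by side (`|log2FC| ≥ 1`, inclusive; fold
  strictly > 1.5 with P < 0.05) because different figures state different
  rules; the user must pick a mode explicitly.
* **PCA**: top 500 most-variable genes, gene-centred, components
  sign-fixed by making each component's largest-magnitude loading positive
  so trajectories never flip between runs.

Fuzzy c-means is implemented in full rather than wrapped, because its exact
semantics matter downstream: memberships `u_ij ∝ d_ij^(−2/(m−1))` rows
summing to 1, centroids as `u^m`-weighted means, objective `Σ u^m d²`
monotone non-increasing, convergence when the objective moves less than
`tol = 1e-6`, hard labels by argmax with ties to the lowest cluster index,
and full determinism from the seed that initializes the membership matrix.
The defaults c = 9 and m = 2 match the nine-cluster decomposition such
time courses are typically summarized with; m is not printed in the source
analyses, and 2 is the field-standard choice. Profiles must be standardized
per gene (`standardize_profiles()` drops zero-variance genes, which carry
no temporal shape).

## Over-representation and ELISA

ORA is the upper-tail hypergeometric test `P(X ≥ k)` via `phyper`, with the
universe defined as the genes passing the expression filter (not the
genome), term sizes gated to 3–2000 after intersection with the universe,
and BH across tested terms. The test suite checks p-values against
exhaustive combinatorial enumeration for universes up to 25 genes at 1e-12.

The ELISA module fits a linear standard curve over the kit's 0.02–0.4
ng/well range — the quoted protocol implies a linear standard range, so no
four-parameter logistic is attempted — and converts OD to
`m6A% = amount/input × 100` on a default 200 ng input. Amounts below the
curve intercept are floored at zero and flagged below detection; background
subtraction is left to the caller since blank handling is kit-specific.

## The synthetic-data generators

The generators define the conditions under which the pipeline is validated:

* `simulate_timecourse_counts()`: negative-binomial counts (dispersion
  0.05, Poisson at 0) over planted temporal templates, days 3/5/7, two
  conditions, two biological replicates, library size 10^6. Templates are
  scaled by one global factor so planted shapes are preserved exactly; the
  nine default templates are time-balanced so the expected library size is
  constant over the course.
* `simulate_decay_experiment()`: Poisson counts with gene means
  `baseline × 2^(−t/t½) × distortion` and spike means constant before the
  same distortion — the defining asymmetry that makes spike anchoring work.
  Twenty synthetic spike-ins span expected counts 50–5000.
* `simulate_merip_coverage()`: per-nt Poisson coverage, background depth 30,
  IP mean multiplied by the planted enrichment inside truth intervals; one
  IP/input pair (replicate structure for MeRIP is rarely reported, so the
  generator defaults to a single pair).

What the generators do **not** emulate — and what passing tests therefore do
not establish about real data: fragment-level effects (GC and length bias,
fragmentation non-uniformity), spliced genome-coordinate peaks, batch
structure beyond a rank-1 library effect, overdispersion in the decay
counts, and biological covariance between genes. They are validation
instruments, not data twins.

## Problem sizes and limitations

The shipped checks run at deliberately modest sizes — 400 transcripts of
3 kb for peak recovery, 200 genes per half-life stratum, 100–270 genes for
clustering — chosen so the whole suite completes in seconds while leaving
the measured properties (≥95% peak recovery at one-step boundary accuracy,
<10% median half-life error, ARI 1.0 on well-separated patterns) far from
their thresholds.

Known limitations: the peak caller assigns no statistical significance to
peaks (no Poisson/Fisher test, no replicate reconciliation); the DE stage is
a threshold classifier around a low-powered test, not a shrinkage
estimator; ORA ignores the GO DAG; and the decay model is single-rate
first-order, which will underfit biphasic decay.
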