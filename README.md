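# m6akit

Transcriptome-level analysis of N6-methyladenosine (m6A) regulation during
cell-state transitions — for example the primed-to-naïve transition (PNT) of
pluripotent stem cells, where METTL3-deposited m6A marks naïve pluripotency
transcripts for YTHDF2-mediated degradation. The package covers the five
computational stages such a study needs once reads have been reduced to
counts and coverage, plus ground-truthed synthetic-data generators so every
stage can be validated end to end without raw sequencing data.

## What it computes

**MeRIP-seq peak calling.** Paired IP/input per-nucleotide coverage is
scanned with 100-nt windows stepped every 50 nt. Each window is scored by
RPKM (`mean depth × 10⁹ / library total`) in both libraries, and the
pseudocounted enrichment

    fold = (RPKM_IP + α) / (RPKM_input + α),   α = 0.5

is thresholded at **fold ≥ 4** (inclusive). Adjacent enriched windows —
overlapping or book-ended — merge into final peaks; a coverage gate
(≥ 10 raw read-equivalents per window) suppresses calls from near-empty
windows. Per-transcript summaries report peak count, peak nucleotides and
mean fold over the peak union.

**mRNA decay kinetics.** Actinomycin-D chase counts at t = 0, 4, 8 h are
anchored on ERCC spike-ins (added per unit RNA, hence immune to global mRNA
loss): per-sample size factors are spike totals over their geometric mean,
optionally followed by RUV-style removal of `k` unwanted factors (top left
singular vectors of the centred spike submatrix, projected out of every
gene). Each gene is then fit by first-order decay,

    ln(count + 0.5) = a − k·t,   t½ = ln 2 / k,

with negative decay clipped to k = 0 (no synthesis under ActD). Genes
degradation-inhibited under treatment are called by
`t½(trt)/t½(ctrl) ≥ 1.5` with an `r² ≥ 0.5` quality gate.

**Time-course expression.** Low-count filtering (row sum > 1),
median-of-ratios size factors, Welch-test differential expression on
`log2(norm + 1)` with Benjamini–Hochberg adjustment, classification under
both published threshold rules (`|log2FC| ≥ 1`; or fold > 1.5 & P < 0.05),
Venn partitions of 2–4 gene sets, a PCA trajectory of samples, and fuzzy
c-means clustering of standardized temporal profiles (default c = 9,
fuzzifier m = 2) with a full membership matrix.

**Over-representation analysis.** Upper-tail hypergeometric tests of a gene
list against a GMT collection with BH correction.

**m6A-ELISA.** Linear standard curve over the 0.02–0.4 ng/well range and
`m6A% = (m6A amount / input mRNA) × 100` on 200 ng input.

## Worked example

```r
library(m6akit)

# 1) MeRIP-seq peak calling on simulated coverage with two planted 5x peaks
lengths <- setNames(rep(2000L, 40), sprintf("tx%02d", 1:40))
planted <- data.frame(transcript = c("tx01", "tx02"),
                      start = c(400, 1000), end = c(550, 1150), enrichment = 5)
merip <- simulate_merip_coverage(lengths, planted, background_depth = 30, seed = 42)
res <- call_peaks_all(merip$pairs)
res$peaks
#>   transcript start  end    score n_windows
#> 1       tx01   400  550 4.941162         2
#> 2       tx02  1000 1150 4.928329         2

# 2) half-lives from an ActD chase, anchored on ERCC spike-ins
truth <- data.frame(gene = c("Esrrb_like", "Nanog_like", "housekeeping"),
                    half_life = c(2, 4, Inf), baseline = 1000)
chase <- simulate_decay_experiment(truth, timepoints = c(0, 4, 8), seed = 42)
estimate_half_lives(chase$counts)
#>           gene     k half_life    r2 n_points
#> 1   Esrrb_like 0.348      1.99 1.000        3
#> 2   Nanog_like 0.167      4.14 0.996        3
#> 3 housekeeping 0.000       Inf 0.368        3

# 3) m6A-ELISA quantification
ng <- c(0.02, 0.1, 0.2, 0.4)
curve <- fit_standard_curve(ng, 2 * ng + 0.5)
m6a_percent(0.9, curve, input_ng = 200)
#>    od amount_ng m6a_percent below_detection
#> 1 0.9       0.2         0.1           FALSE
```

Both planted peaks come back with exact boundaries and near-5× scores
(library composition slightly dilutes the fold); the three half-lives are
recovered at 1.99 h, 4.14 h and ∞ against truths of 2 h, 4 h and ∞; an OD
of 0.9 on a curve `OD = 2·ng + 0.5` is 0.2 ng of m6A, i.e. 0.1 % of a
200 ng mRNA input.

A command-line wrapper with subcommands
(`simulate-{timecourse,decay,merip}`, `callpeaks`, `decay`, `deg`,
`cluster`, `ora`, `elisa`) is installed at `inst/scripts/m6akit`; all flags
mirror `pipeline_config()` and every run is reproducible from `--seed` and
`--config`.

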