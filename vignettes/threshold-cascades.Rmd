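---
title: "Threshold cascades in untargeted LC/MS peak tables: model, assumptions, and the synthetic study generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold cascades in untargeted LC/MS peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thresholdscape)
```

## The problem

Untargeted LC/MS profiling of bio-fluids detects tens of thousands of
chromatographic peaks per file, most of them low-abundance. Standard data
processing applies a cascade of thresholds before any statistics are run:

* **TH2** — a chromatographic peak-height threshold at the individual-file
  level (ion counts);
* **TH3** — at alignment, a peak must reach TH2 in a minimum *fraction of
  samples*;
* **TH4** — after gap filling, a peak must be confidently detected in a
  minimum fraction of samples (the "% fill" detection frequency);
* **TH5** — an intensity floor used when deciding whether a gap-filled value
  counts as detected.

(A scan-level intensity threshold, often called TH1, acts during
acquisition/peak picking, before any peak table exists. It cannot be applied
to an exported table, so in this package it appears only inside the
simulator, as the limit of detection.)

Because instrument limits of detection couple a compound's abundance to its
detection prevalence — an abundant compound is seen in every sample, a trace
compound only in the samples where it happens to exceed the LoD — these
thresholds preferentially discard exactly the low-abundance, low-prevalence
features that carry exposure signal. `thresholdscape` quantifies that
discard: how the retained peak count shrinks along the cascade, and how many
peaks that are significantly associated with a continuous phenotype (e.g.
birth weight) are rejected before anyone looks at them ("insight loss").

## Cascade semantics and conventions

All filters pass on **≥**: height ≥ TH2, qualifying-sample count ≥ required,
fill ≥ TH4. The "at least" phrasing that accompanies these thresholds in
practice motivates the closed boundary; no strict variant is provided.

The required sample count for a fractional threshold f over n samples is
`max(1, ceiling(f * n))` — a fractional sample cannot satisfy "at least",
so 2% of 499 samples means 10 samples, and f = 0 degenerates to "detected in
at least one sample".

`fill_filter()` uses the table's stored fill fraction when the TH5 floor is
zero. A positive TH5 recomputes the detection frequency as the fraction of
samples with height ≥ TH5. Exports carry only the aggregate fill column, not
per-sample detected-vs-gap-filled flags, so recomputation against the height
matrix is the only TH5 semantics executable on an export; this is the
package's chosen interpretation of an otherwise ambiguous rule.

`retention_curve()` exposes **two** frequency-axis semantics, because
published retention curves conflate them:

* `"th4_fill"` (default): a peak must reach TH2 in ≥ 1 sample *and* have
  stored fill fraction ≥ f — the "% fill as positive-detection indicator"
  reading;
* `"th3_count"`: a peak must reach TH2 itself in ≥ `max(1, ceil(f·n))`
  samples.

Neither is asserted to be what any particular study did; the default matches
the fill-column reading. The additional-loss value reported for a pair
(TH2, f) is `(retained(TH2, f=0) − retained(TH2, f)) / n_total`, i.e. the
loss attributable to the frequency cutoff beyond the height cutoff alone.

Percentages in written tables are rounded to one decimal place.

## The association scan

For each peak the scan computes the Spearman coefficient between per-sample
heights and the phenotype — Pearson correlation on average ranks, so ties are
handled by midranks. Two-sided p-values use the t approximation
`t = ρ√((n−2)/(1−ρ²))` on n − 2 degrees of freedom for n > 10, and the exact
permutation distribution of the rank statistic (full enumeration, ties kept
as midranks) for n ≤ 10, where the approximation is poorest and enumeration
is cheap.

Gap-filled zeros are genuine "below confident detection" observations, and
the matrix being scanned is a gap-filled export, so the default
`zero_policy = "include"` ranks zeros as the lowest tied values. Censoring is
a monotone map on the low tail, so including zeros preserves most of the rank
signal; the `"exclude"` policy (drop zero-height samples per peak) is
provided for sensitivity analysis. Peaks with fewer than 3 usable pairs or
zero variance are reported as `NA` and — because an untestable peak is not a
hypothesis — excluded from the Benjamini–Hochberg m. The BH step-up itself is
delegated to `stats::p.adjust(method = "BH")` on the non-NA subset; an
independent O(m²) implementation exists only in the test suite as an oracle.

`significant_set()` returns ids with q ≤ α (default α = 0.05) ordered by
ascending p for deterministic downstream joins. `insight_loss()` intersects
that set with any collection of retention masks; `loss_fraction` is the
fraction of significant peaks a mask rejects.

## The synthetic study generator

`simulate_study()` generates the joint structure the analysis assumes, so
every stage of the pipeline is testable without raw spectra:

1. per-peak base abundance `10^Normal(3.5, 1)` ion counts — a log-normal
   spanning roughly four orders of magnitude across peaks, matching the
   dynamic range of a high-resolution QTOF and placing the bulk of peaks in
   the low thousands of counts;
2. per-cell multiplicative log-normal noise at a biological CV of 0.5 —
   mid-range for untargeted metabolomics of human blood;
3. a phenotype with marginal Normal(3400, 500) grams (a plausible
   birth-weight stand-in; the scale is irrelevant to rank statistics);
4. a planted set of `n_associated` peaks whose sample values are re-ordered
   against the phenotype by a Gaussian copula with correlation
   `r = 2·sin(π·ρ_target/6)`, which yields Spearman correlation exactly
   `ρ_target` without touching the marginal abundance distribution. A
   fraction `low_abundance_enrichment` (default 0.8) of planted peaks is
   drawn from the bottom tercile of base abundance, mimicking the
   concentration of exposure signal among low-abundance features;
5. acquisition censoring: values below `lod = 300` counts become 0. Because
   censoring happens *after* the noise, a compound near the LoD is observed
   in only some samples — the mechanism that generates the
   abundance–prevalence triangle;
6. gap filling: values in `[lod, confident_height)` with
   `confident_height = 1000` survive with probability `p_gapfill = 0.7`,
   else 0 (relaxed recovery criteria recover most, not all, sub-confident
   peaks); the fill fraction is the share of samples at or above the
   confident height.

The LoD default sits near the bottom decile of the abundance distribution
(the region where per-file height summaries of real studies bottom out at a
few hundred counts); the confident-detection height matches the
minimum-peak-height defaults of common peak-picking software. One global
seed drives a single RNG stream in the fixed order above, so studies are
bit-reproducible.

With the default 500 samples × 5,000 peaks, 200 planted associations at
ρ_target = 0.25 and 0.8 low-abundance enrichment, roughly 80% of planted
peaks never reach a height of 10,000 counts in any sample — the regime in
which the classical cascade (TH2 = 10,000 in ≥ 2% of samples, fill ≥ 60%)
rejects about 80% of the planted peaks that the scan detects as significant.
This figure is *computed* by `planted_recovery_report()` and checked by the
test suite; it is a property of the defaults above, not an input.

What the generator does **not** emulate: retention-time or signal drift,
batch effects, QC-sample structure, adduct/isotope/in-source-fragment
redundancy, missing-not-at-random mechanisms beyond LoD censoring, and
heavy-tailed abundance mixtures. Passing tests therefore demonstrate correct
threshold arithmetic and statistically calibrated machinery under LoD-driven
sparsity — not robustness to chromatographic artefacts. The true abundance
distribution of any given study is unknown; the log-normal is an assumption,
isolated behind `sim_params()` so it can be replaced.

## Descriptive summaries

Per-file distributions are summarised by equal-count quantile bins (default
20): values sorted ascending, split into contiguous groups of near-equal
size (remainder spread over the lowest bins), each bin reported by its group
maximum ("upper boundary"), so the top bin boundary is the file's maximum.
Equal-count bins are adopted because percentile-style bin labels imply them;
ties stay in their sorted positions, spanning bins if need be, and no
interpolation is done. Zero values are removed *before* binning (zeros code
for "not measured"), never inside the cascade filters. Cross-file
aggregation reports the per-bin mean boundary and relative standard
deviation (sample SD / mean × 100; sample SD because the files are a sample
of an instrument's behaviour). `dynamic_range_floor(max_height, orders)` is
`floor(max_height / 10^orders)` — with the published study maximum of
12,392,001 counts and a four-order dynamic range it returns the 1,239-count
floor quoted for that instrument class.

## Numerical and interface choices

* MS-DIAL dialect: column matching is case-insensitive with whitespace
  stripped; the fill column accepts percent (0–100) and fraction (0–1)
  encodings, auto-detected by whether any value exceeds 1 (the encoding used
  is recorded on the returned object). Missing fill columns are tolerated:
  the fraction of non-zero samples is substituted with a warning.
* Zero heights mean "not measured or not recovered"; no distinction from a
  true zero is attempted at ingest because the export carries none.
* Heights round-trip bit-exactly through the writer (17 significant digits).
* The packaged top-significant-peak fixture carries 49 rows because exactly
  49 are printed in its source table despite its "Top 50" caption; the
  transcription is pinned by checksum in the tests.
* Degenerate inputs: a zero-peak table passes through every filter with an
  empty mask and rejected fraction 0; an empty significant set gives
  loss 0.
* Test problem sizes: oracle-equivalence tests use ~1,000 random vectors of
  5–30 observations; cascade algebra uses 50 random 25 × 10 tables; the
  planted-loss check uses ten 500 × 5,000 studies and the null calibration
  twenty 200 × 2,000 studies — sizes chosen to estimate each property
  stably while keeping the default suite under a minute of simulation time.

## Limitations

Covariate-adjusted models are out of scope (the scan is deliberately a
crude, unadjusted rank association); so are peak annotation, adduct
grouping, QC-drift correction and anything upstream of the exported peak
tables (peak picking, mzML conversion). The insight-loss machinery treats
the significant set as exchangeable — it counts rejected discoveries and
does not weight them by effect size or chemical interest.
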