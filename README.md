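# metabodisc

Two-class discrimination of ¹H-NMR metabolomic profiles, built around a
veterinary case: separating dairy cows with displaced abomasum (left,
LDA, or right, RDA) from healthy controls using serum, liver and urine
extracts. The original cohort's raw spectra were never deposited, so the
package pairs the statistical pipeline with a seeded synthetic-spectrum
generator whose group structure follows the published metabolite
concentration tables — every stage is testable against a known truth
record.

## What it computes

**Processing.** Spectra (or simulated FIDs put through exponential
apodization and Fourier transform) are calibrated against a reference
resonance, segmented into 0.02 ppm buckets over 0.2–10.0 ppm (490 bins),
stripped of solvent regions (4.60–4.85 ppm water; 6.90–7.55 ppm
chloroform), and normalized by the probabilistic quotient method: after
total-area scaling, each sample *x* is divided by its median bin-wise
quotient against a reference spectrum *r*,

    q_i = median_j ( x_ij / r_j ),   x_i  <-  x_i / q_i

which corrects per-sample dilution (the recovered scale is exposed as
`pqnScale()`).

**Discrimination.** PCA gives the unsupervised overview. The supervised
classifier is OPLS: with classes coded y ∈ {−1, +1}, response-orthogonal
variation is removed from the centred bucket matrix by k orthogonal
components before a single predictive component t = Xw is fitted; for a
single response the fitted values equal PLS1 with k+1 components, the
orthogonal split existing for interpretability. Accuracy is estimated by
Monte Carlo cross-validation: 100 cycles of random stratified 90/10
train/test splits, with centring statistics and the per-cycle choice of
k (inner 7-fold CV, k ≤ 3) computed on the training split only.

**Univariate table.** Assigned ppm windows are integrated to
per-metabolite concentrations (arbitrary units), summarized as
median ± MAD (unscaled), and compared between groups with two-sample
Wilcoxon rank-sum tests under Benjamini–Hochberg FDR control at
adjusted p < 0.05, per comparison.

## Worked example

```r
library(metabodisc)

res <- runPipeline(pipelineConfig("serum", "water", seed = 1))
#> generated 70 synthetic serum/water spectra
#> bucketed into 490 bins (13 masked)
#> MCCV healthy vs LDA: mean accuracy 0.970
#> MCCV healthy vs RDA: mean accuracy 0.973
#> MCCV LDA vs RDA: mean accuracy 0.998
```

The cohort is 20 healthy / 42 LDA / 8 RDA simulated animals with
fold-changes patterned on the published serum water-soluble panel
(e.g. hippurate at 58.2/437.2 ≈ 0.13 of the healthy median in LDA),
log-uniform dilution in [0.5, 2], lognormal biological variation
(CV 0.25) and 0.004 ppm peak jitter. The three printed accuracies are
100-cycle MCCV means for the pairwise comparisons; `res$univariate` is
the median ± MAD table with raw/adjusted p values and significance
flags, and `res$report` carries seed, config hash and summary numbers.
With an `output_dir` configured, all artifacts (bucket table CSV +
sidecars, per-cycle accuracy TSVs, univariate CSV, truth record, report
JSON) are written and independently re-loadable.

A thin command-line wrapper with `simulate` / `process` /
`discriminate` / `compare` / `run` subcommands ships in
`inst/scripts/metabodisc.R`.

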