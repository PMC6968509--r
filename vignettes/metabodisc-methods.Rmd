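---
title: "Methods: synthetic NMR cohorts, PQN, OPLS and rank-based metabolite comparison"
author: "metabodisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic NMR cohorts, PQN, OPLS and rank-based metabolite comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodisc)
```

# The problem

Displaced abomasum (DA) is a common metabolic disorder of dairy cows in
which the fourth stomach shifts left (LDA) or right (RDA) of its normal
position. 1H-NMR profiles of serum, liver and urine extracts (each in a
water-soluble and a lipid-soluble fraction) separate diseased from
healthy animals, and a panel of assigned metabolites differs strongly
between groups. `metabodisc` implements that analysis chain as a
reusable, fully seeded pipeline:

1. generation of synthetic cohorts of 1D spectra with known group
   structure (no raw spectra from the original cohort were deposited,
   so every downstream stage is exercised on simulated data with a
   known truth record);
2. spectral processing: apodization/Fourier transform (for simulated
   FIDs), rigid chemical-shift calibration, 0.02 ppm bucketing over
   0.2--10.0 ppm, solvent-region exclusion, probabilistic quotient
   normalization (PQN);
3. multivariate statistics: PCA as the unsupervised overview, OPLS as
   the supervised two-class discriminator, validated by 100-cycle Monte
   Carlo cross-validation (MCCV);
4. univariate statistics: region integration to per-metabolite
   arbitrary-unit concentrations, median ± MAD summaries, two-sample
   Wilcoxon rank tests with Benjamini--Hochberg FDR control.

# The synthetic-data generator

## What it emulates

Each cohort follows the study design: 20 healthy, 42 LDA and 8 RDA
animals, one spectrum per animal. A spectrum is a sum of Lorentzian
multiplets (solution-state NMR lines decay exponentially in time, so
the Lorentzian is the natural lineshape; Gaussian blending is not
modelled). Per-sample amplitudes are

    base area x group fold-change x lognormal biological factor x dilution,

with additive Gaussian intensity noise on the frequency-domain grid.

* **Fold-changes** come packaged per matrix/phase combination as the
  ratio of published group medians to the healthy median
  (`defaultEffectTable()`). Panels carry 13--16 metabolites per
  combination (8 for urine lipid extracts, all the published table
  lists).
* **Dilution** is log-uniform in [0.5, 2] — a four-fold span that makes
  PQN a meaningful step rather than a no-op.
* **Biological variability** is lognormal with CV 0.25 per metabolite
  per sample: amplitudes stay positive and concentrations are skewed,
  consistent with choosing rank tests over t tests downstream.
* **Jitter**: each peak centre receives an independent per-sample shift
  (sd 0.004 ppm, small against the 0.02 ppm bucket). A single rigid
  per-sample shift would be removed entirely by calibration, making the
  bucketing-robustness question vacuous; independent per-peak shifts
  are what fixed-width bucketing actually has to absorb.
* **Calibration references** are mandatory members of each library: the
  anomeric glucose doublet at 5.24 ppm (serum water extracts), TMSP at
  0.00 ppm (liver/urine water extracts) and chloroform at 7.20 ppm
  (lipid extracts).
* **Background comb**: real biofluid spectra are crowded — hundreds of
  low-level resonances fill most of the spectral range. The libraries
  therefore add ~300 minor fold-1 resonances at low-discrepancy
  positions (kept at least 0.03 ppm clear of every quantifier window).
  Without this background, most 0.02 ppm bins would contain pure noise
  and the PQN median quotient would be dominated by noise-bin ratios —
  a failure mode real spectra do not exhibit.

The generator has two output paths that agree on bucket integrals: a
fast analytic path (absorption-mode Lorentzians evaluated on the ppm
grid) and a time-domain path (`makeFid()` + `apodizeTransform()`), which
exercises apodization and the discrete Fourier transform. Unit-scale
random deviates are drawn once and scaled afterwards, so designs
differing only in a noise/jitter/CV level share the same random stream
and can be compared draw for draw.

## What it does not emulate

No J-coupling evolution (multiplets are fixed line patterns), no phase
or baseline distortion (vendor-corrected spectra are the modelled
input), no T2 editing physics behind the CPMG tag (metadata only), and
no peak-position drift beyond the rigid + per-peak jitter model. Passing
tests on these cohorts demonstrate the statistical machinery under
realistic amplitude structure; they cannot certify behaviour under
baseline roll, water-suppression artefacts or pH-driven shift drift.

# Spectral processing

* **Bucketing** integrates each half-open 0.02 ppm bin by the
  trapezoidal rule with linear interpolation at bin boundaries, so the
  result is independent of how the acquisition grid aligns with bin
  edges, and the bin sum equals the full-range trapezoidal integral to
  machine precision. Bins are stored ascending; writers emit descending
  ppm for display only.
* **Exclusion** removes bins *overlapping* the solvent regions
  (4.60--4.85 ppm residual water for water extracts; 6.90--7.55 ppm
  chloroform for lipid extracts). Overlap, not bin-centre membership,
  decides — conservative and unambiguous at region boundaries; a
  1e-8 ppm tolerance guards against floating-point edge drift. Excluded
  bins stay in the container but are inert everywhere downstream.
* **PQN** follows the two-step quotient method: total-area
  normalization to a constant (100), then division by the median of
  bin-wise quotients against a reference spectrum. The default
  reference is the median across all samples; `reference = "control"`
  uses the healthy-group median (the quotient method's originally
  recommended reference when a control group exists). Reference bins below 1e-9 of the
  reference maximum are skipped to avoid division blow-up. The stored
  `pqnScale()` — total-area factor x median quotient / 100 — is the
  recovered per-sample dilution; on a no-effect cohort it tracks the
  injected dilution factors almost perfectly.
* **Calibration** searches ±0.05 ppm around the nominal reference
  position and shifts the axis rigidly; the located maximum must exceed
  5x the median absolute intensity, otherwise the spectrum is declared
  uncalibratable rather than silently mis-anchored.

**Known limitation — PQN under global metabolome shifts.** The quotient
method assumes most bins reflect dilution only. In the serum LDA
pattern, most panel metabolites decrease, so LDA median quotients are
biased and fold-changes of normalized concentrations compress toward 1
by roughly 10 percent; quantifier-window cross-talk adds a few percent
more for metabolites with very large down-folds. The control-median
reference recovers only part of this. Consumers of absolute fold
estimates should treat them as compressed; directions and ranks are
unaffected.

# Multivariate analysis

PCA is the SVD of the column-centred samples x bins matrix; explained
variance fractions are squared singular values over their total.

OPLS separates response-correlated from response-orthogonal variation:
with the predictive weight fixed by the (centred) response covariance,
`nOrth` orthogonal components are peeled off before a single predictive
component is fitted. For a single response the fitted values coincide
with PLS1 using `nOrth + 1` components (verified against an independent
NIPALS implementation to 1e-8); the gain is interpretability, not fit.
The orthogonal-score columns are mutually orthogonal and orthogonal to
the predictive score.

**Decision rule.** Classes are coded -1/+1. The default cutoff is the
fixed class-prior threshold: predict the +1 class when the centred
fitted response exceeds `-mean(coded y)`, exactly the conventional 0.5
cutoff on a 0/1 dummy-coded PLS-DA response. Under this rule a model
whose response carries no class information degrades gracefully into
majority-class prediction, so a label-permutation baseline lands at the
majority-class proportion — the behaviour a sanity-check permutation
test should see. The symmetric midpoint-of-class-means rule is
available (`thresholdRule = "midpoint"`); it centres the null at a
weighted coin instead and is preferable only when equal per-class error
costs matter more than a calibrated null. Ties at the threshold go to
the +1-coded class.

**MCCV.** Each of 100 cycles draws a stratified 90 percent training
split (stratification preserves the 8-member RDA group in the held-out
tenth; non-stratified splitting is available behind a flag, with
class-missing splits redrawn and logged). All centring/scaling
statistics are computed on the training split only and replayed on the
test split; the number of orthogonal components is re-selected each
cycle by 7-fold inner cross-validation over k = 0..3, ties toward the
simpler model. Both accuracy aggregations are kept: the mean of
per-cycle accuracies (the headline number) and the pooled
confusion-matrix accuracy. Scaling defaults to mean-centring only —
bucket tables are already area- and dilution-normalized, and variance
scaling would inflate noise bins.

Multiclass structure is handled as pairwise two-class models
(healthy-vs-LDA, healthy-vs-RDA, LDA-vs-RDA); no multiclass OPLS.

# Univariate analysis

Assigned ppm windows (packaged per matrix/phase; literature-patterned
stand-ins, since the original integration regions were not published)
are integrated with overlap-fraction weighting over included bins.
Group summaries are median ± MAD with the *unscaled* MAD (no 1.4826
consistency factor), matching the published table convention.

Group differences use the two-sample Wilcoxon rank-sum test: exact
enumeration when the smaller group has at most 8 observations and no
ties, otherwise the normal approximation with mid-rank tie correction
and continuity correction. The original text names the signed-rank
test, but the compared groups are independent animals, so the rank-sum
test is the applicable variant; a paired signed-rank mode exists for
completeness. Degenerate all-identical input returns p = 1 with a
warning. BH adjustment is applied within each comparison across
metabolites (each comparison is reported as its own family, matching
the per-comparison layout of the published table; pooling across
comparisons is a configuration choice). Significance is adjusted
p < 0.05.

The truth record marks a metabolite as differential for a comparison
when the injected fold ratio is at least 2 in either direction
(|log2| >= 1); weaker injected folds exist in the packaged tables but
are not what a power claim should be anchored on. The exact injected
ratio is always carried alongside.

# Numerical choices and degenerate inputs

* Half-open bins `[lo, hi)`; 490 bins over 0.2--10.0 ppm at 0.02 ppm.
* FID first point halved before the transform (t = 0 window factor),
  conserving the integral under line broadening to well under 1
  percent.
* Zero-variance columns under variance scaling are flagged and left
  centred rather than producing NaNs.
* OPLS errors when the predictive score collapses (rank exhausted);
  response-aligned rank-1 data yield a zero orthogonal component rather
  than an error.
* A single master seed fans out to stage-specific sub-seeds
  (generation, MCCV splits, inner folds), so stages re-run
  independently and reproducibly; seeded functions restore the
  caller's random stream.

# Problem sizes

Default cohorts are 70 samples x 16384 grid points, bucketed to 490
bins (477 after water-region exclusion). The test suite runs MCCV at
100 cycles on two full cohorts, the OPLS/PLS equivalence on 50 random
30 x 40 instances, the FDR null on 500 concentration-level cohorts of
30 metabolites (the statistical layer is what that check exercises;
spectra add nothing to it), and the permutation baseline on 6 permuted
label vectors x 50 cycles.
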