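#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## ---------------------------------------------------------------------------
## PeakSpec
## ---------------------------------------------------------------------------

#' Lorentzian resonance specification
#'
#' One metabolite resonance used by the synthetic-spectrum generator: a
#' Lorentzian multiplet centred at \code{centerPpm} with full width at half
#' maximum \code{linewidthHz} and total integrated area
#' \code{baseAmplitude} (arbitrary units). \code{multiplet} is a
#' two-column matrix of (ppm offset, relative intensity) pairs; relative
#' intensities are normalized internally so the multiplet's total area
#' equals \code{baseAmplitude}.
#'
#' @slot metabolite character metabolite name.
#' @slot centerPpm numeric chemical shift (ppm) of the multiplet centre.
#' @slot linewidthHz numeric Lorentzian FWHM in Hz (> 0).
#' @slot baseAmplitude numeric total area in arbitrary units (>= 0).
#' @slot multiplet numeric matrix with columns \code{offset} (ppm) and
#'   \code{rel} (relative intensity, > 0).
#' @exportClass PeakSpec
setClass("PeakSpec", representation(
  metabolite = "character",
  centerPpm = "numeric",
  linewidthHz = "numeric",
  baseAmplitude = "numeric",
  multiplet = "matrix"
))

setValidity("PeakSpec", function(object) {
  msg <- character()
  if (length(object@linewidthHz) != 1L || !is.finite(object@linewidthHz) ||
      object@linewidthHz <= 0)
    msg <- c(msg, "linewidthHz must be a single positive number")
  if (length(object@baseAmplitude) != 1L || !is.finite(object@baseAmplitude) ||
      object@baseAmplitude < 0)
    msg <- c(msg, "baseAmplitude must be a single non-negative number")
  if (ncol(object@multiplet) != 2L)
    msg <- c(msg, "multiplet must have two columns (offset, rel)")
  else if (any(object@multiplet[, 2L] <= 0))
    msg <- c(msg, "multiplet relative intensities must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSpec
#'
#' @param metabolite metabolite name.
#' @param centerPpm chemical shift of the multiplet centre (ppm).
#' @param linewidthHz Lorentzian FWHM (Hz).
#' @param baseAmplitude total multiplet area (arbitrary units).
#' @param offsets ppm offsets of the multiplet lines relative to
#'   \code{centerPpm} (default a singlet at offset 0).
#' @param rel relative line intensities, recycled against \code{offsets}.
#' @return A \linkS4class{PeakSpec}.
#' @examples
#' peakSpec("alanine", 1.48, 1.5, 1603, offsets = c(-0.006, 0.006))
#' @export
peakSpec <- function(metabolite, centerPpm, linewidthHz, baseAmplitude,
                     offsets = 0, rel = 1) {
  rel <- rep_len(rel, length(offsets))
  new("PeakSpec", metabolite = metabolite, centerPpm = centerPpm,
      linewidthHz = linewidthHz, baseAmplitude = baseAmplitude,
      multiplet = cbind(offset = offsets, rel = rel))
}

## ---------------------------------------------------------------------------
## CohortDesign
## ---------------------------------------------------------------------------

#' Synthetic cohort design
#'
#' Full description of a simulated three-group study: group sizes, sample
#' matrix and extraction phase, the per-group multiplicative effect table,
#' dilution/noise/jitter levels and the spectral grid. The defaults
#' reproduce the study conditions: 20 healthy, 42 LDA (left displaced
#' abomasum) and 8 RDA cows, fold-changes derived from the published
#' metabolite concentration table, per-sample log-uniform dilution in
#' [0.5, 2], lognormal biological variation (CV 0.25) and 0.004 ppm peak
#' jitter.
#'
#' @slot groupSizes named integer vector (healthy, LDA, RDA), each >= 2.
#' @slot sampleMatrix one of "serum", "liver", "urine".
#' @slot phase one of "water", "lipid".
#' @slot effectTable data.frame with columns metabolite, healthy, LDA, RDA
#'   giving per-group fold-changes relative to healthy (healthy all 1).
#' @slot dilutionLogRange numeric length-2, natural-log bounds of the
#'   per-sample global scale factor.
#' @slot noiseSd additive Gaussian intensity noise sd (arbitrary units).
#' @slot jitterSdPpm per-sample, per-peak sd of random centre shifts (ppm).
#' @slot biologicalCv lognormal per-sample per-metabolite coefficient of
#'   variation.
#' @slot seed integer random seed.
#' @slot nPoints spectral grid size.
#' @slot ppmRange numeric length-2 axis bounds (must span 0.2-10.0 ppm).
#' @exportClass CohortDesign
setClass("CohortDesign", representation(
  groupSizes = "integer",
  sampleMatrix = "character",
  phase = "character",
  effectTable = "data.frame",
  dilutionLogRange = "numeric",
  noiseSd = "numeric",
  jitterSdPpm = "numeric",
  biologicalCv = "numeric",
  seed = "integer",
  nPoints = "integer",
  ppmRange = "numeric"
))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (!all(names(object@groupSizes) %in% .GROUPS))
    msg <- c(msg, "groupSizes names must be among healthy, LDA, RDA")
  if (any(object@groupSizes < 2L))
    msg <- c(msg, "all group sizes must be >= 2")
  if (!object@sampleMatrix %in% .MATRICES)
    msg <- c(msg, "sampleMatrix must be serum, liver or urine")
  if (!object@phase %in% .PHASES)
    msg <- c(msg, "phase must be water or lipid")
  if (length(object@dilutionLogRange) != 2L ||
      any(!is.finite(object@dilutionLogRange)))
    msg <- c(msg, "dilutionLogRange must be two finite numbers")
  if (object@jitterSdPpm < 0 || object@jitterSdPpm >= 0.02)
    msg <- c(msg, "jitterSdPpm must be >= 0 and smaller than the 0.02 ppm bucket width")
  if (length(object@ppmRange) != 2L || object@ppmRange[1] > 0.2 ||
      object@ppmRange[2] < 10.0)
    msg <- c(msg, "ppmRange must span at least 0.2-10.0 ppm")
  if (!all(c("metabolite", "healthy", "LDA", "RDA") %in%
           colnames(object@effectTable)))
    msg <- c(msg, "effectTable needs columns metabolite, healthy, LDA, RDA")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Spectrum / FID
## ---------------------------------------------------------------------------

#' One-dimensional NMR spectrum
#'
#' A frequency-domain spectrum: a strictly monotone ppm axis with real
#' intensities and per-sample metadata (sample id, group, matrix, phase,
#' pulse program). Stored with an ascending ppm axis; display convention
#' (descending ppm) is a writer concern only.
#'
#' @slot ppm numeric, strictly increasing chemical-shift grid (ppm).
#' @slot intensity numeric, same length as \code{ppm}, finite.
#' @slot sampleMeta named list with elements sample_id, group, matrix,
#'   phase, pulse_program.
#' @exportClass NMRSpectrum
setClass("NMRSpectrum", representation(
  ppm = "numeric", intensity = "numeric", sampleMeta = "list"
))

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) >= 2L && any(diff(object@ppm) <= 0))
    msg <- c(msg, "ppm axis must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an NMRSpectrum
#' @param ppm ascending ppm axis.
#' @param intensity real intensities.
#' @param sampleMeta named list of sample metadata.
#' @return An \linkS4class{NMRSpectrum}.
#' @export
nmrSpectrum <- function(ppm, intensity, sampleMeta = list()) {
  new("NMRSpectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      sampleMeta = sampleMeta)
}

#' Free induction decay
#'
#' Complex time-domain NMR signal with its sampling parameters. The
#' default spectrometer frequency is 600.13 MHz (proton Larmor frequency
#' of the acquiring instrument).
#'
#' @slot signal complex time-domain samples.
#' @slot dwellTime sampling interval (s).
#' @slot spectrometerFreq spectrometer frequency (MHz), converts ppm to Hz.
#' @slot carrierPpm ppm value at zero offset frequency (axis anchor).
#' @slot sampleMeta named list of sample metadata.
#' @exportClass NMRFid
setClass("NMRFid", representation(
  signal = "complex", dwellTime = "numeric", spectrometerFreq = "numeric",
  carrierPpm = "numeric", sampleMeta = "list"
))

setValidity("NMRFid", function(object) {
  msg <- character()
  if (length(object@signal) < 2L)
    msg <- c(msg, "signal must have length >= 2")
  if (object@dwellTime <= 0) msg <- c(msg, "dwellTime must be > 0")
  if (object@spectrometerFreq <= 0)
    msg <- c(msg, "spectrometerFreq must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## NMRCohort
## ---------------------------------------------------------------------------

#' Simulated cohort container
#'
#' Holds the generated spectra (or FIDs), the per-sample metadata, the
#' per-sample truth (dilution factors, realized per-metabolite scale) and
#' the truth record listing which metabolites truly differ per comparison.
#'
#' @slot spectra list of \linkS4class{NMRSpectrum} or \linkS4class{NMRFid}.
#' @slot sampleMeta \link[S4Vectors]{DataFrame} with columns sample_id,
#'   group, matrix, phase, pulse_program.
#' @slot dilution numeric per-sample dilution factors (truth).
#' @slot truth data.frame with columns metabolite, comparison,
#'   true_fold_change, is_differential.
#' @slot design the generating \linkS4class{CohortDesign}.
#' @exportClass NMRCohort
setClass("NMRCohort", representation(
  spectra = "list", sampleMeta = "DataFrame", dilution = "numeric",
  truth = "data.frame", design = "CohortDesign"
))

setValidity("NMRCohort", function(object) {
  msg <- character()
  if (length(object@spectra) != nrow(object@sampleMeta))
    msg <- c(msg, "one metadata row per spectrum required")
  if (anyDuplicated(object@sampleMeta$sample_id))
    msg <- c(msg, "sample_id must be unique within a cohort")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## BucketTable
## ---------------------------------------------------------------------------

#' Bucketed spectral data table
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose single assay
#' \code{"area"} holds integrated bucket areas (bins in rows, samples in
#' columns). \code{rowData} carries the bin edges (\code{ppm_lo},
#' \code{ppm_hi}) and the \code{included} exclusion mask; \code{colData}
#' carries the sample metadata. The normalization state
#' (\code{raw}, \code{total_area} or \code{pqn}) and, after PQN, the
#' per-sample median quotients and recovered dilution scales live in
#' \code{metadata()}.
#'
#' @exportClass BucketTable
setClass("BucketTable", contains = "SummarizedExperiment")

setValidity("BucketTable", function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!all(c("ppm_lo", "ppm_hi", "included") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain ppm_lo, ppm_hi, included")
  else {
    w <- rd$ppm_hi - rd$ppm_lo
    if (any(w <= 0)) msg <- c(msg, "bin widths must be positive")
  }
  st <- metadata(object)$normalization_state %||% "raw"
  if (!st %in% c("raw", "total_area", "pqn"))
    msg <- c(msg, "normalization_state must be raw, total_area or pqn")
  if (st == "pqn" && is.null(metadata(object)$pqn_quotients))
    msg <- c(msg, "pqn state requires stored pqn_quotients")
  if (any(!is.finite(assay(object))))
    msg <- c(msg, "bucket values must be finite")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Multivariate models
## ---------------------------------------------------------------------------

#' Principal component analysis model
#'
#' SVD-based PCA of a samples x bins matrix: per-bin mean, orthonormal
#' loadings, scores (centred data projected on the loadings) and the
#' fraction of variance explained per component.
#'
#' @slot mean per-bin centring vector.
#' @slot loadings bins x components matrix, orthonormal columns.
#' @slot scores samples x components matrix.
#' @slot explainedVariance fraction of total variance per component,
#'   non-increasing.
#' @exportClass PCAModel
setClass("PCAModel", representation(
  mean = "numeric", loadings = "matrix", scores = "matrix",
  explainedVariance = "numeric"
))

#' Orthogonal projections to latent structures model
#'
#' Two-class OPLS with a single predictive component: response-orthogonal
#' variation is removed from the predictors by \code{nOrth} orthogonal
#' components before the predictive component is fitted, separating
#' response-correlated from response-unrelated variation.
#'
#' @slot center per-bin centring vector (training column means).
#' @slot yMean mean of the coded response used during fitting.
#' @slot predictiveWeights,predictiveLoadings per-bin vectors of the
#'   predictive component.
#' @slot predictiveScores per-training-sample predictive scores.
#' @slot orthogonalWeights,orthogonalLoadings bins x nOrth matrices.
#' @slot orthogonalScores samples x nOrth matrix.
#' @slot yLoading scalar regression of the response on the predictive score.
#' @slot nOrth number of orthogonal components (>= 0).
#' @slot classCoding named numeric mapping group label to -1/+1.
#' @slot decisionThreshold classification cutoff on the centred fitted
#'   response (see \code{\link{oplsFit}}); ties at the threshold go to
#'   the +1-coded class.
#' @exportClass OPLSModel
setClass("OPLSModel", representation(
  center = "numeric", yMean = "numeric",
  predictiveWeights = "numeric", predictiveLoadings = "numeric",
  predictiveScores = "numeric",
  orthogonalWeights = "matrix", orthogonalLoadings = "matrix",
  orthogonalScores = "matrix",
  yLoading = "numeric", nOrth = "integer",
  classCoding = "numeric", decisionThreshold = "numeric"
))

#' Monte Carlo cross-validation result
#'
#' Per-cycle held-out accuracies of repeated random 90/10 train/test
#' splitting (100 cycles by default), the pooled 2x2 confusion matrix
#' (rows = true class, columns = predicted class), and both accuracy
#' aggregations: the mean of per-cycle accuracies and the pooled
#' diagonal fraction.
#'
#' @slot cycleAccuracies numeric per-cycle accuracies in [0, 1].
#' @slot meanAccuracy mean of the per-cycle accuracies.
#' @slot pooledAccuracy diagonal sum / total of the pooled confusion matrix.
#' @slot confusionMatrix 2x2 pooled counts.
#' @slot nCycles number of cycles.
#' @slot trainFraction training proportion per cycle.
#' @slot seed seed the splits were drawn from.
#' @slot classLevels the two group labels in coding order (-1 then +1).
#' @slot cycles list of per-cycle detail (test indices, predicted response
#'   and class, selected number of orthogonal components).
#' @exportClass MCCVResult
setClass("MCCVResult", representation(
  cycleAccuracies = "numeric", meanAccuracy = "numeric",
  pooledAccuracy = "numeric", confusionMatrix = "matrix",
  nCycles = "integer", trainFraction = "numeric", seed = "integer",
  classLevels = "character", cycles = "list"
))

setValidity("MCCVResult", function(object) {
  msg <- character()
  if (any(object@cycleAccuracies < 0 | object@cycleAccuracies > 1))
    msg <- c(msg, "cycle accuracies must lie in [0, 1]")
  if (!isTRUE(all.equal(object@meanAccuracy,
                        mean(object@cycleAccuracies))))
    msg <- c(msg, "meanAccuracy must equal the mean of cycleAccuracies")
  if (length(msg)) msg else TRUE
})
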