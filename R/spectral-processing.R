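#' Apodize and Fourier-transform an FID
#'
#' Multiplies the FID by a decaying exponential \code{exp(-pi * lb * t)}
#' (equivalent to \code{lb} Hz of extra Lorentzian line broadening; the
#' conventional processing value is 0.3 Hz), applies the discrete Fourier
#' transform with the first time point halved (the standard correction
#' for the t = 0 integration window), and returns the real part on an
#' ascending ppm axis derived from the dwell time, spectrometer frequency
#' and carrier position.
#'
#' @param fid an \linkS4class{NMRFid}.
#' @param lineBroadening exponential line-broadening factor in Hz (>= 0).
#' @return An \linkS4class{NMRSpectrum}.
#' @export
apodizeTransform <- function(fid, lineBroadening = 0.3) {
  validObject(fid)
  if (lineBroadening < 0) stopf("lineBroadening must be >= 0")
  if (fid@dwellTime <= 0) stopf("dwell time must be positive")
  n <- length(fid@signal)
  tt <- (seq_len(n) - 1) * fid@dwellTime
  s <- fid@signal * exp(-pi * lineBroadening * tt)
  s[1] <- s[1] / 2
  spec <- stats::fft(s) * fid@dwellTime
  ## reorder to an ascending frequency axis (-sw/2 .. sw/2 - df)
  half <- n %/% 2
  ord <- c((half + 1):n, 1:half)
  freq <- (seq_len(n) - 1 - half) / (n * fid@dwellTime)
  ppm <- fid@carrierPpm + freq / fid@spectrometerFreq
  nmrSpectrum(ppm, Re(spec[ord]), sampleMeta = fid@sampleMeta)
}

#' Calibrate the chemical-shift axis against a reference resonance
#'
#' Rigidly shifts the ppm axis so that the highest local maximum found
#' within \code{nominalPpm +/- searchHalfwidth} lands exactly on
#' \code{nominalPpm}; intensities are untouched. The located maximum must
#' exceed a prominence threshold (default 5 x the median absolute
#' intensity of the spectrum), otherwise the spectrum is declared
#' uncalibratable.
#'
#' @param spec an \linkS4class{NMRSpectrum}.
#' @param referenceName name of the reference resonance (used in error
#'   messages only).
#' @param nominalPpm nominal position of the reference (ppm).
#' @param searchHalfwidth half-width of the search window (ppm).
#' @param prominence minimal peak intensity, in multiples of the median
#'   absolute spectrum intensity.
#' @return The calibrated \linkS4class{NMRSpectrum}.
#' @export
calibrateSpectrum <- function(spec, referenceName = "reference",
                              nominalPpm, searchHalfwidth = 0.05,
                              prominence = 5) {
  win <- which(spec@ppm >= nominalPpm - searchHalfwidth &
               spec@ppm <= nominalPpm + searchHalfwidth)
  if (length(win) < 3)
    stopf("search window around %.3f ppm not covered by the axis", nominalPpm)
  i <- win[which.max(spec@intensity[win])]
  thr <- prominence * stats::median(abs(spec@intensity))
  if (spec@intensity[i] < thr)
    stopf("no peak above prominence for reference '%s' near %.3f ppm: spectrum uncalibratable",
          referenceName, nominalPpm)
  shift <- nominalPpm - spec@ppm[i]
  nmrSpectrum(spec@ppm + shift, spec@intensity, spec@sampleMeta)
}

#' Integrate a spectrum into fixed-width chemical-shift buckets
#'
#' Segments \code{[rangeLo, rangeHi)} into half-open bins of
#' \code{binWidth} ppm (defaults: 0.02 ppm over 0.2-10.0 ppm, i.e. 490
#' bins) and integrates the intensity over each bin by the trapezoidal
#' rule, with linear interpolation of the intensity at bin boundaries so
#' the result is independent of how the grid aligns with the bin edges.
#' The bin sum equals the trapezoidal integral of the full range to
#' machine precision.
#'
#' @param spec an \linkS4class{NMRSpectrum} whose axis covers the range.
#' @param binWidth bin width (ppm); must divide the range.
#' @param rangeLo,rangeHi integration range bounds (ppm).
#' @return list with \code{values} (bin integrals) and \code{edges}
#'   (length \code{nbins + 1} vector of bin boundaries).
#' @examples
#' sp <- nmrSpectrum(seq(0, 11, by = 0.001), rep(2, 11001))
#' b <- bucketSpectrum(sp)
#' length(b$values)      # 490
#' all.equal(sum(b$values), 2 * 9.8)
#' @export
bucketSpectrum <- function(spec, binWidth = 0.02, rangeLo = 0.2,
                           rangeHi = 10.0) {
  nbins <- (rangeHi - rangeLo) / binWidth
  if (abs(nbins - round(nbins)) > 1e-8)
    stopf("binWidth %.4g does not divide the range [%.3f, %.3f]",
          binWidth, rangeLo, rangeHi)
  nbins <- as.integer(round(nbins))
  if (min(spec@ppm) > rangeLo || max(spec@ppm) < rangeHi)
    stopf("spectrum axis [%.3f, %.3f] does not cover [%.3f, %.3f]",
          min(spec@ppm), max(spec@ppm), rangeLo, rangeHi)
  edges <- rangeLo + binWidth * (0:nbins)
  ## refined grid: original points within range plus interpolated edges
  inside <- spec@ppm > rangeLo & spec@ppm < rangeHi
  gx <- c(spec@ppm[inside], edges)
  gy <- c(spec@intensity[inside],
          stats::approx(spec@ppm, spec@intensity, xout = edges)$y)
  o <- order(gx)
  gx <- gx[o]; gy <- gy[o]
  ## cumulative trapezoid on the refined grid, read off at the edges
  ct <- c(0, cumsum((gy[-1] + gy[-length(gy)]) * diff(gx) / 2))
  idx <- findInterval(edges, gx)
  ## edges are exact members of gx; findInterval returns their position
  cumAt <- ct[idx]
  list(values = diff(cumAt), edges = edges)
}

#' Build a BucketTable from a cohort of spectra
#'
#' Buckets every spectrum (see \code{\link{bucketSpectrum}}) and
#' assembles the \linkS4class{BucketTable}; all bins start included and
#' the normalization state is \code{"raw"}.
#'
#' @param spectra list of \linkS4class{NMRSpectrum} (or an
#'   \linkS4class{NMRCohort}, whose metadata is then reused).
#' @param sampleMeta \link[S4Vectors]{DataFrame} of per-sample metadata;
#'   ignored when \code{spectra} is a cohort.
#' @inheritParams bucketSpectrum
#' @return A \linkS4class{BucketTable}.
#' @export
buildBucketTable <- function(spectra, sampleMeta = NULL, binWidth = 0.02,
                             rangeLo = 0.2, rangeHi = 10.0) {
  extra <- list()
  if (is(spectra, "NMRCohort")) {
    sampleMeta <- spectra@sampleMeta
    extra <- list(dilution = spectra@dilution, truth = spectra@truth)
    spectra <- spectra@spectra
  }
  buckets <- lapply(spectra, bucketSpectrum, binWidth = binWidth,
                    rangeLo = rangeLo, rangeHi = rangeHi)
  values <- vapply(buckets, `[[`, numeric(length(buckets[[1]]$values)),
                   "values")
  edges <- buckets[[1]]$edges
  if (is.null(sampleMeta))
    sampleMeta <- S4Vectors::DataFrame(
      sample_id = sprintf("S%03d", seq_along(spectra)))
  colnames(values) <- sampleMeta$sample_id
  rd <- S4Vectors::DataFrame(ppm_lo = edges[-length(edges)],
                             ppm_hi = edges[-1],
                             included = TRUE)
  se <- SummarizedExperiment(assays = list(area = values), rowData = rd,
                             colData = sampleMeta)
  metadata(se)$normalization_state <- "raw"
  metadata(se)$excluded_regions <- list()
  metadata(se) <- c(metadata(se), extra)
  new("BucketTable", se)
}

#' Default solvent exclusion regions by phase
#'
#' Water-soluble extracts: 4.60-4.85 ppm (residual water signal);
#' lipid-soluble extracts: 6.90-7.55 ppm (chloroform signal).
#'
#' @param phase "water" or "lipid".
#' @return list of length-2 numeric vectors (ppm_lo, ppm_hi).
#' @export
defaultExclusionRegions <- function(phase) {
  phase <- checkVocab(phase, .PHASES, "phase")
  if (phase == "water") list(c(4.60, 4.85)) else list(c(6.90, 7.55))
}

#' Mask bins overlapping exclusion regions
#'
#' Any bin whose half-open interval overlaps any of the given regions has
#' its \code{included} flag cleared. Overlap (not bin-centre membership)
#' defines exclusion, so region boundaries are handled conservatively;
#' comparisons carry a 1e-8 ppm tolerance against floating-point edge
#' drift. Excluded bins are inert in all downstream statistics.
#'
#' @param table a \linkS4class{BucketTable}.
#' @param regions list of length-2 numeric vectors (ppm_lo, ppm_hi), or
#'   \code{NULL} to use \code{\link{defaultExclusionRegions}} for the
#'   table's phase.
#' @return The masked \linkS4class{BucketTable}.
#' @export
excludeRegions <- function(table, regions = NULL) {
  if (is.null(regions)) {
    phase <- unique(colData(table)$phase)
    if (length(phase) != 1L)
      stopf("cannot infer exclusion regions: table has no single phase")
    regions <- defaultExclusionRegions(phase)
  }
  rd <- rowData(table)
  inc <- rd$included
  tol <- 1e-8
  for (r in regions) {
    if (length(r) != 2L || r[1] >= r[2])
      stopf("inverted or malformed exclusion region [%s]",
            paste(r, collapse = ", "))
    hit <- rd$ppm_lo < r[2] - tol & rd$ppm_hi > r[1] + tol
    inc <- inc & !hit
  }
  rowData(table)$included <- inc
  metadata(table)$excluded_regions <-
    c(metadata(table)$excluded_regions, regions)
  table
}

#' Normalize each sample to constant total included area
#'
#' Divides every sample by its summed included-bin area and rescales to a
#' fixed constant (100), the integral-normalization step that precedes
#' quotient computation in probabilistic quotient normalization.
#'
#' @param table a \linkS4class{BucketTable} with positive included areas.
#' @param constant the post-normalization total area.
#' @return The normalized \linkS4class{BucketTable}
#'   (state \code{"total_area"}); per-sample original totals are kept in
#'   \code{metadata()$total_area}.
#' @export
totalAreaNormalize <- function(table, constant = 100) {
  v <- assay(table, "area")
  inc <- includedBins(table)
  totals <- colSums(v[inc, , drop = FALSE])
  bad <- totals <= 0
  if (any(bad))
    stopf("non-positive total included area for sample(s): %s",
          paste(colnames(v)[bad], collapse = ", "))
  assay(table, "area") <- sweep(v, 2, totals / constant, "/")
  metadata(table)$normalization_state <- "total_area"
  metadata(table)$total_area <- structure(totals, names = colnames(v))
  table
}

#' Probabilistic quotient normalization
#'
#' Dilution correction by the median-quotient method: after total-area
#' normalization, a reference spectrum is computed over the included bins
#' (default: the median across all samples), per-sample quotients
#' sample/reference are formed on bins whose reference value exceeds a
#' small floor, and each sample is divided by its median quotient. The
#' median quotients are stored, together with the recovered per-sample
#' dilution scale (total-area factor x median quotient / constant),
#' which on a no-effect cohort tracks the injected dilution factors.
#'
#' @param table a \linkS4class{BucketTable}; total-area normalization is
#'   applied internally if the table is still raw.
#' @param reference "median" (default: median across all samples),
#'   "mean", "control" (median across the \code{controlGroup} samples
#'   only, the quotient method's originally recommended reference when
#'   a control group exists; slightly reduces quotient bias when a
#'   large fraction of the metabolome shifts with disease), or a
#'   numeric vector of length nbins giving an explicit reference
#'   spectrum.
#' @param controlGroup group label used by \code{reference = "control"}.
#' @param quotientFloor reference bins below
#'   \code{quotientFloor * max(reference)} are skipped when computing
#'   quotients, to avoid division blow-up.
#' @param minQuotientBins minimal number of usable quotient bins.
#' @return The normalized \linkS4class{BucketTable} (state \code{"pqn"}).
#' @export
pqnNormalize <- function(table, reference = "median",
                         quotientFloor = 1e-9, minQuotientBins = 10,
                         controlGroup = "healthy") {
  if (normalizationState(table) == "raw")
    table <- totalAreaNormalize(table)
  v <- assay(table, "area")
  inc <- includedBins(table)
  vi <- v[inc, , drop = FALSE]
  if (is.numeric(reference)) {
    if (length(reference) != nrow(v))
      stopf("explicit reference must have one value per bin")
    ref <- reference[inc]
  } else if (identical(reference, "mean")) {
    ref <- rowMeans(vi)
  } else if (identical(reference, "control")) {
    ctrl <- colData(table)$group == controlGroup
    if (sum(ctrl, na.rm = TRUE) < 3)
      stopf("control reference requires >= 3 samples in group '%s'",
            controlGroup)
    ref <- apply(vi[, which(ctrl), drop = FALSE], 1, stats::median)
  } else if (identical(reference, "median")) {
    if (ncol(vi) < 3)
      stopf("median reference requires at least 3 samples")
    ref <- apply(vi, 1, stats::median)
  } else stopf("reference must be 'median', 'mean' or a numeric vector")
  usable <- ref > quotientFloor * max(ref)
  if (sum(usable) < minQuotientBins)
    stopf("only %d usable quotient bins (minimum %d)", sum(usable),
          minQuotientBins)
  quot <- apply(vi[usable, , drop = FALSE] / ref[usable], 2, stats::median)
  assay(table, "area") <- sweep(v, 2, quot, "/")
  const <- if (!is.null(metadata(table)$total_area)) 100 else NA_real_
  totals <- metadata(table)$total_area
  metadata(table)$normalization_state <- "pqn"
  metadata(table)$pqn_quotients <- quot
  metadata(table)$pqn_scale <- if (!is.null(totals))
    totals * quot / 100 else quot
  table
}
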