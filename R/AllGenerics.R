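#' @include AllClasses.R
NULL

#' Accessors for metabodisc objects
#'
#' Small accessor family: bucket values and bin geometry of a
#' \linkS4class{BucketTable}, normalization provenance, PQN quotients and
#' recovered dilution scales, and model components.
#'
#' @param object a metabodisc S4 object.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bucketValues", function(object) standardGeneric("bucketValues"))

#' @describeIn accessors samples x bins matrix of bucket areas
#'   (transpose of the stored assay).
#' @export
setMethod("bucketValues", "BucketTable", function(object)
  t(assay(object, "area")))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @describeIn accessors data.frame of bin edges and centres.
#' @export
setMethod("binEdges", "BucketTable", function(object) {
  rd <- rowData(object)
  data.frame(ppm_lo = rd$ppm_lo, ppm_hi = rd$ppm_hi,
             ppm_center = (rd$ppm_lo + rd$ppm_hi) / 2)
})

#' @rdname accessors
#' @export
setGeneric("includedBins", function(object) standardGeneric("includedBins"))

#' @describeIn accessors logical mask of bins that survive exclusion.
#' @export
setMethod("includedBins", "BucketTable", function(object)
  rowData(object)$included)

#' @rdname accessors
#' @export
setGeneric("includedValues", function(object) standardGeneric("includedValues"))

#' @describeIn accessors samples x bins matrix restricted to included
#'   bins (columns named by bin-centre ppm); the matrix every downstream
#'   statistic operates on.
#' @export
setMethod("includedValues", "BucketTable", function(object) {
  v <- t(assay(object, "area"))
  inc <- rowData(object)$included
  ctr <- (rowData(object)$ppm_lo + rowData(object)$ppm_hi) / 2
  m <- v[, inc, drop = FALSE]
  colnames(m) <- sprintf("%.3f", ctr[inc])
  m
})

#' @rdname accessors
#' @export
setGeneric("normalizationState",
           function(object) standardGeneric("normalizationState"))

#' @describeIn accessors normalization state: raw, total_area or pqn.
#' @export
setMethod("normalizationState", "BucketTable", function(object)
  metadata(object)$normalization_state %||% "raw")

#' @rdname accessors
#' @export
setGeneric("pqnQuotients", function(object) standardGeneric("pqnQuotients"))

#' @describeIn accessors per-sample median quotients stored by PQN.
#' @export
setMethod("pqnQuotients", "BucketTable", function(object)
  metadata(object)$pqn_quotients)

#' @rdname accessors
#' @export
setGeneric("pqnScale", function(object) standardGeneric("pqnScale"))

#' @describeIn accessors per-sample recovered dilution scale
#'   (total-area factor combined with the median quotient); on a
#'   no-effect cohort this tracks the injected dilution factors.
#' @export
setMethod("pqnScale", "BucketTable", function(object)
  metadata(object)$pqn_scale)

#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))

#' @describeIn accessors per-component explained variance fractions.
#' @export
setMethod("explainedVariance", "PCAModel", function(object)
  object@explainedVariance)

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @describeIn accessors PCA scores (samples x components).
#' @export
setMethod("scores", "PCAModel", function(object) object@scores)

#' @describeIn accessors OPLS predictive scores.
#' @export
setMethod("scores", "OPLSModel", function(object) object@predictiveScores)

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))

#' @describeIn accessors PCA loadings (bins x components).
#' @export
setMethod("pcaLoadings", "PCAModel", function(object) object@loadings)

#' @rdname accessors
#' @export
setGeneric("cycleAccuracies",
           function(object) standardGeneric("cycleAccuracies"))

#' @describeIn accessors per-cycle MCCV accuracies.
#' @export
setMethod("cycleAccuracies", "MCCVResult", function(object)
  object@cycleAccuracies)

#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(object) standardGeneric("meanAccuracy"))

#' @describeIn accessors mean of per-cycle MCCV accuracies.
#' @export
setMethod("meanAccuracy", "MCCVResult", function(object)
  object@meanAccuracy)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix",
           function(object) standardGeneric("confusionMatrix"))

#' @describeIn accessors pooled 2x2 confusion matrix (rows = truth).
#' @export
setMethod("confusionMatrix", "MCCVResult", function(object)
  object@confusionMatrix)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "PeakSpec", function(object) {
  cat(sprintf("PeakSpec '%s': %d line(s) at %.3f ppm, FWHM %.2f Hz, area %.4g\n",
              object@metabolite, nrow(object@multiplet), object@centerPpm,
              object@linewidthHz, object@baseAmplitude))
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:", object@sampleMatrix, "/", object@phase, "\n")
  cat("  groups:", paste(sprintf("%s=%d", names(object@groupSizes),
                                 object@groupSizes), collapse = ", "), "\n")
  cat(sprintf("  effect table: %d metabolites; dilution exp[%.3g, %.3g]; CV %.2f\n",
              nrow(object@effectTable), object@dilutionLogRange[1],
              object@dilutionLogRange[2], object@biologicalCv))
  cat(sprintf("  noise sd %.3g; jitter sd %.3g ppm; %d points over [%.2f, %.2f] ppm; seed %d\n",
              object@noiseSd, object@jitterSdPpm, object@nPoints,
              object@ppmRange[1], object@ppmRange[2], object@seed))
})

setMethod("show", "NMRSpectrum", function(object) {
  cat(sprintf("NMRSpectrum '%s': %d points over [%.2f, %.2f] ppm\n",
              object@sampleMeta$sample_id %||% "?", length(object@ppm),
              min(object@ppm), max(object@ppm)))
})

setMethod("show", "NMRFid", function(object) {
  cat(sprintf("NMRFid '%s': %d complex points, dwell %.3g s, %.2f MHz\n",
              object@sampleMeta$sample_id %||% "?", length(object@signal),
              object@dwellTime, object@spectrometerFreq))
})

setMethod("show", "NMRCohort", function(object) {
  tab <- table(object@sampleMeta$group)
  cat(sprintf("NMRCohort: %d samples (%s), %s/%s\n",
              length(object@spectra),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              object@design@sampleMatrix, object@design@phase))
})

setMethod("show", "BucketTable", function(object) {
  cat(sprintf("BucketTable: %d bins x %d samples (%d included), state '%s'\n",
              nrow(object), ncol(object), sum(includedBins(object)),
              normalizationState(object)))
})

setMethod("show", "PCAModel", function(object) {
  ev <- object@explainedVariance
  cat(sprintf("PCAModel: %d components; explained variance %s\n",
              ncol(object@loadings),
              paste(sprintf("%.1f%%", 100 * utils::head(ev, 3)),
                    collapse = ", ")))
})

setMethod("show", "OPLSModel", function(object) {
  cat(sprintf("OPLSModel: 1 predictive + %d orthogonal component(s); classes %s -> %+d/%+d\n",
              object@nOrth, paste(names(object@classCoding), collapse = " vs "),
              object@classCoding[1], object@classCoding[2]))
})

setMethod("show", "MCCVResult", function(object) {
  cat(sprintf("MCCVResult: %d cycles (train fraction %.2f), mean accuracy %.3f (pooled %.3f)\n",
              object@nCycles, object@trainFraction, object@meanAccuracy,
              object@pooledAccuracy))
  print(object@confusionMatrix)
})
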