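# Shared fixtures. Expensive full-size cohorts are built lazily and
# cached for the session so several test files can reuse them.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

## small, fast design for unit-level checks
tinyDesign <- function(matrix = "serum", phase = "water", seed = 7,
                       groupSizes = c(healthy = 4L, LDA = 4L, RDA = 2L),
                       nPoints = 8192L, ...) {
  cohortDesign(matrix, phase, groupSizes = groupSizes,
               nPoints = nPoints, seed = seed, ...)
}

## full study-condition cohort, processed to the normalized bucket table
processedCohort <- function(matrix, phase, seed) {
  key <- sprintf("cohort_%s_%s_%d", matrix, phase, seed)
  cached(key, {
    design <- cohortDesign(matrix, phase, seed = seed)
    coh <- makeCohort(design)
    ref <- metabodisc:::.calibrationReference(matrix, phase)
    spectra <- lapply(coh@spectra, function(s)
      calibrateSpectrum(s, ref$name, ref$ppm))
    bt <- pqnNormalize(excludeRegions(buildBucketTable(spectra,
                                                       coh@sampleMeta)))
    list(cohort = coh, table = bt,
         X = includedValues(bt),
         groups = as.character(SummarizedExperiment::colData(bt)$group))
  })
}

## two-bin toy bucket table from a samples x bins value matrix
toyBucketTable <- function(values, included = rep(TRUE, ncol(values)),
                           group = NULL) {
  nb <- ncol(values)
  edges <- 1 + 0.02 * (0:nb)
  ids <- sprintf("S%02d", seq_len(nrow(values)))
  cd <- S4Vectors::DataFrame(sample_id = ids)
  if (!is.null(group)) cd$group <- group
  a <- t(values)
  colnames(a) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(area = a),
    rowData = S4Vectors::DataFrame(ppm_lo = edges[-(nb + 1)],
                                   ppm_hi = edges[-1],
                                   included = included),
    colData = cd)
  S4Vectors::metadata(se)$normalization_state <- "raw"
  S4Vectors::metadata(se)$excluded_regions <- list()
  new("BucketTable", se)
}
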