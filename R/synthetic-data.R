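#' Construct a cohort design
#'
#' Builds a validated \linkS4class{CohortDesign}. Defaults reproduce the
#' study conditions: 20 healthy / 42 LDA / 8 RDA animals, fold-changes
#' from the packaged effect table of the chosen matrix/phase, per-sample
#' log-uniform dilution factors in [0.5, 2], lognormal biological
#' variation with CV 0.25, 0.004 ppm peak-position jitter and additive
#' Gaussian intensity noise.
#'
#' @param matrix sample matrix: "serum", "liver" or "urine".
#' @param phase extraction phase: "water" or "lipid".
#' @param groupSizes named vector of cohort sizes (healthy, LDA, RDA),
#'   each >= 2.
#' @param effectTable data.frame of per-group fold-changes (columns
#'   metabolite, healthy, LDA, RDA); defaults to
#'   \code{\link{defaultEffectTable}}.
#' @param dilutionRange length-2 positive bounds of the per-sample
#'   log-uniform dilution factor.
#' @param noiseSd additive Gaussian intensity noise sd (arbitrary units).
#' @param jitterSdPpm per-sample, per-peak sd of random centre shifts (ppm).
#' @param biologicalCv lognormal per-sample per-metabolite coefficient of
#'   variation.
#' @param seed integer random seed.
#' @param nPoints spectral grid size (>= 1024 for FID generation).
#' @param ppmRange length-2 axis bounds; must span 0.2-10.0 ppm.
#' @return A \linkS4class{CohortDesign}.
#' @examples
#' design <- cohortDesign("serum", "water", seed = 1)
#' design
#' @export
cohortDesign <- function(matrix, phase,
                         groupSizes = c(healthy = 20L, LDA = 42L, RDA = 8L),
                         effectTable = defaultEffectTable(matrix, phase),
                         dilutionRange = c(0.5, 2),
                         noiseSd = 0.5,
                         jitterSdPpm = 0.004,
                         biologicalCv = 0.25,
                         seed = 1L,
                         nPoints = 16384L,
                         ppmRange = c(-0.5, 10.5)) {
  if (any(dilutionRange <= 0)) stopf("dilutionRange must be positive")
  new("CohortDesign",
      groupSizes = structure(as.integer(groupSizes), names = names(groupSizes)),
      sampleMatrix = checkVocab(matrix, .MATRICES, "matrix"),
      phase = checkVocab(phase, .PHASES, "phase"),
      effectTable = effectTable,
      dilutionLogRange = log(sort(dilutionRange)),
      noiseSd = noiseSd, jitterSdPpm = jitterSdPpm,
      biologicalCv = biologicalCv, seed = as.integer(seed),
      nPoints = as.integer(nPoints), ppmRange = as.numeric(ppmRange))
}

## flatten a list of PeakSpec into one line table (one row per
## Lorentzian line), optionally with a per-peak centre jitter
.lineTable <- function(peaks, jitterPpm = NULL) {
  stopifnot(length(peaks) > 0)
  if (is.null(jitterPpm)) jitterPpm <- numeric(length(peaks))
  do.call(rbind, lapply(seq_along(peaks), function(i) {
    p <- peaks[[i]]
    rel <- p@multiplet[, "rel"] / sum(p@multiplet[, "rel"])
    data.frame(metabolite = p@metabolite,
               ppm = p@centerPpm + jitterPpm[i] + p@multiplet[, "offset"],
               lw = p@linewidthHz,
               area = p@baseAmplitude * rel)
  }))
}

#' Simulate a free induction decay
#'
#' Sum of complex exponentials, one per multiplet line: each line at
#' chemical shift delta contributes
#' \code{area * exp(2i * pi * f * t - pi * lw * t)} with offset frequency
#' \code{f = (delta - carrier) * spectrometerFreq}, so the transformed
#' line is a Lorentzian of FWHM \code{lw} Hz. The FID magnitude at t = 0
#' therefore equals the summed line areas. Deterministic given
#' \code{jitterPpm}.
#'
#' @param peaks list of \linkS4class{PeakSpec}.
#' @param design a \linkS4class{CohortDesign} supplying the grid
#'   (nPoints, ppmRange) and spectrometer frequency context.
#' @param sampleScale positive per-sample scale multiplying all areas.
#' @param jitterPpm per-peak centre shifts (ppm); default none.
#' @param amplitudeScale optional named per-metabolite multipliers
#'   (fold-change x biological factor); default 1.
#' @param sampleMeta named list of sample metadata to carry along.
#' @param spectrometerFreq spectrometer frequency in MHz.
#' @return An \linkS4class{NMRFid}.
#' @examples
#' d <- cohortDesign("serum", "water", nPoints = 2048)
#' fid <- makeFid(list(peakSpec("x", 5, 1, 10)), d)
#' Mod(fid@signal[1])  # == 10
#' @export
makeFid <- function(peaks, design, sampleScale = 1, jitterPpm = NULL,
                    amplitudeScale = NULL, sampleMeta = list(),
                    spectrometerFreq = 600.13) {
  if (length(peaks) == 0) stopf("peaks must be non-empty")
  if (design@nPoints < 1024) stopf("nPoints must be >= 1024 for FID simulation")
  lines <- .lineTable(peaks, jitterPpm)
  out <- lines$ppm < design@ppmRange[1] | lines$ppm > design@ppmRange[2]
  if (any(out))
    stopf("peak(s) outside ppm range [%.2f, %.2f]: %s",
          design@ppmRange[1], design@ppmRange[2],
          paste(unique(lines$metabolite[out]), collapse = ", "))
  if (!is.null(amplitudeScale)) {
    m <- amplitudeScale[lines$metabolite]
    m[is.na(m)] <- 1
    lines$area <- lines$area * m
  }
  lines$area <- lines$area * sampleScale
  carrier <- mean(design@ppmRange)
  sw <- diff(design@ppmRange) * spectrometerFreq
  dwell <- 1 / sw
  tt <- (seq_len(design@nPoints) - 1) * dwell
  sig <- complex(design@nPoints)
  for (i in seq_len(nrow(lines))) {
    f <- (lines$ppm[i] - carrier) * spectrometerFreq
    sig <- sig + lines$area[i] *
      exp((2i * pi * f - pi * lines$lw[i]) * tt)
  }
  new("NMRFid", signal = sig, dwellTime = dwell,
      spectrometerFreq = spectrometerFreq, carrierPpm = carrier,
      sampleMeta = sampleMeta)
}

## analytic absorption-mode Lorentzian evaluation on a ppm grid;
## matches the Fourier transform of the FID path (peak area in the
## frequency domain is area/2, the one-sided transform convention)
.directSpectrum <- function(lines, ppm, spectrometerFreq = 600.13) {
  nu <- ppm * spectrometerFreq
  intensity <- numeric(length(nu))
  for (i in seq_len(nrow(lines))) {
    gam <- lines$lw[i] / 2
    d <- nu - lines$ppm[i] * spectrometerFreq
    intensity <- intensity + (lines$area[i] / (2 * pi)) * gam / (gam^2 + d^2)
  }
  intensity
}

#' Generate a seeded synthetic cohort
#'
#' One sample per animal: per-metabolite amplitudes are
#' base x group fold-change x lognormal biological factor x dilution
#' factor, peak centres receive per-sample per-peak jitter, and additive
#' Gaussian noise is applied to the frequency-domain intensities. Fully
#' reproducible from the design seed; two calls with equal designs give
#' bitwise-identical cohorts.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param peaks peak library; defaults to
#'   \code{\link{defaultPeakLibrary}} for the design's matrix/phase.
#' @param output "spectrum" (default fast path: analytic Lorentzian
#'   evaluation plus noise) or "fid" (time-domain signals, noiseless, to
#'   exercise apodization and transform).
#' @return An \linkS4class{NMRCohort}; its truth record lists, for every
#'   effect-table metabolite and pairwise comparison, the injected fold
#'   ratio and whether the metabolite truly differs (fold ratio at least
#'   2 in either direction).
#' @examples
#' d <- cohortDesign("serum", "water", groupSizes = c(healthy = 3, LDA = 3, RDA = 2),
#'                   nPoints = 4096, seed = 7)
#' coh <- makeCohort(d)
#' coh
#' @export
makeCohort <- function(design, peaks = NULL, output = c("spectrum", "fid")) {
  output <- match.arg(output)
  validObject(design)
  if (is.null(peaks))
    peaks <- defaultPeakLibrary(design@sampleMatrix, design@phase)
  peakMetab <- vapply(peaks, function(p) p@metabolite, character(1))
  missing <- setdiff(design@effectTable$metabolite, peakMetab)
  if (length(missing))
    stopf("effect table references metabolite(s) with no PeakSpec: %s",
          paste(missing, collapse = ", "))

  groups <- rep(names(design@groupSizes), design@groupSizes)
  n <- length(groups)
  ids <- sprintf("S%03d_%s", seq_len(n), groups)
  pulse <- if (design@sampleMatrix == "serum" && design@phase == "water")
    "CPMG" else "NOESY"
  meta <- S4Vectors::DataFrame(sample_id = ids, group = groups,
                               matrix = design@sampleMatrix,
                               phase = design@phase, pulse_program = pulse)

  et <- design@effectTable
  foldOf <- function(group) {
    f <- et[[group]][match(peakMetab, et$metabolite)]
    f[is.na(f)] <- 1  # peaks outside the effect table (background, refs)
    structure(f, names = peakMetab)
  }
  sigmaLog <- sqrt(log(1 + design@biologicalCv^2))
  metabNames <- unique(peakMetab)
  ppmGrid <- seq(design@ppmRange[1], design@ppmRange[2],
                 length.out = design@nPoints)

  spectra <- vector("list", n)
  dilution <- numeric(n)
  withLocalSeed(design@seed, {
    dilution <- exp(stats::runif(n, design@dilutionLogRange[1],
                                 design@dilutionLogRange[2]))
    for (s in seq_len(n)) {
      ## draw unit-scale deviates and scale afterwards, so the random
      ## stream stays aligned across designs differing only in noise,
      ## jitter or CV levels (enables paired jitter-on/off comparisons)
      biol <- structure(
        exp(stats::rnorm(length(metabNames)) * sigmaLog - sigmaLog^2 / 2),
        names = metabNames)
      jit <- stats::rnorm(length(peaks)) * design@jitterSdPpm
      noise <- stats::rnorm(design@nPoints) * design@noiseSd
      scalePer <- foldOf(groups[s]) * biol[peakMetab]
      names(scalePer) <- peakMetab
      sm <- as.list(meta[s, , drop = FALSE])
      if (output == "fid") {
        ## amplitudeScale is keyed by metabolite name so multiplets of
        ## one metabolite share their biological factor
        spectra[[s]] <- makeFid(peaks, design, sampleScale = dilution[s],
                                jitterPpm = jit, amplitudeScale = scalePer,
                                sampleMeta = sm)
      } else {
        lines <- .lineTable(peaks, jit)
        lines$area <- lines$area * scalePer[lines$metabolite] * dilution[s]
        spectra[[s]] <- nmrSpectrum(ppmGrid,
                                    .directSpectrum(lines, ppmGrid) + noise,
                                    sampleMeta = sm)
      }
    }
  })

  truth <- .truthRecord(et)
  new("NMRCohort", spectra = spectra, sampleMeta = meta,
      dilution = dilution, truth = truth, design = design)
}

.DEFAULT_COMPARISONS <- list(c("healthy", "LDA"), c("healthy", "RDA"),
                             c("LDA", "RDA"))

.truthRecord <- function(effectTable, log2Threshold = 1) {
  rows <- lapply(.DEFAULT_COMPARISONS, function(cmp) {
    ratio <- effectTable[[cmp[2]]] / effectTable[[cmp[1]]]
    data.frame(metabolite = effectTable$metabolite,
               comparison = paste(cmp, collapse = "-vs-"),
               true_fold_change = ratio,
               is_differential = abs(log2(ratio)) >= log2Threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
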