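test_that("apodization preserves the included-region integral and linearity", {
  d <- tinyDesign(noiseSd = 0)
  fid <- makeFid(list(peakSpec("a", 3, 1.5, 50),
                      peakSpec("b", 8, 2, 20)), d)
  s0 <- apodizeTransform(fid, 0)
  s3 <- apodizeTransform(fid, 0.3)
  # peak lands at its shift within one grid step
  step <- diff(s0@ppm[1:2])
  expect_lt(abs(s0@ppm[which.max(s0@intensity)] - 3), step + 1e-12)
  # 0.3 Hz broadening redistributes but conserves area within 1 percent
  i0 <- sum(bucketSpectrum(s0)$values)
  i3 <- sum(bucketSpectrum(s3)$values)
  expect_lt(abs(i3 - i0) / i0, 0.01)
  # doubling the FID doubles the spectrum
  fid2 <- fid; fid2@signal <- 2 * fid@signal
  expect_equal(apodizeTransform(fid2, 0.3)@intensity,
               2 * s3@intensity, tolerance = 1e-12)
  expect_error(apodizeTransform(fid, -1), ">= 0")
})

test_that("calibration restores a known injected offset and errors sensibly", {
  d <- tinyDesign(noiseSd = 0)
  peaks <- list(peakSpec("glucose", 5.24, 1.5, 100),
                peakSpec("other", 2.0, 1.5, 80))
  mkSpec <- function(offset) {
    lines <- metabodisc:::.lineTable(peaks)
    lines$ppm <- lines$ppm + offset
    ppm <- seq(d@ppmRange[1], d@ppmRange[2], length.out = d@nPoints)
    nmrSpectrum(ppm, metabodisc:::.directSpectrum(lines, ppm))
  }
  step <- diff(seq(d@ppmRange[1], d@ppmRange[2],
                   length.out = d@nPoints)[1:2])
  aligned <- mkSpec(0)
  cal0 <- calibrateSpectrum(aligned, "glucose", 5.24)
  expect_lt(max(abs(cal0@ppm - aligned@ppm)), step + 1e-12)
  shifted <- mkSpec(0.01)
  cal <- calibrateSpectrum(shifted, "glucose", 5.24)
  for (target in c(5.24, 2.0)) {
    win <- abs(cal@ppm - target) < 0.05
    expect_lt(abs(cal@ppm[win][which.max(cal@intensity[win])] - target),
              step + 1e-12)
  }
  # intensities never touched
  expect_identical(cal@intensity, shifted@intensity)
  # reference far outside the window -> no prominent peak -> error
  expect_error(calibrateSpectrum(mkSpec(0), "glucose", 9.5),
               "uncalibratable")
})

test_that("bucketing arithmetic matches its definitions", {
  grid <- seq(0, 10.4, by = 0.001)
  const <- nmrSpectrum(grid, rep(3, length(grid)))
  b <- bucketSpectrum(const)
  expect_length(b$values, 490)
  expect_equal(b$edges[1], 0.2)
  expect_equal(b$edges[491], 10.0)
  expect_equal(b$values, rep(3 * 0.02, 490), tolerance = 1e-12)
  expect_equal(sum(b$values), 3 * 9.8, tolerance = 1e-12)
  # narrow peak: bin sum equals the direct trapezoidal integral
  y <- 5 / (1 + ((grid - 4.317) / 0.002)^2)
  sp <- nmrSpectrum(grid, y)
  bs <- bucketSpectrum(sp)
  inRange <- grid >= 0.2 & grid <= 10
  expect_equal(sum(bs$values), oracleTrapz(grid[inRange], y[inRange]),
               tolerance = 1e-9)
  # misaligned grid (prime spacing) still conserves the integral
  grid2 <- seq(0.1, 10.3, by = 0.0013)
  y2 <- 2 + sin(grid2)
  b2 <- bucketSpectrum(nmrSpectrum(grid2, y2))
  in2 <- grid2 >= 0.2 & grid2 <= 10
  ref <- oracleTrapz(c(0.2, grid2[in2], 10),
                     c(approx(grid2, y2, 0.2)$y, y2[in2],
                       approx(grid2, y2, 10)$y))
  expect_equal(sum(b2$values), ref, tolerance = 1e-9)
  expect_error(bucketSpectrum(const, binWidth = 0.03), "divide")
  expect_error(bucketSpectrum(nmrSpectrum(seq(1, 5, 0.01), rep(1, 401))),
               "cover")
})

test_that("exclusion masks exactly the overlapping bins", {
  grid <- seq(0, 10.4, by = 0.002)
  spectra <- list(nmrSpectrum(grid, rep(1, length(grid))))
  bt <- buildBucketTable(spectra)
  # water region: 13 bins starting 4.60 .. 4.84
  btw <- excludeRegions(bt, list(c(4.60, 4.85)))
  masked <- binEdges(btw)$ppm_lo[!includedBins(btw)]
  expect_length(masked, 13)
  expect_equal(range(masked), c(4.60, 4.84), tolerance = 1e-9)
  # lipid region: 33 bins
  btl <- excludeRegions(bt, list(c(6.90, 7.55)))
  expect_equal(sum(!includedBins(btl)), 33)
  # enumeration oracle over arbitrary regions
  set.seed(42)
  for (r in 1:20) {
    lo <- runif(1, 0.3, 9); hi <- lo + runif(1, 0.01, 0.8)
    bte <- excludeRegions(bt, list(c(lo, hi)))
    ed <- binEdges(bt)
    oracle <- ed$ppm_lo < hi - 1e-8 & ed$ppm_hi > lo + 1e-8
    expect_equal(!includedBins(bte), oracle)
  }
  # identity and error cases
  expect_identical(includedBins(excludeRegions(bt, list())),
                   includedBins(bt))
  expect_error(excludeRegions(bt, list(c(5, 4))), "inverted")
})

test_that("total-area normalization matches hand arithmetic and is scale invariant", {
  tab <- toyBucketTable(rbind(c(1, 1), c(3, 1)))
  norm <- totalAreaNormalize(tab)
  expect_equal(unname(bucketValues(norm)), rbind(c(50, 50), c(75, 25)))
  expect_equal(unname(rowSums(bucketValues(norm))), c(100, 100))
  # scaling a sample leaves its normalized row unchanged
  tab3 <- toyBucketTable(rbind(c(3, 3), c(3, 1)))
  expect_equal(bucketValues(totalAreaNormalize(tab3))[1, ],
               bucketValues(norm)[1, ])
  expect_error(totalAreaNormalize(toyBucketTable(rbind(c(0, 0), c(1, 1)))),
               "S01")
})

test_that("PQN recovers pure dilution and is invariant to per-sample scaling", {
  base <- c(4, 2, 6, 1, 3, 5, 2, 7)
  vals <- rbind(base, 2 * base, 0.5 * base, base * 1.0)
  tab <- toyBucketTable(vals)
  norm <- pqnNormalize(tab, minQuotientBins = 3)
  # all rows collapse to the common profile
  for (i in 2:4)
    expect_equal(bucketValues(norm)[i, ], bucketValues(norm)[1, ],
                 tolerance = 1e-12)
  expect_equal(normalizationState(norm), "pqn")
  # sample identical to the reference has median quotient 1
  expect_equal(unname(pqnQuotients(norm)[1]), 1, tolerance = 1e-12)
  # recovered dilution scale proportional to the injected factors
  sc <- pqnScale(norm)
  expect_equal(unname(sc / sc[1]), c(1, 2, 0.5, 1), tolerance = 1e-12)
  expect_error(pqnNormalize(toyBucketTable(vals[1:2, ]),
                            minQuotientBins = 3),
               "3 samples")
})

test_that("the processing pipeline is invariant to raw per-sample scale", {
  coh <- makeCohort(tinyDesign(noiseSd = 0))
  bt <- excludeRegions(buildBucketTable(coh))
  v <- t(SummarizedExperiment::assay(bt, "area"))
  scaled <- bt
  SummarizedExperiment::assay(scaled, "area") <-
    t(v * rep(c(1, 17.3), length.out = nrow(v)))
  n1 <- bucketValues(pqnNormalize(bt))
  n2 <- bucketValues(pqnNormalize(scaled))
  expect_equal(n2, n1, tolerance = 1e-12)
})

test_that("excluded bins are inert in every downstream statistic", {
  coh <- makeCohort(tinyDesign())
  bt <- excludeRegions(buildBucketTable(coh))
  poisoned <- bt
  v <- SummarizedExperiment::assay(poisoned, "area")
  v[!includedBins(poisoned), ] <- 1e6
  SummarizedExperiment::assay(poisoned, "area") <- v
  inc <- includedBins(bt)
  n1 <- pqnNormalize(bt); n2 <- pqnNormalize(poisoned)
  expect_equal(bucketValues(n2)[, inc], bucketValues(n1)[, inc])
  expect_identical(includedValues(n1), includedValues(n2))
  asn <- defaultAssignments("serum", "water")
  expect_equal(integrateRegions(n2, asn), integrateRegions(n1, asn))
})

test_that("0.02 ppm buckets absorb 0.004 ppm peak jitter", {
  ## full default grid resolution: 1.5 Hz lines need ~0.4 Hz/point
  dj <- cohortDesign("serum", "water",
                     groupSizes = c(healthy = 5, LDA = 5, RDA = 2),
                     noiseSd = 0, seed = 9)
  d0 <- cohortDesign("serum", "water",
                     groupSizes = c(healthy = 5, LDA = 5, RDA = 2),
                     noiseSd = 0, jitterSdPpm = 0, seed = 9)
  asn <- defaultAssignments("serum", "water")
  cj <- integrateRegions(buildBucketTable(makeCohort(dj)), asn)
  c0 <- integrateRegions(buildBucketTable(makeCohort(d0)), asn)
  expect_lt(mean(abs(cj - c0) / c0), 0.05)
})
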