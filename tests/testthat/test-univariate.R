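test_that("region integration sums bins with overlap-fraction weighting", {
  # 4 bins of width 0.02 at [1.00, 1.08), one sample with value 2 each
  tab <- toyBucketTable(matrix(2, 1, 4))
  a <- data.frame(metabolite = "m", ppm_lo = 1.00, ppm_hi = 1.06)
  expect_equal(unname(integrateRegions(tab, a)[1, "m"]), 6)
  # half a bin of value 4 contributes 2
  tab4 <- toyBucketTable(matrix(4, 1, 4))
  ah <- data.frame(metabolite = "m", ppm_lo = 1.02, ppm_hi = 1.03)
  expect_equal(unname(integrateRegions(tab4, ah)[1, "m"]), 2)
  # multiple regions per metabolite add up; overlap within one errors
  a2 <- data.frame(metabolite = c("m", "m"),
                   ppm_lo = c(1.00, 1.04), ppm_hi = c(1.02, 1.06))
  expect_equal(unname(integrateRegions(tab, a2)[1, "m"]), 4)
  aBad <- data.frame(metabolite = c("m", "m"),
                     ppm_lo = c(1.00, 1.01), ppm_hi = c(1.03, 1.05))
  expect_error(integrateRegions(tab, aBad), "overlapping")
  # region entirely inside excluded bins errors with the name
  tabX <- toyBucketTable(matrix(2, 1, 4),
                         included = c(FALSE, FALSE, TRUE, TRUE))
  aX <- data.frame(metabolite = "ghost", ppm_lo = 1.00, ppm_hi = 1.04)
  expect_error(integrateRegions(tabX, aX), "ghost")
})

test_that("medianMad matches hand enumeration and its invariances", {
  expect_equal(medianMad(c(1, 2, 3, 4, 100)),
               c(median = 3, mad = 1))
  expect_equal(medianMad(rep(7, 5)), c(median = 7, mad = 0))
  expect_equal(medianMad(42), c(median = 42, mad = 0))
  expect_error(medianMad(numeric(0)), "at least one")
  set.seed(41)
  for (r in 1:20) {
    x <- rnorm(sample(3:15, 1))
    cc <- runif(1, 0.1, 10)
    expect_equal(medianMad(sample(x)), medianMad(x))
    expect_equal(medianMad(cc * x), cc * medianMad(x))
  }
})

test_that("exact rank test agrees with full enumeration for n1+n2 <= 10", {
  expect_equal(unname(rankTest(c(1, 2, 3), c(4, 5, 6))["p.value"]), 0.1,
               tolerance = 1e-12)
  set.seed(43)
  for (r in 1:40) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:(10 - n1), 1)
    x <- sample(seq_len(100), n1 + n2)  # untied by construction
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    expect_equal(unname(rankTest(a, b, mode = "exact")["p.value"]),
                 oracleWilcoxExact(a, b), tolerance = 1e-10,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("rank test handles degeneracy, ties and the paired variant", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(unname(rankTest(x, x)["p.value"]), 1)
  expect_warning(p <- rankTest(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(unname(p["p.value"]), 1)
  # the continuity-corrected normal approximation tracks the exact
  # distribution at 8 vs 8 without ties (worst-case gap ~0.013 near
  # the centre of the W distribution)
  set.seed(44)
  for (r in 1:15) {
    x <- sample(seq_len(200), 16)
    a <- x[1:8]; b <- x[9:16]
    pe <- rankTest(a, b, mode = "exact")["p.value"]
    pa <- rankTest(a, b, mode = "approx")["p.value"]
    expect_lt(abs(pe - pa), 0.02)
  }
  # auto: exact for small untied samples, approx in presence of ties
  expect_error(rankTest(c(1, 1, 2), c(1, 3, 4), mode = "exact"), "ties")
  expect_silent(rankTest(c(1, 1, 2), c(1, 3, 4), mode = "auto"))
  # paired signed-rank variant runs and detects a constant shift
  set.seed(45)
  before <- rnorm(12); after <- before + 1
  expect_lt(rankTest(after, before, mode = "paired")["p.value"], 0.01)
})

test_that("rank test holds its nominal type-I error level", {
  set.seed(46)
  rej <- mean(replicate(1000, {
    rankTest(rnorm(30), rnorm(30))["p.value"] < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("BH adjustment matches step-up arithmetic and is order invariant", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
  set.seed(47)
  p <- runif(25)^2
  perm <- sample(25)
  adj <- bhAdjust(p)
  adjPerm <- bhAdjust(p[perm])
  expect_equal(adjPerm[order(perm)], adj)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("group comparison emits the fixed comparison order with coherent columns", {
  set.seed(48)
  conc <- matrix(rlnorm(24 * 5), 24, 5,
                 dimnames = list(NULL, paste0("m", 1:5)))
  meta <- data.frame(group = rep(c("healthy", "LDA", "RDA"), c(10, 10, 4)))
  tab <- compareGroups(conc, meta)
  pcols <- grep("^p_", colnames(tab), value = TRUE)
  expect_equal(pcols, c("p_healthy_vs_LDA", "p_healthy_vs_RDA",
                        "p_LDA_vs_RDA"))
  for (tag in sub("^p_", "", pcols)) {
    expect_true(all(tab[[paste0("padj_", tag)]] >=
                    tab[[paste0("p_", tag)]] - 1e-12))
    expect_identical(tab[[paste0("sig_", tag)]],
                     tab[[paste0("padj_", tag)]] < 0.05)
  }
  # a too-small group is skipped with a warning, not an error (both
  # RDA comparisons are skipped, so two warnings arrive)
  meta2 <- data.frame(group = rep(c("healthy", "LDA", "RDA"), c(12, 11, 1)))
  warns <- capture_warnings(tab2 <- compareGroups(conc, meta2))
  expect_length(warns, 2)
  expect_match(warns, "skipped", all = TRUE)
  expect_false("p_healthy_vs_RDA" %in% colnames(tab2))
  expect_error(compareGroups(conc, meta,
                             comparisons = list(c("healthy", "cured"))),
               "cured")
})

test_that("integration recovers an injected single-metabolite fold within its error budget", {
  ## single-effect cohort: only hippurate reduced; PQN's dilution-only
  ## assumption holds, so the residual error is quantifier-window
  ## cross-talk (about 2 percent of the healthy window, amplified ~6.5x
  ## by the 7.5-fold down-change) plus median sampling noise
  et <- defaultEffectTable("serum", "water")
  et$LDA[] <- 1; et$RDA[] <- 1
  et$LDA[et$metabolite == "hippurate"] <- 58.2 / 437.2
  d <- cohortDesign("serum", "water", effectTable = et, seed = 4)
  coh <- makeCohort(d)
  ref <- metabodisc:::.calibrationReference("serum", "water")
  sp <- lapply(coh@spectra, function(s)
    calibrateSpectrum(s, ref$name, ref$ppm))
  bt <- pqnNormalize(excludeRegions(buildBucketTable(sp, coh@sampleMeta)))
  conc <- integrateRegions(bt, defaultAssignments("serum", "water"))
  g <- as.character(SummarizedExperiment::colData(bt)$group)
  fold <- median(conc[g == "LDA", "hippurate"]) /
    median(conc[g == "healthy", "hippurate"])
  expect_lt(abs(fold - 58.2 / 437.2) / (58.2 / 437.2), 0.25)
})
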