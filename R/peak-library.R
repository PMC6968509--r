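## Packaged resonance libraries and effect tables for the six sample
## matrices (serum/liver/urine x water/lipid extracts).
##
## Group medians (arbitrary units, healthy/LDA/RDA) come from the
## published metabolite concentration table of the displaced-abomasum
## study; chemical shifts and multiplet shapes are literature stand-ins
## (the study did not report its integration regions), chosen so each
## metabolite has a reasonably clean quantifier multiplet. Multiplet
## "share" is the fraction of the metabolite's total area carried by
## that multiplet; "quant" marks the quantifier whose [qlo, qhi) window
## becomes the packaged assignment region.

## multiplet shape codes -> (ppm offsets, relative intensities)
.multShape <- function(code) {
  switch(code,
    s = list(off = 0, rel = 1),
    d = list(off = c(-0.006, 0.006), rel = c(1, 1)),
    t = list(off = c(-0.012, 0, 0.012), rel = c(1, 2, 1)),
    q = list(off = c(-0.018, -0.006, 0.006, 0.018), rel = c(1, 3, 3, 1)),
    dd = list(off = c(-0.064, -0.056, 0.056, 0.064), rel = c(1, 1, 1, 1)),
    stopf("unknown multiplet code '%s'", code))
}

.mrow <- function(metabolite, healthy, LDA, RDA, center, lw, mult, share,
                  quant, qlo = NA_real_, qhi = NA_real_) {
  data.frame(metabolite = metabolite, healthy = healthy, LDA = LDA, RDA = RDA,
             center = center, lw = lw, mult = mult, share = share,
             quant = quant, qlo = qlo, qhi = qhi,
             stringsAsFactors = FALSE)
}

.libSerumWater <- function() rbind(
  .mrow("2-hydroxybutyrate",    3.2,    201.2,  311.4, 0.90, 1.5, "t", 0.60, TRUE, 0.88, 0.92),
  .mrow("2-hydroxybutyrate",    3.2,    201.2,  311.4, 3.75, 1.5, "s", 0.40, FALSE),
  .mrow("isoleucine",         675.8,    352.1,  150.2, 0.94, 1.5, "t", 0.50, TRUE, 0.92, 0.96),
  .mrow("isoleucine",         675.8,    352.1,  150.2, 1.00, 1.5, "d", 0.50, FALSE),
  .mrow("valine",            1037.2,    798.0,  360.8, 1.04, 1.5, "d", 0.55, TRUE, 1.02, 1.06),
  .mrow("valine",            1037.2,    798.0,  360.8, 0.99, 1.5, "d", 0.45, FALSE),
  .mrow("3-hydroxybutyrate", 4896.0,   8454.3, 3221.2, 1.20, 1.5, "d", 0.55, TRUE, 1.18, 1.22),
  .mrow("3-hydroxybutyrate", 4896.0,   8454.3, 3221.2, 2.31, 1.5, "d", 0.20, FALSE),
  .mrow("3-hydroxybutyrate", 4896.0,   8454.3, 3221.2, 4.13, 1.5, "s", 0.25, FALSE),
  .mrow("lactate",           2240.6,   3023.0, 3024.6, 1.33, 1.5, "d", 0.75, TRUE, 1.31, 1.35),
  .mrow("lactate",           2240.6,   3023.0, 3024.6, 4.11, 1.5, "q", 0.25, FALSE),
  .mrow("alanine",           1603.0,   1082.9,  800.8, 1.48, 1.5, "d", 1.00, TRUE, 1.46, 1.50),
  .mrow("acetate",          15866.6,     0.01,   0.01, 1.92, 1.5, "s", 1.00, TRUE, 1.90, 1.94),
  .mrow("citrate",           2814.4,    698.6,  907.5, 2.60, 1.5, "dd", 1.00, TRUE, 2.50, 2.70),
  .mrow("creatine",          2285.0,   1788.7, 1518.3, 3.04, 1.5, "s", 0.60, TRUE, 3.02, 3.06),
  .mrow("creatine",          2285.0,   1788.7, 1518.3, 3.93, 1.5, "s", 0.40, FALSE),
  .mrow("dimethyl-sulfone",   661.9,    179.7,  136.3, 3.15, 1.5, "s", 1.00, TRUE, 3.13, 3.17),
  .mrow("trimethylamine-N-oxide", 4120.1, 1263.6, 1535.7, 3.27, 1.5, "s", 1.00, TRUE, 3.25, 3.29),
  .mrow("glycine",           2180.8,   1270.3,  184.8, 3.56, 1.5, "s", 1.00, TRUE, 3.54, 3.58),
  .mrow("glucose",           1233.0,   1105.7, 1434.0, 5.24, 1.5, "d", 0.35, TRUE, 5.22, 5.26),
  .mrow("glucose",           1233.0,   1105.7, 1434.0, 3.47, 1.5, "s", 0.65, FALSE),
  .mrow("tyrosine",           210.2,     79.7,   65.7, 6.90, 1.5, "d", 0.50, TRUE, 6.88, 6.92),
  .mrow("tyrosine",           210.2,     79.7,   65.7, 7.19, 1.5, "d", 0.50, FALSE),
  .mrow("hippurate",          437.2,     58.2,   54.0, 7.83, 1.5, "d", 0.35, TRUE, 7.81, 7.85),
  .mrow("hippurate",          437.2,     58.2,   54.0, 7.64, 1.5, "t", 0.18, FALSE),
  .mrow("hippurate",          437.2,     58.2,   54.0, 7.55, 1.5, "t", 0.22, FALSE),
  .mrow("hippurate",          437.2,     58.2,   54.0, 4.00, 1.5, "d", 0.25, FALSE),
  .mrow("formate",            650.8,    509.9,  564.1, 8.46, 1.5, "s", 1.00, TRUE, 8.44, 8.48)
)

.libUrineWater <- function() rbind(
  .mrow("3-hydroxybutyrate", 2057.4,   3756.0, 1168.0, 1.20, 1.5, "d", 0.55, TRUE, 1.18, 1.22),
  .mrow("3-hydroxybutyrate", 2057.4,   3756.0, 1168.0, 2.31, 1.5, "d", 0.20, FALSE),
  .mrow("3-hydroxybutyrate", 2057.4,   3756.0, 1168.0, 4.13, 1.5, "s", 0.25, FALSE),
  .mrow("lactate",           1473.5,   5027.5,  360.1, 1.33, 1.5, "d", 0.75, TRUE, 1.31, 1.35),
  .mrow("lactate",           1473.5,   5027.5,  360.1, 4.11, 1.5, "q", 0.25, FALSE),
  .mrow("alanine",            336.6,    417.8,  243.7, 1.48, 1.5, "d", 1.00, TRUE, 1.46, 1.50),
  .mrow("acetate",           6830.7,   1482.6, 4481.2, 1.92, 1.5, "s", 1.00, TRUE, 1.90, 1.94),
  .mrow("citrate",           4678.6,   1507.7, 1985.2, 2.60, 1.5, "dd", 1.00, TRUE, 2.50, 2.70),
  .mrow("dimethylamine",       27.9,   2248.5, 2272.1, 2.74, 1.5, "s", 1.00, TRUE, 2.72, 2.76),
  .mrow("creatine",          8791.9,  21502.2, 12218.0, 3.04, 1.5, "s", 0.60, FALSE),
  .mrow("creatine",          8791.9,  21502.2, 12218.0, 3.93, 1.5, "s", 0.40, TRUE, 3.91, 3.95),
  .mrow("creatinine",       10687.5,  16234.4, 23289.9, 3.05, 1.5, "s", 0.60, FALSE),
  .mrow("creatinine",       10687.5,  16234.4, 23289.9, 4.06, 1.5, "s", 0.40, TRUE, 4.04, 4.08),
  .mrow("dimethyl-sulfone",  1348.3,    275.6,  484.4, 3.15, 1.5, "s", 1.00, TRUE, 3.13, 3.17),
  .mrow("trimethylamine-N-oxide", 40396.6, 11389.4, 9964.5, 3.27, 1.5, "s", 1.00, TRUE, 3.25, 3.29),
  .mrow("allantoin",          349.2,   5061.5, 5761.6, 5.39, 1.5, "s", 1.00, TRUE, 5.37, 5.41),
  .mrow("benzoate",            22.8,    212.6,    0.8, 7.48, 1.5, "t", 0.50, TRUE, 7.46, 7.50),
  .mrow("benzoate",            22.8,    212.6,    0.8, 7.87, 1.5, "d", 0.50, FALSE),
  .mrow("hippurate",        95714.3,  24948.8, 26049.2, 7.83, 1.5, "d", 0.35, TRUE, 7.81, 7.85),
  .mrow("hippurate",        95714.3,  24948.8, 26049.2, 7.64, 1.5, "t", 0.18, FALSE),
  .mrow("hippurate",        95714.3,  24948.8, 26049.2, 7.55, 1.5, "t", 0.22, FALSE),
  .mrow("hippurate",        95714.3,  24948.8, 26049.2, 4.00, 1.5, "d", 0.25, FALSE),
  .mrow("tyrosine",           567.0,    145.2,  497.0, 6.90, 1.5, "d", 0.50, TRUE, 6.88, 6.92),
  .mrow("tyrosine",           567.0,    145.2,  497.0, 7.19, 1.5, "d", 0.50, FALSE),
  .mrow("formate",           1068.1,    231.5, 1282.3, 8.46, 1.5, "s", 1.00, TRUE, 8.44, 8.48)
)

.libLiverWater <- function() rbind(
  .mrow("2-hydroxybutyrate",   39.1,     57.1,   58.5, 0.90, 1.5, "t", 0.60, TRUE, 0.88, 0.92),
  .mrow("2-hydroxybutyrate",   39.1,     57.1,   58.5, 3.75, 1.5, "s", 0.40, FALSE),
  .mrow("lactate",            977.6,    657.6,  837.5, 1.33, 1.5, "d", 0.75, TRUE, 1.31, 1.35),
  .mrow("lactate",            977.6,    657.6,  837.5, 4.11, 1.5, "q", 0.25, FALSE),
  .mrow("alanine",           1684.8,   1251.5,  901.6, 1.48, 1.5, "d", 1.00, TRUE, 1.46, 1.50),
  .mrow("acetate",            156.7,     99.7,  202.5, 1.92, 1.5, "s", 1.00, TRUE, 1.90, 1.94),
  .mrow("succinate",          236.6,    223.0,  193.7, 2.41, 1.5, "s", 1.00, TRUE, 2.39, 2.43),
  .mrow("aspartate",          223.3,    137.5,  117.9, 2.80, 1.5, "d", 0.55, TRUE, 2.78, 2.82),
  .mrow("aspartate",          223.3,    137.5,  117.9, 2.68, 1.5, "d", 0.45, FALSE),
  .mrow("creatine",           613.5,    663.8, 1152.4, 3.04, 1.5, "s", 0.60, FALSE),
  .mrow("creatine",           613.5,    663.8, 1152.4, 3.93, 1.5, "s", 0.40, TRUE, 3.91, 3.95),
  .mrow("creatinine",         429.1,    463.8,  401.9, 3.05, 1.5, "s", 0.60, FALSE),
  .mrow("creatinine",         429.1,    463.8,  401.9, 4.06, 1.5, "s", 0.40, TRUE, 4.04, 4.08),
  .mrow("choline",           5494.4,   6712.6, 6621.9, 3.20, 1.2, "s", 1.00, TRUE, 3.18, 3.22),
  .mrow("myoinositol",         39.5,     91.2,  117.0, 3.29, 1.5, "s", 1.00, TRUE, 3.27, 3.31),
  .mrow("glycine",           1180.1,   2091.9, 1759.6, 3.56, 1.5, "s", 1.00, TRUE, 3.54, 3.58),
  .mrow("glycerol",           335.5,    678.9,  638.2, 3.65, 1.5, "s", 0.60, TRUE, 3.63, 3.67),
  .mrow("glycerol",           335.5,    678.9,  638.2, 3.78, 1.5, "s", 0.40, FALSE),
  .mrow("glucose",            316.3,     25.7,    3.1, 5.24, 1.5, "d", 0.35, TRUE, 5.22, 5.26),
  .mrow("glucose",            316.3,     25.7,    3.1, 3.47, 1.5, "s", 0.65, FALSE),
  .mrow("uridine",             69.3,    125.3,  113.3, 5.90, 1.5, "d", 1.00, TRUE, 5.88, 5.92),
  .mrow("formate",             42.7,     51.0,   85.2, 8.46, 1.5, "s", 1.00, TRUE, 8.44, 8.48)
)

.libSerumLipid <- function() rbind(
  .mrow("cholesterol-C18H3",  92228.9,  47223.8,  51198.9, 0.68, 5, "s", 1, TRUE, 0.64, 0.72),
  .mrow("fatty-acid-CH3",    142111.4,  80141.0,  88449.1, 0.88, 6, "s", 1, TRUE, 0.84, 0.92),
  .mrow("fatty-acid-CH2n",  1615749.3, 1233196.9, 1173938.0, 1.26, 8, "s", 1, TRUE, 1.18, 1.34),
  .mrow("fatty-acid-allylic", 81686.8,  34361.4,  30264.7, 2.02, 6, "s", 1, TRUE, 1.96, 2.08),
  .mrow("fatty-acid-CH2CO",   56704.1,  28166.0,  29411.3, 2.24, 6, "s", 1, TRUE, 2.18, 2.30),
  .mrow("pufa-bisallylic",    57311.7,  25810.8,  21921.8, 2.77, 6, "s", 1, TRUE, 2.71, 2.83),
  .mrow("phospholipid-NCH3", 169112.5, 107897.8,  93096.8, 3.22, 5, "s", 1, TRUE, 3.17, 3.27),
  .mrow("free-cholesterol-C3H", 8083.6,  5712.1,   6336.3, 3.52, 6, "s", 1, TRUE, 3.46, 3.58),
  .mrow("glycerol-backbone",   2870.3,   1761.0,   1337.1, 4.28, 6, "s", 1, TRUE, 4.22, 4.34),
  .mrow("cholesteryl-ester-C3H", 18006.6, 7914.7,  9110.7, 4.65, 6, "s", 1, TRUE, 4.59, 4.71),
  .mrow("phosphoglyceride-CH", 13212.6,  8006.1,   5869.4, 5.21, 5, "s", 1, TRUE, 5.17, 5.25),
  .mrow("unsaturated-CHCH",  185955.1, 117222.1, 109687.6, 5.33, 7, "s", 1, TRUE, 5.27, 5.39),
  .mrow("sphingomyelin-CHCH",  2997.6,   2024.2,   2359.6, 5.70, 5, "s", 1, TRUE, 5.66, 5.74)
)

.libLiverLipid <- function() rbind(
  .mrow("cholesterol-C18H3",   3367.7,   4317.6,   4667.2, 0.68, 5, "s", 1, TRUE, 0.64, 0.72),
  .mrow("fatty-acid-CH3",     78874.6, 130014.7,  97446.8, 0.88, 6, "s", 1, TRUE, 0.84, 0.92),
  .mrow("cholesterol-multi",   4930.3,   6027.2,   6327.8, 1.07, 6, "s", 1, TRUE, 1.03, 1.11),
  .mrow("fatty-acid-CH2n",   672145.9, 1034204.0, 853648.9, 1.26, 8, "s", 1, TRUE, 1.18, 1.34),
  .mrow("fatty-acid-beta-CH2", 455655.5, 549820.1, 601105.4, 1.58, 6, "s", 1, TRUE, 1.52, 1.64),
  .mrow("fatty-acid-allylic",  34891.7,  57371.2,  52710.2, 2.02, 6, "s", 1, TRUE, 1.96, 2.08),
  .mrow("fatty-acid-CH2CO",    47047.6,  79889.6,  64893.3, 2.24, 6, "s", 1, TRUE, 2.18, 2.30),
  .mrow("pufa-bisallylic",     26475.0,  30851.1,  24588.6, 2.77, 6, "s", 1, TRUE, 2.71, 2.83),
  .mrow("phosphatidylcholine", 12167.2,   9516.6,  12207.6, 3.22, 5, "s", 1, TRUE, 3.18, 3.26),
  .mrow("sphingomyelin-choline", 40154.9, 29159.9, 38578.1, 3.31, 5, "s", 1, TRUE, 3.27, 3.35),
  .mrow("free-cholesterol-C3H",  873.5,   1112.8,   1205.4, 3.52, 6, "s", 1, TRUE, 3.46, 3.58),
  .mrow("glycerol-backbone",    199.2,   9267.3,   1655.4, 4.28, 6, "s", 1, TRUE, 4.22, 4.34),
  .mrow("phosphoglyceride-CH", 13916.0,  13895.6,  16490.1, 5.21, 5, "s", 1, TRUE, 5.17, 5.25),
  .mrow("unsaturated-CHCH",    47835.0,  78192.9,  56367.3, 5.33, 7, "s", 1, TRUE, 5.27, 5.39)
)

.libUrineLipid <- function() rbind(
  .mrow("cholesterol-C18H3",    171.8,     53.6,     0.01, 0.68, 5, "s", 1, TRUE, 0.64, 0.72),
  .mrow("fatty-acid-CH3",    122298.2,   9413.9,  14060.8, 0.88, 6, "s", 1, TRUE, 0.84, 0.92),
  .mrow("fatty-acid-CH2n",    85753.5,  56153.8,  94974.8, 1.26, 8, "s", 1, TRUE, 1.18, 1.34),
  .mrow("fatty-acid-beta-CH2", 274637.5, 214963.2, 217487.8, 1.58, 6, "s", 1, TRUE, 1.52, 1.64),
  .mrow("pufa-bisallylic",      140.6,     51.6,     96.8, 2.77, 6, "s", 1, TRUE, 2.71, 2.83),
  .mrow("unassigned-lipid",    1249.2,   1142.7,    983.2, 3.65, 6, "s", 1, TRUE, 3.59, 3.71),
  .mrow("glycerol-backbone",     18.4,    197.6,    165.3, 4.28, 6, "s", 1, TRUE, 4.22, 4.34),
  .mrow("unsaturated-CHCH",     643.0,    384.6,    325.7, 5.33, 7, "s", 1, TRUE, 5.27, 5.39)
)

.libraryDef <- function(matrix, phase) {
  matrix <- checkVocab(matrix, .MATRICES, "matrix")
  phase <- checkVocab(phase, .PHASES, "phase")
  switch(paste(matrix, phase, sep = "."),
    serum.water = .libSerumWater(),
    urine.water = .libUrineWater(),
    liver.water = .libLiverWater(),
    serum.lipid = .libSerumLipid(),
    liver.lipid = .libLiverLipid(),
    urine.lipid = .libUrineLipid())
}

## low-discrepancy background comb: ~300 minor fold-1 resonances spread
## over the spectral range, kept clear of the assignment regions so
## quantifier windows stay attributable to their metabolite. Emulates
## the crowded small-signal background of real biofluid spectra (and is
## what makes median-quotient normalization meaningful bin by bin).
.backgroundPeaks <- function(matrix, phase, n = 300) {
  def <- .libraryDef(matrix, phase)
  q <- def[def$quant, , drop = FALSE]
  k <- seq_len(n)
  pos <- 0.3 + 9.6 * ((k * 0.6180339887498949) %% 1)
  amp <- 0.5 + ((k * 1.4142135623730951) %% 1)
  keep <- !vapply(pos, function(p)
    any(p >= q$qlo - 0.03 & p <= q$qhi + 0.03), logical(1))
  pos <- pos[keep]; amp <- amp[keep]
  total <- 0.4 * sum(q$healthy * 1)  # 40% of major healthy area
  amp <- amp / sum(amp) * total
  lw <- if (phase == "lipid") 5 else 1.8
  data.frame(metabolite = sprintf("background.%03d", seq_along(pos)),
             center = pos, lw = lw, amplitude = amp,
             stringsAsFactors = FALSE)
}

## calibration reference resonance per matrix/phase: the anomeric
## glucose doublet (serum water), the TMSP singlet at 0.00 ppm
## (liver/urine water) and the chloroform singlet (lipid extracts)
.calibrationReference <- function(matrix, phase) {
  if (phase == "lipid")
    list(name = "chloroform", ppm = 7.20)
  else if (matrix == "serum")
    list(name = "glucose", ppm = 5.24)
  else
    list(name = "tmsp", ppm = 0.00)
}

#' Packaged effect table for one matrix/phase combination
#'
#' Per-group multiplicative fold-changes relative to healthy, computed as
#' the ratio of published group medians to the healthy median for the
#' packaged metabolite panel of that sample matrix and extraction phase.
#' The healthy column is 1 for every metabolite by construction.
#'
#' @param matrix sample matrix: "serum", "liver" or "urine".
#' @param phase extraction phase: "water" or "lipid".
#' @return data.frame with columns \code{metabolite}, \code{healthy},
#'   \code{LDA}, \code{RDA}; attribute \code{"medians"} carries the
#'   underlying group medians (arbitrary units).
#' @examples
#' et <- defaultEffectTable("serum", "water")
#' et[et$metabolite == "hippurate", ]  # LDA fold ~ 58.2 / 437.2
#' @export
defaultEffectTable <- function(matrix, phase) {
  def <- .libraryDef(matrix, phase)
  med <- unique(def[, c("metabolite", "healthy", "LDA", "RDA")])
  out <- data.frame(metabolite = med$metabolite,
                    healthy = rep(1, nrow(med)),
                    LDA = med$LDA / med$healthy,
                    RDA = med$RDA / med$healthy,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "medians") <- med
  out
}

#' Packaged peak library for one matrix/phase combination
#'
#' The list of \linkS4class{PeakSpec} objects the generator uses for the
#' given combination: the metabolite panel (base amplitudes = published
#' healthy medians, split over literature-patterned multiplets), the
#' mandatory calibration reference resonance, and a low-amplitude
#' background comb emulating the crowded small-signal baseline of real
#' biofluid spectra.
#'
#' @inheritParams defaultEffectTable
#' @param background number of background comb resonances before
#'   assignment-region filtering (0 disables the comb).
#' @return list of \linkS4class{PeakSpec}.
#' @export
defaultPeakLibrary <- function(matrix, phase, background = 300) {
  def <- .libraryDef(matrix, phase)
  peaks <- lapply(seq_len(nrow(def)), function(i) {
    shp <- .multShape(def$mult[i])
    peakSpec(def$metabolite[i], def$center[i], def$lw[i],
             def$healthy[i] * def$share[i], offsets = shp$off, rel = shp$rel)
  })
  ref <- .calibrationReference(matrix, phase)
  if (!ref$name %in% def$metabolite) {
    amp <- if (ref$name == "chloroform") 5 * stats::median(def$healthy)
           else 2 * stats::median(def$healthy)
    peaks <- c(peaks, list(peakSpec(ref$name, ref$ppm, 1.2, amp)))
  }
  if (background > 0) {
    bg <- .backgroundPeaks(matrix, phase, background)
    peaks <- c(peaks, lapply(seq_len(nrow(bg)), function(i)
      peakSpec(bg$metabolite[i], bg$center[i], bg$lw[i], bg$amplitude[i])))
  }
  peaks
}

#' Packaged metabolite assignment table
#'
#' Quantifier ppm windows per metabolite for region integration, one row
#' per region (a metabolite may own several). Regions lie inside
#' 0.2-10.0 ppm and outside the phase's solvent exclusion region. These
#' windows are literature-patterned stand-ins, not a reconstruction of
#' the study's (unreported) integration regions.
#'
#' @inheritParams defaultEffectTable
#' @return data.frame with columns \code{metabolite}, \code{matrix},
#'   \code{phase}, \code{ppm_lo}, \code{ppm_hi}.
#' @export
defaultAssignments <- function(matrix, phase) {
  def <- .libraryDef(matrix, phase)
  q <- def[def$quant, , drop = FALSE]
  data.frame(metabolite = q$metabolite, matrix = matrix, phase = phase,
             ppm_lo = q$qlo, ppm_hi = q$qhi, stringsAsFactors = FALSE,
             row.names = NULL)
}
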