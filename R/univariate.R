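#' Integrate assigned ppm regions into metabolite concentrations
#'
#' For every sample and metabolite, sums the included-bin areas over the
#' metabolite's assigned regions; bins partially overlapping a region
#' contribute in proportion to the overlap fraction. The result is a
#' concentration in arbitrary units on the table's current normalization
#' scale. A metabolite whose regions fall entirely inside excluded bins
#' raises an error naming it.
#'
#' @param table a \linkS4class{BucketTable}.
#' @param assignments data.frame with columns \code{metabolite},
#'   \code{ppm_lo}, \code{ppm_hi} (one region per row; a metabolite may
#'   own several rows). Regions must be non-overlapping within a
#'   metabolite.
#' @return samples x metabolites numeric matrix.
#' @export
integrateRegions <- function(table, assignments) {
  req <- c("metabolite", "ppm_lo", "ppm_hi")
  if (!all(req %in% colnames(assignments)))
    stopf("assignments must have columns %s", paste(req, collapse = ", "))
  bad <- assignments$ppm_lo >= assignments$ppm_hi
  if (any(bad))
    stopf("inverted assignment region for %s",
          paste(assignments$metabolite[bad], collapse = ", "))
  ## non-overlap within metabolite
  for (m in unique(assignments$metabolite)) {
    r <- assignments[assignments$metabolite == m, , drop = FALSE]
    r <- r[order(r$ppm_lo), , drop = FALSE]
    if (nrow(r) > 1 && any(r$ppm_lo[-1] < r$ppm_hi[-nrow(r)] - 1e-9))
      stopf("overlapping regions within metabolite '%s'", m)
  }
  v <- assay(table, "area")
  rd <- rowData(table)
  inc <- rd$included
  metabs <- unique(assignments$metabolite)
  conc <- matrix(0, ncol(v), length(metabs),
                 dimnames = list(colnames(v), metabs))
  for (m in metabs) {
    rows <- which(assignments$metabolite == m)
    weight <- numeric(nrow(v))
    anyBin <- FALSE
    for (r in rows) {
      lo <- assignments$ppm_lo[r]; hi <- assignments$ppm_hi[r]
      ov <- pmax(0, pmin(rd$ppm_hi, hi) - pmax(rd$ppm_lo, lo))
      frac <- ov / (rd$ppm_hi - rd$ppm_lo)
      if (any(frac > 1e-9)) anyBin <- TRUE
      weight <- weight + frac
    }
    usable <- weight > 1e-9 & inc
    if (anyBin && !any(usable))
      stopf("assignment region(s) for metabolite '%s' lie entirely in excluded bins", m)
    if (!anyBin)
      stopf("assignment region(s) for metabolite '%s' cover no bins", m)
    conc[, m] <- drop(crossprod(v[usable, , drop = FALSE], weight[usable]))
  }
  conc
}

#' Median and (unscaled) median absolute deviation
#'
#' The MAD here is the raw median of absolute deviations from the
#' median, without the 1.4826 normal-consistency factor, matching the
#' median +/- MAD convention of the concentration tables.
#'
#' @param values numeric vector (>= 1 value).
#' @return named numeric vector \code{c(median, mad)}.
#' @examples
#' medianMad(c(1, 2, 3, 4, 100))  # median 3, MAD 1
#' @export
medianMad <- function(values) {
  if (length(values) < 1) stopf("medianMad needs at least one value")
  m <- stats::median(values)
  c(median = m, mad = stats::median(abs(values - m)))
}

#' Two-sample Wilcoxon rank test
#'
#' Two-sided two-sample Wilcoxon rank-sum (Mann-Whitney) test: exact
#' enumeration when the smaller group has at most 8 observations and
#' there are no ties, otherwise the normal approximation with mid-rank
#' tie correction and continuity correction ("auto"); either behaviour
#' can be forced. Group concentrations in this pipeline are skewed and
#' not normally distributed, hence the rank test rather than a t test.
#' A paired signed-rank variant is available (\code{mode = "paired"})
#' but is not used by the group-comparison pipeline, which compares
#' independent animals.
#'
#' If all values are identical across both groups the test is
#' degenerate; p = 1 is returned with a warning.
#'
#' @param a,b numeric group values (both non-empty).
#' @param mode "auto", "exact", "approx" or "paired".
#' @return named numeric vector \code{c(statistic, p.value)} (statistic
#'   is the Mann-Whitney U / Wilcoxon W of \code{a}, or the signed-rank
#'   V in paired mode).
#' @examples
#' rankTest(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
rankTest <- function(a, b, mode = c("auto", "exact", "approx", "paired")) {
  mode <- match.arg(mode)
  if (length(a) < 1 || length(b) < 1) stopf("both groups must be non-empty")
  if (all(c(a, b) == c(a, b)[1])) {
    warning("all values identical across both groups; returning p = 1")
    return(c(statistic = NA_real_, p.value = 1))
  }
  if (mode == "paired") {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = NULL, correct = TRUE))
    return(c(statistic = unname(wt$statistic), p.value = wt$p.value))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode, exact = TRUE, approx = FALSE,
                  auto = min(length(a), length(b)) <= 8 && !ties)
  if (exact && ties)
    stopf("exact mode is undefined in the presence of ties")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  c(statistic = unname(wt$statistic), p.value = min(wt$p.value, 1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p values: sort ascending, compute p * m / rank,
#' enforce monotonicity from the largest p down, cap at 1, and return in
#' the original order. Invariant to the input ordering.
#'
#' @param pvals numeric vector of raw p values in [0, 1].
#' @return adjusted p values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Compare metabolite concentrations between groups
#'
#' For each metabolite and each requested group pair, runs the
#' two-sample Wilcoxon rank test on the per-sample concentrations,
#' adjusts p values with Benjamini-Hochberg within each comparison
#' (across metabolites), and reports per-group median and unscaled MAD
#' plus significance flags at adjusted p < alpha. Comparisons involving
#' a group with fewer than 2 samples are skipped with a warning.
#'
#' @param conc samples x metabolites concentration matrix (from
#'   \code{\link{integrateRegions}}).
#' @param meta per-sample metadata with a \code{group} column aligned
#'   with the rows of \code{conc}.
#' @param comparisons list of length-2 character vectors; default the
#'   three pairwise comparisons healthy-vs-LDA, healthy-vs-RDA,
#'   LDA-vs-RDA, emitted in that fixed order.
#' @param alpha significance level on the adjusted p value.
#' @param mode rank-test mode (see \code{\link{rankTest}}).
#' @return data.frame (one row per metabolite): per-group
#'   \code{<group>_median} / \code{<group>_mad} columns, then per
#'   comparison \code{p_<g1>_vs_<g2>}, \code{padj_<g1>_vs_<g2>} and
#'   \code{sig_<g1>_vs_<g2>}.
#' @export
compareGroups <- function(conc, meta, comparisons = NULL, alpha = 0.05,
                          mode = "auto") {
  groups <- as.character(meta$group)
  if (nrow(conc) != length(groups))
    stopf("conc rows (%d) and metadata rows (%d) differ", nrow(conc),
          length(groups))
  if (is.null(comparisons)) {
    present <- intersect(.GROUPS, unique(groups))
    comparisons <- Filter(function(cmp) all(cmp %in% present),
                          .DEFAULT_COMPARISONS)
  }
  for (cmp in comparisons) {
    missing <- setdiff(cmp, unique(groups))
    if (length(missing))
      stopf("group(s) not present in metadata: %s",
            paste(missing, collapse = ", "))
  }
  metabs <- colnames(conc)
  out <- data.frame(metabolite = metabs, stringsAsFactors = FALSE)
  for (g in unique(groups)) {
    mm <- t(apply(conc[groups == g, , drop = FALSE], 2, medianMad))
    out[[paste0(g, "_median")]] <- mm[, "median"]
    out[[paste0(g, "_mad")]] <- mm[, "mad"]
  }
  for (cmp in comparisons) {
    tag <- paste0(cmp[1], "_vs_", cmp[2])
    if (sum(groups == cmp[1]) < 2 || sum(groups == cmp[2]) < 2) {
      warning(sprintf("comparison %s skipped: a group has < 2 samples", tag))
      next
    }
    p <- vapply(metabs, function(m)
      rankTest(conc[groups == cmp[1], m], conc[groups == cmp[2], m],
               mode = mode)[["p.value"]], numeric(1))
    padj <- bhAdjust(p)
    out[[paste0("p_", tag)]] <- p
    out[[paste0("padj_", tag)]] <- padj
    out[[paste0("sig_", tag)]] <- padj < alpha
  }
  rownames(out) <- NULL
  out
}
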