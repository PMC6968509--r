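#' @importFrom data.table fread fwrite
#' @importFrom jsonlite write_json read_json
#' @importFrom utils read.delim write.table
NULL

.readSampleSheet <- function(path) {
  ss <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "matrix", "phase", "pulse_program")
  if (!all(req %in% colnames(ss)))
    stopf("sample sheet must have columns: %s", paste(req, collapse = ", "))
  badGroup <- setdiff(unique(ss$group), .GROUPS)
  if (length(badGroup))
    stopf("unknown group label(s) %s; allowed: %s",
          paste(badGroup, collapse = ", "), paste(.GROUPS, collapse = ", "))
  ss
}

#' Write spectra to disk
#'
#' \code{format = "two_column"} writes one whitespace-free two-column
#' file (ppm, intensity) per sample, in descending-ppm display order;
#' \code{format = "matrix_csv"} writes a single samples x points CSV
#' whose header row is the ppm axis. Both are accompanied by a
#' tab-separated sample sheet (sample_id, group, matrix, phase,
#' pulse_program).
#'
#' @param spectra list of \linkS4class{NMRSpectrum} or an
#'   \linkS4class{NMRCohort}.
#' @param dir output directory (created if absent).
#' @param format "two_column" or "matrix_csv".
#' @return Invisibly, the paths written.
#' @export
writeSpectra <- function(spectra, dir, format = c("two_column", "matrix_csv")) {
  format <- match.arg(format)
  meta <- NULL
  if (is(spectra, "NMRCohort")) {
    meta <- as.data.frame(spectra@sampleMeta)
    spectra <- spectra@spectra
  } else {
    meta <- do.call(rbind, lapply(spectra, function(s)
      as.data.frame(s@sampleMeta, stringsAsFactors = FALSE)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "samples.tsv")
  write.table(meta, paths, sep = "\t", quote = FALSE, row.names = FALSE)
  if (format == "two_column") {
    for (s in spectra) {
      p <- file.path(dir, paste0(s@sampleMeta$sample_id, ".txt"))
      ord <- order(s@ppm, decreasing = TRUE)  # display convention
      fwrite(data.frame(ppm = s@ppm[ord], intensity = s@intensity[ord]),
             p, sep = "\t")
      paths <- c(paths, p)
    }
  } else {
    mat <- t(vapply(spectra, function(s) s@intensity,
                    numeric(length(spectra[[1]]@ppm))))
    df <- data.frame(sample_id = meta$sample_id, mat,
                     check.names = FALSE)
    colnames(df) <- c("sample_id", sprintf("%.6f", spectra[[1]]@ppm))
    p <- file.path(dir, "spectra.csv")
    fwrite(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read spectra from disk
#'
#' Counterpart of \code{\link{writeSpectra}}: loads either per-sample
#' two-column files or the cohort-wide matrix CSV, joins the sample
#' sheet, validates group labels against the closed vocabulary and the
#' ppm axes for monotonicity, and returns the spectra in sample-sheet
#' order.
#'
#' @param dir directory holding the files and \code{samples.tsv}.
#' @param format "two_column" or "matrix_csv".
#' @return list with \code{spectra} (list of \linkS4class{NMRSpectrum})
#'   and \code{sampleMeta} (\link[S4Vectors]{DataFrame}).
#' @export
readSpectra <- function(dir, format = c("two_column", "matrix_csv")) {
  format <- match.arg(format)
  ss <- .readSampleSheet(file.path(dir, "samples.tsv"))
  spectra <- vector("list", nrow(ss))
  if (format == "two_column") {
    for (i in seq_len(nrow(ss))) {
      p <- file.path(dir, paste0(ss$sample_id[i], ".txt"))
      if (!file.exists(p))
        stopf("no spectrum file for sample '%s'", ss$sample_id[i])
      d <- fread(p, data.table = FALSE, header = TRUE)
      ord <- order(d[[1]])
      spectra[[i]] <- nmrSpectrum(d[[1]][ord], d[[2]][ord],
                                  sampleMeta = as.list(ss[i, ]))
    }
  } else {
    d <- fread(file.path(dir, "spectra.csv"), data.table = FALSE, header = TRUE)
    ppm <- as.numeric(colnames(d)[-1])
    if (any(diff(ppm) <= 0)) stopf("matrix CSV ppm axis is not monotone")
    missing <- setdiff(ss$sample_id, d[[1]])
    if (length(missing))
      stopf("sample sheet id(s) missing from data: %s",
            paste(missing, collapse = ", "))
    for (i in seq_len(nrow(ss))) {
      row <- which(d[[1]] == ss$sample_id[i])
      spectra[[i]] <- nmrSpectrum(ppm, as.numeric(d[row, -1]),
                                  sampleMeta = as.list(ss[i, ]))
    }
  }
  list(spectra = spectra, sampleMeta = S4Vectors::DataFrame(ss))
}

#' Write a BucketTable to CSV with sidecars
#'
#' Main CSV: first column \code{sample_id}, remaining header = bin-centre
#' ppm (descending display order). Sidecar TSV \code{<stem>_bins.tsv}
#' holds bin edges and the inclusion mask; sidecar JSON
#' \code{<stem>_meta.json} records the normalization state, exclusion
#' regions and PQN quotients.
#'
#' @param table a \linkS4class{BucketTable}.
#' @param stem output path stem (no extension).
#' @return Invisibly, the paths written.
#' @export
writeBucketTable <- function(table, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  rd <- rowData(table)
  ctr <- (rd$ppm_lo + rd$ppm_hi) / 2
  ord <- order(ctr, decreasing = TRUE)
  v <- t(assay(table, "area"))[, ord, drop = FALSE]
  df <- data.frame(sample_id = colnames(table), v, check.names = FALSE)
  colnames(df) <- c("sample_id", sprintf("%.3f", ctr[ord]))
  main <- paste0(stem, ".csv")
  fwrite(df, main)
  bins <- paste0(stem, "_bins.tsv")
  write.table(data.frame(ppm_lo = rd$ppm_lo, ppm_hi = rd$ppm_hi,
                         included = rd$included),
              bins, sep = "\t", quote = FALSE, row.names = FALSE)
  metaPath <- paste0(stem, "_meta.json")
  md <- metadata(table)
  write_json(list(normalization_state = normalizationState(table),
                  excluded_regions = md$excluded_regions,
                  pqn_quotients = as.list(md$pqn_quotients),
                  pqn_scale = as.list(md$pqn_scale),
                  sample_meta = as.data.frame(colData(table))),
             metaPath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(main, bins, metaPath))
}

#' Read a BucketTable written by writeBucketTable
#'
#' @param stem the path stem used when writing.
#' @return A \linkS4class{BucketTable}.
#' @export
readBucketTable <- function(stem) {
  df <- fread(paste0(stem, ".csv"), data.table = FALSE, header = TRUE)
  bins <- read.delim(paste0(stem, "_bins.tsv"))
  md <- read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  ctrFile <- as.numeric(colnames(df)[-1])
  ctr <- (bins$ppm_lo + bins$ppm_hi) / 2
  ord <- match(round(ctr, 6), round(ctrFile, 6))
  v <- t(as.matrix(df[, -1, drop = FALSE]))[ord, , drop = FALSE]
  colnames(v) <- df$sample_id
  rownames(v) <- NULL
  cd <- if (!is.null(md$sample_meta) && length(md$sample_meta))
    S4Vectors::DataFrame(md$sample_meta)
  else S4Vectors::DataFrame(sample_id = df$sample_id)
  se <- SummarizedExperiment(
    assays = list(area = v),
    rowData = S4Vectors::DataFrame(ppm_lo = bins$ppm_lo,
                                   ppm_hi = bins$ppm_hi,
                                   included = bins$included),
    colData = cd)
  metadata(se)$normalization_state <- md$normalization_state
  metadata(se)$excluded_regions <- md$excluded_regions
  if (length(md$pqn_quotients))
    metadata(se)$pqn_quotients <- unlist(md$pqn_quotients)
  if (length(md$pqn_scale))
    metadata(se)$pqn_scale <- unlist(md$pqn_scale)
  new("BucketTable", se)
}

#' Write the cohort truth record as TSV
#'
#' Columns: metabolite, comparison, true_fold_change, is_differential.
#'
#' @param cohort an \linkS4class{NMRCohort}.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
writeTruthRecord <- function(cohort, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(cohort@truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a univariate comparison table as CSV
#'
#' Mirrors the published report shape: metabolite, per-group median and
#' MAD, then per-comparison raw p, adjusted p and significance flag.
#'
#' @param table data.frame from \code{\link{compareGroups}}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeUnivariateTable <- function(table, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  fwrite(table, path)
  invisible(path)
}
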