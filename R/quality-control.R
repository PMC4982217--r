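#' Mask wells with insufficient bead counts
#'
#' The instrument's MFI readout is only considered valid when more than
#' `min_beads` beads were measured for the bead ID in that well (the
#' vendor's ">35 beads" criterion). Cells at or below the threshold are set
#' missing; the inequality is strict, so a count of exactly 35 is masked
#' and 36 is retained.
#'
#' @param matrix an [assay_matrix()] carrying bead counts. Without bead
#'   counts the matrix is returned unchanged with a warning.
#' @param min_beads threshold; wells with `count <= min_beads` are masked.
#' @return the filtered [assay_matrix()], with an attribute
#'   `n_cells_masked_beadcount`.
#' @export
filter_bead_counts <- function(matrix, min_beads = 35) {
  stopifnot(inherits(matrix, "assay_matrix"))
  if (is.null(matrix$bead_counts)) {
    warning("no bead counts present; returning matrix unchanged")
    attr(matrix, "n_cells_masked_beadcount") <- 0L
    return(matrix)
  }
  if (any(matrix$bead_counts < 0, na.rm = TRUE))
    stop("negative bead counts encountered")
  low <- !is.na(matrix$bead_counts) & matrix$bead_counts <= min_beads
  n_masked <- sum(low & !is.na(matrix$values))
  matrix$values[low] <- NA_real_
  attr(matrix, "n_cells_masked_beadcount") <- as.integer(n_masked)
  matrix
}

#' Quality-control filter
#'
#' Applies the QC rules in their stated order on the raw matrix:
#' \enumerate{
#'   \item signal intensities <= 0 are set missing;
#'   \item analytes whose fraction of null values (missing-or-nonpositive,
#'     which coincide after step 1) exceeds `analyte_null_max` are dropped;
#'   \item samples whose null fraction exceeds `sample_null_max` are
#'     dropped, with fractions computed on the surviving analytes
#'     (switchable to pre-exclusion fractions).
#' }
#' Both thresholds are strict ("exceeding"): an analyte missing in exactly
#' 8 of 42 samples (19.05 %) is excluded under the 19 % rule, while 7 of 42
#' (16.67 %) is retained.
#'
#' @param matrix an [assay_matrix()] with `scale_tag = "raw"`.
#' @param analyte_null_max maximum tolerated null fraction per analyte.
#' @param sample_null_max maximum tolerated null fraction per sample.
#' @param sample_fractions whether sample null fractions are computed after
#'   (`"post_analyte_exclusion"`, default) or before analyte exclusion.
#' @param n_cells_masked_beadcount carried into the report when
#'   [filter_bead_counts()] ran beforehand.
#' @return list with elements `matrix` (filtered) and `report`
#'   (class `qc_report`).
#' @export
qc_filter <- function(matrix, analyte_null_max = 0.19,
                      sample_null_max = 0.20,
                      sample_fractions = c("post_analyte_exclusion",
                                           "pre_analyte_exclusion"),
                      n_cells_masked_beadcount = NULL) {
  stopifnot(inherits(matrix, "assay_matrix"))
  if (matrix$scale_tag != "raw")
    stop("qc_filter expects a raw-scale matrix, got scale_tag = '",
         matrix$scale_tag, "'")
  sample_fractions <- match.arg(sample_fractions)
  if (is.null(n_cells_masked_beadcount))
    n_cells_masked_beadcount <-
      attr(matrix, "n_cells_masked_beadcount") %||% 0L

  vals <- matrix$values
  nonpos <- !is.na(vals) & vals <= 0
  vals[nonpos] <- NA_real_

  null_frac_analyte <- rowMeans(is.na(vals))
  drop_analyte <- null_frac_analyte > analyte_null_max
  kept <- vals[!drop_analyte, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("all analytes excluded by the ", 100 * analyte_null_max,
         " % null rule")

  null_frac_sample <- if (sample_fractions == "post_analyte_exclusion")
    colMeans(is.na(kept)) else colMeans(is.na(vals))
  drop_sample <- null_frac_sample > sample_null_max
  kept <- kept[, !drop_sample, drop = FALSE]
  if (ncol(kept) == 0L)
    stop("all samples excluded by the ", 100 * sample_null_max,
         " % null rule")

  bc <- matrix$bead_counts
  if (!is.null(bc)) bc <- bc[!drop_analyte, !drop_sample, drop = FALSE]
  out <- assay_matrix(kept, bead_counts = bc, scale_tag = "raw")

  report <- structure(list(
    excluded_analytes = data.frame(
      analyte_id = rownames(matrix$values)[drop_analyte],
      null_fraction = unname(null_frac_analyte[drop_analyte]),
      stringsAsFactors = FALSE),
    excluded_samples = data.frame(
      sample_id = colnames(matrix$values)[drop_sample],
      null_fraction = unname(null_frac_sample[drop_sample]),
      stringsAsFactors = FALSE),
    n_cells_masked_nonpositive = sum(nonpos),
    n_cells_masked_beadcount = as.integer(n_cells_masked_beadcount),
    n_cells_imputed = 0L), class = "qc_report")
  list(matrix = out, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  cells masked (<= 0):        %d\n",
              x$n_cells_masked_nonpositive))
  cat(sprintf("  cells masked (bead count):  %d\n",
              x$n_cells_masked_beadcount))
  cat(sprintf("  analytes excluded:          %d\n",
              nrow(x$excluded_analytes)))
  if (nrow(x$excluded_analytes))
    cat("   ", paste(sprintf("%s (%.1f%%)", x$excluded_analytes$analyte_id,
                             100 * x$excluded_analytes$null_fraction),
                     collapse = ", "), "\n")
  cat(sprintf("  samples excluded:           %d\n",
              nrow(x$excluded_samples)))
  if (nrow(x$excluded_samples))
    cat("   ", paste(sprintf("%s (%.1f%%)", x$excluded_samples$sample_id,
                             100 * x$excluded_samples$null_fraction),
                     collapse = ", "), "\n")
  cat(sprintf("  cells imputed:              %d\n", x$n_cells_imputed))
  invisible(x)
}

#' Write a QC report as CSV
#'
#' @param report a `qc_report` from [qc_filter()].
#' @param path output CSV path.
#' @export
write_qc_report <- function(report, path) {
  lines <- c("section,id,value",
             sprintf("counts,n_cells_masked_nonpositive,%d",
                     report$n_cells_masked_nonpositive),
             sprintf("counts,n_cells_masked_beadcount,%d",
                     report$n_cells_masked_beadcount),
             sprintf("counts,n_cells_imputed,%d", report$n_cells_imputed))
  if (nrow(report$excluded_analytes))
    lines <- c(lines, sprintf("excluded_analyte,%s,%.17g",
                              report$excluded_analytes$analyte_id,
                              report$excluded_analytes$null_fraction))
  if (nrow(report$excluded_samples))
    lines <- c(lines, sprintf("excluded_sample,%s,%.17g",
                              report$excluded_samples$sample_id,
                              report$excluded_samples$null_fraction))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Median imputation
#'
#' Replaces every missing cell by the median of its analyte's observed
#' values across samples (reference pool included). The pipeline calls
#' this after transformation and before normalization; observed values are
#' never altered, and per-analyte medians are invariant under the
#' imputation.
#'
#' @param matrix an [assay_matrix()].
#' @return the imputed [assay_matrix()] (no missing cells), with an
#'   attribute `n_cells_imputed`.
#' @export
impute_median <- function(matrix) {
  stopifnot(inherits(matrix, "assay_matrix"))
  vals <- matrix$values
  miss <- is.na(vals)
  n_imp <- sum(miss)
  if (n_imp > 0) {
    all_missing <- rowSums(!miss) == 0L
    if (any(all_missing))
      stop("analyte(s) with zero observed values (QC should have removed ",
           "them): ", paste(rownames(vals)[all_missing], collapse = ", "))
    med <- apply(vals, 1L, stats::median, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    vals[idx] <- med[idx[, 1L]]
  }
  out <- assay_matrix(vals, bead_counts = matrix$bead_counts,
                      scale_tag = matrix$scale_tag)
  attr(out, "n_cells_imputed") <- as.integer(n_imp)
  out
}
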