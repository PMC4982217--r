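#' Read an assay matrix with its sample annotation
#'
#' The canonical file contract is two (optionally three) comma-separated
#' UTF-8 files: a matrix CSV with analytes as rows (first column
#' `analyte_id`, remaining columns one per sample), a sample annotation CSV
#' with columns `sample_id`, `group`, `plate` and optionally `replicate`,
#' and an optional bead-count CSV of the same shape as the matrix. Blank
#' cells, `NA` and `NaN` are parsed as missing; decimal separator is always
#' the dot regardless of locale.
#'
#' @param matrix_path path to the matrix CSV.
#' @param meta_path path to the sample annotation CSV.
#' @param beadcount_path optional path to a bead-count CSV.
#' @return list with elements `matrix` (an [assay_matrix()] with
#'   `scale_tag = "raw"`) and `meta` (a [sample_meta()] table).
#' @export
read_assay <- function(matrix_path, meta_path, beadcount_path = NULL) {
  vals <- .read_matrix_csv(matrix_path)
  meta_raw <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                              na.strings = c("", "NA", "NaN"))
  need <- c("sample_id", "group", "plate")
  if (!all(need %in% names(meta_raw)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  meta <- sample_meta(meta_raw$sample_id, meta_raw$group, meta_raw$plate,
                      if ("replicate" %in% names(meta_raw))
                        meta_raw$replicate else NA_integer_)
  beads <- NULL
  if (!is.null(beadcount_path)) {
    beads <- .read_matrix_csv(beadcount_path)
    if (!identical(dim(beads), dim(vals)) ||
        !identical(dimnames(beads), dimnames(vals)))
      stop("bead-count file is not aligned with the matrix file")
  }
  mat <- assay_matrix(vals, bead_counts = beads, scale_tag = "raw")
  validate_samples(mat, meta)
  list(matrix = mat, meta = meta)
}

.read_matrix_csv <- function(path) {
  # read.csv silently uniquifies duplicate header names; catch them first
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(header))
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA", "NaN"))
  if (ncol(df) < 1L) stop("matrix file has no columns: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate analyte IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  m
}

# Full-precision, locale-independent number formatting (round-trip safe).
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

.write_matrix_csv <- function(m, path) {
  header <- paste(c("analyte_id", colnames(m)), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], .fmt_num(m[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Write an assay matrix (and companion files)
#'
#' Writes the matrix CSV in input row/column order with missing cells as
#' empty fields and full float precision, so that write -> read -> write
#' reproduces a byte-identical file. When bead counts are present, a
#' companion file `<path-sans-ext>_beadcounts.csv` of identical shape is
#' written alongside.
#'
#' @param matrix an [assay_matrix()].
#' @param path output CSV path.
#' @return invisibly, the paths written.
#' @export
write_assay <- function(matrix, path) {
  stopifnot(inherits(matrix, "assay_matrix"))
  paths <- .write_matrix_csv(matrix$values, path)
  if (!is.null(matrix$bead_counts)) {
    bc_path <- paste0(tools::file_path_sans_ext(path), "_beadcounts.",
                      tools::file_ext(path))
    .write_matrix_csv(matrix$bead_counts, bc_path)
    paths <- c(paths, bc_path)
  }
  invisible(paths)
}

#' Write a sample annotation table
#'
#' @param meta a [sample_meta()] table.
#' @param path output CSV path.
#' @export
write_sample_meta <- function(meta, path) {
  header <- "sample_id,group,plate,replicate"
  body <- paste(meta$sample_id, as.character(meta$group), meta$plate,
                ifelse(is.na(meta$replicate), "", meta$replicate),
                sep = ",")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Write the per-combination score table
#'
#' One row per transformation/normalization combination, ordered by
#' combination name, with the six criterion scores and the 0--12 total.
#'
#' @param scores data.frame as returned in `$scores` by [run_pipeline()]
#'   (columns `combo`, the six criteria, `total`, optionally `status`).
#' @param path output CSV path.
#' @export
write_scores <- function(scores, path) {
  cols <- c("combo", .criterion_names, "total")
  if ("status" %in% names(scores)) cols <- c(cols, "status")
  missing_cols <- setdiff(cols, names(scores))
  if (length(missing_cols))
    stop("scores table lacks columns: ", paste(missing_cols, collapse = ", "))
  scores <- scores[order(scores$combo), cols, drop = FALSE]
  header <- paste(cols, collapse = ",")
  fmt_cell <- function(v) {
    out <- as.character(v)
    out[is.na(v)] <- ""
    out
  }
  body <- if (nrow(scores) == 0) character(0) else
    do.call(paste, c(lapply(scores, fmt_cell), sep = ","))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

.criterion_names <- c("mean_sd", "bland_altman", "volcano",
                      "skewness", "tail", "cv")

#' Read / write reader-rating tables
#'
#' Ratings of the three plot criteria by blinded readers: one row per
#' (combo, criterion, round, reader), rating in \{0, 1, 2\}. Fifteen
#' readers and two rounds are expected by the aggregation rules.
#'
#' @param path CSV path.
#' @return data.frame with columns `combo`, `criterion`, `round`,
#'   `reader_id`, `rating`.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("combo", "criterion", "round", "reader_id", "rating")
  if (!all(need %in% names(df)))
    stop("ratings file must have columns: ", paste(need, collapse = ", "))
  if (!all(df$rating %in% 0:2)) stop("ratings must be 0, 1 or 2")
  if (!all(df$criterion %in% c("mean_sd", "bland_altman", "volcano")))
    stop("criterion must be one of mean_sd, bland_altman, volcano")
  df
}

#' @rdname read_ratings
#' @param ratings data.frame in the same layout.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
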