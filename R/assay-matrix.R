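#' Assay matrix container
#'
#' The central data structure of the package: a numeric analytes x samples
#' matrix of median fluorescence intensities (MFI) with `NA` encoding missing
#' readouts, optionally accompanied by a same-shaped matrix of per-well bead
#' counts, and a `scale_tag` recording where the object sits in the
#' pre-processing chain (`"raw"` -> `"transformed"` -> `"normalized"`).
#'
#' Rows are analytes (bead IDs, one coupled antigen each), columns are
#' samples. Row and column names are mandatory and must be unique; every
#' stage of the pipeline preserves them.
#'
#' @param values numeric matrix with unique rownames (analyte IDs) and
#'   colnames (sample IDs); `NA` marks missing cells.
#' @param bead_counts optional matrix of non-negative integer bead counts,
#'   same dimensions and dimnames as `values`.
#' @param scale_tag one of `"raw"`, `"transformed"`, `"normalized"`.
#' @return An object of class `assay_matrix`: a list with elements
#'   `values`, `bead_counts` and `scale_tag`.
#' @examples
#' m <- matrix(c(10, 20, 30, 40), 2, 2,
#'             dimnames = list(c("A1", "A2"), c("s1", "s2")))
#' am <- assay_matrix(m)
#' dim(am)
#' @export
assay_matrix <- function(values, bead_counts = NULL,
                         scale_tag = c("raw", "transformed", "normalized")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("'values' must have rownames (analyte IDs) and colnames (sample IDs)")
  if (nrow(values) == 0L && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate analyte IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.null(bead_counts)) {
    if (!is.matrix(bead_counts) || !all(dim(bead_counts) == dim(values)))
      stop("'bead_counts' must be a matrix with the same shape as 'values'")
    if (any(bead_counts < 0, na.rm = TRUE))
      stop("negative bead counts are not allowed")
    dimnames(bead_counts) <- dimnames(values)
    storage.mode(bead_counts) <- "integer"
  }
  structure(list(values = values, bead_counts = bead_counts,
                 scale_tag = scale_tag),
            class = "assay_matrix")
}

#' @export
dim.assay_matrix <- function(x) dim(x$values)

#' @export
print.assay_matrix <- function(x, ...) {
  cat(sprintf("assay_matrix: %d analytes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  cat(sprintf("  missing cells: %d; bead counts: %s\n",
              sum(is.na(x$values)),
              if (is.null(x$bead_counts)) "absent" else "present"))
  invisible(x)
}

#' @rdname assay_matrix
#' @param x an `assay_matrix`.
#' @export
analyte_ids <- function(x) rownames(x$values)

#' @rdname assay_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Sample annotation table
#'
#' Builds and validates the per-sample annotation used throughout the
#' pipeline: the biological group, the assay plate and (for reference-pool
#' measurements) a replicate index.
#'
#' @param sample_id character vector of sample IDs.
#' @param group character/factor with levels among
#'   `reference_pool`, `control`, `case_MS`, `case_NMO`.
#' @param plate plate identifier per sample.
#' @param replicate optional integer replicate index (reference pool).
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, group, plate, replicate = NA_integer_) {
  group <- as.character(group)
  bad <- setdiff(unique(group), .group_levels)
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.group_levels, collapse = ", "), ")")
  if (anyDuplicated(sample_id))
    stop("duplicate sample IDs in annotation: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  out <- data.frame(sample_id = as.character(sample_id),
                    group = factor(group, levels = .group_levels),
                    plate = plate,
                    replicate = as.integer(replicate),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

.group_levels <- c("reference_pool", "control", "case_MS", "case_NMO")

#' Check that a matrix and its annotation describe the same samples
#'
#' Errors (naming the offending IDs) when the sample sets of the matrix and
#' the annotation differ, or when the annotation carries duplicates.
#'
#' @param matrix an `assay_matrix`.
#' @param meta a `sample_meta` data.frame.
#' @return invisibly `TRUE`.
#' @export
validate_samples <- function(matrix, meta) {
  stopifnot(inherits(matrix, "assay_matrix"))
  ids <- sample_ids(matrix)
  missing_meta <- setdiff(ids, meta$sample_id)
  extra_meta <- setdiff(meta$sample_id, ids)
  if (length(missing_meta) || length(extra_meta))
    stop("sample sets of matrix and annotation differ; ",
         "missing from annotation: [",
         paste(missing_meta, collapse = ", "), "]; ",
         "absent from matrix: [",
         paste(extra_meta, collapse = ", "), "]")
  invisible(TRUE)
}

#' Reference-pool sample IDs
#'
#' Convenience accessor for the samples used by the repeatability criteria
#' (mean-SD, Bland-Altman, CV): the replicate measurements of the pooled
#' reference serum.
#'
#' @param meta a `sample_meta` data.frame.
#' @return character vector of sample IDs with group `reference_pool`.
#' @export
reference_sample_ids <- function(meta) {
  as.character(meta$sample_id[meta$group == "reference_pool"])
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
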