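#' Box-Cox power transformation
#'
#' The original Box-Cox map \eqn{y_t = (y^\lambda - 1)/\lambda} for
#' \eqn{\lambda \neq 0} and \eqn{y_t = \log y} for \eqn{\lambda = 0}
#' (natural log). Continuous in \eqn{\lambda} at 0.
#'
#' @param y positive numeric vector.
#' @param lambda the power parameter \eqn{\lambda}.
#' @return transformed values.
#' @examples
#' boxcox_transform(5, 1)        # 4
#' boxcox_transform(exp(1), 0)   # 1
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0, na.rm = TRUE))
    stop("boxcox_transform requires strictly positive values")
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' Weighted Box-Cox transformation
#'
#' The geometric-mean-weighted variant
#' \eqn{y_t = (y^\lambda - 1)/(\lambda \dot{y}^{\lambda - 1})} for
#' \eqn{\lambda \neq 0} and \eqn{y_t = \log(y)\,\dot{y}} for
#' \eqn{\lambda = 0}, where \eqn{\dot{y}} is the geometric mean of the
#' data. The weighting makes the transform scale-matched to the data, so
#' transformed values stay on a comparable magnitude across \eqn{\lambda}.
#' For `gmean = 1` it coincides with [boxcox_transform()].
#'
#' @param y positive numeric vector.
#' @param lambda the power parameter.
#' @param gmean positive geometric mean \eqn{\dot{y}}.
#' @return transformed values.
#' @export
boxcox_weighted_transform <- function(y, lambda, gmean) {
  if (any(y <= 0, na.rm = TRUE))
    stop("boxcox_weighted_transform requires strictly positive values")
  if (gmean <= 0) stop("'gmean' must be positive")
  if (lambda == 0) log(y) * gmean
  else (y^lambda - 1) / (lambda * gmean^(lambda - 1))
}

#' Profile-likelihood estimate of the Box-Cox parameter
#'
#' Maximizes the Box-Cox profile log-likelihood
#' \deqn{\ell(\lambda) = -\frac{n}{2}\log \hat\sigma^2_\lambda +
#'       (\lambda - 1)\sum \log y_i}
#' over a grid of candidate \eqn{\lambda}, where \eqn{\hat\sigma^2_\lambda}
#' is the maximum-likelihood variance of the transformed values. Ties are
#' broken toward the \eqn{\lambda} nearest 0, then the smallest.
#'
#' @param values positive numeric vector (missing values dropped);
#'   at least 3 observations required.
#' @param grid candidate \eqn{\lambda} values; default -2 to 2 in steps of
#'   0.01.
#' @return the selected \eqn{\lambda}.
#' @export
estimate_lambda <- function(values, grid = seq(-2, 2, by = 0.01)) {
  y <- values[!is.na(values)]
  if (!length(grid)) stop("'grid' must be non-empty")
  if (any(y <= 0)) stop("estimate_lambda requires strictly positive values")
  if (length(y) < 3L) stop("need at least 3 positive observed values")
  if (stats::sd(y) == 0) {
    warning("constant input; returning lambda = 1")
    return(1)
  }
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(grid, function(lam) {
    yt <- boxcox_transform(y, lam)
    v <- sum((yt - mean(yt))^2) / n
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * slog
  }, numeric(1))
  best <- max(ll)
  cand <- grid[ll >= best - 1e-9 * max(1, abs(best))]
  cand[order(abs(cand), cand)][1L]
}

#' Variance-stabilizing transformation from reference replicates
#'
#' A generalized-log surrogate \eqn{h(y) = \mathrm{asinh}(a + b\,y)} whose
#' strength is fitted from the replicate mean--variance trend: per-analyte
#' means and SDs over the reference-pool replicates are computed and the
#' line \eqn{SD \approx c_0 + c_1\,\mathrm{mean}} is fitted by robust
#' regression ([MASS::rlm()]); setting \eqn{b = c_1/c_0} (and \eqn{a = 0})
#' makes the transformed replicate SD approximately independent of the
#' mean (it equals \eqn{\approx c_1} at both ends of the intensity range).
#' With no mean dependence (\eqn{c_1 \le 0}) the map degenerates to a
#' nearly affine, rank-preserving function.
#'
#' @param matrix an [assay_matrix()].
#' @param reference_samples character vector of at least 2 reference-pool
#'   sample IDs present in the matrix.
#' @return list with `matrix` (transformed) and `params`
#'   (`a`, `b`, `c0`, `c1`).
#' @export
vst_transform <- function(matrix, reference_samples) {
  stopifnot(inherits(matrix, "assay_matrix"))
  refs <- intersect(reference_samples, sample_ids(matrix))
  if (length(refs) < 2L)
    stop("vst needs >= 2 reference replicate columns; available reference ",
         "samples in the matrix: [", paste(refs, collapse = ", "), "]")
  rv <- matrix$values[, refs, drop = FALSE]
  m <- rowMeans(rv, na.rm = TRUE)
  s <- apply(rv, 1L, stats::sd, na.rm = TRUE)
  ok <- is.finite(m) & is.finite(s)
  m <- m[ok]; s <- s[ok]
  if (!length(m)) stop("no analyte has >= 2 observed reference replicates")
  if (all(s == 0) || stats::sd(m) == 0) {
    c0 <- max(mean(s), 1e-8); c1 <- 0
  } else {
    fit <- tryCatch(MASS::rlm(s ~ m, maxit = 50),
                    error = function(e) stats::lm(s ~ m))
    c0 <- unname(stats::coef(fit)[1L])
    c1 <- unname(stats::coef(fit)[2L])
  }
  floor0 <- max(1e-8, 1e-3 * stats::median(s))
  c0_eff <- max(c0, floor0)
  b <- if (c1 > 0) c1 / c0_eff else 1e-6 / max(mean(abs(m)), 1)
  a <- 0
  vals <- matrix$values
  obs <- !is.na(vals)
  vals[obs] <- asinh(a + b * vals[obs])
  list(matrix = assay_matrix(vals, bead_counts = matrix$bead_counts,
                             scale_tag = "transformed"),
       params = list(a = a, b = b, c0 = c0, c1 = c1))
}

.transform_methods <- c("no", "log2", "asinh", "boxcox", "boxcoxweights",
                        "vst")

#' Apply a transformation to a QC'd assay matrix
#'
#' Element-wise map applied to the observed values only; missing cells stay
#' missing and the missing mask is never altered. All six methods are
#' strictly increasing on the positive reals, so within-sample ranks are
#' preserved. For the Box-Cox variants, \eqn{\lambda} is estimated by
#' [estimate_lambda()] on all observed values pooled (`lambda_scope =
#' "global"`, the default) or per analyte; the weighted variant uses the
#' geometric mean of the strictly positive observed values. `log2` and the
#' Box-Cox maps require all observed values to be positive, which QC
#' guarantees by masking nonpositive readouts.
#'
#' @param matrix an [assay_matrix()] with `scale_tag = "raw"`.
#' @param method one of `"no"`, `"log2"`, `"asinh"`, `"boxcox"`,
#'   `"boxcoxweights"`, `"vst"`.
#' @param lambda optional fixed \eqn{\lambda} (skips estimation).
#' @param lambda_grid candidate grid for [estimate_lambda()].
#' @param lambda_scope `"global"` (one \eqn{\lambda} for the dataset) or
#'   `"per_analyte"`.
#' @param reference_samples reference-pool sample IDs, required for
#'   `method = "vst"`.
#' @return list with `matrix` (`scale_tag = "transformed"`) and `params`
#'   (fitted parameters, reusable).
#' @export
transform_assay <- function(matrix, method = .transform_methods,
                            lambda = NULL,
                            lambda_grid = seq(-2, 2, by = 0.01),
                            lambda_scope = c("global", "per_analyte"),
                            reference_samples = NULL) {
  stopifnot(inherits(matrix, "assay_matrix"))
  method <- match.arg(method)
  lambda_scope <- match.arg(lambda_scope)
  if (matrix$scale_tag != "raw")
    stop("transform_assay expects a raw-scale matrix")
  vals <- matrix$values
  obs <- !is.na(vals)
  y <- vals[obs]
  needs_pos <- method %in% c("log2", "boxcox", "boxcoxweights")
  if (needs_pos && any(y <= 0))
    stop("non-positive value reached a log/power transform; ",
         "run qc_filter first (it masks values <= 0)")
  params <- list(method = method)
  if (method == "no") {
    # identity, but the matrix advances to the transformed stage
  } else if (method == "log2") {
    vals[obs] <- log2(y)
  } else if (method == "asinh") {
    vals[obs] <- asinh(y)
  } else if (method == "vst") {
    if (is.null(reference_samples))
      stop("method 'vst' requires 'reference_samples'")
    fit <- vst_transform(matrix, reference_samples)
    fit$params$method <- "vst"
    return(list(matrix = fit$matrix, params = fit$params))
  } else {
    gmean_of <- function(v) exp(mean(log(v)))
    if (lambda_scope == "global") {
      lam <- if (!is.null(lambda)) lambda else
        estimate_lambda(y, lambda_grid)
      if (method == "boxcox") {
        vals[obs] <- boxcox_transform(y, lam)
        params$lambda <- lam
      } else {
        gm <- gmean_of(y)
        vals[obs] <- boxcox_weighted_transform(y, lam, gm)
        params$lambda <- lam
        params$geometric_mean <- gm
      }
    } else {
      lam <- numeric(nrow(vals))
      gm <- numeric(nrow(vals))
      for (i in seq_len(nrow(vals))) {
        yi <- vals[i, !is.na(vals[i, ])]
        lam[i] <- if (!is.null(lambda)) lambda else
          estimate_lambda(yi, lambda_grid)
        if (method == "boxcox") {
          vals[i, !is.na(vals[i, ])] <- boxcox_transform(yi, lam[i])
        } else {
          gm[i] <- gmean_of(yi)
          vals[i, !is.na(vals[i, ])] <-
            boxcox_weighted_transform(yi, lam[i], gm[i])
        }
      }
      params$lambda <- lam
      if (method == "boxcoxweights") params$geometric_mean <- gm
    }
  }
  list(matrix = assay_matrix(vals, bead_counts = matrix$bead_counts,
                             scale_tag = "transformed"),
       params = params)
}
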