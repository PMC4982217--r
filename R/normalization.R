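.norm_methods <- c("loess", "global", "quantile", "quanimpr", "rsn",
                   "zscore", "vsn")

.as_values <- function(x) {
  if (inherits(x, "assay_matrix")) x$values
  else if (inherits(x, "norm_result")) x$matrix$values
  else if (is.matrix(x)) x
  else stop("expected an assay_matrix, norm_result or matrix")
}

.norm_result <- function(src, values, method, params) {
  bc <- if (inherits(src, "assay_matrix")) src$bead_counts else NULL
  structure(list(matrix = assay_matrix(values, bead_counts = bc,
                                       scale_tag = "normalized"),
                 method = method, params = params),
            class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat(sprintf("norm_result [%s]\n", x$method))
  print(x$matrix)
  invisible(x)
}

#' Between-sample normalization
#'
#' Dispatches to one of the seven normalization methods studied by the
#' benchmark. All methods preserve the matrix shape and labels and require
#' an imputed matrix (no missing cells); `vsn` additionally requires the
#' raw-scale pathway, because it carries its own built-in transformation
#' and is applied directly to the quality-controlled, imputed raw data.
#'
#' @param matrix an [assay_matrix()] without missing cells.
#' @param method one of `"loess"`, `"global"`, `"quantile"`, `"quanimpr"`,
#'   `"rsn"`, `"zscore"`, `"vsn"`.
#' @param seed integer seed, mandatory for `"quanimpr"` (dithering).
#' @param span loess span for `"loess"`.
#' @param knots number of quantile anchors for `"rsn"`.
#' @param dither_scale optional fixed dither width for `"quanimpr"`.
#' @return a `norm_result`: list with `matrix`
#'   (`scale_tag = "normalized"`), `method` and `params`.
#' @export
normalize_assay <- function(matrix, method = .norm_methods, seed = NULL,
                            span = 0.4, knots = 8, dither_scale = NULL) {
  stopifnot(inherits(matrix, "assay_matrix"))
  method <- match.arg(method)
  if (anyNA(matrix$values))
    stop("normalization requires an imputed matrix (no missing cells); ",
         "run impute_median first")
  if (method == "vsn" && matrix$scale_tag != "raw")
    stop("vsn carries its own transformation and must be applied to the ",
         "raw (quality-controlled, imputed) matrix, not to '",
         matrix$scale_tag, "' data")
  switch(method,
         loess = loess_normalize(matrix, span = span),
         global = global_median_normalize(matrix),
         quantile = quantile_normalize(matrix),
         quanimpr = improved_quantile_normalize(matrix, seed = seed,
                                                dither_scale = dither_scale),
         rsn = rsn_normalize(matrix, knots = knots),
         zscore = zscore_normalize(matrix),
         vsn = vsn_normalize(matrix))
}

# mean-across-columns of order statistics: the reference distribution
# shared by quantile, quanimpr and rsn
.quantile_reference <- function(X) {
  rowMeans(apply(X, 2L, sort))
}

#' Quantile normalization
#'
#' Replaces each column's sorted values by the mean across columns of the
#' order statistics, forcing all sample distributions to be identical.
#' Tied values receive the mean of the reference values their ranks span.
#'
#' @param matrix an [assay_matrix()] (or plain matrix) without missing
#'   cells.
#' @return a `norm_result`; `params$reference` holds the reference
#'   distribution (sorted).
#' @export
quantile_normalize <- function(matrix) {
  X <- .as_values(matrix)
  ref <- .quantile_reference(X)
  out <- X
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    v <- ref
    xs <- X[o, j]
    # ties: average the reference values spanned by each tie group
    v <- stats::ave(v, match(xs, xs))
    out[o, j] <- v
  }
  .norm_result(matrix, out, "quantile", list(reference = ref))
}

#' Dithered ("improved") quantile normalization
#'
#' Quantile normalization is sensitive to a few very strong signals: they
#' dominate the top order statistics of the reference distribution.
#' Borrowing from dithering in digital signal processing, uniform noise
#' \eqn{U(-d/2, d/2)} is added element-wise before quantile-normalizing,
#' with `d` per column defaulting to the smallest nonzero gap between
#' distinct values (the 1-LSB analogue). With `dither_scale = 0` the
#' result is exactly plain quantile normalization.
#'
#' @inheritParams quantile_normalize
#' @param seed mandatory integer seed for the dither noise.
#' @param dither_scale optional fixed dither width `d` (scalar); default
#'   is the per-column smallest nonzero gap.
#' @return a `norm_result`; `params` records `d` per column and the seed.
#' @export
improved_quantile_normalize <- function(matrix, seed, dither_scale = NULL) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory for the dithered quantile normalization")
  X <- .as_values(matrix)
  d <- if (!is.null(dither_scale)) rep(dither_scale, ncol(X)) else
    apply(X, 2L, function(x) {
      g <- diff(sort(unique(x)))
      if (length(g)) min(g) else 0
    })
  Xd <- with_seed(seed, {
    noise <- matrix(stats::runif(length(X), -0.5, 0.5), nrow(X), ncol(X))
    X + sweep(noise, 2L, d, `*`)
  })
  dimnames(Xd) <- dimnames(X)
  res <- quantile_normalize(Xd)
  .norm_result(matrix, res$matrix$values, "quanimpr",
               list(d = d, seed = seed,
                    reference = res$params$reference))
}

#' Loess (MA) normalization against a pseudo-reference
#'
#' The pseudo-reference is the per-analyte mean across samples. For each
#' sample, a locally weighted regression of \eqn{M = x - r} on
#' \eqn{A = (x + r)/2} is fitted and the fitted trend subtracted, removing
#' intensity-dependent bias of the sample relative to the reference.
#'
#' @inheritParams quantile_normalize
#' @param span loess span (fraction of points in each local fit).
#' @return a `norm_result`.
#' @export
loess_normalize <- function(matrix, span = 0.4) {
  X <- .as_values(matrix)
  r <- rowMeans(X)
  out <- X
  for (j in seq_len(ncol(X))) {
    M <- X[, j] - r
    A <- (X[, j] + r) / 2
    if (stats::sd(A) == 0 || stats::sd(M) == 0) {
      fitted_m <- rep(mean(M), length(M))
    } else {
      fit <- stats::loess(M ~ A, span = span, degree = 1,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      fitted_m <- stats::fitted(fit)
    }
    out[, j] <- X[, j] - fitted_m
  }
  .norm_result(matrix, out, "loess", list(span = span))
}

#' Global median normalization
#'
#' Location-only adjustment: each sample's median is subtracted and the
#' grand median of the pre-normalization sample medians added back, so all
#' sample medians coincide afterwards. Additive (not multiplicative)
#' matching, because the inputs are on a transformed scale.
#'
#' @inheritParams quantile_normalize
#' @return a `norm_result`; `params$medians` holds the per-sample medians.
#' @export
global_median_normalize <- function(matrix) {
  X <- .as_values(matrix)
  med <- apply(X, 2L, stats::median)
  grand <- stats::median(med)
  out <- sweep(X, 2L, med, `-`) + grand
  .norm_result(matrix, out, "global",
               list(medians = med, grand_median = grand))
}

#' Robust spline normalization
#'
#' Maps each sample's distribution onto the quantile-normalization
#' reference distribution through a monotone cubic spline fitted to `knots`
#' evenly spaced quantile anchor pairs (sample quantile -> reference
#' quantile), winsorized at the 1st/99th percentiles. Outside the anchor
#' range the map continues linearly with the boundary slope, so
#' monotonicity holds everywhere.
#'
#' @inheritParams quantile_normalize
#' @param knots number of quantile anchors (default 8).
#' @return a `norm_result`; `params$anchors` holds the per-sample anchor
#'   pairs.
#' @export
rsn_normalize <- function(matrix, knots = 8) {
  X <- .as_values(matrix)
  ref <- .quantile_reference(X)
  probs <- seq(0.01, 0.99, length.out = knots)
  yq <- stats::quantile(ref, probs, type = 7, names = FALSE)
  out <- X
  anchors <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    xq <- stats::quantile(X[, j], probs, type = 7, names = FALSE)
    keep <- !duplicated(xq)
    xk <- xq[keep]
    yk <- vapply(split(yq, cumsum(keep)), mean, numeric(1))
    if (length(xk) < 2L) {
      # (near-)constant sample: fall back to a pure shift
      out[, j] <- X[, j] - stats::median(X[, j]) + stats::median(ref)
      anchors[[j]] <- cbind(sample = xk, reference = yk)
      next
    }
    sf <- stats::splinefun(xk, yk, method = "monoH.FC")
    x <- X[, j]
    y <- numeric(length(x))
    lo <- x < xk[1L]; hi <- x > xk[length(xk)]
    mid <- !lo & !hi
    y[mid] <- sf(x[mid])
    sl_lo <- max(sf(xk[1L], deriv = 1), 0)
    sl_hi <- max(sf(xk[length(xk)], deriv = 1), 0)
    y[lo] <- yk[1L] + sl_lo * (x[lo] - xk[1L])
    y[hi] <- yk[length(yk)] + sl_hi * (x[hi] - xk[length(xk)])
    out[, j] <- y
    anchors[[j]] <- cbind(sample = xk, reference = yk)
  }
  names(anchors) <- colnames(X)
  .norm_result(matrix, out, "rsn",
               list(knots = knots, reference = ref, anchors = anchors))
}

#' Z-score normalization
#'
#' Per sample column: \eqn{(x - \bar{x}) / s}. Errors on constant columns
#' (zero SD).
#'
#' @inheritParams quantile_normalize
#' @return a `norm_result`; `params` holds per-sample means and SDs.
#' @export
zscore_normalize <- function(matrix) {
  X <- .as_values(matrix)
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  if (any(s == 0))
    stop("zscore normalization undefined for constant sample column(s): ",
         paste(colnames(X)[s == 0], collapse = ", "))
  out <- sweep(sweep(X, 2L, mu, `-`), 2L, s, `/`)
  .norm_result(matrix, out, "zscore", list(mean = mu, sd = s))
}

#' Variance-stabilizing normalization (vsn-type model)
#'
#' Fits, per sample, an affine calibration inside an arsinh transform,
#' \eqn{h_s(x) = \mathrm{asinh}(a_s + b_s x)} with \eqn{b_s > 0}, by
#' minimizing a robust least-trimmed-squares criterion of the deviations
#' of \eqn{h_s(x_{is})} from the per-analyte row means, with the Jacobian
#' term of the profile likelihood preventing the trivial collapse of all
#' scale factors. The calibration parameters are optimized jointly (BFGS
#' with analytic gradient, row means profiled out), alternating with
#' re-trimming of the analyte set until the trimmed set is stable or the
#' objective changes by less than `tol` (relative); failure to converge
#' within `max_iter` outer iterations is an error carrying the trace.
#' This is a simplified robust fit of the model class of the cited
#' microarray method, not a wrapper of it.
#'
#' @inheritParams quantile_normalize
#' @param lts_quantile fraction of analytes (smallest residuals) used in
#'   each fitting sweep.
#' @param tol relative convergence tolerance on the objective.
#' @param max_iter maximum number of coordinate sweeps.
#' @return a `norm_result`; `params` holds `a`, `b` per sample and the
#'   objective trace.
#' @export
vsn_normalize <- function(matrix, lts_quantile = 0.9, tol = 1e-6,
                          max_iter = 50L) {
  X <- .as_values(matrix)
  A <- nrow(X); S <- ncol(X)
  if (S < 2L) stop("vsn needs at least 2 samples")
  scale_s <- apply(X, 2L, function(x) {
    s <- stats::mad(x)
    if (s == 0) s <- stats::sd(x)
    max(s, 1e-8)
  })
  b <- 1 / scale_s
  a <- -apply(X, 2L, stats::median) * b

  # negative profile log-likelihood (row means profiled out) and its
  # analytic gradient in theta = (a_1..a_S, log b_1..log b_S), restricted
  # to the trimmed analyte set `keep`
  nll <- function(theta, keep) {
    a <- theta[seq_len(S)]
    b <- exp(theta[S + seq_len(S)])
    Xk <- X[keep, , drop = FALSE]
    Z <- sweep(sweep(Xk, 2L, b, `*`), 2L, a, `+`)
    H <- asinh(Z)
    R <- H - rowMeans(H)
    nk <- sum(keep)
    n_use <- nk * S
    rss <- max(sum(R^2), 1e-300)
    logjac <- nk * sum(log(b)) - 0.5 * sum(log1p(Z^2))
    n_use / 2 * log(rss / n_use) - logjac
  }
  nll_grad <- function(theta, keep) {
    a <- theta[seq_len(S)]
    b <- exp(theta[S + seq_len(S)])
    Xk <- X[keep, , drop = FALSE]
    Z <- sweep(sweep(Xk, 2L, b, `*`), 2L, a, `+`)
    H <- asinh(Z)
    R <- H - rowMeans(H)
    nk <- sum(keep)
    n_use <- nk * S
    rss <- max(sum(R^2), 1e-300)
    W <- 1 / (1 + Z^2)          # (h')^2; h' = 1/sqrt(1+z^2)
    Hp <- sqrt(W)
    # envelope theorem: gradient through the profiled row means vanishes
    dRSS_da <- 2 * colSums(R * Hp)
    dRSS_db <- 2 * colSums(R * Hp * Xk)
    dJ_da <- -colSums(Z * W)
    dJ_db <- nk / b - colSums(Z * W * Xk)
    g_a <- n_use / (2 * rss) * dRSS_da - dJ_da
    g_b <- (n_use / (2 * rss) * dRSS_db - dJ_db) * b  # chain rule, log b
    c(g_a, g_b)
  }

  theta <- c(a, log(b))
  trim_of <- function(theta) {
    a <- theta[seq_len(S)]
    b <- exp(theta[S + seq_len(S)])
    H <- asinh(sweep(sweep(X, 2L, b, `*`), 2L, a, `+`))
    rr <- rowSums((H - rowMeans(H))^2)
    rr <= stats::quantile(rr, lts_quantile, type = 7)
  }
  keep <- trim_of(theta)
  obj <- nll(theta, keep)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    opt <- stats::optim(theta, nll, gr = nll_grad, keep = keep,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    theta <- opt$par
    keep_new <- trim_of(theta)
    obj_new <- nll(theta, keep_new)
    trace <- c(trace, obj_new)
    if (identical(keep, keep_new) ||
        abs(obj - obj_new) <= tol * (1 + abs(obj_new))) {
      converged <- TRUE
      break
    }
    keep <- keep_new
    obj <- obj_new
  }
  if (!converged)
    stop("vsn did not converge within ", max_iter,
         " iterations; objective trace: ",
         paste(sprintf("%.6g", trace), collapse = ", "))
  a <- theta[seq_len(S)]
  b <- exp(theta[S + seq_len(S)])
  out <- asinh(sweep(sweep(X, 2L, b, `*`), 2L, a, `+`))
  dimnames(out) <- dimnames(X)
  .norm_result(matrix, out, "vsn",
               list(a = a, b = b, iterations = length(trace) - 1L,
                    objective_trace = trace))
}
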