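#' Quantile estimator
#'
#' Linear interpolation of order statistics (the default convention of the
#' R ecosystem the benchmark was computed in, `type = 7`). Fixed here so
#' that the threshold-sensitive skewness and tail-length scores are
#' reproducible; the convention is switchable via `type`.
#'
#' @param values numeric vector with at least 2 finite values.
#' @param q probabilities in \[0, 1\].
#' @param type quantile algorithm, passed to [stats::quantile()].
#' @return estimated quantiles (unnamed).
#' @export
quantile_est <- function(values, q, type = 7) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least 2 finite values")
  stats::quantile(v, q, type = type, names = FALSE)
}

#' Quantile-based skewness
#'
#' \deqn{\log S = \log\frac{\tilde{x}_{0.975} - \tilde{x}_{0.5}}
#'                         {\tilde{x}_{0.5} - \tilde{x}_{0.025}}}
#' Zero for symmetric distributions, negative for left skew, positive for
#' right skew. Undefined (returned as `NA` with a warning) when either
#' quantile difference is non-positive.
#'
#' @param values numeric vector.
#' @return the statistic \eqn{\log S} (natural log).
#' @export
skewness_logS <- function(values) {
  qs <- quantile_est(values, c(0.025, 0.5, 0.975))
  num <- qs[3L] - qs[2L]
  den <- qs[2L] - qs[1L]
  if (den <= 0 || num <= 0) {
    warning("log S undefined: non-positive quantile difference")
    return(NA_real_)
  }
  log(num / den)
}

#' Quantile-based tail length
#'
#' \deqn{T = \frac{\tilde{x}_{0.975} - \tilde{x}_{0.025}}
#'                {\tilde{x}_{0.875} - \tilde{x}_{0.125}}}
#' Takes values between 1 and infinity; the longer the tails, the larger
#' \eqn{T}. The standard normal distribution has \eqn{T = 1.704}.
#'
#' @param values numeric vector.
#' @return the statistic \eqn{T}, or `NA` with a warning when the central
#'   quantile range is zero.
#' @export
tail_length_T <- function(values) {
  qs <- quantile_est(values, c(0.025, 0.125, 0.875, 0.975))
  den <- qs[3L] - qs[2L]
  if (den <= 0) {
    warning("T undefined: zero central quantile range")
    return(NA_real_)
  }
  (qs[4L] - qs[1L]) / den
}

#' Population tail length from a quantile function
#'
#' Evaluates the tail-length statistic on exact population quantiles,
#' e.g. `population_tail_length(qnorm)` gives the normal-distribution
#' value 1.704.
#'
#' @param qfun quantile function, e.g. [stats::qnorm()].
#' @param ... passed on to `qfun`.
#' @return the population value of \eqn{T}.
#' @export
population_tail_length <- function(qfun = stats::qnorm, ...) {
  (qfun(0.975, ...) - qfun(0.025, ...)) /
    (qfun(0.875, ...) - qfun(0.125, ...))
}

#' Score the skewness statistic
#'
#' Almost symmetric (score 2) when \eqn{-0.5 < \log S < 0.5}; score 0 when
#' \eqn{|\log S| > 0.75}; score 1 otherwise.
#'
#' @param log_S the statistic from [skewness_logS()]; vectorized.
#' @return integer score(s) in \{0, 1, 2\} (`NA` propagates).
#' @export
score_skewness <- function(log_S) {
  ifelse(is.na(log_S), NA_integer_,
         ifelse(abs(log_S) < 0.5, 2L,
                ifelse(abs(log_S) <= 0.75, 1L, 0L)))
}

#' Score the tail-length statistic
#'
#' Good (2) when \eqn{1.625 < T < 2}; poor (0) when \eqn{T \le 1.525} or
#' \eqn{T \ge 2.1} (boundaries inclusive); fair (1) otherwise.
#'
#' @param T the statistic from [tail_length_T()]; vectorized.
#' @return integer score(s) in \{0, 1, 2\} (`NA` propagates).
#' @export
score_tail <- function(T) {
  ifelse(is.na(T), NA_integer_,
         ifelse(T > 1.625 & T < 2, 2L,
                ifelse(T <= 1.525 | T >= 2.1, 0L, 1L)))
}

#' Score the CV rank-sum percentage
#'
#' @param cv_sp the percentage \eqn{CV_{s,p}}; vectorized.
#' @return 2 if \eqn{CV_{s,p} \le 50}, 1 if \eqn{\le 80}, else 0.
#' @export
score_cv <- function(cv_sp) {
  ifelse(is.na(cv_sp), NA_integer_,
         ifelse(cv_sp <= 50, 2L, ifelse(cv_sp <= 80, 1L, 0L)))
}

#' Rank-sum repeatability score across pre-processing combinations
#'
#' For each combination, the coefficient of variation (SD / |mean| over the
#' reference-pool replicates) is computed per analyte; CVs are then ranked
#' per analyte across combinations (smallest first, ties averaged) and the
#' ranks summed per combination (\eqn{CV_s}). The smallest possible
#' \eqn{CV_s} equals the number of analytes \eqn{A}, the largest
#' \eqn{A \cdot M} for \eqn{M} combinations; the percentage form is
#' \eqn{CV_{s,p} = 100 \cdot CV_s / (A M)}, scored by [score_cv()].
#' Analytes whose |mean| falls below `mean_tol` in any combination are
#' excluded from the ranking for all combinations symmetrically.
#'
#' @param matrices named list of `assay_matrix`/`norm_result` objects, one
#'   per combination, with a common analyte set.
#' @param reference_samples >= 2 reference-pool sample IDs.
#' @param mean_tol threshold below which a per-analyte |mean| makes the CV
#'   undefined.
#' @return data.frame (one row per combination): `combo`, `cv_s`, `cv_sp`,
#'   `score`; attribute `dropped_analytes` lists exclusions, attribute
#'   `cv` holds the analyte x combination CV matrix used.
#' @export
cv_rank_score <- function(matrices, reference_samples, mean_tol = 1e-12) {
  if (is.null(names(matrices)) || any(names(matrices) == ""))
    stop("'matrices' must be a named list (one name per combination)")
  M <- length(matrices)
  vlist <- lapply(matrices, .as_values)
  ids <- rownames(vlist[[1L]])
  for (v in vlist)
    if (!identical(rownames(v), ids))
      stop("all combinations must share the same analyte set")
  cvm <- vapply(vlist, function(v) {
    refs <- intersect(reference_samples, colnames(v))
    if (length(refs) < 2L)
      stop("cv_rank_score needs >= 2 reference replicate columns; found ",
           length(refs))
    rv <- v[, refs, drop = FALSE]
    m <- rowMeans(rv)
    s <- apply(rv, 1L, stats::sd)
    ifelse(abs(m) < mean_tol, NA_real_, s / abs(m))
  }, numeric(length(ids)))
  cvm <- matrix(cvm, nrow = length(ids),
                dimnames = list(ids, names(matrices)))
  bad <- rowSums(is.na(cvm)) > 0L
  if (any(bad))
    message("dropping ", sum(bad),
            " analyte(s) with |mean| < mean_tol from the CV ranking: ",
            paste(utils::head(ids[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "")
  use <- cvm[!bad, , drop = FALSE]
  A <- nrow(use)
  if (A == 0L) stop("no analyte with a defined CV in all combinations")
  ranks <- t(apply(use, 1L, rank, ties.method = "average"))
  if (M == 1L) ranks <- matrix(ranks, ncol = 1L)
  cv_s <- colSums(ranks)
  cv_sp <- 100 * cv_s / (A * M)
  out <- data.frame(combo = names(matrices), cv_s = unname(cv_s),
                    cv_sp = unname(cv_sp),
                    score = score_cv(unname(cv_sp)),
                    stringsAsFactors = FALSE)
  attr(out, "dropped_analytes") <- ids[bad]
  attr(out, "cv") <- cvm
  attr(out, "n_analytes_used") <- A
  out
}

#' Mean-SD statistics over the reference replicates
#'
#' Per-analyte mean and SD over the reference-pool replicates, ordered by
#' the rank of the mean, with a locally weighted trend of SD on
#' rank(mean). In a homoscedastic (well pre-processed) dataset the trend
#' is flat; a rising trend or funnel indicates variance that depends on
#' signal magnitude.
#'
#' @param matrix an `assay_matrix`/`norm_result`.
#' @param reference_samples >= 2 reference-pool sample IDs.
#' @param trend_span loess span of the trend curve.
#' @return list with `stats` (data.frame `analyte_id`, `mean`, `sd`,
#'   `rank_mean`), `trend` (fitted SD at each rank) and `spearman`
#'   (rank correlation of mean and SD; 0 when SD is constant).
#' @export
mean_sd_stats <- function(matrix, reference_samples, trend_span = 0.75) {
  v <- .as_values(matrix)
  refs <- intersect(reference_samples, colnames(v))
  if (length(refs) < 2L)
    stop("mean_sd_stats needs >= 2 reference replicate columns; the ",
         "matrix contains ", length(refs), " of them")
  rv <- v[, refs, drop = FALSE]
  m <- rowMeans(rv)
  s <- apply(rv, 1L, stats::sd)
  rk <- rank(m, ties.method = "average")
  df <- data.frame(analyte_id = rownames(v), mean = m, sd = s,
                   rank_mean = rk, stringsAsFactors = FALSE)
  df <- df[order(df$rank_mean), ]
  trend <- if (stats::sd(s) == 0 || nrow(df) < 10L)
    rep(mean(s), nrow(df))
  else stats::fitted(stats::loess(sd ~ rank_mean, data = df,
                                  span = trend_span, degree = 1))
  rho <- if (stats::sd(s) == 0 || stats::sd(m) == 0) 0 else
    stats::cor(m, s, method = "spearman")
  list(stats = df, trend = data.frame(rank_mean = df$rank_mean,
                                      sd_fitted = trend),
       spearman = rho)
}

#' Bland-Altman pairs of the reference replicates
#'
#' All pairs of the reference replicate measurements (66 pairs for 12
#' replicates), per analyte, in the canonical orientation earlier minus
#' later replicate. Summarized by the mean difference and the 95 % limits
#' of agreement (mean +/- 1.96 SD).
#'
#' @inheritParams mean_sd_stats
#' @return list with `pairs` (data.frame `analyte_id`, `rep_a`, `rep_b`,
#'   `mean`, `diff`), `mean_diff`, `sd_diff`, `lower`, `upper`.
#' @export
bland_altman_pairs <- function(matrix, reference_samples) {
  v <- .as_values(matrix)
  refs <- intersect(reference_samples, colnames(v))
  if (length(refs) < 2L)
    stop("bland_altman_pairs needs >= 2 reference replicate columns; the ",
         "matrix contains ", length(refs), " of them")
  cmb <- utils::combn(length(refs), 2L)
  pieces <- lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1L, k]; j <- cmb[2L, k]
    data.frame(analyte_id = rownames(v),
               rep_a = refs[i], rep_b = refs[j],
               mean = (v[, refs[i]] + v[, refs[j]]) / 2,
               diff = v[, refs[i]] - v[, refs[j]],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pieces)
  rownames(pairs) <- NULL
  md <- mean(pairs$diff)
  sdd <- stats::sd(pairs$diff)
  list(pairs = pairs, mean_diff = md, sd_diff = sdd,
       lower = md - 1.96 * sdd, upper = md + 1.96 * sdd)
}

# Midrank Wilcoxon rank-sum machinery -------------------------------------

#' Wilcoxon rank-sum test with rank-based relative effect
#'
#' Two-sided Wilcoxon rank-sum test of `a` versus `b` plus the
#' nonparametric relative effect
#' \eqn{\hat{p} = (\bar{R}_b - (n_b + 1)/2)/n_a}, the rank-based estimate
#' of \eqn{P(A < B) + \frac12 P(A = B)} (midranks for ties). On tie-free
#' data \eqn{\hat{p} = U_b/(n_a n_b)} exactly. For tie-free samples with
#' both group sizes below 50 the p-value is computed from the exact null
#' distribution of \eqn{U}; otherwise the normal approximation with
#' midrank tie correction and continuity correction is used (the
#' convention of the software the benchmark was computed with).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact p-value;
#'   default `NULL` selects it automatically as described.
#' @return list with `U` (statistic of group b), `relative_effect`,
#'   `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both groups need >= 2 observations")
  r <- rank(c(a, b), ties.method = "average")
  rb <- r[(na + 1L):(na + nb)]
  U <- sum(rb) - nb * (nb + 1) / 2
  p_hat <- (mean(rb) - (nb + 1) / 2) / na
  ties <- table(c(a, b))
  has_ties <- any(ties > 1L)
  use_exact <- if (is.null(exact)) !has_ties && na < 50L && nb < 50L
  else isTRUE(exact)
  if (use_exact && has_ties)
    stop("exact p-value is not defined with ties")
  if (use_exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, nb, na),
                        1 - stats::pwilcox(U - 1, nb, na)))
    method <- "exact"
  } else {
    N <- na + nb
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approximation"
  }
  list(U = U, relative_effect = p_hat, p_value = min(1, p), method = method)
}

#' Per-analyte volcano statistics (cases versus controls)
#'
#' For every analyte, the two-sided Wilcoxon rank-sum p-value of group b
#' (cases) versus group a (controls) and the rank-based relative effect
#' \eqn{\hat{p}}, the nonparametric stand-in for a fold change. Under
#' exchangeability \eqn{\hat{p} = 0.5}; values toward 0 or 1 indicate
#' stochastically smaller or larger case intensities. Plotted as
#' \eqn{-\log_{10} p} against \eqn{\hat{p}} the points form a funnel,
#' because both axes derive from the same rank sums.
#'
#' @param matrix an `assay_matrix`/`norm_result`.
#' @param group_a_samples,group_b_samples sample IDs of the two groups
#'   (>= 2 each).
#' @param exact see [wilcoxon_rank_sum()].
#' @return data.frame: `analyte_id`, `relative_effect`, `p_value`,
#'   `minus_log10_p`.
#' @export
volcano_stats <- function(matrix, group_a_samples, group_b_samples,
                          exact = NULL) {
  v <- .as_values(matrix)
  ga <- intersect(group_a_samples, colnames(v))
  gb <- intersect(group_b_samples, colnames(v))
  if (length(ga) < 2L || length(gb) < 2L)
    stop("both groups need >= 2 samples present in the matrix (got ",
         length(ga), " and ", length(gb), ")")
  res <- lapply(seq_len(nrow(v)), function(i)
    wilcoxon_rank_sum(v[i, ga], v[i, gb], exact = exact))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  data.frame(analyte_id = rownames(v),
             relative_effect = vapply(res, `[[`, numeric(1),
                                      "relative_effect"),
             p_value = p,
             minus_log10_p = -log10(p),
             stringsAsFactors = FALSE)
}

#' QQ diagnostic: Mann-Whitney statistics of random case-group splits
#'
#' Randomly splits one case group into two equally sized halves, computes
#' the per-analyte Mann-Whitney U statistic between the halves and
#' standardizes it by the null mean \eqn{n_1 n_2/2} and the tie-corrected
#' null SD. Repeating `n_reps` times and pooling all standardized
#' statistics over analytes and replications gives an empirical null
#' sample: after good pre-processing its quantiles track the standard
#' normal closely. An odd-sized group is trimmed by one randomly chosen
#' sample per replication.
#'
#' @param matrix an `assay_matrix`/`norm_result`.
#' @param case_group_samples sample IDs of the case group to split.
#' @param n_reps number of random splits (default 25).
#' @param seed mandatory integer seed.
#' @return list with `qq` (data.frame `theoretical`, `empirical`, both
#'   sorted) and `slope` (IQR ratio of empirical to theoretical; 1 under
#'   the null).
#' @export
qq_mannwhitney <- function(matrix, case_group_samples, n_reps = 25,
                           seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  v <- .as_values(matrix)
  cases <- intersect(case_group_samples, colnames(v))
  if (length(cases) < 4L)
    stop("need at least 4 case samples to split into two groups")
  with_seed(seed, {
    z_all <- numeric(0)
    m <- length(cases)
    m_use <- if (m %% 2L == 0L) m else m - 1L
    half <- m_use / 2L
    for (r in seq_len(n_reps)) {
      perm <- sample(cases, m_use)
      g1 <- perm[seq_len(half)]
      g2 <- perm[(half + 1L):m_use]
      z <- apply(v, 1L, function(x) {
        rk <- rank(c(x[g1], x[g2]), ties.method = "average")
        U <- sum(rk[(half + 1L):m_use]) - half * (half + 1) / 2
        N <- m_use
        ties <- table(c(x[g1], x[g2]))
        tie_term <- sum(ties^3 - ties) / (N * (N - 1))
        s2 <- half * half / 12 * ((N + 1) - tie_term)
        if (s2 <= 0) NA_real_ else (U - half * half / 2) / sqrt(s2)
      })
      z_all <- c(z_all, z[!is.na(z)])
    }
    z_all <- sort(z_all)
    theo <- stats::qnorm(stats::ppoints(length(z_all)))
    slope <- (stats::quantile(z_all, 0.75, names = FALSE) -
                stats::quantile(z_all, 0.25, names = FALSE)) /
      (stats::qnorm(0.75) - stats::qnorm(0.25))
    list(qq = data.frame(theoretical = theo, empirical = z_all),
         slope = slope)
  })
}

#' Aggregate blinded-reader ratings for one plot
#'
#' Fifteen readers rate a plot 0 (poor), 1 (fair) or 2 (good); the sum of
#' the ratings (0--30) is classified as good (2) for 21--30, fair (1) for
#' 11--20 and poor (0) otherwise. Totals use the first of the two rating
#' rounds.
#'
#' @param ratings integer vector of exactly 15 ratings in \{0, 1, 2\}.
#' @return list with `sum` (0--30) and `class` (0, 1 or 2).
#' @export
aggregate_reader_scores <- function(ratings) {
  if (length(ratings) != 15L)
    stop("exactly 15 ratings expected, got ", length(ratings))
  if (!all(ratings %in% 0:2)) stop("ratings must be 0, 1 or 2")
  s <- sum(ratings)
  cls <- if (s >= 21L) 2L else if (s >= 11L) 1L else 0L
  list(sum = s, class = cls)
}

#' Intra-rater reliability between rating rounds
#'
#' Pearson correlation between the per-combination totals of the two
#' rating rounds.
#'
#' @param round1_totals,round2_totals numeric vectors of equal length.
#' @return the correlation coefficient.
#' @export
intra_rater_reliability <- function(round1_totals, round2_totals) {
  if (length(round1_totals) != length(round2_totals))
    stop("the two rounds must have the same number of totals")
  stats::cor(round1_totals, round2_totals)
}

#' Automated surrogate rating of the three plot criteria
#'
#' A deterministic, threshold-based stand-in for the blinded human
#' readers, calibrated to the written rating instructions. It is *not* the
#' canonical rating path -- when reader ratings are supplied they always
#' take precedence -- but it makes the benchmark runnable unattended.
#' \describe{
#'   \item{mean_sd}{flat trend is good: |Spearman(mean, SD)| < 0.1 -> 2,
#'     < 0.3 -> 1, else 0.}
#'   \item{bland_altman}{funnel (|Spearman(|diff|, mean)| >= 0.3) -> 0;
#'     otherwise good when the mean difference is small relative to the
#'     width of the limits of agreement (< 0.05) and there is no trend
#'     (|Spearman(mean, diff)| < 0.1); else 1.}
#'   \item{volcano}{side-length ratio of the funnel, min/max of the
#'     largest \eqn{-\log_{10} p} on either side of relative effect 0.5:
#'     >= 0.5 -> 2, >= 0.2 -> 1, else 0.}
#' }
#'
#' @param criterion `"mean_sd"`, `"bland_altman"` or `"volcano"`.
#' @param statistics the output of [mean_sd_stats()],
#'   [bland_altman_pairs()] or [volcano_stats()] respectively.
#' @param thresholds named list overriding any of the defaults
#'   `mean_sd_good`, `mean_sd_fair`, `ba_funnel`, `ba_trend`,
#'   `ba_mean_ratio`, `volcano_good`, `volcano_fair`.
#' @return integer class 0, 1 or 2.
#' @export
auto_rate_plot <- function(criterion = c("mean_sd", "bland_altman",
                                         "volcano"),
                           statistics, thresholds = list()) {
  criterion <- match.arg(criterion)
  th <- utils::modifyList(list(mean_sd_good = 0.1, mean_sd_fair = 0.3,
                               ba_funnel = 0.3, ba_trend = 0.1,
                               ba_mean_ratio = 0.05,
                               volcano_good = 0.5, volcano_fair = 0.2),
                          thresholds)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y, method = "spearman")
  }
  if (criterion == "mean_sd") {
    rho <- abs(statistics$spearman)
    return(if (rho < th$mean_sd_good) 2L
           else if (rho < th$mean_sd_fair) 1L else 0L)
  }
  if (criterion == "bland_altman") {
    p <- statistics$pairs
    funnel <- abs(safe_cor(abs(p$diff), p$mean))
    if (funnel >= th$ba_funnel) return(0L)
    trend <- abs(safe_cor(p$mean, p$diff))
    width <- statistics$upper - statistics$lower
    ratio <- if (width > 0) abs(statistics$mean_diff) / width
    else if (abs(statistics$mean_diff) == 0) 0 else Inf
    return(if (ratio < th$ba_mean_ratio && trend < th$ba_trend) 2L else 1L)
  }
  # volcano: compare funnel side lengths
  left <- statistics$minus_log10_p[statistics$relative_effect < 0.5]
  right <- statistics$minus_log10_p[statistics$relative_effect > 0.5]
  if (!length(left) || !length(right)) return(0L)
  side <- c(max(left), max(right))
  if (max(side) <= 0) return(0L)
  ratio <- min(side) / max(side)
  if (ratio >= th$volcano_good) 2L
  else if (ratio >= th$volcano_fair) 1L else 0L
}

#' Total quality score
#'
#' Sum of the six criterion scores (each 0--2), giving a total between 0
#' and 12 per pre-processing combination.
#'
#' @param scores numeric vector (or one-row data.frame/list) of the six
#'   criterion scores.
#' @return integer total in 0--12 (`NA` if any score is missing).
#' @export
total_score <- function(scores) {
  s <- unlist(scores, use.names = FALSE)
  if (length(s) != 6L) stop("expected exactly 6 criterion scores")
  if (anyNA(s)) return(NA_integer_)
  if (!all(s %in% 0:2)) stop("criterion scores must be 0, 1 or 2")
  as.integer(sum(s))
}
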