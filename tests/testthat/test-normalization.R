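trans_am <- function(m) make_am(m, scale_tag = "transformed")

test_that("quantile normalization: definition, ties, oracle agreement", {
  # hand-computed order-statistic means
  m <- trans_am(matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  out <- quantile_normalize(m)$matrix$values
  expect_equal(unname(out), matrix(c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5), 3, 2))
  # identical columns unchanged
  m2 <- trans_am(matrix(c(5, 1, 9, 5, 1, 9), 3, 2))
  expect_equal(quantile_normalize(m2)$matrix$values, m2$values)
  # all-tied column: every cell gets the reference mean
  m3 <- trans_am(matrix(c(7, 7, 7, 1, 2, 3), 3, 2))
  out3 <- quantile_normalize(m3)$matrix$values
  ref <- rowMeans(apply(m3$values, 2, sort))
  expect_equal(unname(out3[, 1]), rep(mean(ref), 3))
  # columns share identical sorted values afterwards
  set.seed(4)
  m4 <- trans_am(matrix(rnorm(200), 40, 5))
  out4 <- quantile_normalize(m4)$matrix$values
  sorted <- apply(out4, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)], ignore_attr = TRUE)
  # within-column ranks unchanged
  expect_equal(apply(out4, 2, rank), apply(m4$values, 2, rank))
  # independent oracle on tie-free data
  expect_equal(unname(out4), unname(limma::normalizeQuantiles(m4$values)))
})

test_that("dithered quantile normalization", {
  set.seed(9)
  m <- trans_am(matrix(rnorm(120), 30, 4))
  plain <- quantile_normalize(m)$matrix$values
  # zero dither reproduces plain quantile normalization
  expect_equal(improved_quantile_normalize(m, seed = 5,
                                           dither_scale = 0)$matrix$values,
               plain)
  # same seed -> identical, different seed -> different
  a <- improved_quantile_normalize(m, seed = 5)
  b <- improved_quantile_normalize(m, seed = 5)
  c <- improved_quantile_normalize(m, seed = 6)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_false(identical(a$matrix$values, c$matrix$values))
  expect_error(improved_quantile_normalize(m, seed = NULL), "seed")
  # one extreme outlier: reference maximum moves by at most d
  mo <- trans_am(cbind(c(1, 2, 3, 1000), c(1.1, 2.1, 2.9, 3.5)))
  d <- 0.5
  q1 <- max(quantile_normalize(mo)$params$reference)
  q2 <- max(improved_quantile_normalize(mo, seed = 1,
                                        dither_scale = d)$params$reference)
  expect_lte(abs(q1 - q2), d)
})

test_that("loess normalization removes offsets and intensity-dependent bias", {
  base <- seq(4, 10, length.out = 50)
  # identical columns: output equals input (M == 0)
  mi <- trans_am(cbind(base, base, base))
  expect_equal(loess_normalize(mi)$matrix$values, mi$values,
               tolerance = 1e-10)
  # constant offset: column pulled back onto the pseudo-reference
  ms <- trans_am(cbind(base, base, base + 3))
  out <- loess_normalize(ms)$matrix$values
  r <- rowMeans(ms$values)
  expect_equal(unname(out[, 3]), unname(r), tolerance = 1e-6)
  # intensity-dependent bow (bias proportional to intensity) is flattened
  set.seed(8)
  noisy <- function() base + rnorm(50, 0, 0.05)
  X <- cbind(noisy(), noisy(), noisy() * 1.1)
  mb <- trans_am(X)
  r0 <- rowMeans(X)
  rho_pre <- cor(X[, 3] - r0, (X[, 3] + r0) / 2, method = "spearman")
  expect_gt(abs(rho_pre), 0.8)
  outb <- loess_normalize(mb)$matrix$values
  M_post <- outb[, 3] - r0
  A_post <- (outb[, 3] + r0) / 2
  expect_lt(abs(cor(M_post, A_post, method = "spearman")), 0.3)
})

test_that("global median normalization equalizes sample medians", {
  set.seed(2)
  m <- trans_am(matrix(rnorm(60, 10), 15, 4) +
                  rep(c(0, 2, -1, 5), each = 15))
  out <- global_median_normalize(m)
  med <- apply(m$values, 2, median)
  expect_equal(unname(apply(out$matrix$values, 2, median)),
               rep(median(med), 4))
  # single sample unchanged
  m1 <- trans_am(matrix(c(1, 5, 9), 3, 1))
  expect_equal(global_median_normalize(m1)$matrix$values, m1$values)
  # two samples offset by a constant: offset removed
  m2 <- trans_am(cbind(c(1, 2, 3), c(4, 5, 6)))
  out2 <- global_median_normalize(m2)$matrix$values
  expect_equal(unname(out2[, 1]), unname(out2[, 2]))
})

test_that("robust spline normalization maps onto the reference", {
  set.seed(10)
  base <- sort(rnorm(100, 10, 2))
  # all columns identical: each equals the reference -> identity
  mi <- trans_am(cbind(base, base, base))
  expect_equal(rsn_normalize(mi)$matrix$values, mi$values,
               tolerance = 1e-8)
  # affine-shifted sample recovered at interior quantiles
  ms <- trans_am(cbind(base, base + 4))
  out <- rsn_normalize(ms)$matrix$values
  ref <- rowMeans(apply(ms$values, 2, sort))
  inner <- 10:90
  expect_equal(sort(out[, 2])[inner], ref[inner], tolerance = 1e-3,
               ignore_attr = TRUE)
  # monotone input stays monotone
  set.seed(11)
  mm <- trans_am(matrix(rnorm(300, 5), 75, 4))
  outm <- rsn_normalize(mm)$matrix$values
  for (j in 1:4)
    expect_equal(rank(outm[, j]), rank(mm$values[, j]))
})

test_that("z-score normalization standardizes each sample", {
  set.seed(6)
  m <- trans_am(matrix(rnorm(80, 3, 2), 20, 4))
  out <- zscore_normalize(m)$matrix$values
  expect_equal(unname(colMeans(out)), rep(0, 4))
  expect_equal(unname(apply(out, 2, sd)), rep(1, 4))
  two <- zscore_normalize(trans_am(cbind(c(1, 3), c(2, 8))))$matrix$values
  expect_true(all(two[1, ] < 0) && all(two[2, ] > 0))
  const <- trans_am(cbind(c(1, 1), c(2, 8)))
  expect_error(zscore_normalize(const), "constant")
})

test_that("vsn: symmetry, scale recovery and variance stabilization", {
  set.seed(15)
  base <- exp(rnorm(150, 6, 1))
  noise <- function() matrix(exp(rnorm(150 * 6, 0, 0.1)), 150, 6)
  X <- base * noise()
  X[, 6] <- X[, 6] * 2          # sample 6 measured at twice the scale
  m <- make_am(X, scale_tag = "raw")
  res <- vsn_normalize(m)
  b <- unname(res$params$b)
  expect_equal(b[6] / mean(b[1:5]), 0.5, tolerance = 0.05)
  # identical columns: equal parameters, identical output columns
  Xi <- matrix(rep(base, 4), 150, 4)
  mi <- make_am(Xi, scale_tag = "raw")
  resi <- vsn_normalize(mi)
  expect_equal(max(resi$params$b) / min(resi$params$b), 1,
               tolerance = 1e-4)
  expect_equal(resi$matrix$values[, 1], resi$matrix$values[, 4],
               ignore_attr = TRUE, tolerance = 1e-6)
  # multiplicative noise: replicate SD-vs-mean slope shrinks toward 0
  slope_of <- function(v) {
    mu <- rowMeans(v); s <- apply(v, 1, sd)
    unname(coef(lm(s ~ mu))[2] * mean(mu) / mean(s))  # scale-free slope
  }
  expect_lt(abs(slope_of(res$matrix$values[, 1:5])),
            abs(slope_of(X[, 1:5])))
  # vsn on transformed data is refused
  expect_error(normalize_assay(trans_am(X), "vsn"), "raw")
})

test_that("all methods preserve shape and labels; exact idempotence for
           quantile/global/zscore", {
  sim <- small_sim(frac_missing = 0, frac_nonpositive = 0)
  tr <- transform_assay(sim$matrix, "log2")$matrix
  for (method in c("loess", "global", "quantile", "quanimpr", "rsn",
                   "zscore")) {
    res <- normalize_assay(tr, method, seed = 7)
    expect_identical(dim(res$matrix$values), dim(tr$values))
    expect_identical(dimnames(res$matrix$values), dimnames(tr$values))
    expect_identical(res$matrix$scale_tag, "normalized")
  }
  for (method in c("quantile", "global", "zscore")) {
    once <- normalize_assay(tr, method)$matrix
    twice <- normalize_assay(once, method)$matrix
    expect_lt(max(abs(twice$values - once$values)), 1e-6)
  }
  # missing cells are refused
  holey <- tr
  holey$values[1, 1] <- NA
  expect_error(normalize_assay(holey, "quantile"), "imputed")
})
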