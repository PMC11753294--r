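# Differential expression: sample QC, balancing, normalization, dispersion
# and the NB likelihood-ratio test.

test_that("sample_qc keeps identical samples and drops a permuted one", {
  m <- matrix(rep(rpois(200, 50), 4), ncol = 4)
  cm <- make_cm(m)
  out <- sample_qc(cm)
  expect_equal(ncol(out$counts), 4)
  expect_length(attr(out, "removed"), 0)

  set.seed(1)
  base <- rpois(300, 100) * rep(c(1, 5, 25), each = 100)
  m <- sapply(1:4, function(i) pmax(0L, base + rpois(300, 10) - 10))
  m[, 4] <- sample(m[, 4])   # destroy the correlation of sample 4
  cm <- make_cm(m)
  # oracle: explicit correlation matrix on log2(count + 1)
  r <- cor(log2(m + 1))
  expect_true(all(r[4, -4] < 0.8))
  out <- sample_qc(cm)
  expect_identical(attr(out, "removed"), "s04")
  expect_equal(colnames(out$counts), c("s01", "s02", "s03"))
})

test_that("sample_qc with a vacuous threshold returns the input unchanged", {
  m <- matrix(rpois(40, 20), ncol = 4)
  cm <- make_cm(m)
  out <- sample_qc(cm, min_correlation = 0)
  expect_identical(out$counts, cm$counts)
})

test_that("balance_groups subsamples the larger group reproducibly", {
  m <- matrix(rpois(80, 30), ncol = 8)
  cm <- make_cm(m, group = c(rep("case", 5), rep("control", 3)))
  bal <- balance_groups(cm, seed = 2)
  expect_equal(as.vector(table(bal$meta$group)), c(3, 3))
  bal2 <- balance_groups(cm, seed = 2)
  expect_identical(colnames(bal$counts), colnames(bal2$counts))
  # already balanced: unchanged
  cm_even <- make_cm(m, group = rep(c("case", "control"), each = 4))
  expect_identical(balance_groups(cm_even, seed = 1), cm_even)
  # missing condition errors
  cm_one <- make_cm(m, group = rep("case", 8))
  expect_error(balance_groups(cm_one), "case and control")
})

test_that("size factors recover exact scalings and match the direct formula", {
  m <- matrix(rpois(100, 100) + 1, ncol = 2)
  m[, 2] <- 2L * m[, 1]
  sf <- size_factors(make_cm(m))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  m_same <- matrix(rep(rpois(50, 80) + 1, 3), ncol = 3)
  expect_equal(unname(size_factors(make_cm(m_same))), rep(1, 3),
               tolerance = 1e-12)

  set.seed(7)
  m <- matrix(rnbinom(600, mu = 100, size = 5), ncol = 6)
  m[m == 0] <- 1L
  sf <- size_factors(make_cm(m))
  # oracle: median-of-ratios computed independently, loop per sample
  ref <- exp(rowMeans(log(m)))
  raw <- vapply(seq_len(ncol(m)), function(j) median(m[, j] / ref), numeric(1))
  expect_equal(unname(sf), raw / exp(mean(log(raw))), tolerance = 1e-12)
})

test_that("size factors agree with the reference median-of-ratios code", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  # odd gene count so the median ratio is a single order statistic and the
  # log-median and plain-median conventions coincide
  m <- matrix(rnbinom(505, mu = 200, size = 10) + 1L, ncol = 5,
              dimnames = list(sprintf("g%03d", 1:101), sprintf("s%d", 1:5)))
  sf <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ratio <- unname(sf) / unname(ref)
  expect_equal(ratio, rep(ratio[1], 5), tolerance = 1e-10)
})

test_that("no all-positive gene triggers the pseudo-reference advice", {
  m <- matrix(c(0L, 5L, 5L, 0L), ncol = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(m), "pseudo-reference")
})

test_that("moment dispersion estimates are calibrated", {
  set.seed(11)
  n <- 200
  # Poisson gene: alpha -> 0
  y_pois <- matrix(rpois(2 * n, 100), nrow = 1)
  cm <- make_cm(rbind(y_pois, y_pois + 0L),
                group = rep(c("case", "control"), each = n))
  a <- estimate_dispersion(cm, sf = rep(1, 2 * n))
  expect_lt(a[1], 0.02)
  # constant gene: floored
  cm_const <- make_cm(matrix(5L, 2, 8), group = rep(c("case", "control"), 4))
  a_const <- estimate_dispersion(cm_const, sf = rep(1, 8))
  expect_equal(unname(a_const), rep(1e-8, 2))
  # NB alpha = 0.5
  y_nb <- matrix(rnbinom(2 * n, mu = 100, size = 2), nrow = 1)
  cm_nb <- make_cm(rbind(y_nb, y_nb), group = rep(c("case", "control"), each = n))
  a_nb <- estimate_dispersion(cm_nb, sf = rep(1, 2 * n))
  expect_gt(a_nb[1], 0.3)
  expect_lt(a_nb[1], 0.7)
})

test_that("nb_lrt gives null results for equal group means", {
  m <- matrix(rep(c(40L, 40L), each = 5), nrow = 1,
              dimnames = list("g1", sprintf("s%02d", 1:10)))
  m <- rbind(g1 = rep(40L, 10), g2 = rep(25L, 10))
  cm <- make_cm(m, group = rep(c("case", "control"), each = 5))
  res <- nb_lrt(cm, sf = rep(1, 10), alpha = 0.1)
  expect_true(all(abs(res$stat) < 1e-6))
  expect_true(all(res$pvalue > 0.99))
})

test_that("nb_lrt matches a fixed-dispersion GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(13)
  n <- 8
  alpha <- 0.15
  mu <- rep(c(100, 260), each = n)
  y <- matrix(rnbinom(10 * 2 * n, mu = mu, size = 1 / alpha), nrow = 10,
              byrow = TRUE,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:(2 * n))))
  grp <- rep(c("case", "control"), each = n)
  cm <- make_cm(y, group = grp)
  sf <- rep(1, 2 * n)
  names(sf) <- colnames(y)
  res <- nb_lrt(cm, sf = sf, alpha = alpha)
  x <- as.numeric(grp == "case")
  for (i in 1:10) {
    fit_full <- suppressWarnings(
      stats::glm(y[i, ] ~ x, family = MASS::negative.binomial(theta = 1 / alpha)))
    fit_red <- suppressWarnings(
      stats::glm(y[i, ] ~ 1, family = MASS::negative.binomial(theta = 1 / alpha)))
    expect_equal(res$log2fc[i], unname(coef(fit_full)[2]) / log(2),
                 tolerance = 1e-4)
    lr_ref <- as.numeric(2 * (logLik(fit_full) - logLik(fit_red)))
    expect_equal(res$stat[i], lr_ref, tolerance = 1e-4)
  }
})

test_that("results are invariant to the size-factor scale and sample order", {
  set.seed(17)
  y <- matrix(rnbinom(40 * 12, mu = 150, size = 10), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:12)))
  grp <- rep(c("case", "control"), each = 6)
  sf <- exp(rnorm(12, 0, 0.2)); names(sf) <- colnames(y)
  res1 <- nb_lrt(make_cm(y, group = grp), sf = sf, alpha = 0.1)
  # a global rescaling of all size factors is absorbed by the intercept
  res2 <- nb_lrt(make_cm(y, group = grp), sf = sf * 7, alpha = 0.1)
  expect_equal(res1$log2fc, res2$log2fc, tolerance = 1e-6)
  expect_equal(res1$pvalue, res2$pvalue, tolerance = 1e-6)
  # reordering samples (with their size factors) changes nothing
  perm <- sample(12)
  res3 <- nb_lrt(make_cm(y[, perm], group = grp[perm]), sf = sf[perm],
                 alpha = 0.1)
  expect_equal(res3$log2fc, res1$log2fc, tolerance = 1e-8)
  expect_equal(res3$pvalue, res1$pvalue, tolerance = 1e-8)
  # in the Poisson limit with unit factors the estimate is the closed-form
  # ratio of group means
  sf1 <- rep(1, 12); names(sf1) <- colnames(y)
  res4 <- nb_lrt(make_cm(y, group = grp), sf = sf1, alpha = 1e-8)
  expect_equal(res4$log2fc[1], log2(mean(y[1, 1:6]) / mean(y[1, 7:12])),
               tolerance = 1e-6)
})

test_that("planted fold changes are recovered with direction and size", {
  set.seed(19)
  n <- 10; n_genes <- 150; alpha <- 0.05
  mu0 <- exp(runif(n_genes, log(80), log(400)))
  mu <- cbind(matrix(mu0 * 4, n_genes, n), matrix(mu0, n_genes, n))
  y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:(2 * n))))
  cm <- make_cm(y, group = rep(c("case", "control"), each = n))
  sf <- rep(1, 2 * n); names(sf) <- colnames(y)
  res <- nb_lrt(cm, sf = sf, alpha = alpha)
  ok <- res$pvalue < 0.01 & abs(res$log2fc - 2) < 0.5
  expect_gte(mean(ok), 0.9)
  expect_true(all(res$stat >= -1e-6))
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(23)
  y <- matrix(rnbinom(100 * 8, mu = 100, size = 10), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:8)))
  res <- nb_lrt(make_cm(y, group = rep(c("case", "control"), each = 4)))
  ord <- order(res$pvalue)
  expect_true(all(diff(res$padj[ord]) >= -1e-12))
  expect_true(all(res$padj >= res$pvalue - 1e-12))
})
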