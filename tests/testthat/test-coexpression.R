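# Expression preprocessing, soft-threshold selection, signed network / TOM
# construction, module detection, eigengenes and module-trait correlation.

test_that("low-count filter applies the per-dataset rule", {
  m1 <- matrix(20L, 4, 6); m2 <- matrix(20L, 4, 4)
  rownames(m1) <- rownames(m2) <- sprintf("g%d", 1:4)
  m1[1, ] <- 0L                      # all-zero everywhere: removed
  m2[2, 1:3] <- 5L                   # low in 3/4 samples of dataset 2: removed
  m1[3, 1:3] <- 5L                   # low in exactly half of dataset 1: kept
  cms <- list(make_cm(m1, dataset = "d1"), make_cm(m2, dataset = "d2"))
  expect_identical(low_count_filter(cms), c("g3", "g4"))

  set.seed(63)
  m <- matrix(rnbinom(50 * 8, mu = 25, size = 2), 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  got <- low_count_filter(list(make_cm(m)), min_count = 15, frac = 0.5)
  want <- rownames(m)[rowMeans(m < 15) <= 0.5]   # direct counting oracle
  expect_identical(got, want)
})

test_that("the variance-stabilizing transform has its closed-form values", {
  m <- matrix(c(0L, 3L, 6L, 0L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- make_cm(m)
  v1 <- vst_transform(cm, sf = c(s1 = 1, s2 = 2))
  expect_equal(v1["g1", "s1"], 0)
  expect_equal(v1["g2", "s1"], 2)            # log2(3/1 + 1)
  expect_equal(v1["g2", "s2"], log2(0 + 1))
  # doubling count and size factor together changes nothing
  v2 <- vst_transform(make_cm(m * 2L), sf = c(s1 = 2, s2 = 4))
  expect_equal(v1, v2)
})

test_that("batch adjustment removes planted offsets but keeps the condition effect", {
  set.seed(67)
  n_genes <- 300; n <- 10
  base <- matrix(rnorm(n_genes * 4 * n, 8, 2), n_genes)
  rownames(base) <- sprintf("g%03d", 1:n_genes)
  colnames(base) <- sprintf("s%02d", 1:(4 * n))
  batch <- rep(c("b1", "b2"), each = 2 * n)
  group <- rep(rep(c("case", "control"), each = n), 2)
  offsets <- rnorm(n_genes, 0, 1.5)
  de_genes <- 1:30
  x <- base
  x[, batch == "b2"] <- x[, batch == "b2"] + offsets
  x[de_genes, group == "case"] <- x[de_genes, group == "case"] + 2
  adj <- batch_adjust(x, batch, group)
  gap <- function(m) rowMeans(m[, batch == "b2"]) - rowMeans(m[, batch == "b1"])
  expect_lt(mean(abs(gap(adj))), 0.2 * mean(abs(gap(x))))
  de_gap <- function(m) mean(rowMeans(m[de_genes, group == "case"]) -
                               rowMeans(m[de_genes, group == "control"]))
  expect_lt(abs(de_gap(adj) - de_gap(x)) / abs(de_gap(x)), 0.2)
  # single batch: identity
  expect_identical(batch_adjust(x, rep("b1", ncol(x)), group), x)
})

test_that("the scale-free fit statistic equals an independent binned regression", {
  set.seed(71)
  expr <- matrix(rnorm(40 * 20), 40,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:20)))
  expr[1:15, ] <- expr[1:15, ] + matrix(rnorm(20, 0, 2), 15, 20, byrow = TRUE)
  beta <- suppressWarnings(pick_soft_threshold(expr, powers = c(2, 4, 6)))
  tab <- attr(beta, "fit_table")
  r <- cor(t(expr))
  for (row in seq_len(nrow(tab))) {
    b <- tab$power[row]
    a <- ((1 + r) / 2)^b
    diag(a) <- 0
    k <- rowSums(a)
    cuts <- cut(k, 10)
    freq <- tapply(k, cuts, length)
    km <- tapply(k, cuts, mean)
    ok <- !is.na(freq) & freq > 0 & km > 0
    fit <- lm(log10(freq[ok]) ~ log10(km[ok]))
    want <- summary(fit)$r.squared * (-sign(coef(fit)[2]))
    expect_equal(tab$fit[row], unname(want), tolerance = 1e-10)
  }
  expect_error(pick_soft_threshold(expr[1:10, ]), ">= 30")
})

test_that("degenerate correlation values force the adjacency extremes", {
  s <- seq_len(10)
  expr <- rbind(g1 = s, g2 = 2 * s + 3, g3 = -s + 20)  # r(1,2)=1, r(1,3)=-1
  colnames(expr) <- sprintf("s%02d", 1:10)
  net <- build_network(expr[1:2, ], beta = 6)
  expect_equal(unname(net$adjacency[1, 2]), 1)
  expect_equal(unname(net$tom[1, 2]), 1)
  expect_equal(unname(net$diss[1, 2]), 0)
  net3 <- build_network(expr, beta = 6)
  expect_equal(unname(net3$adjacency["g1", "g3"]), 0)
  expect_error(build_network(rbind(expr, g4 = rep(1, 10)), 6), "g4")
})

test_that("TOM equals the brute-force triple loop and stays in [0, 1]", {
  set.seed(73)
  for (i in 1:3) {
    expr <- matrix(rnorm(12 * 15), 12,
                   dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:15)))
    net <- build_network(expr, beta = sample(3:9, 1))
    want <- oracle_tom(net$adjacency)
    expect_lt(max(abs(net$tom - want)), 1e-10)
    expect_true(all(net$tom >= 0 & net$tom <= 1))
  }
})

test_that("adjacency decreases in beta for imperfect correlations", {
  set.seed(79)
  expr <- matrix(rnorm(10 * 12), 10,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:12)))
  a1 <- build_network(expr, 2)$adjacency
  a2 <- build_network(expr, 5)$adjacency
  off <- lower.tri(a1)
  expect_true(all(a2[off] <= a1[off] + 1e-12))
})

test_that("planted correlation blocks are recovered as modules", {
  set.seed(83)
  n <- 40
  mk_block <- function(size, factor_sd = 1) {
    f <- rnorm(n)
    matrix(rep(f, size), size, byrow = TRUE) * factor_sd +
      matrix(rnorm(size * n, 0, 0.45), size)
  }
  expr <- rbind(mk_block(50), mk_block(60))
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  colnames(expr) <- sprintf("s%02d", seq_len(n))
  truth <- rep(1:2, c(50, 60))
  net <- build_network(expr, beta = 6)
  labels <- detect_modules(net, expr, min_module_size = 20)
  expect_equal(length(setdiff(unique(labels), 0L)), 2)
  expect_equal(adjusted_rand_index(labels, truth), 1)
  # gene order invariance (up to labels): permute the input genes
  perm <- sample(nrow(expr))
  net_p <- build_network(expr[perm, ], beta = 6)
  labels_p <- detect_modules(net_p, expr[perm, ], min_module_size = 20)
  expect_equal(adjusted_rand_index(labels_p[rownames(expr)], labels), 1)
})

test_that("modules driven by one factor are merged by the eigengene rule", {
  set.seed(89)
  n <- 40
  f <- rnorm(n)
  block <- function(size, noise) matrix(rep(f, size), size, byrow = TRUE) +
    matrix(rnorm(size * n, 0, noise), size)
  expr <- rbind(block(40, 0.3), block(40, 0.6))
  rownames(expr) <- sprintf("g%03d", 1:80)
  colnames(expr) <- sprintf("s%02d", 1:n)
  net <- build_network(expr, beta = 6)
  labels <- detect_modules(net, expr, min_module_size = 20, merge_height = 0.25)
  expect_equal(length(setdiff(unique(labels), 0L)), 1)
})

test_that("pure noise yields no coherent modules", {
  set.seed(97)
  expr <- matrix(rnorm(200 * 30), 200,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:30)))
  net <- build_network(expr, beta = 12)
  labels <- detect_modules(net, expr, min_module_size = 30)
  if (any(labels > 0)) {
    me <- module_eigengenes(expr, labels)
    expect_true(all(me$var_explained < 0.5))
  } else {
    expect_true(all(labels == 0))
  }
})

test_that("eigengenes summarize modules as their first principal component", {
  n <- 20
  profile <- rnorm(n)
  expr <- matrix(rep(profile, 5), 5, byrow = TRUE,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:n)))
  labels <- setNames(rep(1L, 5), rownames(expr))
  me <- module_eigengenes(expr, labels)
  expect_equal(abs(cor(me$eigengenes[, 1], profile)), 1, tolerance = 1e-10)
  expect_equal(unname(me$kme[, 1]), rep(1, 5), tolerance = 1e-10)
  expect_equal(sum(me$eigengenes[, 1]^2), 1, tolerance = 1e-10)

  # flipping all member genes leaves the oriented eigengene's kME positive
  me_flip <- module_eigengenes(-expr, labels)
  expect_gt(mean(me_flip$kme[, 1]), 0)

  # variance along the eigengene beats random unit directions
  set.seed(101)
  expr2 <- matrix(rnorm(30 * 25), 30,
                  dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:25)))
  expr2[1:15, ] <- expr2[1:15, ] + matrix(rnorm(25), 15, 25, byrow = TRUE)
  lab2 <- setNames(rep(c(1L, 0L), each = 15), rownames(expr2))
  me2 <- module_eigengenes(expr2, lab2)
  xs <- t(scale(t(expr2[1:15, ])))
  v_var <- sum((xs %*% me2$eigengenes[, 1])^2)
  for (i in 1:100) {
    u <- rnorm(25); u <- u / sqrt(sum(u^2))
    expect_lte(sum((xs %*% u)^2), v_var + 1e-8)
  }
})

test_that("module-trait correlation matches the explicit t-test", {
  set.seed(103)
  n <- 30
  expr <- matrix(rnorm(40 * n), 40,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:n)))
  trait <- rep(c(1, 0), each = n / 2)
  expr[1:20, ] <- expr[1:20, ] + matrix(rep(trait * 2, 20), 20, byrow = TRUE)
  labels <- setNames(rep(c(1L, 2L), each = 20), rownames(expr))
  me <- module_eigengenes(expr, labels)
  mt <- module_trait_correlation(me, trait)
  for (i in 1:2) {
    ref <- cor.test(me$eigengenes[, i], trait)
    expect_equal(mt$r[i], unname(ref$estimate), tolerance = 1e-10)
    expect_equal(mt$pvalue[i], ref$p.value, tolerance = 1e-10)
  }
  expect_true(mt$significant[1])
  # consistent permutation of samples leaves r unchanged
  perm <- sample(n)
  me_perm <- me
  me_perm$eigengenes <- me$eigengenes[perm, , drop = FALSE]
  mt_perm <- module_trait_correlation(me_perm, trait[perm])
  expect_equal(mt_perm$r, mt$r, tolerance = 1e-12)
  expect_error(module_trait_correlation(me, rep(1, n)), "constant")
})

test_that("an eigengene equal to the trait correlates perfectly", {
  n <- 16
  trait <- rep(c(1, 0), each = n / 2)
  profile <- trait - mean(trait)
  expr <- matrix(rep(profile, 4), 4, byrow = TRUE,
                 dimnames = list(sprintf("g%d", 1:4), sprintf("s%02d", 1:n)))
  expr <- expr + matrix(rnorm(4 * n, 0, 1e-6), 4)
  me <- module_eigengenes(expr, setNames(rep(1L, 4), rownames(expr)))
  mt <- module_trait_correlation(me, trait)
  expect_equal(abs(mt$r), 1, tolerance = 1e-4)
})
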