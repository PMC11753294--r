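# Signed weighted co-expression networks: expression preprocessing
# (low-count filter, variance stabilization, batch adjustment), soft
# threshold selection against scale-free topology, signed adjacency and
# topological overlap, module detection by average-linkage clustering of the
# TOM dissimilarity with eigengene-based merging, module eigengenes/kME, and
# module-trait correlation.

#' Filter genes with low counts in their original dataset
#'
#' A gene is removed if, in any one of its original datasets, its count falls
#' below `min_count` in more than `frac` of that dataset's samples; it is
#' retained otherwise. Applying the rule per original dataset keeps genes
#' that are reliably measured everywhere they were assayed.
#'
#' @param cms List of [count_matrix()] objects, one per original dataset.
#' @param min_count Count threshold.
#' @param frac Maximum tolerated fraction of below-threshold samples.
#' @return Character vector of retained gene ids.
#' @export
low_count_filter <- function(cms, min_count = 15, frac = 0.5) {
  genes <- rownames(cms[[1]]$counts)
  bad <- rep(FALSE, length(genes))
  for (cm in cms) {
    m <- cm$counts[genes, , drop = FALSE]
    frac_low <- rowMeans(m < min_count)
    bad <- bad | frac_low > frac
  }
  genes[!bad]
}

#' Variance-stabilizing transform (log2 of normalized counts)
#'
#' `log2(count / sizefactor + 1)` per entry: a monotone variance-stabilizing
#' transform of normalized counts used upstream of the correlation-based
#' network construction, where the downstream statistics depend on ranks and
#' linear association rather than the exact variance function.
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors.
#' @return Numeric matrix, genes x samples.
#' @export
vst_transform <- function(cm, sf = size_factors(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  log2(sweep(cm$counts, 2, sf, "/") + 1)
}

#' Empirical-Bayes batch adjustment on the transformed scale
#'
#' Removes additive/multiplicative dataset (batch) effects from a
#' variance-stabilized expression matrix by ComBat-style empirical-Bayes
#' location/scale adjustment, protecting the case/control contrast as a
#' model covariate so planted condition effects survive. A single batch is
#' returned unchanged; batches with a single sample are adjusted in
#' mean-only mode.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param batch Factor/character of batch (dataset) labels per sample.
#' @param group Factor/character of case/control labels per sample, kept as
#'   a covariate.
#' @return Adjusted matrix of the same shape.
#' @export
batch_adjust <- function(expr, batch, group = NULL) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) return(expr)
  mod <- NULL
  if (!is.null(group) && length(unique(group)) >= 2L) {
    mod <- stats::model.matrix(~ as.factor(group))
  }
  mean_only <- any(table(batch) < 2L)
  # constant genes break the EB scale step; pass-through and restore
  keep <- apply(expr, 1, stats::sd) > 0
  out <- expr
  adj <- NULL
  invisible(utils::capture.output(
    adj <- sva::ComBat(dat = expr[keep, , drop = FALSE], batch = batch,
                       mod = mod, mean.only = mean_only, prior.plots = FALSE),
    type = "message"))
  out[keep, ] <- adj
  out
}

# Signed adjacency from a correlation matrix: ((1 + r) / 2)^beta, diagonal 1.
signed_adjacency <- function(r, beta) {
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

#' Soft-threshold selection for scale-free topology
#'
#' For each candidate power, computes the signed adjacency, each gene's
#' connectivity `k_i = sum_{j != i} a_ij`, bins `k` into 10 intervals, and
#' regresses `log10(frequency)` on `log10(mean k)` per bin; the fit index is
#' `R^2 * (-sign(slope))`. Returns the smallest power whose fit reaches
#' `target_r2`, or the power maximizing the fit (with a warning) if none
#' does.
#'
#' @param expr Numeric matrix, genes x samples (>= 30 genes).
#' @param powers Candidate powers.
#' @param target_r2 Scale-free fit target.
#' @return Integer power, with attribute `"fit_table"` (power, fit,
#'   mean connectivity).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_r2 = 0.8) {
  if (nrow(expr) < 30L) stop("need >= 30 genes", call. = FALSE)
  if (any(apply(expr, 1, stats::sd) == 0)) {
    stop("constant gene expression: correlations undefined", call. = FALSE)
  }
  r <- stats::cor(t(expr))
  base <- (1 + r) / 2
  diag(base) <- 0   # exclude self from connectivity
  fits <- vapply(powers, function(beta) {
    k <- rowSums(base^beta)
    scale_free_fit(k)
  }, numeric(1))
  mean_k <- vapply(powers, function(beta) mean(rowSums(base^beta)), numeric(1))
  tab <- data.frame(power = powers, fit = fits, mean_connectivity = mean_k)
  ok <- which(fits >= target_r2)
  beta <- if (length(ok)) powers[min(ok)] else {
    warning(sprintf("no power reached fit %.2f; using the best (%.3f at %d)",
                    target_r2, max(fits), powers[which.max(fits)]))
    powers[which.max(fits)]
  }
  attr(beta, "fit_table") <- tab
  beta
}

# Signed scale-free fit index for a connectivity vector: R^2 of the binned
# log-log degree-distribution regression times -sign(slope).
scale_free_fit <- function(k, n_bins = 10) {
  cuts <- cut(k, n_bins)
  freq <- tapply(k, cuts, length)
  kmean <- tapply(k, cuts, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  x <- log10(kmean[keep]); y <- log10(freq[keep])
  if (length(x) < 3L || stats::sd(x) == 0) return(0)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  r2 * (-sign(stats::coef(fit)[2]))
}

#' Build a signed co-expression network
#'
#' Computes the gene-gene Pearson correlation matrix across samples, raises
#' the signed similarity `((1 + r) / 2)` to the power `beta` to obtain the
#' adjacency, and converts it to the topological overlap matrix
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `dissTOM = 1 - TOM` is the module-detection distance.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param beta Soft-threshold power (>= 1).
#' @return Object of class `coex_network`: list with `genes`, `beta`, `cor`,
#'   `adjacency`, `tom`, `diss`.
#' @export
build_network <- function(expr, beta) {
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(t(expr))
  a <- signed_adjacency(r, beta)
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a          # removes u = i and u = j terms (diag(a) = 1)
  min_k <- outer(k, k, pmin)
  tom <- (l + a) / (min_k + 1 - a)
  diag(tom) <- 1
  tom[tom > 1] <- 1             # guard against rounding spill
  structure(list(genes = rownames(expr), beta = beta, cor = r,
                 adjacency = a, tom = tom, diss = 1 - tom),
            class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("<coex_network> %d genes, beta = %s\n",
              length(x$genes), format(x$beta)))
  invisible(x)
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity; initial
#' modules are dendrogram branches below a static cut at dissimilarity
#' `cut_height` with at least `min_module_size` members (smaller branches
#' are unassigned, label 0); modules whose eigengene dissimilarity
#' `1 - cor(ME_i, ME_j)` falls below `merge_height` are then merged
#' iteratively until stable. Labels are renumbered 1..K by decreasing size.
#' The default cut of 0.96 exploits that unconnected or weakly chained
#' branches merge at TOM dissimilarities close to 1 (typically above 0.98),
#' while genuinely co-expressed branches complete well below 0.95.
#'
#' @param network A `coex_network`.
#' @param expr The expression matrix used to build it (needed for eigengene
#'   merging).
#' @param min_module_size Minimum branch size to form a module.
#' @param merge_height Eigengene dissimilarity below which modules merge.
#' @param cut_height Static tree-cut height on the TOM dissimilarity scale.
#' @return Named integer vector gene -> module label (0 = unassigned), with
#'   the dendrogram attached as attribute `"hclust"`.
#' @export
detect_modules <- function(network, expr, min_module_size = 30,
                           merge_height = 0.25, cut_height = 0.96) {
  stopifnot(inherits(network, "coex_network"))
  genes <- network$genes
  if (length(genes) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    labels <- setNames(integer(length(genes)), genes)
    return(labels)
  }
  h <- stats::hclust(stats::as.dist(network$diss), method = "average")
  cut_height <- min(cut_height, max(h$height) - .Machine$double.eps)
  branches <- stats::cutree(h, h = cut_height)
  sizes <- table(branches)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(genes))
  for (i in seq_along(big)) {
    labels[branches == as.integer(big[i])] <- i
  }
  names(labels) <- genes
  labels <- renumber_by_size(labels)
  # eigengene-based merging
  repeat {
    mods <- setdiff(sort(unique(labels)), 0L)
    if (length(mods) < 2L) break
    me <- module_eigengenes(expr, labels)$eigengenes
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    if (min(d) >= merge_height) break
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    m_from <- mods[max(idx)]; m_to <- mods[min(idx)]
    labels[labels == m_from] <- m_to
    labels <- renumber_by_size(labels)
  }
  attr(labels, "hclust") <- h
  labels
}

# Relabel modules 1..K by decreasing size (ties by first occurrence),
# keeping 0 as the unassigned label.
renumber_by_size <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sizes, match(mods, labels))]
  new <- labels
  for (i in seq_along(ord)) new[labels == ord[i]] <- i
  attributes(new) <- attributes(labels)
  new
}

#' Module eigengenes and module membership (kME)
#'
#' Per module, standardizes member genes across samples and takes the first
#' right singular vector of the member x sample matrix as the per-sample
#' eigengene (unit norm, the first principal component of the module's
#' expression), sign-aligned so the mean member kME is positive. kME is
#' computed for all genes against every module eigengene.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Named gene -> module labels (0 ignored).
#' @return Object of class `module_eigengenes`: list with `eigengenes`
#'   (samples x modules matrix, columns `ME<k>`), `kme` (genes x modules),
#'   `var_explained` (per module).
#' @export
module_eigengenes <- function(expr, labels) {
  labels <- labels[rownames(expr)]
  mods <- setdiff(sort(unique(labels)), 0L)
  if (!length(mods)) stop("no modules to summarize", call. = FALSE)
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  var_expl <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    x <- expr[members, , drop = FALSE]
    xs <- t(scale(t(x)))                     # standardize genes across samples
    xs[is.na(xs)] <- 0
    if (nrow(xs) == 1L) {
      v <- as.numeric(xs)
      v <- v / sqrt(sum(v^2))
      me[, i] <- v
      var_expl[i] <- 1
    } else {
      sv <- svd(xs, nu = 0, nv = 1)
      v <- sv$v[, 1]
      me[, i] <- v
      var_expl[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    mean_kme <- mean(stats::cor(t(expr[members, , drop = FALSE]), me[, i]))
    if (is.finite(mean_kme) && mean_kme < 0) me[, i] <- -me[, i]
  }
  kme <- suppressWarnings(stats::cor(t(expr), me))
  kme[is.na(kme)] <- 0
  structure(list(eigengenes = me, kme = kme, var_explained = var_expl),
            class = "module_eigengenes")
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and a binary per-sample
#' trait, with the p-value from the t-distribution with n - 2 degrees of
#' freedom; modules with p < 0.05 are flagged as significantly correlated.
#'
#' @param me A `module_eigengenes` object.
#' @param trait Numeric/logical 0-1 vector, one value per sample.
#' @param p_threshold Significance threshold.
#' @return Data frame: `module`, `r`, `pvalue`, `significant`.
#' @export
module_trait_correlation <- function(me, trait, p_threshold = 0.05) {
  trait <- as.numeric(trait)
  if (length(trait) != nrow(me$eigengenes)) {
    stop("trait length must equal the sample count", call. = FALSE)
  }
  if (stats::sd(trait) == 0) stop("constant trait", call. = FALSE)
  n <- length(trait)
  r <- as.numeric(stats::cor(me$eigengenes, trait))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(module = colnames(me$eigengenes), r = r, pvalue = p,
             significant = p < p_threshold, stringsAsFactors = FALSE,
             row.names = NULL)
}
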