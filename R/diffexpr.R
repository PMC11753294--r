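# Negative-binomial differential expression with likelihood-ratio testing,
# preceded by the sample-correlation QC and group-balancing steps applied to
# each dataset before testing.

#' Correlation-based sample quality control
#'
#' Iteratively removes the sample whose mean pairwise Pearson correlation
#' (computed on log2(count + 1)) with the remaining samples is lowest, as
#' long as that mean falls below `min_correlation`. This mirrors the common
#' bulk RNA-seq recommendation of discarding samples that correlate < 0.8
#' with the rest of their dataset.
#'
#' @param cm A [count_matrix()] with at least 3 samples.
#' @param min_correlation Minimum acceptable mean correlation with the other
#'   retained samples.
#' @return The retained [count_matrix()], with attribute `"removed"` listing
#'   removed sample ids.
#' @export
sample_qc <- function(cm, min_correlation = 0.8) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 3L) stop("sample_qc needs >= 3 samples", call. = FALSE)
  lg <- log2(cm$counts + 1)
  keep <- colnames(lg)
  removed <- character()
  repeat {
    if (min_correlation <= 0) break   # vacuous threshold
    if (length(keep) < 2L) {
      stop("sample QC removed all usable samples; dataset unusable",
           call. = FALSE)
    }
    r <- suppressWarnings(stats::cor(lg[, keep, drop = FALSE]))
    r[is.na(r)] <- 0
    diag(r) <- NA
    mean_r <- rowMeans(r, na.rm = TRUE)
    worst <- which.min(mean_r)
    if (mean_r[worst] >= min_correlation) break
    removed <- c(removed, keep[worst])
    keep <- keep[-worst]
  }
  out <- count_matrix(cm$counts[, keep, drop = FALSE],
                      cm$meta[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Balance case and control group sizes by random subsampling
#'
#' Randomly subsamples (without replacement) the larger of the two groups
#' down to the size of the smaller, so the design is balanced before
#' differential testing.
#'
#' @param cm A [count_matrix()] containing both groups.
#' @param seed Integer seed for the subsample draw.
#' @return A balanced [count_matrix()].
#' @export
balance_groups <- function(cm, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  g <- cm$meta$group
  if (!all(c("case", "control") %in% g)) {
    stop("both case and control samples are required", call. = FALSE)
  }
  n_case <- sum(g == "case"); n_ctrl <- sum(g == "control")
  if (n_case == n_ctrl) return(cm)
  n_keep <- min(n_case, n_ctrl)
  larger <- if (n_case > n_ctrl) "case" else "control"
  idx_larger <- cm$meta$sample[g == larger]
  kept_larger <- with_seed(seed, sample(idx_larger, n_keep))
  keep <- cm$meta$sample[g != larger | cm$meta$sample %in% kept_larger]
  count_matrix(cm$counts[, keep, drop = FALSE], cm$meta[keep, , drop = FALSE])
}

#' Median-of-ratios size factors
#'
#' The standard count-normalization for NB differential expression: for each
#' sample, the median over genes (restricted to genes positive in every
#' sample) of the ratio between that sample's count and the gene's geometric
#' mean across samples; factors are rescaled to geometric mean 1.
#'
#' @param counts Integer matrix or [count_matrix()].
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    stop(paste("no gene has positive counts in all samples;",
               "consider a pseudo-reference fallback"), call. = FALSE)
  }
  lg <- log(m[all_pos, , drop = FALSE])
  ref <- rowMeans(lg)               # log geometric mean per gene
  sf <- apply(lg, 2, function(x) stats::median(exp(x - ref)))
  sf / exp(mean(log(sf)))
}

#' Method-of-moments per-gene NB dispersion
#'
#' On size-factor-normalized counts, estimates per-gene dispersion alpha in
#' Var = mu + alpha mu^2 by the moment formula alpha = (s^2 - mu) / mu^2,
#' pooled within each group and then averaged, floored at 1e-8. This is a
#' deliberately simple estimator: the downstream tests need directions and
#' ranks, not shrunken dispersion estimates.
#'
#' @param cm A [count_matrix()] with >= 2 samples per group.
#' @param sf Size factors from [size_factors()].
#' @return Named non-negative numeric vector, one alpha per gene.
#' @export
estimate_dispersion <- function(cm, sf = size_factors(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  norm <- sweep(cm$counts, 2, sf, "/")
  groups <- split(seq_len(ncol(norm)), cm$meta$group)
  if (any(lengths(groups) < 2L)) {
    stop("estimate_dispersion needs >= 2 samples per group", call. = FALSE)
  }
  per_group <- vapply(groups, function(idx) {
    x <- norm[, idx, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    a <- (v - mu) / mu^2
    a[!is.finite(a)] <- 0
    pmax(a, 0)
  }, numeric(nrow(norm)))
  alpha <- rowMeans(per_group)
  pmax(alpha, 1e-8)
}

# NB log-likelihood at fixed dispersion alpha (vector over genes, recycled
# over samples of the gene).
nb_loglik <- function(y, mu, alpha) {
  size <- 1 / alpha
  sum(lgamma(y + size) - lgamma(size) - lgamma(y + 1) +
        y * log(alpha * mu / (1 + alpha * mu)) - size * log1p(alpha * mu))
}

# Vectorized IRLS for the two-group NB GLM with log link, fixed per-gene
# dispersion and log size-factor offsets.  Design: eta = b0 + b1 * x + log s,
# x = 1 for case samples.  All genes are iterated simultaneously; the 2x2
# normal equations are solved in closed form per gene.
nb_irls <- function(y, x, log_sf, alpha, full = TRUE,
                    tol = 1e-10, max_iter = 100L) {
  n_genes <- nrow(y); n_samp <- ncol(y)
  off <- matrix(log_sf, n_genes, n_samp, byrow = TRUE)
  xm <- matrix(x, n_genes, n_samp, byrow = TRUE)
  norm_y <- sweep(y, 2, exp(log_sf), "/")
  mu_case <- rowMeans(norm_y[, x == 1, drop = FALSE])
  mu_ctrl <- rowMeans(norm_y[, x == 0, drop = FALSE])
  b0 <- log(mu_ctrl + 0.1)
  b1 <- if (full) log((mu_case + 0.1) / (mu_ctrl + 0.1)) else numeric(n_genes)
  if (!full) b0 <- log((mu_case + mu_ctrl) / 2 + 0.1)
  am <- matrix(alpha, n_genes, n_samp)
  ll <- rep(-Inf, n_genes)
  active <- rep(TRUE, n_genes)
  converged <- rep(FALSE, n_genes)
  for (iter in seq_len(max_iter)) {
    prev_b0 <- b0; prev_b1 <- b1
    eta <- b0 + if (full) b1 * xm else 0
    mu <- exp(eta + off)
    mu <- pmin(pmax(mu, 1e-10), 1e12)
    w <- mu / (1 + am * mu)
    z <- eta + (y - mu) / mu
    if (full) {
      sw <- rowSums(w); swx <- rowSums(w * xm)
      swz <- rowSums(w * z); swxz <- rowSums(w * xm * z)
      det <- sw * swx - swx * swx       # since x^2 = x
      det[abs(det) < 1e-12] <- NA
      new_b0 <- (swx * swz - swx * swxz) / det
      new_b1 <- (sw * swxz - swx * swz) / det
      bad <- !is.finite(new_b0) | !is.finite(new_b1)
      new_b0[bad] <- b0[bad]; new_b1[bad] <- b1[bad]
      b0 <- ifelse(active, pmin(pmax(new_b0, -30), 30), b0)
      b1 <- ifelse(active, pmin(pmax(new_b1, -30), 30), b1)
      step <- pmax(abs(b0 - prev_b0), abs(b1 - prev_b1))
    } else {
      new_b0 <- rowSums(w * z) / rowSums(w)
      new_b0[!is.finite(new_b0)] <- b0[!is.finite(new_b0)]
      b0 <- ifelse(active, pmin(pmax(new_b0, -30), 30), b0)
      step <- abs(b0 - prev_b0)
    }
    newly <- active & step < tol
    converged[newly] <- TRUE
    active <- active & !newly
    if (!any(active)) break
  }
  eta <- b0 + if (full) b1 * xm else 0
  mu <- pmin(pmax(exp(eta + off), 1e-10), 1e12)
  size <- 1 / am
  ll_mat <- lgamma(y + size) - lgamma(size) - lgamma(y + 1) +
    y * log(am * mu / (1 + am * mu)) - size * log1p(am * mu)
  list(b0 = b0, b1 = if (full) b1 else NULL, loglik = rowSums(ll_mat),
       converged = converged)
}

#' Negative-binomial likelihood-ratio differential test
#'
#' Per gene, fits the NB GLM (log link, size factors as offsets, fixed
#' per-gene dispersion) under a full model (intercept + case indicator) and a
#' reduced model (intercept only), and tests the case effect with the
#' likelihood ratio against a chi-squared distribution with one degree of
#' freedom. Genes with raw p < `p_threshold` are flagged as differential with
#' direction `sign(log2FC)`; BH-adjusted p-values are reported alongside.
#'
#' @param cm A [count_matrix()] with both groups present.
#' @param sf Size factors.
#' @param alpha Per-gene dispersions (recycled if scalar).
#' @param p_threshold Raw p-value threshold for the differential call.
#' @return A data frame of class `de_result`: `gene`, `base_mean` (mean
#'   normalized count), `log2fc` (case vs control), `stat`, `pvalue`, `padj`,
#'   `de` (logical), `direction` (+1/-1/0), `converged`. All-zero genes are
#'   skipped.
#' @export
nb_lrt <- function(cm, sf = size_factors(cm), alpha = estimate_dispersion(cm, sf),
                   p_threshold = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!all(c("case", "control") %in% cm$meta$group)) {
    stop("both case and control samples are required", call. = FALSE)
  }
  y <- cm$counts
  nonzero <- rowSums(y) > 0
  y <- y[nonzero, , drop = FALSE]
  if (length(alpha) == 1L) alpha <- rep(alpha, nrow(y))
  if (!is.null(names(alpha))) alpha <- alpha[rownames(y)]
  alpha <- pmax(unname(alpha), 1e-8)
  x <- as.numeric(cm$meta$group == "case")
  if (!is.null(names(sf))) sf <- sf[colnames(y)]
  log_sf <- unname(log(sf))
  fit_full <- nb_irls(y, x, log_sf, alpha, full = TRUE)
  fit_red <- nb_irls(y, x, log_sf, alpha, full = FALSE)
  lr <- 2 * (fit_full$loglik - fit_red$loglik)
  lr <- pmax(lr, 0)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  conv <- fit_full$converged & fit_red$converged
  p[!conv] <- 1
  log2fc <- fit_full$b1 / log(2)
  base_mean <- rowMeans(sweep(y, 2, exp(log_sf), "/"))
  res <- data.frame(
    gene = rownames(y),
    base_mean = base_mean,
    log2fc = log2fc,
    stat = lr,
    pvalue = p,
    padj = bh_adjust(p),
    converged = conv,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$de <- res$pvalue < p_threshold & res$log2fc != 0
  res$direction <- ifelse(res$de, sign(res$log2fc), 0)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Extract a gene -> direction signature from a differential result
#'
#' @param res A `de_result` (from [nb_lrt()]).
#' @return Named numeric vector of +1/-1 directions for called genes.
#' @export
de_signature <- function(res) {
  called <- res[res$de & res$direction != 0, ]
  setNames(called$direction, called$gene)
}
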