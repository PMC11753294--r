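# Functional enrichment: hypergeometric over-representation analysis,
# weighted-KS gene-set enrichment on a ranked list (genes ranked by the mean
# log2 fold change across the two conditions), and similarity clustering of
# enriched terms.

#' Over-representation analysis (hypergeometric upper tail)
#'
#' Per term, tests whether the query gene list overlaps the term's gene set
#' more than expected under sampling without replacement from the universe:
#' p = P(X >= k) for X hypergeometric with `N = |universe|`,
#' `M = |set in universe|`, `n = |query|`. BH correction across terms.
#'
#' @param query Character vector of genes (must be a subset of `universe`).
#' @param universe Character vector: the tested gene universe.
#' @param sets Named list of character vectors (gene-set collection).
#' @param padj_threshold Adjusted-p threshold for the `significant` flag.
#' @return Data frame: `term`, `k` (overlap), `set_size` (M), `query_size`,
#'   `universe_size`, `pvalue`, `padj`, `significant`, ordered by p-value.
#' @export
ora <- function(query, universe, sets, padj_threshold = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!all(query %in% universe)) {
    stop("query genes must be contained in the universe", call. = FALSE)
  }
  n <- length(query); N <- length(universe)
  res <- lapply(names(sets), function(term) {
    set <- intersect(sets[[term]], universe)
    M <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
    data.frame(term = term, k = k, set_size = M, query_size = n,
               universe_size = N, pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- bh_adjust(res$pvalue)
  res$significant <- res$padj < padj_threshold
  res <- res[order(res$pvalue, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Running-sum enrichment score for one set on a (descending-sorted) ranking.
# Hits step up by |r|^w / sum(|r_hits|^w); misses step down by 1/(N - M).
# Returns the extremum of the running sum, its position, and the running sum
# itself.
gsea_es <- function(ranked_values, hit, w = 1) {
  N <- length(ranked_values)
  M <- sum(hit)
  wts <- abs(ranked_values)^w
  denom_hit <- sum(wts[hit])
  step <- numeric(N)
  step[!hit] <- -1 / (N - M)
  step[hit] <- if (denom_hit > 0) wts[hit] / denom_hit else 1 / M
  rs <- cumsum(step)
  i_max <- which.max(rs); i_min <- which.min(rs)
  es <- if (abs(rs[i_max]) >= abs(rs[i_min])) rs[i_max] else rs[i_min]
  list(es = es, arg = if (es >= 0) i_max else i_min, running = rs)
}

#' Gene-set enrichment analysis on a ranked gene list
#'
#' Classic weighted Kolmogorov-Smirnov running-sum GSEA (weight exponent
#' `w = 1`) on a gene-level ranking statistic, here intended to be the mean
#' log2 fold change across the two study conditions. Because the ranking is
#' a derived statistic rather than per-sample data, significance is assessed
#' by gene-label permutation: null enrichment scores are computed for random
#' gene sets of the same size, and `p = (1 + #{|ES*| >= |ES|}) / (1 +
#' n_perm)`. BH correction across sets.
#'
#' @param ranking Named numeric vector, gene -> ranking statistic (no NAs).
#' @param sets Named list of character vectors.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation draws.
#' @param w Weight exponent of the running sum.
#' @return Data frame: `term`, `set_size` (genes in ranking), `es`,
#'   `pvalue`, `padj`, `leading_edge` (comma-separated genes up to the
#'   extremum), ordered by p then |ES| descending. Sets with no gene in the
#'   ranking are skipped with a warning.
#' @export
gsea <- function(ranking, sets, n_perm = 1000, seed = 1L, w = 1) {
  if (anyNA(ranking)) stop("ranking contains NA", call. = FALSE)
  if (is.null(names(ranking))) stop("ranking must be named", call. = FALSE)
  ord <- order(-ranking, names(ranking))   # deterministic tie-break
  genes <- names(ranking)[ord]
  values <- unname(ranking[ord])
  N <- length(genes)
  in_ranking <- lapply(sets, function(s) intersect(s, genes))
  empty <- lengths(in_ranking) == 0L
  if (any(empty)) {
    warning(sprintf("%d set(s) with no genes in the ranking skipped", sum(empty)))
  }
  use <- names(sets)[!empty & lengths(in_ranking) < N]
  if (!length(use)) {
    return(data.frame(term = character(), set_size = integer(), es = numeric(),
                      pvalue = numeric(), padj = numeric(),
                      leading_edge = character()))
  }
  obs <- lapply(use, function(term) {
    hit <- genes %in% in_ranking[[term]]
    r <- gsea_es(values, hit, w)
    le <- if (r$es >= 0) genes[seq_len(r$arg)][hit[seq_len(r$arg)]] else
      genes[r$arg:N][hit[r$arg:N]]
    list(es = r$es, size = sum(hit), leading_edge = le)
  })
  names(obs) <- use
  sizes <- sort(unique(vapply(obs, `[[`, integer(1), "size")))
  null_es <- with_seed(seed, {
    out <- list()
    for (m in sizes) {
      out[[as.character(m)]] <- vapply(seq_len(n_perm), function(i) {
        hit <- logical(N)
        hit[sample.int(N, m)] <- TRUE
        gsea_es(values, hit, w)$es
      }, numeric(1))
    }
    out
  })
  p <- vapply(use, function(term) {
    nulls <- null_es[[as.character(obs[[term]]$size)]]
    (1 + sum(abs(nulls) >= abs(obs[[term]]$es))) / (1 + n_perm)
  }, numeric(1))
  res <- data.frame(
    term = use,
    set_size = vapply(obs, `[[`, integer(1), "size"),
    es = vapply(obs, `[[`, numeric(1), "es"),
    pvalue = p,
    stringsAsFactors = FALSE
  )
  res$padj <- bh_adjust(res$pvalue)
  res$leading_edge <- vapply(obs, function(o) paste(o$leading_edge, collapse = ","),
                             character(1))
  res <- res[order(res$pvalue, -abs(res$es), res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cluster enriched terms by gene-set similarity
#'
#' Computes pairwise Jaccard similarity between the gene sets of enriched
#' terms, runs average-linkage hierarchical clustering on `1 - Jaccard`, and
#' cuts the tree into exactly `k` clusters, as used to group enriched
#' biological processes into interpretable themes.
#'
#' @param terms Character vector of term ids.
#' @param sets Named list of gene sets covering `terms`.
#' @param k Number of clusters.
#' @return Named integer vector: term -> cluster id; the dendrogram is
#'   attached as attribute `"hclust"`.
#' @export
term_similarity_clusters <- function(terms, sets, k = 5) {
  if (k > length(terms)) stop("k exceeds the number of terms", call. = FALSE)
  gs <- sets[terms]
  n <- length(terms)
  sim <- matrix(1, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      u <- length(union(gs[[i]], gs[[j]]))
      sim[i, j] <- sim[j, i] <- if (u == 0) 0 else
        length(intersect(gs[[i]], gs[[j]])) / u
    }
  }
  h <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(h, k = k)
  attr(cl, "hclust") <- h
  cl
}
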