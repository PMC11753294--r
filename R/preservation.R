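# Permutation-based module preservation between a discovery and a test
# co-expression network (seven density and connectivity statistics, one-sided
# permutation p-values, BH correction), and hub-gene identification in
# preserved, trait-correlated modules.

# Eigengene (first right singular vector) of a standardized gene x sample
# matrix, sign-aligned so the mean correlation of members with it is >= 0.
set_eigengene <- function(x) {
  xs <- t(scale(t(x)))
  xs[is.na(xs)] <- 0
  v <- if (nrow(xs) == 1L) as.numeric(xs) else svd(xs, nu = 0, nv = 1)$v[, 1]
  nv <- sqrt(sum(v^2))
  if (nv > 0) v <- v / nv
  kme <- suppressWarnings(stats::cor(t(x), v))
  kme[is.na(kme)] <- 0
  if (mean(kme) < 0) {
    v <- -v
    kme <- -kme
  }
  list(v = v, kme = as.numeric(kme))
}

offdiag <- function(m) m[lower.tri(m)]

#' Seven module preservation statistics
#'
#' Measures how well a discovery module's density and connectivity structure
#' recurs in a test network, on the module's own gene set:
#' \describe{
#'   \item{avg.weight}{mean off-diagonal test adjacency (average edge weight).}
#'   \item{coherence}{mean squared test kME of members: proportion of member
#'     variance explained by the test eigengene.}
#'   \item{avg.cor}{mean absolute off-diagonal test correlation (density of
#'     correlation structure).}
#'   \item{avg.contrib}{mean absolute test kME (average node contribution).}
#'   \item{cor.cor}{correlation between discovery and test off-diagonal
#'     correlations (concordance of correlation structure).}
#'   \item{cor.degree}{correlation between within-module weighted degrees in
#'     the two networks (concordance of weighted degree).}
#'   \item{cor.contrib}{correlation between discovery and test kME vectors
#'     (concordance of node contribution).}
#' }
#'
#' @param discovery List with `expr` (genes x samples), `network`
#'   (`coex_network`).
#' @param test Same structure for the test condition.
#' @param module Character vector of member genes (>= 3, present in both
#'   networks).
#' @return Named numeric vector of the seven statistics.
#' @export
preservation_stats <- function(discovery, test, module) {
  if (length(module) < 3L) stop("module must have >= 3 genes", call. = FALSE)
  if (!all(module %in% discovery$network$genes) ||
        !all(module %in% test$network$genes)) {
    stop("module genes must be present in both networks", call. = FALSE)
  }
  disc_side <- preservation_discovery_side(discovery, module)
  preservation_test_side(disc_side, test, module)
}

# Discovery-side quantities of a module, computed once and reused across
# permutations (the permutation null re-draws only the test-side gene set).
preservation_discovery_side <- function(discovery, module) {
  r_d <- discovery$network$cor[module, module]
  a_d <- discovery$network$adjacency[module, module]
  kme_d <- set_eigengene(discovery$expr[module, , drop = FALSE])$kme
  list(cor_offdiag = offdiag(r_d),
       degree = rowSums(a_d) - 1,
       kme = kme_d)
}

# Test-side evaluation against fixed discovery-side vectors, for an
# arbitrary same-size gene set (the observed module or a null draw).
preservation_test_side <- function(disc_side, test, genes) {
  r_t <- test$network$cor[genes, genes]
  a_t <- test$network$adjacency[genes, genes]
  kme_t <- set_eigengene(test$expr[genes, , drop = FALSE])$kme
  deg_t <- rowSums(a_t) - 1
  c(
    avg.contrib = mean(abs(kme_t)),
    avg.cor = mean(abs(offdiag(r_t))),
    avg.weight = mean(offdiag(a_t)),
    coherence = mean(kme_t^2),
    cor.contrib = stats::cor(disc_side$kme, kme_t),
    cor.cor = stats::cor(disc_side$cor_offdiag, offdiag(r_t)),
    cor.degree = stats::cor(disc_side$degree, deg_t)
  )
}

#' Permutation test of module preservation
#'
#' For every discovery module, compares each of the seven preservation
#' statistics with a null distribution obtained by recomputing the statistic
#' on random same-size gene sets drawn from the gene universe shared by both
#' networks (the discovery module's side stays fixed for the concordance
#' statistics). One-sided `p = (1 + #{null >= observed}) / (1 + n_perm)`,
#' BH-corrected jointly across modules x statistics; a module is preserved
#' when all seven adjusted p-values fall below `alpha`.
#'
#' @param discovery List with `expr`, `network`, `labels` (named module
#'   labels; 0 ignored).
#' @param test List with `expr`, `network`.
#' @param n_perm Number of permutations (>= 20).
#' @param seed Integer seed.
#' @param alpha Adjusted-p threshold for preservation.
#' @param exclude_module_genes If `TRUE`, null draws avoid the module's own
#'   genes.
#' @param per_statistic_bh If `TRUE`, BH is applied within each statistic
#'   instead of jointly.
#' @return Object of class `preservation_report`: list with `stats` (long
#'   data frame: module, statistic, observed, pvalue, padj) and `modules`
#'   (data frame: module, size, preserved).
#' @export
preservation_permutation <- function(discovery, test, n_perm = 1000,
                                     seed = 1L, alpha = 0.05,
                                     exclude_module_genes = FALSE,
                                     per_statistic_bh = FALSE) {
  if (n_perm < 20L) stop("n_perm must be >= 20 for usable p resolution",
                         call. = FALSE)
  labels <- discovery$labels
  mods <- setdiff(sort(unique(labels)), 0L)
  if (!length(mods)) stop("no modules in the discovery labeling", call. = FALSE)
  universe <- intersect(discovery$network$genes, test$network$genes)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  if (max(sizes) >= length(universe)) {
    stop("test universe must exceed the largest module", call. = FALSE)
  }
  stat_names <- c("avg.contrib", "avg.cor", "avg.weight", "coherence",
                  "cor.contrib", "cor.cor", "cor.degree")
  rows <- list()
  with_seed(seed, {
    for (mi in seq_along(mods)) {
      m <- mods[mi]
      members <- intersect(names(labels)[labels == m], universe)
      disc_side <- preservation_discovery_side(discovery, members)
      observed <- preservation_test_side(disc_side, test, members)
      pool <- if (exclude_module_genes) setdiff(universe, members) else universe
      null_mat <- matrix(NA_real_, n_perm, length(stat_names),
                         dimnames = list(NULL, stat_names))
      for (p in seq_len(n_perm)) {
        draw <- sample(pool, length(members))
        null_mat[p, ] <- preservation_test_side(disc_side, test, draw)
      }
      pvals <- vapply(stat_names, function(s) {
        (1 + sum(null_mat[, s] >= observed[s])) / (1 + n_perm)
      }, numeric(1))
      rows[[mi]] <- data.frame(module = m, size = length(members),
                               statistic = stat_names,
                               observed = as.numeric(observed[stat_names]),
                               pvalue = as.numeric(pvals),
                               stringsAsFactors = FALSE)
    }
  })
  stats_df <- do.call(rbind, rows)
  if (per_statistic_bh) {
    stats_df$padj <- stats::ave(stats_df$pvalue, stats_df$statistic,
                                FUN = bh_adjust)
  } else {
    stats_df$padj <- bh_adjust(stats_df$pvalue)
  }
  mod_df <- do.call(rbind, lapply(mods, function(m) {
    sub <- stats_df[stats_df$module == m, ]
    data.frame(module = m, size = sub$size[1],
               preserved = all(sub$padj < alpha))
  }))
  rownames(stats_df) <- rownames(mod_df) <- NULL
  structure(list(stats = stats_df, modules = mod_df,
                 n_perm = n_perm, alpha = alpha),
            class = "preservation_report")
}

#' @export
print.preservation_report <- function(x, ...) {
  cat(sprintf("<preservation_report> %d modules, %d permutations\n",
              nrow(x$modules), x$n_perm))
  print(x$modules)
  invisible(x)
}

#' Hub genes by intramodular connectivity and module membership
#'
#' Within each module, a gene is a hub when its intramodular connectivity
#' `kIM_i = sum_{j in module, j != i} a_ij` reaches the module's
#' `degree_quantile` (default: top 10%) and its kME exceeds `kme_min`
#' (default 0.8). The `top_n` hubs are ranked by kIM descending (ties broken
#' by kME, then gene id).
#'
#' @param network A `coex_network`.
#' @param labels Named gene -> module labels.
#' @param me A `module_eigengenes` for the same universe.
#' @param degree_quantile kIM quantile a hub must reach within its module.
#' @param kme_min Minimum kME.
#' @param top_n Size of the top hub list per module.
#' @return Object of class `hub_report`: list with `genes` (data frame:
#'   module, gene, kim, kme, hub, rank) and `top` (named list of top-`n`
#'   hub gene vectors per module).
#' @export
hub_genes <- function(network, labels, me, degree_quantile = 0.9,
                      kme_min = 0.8, top_n = 5) {
  labels <- labels[network$genes]
  mods <- setdiff(sort(unique(labels)), 0L)
  rows <- list()
  top <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    a <- network$adjacency[members, members, drop = FALSE]
    kim <- rowSums(a) - 1
    kme <- me$kme[members, paste0("ME", m)]
    thr <- stats::quantile(kim, degree_quantile, names = FALSE)
    hub <- kim >= thr & kme > kme_min
    if (!any(hub)) {
      warning(sprintf("module %d has no gene meeting both hub criteria", m))
    }
    ord <- order(-kim, -kme, members)
    rnk <- integer(length(members)); rnk[ord] <- seq_along(members)
    rows[[length(rows) + 1L]] <- data.frame(
      module = m, gene = members, kim = unname(kim), kme = unname(kme),
      hub = unname(hub), rank = rnk, stringsAsFactors = FALSE
    )
    hubs_ranked <- members[ord][hub[ord]]
    top[[as.character(m)]] <- utils::head(hubs_ranked, top_n)
  }
  genes_df <- do.call(rbind, rows)
  rownames(genes_df) <- NULL
  structure(list(genes = genes_df, top = top), class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat("<hub_report>\n")
  for (m in names(x$top)) {
    cat(sprintf("  module %s: %s\n", m, paste(x$top[[m]], collapse = ", ")))
  }
  invisible(x)
}
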