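# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (loops, exhaustive scans) and independent of
# the package's implementation paths.

# Small simulated study used by several unit tests.
small_config <- function(seed = 1, ...) {
  sim_config(
    n_genes = 300,
    samples_per_group = 6,
    module_spec = data.frame(module = 1:2, size = c(40, 30),
                             shared = c(TRUE, FALSE), loading = 0.9),
    n_background_peaks = 60,
    seed = seed,
    ...
  )
}

# A count_matrix built from explicit values.
make_cm <- function(m, group = NULL, dataset = "d1", condition = "condA") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (is.null(group)) group <- rep(c("case", "control"), length.out = ncol(m))
  count_matrix(m, data.frame(sample = colnames(m), group = group,
                             dataset = dataset, condition = condition))
}

# O(n^3) triple-loop topological overlap oracle.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# Exact hypergeometric upper-tail by direct combinatorial summation.
oracle_hyper_tail <- function(k, M, N, n) {
  xs <- k:min(M, n)
  sum(choose(M, xs) * choose(N - M, n - xs)) / choose(N, n)
}

# Step-by-step GSEA running sum, written independently of the package.
oracle_gsea_es <- function(values, hit, w = 1) {
  N <- length(values)
  nr <- sum(abs(values[hit])^w)
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (hit[i]) abs(values[i])^w / nr else -1 / (N - sum(hit))
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Brute-force dictionary merge of (gene, direction) evidence lists.
oracle_merge <- function(lists) {
  seen <- list()
  for (entry in lists) {
    for (g in names(entry$signature)) {
      seen[[g]] <- union(seen[[g]], entry$signature[[g]])
    }
  }
  genes <- names(seen)
  disc <- genes[vapply(seen, length, integer(1)) > 1L]
  kept <- setdiff(genes, disc)
  list(signature = setNames(vapply(kept, function(g) seen[[g]], numeric(1)), kept),
       discordant = sort(disc))
}

# Exhaustive pairwise-overlap consensus merge (single chromosome assumed
# handled by splitting beforehand).
oracle_consensus <- function(replicates, min_replicates) {
  peaks <- do.call(rbind, lapply(seq_along(replicates), function(i) {
    df <- replicates[[i]][, c("chrom", "start", "end")]
    df$rep <- i
    df
  }))
  n <- nrow(peaks)
  overlap <- function(i, j) {
    peaks$chrom[i] == peaks$chrom[j] &&
      peaks$start[i] < peaks$end[j] && peaks$start[j] < peaks$end[i]
  }
  # transitive closure of the overlap relation
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && overlap(i, j) && comp[j] != comp[i]) {
          tgt <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- tgt
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- NULL
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    if (length(unique(peaks$rep[idx])) >= min_replicates) {
      out <- rbind(out, data.frame(chrom = peaks$chrom[idx[1]],
                                   start = min(peaks$start[idx]),
                                   end = max(peaks$end[idx])))
    }
  }
  if (is.null(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# All-pairs interval overlap test (0-based half-open).
oracle_any_overlap <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
            a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# Direct-formula implementation of the seven preservation statistics.
oracle_preservation <- function(disc_expr, disc_adj, disc_cor,
                                test_expr, test_adj, test_cor) {
  first_pc <- function(x) {
    xs <- t(scale(t(x)))
    v <- svd(xs)$v[, 1]
    kme <- as.numeric(cor(t(x), v))
    if (mean(kme) < 0) kme <- -kme
    kme
  }
  m <- nrow(disc_expr)
  kme_d <- first_pc(disc_expr)
  kme_t <- first_pc(test_expr)
  lower <- which(lower.tri(test_cor))
  deg <- function(a) vapply(seq_len(m), function(i) sum(a[i, -i]), numeric(1))
  c(avg.contrib = mean(abs(kme_t)),
    avg.cor = mean(abs(test_cor[lower])),
    avg.weight = mean(test_adj[lower]),
    coherence = mean(kme_t^2),
    cor.contrib = cor(kme_d, kme_t),
    cor.cor = cor(disc_cor[lower], test_cor[lower]),
    cor.degree = cor(deg(disc_adj), deg(test_adj)))
}

# Toy genome with hand-placed genes and enhancers for annotation tests:
# all coordinates chosen so the expected classification is computable by
# hand (see test-chip.R for the case table).
toy_genome <- function() {
  ann <- data.frame(
    gene = c("gA", "gB", "gC", "gD", "gE", "gF"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr3", "chr3"),
    start = c(10000L, 40000L, 100000L, 5000L, 1000L, 5000L),
    end = c(20000L, 60000L, 130000L, 9000L, 3000L, 8000L),
    strand = c("+", "-", "+", "+", "+", "+"),
    tss = c(10000L, 60000L, 100000L, 5000L, 1000L, 5000L),
    stringsAsFactors = FALSE
  )
  enh <- data.frame(
    chrom = c("chr1", "chr1"),
    start = c(80000L, 75000L),
    end = c(81000L, 76000L),
    enhancer_id = c("e1", "e2"),
    score = c(1.0, 1.0),
    stringsAsFactors = FALSE
  )
  assoc <- data.frame(
    enhancer_id = c("e1", "e1", "e2"),
    gene = c("gB", "gC", "gA"),
    score = c(10, 12, 8),
    stringsAsFactors = FALSE
  )
  list(annotation = ann, db = enhancer_db(enh, assoc))
}
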