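# Synthetic multi-omics study generator.  Every downstream stage of the
# pipeline is validated against the planted ground truth produced here:
# co-expressed gene modules driven by latent factors (some shared between the
# two study conditions, some condition-specific), differentially expressed
# genes with known directions, per-dataset batch offsets, and H3K27ac peak
# gains/losses at promoters or enhancers of chosen genes.

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic study. The defaults define the
#' package's reference synthetic study: two study conditions (an exposure and
#' a disease), two RNA-seq datasets per condition with 10 case + 10 control
#' samples each (40 samples per condition), 2000 genes, five planted
#' co-expression modules of which three are shared between conditions and two
#' are specific to the first condition, planted differential genes at
#' |log2FC| = 1-2, negative-binomial dispersion 0.1, and moderate additive
#' batch effects on the log scale.
#'
#' @param n_genes Number of genes.
#' @param conditions Character vector of two study-condition labels.
#' @param n_datasets_per_condition RNA-seq datasets (batches) per condition.
#' @param samples_per_group Samples per case and per control group in each
#'   dataset.
#' @param module_spec Data frame with columns `module` (integer id), `size`,
#'   `shared` (logical: active in both conditions) and `loading` (module
#'   latent-factor loading strength in \[0, 1\]; each member gene receives a
#'   fixed loading drawn uniformly in 0.6-1 times this value, giving modules
#'   a reproducible hub/periphery degree profile). Non-shared modules are
#'   active only in the first condition. Genes are assigned to modules in id
#'   order from the start of the gene universe, so modules are disjoint by
#'   construction.
#' @param de_spec Data frame with columns `gene`, `condition`, `log2fc`:
#'   planted expression shifts applied to case samples of that condition.
#' @param nb_dispersion Negative-binomial dispersion alpha (Var = mu + alpha
#'   mu^2), shared by all genes.
#' @param baseline_mean_log_range Range (natural log scale) of per-gene
#'   baseline mean expression.
#' @param batch_effect_sd SD of the per-gene, per-dataset Gaussian offset on
#'   the log scale.
#' @param peak_spec Data frame with columns `gene`, `element`
#'   (`"promoter"`/`"enhancer"`), `change` (`"gain"`/`"loss"`), `condition`:
#'   planted H3K27ac differential peaks.
#' @param n_background_peaks Peaks present in both case and control of each
#'   condition's ChIP experiment.
#' @param chip_replicates ChIP replicates per group.
#' @param peak_jitter Maximum absolute replicate-to-replicate peak coordinate
#'   jitter in bp.
#' @param genes_per_chrom Genes placed per synthetic chromosome.
#' @param chrom_length Optional fixed chromosome length in bp; by default
#'   chromosomes are sized to fit their genes. Too short a length is an error
#'   at annotation time.
#' @param seed Integer seed; all outputs are pure functions of it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       conditions = c("pm25", "asthma"),
                       n_datasets_per_condition = 2,
                       samples_per_group = 10,
                       module_spec = default_module_spec(),
                       de_spec = NULL,
                       nb_dispersion = 0.1,
                       baseline_mean_log_range = log(c(30, 3000)),
                       batch_effect_sd = 0.3,
                       peak_spec = NULL,
                       n_background_peaks = 300,
                       chip_replicates = 2,
                       peak_jitter = 50,
                       genes_per_chrom = 500,
                       chrom_length = NULL,
                       seed = 1L) {
  stopifnot_scalar(n_genes, "n_genes", 1)
  if (length(conditions) != 2L || anyDuplicated(conditions)) {
    stop("conditions must be two distinct labels", call. = FALSE)
  }
  stopifnot_scalar(n_datasets_per_condition, "n_datasets_per_condition", 1)
  stopifnot_scalar(samples_per_group, "samples_per_group", 2)
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (batch_effect_sd < 0) stop("batch_effect_sd must be >= 0", call. = FALSE)
  module_spec <- as.data.frame(module_spec)
  if (nrow(module_spec)) {
    needed <- c("module", "size", "shared", "loading")
    if (!all(needed %in% names(module_spec))) {
      stop("module_spec needs columns: ", paste(needed, collapse = ", "),
           call. = FALSE)
    }
    if (any(module_spec$size < 2)) stop("module sizes must be >= 2", call. = FALSE)
    if (sum(module_spec$size) > n_genes) {
      stop("module sizes sum exceeds n_genes (modules must be disjoint)",
           call. = FALSE)
    }
    if (any(module_spec$loading < 0 | module_spec$loading > 1)) {
      stop("loadings must lie in [0, 1]", call. = FALSE)
    }
    if (anyDuplicated(module_spec$module)) {
      stop("duplicate module ids", call. = FALSE)
    }
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(de_spec)) {
    de_spec <- default_de_spec(genes, module_spec, conditions)
  }
  de_spec <- as.data.frame(de_spec)
  if (nrow(de_spec) && !all(de_spec$condition %in% conditions)) {
    stop("de_spec references unknown conditions", call. = FALSE)
  }
  if (is.null(peak_spec)) {
    peak_spec <- default_peak_spec(genes, de_spec, conditions)
  }
  peak_spec <- as.data.frame(peak_spec)
  if (nrow(peak_spec)) {
    if (!all(peak_spec$element %in% c("promoter", "enhancer"))) {
      stop('peak_spec$element must be "promoter" or "enhancer"', call. = FALSE)
    }
    if (!all(peak_spec$change %in% c("gain", "loss"))) {
      stop('peak_spec$change must be "gain" or "loss"', call. = FALSE)
    }
    if (!all(peak_spec$gene %in% genes)) {
      stop("peak_spec references unknown genes", call. = FALSE)
    }
  }
  structure(list(
    n_genes = as.integer(n_genes),
    genes = genes,
    conditions = conditions,
    n_datasets_per_condition = as.integer(n_datasets_per_condition),
    samples_per_group = as.integer(samples_per_group),
    module_spec = module_spec,
    de_spec = de_spec,
    nb_dispersion = nb_dispersion,
    baseline_mean_log_range = baseline_mean_log_range,
    batch_effect_sd = batch_effect_sd,
    peak_spec = peak_spec,
    n_background_peaks = as.integer(n_background_peaks),
    chip_replicates = as.integer(chip_replicates),
    peak_jitter = as.integer(peak_jitter),
    genes_per_chrom = as.integer(genes_per_chrom),
    chrom_length = chrom_length,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default planted module layout: five modules, three shared
#'
#' @return Data frame usable as `module_spec` in [sim_config()].
#' @export
default_module_spec <- function() {
  data.frame(
    module = 1:5,
    size = c(200L, 150L, 100L, 120L, 80L),
    shared = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    loading = 0.8
  )
}

# Planted differential genes.  Module members are differentially expressed in
# the conditions where their module is active (alternating sign per module),
# so modules correlate with the case/control trait; on top of that, 100
# background genes get planted shifts per condition: 60 shared-concordant, 20
# shared-discordant and 20 condition-unique, exercising the signature
# integration logic.
default_de_spec <- function(genes, module_spec, conditions) {
  out <- list()
  offset <- 0L
  if (nrow(module_spec)) {
    for (i in seq_len(nrow(module_spec))) {
      m <- module_spec[i, ]
      members <- genes[(offset + 1L):(offset + m$size)]
      offset <- offset + m$size
      sgn <- if (m$module %% 2 == 1) 1 else -1
      active <- if (m$shared) conditions else conditions[1]
      for (cond in active) {
        out[[length(out) + 1L]] <-
          data.frame(gene = members, condition = cond, log2fc = sgn * 1)
      }
    }
  }
  bg <- genes[(offset + 1L):min(length(genes), offset + 100L)]
  n <- length(bg)
  idx_conc <- bg[seq_len(min(60L, n))]
  idx_disc <- bg[seq_len(min(80L, n))][-seq_len(min(60L, n))]
  idx_uni <- setdiff(bg, c(idx_conc, idx_disc))
  half <- length(idx_uni) %/% 2L
  out[[length(out) + 1L]] <- data.frame(
    gene = rep(idx_conc, 2L),
    condition = rep(conditions, each = length(idx_conc)),
    log2fc = rep(rep(c(2, -2), length.out = length(idx_conc)), 2L)
  )
  if (length(idx_disc)) {
    out[[length(out) + 1L]] <- data.frame(
      gene = rep(idx_disc, 2L),
      condition = rep(conditions, each = length(idx_disc)),
      log2fc = c(rep(2, length(idx_disc)), rep(-2, length(idx_disc)))
    )
  }
  if (length(idx_uni)) {
    out[[length(out) + 1L]] <- data.frame(
      gene = idx_uni,
      condition = rep(conditions, length.out = length(idx_uni)),
      log2fc = rep(c(2, -2), length.out = length(idx_uni))
    )
  }
  do.call(rbind, out)
}

# Planted H3K27ac differential peaks: for each condition, promoter
# gains/losses at 24 planted differential genes (gain where the gene is up,
# loss where down) and enhancer gains at 8 further genes.
default_peak_spec <- function(genes, de_spec, conditions) {
  out <- list()
  for (cond in conditions) {
    de_c <- de_spec[de_spec$condition == cond, ]
    de_c <- de_c[!duplicated(de_c$gene), ]
    pick <- de_c[seq_len(min(32L, nrow(de_c))), ]
    if (!nrow(pick)) next
    n_prom <- min(24L, nrow(pick))
    prom <- pick[seq_len(n_prom), ]
    enh <- pick[-seq_len(n_prom), ]
    out[[length(out) + 1L]] <- data.frame(
      gene = prom$gene, element = "promoter",
      change = ifelse(prom$log2fc > 0, "gain", "loss"), condition = cond
    )
    if (nrow(enh)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = enh$gene, element = "enhancer",
        change = ifelse(enh$log2fc > 0, "gain", "loss"), condition = cond
      )
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), element = character(),
                      change = character(), condition = character()))
  }
  do.call(rbind, out)
}

# Gene -> module id (0 = background), in generator order.
module_labels_from_spec <- function(config) {
  labels <- setNames(integer(config$n_genes), config$genes)
  offset <- 0L
  if (nrow(config$module_spec)) {
    for (i in seq_len(nrow(config$module_spec))) {
      m <- config$module_spec[i, ]
      labels[(offset + 1L):(offset + m$size)] <- m$module
      offset <- offset + m$size
    }
  }
  labels
}

#' Simulate multi-dataset RNA-seq count matrices with planted structure
#'
#' Draws gene-level counts from a negative-binomial model whose log mean is
#' the sum of a per-gene baseline, a per-(gene, dataset) batch offset, a
#' planted case-group shift for differential genes, and `loading * factor`
#' for module members, with one latent factor per module per sample. Shared
#' modules use the same loading in both study conditions; condition-specific
#' modules are flat noise outside their condition.
#'
#' @param config A [sim_config()].
#' @return A list with `datasets` (named list of [count_matrix()] objects,
#'   one per condition x dataset) and `truth` (a `ground_truth` list with
#'   `modules`, `de`, `peak_spec`).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, samples_per_group = 4,
#'                                   module_spec = data.frame(module = 1,
#'                                     size = 30, shared = TRUE, loading = 0.9)))
#' names(sim$datasets)
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 1L), {
    genes <- config$genes
    labels <- module_labels_from_spec(config)
    baseline <- stats::runif(config$n_genes,
                             config$baseline_mean_log_range[1],
                             config$baseline_mean_log_range[2])
    # per-gene loadings: a fixed gene property (drawn once, shared by both
    # conditions) so modules have the hub/periphery degree structure that
    # connectivity-based statistics and hub ranking presume
    gene_loading <- setNames(numeric(config$n_genes), genes)
    if (nrow(config$module_spec)) {
      for (i in seq_len(nrow(config$module_spec))) {
        m <- config$module_spec[i, ]
        members <- which(labels == m$module)
        gene_loading[members] <- m$loading *
          stats::runif(length(members), 0.6, 1)
      }
    }
    datasets <- list()
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      active <- config$module_spec[config$module_spec$shared |
                                     ci == 1L, , drop = FALSE]
      de_c <- config$de_spec[config$de_spec$condition == cond, , drop = FALSE]
      shift <- setNames(numeric(config$n_genes), genes)
      if (nrow(de_c)) shift[de_c$gene] <- de_c$log2fc * log(2)
      for (d in seq_len(config$n_datasets_per_condition)) {
        ds_id <- sprintf("%s_ds%d", cond, d)
        batch <- stats::rnorm(config$n_genes, 0, config$batch_effect_sd)
        n_case <- config$samples_per_group
        n_ctrl <- config$samples_per_group
        n_samp <- n_case + n_ctrl
        group <- rep(c("case", "control"), c(n_case, n_ctrl))
        sample_ids <- sprintf("%s_%s%d", ds_id, substr(group, 1, 2),
                              c(seq_len(n_case), seq_len(n_ctrl)))
        logmu <- matrix(baseline + batch, nrow = config$n_genes, ncol = n_samp)
        logmu[, group == "case"] <- logmu[, group == "case"] + shift
        if (nrow(active)) {
          for (i in seq_len(nrow(active))) {
            m <- active[i, ]
            members <- which(labels == m$module)
            f <- stats::rnorm(n_samp)
            logmu[members, ] <- logmu[members, ] +
              gene_loading[members] * matrix(f, nrow = length(members),
                                             ncol = n_samp, byrow = TRUE)
          }
        }
        mu <- exp(logmu)
        y <- matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / config$nb_dispersion),
                    nrow = config$n_genes,
                    dimnames = list(genes, sample_ids))
        datasets[[ds_id]] <- count_matrix(
          y, data.frame(sample = sample_ids, group = group,
                        dataset = ds_id, condition = cond)
        )
      }
    }
    de_truth <- config$de_spec
    de_truth$direction <- sign(de_truth$log2fc)
    truth <- structure(list(
      modules = labels,
      module_spec = config$module_spec,
      de = de_truth,
      peak_spec = config$peak_spec
    ), class = "ground_truth")
    list(datasets = datasets, truth = truth)
  })
}

#' Simulate a gene annotation and an enhancer association table
#'
#' Places the configured genes on synthetic chromosomes as non-overlapping
#' gene bodies separated by intergenic gaps (coordinates 0-based half-open;
#' TSS = interval start on `+`, interval end on `-`), and drops enhancers
#' into intergenic space, each with an enhancer score and 1-8 associated
#' nearby genes carrying association scores. Genes that the configuration's
#' `peak_spec` marks for enhancer-level peaks are guaranteed at least one
#' enhancer association.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (data frame: gene, chrom, start, end, strand,
#'   tss) and `enhancers` (an [enhancer_db()]).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 2L), {
    genes <- config$genes
    n <- length(genes)
    per_chrom <- min(config$genes_per_chrom, n)
    chrom_of <- paste0("chr", (seq_len(n) - 1L) %/% per_chrom + 1L)
    len <- round(stats::runif(n, 2000, 8000))
    gap <- round(stats::runif(n, 12000, 20000))
    start <- integer(n); end <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      if (i > 1L && chrom_of[i] != chrom_of[i - 1L]) pos <- 0L
      start[i] <- pos + gap[i]
      end[i] <- start[i] + len[i]
      pos <- end[i]
    }
    if (!is.null(config$chrom_length)) {
      need <- tapply(end, chrom_of, max)
      if (any(need > config$chrom_length)) {
        stop("chromosome too short to place genes", call. = FALSE)
      }
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- ifelse(strand == "+", start, end)
    ann <- data.frame(gene = genes, chrom = chrom_of, start = start,
                      end = end, strand = strand, tss = tss,
                      stringsAsFactors = FALSE)
    # enhancers centred in intergenic gaps, clear of +/-3 kb promoter windows
    keep <- which(gap > 9000 & stats::runif(n) < 0.6)
    e_len <- round(stats::runif(length(keep), 300, 900))
    e_mid <- start[keep] - gap[keep] %/% 2L
    e_start <- pmax(0L, e_mid - e_len %/% 2L)
    e_end <- e_start + e_len
    enh <- data.frame(
      chrom = chrom_of[keep], start = e_start, end = e_end,
      enhancer_id = sprintf("e%04d", seq_along(keep)),
      score = round(stats::rgamma(length(keep), shape = 2, scale = 0.35), 3),
      stringsAsFactors = FALSE
    )
    assoc <- list()
    for (j in seq_along(keep)) {
      same <- which(chrom_of == enh$chrom[j])
      d <- abs(tss[same] - (enh$start[j] + enh$end[j]) / 2)
      cand <- same[order(d)][seq_len(min(10L, length(same)))]
      k <- sample(1:8, 1L)
      chosen <- cand[seq_len(min(k, length(cand)))]
      assoc[[j]] <- data.frame(
        enhancer_id = enh$enhancer_id[j], gene = genes[chosen],
        score = round(stats::rgamma(length(chosen), 2, rate = 0.15), 2),
        stringsAsFactors = FALSE
      )
    }
    assoc <- do.call(rbind, assoc)
    # guarantee associations for genes planted with enhancer peaks
    want <- unique(config$peak_spec$gene[config$peak_spec$element == "enhancer"])
    for (g in want) {
      if (!g %in% assoc$gene) {
        gi <- match(g, genes)
        same <- which(enh$chrom == chrom_of[gi])
        if (!length(same)) next
        d <- abs((enh$start[same] + enh$end[same]) / 2 - tss[gi])
        j <- same[which.min(d)]
        assoc <- rbind(assoc, data.frame(
          enhancer_id = enh$enhancer_id[j], gene = g,
          score = round(stats::rgamma(1, 2, rate = 0.15), 2)
        ))
      }
    }
    list(genes = ann, enhancers = enhancer_db(enh, assoc))
  })
}

#' Simulate replicate H3K27ac peak sets per condition
#'
#' Produces, for each study condition, case and control replicate peak sets:
#' shared background peaks present in both groups (with replicate coordinate
#' jitter of at most `peak_jitter` bp), plus planted gains (case-only peaks)
#' and losses (control-only peaks) at the promoter window or an associated
#' enhancer of the genes named in the configuration's `peak_spec`.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config A [sim_config()].
#' @return Named list (one element per condition), each a list with `case`
#'   and `control`: lists of replicate peak data frames (BED-like, 0-based
#'   half-open) and `planted`: data frame of planted differential intervals.
#' @export
simulate_peaks <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- annotation$genes
  db <- annotation$enhancers
  with_seed(stage_seed(config$seed, 3L), {
    out <- list()
    for (cond in config$conditions) {
      spec <- config$peak_spec[config$peak_spec$condition == cond, , drop = FALSE]
      planted <- NULL
      if (nrow(spec)) {
        rows <- lapply(seq_len(nrow(spec)), function(i) {
          s <- spec[i, ]
          gi <- match(s$gene, ann$gene)
          if (s$element == "promoter") {
            centre <- ann$tss[gi]
            width <- round(stats::runif(1, 600, 1200))
            data.frame(chrom = ann$chrom[gi],
                       start = max(0L, centre - width %/% 2L),
                       end = centre + width %/% 2L,
                       gene = s$gene, element = s$element, change = s$change,
                       stringsAsFactors = FALSE)
          } else {
            aj <- db$associations[db$associations$gene == s$gene, ]
            if (!nrow(aj)) {
              stop(sprintf("gene %s has no associated enhancer", s$gene),
                   call. = FALSE)
            }
            e <- db$enhancers[match(aj$enhancer_id[1], db$enhancers$enhancer_id), ]
            data.frame(chrom = e$chrom, start = e$start, end = e$end,
                       gene = s$gene, element = s$element, change = s$change,
                       stringsAsFactors = FALSE)
          }
        })
        planted <- do.call(rbind, rows)
      }
      # background peaks at random promoters, identical truth in both groups
      bg_genes <- sample(ann$gene, min(config$n_background_peaks, nrow(ann)))
      bgi <- match(bg_genes, ann$gene)
      bg_width <- round(stats::runif(length(bgi), 600, 1500))
      bg <- data.frame(chrom = ann$chrom[bgi],
                       start = pmax(0L, ann$tss[bgi] - bg_width %/% 2L),
                       end = ann$tss[bgi] + bg_width %/% 2L,
                       stringsAsFactors = FALSE)
      jitter_df <- function(df) {
        j1 <- sample(-config$peak_jitter:config$peak_jitter, nrow(df), TRUE)
        j2 <- sample(-config$peak_jitter:config$peak_jitter, nrow(df), TRUE)
        df$start <- pmax(0L, df$start + j1)
        df$end <- pmax(df$start + 50L, df$end + j2)
        df
      }
      make_reps <- function(group) {
        extra <- if (is.null(planted)) NULL else {
          wanted <- if (group == "case") "gain" else "loss"
          planted[planted$change == wanted, c("chrom", "start", "end")]
        }
        base <- rbind(bg, extra)
        lapply(seq_len(config$chip_replicates), function(r) {
          df <- jitter_df(base)
          df <- df[order(df$chrom, df$start, df$end), ]
          df$name <- sprintf("%s_%s_rep%d_p%04d", cond, group, r,
                             seq_len(nrow(df)))
          df$score <- round(stats::runif(nrow(df), 5, 100), 2)
          df$strand <- "."
          rownames(df) <- NULL
          df
        })
      }
      out[[cond]] <- list(case = make_reps("case"),
                          control = make_reps("control"),
                          planted = planted)
    }
    out
  })
}

#' Simulate a peak-count matrix over consensus peaks
#'
#' For exercising the count-based differential-region mode: negative-binomial
#' counts per consensus peak and ChIP sample, with planted fold changes for
#' peaks overlapping planted gain/loss intervals (gains enriched in cases,
#' losses in controls).
#'
#' @param consensus Consensus peak data frame (`chrom`, `start`, `end`,
#'   `name`).
#' @param planted Data frame of planted differential intervals with columns
#'   `chrom`, `start`, `end`, `change`; may be `NULL`.
#' @param n_per_group Samples per group.
#' @param log2fc Planted absolute log2 fold change of differential peaks.
#' @param dispersion NB dispersion.
#' @param seed Integer seed.
#' @return A [count_matrix()] whose rows are consensus peak names.
#' @export
simulate_peak_counts <- function(consensus, planted, n_per_group = 4,
                                 log2fc = 2, dispersion = 0.05, seed = 1L) {
  with_seed(seed, {
    n <- nrow(consensus)
    base <- exp(stats::runif(n, log(80), log(400)))
    shift <- numeric(n)
    if (!is.null(planted) && nrow(planted)) {
      ov <- overlaps_any(consensus, planted)
      hit <- which(ov)
      for (i in hit) {
        ch <- planted$change[first_overlap(consensus[i, ], planted)]
        shift[i] <- if (ch == "gain") log2fc * log(2) else -log2fc * log(2)
      }
    }
    group <- rep(c("case", "control"), each = n_per_group)
    ids <- sprintf("chip_%s%d", substr(group, 1, 2),
                   c(seq_len(n_per_group), seq_len(n_per_group)))
    mu <- matrix(base, n, length(group))
    mu[, group == "case"] <- mu[, group == "case"] * exp(shift)
    y <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                n, dimnames = list(consensus$name, ids))
    count_matrix(y, data.frame(sample = ids, group = group, dataset = "chip"))
  })
}

#' Build a gene-set collection from the planted truth
#'
#' Returns the planted modules as gene sets plus random background sets, for
#' exercising over-representation and gene-set enrichment analysis with a
#' known signal.
#'
#' @param truth A `ground_truth` object from [simulate_counts()].
#' @param n_random Number of random background sets.
#' @param size_range Size range of random sets.
#' @param seed Integer seed.
#' @return A named list of character vectors (a gene-set collection).
#' @export
simulate_genesets <- function(truth, n_random = 20, size_range = c(20, 100),
                              seed = 1L) {
  with_seed(seed, {
    genes <- names(truth$modules)
    sets <- list()
    for (m in sort(unique(truth$modules[truth$modules > 0]))) {
      sets[[sprintf("MODULE_%d", m)]] <- genes[truth$modules == m]
    }
    for (i in seq_len(n_random)) {
      sz <- sample(size_range[1]:size_range[2], 1L)
      sets[[sprintf("RANDOM_%02d", i)]] <- sample(genes, sz)
    }
    sets
  })
}
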