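# Config-driven end-to-end orchestration: simulate (or accept) inputs,
# run per-dataset differential expression, call and annotate differential
# H3K27ac regions, integrate signatures across datasets and conditions, run
# enrichment, build the two co-expression networks, test module
# preservation, and report hub genes.  One global seed fans out to
# per-stage seeds so every stage is individually reproducible.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with defaults matching
#' the analysis parameters the package implements: raw p < 0.05 for
#' differential genes, FDR 0.05 for count-based differential regions, a
#' +/-3 kb promoter window, the count >= 15 in at least half the samples
#' expression filter, minimum module size 30 with eigengene merge height
#' 0.25, scale-free fit target R^2 = 0.8, 1000 preservation permutations,
#' and hub criteria kME > 0.8 plus top-10% intramodular connectivity with
#' top-5 reporting.
#'
#' @param sim A [sim_config()] describing the synthetic study (or `NULL`
#'   when `data` is supplied to [run_pipeline()]).
#' @param p_de Raw p threshold for differential expression calls.
#' @param fdr_der BH-adjusted p threshold for count-based regions.
#' @param min_correlation Sample-QC correlation threshold.
#' @param promoter_halfwidth Promoter window half-width (bp).
#' @param min_count,count_frac Low-expression filter parameters.
#' @param min_module_size,merge_height Module detection parameters.
#' @param target_r2 Scale-free fit target for soft-threshold selection.
#' @param soft_power Optional numeric vector of length 2 pinning the soft
#'   threshold per condition and bypassing selection.
#' @param n_perm Preservation permutations (>= 20).
#' @param kme_min,degree_quantile,top_n Hub criteria.
#' @param gsea_n_perm Permutations for GSEA.
#' @param der_mode Character vector of length 2: differential-region mode
#'   per condition, `"presence"` or `"counts"`.
#' @param seed Global seed.
#' @param outdir Optional output directory for result tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            p_de = 0.05,
                            fdr_der = 0.05,
                            min_correlation = 0.8,
                            promoter_halfwidth = 3000,
                            min_count = 15,
                            count_frac = 0.5,
                            min_module_size = 30,
                            merge_height = 0.25,
                            target_r2 = 0.8,
                            soft_power = NULL,
                            n_perm = 1000,
                            kme_min = 0.8,
                            degree_quantile = 0.9,
                            top_n = 5,
                            gsea_n_perm = 200,
                            der_mode = c("presence", "counts"),
                            seed = 1L,
                            outdir = NULL) {
  stopifnot_scalar(p_de, "p_de", 0, 1)
  stopifnot_scalar(fdr_der, "fdr_der", 0, 1)
  stopifnot_scalar(min_correlation, "min_correlation", 0, 1)
  stopifnot_scalar(promoter_halfwidth, "promoter_halfwidth", 0)
  stopifnot_scalar(merge_height, "merge_height", 0, 1)
  stopifnot_scalar(target_r2, "target_r2", 0, 1)
  stopifnot_scalar(kme_min, "kme_min", 0, 1.01)
  stopifnot_scalar(degree_quantile, "degree_quantile", 0, 1)
  if (n_perm < 20) stop("n_perm must be >= 20", call. = FALSE)
  if (!all(der_mode %in% c("presence", "counts"))) {
    stop('der_mode entries must be "presence" or "counts"', call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

# Short fingerprint of a configuration, embedded as a comment in every
# result table so outputs are traceable to their settings.
config_fingerprint <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "outdir")]),
               collapse = "")
  ints <- utf8ToInt(txt)
  h <- 0
  for (i in seq_along(ints)) h <- (h * 31 + ints[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_result_tsv <- function(df, path, fingerprint) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", fingerprint), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes every stage in order on simulated (or supplied) data: sample QC
#' and group balancing, NB-LRT differential expression per dataset,
#' consensus-peak and differential-region calling with promoter/enhancer
#' annotation per condition, signature merging with discordance exclusion,
#' cross-condition intersection, ORA/GSEA/term clustering, per-condition
#' signed co-expression networks with module detection, eigengenes and
#' module-trait correlation, module preservation (condition 1 as discovery,
#' condition 2 as test), and hub-gene identification in preserved,
#' trait-correlated modules. Identical config and seed give identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param data Optional pre-built inputs: list with `datasets`, `truth`,
#'   `annotation`, `peaks`, `genesets`; by default these are simulated from
#'   `config$sim`.
#' @return A list of class `run_report` with per-stage tallies and results.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (is.null(data)) {
    if (is.null(config$sim)) stop("either config$sim or data is required",
                                  call. = FALSE)
    sim <- config$sim
    sim$seed <- as.integer(seed)
    sim <- do.call(sim_config, sim[setdiff(names(sim), c("genes"))])
    counts_sim <- simulate_counts(sim)
    annotation <- simulate_annotation(sim)
    peaks <- simulate_peaks(annotation, sim)
    data <- list(datasets = counts_sim$datasets, truth = counts_sim$truth,
                 annotation = annotation$genes,
                 enhancers = annotation$enhancers,
                 peaks = peaks,
                 genesets = simulate_genesets(counts_sim$truth,
                                              seed = stage_seed(seed, 4L)))
    conditions <- sim$conditions
  } else {
    conditions <- unique(vapply(data$datasets,
                                function(d) d$meta$condition[1], ""))
  }
  log <- list()
  note <- function(...) log[[length(log) + 1L]] <<- sprintf(...)

  ## --- differential expression per dataset -------------------------------
  de_results <- list()
  de_lists <- list()
  for (ds in names(data$datasets)) {
    cm <- data$datasets[[ds]]
    qc <- sample_qc(cm, config$min_correlation)
    if (length(attr(qc, "removed"))) {
      note("dataset %s: removed samples %s (low correlation)", ds,
           paste(attr(qc, "removed"), collapse = ", "))
    }
    bal <- balance_groups(qc, seed = stage_seed(seed, 10L + match(ds, names(data$datasets))))
    res <- nb_lrt(bal, p_threshold = config$p_de)
    de_results[[ds]] <- res
    cond <- cm$meta$condition[1]
    de_lists[[ds]] <- list(dataset = ds, assay = "rna", condition = cond,
                           signature = de_signature(res))
    note("dataset %s: %d genes tested, %d differential", ds, nrow(res),
         sum(res$de))
  }

  ## --- differential H3K27ac regions per condition ------------------------
  db_filtered <- filter_enhancer_associations(data$enhancers)
  gader_lists <- list()
  gaders <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    pk <- data$peaks[[cond]]
    if (is.null(pk)) next
    cons_case <- consensus_peaks(pk$case)
    cons_ctrl <- consensus_peaks(pk$control)
    mode <- config$der_mode[min(ci, length(config$der_mode))]
    if (mode == "presence") {
      ders <- differential_regions_presence(cons_case, cons_ctrl)
    } else {
      cons_all <- consensus_peaks(c(pk$case, pk$control))
      pc <- simulate_peak_counts(cons_all, pk$planted,
                                 seed = stage_seed(seed, 20L + ci))
      hits <- differential_regions_counts(pc, fdr = config$fdr_der)
      ders <- cons_all[match(hits$peak, cons_all$name), , drop = FALSE]
      ders$direction <- hits$direction
    }
    ann <- annotate_peaks(ders, data$annotation, db_filtered,
                          config$promoter_halfwidth)
    gaders[[cond]] <- ann
    gader_lists[[cond]] <- list(dataset = paste0(cond, "_chip"),
                                assay = "chip", condition = cond,
                                signature = gader_signature(ann))
    note("condition %s: %d differential regions (%s mode) -> %d region-associated genes",
         cond, nrow(ders), mode, length(unique(ann$gene)))
  }

  ## --- signature integration ---------------------------------------------
  signatures <- list()
  for (cond in conditions) {
    entries <- c(Filter(function(e) e$condition == cond, de_lists),
                 Filter(function(e) e$condition == cond, gader_lists))
    entries <- Filter(function(e) length(e$signature) > 0, entries)
    signatures[[cond]] <- merge_condition_signature(entries, condition = cond)
    note("condition %s: signature of %d genes, %d discordant excluded", cond,
         length(signatures[[cond]]$signature),
         length(signatures[[cond]]$excluded_discordant))
  }
  common <- intersect_conditions(signatures[[1]], signatures[[2]])
  note("%d common genes, %d concordant, %d discordant", common$n_common,
       common$n_concordant, length(common$discordant))

  ## --- enrichment ---------------------------------------------------------
  universe <- sort(unique(unlist(lapply(de_results, function(r) r$gene))))
  query <- intersect(names(common$concordant), universe)
  ora_res <- ora(query, universe, data$genesets)
  mean_lfc <- gene_mean_log2fc(de_results, conditions,
                               lapply(data$datasets, function(d) d$meta$condition[1]))
  gsea_res <- gsea(mean_lfc, data$genesets, n_perm = config$gsea_n_perm,
                   seed = stage_seed(seed, 30L))
  sig_terms <- ora_res$term[ora_res$significant]
  term_clusters <- NULL
  if (length(sig_terms) >= 2L) {
    k <- min(5L, length(sig_terms))
    term_clusters <- term_similarity_clusters(sig_terms, data$genesets, k = k)
  }

  ## --- co-expression networks --------------------------------------------
  selected <- sort(unique(c(
    unlist(lapply(signatures, function(s) names(s$signature))),
    unlist(lapply(gaders, function(g) unique(g$gene)))
  )))
  networks <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    beta <- if (!is.null(config$soft_power)) {
      config$soft_power[min(ci, length(config$soft_power))]
    } else NULL
    networks[[cond]] <- condition_network(
      data$datasets, cond, selected = selected,
      min_count = config$min_count, count_frac = config$count_frac,
      target_r2 = config$target_r2, soft_power = beta,
      min_module_size = config$min_module_size,
      merge_height = config$merge_height
    )
    nw <- networks[[cond]]
    note("condition %s network: %d genes, beta = %s, %d modules", cond,
         nrow(nw$expr), format(nw$beta),
         length(setdiff(unique(nw$labels), 0L)))
  }

  ## --- preservation and hubs ---------------------------------------------
  disc <- networks[[conditions[1]]]
  test <- networks[[conditions[2]]]
  preservation <- NULL
  hubs <- NULL
  if (any(disc$labels > 0)) {
    preservation <- preservation_permutation(
      list(expr = disc$expr, network = disc$network, labels = disc$labels),
      list(expr = test$expr, network = test$network),
      n_perm = config$n_perm, seed = stage_seed(seed, 40L)
    )
    preserved_mods <- preservation$modules$module[preservation$modules$preserved]
    correlated <- if (!is.null(disc$module_trait)) {
      as.integer(sub("ME", "", disc$module_trait$module[disc$module_trait$significant]))
    } else integer()
    target_mods <- intersect(preserved_mods, correlated)
    if (length(target_mods)) {
      sub_labels <- disc$labels
      sub_labels[!sub_labels %in% target_mods] <- 0L
      hubs <- hub_genes(disc$network, sub_labels, disc$eigengenes,
                        config$degree_quantile, config$kme_min, config$top_n)
    }
    note("%d of %d modules preserved; hubs reported for %d trait-correlated preserved modules",
         sum(preservation$modules$preserved), nrow(preservation$modules),
         length(target_mods))
  }

  report <- structure(list(
    conditions = conditions,
    de_results = de_results,
    gaders = gaders,
    signatures = signatures,
    common = common,
    ora = ora_res,
    gsea = gsea_res,
    term_clusters = term_clusters,
    networks = networks,
    preservation = preservation,
    hubs = hubs,
    truth = data$truth,
    log = unlist(log),
    fingerprint = config_fingerprint(config)
  ), class = "run_report")

  if (!is.null(config$outdir)) write_run_report(report, config$outdir)
  report
}

#' Build one condition's co-expression network from its count datasets
#'
#' Convenience wrapper tying the preprocessing and network stages together
#' for a single study condition: low-count filtering per original dataset,
#' variance stabilization, batch adjustment (dataset as batch, case/control
#' protected), optional restriction to a selected gene universe,
#' soft-threshold selection (or a pinned power), signed network and TOM
#' construction, module detection, eigengenes and module-trait correlation
#' against the case/control trait.
#'
#' @param datasets Named list of [count_matrix()] objects (all conditions;
#'   the relevant ones are selected by their `condition` metadata).
#' @param condition Condition label to build the network for.
#' @param selected Optional gene universe to restrict to (e.g. the union of
#'   differential and region-associated genes).
#' @param min_count,count_frac Low-count filter parameters.
#' @param target_r2 Scale-free fit target.
#' @param soft_power Optional pinned soft-threshold power.
#' @param min_module_size,merge_height Module detection parameters.
#' @return List with `expr`, `network`, `labels`, `eigengenes`, `trait`,
#'   `module_trait`, `beta`.
#' @export
condition_network <- function(datasets, condition, selected = NULL,
                              min_count = 15, count_frac = 0.5,
                              target_r2 = 0.8, soft_power = NULL,
                              min_module_size = 30, merge_height = 0.25) {
  cond_sets <- Filter(function(d) d$meta$condition[1] == condition, datasets)
  if (!length(cond_sets)) stop("no datasets for condition ", condition,
                               call. = FALSE)
  retained <- low_count_filter(cond_sets, min_count, count_frac)
  genes <- if (is.null(selected)) retained else intersect(selected, retained)
  combined <- bind_count_matrices(cond_sets)
  expr <- vst_transform(combined)
  expr <- batch_adjust(expr, combined$meta$dataset, combined$meta$group)
  expr <- expr[genes, , drop = FALSE]
  expr <- expr[apply(expr, 1, stats::sd) > 0, , drop = FALSE]
  beta <- if (!is.null(soft_power)) soft_power else {
    pick_soft_threshold(expr, target_r2 = target_r2)
  }
  net <- build_network(expr, as.numeric(beta))
  labels <- detect_modules(net, expr, min_module_size, merge_height)
  me <- if (any(labels > 0)) module_eigengenes(expr, labels) else NULL
  trait <- as.numeric(combined$meta$group == "case")
  mt <- if (!is.null(me)) module_trait_correlation(me, trait) else NULL
  list(expr = expr, network = net, labels = labels, eigengenes = me,
       trait = trait, module_trait = mt, beta = as.numeric(beta))
}

# Gene-level ranking statistic for GSEA: the mean log2 fold change across
# the two conditions (per condition, the mean over its datasets).
gene_mean_log2fc <- function(de_results, conditions, dataset_conditions) {
  per_cond <- lapply(conditions, function(cond) {
    res <- de_results[unlist(dataset_conditions) == cond]
    tab <- do.call(rbind, lapply(res, function(r) r[, c("gene", "log2fc")]))
    tapply(tab$log2fc, tab$gene, mean)
  })
  genes <- Reduce(intersect, lapply(per_cond, names))
  ranking <- rowMeans(cbind(per_cond[[1]][genes], per_cond[[2]][genes]))
  setNames(as.numeric(ranking), genes)
}

#' Write the result tables of a pipeline run
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- report$fingerprint
  w <- function(df, name) {
    write_result_tsv(df, file.path(outdir, name), fp)
  }
  for (ds in names(report$de_results)) {
    w(as.data.frame(report$de_results[[ds]]), sprintf("de_%s.tsv", ds))
  }
  for (cond in names(report$gaders)) {
    w(as.data.frame(report$gaders[[cond]]), sprintf("gaders_%s.tsv", cond))
  }
  for (cond in names(report$signatures)) {
    s <- report$signatures[[cond]]
    w(data.frame(gene = names(s$signature), direction = s$signature),
      sprintf("signature_%s.tsv", cond))
  }
  w(data.frame(gene = report$common$common,
               status = ifelse(report$common$common %in% report$common$discordant,
                               "discordant", "concordant"),
               direction = ifelse(report$common$common %in% names(report$common$concordant),
                                  report$common$concordant[report$common$common], NA)),
    "common_signature.tsv")
  w(report$ora, "ora.tsv")
  w(report$gsea, "gsea.tsv")
  for (cond in names(report$networks)) {
    nw <- report$networks[[cond]]
    w(data.frame(gene = names(nw$labels), module = as.integer(nw$labels)),
      sprintf("modules_%s.tsv", cond))
    if (!is.null(nw$module_trait)) {
      w(nw$module_trait, sprintf("module_trait_%s.tsv", cond))
    }
  }
  if (!is.null(report$preservation)) {
    w(report$preservation$stats, "preservation_stats.tsv")
    w(report$preservation$modules, "preservation_modules.tsv")
  }
  if (!is.null(report$hubs)) {
    w(report$hubs$genes, "hub_genes.tsv")
  }
  writeLines(report$log, file.path(outdir, "pipeline_log.txt"))
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = " vs ")))
  cat(sprintf("  common genes: %d (%d concordant)\n", x$common$n_common,
              x$common$n_concordant))
  if (!is.null(x$preservation)) {
    cat(sprintf("  preserved modules: %d of %d\n",
                sum(x$preservation$modules$preserved),
                nrow(x$preservation$modules)))
  }
  invisible(x)
}
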