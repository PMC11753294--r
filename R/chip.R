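# Differential H3K27ac region calling and peak-to-gene annotation.
# Intervals are BED-convention throughout: 0-based, half-open; overlap means
# at least one shared base.  Overlap machinery is delegated to
# GenomicRanges/IRanges behind these helpers.

# data.frame (0-based half-open) -> GRanges (1-based closed)
df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Logical: does each interval in a overlap >= 1 bp with any interval in b?
overlaps_any <- function(a, b) {
  if (is.null(b) || nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  IRanges::overlapsAny(df_to_gr(a), df_to_gr(b), minoverlap = 1L)
}

# Index (into b) of the first interval overlapping the single interval a.
first_overlap <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(df_to_gr(a), df_to_gr(b), minoverlap = 1L)
  S4Vectors::subjectHits(hits)[1]
}

#' Enhancer database: scored intervals plus gene associations
#'
#' @param enhancers Data frame: `chrom`, `start`, `end`, `enhancer_id`,
#'   `score` (0-based half-open intervals).
#' @param associations Data frame: `enhancer_id`, `gene`, `score`.
#' @return A list of class `enhancer_db`.
#' @export
enhancer_db <- function(enhancers, associations) {
  enhancers <- as.data.frame(enhancers)
  associations <- as.data.frame(associations)
  stopifnot(all(c("chrom", "start", "end", "enhancer_id", "score") %in%
                  names(enhancers)),
            all(c("enhancer_id", "gene", "score") %in% names(associations)))
  if (!all(associations$enhancer_id %in% enhancers$enhancer_id)) {
    stop("associations reference unknown enhancers", call. = FALSE)
  }
  if (any(enhancers$score < 0) || any(associations$score < 0)) {
    stop("scores must be >= 0", call. = FALSE)
  }
  structure(list(enhancers = enhancers, associations = associations),
            class = "enhancer_db")
}

#' Consensus peaks across replicates
#'
#' Merges replicate peak sets (union of overlapping intervals, bedtools-merge
#' style clustering at >= 1 bp overlap) and keeps merged intervals supported
#' by peaks from at least `min_replicates` distinct replicates.
#'
#' @param replicates List of peak data frames (`chrom`, `start`, `end`, ...).
#' @param min_replicates Minimum number of supporting replicates.
#' @return Data frame of consensus intervals (`chrom`, `start`, `end`,
#'   `name`, `n_replicates`), 0-based half-open, sorted.
#' @export
consensus_peaks <- function(replicates, min_replicates = 2) {
  if (length(replicates) < 1L) stop("need >= 1 replicate", call. = FALSE)
  if (min_replicates > length(replicates)) {
    stop("min_replicates exceeds the number of replicates", call. = FALSE)
  }
  all_peaks <- do.call(rbind, lapply(seq_along(replicates), function(i) {
    df <- replicates[[i]][, c("chrom", "start", "end")]
    df$replicate <- i
    df
  }))
  gr <- df_to_gr(all_peaks)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr, minoverlap = 1L)
  support <- tapply(all_peaks$replicate[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(r) length(unique(r)))
  n_rep <- integer(length(merged))
  n_rep[as.integer(names(support))] <- as.integer(support)
  keep <- n_rep >= min_replicates
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged))[keep],
    start = GenomicRanges::start(merged)[keep] - 1L,
    end = GenomicRanges::end(merged)[keep],
    n_replicates = n_rep[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$name <- sprintf("peak%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "n_replicates")]
}

#' Count-based differential regions
#'
#' Runs the NB likelihood-ratio test on a peak-count matrix (consensus peaks
#' quantified per ChIP sample) and calls differentially enriched regions at a
#' BH-adjusted p-value below `fdr`, signed by the fold-change direction.
#'
#' @param peak_counts A [count_matrix()] whose rows are consensus peak names.
#' @param fdr Adjusted-p threshold.
#' @return Data frame: `peak`, `log2fc`, `pvalue`, `padj`, `direction`
#'   (+1 gain in case / -1 loss), restricted to called regions.
#' @export
differential_regions_counts <- function(peak_counts, fdr = 0.05) {
  res <- nb_lrt(peak_counts)
  hit <- res[res$padj < fdr & res$log2fc != 0, ]
  data.frame(peak = hit$gene, log2fc = hit$log2fc, pvalue = hit$pvalue,
             padj = hit$padj, direction = sign(hit$log2fc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Presence/absence differential regions
#'
#' For low-quality ChIP designs where count-based testing is unreliable:
#' gains are case consensus peaks with no (>= 1 bp) overlap in the control
#' set, losses are control peaks with no overlap in the case set.
#'
#' @param case,control Consensus peak data frames.
#' @return Data frame: `chrom`, `start`, `end`, `name`, `direction` (+1 gain,
#'   -1 loss).
#' @export
differential_regions_presence <- function(case, control) {
  gains <- case[!overlaps_any(case, control), , drop = FALSE]
  losses <- control[!overlaps_any(control, case), , drop = FALSE]
  out <- rbind(
    if (nrow(gains)) cbind(gains[, c("chrom", "start", "end", "name")],
                           direction = 1) else NULL,
    if (nrow(losses)) cbind(losses[, c("chrom", "start", "end", "name")],
                            direction = -1) else NULL
  )
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      direction = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Filter enhancer-gene associations to a high-confidence subset
#'
#' Keeps enhancers whose enhancer score reaches the first quartile (Q1/P25,
#' linear-interpolation quantile) of all enhancer scores and associations
#' whose association score reaches the Q1 of all association scores; then
#' drops entirely any enhancer still associated with more than five genes.
#'
#' @param db An [enhancer_db()].
#' @param max_genes Maximum retained genes per enhancer.
#' @return A filtered [enhancer_db()].
#' @export
filter_enhancer_associations <- function(db, max_genes = 5) {
  stopifnot(inherits(db, "enhancer_db"))
  if (!nrow(db$enhancers)) stop("empty enhancer database", call. = FALSE)
  q1_enh <- stats::quantile(db$enhancers$score, 0.25, names = FALSE)
  q1_assoc <- stats::quantile(db$associations$score, 0.25, names = FALSE)
  enh <- db$enhancers[db$enhancers$score >= q1_enh, , drop = FALSE]
  assoc <- db$associations[db$associations$score >= q1_assoc &
                             db$associations$enhancer_id %in% enh$enhancer_id, ,
                           drop = FALSE]
  n_genes <- table(assoc$enhancer_id)
  too_many <- names(n_genes)[n_genes > max_genes]
  enh <- enh[!enh$enhancer_id %in% too_many, , drop = FALSE]
  assoc <- assoc[!assoc$enhancer_id %in% too_many, , drop = FALSE]
  if (!nrow(assoc)) {
    warning("no enhancer associations survive filtering")
  }
  enhancer_db(enh, assoc)
}

#' Annotate differential regions to genes
#'
#' Classifies each signed differential region: (i) *promoter* if it overlaps
#' the strand-aware window `[TSS - w, TSS + w)` of any gene, assigned to the
#' gene with the nearest TSS (ties broken by the lexicographically smallest
#' gene id); (ii) otherwise, if it overlaps no gene body, *intergenic* and
#' assigned to all genes associated with overlapping filtered enhancers;
#' (iii) otherwise (genic but not promoter-proximal) discarded. Assigned
#' genes inherit the region's gain/loss direction.
#'
#' @param ders Signed differential regions (`chrom`, `start`, `end`, `name`,
#'   `direction`).
#' @param annotation Gene annotation data frame (`gene`, `chrom`, `start`,
#'   `end`, `strand`, `tss`).
#' @param db A filtered [enhancer_db()] (or `NULL` to skip enhancer
#'   assignment).
#' @param promoter_halfwidth Half-width `w` of the promoter window in bp.
#' @return Data frame of class `gader_set`: `gene`, `direction`, `element`
#'   (`"promoter"`/`"enhancer"`), `peak` (source region name); one row per
#'   (gene, peak), deduplicated.
#' @export
annotate_peaks <- function(ders, annotation, db = NULL,
                           promoter_halfwidth = 3000) {
  if (!nrow(ders)) {
    out <- data.frame(gene = character(), direction = numeric(),
                      element = character(), peak = character())
    class(out) <- c("gader_set", "data.frame")
    return(out)
  }
  known <- ders$chrom %in% annotation$chrom
  if (any(!known)) {
    warning(sprintf("%d region(s) on chromosomes absent from the annotation skipped",
                    sum(!known)))
    ders <- ders[known, , drop = FALSE]
  }
  promoters <- data.frame(chrom = annotation$chrom,
                          start = pmax(0L, annotation$tss - promoter_halfwidth),
                          end = annotation$tss + promoter_halfwidth,
                          gene = annotation$gene,
                          tss = annotation$tss)
  bodies <- annotation[, c("chrom", "start", "end", "gene")]
  der_gr <- df_to_gr(ders)
  prom_hits <- GenomicRanges::findOverlaps(der_gr, df_to_gr(promoters),
                                           minoverlap = 1L)
  body_any <- overlaps_any(ders, bodies)
  enh_hits <- NULL
  if (!is.null(db) && nrow(db$enhancers)) {
    enh_hits <- GenomicRanges::findOverlaps(der_gr, df_to_gr(db$enhancers),
                                            minoverlap = 1L)
  }
  rows <- list()
  prom_q <- S4Vectors::queryHits(prom_hits)
  prom_s <- S4Vectors::subjectHits(prom_hits)
  for (i in seq_len(nrow(ders))) {
    cand <- prom_s[prom_q == i]
    if (length(cand)) {
      # distance from the region to each candidate TSS (0 if TSS inside)
      tss <- promoters$tss[cand]
      d <- pmax(0, pmax(ders$start[i] - tss, tss - (ders$end[i] - 1L)))
      ord <- order(d, promoters$gene[cand])
      g <- promoters$gene[cand][ord[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, direction = ders$direction[i], element = "promoter",
        peak = ders$name[i], stringsAsFactors = FALSE
      )
    } else if (!body_any[i]) {
      if (!is.null(enh_hits)) {
        e_idx <- S4Vectors::subjectHits(enh_hits)[S4Vectors::queryHits(enh_hits) == i]
        if (length(e_idx)) {
          eids <- db$enhancers$enhancer_id[e_idx]
          genes <- unique(db$associations$gene[db$associations$enhancer_id %in% eids])
          if (length(genes)) {
            rows[[length(rows) + 1L]] <- data.frame(
              gene = genes, direction = ders$direction[i],
              element = "enhancer", peak = ders$name[i],
              stringsAsFactors = FALSE
            )
          }
        }
      }
    } # genic non-promoter: discarded
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene = character(), direction = numeric(),
               element = character(), peak = character())
  }
  out <- unique(out)
  out <- out[out$gene %in% annotation$gene, , drop = FALSE]
  out <- out[order(out$gene, out$peak), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gader_set", "data.frame")
  out
}

#' Extract a gene -> direction signature from an annotated region set
#'
#' Collapses a `gader_set` to one direction per gene; genes supported by both
#' gains and losses are dropped here and handled as discordant downstream.
#'
#' @param gaders A `gader_set` from [annotate_peaks()].
#' @return Named numeric vector of +1/-1 directions.
#' @export
gader_signature <- function(gaders) {
  if (!nrow(gaders)) return(setNames(numeric(0), character(0)))
  dirs <- tapply(gaders$direction, gaders$gene, function(d) {
    u <- unique(d)
    if (length(u) == 1L) u else NA_real_
  })
  dirs <- dirs[!is.na(dirs)]
  setNames(as.numeric(dirs), names(dirs))
}
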