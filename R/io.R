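# Plain-text readers and writers for the pipeline's interchange formats:
# counts TSV, sample metadata TSV, gene annotation TSV, enhancer table TSV,
# BED6 peak files (0-based half-open, written natively) and GMT gene-set
# collections.  Every reader validates and reports the offending row on
# malformed input; read(write(x)) round-trips exactly.

#' Write / read a gene x sample count table (TSV)
#'
#' First column `gene`, one integer column per sample.
#'
#' @param cm A [count_matrix()] (counts written; metadata written separately
#'   with [write_sample_meta_tsv()]).
#' @param path Output file.
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param meta_path Metadata TSV written by [write_sample_meta_tsv()].
#' @return `read_counts_tsv` returns a [count_matrix()].
#' @export
read_counts_tsv <- function(path, meta_path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be 'gene'", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer count at row %d (gene %s), column '%s'",
                 bad[1, 1], df$gene[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  }
  rownames(m) <- df$gene
  count_matrix(m, read_sample_meta_tsv(meta_path))
}

#' Write / read the per-sample metadata table (TSV)
#'
#' Columns `sample`, `group`, `dataset`, `condition`.
#'
#' @param meta Data frame (e.g. the `meta` element of a [count_matrix()]).
#' @param path Output file.
#' @export
write_sample_meta_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta_tsv
#' @export
read_sample_meta_tsv <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  required <- c("sample", "group", "dataset")
  if (!all(required %in% names(meta))) {
    stop("metadata needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  meta
}

#' Write / read BED6 peak intervals (0-based, half-open)
#'
#' @param peaks Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output file.
#' @export
write_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name else ".",
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", bad[1]),
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: invalid coordinates", bad[1]),
         call. = FALSE)
  }
  data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = start,
    end = end,
    name = vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".", ""),
    score = suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "0", ""))),
    strand = vapply(fields, function(f) if (length(f) >= 6) f[[6]] else ".", ""),
    stringsAsFactors = FALSE
  )
}

#' Write / read the gene annotation table (TSV)
#'
#' Columns `gene`, `chrom`, `start`, `end`, `strand`, `tss` (0-based
#' half-open gene bodies).
#'
#' @param annotation Data frame as produced by [simulate_annotation()].
#' @param path Output file.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  needed <- c("gene", "chrom", "start", "end", "strand", "tss")
  if (!all(needed %in% names(ann))) {
    stop("annotation needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Write / read the enhancer association table (TSV)
#'
#' One row per (enhancer, gene) association: `chrom`, `start`, `end`,
#' `enhancer_id`, `enhancer_score`, `gene`, `association_score`.
#'
#' @param db An [enhancer_db()].
#' @param path Output file.
#' @export
write_enhancers_tsv <- function(db, path) {
  merged <- merge(db$associations, db$enhancers, by = "enhancer_id",
                  suffixes = c("_assoc", "_enh"))
  out <- data.frame(chrom = merged$chrom, start = merged$start,
                    end = merged$end, enhancer_id = merged$enhancer_id,
                    enhancer_score = merged$score_enh, gene = merged$gene,
                    association_score = merged$score_assoc)
  out <- out[order(out$enhancer_id, out$gene), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enhancers_tsv
#' @export
read_enhancers_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  needed <- c("chrom", "start", "end", "enhancer_id", "enhancer_score",
              "gene", "association_score")
  if (!all(needed %in% names(df))) {
    stop("enhancer table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  enh <- unique(df[, c("chrom", "start", "end", "enhancer_id",
                       "enhancer_score")])
  names(enh)[5] <- "score"
  assoc <- df[, c("enhancer_id", "gene", "association_score")]
  names(assoc)[3] <- "score"
  enhancer_db(enh, assoc)
}

#' Write / read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `id<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions)) {
      descriptions[[id]]
    } else "na"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]),
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, "", 2), ids)
  sets
}

#' Write / read a simulation configuration as YAML
#'
#' Serializes the scalar and table fields of a [sim_config()] so a synthetic
#' study is fully described by a text file plus its seed.
#'
#' @param config A [sim_config()].
#' @param path Output file.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- lapply(config, function(x) if (is.data.frame(x)) as.list(x) else x)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  for (f in c("module_spec", "de_spec", "peak_spec")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.data.frame(obj[[f]])
  }
  obj$baseline_mean_log_range <- as.numeric(obj$baseline_mean_log_range)
  do.call(sim_config, obj[setdiff(names(obj), "genes")])
}
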