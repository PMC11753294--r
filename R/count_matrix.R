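#' Gene-by-sample count matrix with sample metadata
#'
#' The basic expression container of the pipeline: an integer matrix of
#' gene-level counts (rows = genes, columns = samples) together with
#' per-sample metadata giving, for every sample, the contrast group
#' (`"case"` or `"control"`), the originating dataset (batch) and the study
#' condition the dataset interrogates (e.g. exposure vs. disease).
#'
#' @param counts Integer matrix, genes x samples, with row and column names.
#' @param meta Data frame with one row per column of `counts` and columns
#'   `sample`, `group` (`"case"`/`"control"`), `dataset` and optionally
#'   `condition` (study condition label).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `meta`.
#' @export
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' cm <- count_matrix(m, data.frame(sample = colnames(m),
#'                                  group = rep(c("case", "control"), 2),
#'                                  dataset = "d1"))
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) stop("counts must be integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample", "group", "dataset")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("meta is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"condition" %in% names(meta)) meta$condition <- NA_character_
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) {
    stop("every sample column must have a metadata row", call. = FALSE)
  }
  if (!all(meta$group %in% c("case", "control"))) {
    stop('meta$group must be "case" or "control"', call. = FALSE)
  }
  rownames(meta) <- meta$sample
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$meta$dataset, x$meta$group)
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Column subset keeping counts and metadata aligned.
subset_samples <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$meta[cm$meta$sample %in% colnames(cm$counts[, keep, drop = FALSE]), ])
}

# Combine count matrices (same gene universe) column-wise.
bind_count_matrices <- function(cms) {
  genes <- rownames(cms[[1]]$counts)
  for (cm in cms) {
    if (!identical(rownames(cm$counts), genes)) {
      stop("count matrices must share an identical gene universe", call. = FALSE)
    }
  }
  count_matrix(do.call(cbind, lapply(cms, function(cm) cm$counts)),
               do.call(rbind, lapply(cms, function(cm) cm$meta)))
}
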