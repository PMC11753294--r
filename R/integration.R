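# Merging per-dataset differential gene lists (RNA-seq DEGs and
# ChIP-annotated GADERs) into per-condition direction-signed signatures, with
# discordant genes excluded, followed by the cross-condition intersection
# that keeps direction-concordant genes.

#' Merge evidence lists into one condition signature
#'
#' Takes any number of gene -> direction lists (one per dataset/assay) and
#' forms the condition signature as their union, excluding genes observed
#' with both directions across lists ("discordant expression patterns").
#' Duplicate (gene, direction) evidence is collapsed; provenance is retained.
#'
#' @param lists A list of evidence entries; each entry is a list with fields
#'   `dataset` (id), `assay` (`"rna"`/`"chip"`), and `signature` (named
#'   numeric vector of +1/-1 directions).
#' @param condition Condition label attached to the result.
#' @return An object of class `signature_set`: list with `condition`,
#'   `signature` (named +1/-1 vector), `excluded_discordant` (gene set),
#'   `provenance` (data frame: gene, dataset, assay, direction), and
#'   `n_up`/`n_down` tallies.
#' @export
merge_condition_signature <- function(lists, condition = "condition") {
  if (!length(lists)) stop("need >= 1 evidence list", call. = FALSE)
  prov <- list()
  for (entry in lists) {
    sig <- entry$signature
    if (is.null(names(sig))) stop("signatures must be named vectors", call. = FALSE)
    if (!all(sig %in% c(-1, 1))) {
      stop("directions must be +1 or -1", call. = FALSE)
    }
    per_gene <- tapply(sig, names(sig), function(d) length(unique(d)))
    if (any(per_gene > 1L)) {
      stop(sprintf("input list (%s/%s) carries both directions for a gene: malformed",
                   entry$dataset, entry$assay), call. = FALSE)
    }
    sig <- sig[!duplicated(names(sig))]
    prov[[length(prov) + 1L]] <- data.frame(
      gene = names(sig), dataset = entry$dataset, assay = entry$assay,
      direction = as.numeric(sig), stringsAsFactors = FALSE
    )
  }
  prov <- do.call(rbind, prov)
  dirs <- tapply(prov$direction, prov$gene, function(d) unique(d), simplify = FALSE)
  n_dirs <- lengths(dirs)
  discordant <- sort(names(dirs)[n_dirs > 1L])
  kept <- dirs[n_dirs == 1L]
  signature <- setNames(as.numeric(unlist(kept)), names(kept))
  signature <- signature[order(names(signature))]
  structure(list(
    condition = condition,
    signature = signature,
    excluded_discordant = discordant,
    provenance = prov[order(prov$gene, prov$dataset), , drop = FALSE],
    n_up = sum(signature > 0),
    n_down = sum(signature < 0)
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s: %d genes (%d up, %d down), %d discordant excluded\n",
              x$condition, length(x$signature), x$n_up, x$n_down,
              length(x$excluded_discordant)))
  invisible(x)
}

#' Intersect two condition signatures
#'
#' Common genes are those present in both signatures; concordant genes share
#' the direction of change in both conditions, discordant genes flip sign.
#'
#' @param a,b `signature_set` objects.
#' @return An object of class `common_signature`: list with `common` (gene
#'   set), `concordant` (named direction vector), `discordant` (gene set),
#'   and up/down tallies.
#' @export
intersect_conditions <- function(a, b) {
  stopifnot(inherits(a, "signature_set"), inherits(b, "signature_set"))
  if (!length(a$signature) || !length(b$signature)) {
    stop("both signatures must be non-empty", call. = FALSE)
  }
  common <- sort(intersect(names(a$signature), names(b$signature)))
  same <- common[a$signature[common] == b$signature[common]]
  concordant <- a$signature[same]
  discordant <- setdiff(common, same)
  structure(list(
    common = common,
    concordant = concordant,
    discordant = discordant,
    n_common = length(common),
    n_concordant = length(concordant),
    n_up = sum(concordant > 0),
    n_down = sum(concordant < 0)
  ), class = "common_signature")
}

#' @export
print.common_signature <- function(x, ...) {
  cat(sprintf("<common_signature> %d common genes: %d concordant (%d up, %d down), %d discordant\n",
              x$n_common, x$n_concordant, x$n_up, x$n_down,
              length(x$discordant)))
  invisible(x)
}
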