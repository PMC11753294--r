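# Scoring detected structure against the planted ground truth of the
# synthetic study: module recovery and preservation-call accuracy.

#' Score module recovery against planted module labels
#'
#' Computes the adjusted Rand index between detected module labels and the
#' planted labels over the planted-module genes (background genes have no
#' expected co-membership and are ignored), plus a majority-vote mapping of
#' each detected module to a planted module (0 = background).
#'
#' @param labels Named detected labels (0 = unassigned).
#' @param truth_modules Named planted gene -> module vector (0 = background).
#' @return List with `ari` and `mapping` (data frame: detected, planted,
#'   purity, size).
#' @export
score_module_recovery <- function(labels, truth_modules) {
  genes <- intersect(names(labels), names(truth_modules))
  lab <- labels[genes]
  tru <- truth_modules[genes]
  planted <- tru > 0
  ari <- adjusted_rand_index(lab[planted], tru[planted])
  mapping <- do.call(rbind, lapply(setdiff(sort(unique(lab)), 0L), function(m) {
    members <- genes[lab == m]
    tt <- table(tru[members])
    data.frame(detected = m,
               planted = as.integer(names(tt)[which.max(tt)]),
               purity = max(tt) / length(members),
               size = length(members))
  }))
  list(ari = ari, mapping = mapping)
}

#' Score preservation calls against the planted shared/specific design
#'
#' Maps each detected discovery module to its majority planted module and
#' compares the preserved flag with the planted expectation: modules mapping
#' to a shared planted module should be preserved, modules mapping to a
#' condition-specific planted module should not. Modules mapping to
#' background (planted 0) have no expectation and are excluded.
#'
#' @param preservation A `preservation_report`.
#' @param labels Detected discovery labels.
#' @param truth A `ground_truth` (uses `modules` and `module_spec$shared`).
#' @param min_purity Minimum majority purity for a detected module to be
#'   scored.
#' @return List with `sensitivity` (fraction of shared-mapped modules called
#'   preserved), `specificity` (fraction of specific-mapped modules called
#'   not preserved), and the scored `table`.
#' @export
score_preservation_calls <- function(preservation, labels, truth,
                                     min_purity = 0.5) {
  rec <- score_module_recovery(labels, truth$modules)
  map <- rec$mapping
  map <- map[map$planted > 0 & map$purity >= min_purity, , drop = FALSE]
  shared <- truth$module_spec$shared[match(map$planted,
                                           truth$module_spec$module)]
  preserved <- preservation$modules$preserved[match(map$detected,
                                                    preservation$modules$module)]
  tab <- data.frame(detected = map$detected, planted = map$planted,
                    shared = shared, preserved = preserved)
  sens <- if (any(shared)) mean(preserved[shared]) else NA_real_
  spec <- if (any(!shared)) mean(!preserved[!shared]) else NA_real_
  list(sensitivity = sens, specificity = spec, table = tab)
}
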