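# Evaluation of a pipeline run against the generator's planted ground truth.

# Map each called domain to the true TAD with maximal bp overlap.
match_called_to_true <- function(called, truth_tads) {
  true_dom <- truth_tads %>% filter(.data$is_domain)
  vapply(seq_len(nrow(called)), function(i) {
    ov <- pmin(called$end[i], true_dom$end) - pmax(called$start[i], true_dom$start)
    if (max(ov) <= 0) return(NA_character_)
    true_dom$tad_id[which.max(ov)]
  }, character(1))
}

#' Recall of planted TAD boundaries
#'
#' Fraction of true internal boundaries matched by a called domain boundary
#' within `tol_bins` bins.
#'
#' @param called Called segmentation ([call_tads()]).
#' @param truth A `tad_sim` or its `truth` element.
#' @param tol_bins Tolerance in bins (default 1).
#' @return A number in `[0, 1]`.
#' @export
boundary_recall <- function(called, truth, tol_bins = 1) {
  if (inherits(truth, "tad_sim")) truth <- truth$truth
  res <- truth$config$resolution_bp
  true_dom <- truth$tads %>% filter(.data$is_domain)
  chrom_end <- max(truth$tads$end)
  true_bounds <- setdiff(unique(c(true_dom$start, true_dom$end)), c(0, chrom_end))
  called_dom <- called %>% filter(.data$is_domain)
  called_bounds <- unique(c(called_dom$start, called_dom$end))
  if (length(true_bounds) == 0) abort("ground truth has no internal boundaries")
  hit <- vapply(true_bounds, function(b) {
    any(abs(called_bounds - b) <= tol_bins * res)
  }, logical(1))
  mean(hit)
}

#' Precision and recall of planted clique edges
#'
#' Maps each called TAD to the true TAD with maximal overlap, translates the
#' significant called pairs into true-TAD pairs, and compares them with the
#' planted clique edge set.
#'
#' @param pairs Pair-test tibble ([call_significant_interactions()]); only
#'   significant rows are used.
#' @param called Called segmentation the pairs were computed on.
#' @param truth A `tad_sim` or its `truth` element.
#' @return Tibble with `precision`, `recall`, `n_called`, `n_planted`.
#' @export
planted_edge_recovery <- function(pairs, called, truth) {
  if (inherits(truth, "tad_sim")) truth <- truth$truth
  sig <- pairs %>% filter(.data$significant)
  called_dom <- called %>% filter(.data$is_domain)
  lut <- setNames(match_called_to_true(called_dom, truth$tads), called_dom$tad_id)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  called_edges <- unique(stats::na.omit(edge_key(lut[sig$tad_a], lut[sig$tad_b])))
  # self-mapped pairs (two called TADs hitting one true TAD) are not edges
  called_edges <- called_edges[!grepl("^(.*)\r\\1$", called_edges)]
  planted <- edge_key(truth$clique_edges$tad_a, truth$clique_edges$tad_b)
  tp <- sum(called_edges %in% planted)
  tibble(
    precision = if (length(called_edges) == 0) NA_real_ else tp / length(called_edges),
    recall = if (length(planted) == 0) NA_real_ else tp / length(planted),
    n_called = length(called_edges),
    n_planted = length(planted)
  )
}
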