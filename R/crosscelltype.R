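# Matching TAD cliques across cell types by maximal Jaccard index and
# clustering the resulting connectivity profiles.

#' Base-pair footprints of TAD cliques
#'
#' The footprint of a clique is the merged union of its member TADs'
#' intervals, so similarity across cell types does not depend on matching
#' TAD boundary calls.
#'
#' @param cliques List of cliques (character vectors of TAD ids), e.g. the
#'   size >= 3 entries of [maximal_cliques()].
#' @param tads Tibble of TAD intervals with `tad_id`.
#' @return Tibble `clique_id`, `chrom`, `start`, `end` (merged, sorted).
#' @export
clique_footprints <- function(cliques, tads) {
  purrr::imap(cliques, function(members, i) {
    iv <- tads %>% filter(.data$tad_id %in% members)
    if (nrow(iv) != length(members)) {
      abort("clique members missing from the TAD table")
    }
    merge_intervals(iv) %>%
      mutate(clique_id = sprintf("clique_%03d", i), .before = 1)
  }) %>% bind_rows()
}

#' Jaccard index between two genomic footprints
#'
#' Intersection over union in base pairs, summed across chromosomes.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return A number in `[0, 1]`.
#' @export
clique_jaccard <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  if (nrow(a) == 0 && nrow(b) == 0) abort("both footprints are empty")
  inter <- intersect_bp(a, b)
  uni <- total_bp(a) + total_bp(b) - inter
  inter / uni
}

#' Maximal-Jaccard clique match matrix
#'
#' For every clique of the reference cell type, finds the best-matching
#' clique (maximal Jaccard index) in each other cell type.
#'
#' @param reference Footprint tibble of the reference cell type
#'   ([clique_footprints()]).
#' @param others Named list of footprint tibbles, one per other cell type.
#' @return Numeric matrix: rows = reference clique ids, columns = cell types,
#'   entries = maximal JI.
#' @export
max_ji_matrix <- function(reference, others) {
  ref_ids <- unique(reference$clique_id)
  if (length(ref_ids) == 0) abort("reference has no cliques")
  if (is.null(names(others)) || any(!nzchar(names(others)))) {
    abort("`others` must be a named list of footprint tibbles")
  }
  m <- matrix(0, length(ref_ids), length(others),
              dimnames = list(ref_ids, names(others)))
  for (ct in names(others)) {
    fp <- others[[ct]]
    other_ids <- unique(fp$clique_id)
    if (length(other_ids) == 0) {
      warn(sprintf("cell type '%s' has no cliques; its column is all zero", ct))
      next
    }
    for (rid in ref_ids) {
      a <- reference[reference$clique_id == rid, , drop = FALSE]
      m[rid, ct] <- max(vapply(other_ids, function(oid) {
        clique_jaccard(a, fp[fp$clique_id == oid, , drop = FALSE])
      }, double(1)))
    }
  }
  m
}

#' Cluster clique connectivity profiles with k-means
#'
#' Clusters the rows of a maximal-JI matrix with k-means (multiple restarts,
#' seeded). Cluster labels are relabeled in descending order of cluster mean
#' JI so the numbering is deterministic and interpretable: cluster 1 holds
#' the cliques most conserved across cell types.
#'
#' @param ji_matrix Matrix from [max_ji_matrix()].
#' @param k Number of clusters (default 8).
#' @param seed Integer seed.
#' @param nstart Random restarts (default 10).
#' @return A `clique_clusters` object: `labels` tibble (`clique_id`,
#'   `cluster`), `cluster_means` tibble (`cluster`, `n_cliques`, `mean_ji`),
#'   and the total within-cluster sum of squares (`tot_withinss`).
#' @export
cluster_cliques <- function(ji_matrix, k = 8, seed = 1, nstart = 10) {
  if (nrow(ji_matrix) < k) {
    abort(sprintf("only %d cliques but k = %d; use a smaller k",
                  nrow(ji_matrix), k))
  }
  set.seed(seed)
  if (k == nrow(ji_matrix)) {
    # degenerate limit: every profile its own cluster, zero within-cluster SS
    km <- list(cluster = seq_len(k), tot.withinss = 0)
  } else {
    km <- kmeans(ji_matrix, centers = k, nstart = nstart)
  }
  raw_means <- vapply(seq_len(k), function(cl) {
    mean(ji_matrix[km$cluster == cl, , drop = FALSE])
  }, double(1))
  relabel <- match(seq_len(k), order(-raw_means)) # old label -> new label
  labels <- tibble(
    clique_id = rownames(ji_matrix),
    cluster = relabel[km$cluster]
  )
  cluster_means <- labels %>%
    group_by(.data$cluster) %>%
    summarise(n_cliques = dplyr::n(), .groups = "drop") %>%
    mutate(mean_ji = sort(raw_means, decreasing = TRUE)) %>%
    arrange(.data$cluster)
  structure(
    list(labels = labels, cluster_means = cluster_means,
         tot_withinss = km$tot.withinss, k = k),
    class = "clique_clusters"
  )
}

#' @export
print.clique_clusters <- function(x, ...) {
  cat(sprintf("<clique_clusters> k = %d over %d cliques\n", x$k, nrow(x$labels)))
  print(x$cluster_means)
  invisible(x)
}

#' @method tidy clique_clusters
#' @export
tidy.clique_clusters <- function(x, ...) {
  x$labels %>% left_join(x$cluster_means, by = "cluster")
}

#' @method glance clique_clusters
#' @export
glance.clique_clusters <- function(x, ...) {
  tibble(k = x$k, n_cliques = nrow(x$labels), tot_withinss = x$tot_withinss,
         max_mean_ji = max(x$cluster_means$mean_ji))
}
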