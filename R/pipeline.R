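# End-to-end orchestration: simulate/ingest -> call TADs -> test interactions
# -> cliques -> characterize -> cross-cell-type clustering, with a JSON
# provenance manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param gamma,fdr,min_fold,n_strata,window_bp,k Stage parameters (TAD
#'   caller resolution, FDR threshold, fold filter, distance strata, CTCF
#'   boundary window, k-means k).
#' @param n_celltypes Number of synthetic cell types to simulate for the
#'   cross-cell-type stage (replicate noise around the same planted truth).
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = NULL, gamma = 1.2,
                            fdr = 0.01, min_fold = 5, n_strata = 30,
                            window_bp = 50000, k = 8, n_celltypes = 2) {
  list(
    out_dir = out_dir, seed = as.integer(seed),
    sim = sim %||% sim_config(seed = seed),
    gamma = gamma, fdr = fdr, min_fold = min_fold, n_strata = n_strata,
    window_bp = window_bp, k = k, n_celltypes = n_celltypes
  )
}

write_tsv_commented <- function(x, path, params = NULL) {
  hdr <- sprintf("# tadcliques %s%s",
                 as.character(utils::packageVersion("tadcliques")),
                 if (is.null(params)) "" else paste0(" | ", params))
  readr::write_lines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
}

#' Run the full TAD-clique pipeline on synthetic data
#'
#' Executes, in order: simulate, call-tads, test-interactions, cliques,
#' characterize, cluster-cliques. All intermediate artifacts are written as
#' plain text (HiC-Pro matrix/bed, BED, TSV) so any stage can be re-fed with
#' real-data inputs, and a JSON manifest records parameters, seeds, row
#' counts and file checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "tadcliques",
    version = as.character(utils::packageVersion("tadcliques")),
    seed = config$seed,
    parameters = config[c("gamma", "fdr", "min_fold", "n_strata",
                          "window_bp", "k", "n_celltypes")],
    stages = list()
  )
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage,
      files = purrr::map(files, function(f) {
        list(path = basename(f), md5 = unname(tools::md5sum(f)),
             rows = length(readr::read_lines(f, progress = FALSE)))
      })
    )
  }

  # 1. simulate
  sim <- simulate_contact_map(config$sim)
  motifs <- simulate_ctcf_motifs(sim, window_bp = config$window_bp,
                                 seed = config$seed)
  ann <- simulate_annotations(sim, seed = config$seed)
  f_mat <- file.path(out, "sim.matrix")
  f_bins <- file.path(out, "sim_bins.bed")
  write_contact_matrix(sim$map, f_mat, f_bins)
  f_truth <- file.path(out, "truth.json")
  jsonlite::write_json(
    list(
      tads = sim$truth$tads,
      cliques = sim$truth$cliques,
      clique_edges = sim$truth$clique_edges
    ),
    f_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  f_motifs <- file.path(out, "ctcf_motifs.bed")
  write_bed(motifs, f_motifs)
  f_rep <- file.path(out, "repeats.bed")
  write_bed(ann$repeats, f_rep)
  f_sub <- file.path(out, "subcompartments.bed")
  write_bed(ann$subcompartments, f_sub)
  f_expr <- file.path(out, "expression.tsv")
  write_expression_table(ann$expression, f_expr)
  note("simulate", c(f_mat, f_bins, f_truth, f_motifs, f_rep, f_sub, f_expr))

  # 2. call TADs
  map <- read_contact_matrix(f_mat, f_bins)
  seg <- call_tads(map, gamma = config$gamma)
  f_tads <- file.path(out, "tads.bed")
  write_segmentation(seg, f_tads)
  note("call_tads", f_tads)

  # 3. test interactions
  tc <- aggregate_to_tads(map, seg)
  pairs <- call_significant_interactions(tc, fdr = config$fdr,
                                         min_fold = config$min_fold,
                                         n_strata = config$n_strata)
  f_pairs <- file.path(out, "pairs.tsv")
  write_tsv_commented(pairs, f_pairs,
                      sprintf("fdr=%g min_fold=%g strata=%d", config$fdr,
                              config$min_fold, config$n_strata))
  note("test_interactions", f_pairs)

  # 4. cliques
  graph <- build_tad_graph(pairs, nodes = seg$tad_id[seg$is_domain])
  cl <- maximal_cliques(graph)
  stats <- assign_clique_stats(graph, cl)
  f_cl <- file.path(out, "cliques.tsv")
  write_tsv_commented(
    tibble(
      clique_id = sprintf("clique_%03d", seq_along(cl)),
      size = lengths(cl),
      members = purrr::map_chr(cl, paste, collapse = ",")
    ),
    f_cl
  )
  f_stats <- file.path(out, "tad_stats.tsv")
  write_tsv_commented(stats, f_stats)
  note("cliques", c(f_cl, f_stats))

  # 5. characterize
  conv <- convergence_enrichment(stats, seg, motifs, window_bp = config$window_bp)
  f_conv <- file.path(out, "convergence.tsv")
  write_tsv_commented(conv, f_conv, sprintf("window_bp=%d p0=%.4f",
                                            config$window_bp, attr(conv, "p0")))
  cov <- purrr::map(c("LINE", "SINE"), function(class) {
    interval_coverage(seg %>% filter(.data$is_domain),
                      ann$repeats %>% filter(.data$name == class)) %>%
      mutate(repeat_class = class)
  }) %>% bind_rows()
  f_cov <- file.path(out, "coverage.tsv")
  write_tsv_commented(cov, f_cov)
  expr <- expression_compare(ann$expression, seg, stats)
  f_ex <- file.path(out, "expression_stats.tsv")
  write_tsv_commented(glance(expr), f_ex)
  ji <- subcompartment_overlap(seg %>% filter(.data$is_domain),
                               ann$subcompartments)
  f_ji <- file.path(out, "subcompartment_ji.tsv")
  write_tsv_commented(ji, f_ji)
  heat_files <- character(0)
  cat_tbl <- stats %>% filter(.data$max_clique_size >= 3)
  heat_cats <- list(clique = cat_tbl$tad_id,
                    non_clique = setdiff(stats$tad_id, cat_tbl$tad_id))
  for (cat_name in names(heat_cats)) {
    ids <- heat_cats[[cat_name]]
    if (length(ids) == 0) next
    hm <- aggregate_intra_tad_heatmap(map, seg %>% filter(.data$tad_id %in% ids))
    f_hm <- file.path(out, sprintf("heatmap_%s.tsv", cat_name))
    utils::write.table(hm$matrix, f_hm, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    heat_files <- c(heat_files, f_hm)
  }
  note("characterize", c(f_conv, f_cov, f_ex, f_ji, heat_files))

  # 6. cross-cell-type clustering: replicate simulations as extra cell types
  ref_cl <- cl[lengths(cl) >= 3]
  cluster_res <- NULL
  f_cluster <- character(0)
  if (length(ref_cl) >= 2 && config$n_celltypes >= 1) {
    ref_fp <- clique_footprints(ref_cl, seg)
    others <- list()
    for (i in seq_len(config$n_celltypes)) {
      cfg_i <- config$sim
      cfg_i$seed <- config$seed + i
      sim_i <- simulate_contact_map(cfg_i)
      seg_i <- call_tads(sim_i$map, gamma = config$gamma)
      tc_i <- aggregate_to_tads(sim_i$map, seg_i)
      pairs_i <- call_significant_interactions(tc_i, fdr = config$fdr,
                                               min_fold = config$min_fold,
                                               n_strata = config$n_strata)
      graph_i <- build_tad_graph(pairs_i, nodes = seg_i$tad_id[seg_i$is_domain])
      cl_i <- maximal_cliques(graph_i)
      cl_i <- cl_i[lengths(cl_i) >= 3]
      if (length(cl_i) > 0) {
        others[[sprintf("sim%02d", i)]] <- clique_footprints(cl_i, seg_i)
      }
    }
    if (length(others) > 0) {
      jim <- max_ji_matrix(ref_fp, others)
      k_use <- min(config$k, nrow(jim))
      cluster_res <- cluster_cliques(jim, k = k_use, seed = config$seed)
      f_jim <- file.path(out, "ji_matrix.tsv")
      write_tsv_commented(as_tibble(jim, rownames = "clique_id"), f_jim)
      f_lab <- file.path(out, "clusters.tsv")
      write_tsv_commented(cluster_res$labels, f_lab)
      f_cm <- file.path(out, "cluster_means.tsv")
      write_tsv_commented(cluster_res$cluster_means, f_cm)
      f_cluster <- c(f_jim, f_lab, f_cm)
    }
  }
  if (length(f_cluster) == 0) {
    f_skip <- file.path(out, "clusters_skipped.txt")
    readr::write_lines("cross-cell-type clustering skipped: too few cliques", f_skip)
    f_cluster <- f_skip
  }
  note("cluster_cliques", f_cluster)

  f_manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(
    sim = sim, segmentation = seg, pairs = pairs, graph = graph,
    cliques = cl, stats = stats, convergence = conv, coverage = cov,
    expression = expr, subcompartment = ji, clusters = cluster_res,
    manifest = manifest
  ))
}
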