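#' Configuration for the synthetic Hi-C generator
#'
#' Bundles the parameters of the generative model used to build ground-truthed
#' contact maps. Counts for a bin pair (i, j) are Poisson with mean
#' `L * (1 + |i - j|)^(-alpha) * (1 + beta * [same TAD]) * (1 + gamma_c *
#' [planted clique edge])`, i.e. a power-law distance decay modulated by
#' block-enriched TADs and planted long-range clique contacts.
#'
#' @param chrom Chromosome name used in all emitted intervals.
#' @param chrom_length_bp Chromosome length; rounded down to a whole number of
#'   bins.
#' @param resolution_bp Bin size (default 50 kb).
#' @param decay_exponent Power-law distance-decay exponent `alpha` (> 0).
#' @param tad_size_range_bp Two-element range of TAD sizes; domains are drawn
#'   uniformly on this range (default 0.2--1 Mb, the size band typical of
#'   mammalian TADs).
#' @param intra_tad_boost Multiplicative contact enrichment `beta` (>= 0)
#'   inside each TAD.
#' @param clique_sizes Integer vector of planted clique sizes (each >= 3);
#'   members are chosen pairwise linearly non-contiguous (at least one
#'   intervening TAD).
#' @param clique_boost Contact enrichment `gamma_c` (>= 0) applied to bin pairs
#'   spanning two TADs joined by a planted clique edge.
#' @param base_intensity Baseline Poisson intensity `L` (> 0) at distance 0.
#' @param seed Integer seed; the same config and seed reproduce the dataset
#'   byte for byte.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom = "chrS",
                       chrom_length_bp = 40e6,
                       resolution_bp = 50000,
                       decay_exponent = 1,
                       tad_size_range_bp = c(200000, 1000000),
                       intra_tad_boost = 3,
                       clique_sizes = c(3, 5, 8),
                       clique_boost = 8,
                       base_intensity = 100,
                       seed = 1) {
  assert_scalar_number(decay_exponent, "decay_exponent", lower = 1e-9)
  assert_scalar_number(intra_tad_boost, "intra_tad_boost", lower = 0)
  assert_scalar_number(clique_boost, "clique_boost", lower = 0)
  assert_scalar_number(base_intensity, "base_intensity", lower = 1e-12)
  stopifnot(length(tad_size_range_bp) == 2, tad_size_range_bp[1] <= tad_size_range_bp[2])
  if (length(clique_sizes) > 0 && any(clique_sizes < 3)) {
    abort("planted cliques must have size >= 3")
  }
  if (resolution_bp <= 0 || chrom_length_bp < resolution_bp) {
    abort("resolution must be positive and no larger than the chromosome")
  }
  structure(
    list(
      chrom = chrom,
      chrom_length_bp = as.double(chrom_length_bp),
      resolution_bp = as.integer(resolution_bp),
      decay_exponent = decay_exponent,
      tad_size_range_bp = as.double(tad_size_range_bp),
      intra_tad_boost = intra_tad_boost,
      clique_sizes = as.integer(clique_sizes),
      clique_boost = clique_boost,
      base_intensity = base_intensity,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Draw a TAD tiling: sequential sizes uniform on the configured range (in
# bins), truncated at the chromosome end; a trailing fragment shorter than the
# minimum TAD size becomes a gap segment.
draw_tad_tiling <- function(config) {
  res <- config$resolution_bp
  n_bins <- floor(config$chrom_length_bp / res)
  min_bins <- max(2L, as.integer(floor(config$tad_size_range_bp[1] / res)))
  max_bins <- max(min_bins, as.integer(floor(config$tad_size_range_bp[2] / res)))
  if (n_bins < 2 * min_bins) abort("degenerate simulation: chromosome shorter than 2 TADs")

  starts <- integer(0)
  sizes <- integer(0)
  pos <- 0L
  while (n_bins - pos >= min_bins) {
    s <- sample.int(max_bins - min_bins + 1L, 1L) + min_bins - 1L
    s <- min(s, n_bins - pos)
    if (s < min_bins) break
    starts <- c(starts, pos)
    sizes <- c(sizes, s)
    pos <- pos + s
  }
  tads <- tibble(
    chrom = config$chrom,
    start = as.double(starts) * res,
    end = as.double(starts + sizes) * res,
    tad_id = sprintf("tad_%03d", seq_along(starts)),
    is_domain = TRUE
  )
  if (pos < n_bins) {
    tads <- bind_rows(tads, tibble(
      chrom = config$chrom,
      start = as.double(pos) * res,
      end = as.double(n_bins) * res,
      tad_id = "gap_001",
      is_domain = FALSE
    ))
  }
  tads
}

# Choose clique members among domain TADs so that any two members of a clique
# are separated by at least one intervening TAD and no TAD serves two cliques.
plant_cliques <- function(n_domains, clique_sizes) {
  used <- integer(0)
  cliques <- list()
  for (cs in clique_sizes) {
    members <- integer(0)
    candidates <- setdiff(seq_len(n_domains), used)
    for (m in seq_len(cs)) {
      ok <- candidates[vapply(candidates, function(i) all(abs(i - members) >= 2), logical(1))]
      if (length(ok) == 0) {
        abort("could not place planted cliques: chromosome holds too few TADs")
      }
      pick <- ok[sample.int(length(ok), 1L)]
      members <- c(members, pick)
      candidates <- setdiff(candidates, pick)
    }
    members <- sort(members)
    used <- c(used, members)
    cliques[[length(cliques) + 1]] <- members
  }
  cliques
}

#' Simulate a binned contact map with planted TADs and cliques
#'
#' Draws a TAD tiling, plants fully connected cliques of linearly
#' non-contiguous TADs, and samples Poisson contact counts under a power-law
#' distance decay with intra-TAD and clique-edge enrichments.
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `tad_sim` with elements `map` (a [contact_map()])
#'   and `truth`: the true segmentation (`tads`), the planted cliques
#'   (`cliques`, list of TAD-id vectors), the planted edge set
#'   (`clique_edges`, tibble with `tad_a`/`tad_b`), and the config.
#' @export
simulate_contact_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  res <- config$resolution_bp

  tads <- draw_tad_tiling(config)
  domains <- tads %>% filter(.data$is_domain)
  n_domains <- nrow(domains)
  cliques_idx <- plant_cliques(n_domains, config$clique_sizes)
  clique_edges <- purrr::map(cliques_idx, function(members) {
    if (length(members) < 2) return(NULL)
    pairs <- utils::combn(members, 2)
    tibble(tad_a = domains$tad_id[pairs[1, ]], tad_b = domains$tad_id[pairs[2, ]])
  }) %>% bind_rows()
  if (nrow(clique_edges) == 0) {
    clique_edges <- tibble(tad_a = character(), tad_b = character())
  }

  n_bins <- floor(config$chrom_length_bp / res)
  # bin -> domain index (0 = gap / none), by bin midpoint
  bin_dom <- integer(n_bins)
  for (t in seq_len(n_domains)) {
    b0 <- domains$start[t] / res
    b1 <- domains$end[t] / res
    bin_dom[(b0 + 1):b1] <- t
  }

  # domain-pair boost lookup for planted clique edges
  edge_boost <- matrix(FALSE, n_domains, n_domains)
  for (cl in cliques_idx) {
    edge_boost[t(utils::combn(cl, 2))] <- TRUE
  }
  edge_boost <- edge_boost | t(edge_boost)

  ut <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE), arr.ind = TRUE)
  i <- ut[, 1]
  j <- ut[, 2]
  d <- j - i
  dom_i <- bin_dom[i]
  dom_j <- bin_dom[j]
  same_tad <- dom_i > 0 & dom_i == dom_j
  on_edge <- dom_i > 0 & dom_j > 0 & dom_i != dom_j &
    edge_boost[cbind(pmax(dom_i, 1), pmax(dom_j, 1))]
  mu <- config$base_intensity * (1 + d)^(-config$decay_exponent) *
    (1 + config$intra_tad_boost * same_tad) *
    (1 + config$clique_boost * on_edge)
  counts <- rpois(length(mu), mu)
  keep <- counts > 0
  map <- contact_map(
    chrom = config$chrom,
    resolution_bp = res,
    n_bins = n_bins,
    contacts = tibble(
      bin_i = as.integer(i[keep] - 1L),
      bin_j = as.integer(j[keep] - 1L),
      count = as.double(counts[keep])
    )
  )

  in_clique <- domains$tad_id[unlist(cliques_idx)]
  truth <- list(
    config = config,
    tads = tads %>% mutate(in_planted_clique = .data$tad_id %in% in_clique),
    cliques = purrr::map(cliques_idx, ~ domains$tad_id[.x]),
    clique_edges = clique_edges
  )
  structure(list(map = map, truth = truth), class = "tad_sim")
}

#' @export
print.tad_sim <- function(x, ...) {
  cat(sprintf(
    "<tad_sim> %d TADs (%d in planted cliques), %d planted clique edges\n",
    sum(x$truth$tads$is_domain), sum(x$truth$tads$in_planted_clique),
    nrow(x$truth$clique_edges)
  ))
  print(x$map)
  invisible(x)
}

#' Simulate CTCF motif calls around TAD boundaries
#'
#' Places a forward-strand motif near the 5' boundary and a reverse-strand
#' motif near the 3' boundary of each TAD with a category-dependent
#' probability, so that convergent motif configurations are preferentially
#' found at non-clique TADs. Decoy motifs with random strand are scattered
#' uniformly to exercise orientation scoring against off-boundary sites.
#'
#' @param truth A `tad_sim` object or its `truth` element.
#' @param p_convergent_nonclique,p_convergent_clique Probability that a
#'   non-clique / planted-clique TAD receives the convergent motif pair.
#' @param window_bp Motifs are placed within this distance of the boundary
#'   (clamped inside the TAD when the TAD is shorter).
#' @param decoy_per_bp Expected decoy motif density (default 1 per 500 kb; 0
#'   disables decoys).
#' @param seed Integer seed.
#'
#' @return Tibble in BED6 layout: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
simulate_ctcf_motifs <- function(truth,
                                 p_convergent_nonclique = 0.6,
                                 p_convergent_clique = 0.1,
                                 window_bp = 50000,
                                 decoy_per_bp = 1 / 500000,
                                 seed = 1) {
  if (inherits(truth, "tad_sim")) truth <- truth$truth
  stopifnot(
    p_convergent_nonclique >= 0, p_convergent_nonclique <= 1,
    p_convergent_clique >= 0, p_convergent_clique <= 1
  )
  set.seed(seed)
  motif_w <- 19 # CTCF core motif width
  domains <- truth$tads %>% filter(.data$is_domain)
  rows <- list()
  for (t in seq_len(nrow(domains))) {
    p <- if (domains$in_planted_clique[t]) p_convergent_clique else p_convergent_nonclique
    if (runif(1) < p) {
      len <- domains$end[t] - domains$start[t]
      w <- min(window_bp, len - motif_w)
      fwd_mid <- domains$start[t] + runif(1, 0, w)
      rev_mid <- domains$end[t] - runif(1, 0, w)
      rows[[length(rows) + 1]] <- tibble(
        chrom = domains$chrom[t],
        start = round(c(fwd_mid, rev_mid) - motif_w / 2),
        end = round(c(fwd_mid, rev_mid) + motif_w / 2),
        name = paste0("ctcf_", domains$tad_id[t], c("_5p", "_3p")),
        score = runif(2, 0, 20),
        strand = c("+", "-")
      )
    }
  }
  chrom_len <- max(truth$tads$end)
  n_decoy <- if (decoy_per_bp > 0) rpois(1, chrom_len * decoy_per_bp) else 0L
  if (n_decoy > 0) {
    mid <- runif(n_decoy, motif_w, chrom_len - motif_w)
    rows[[length(rows) + 1]] <- tibble(
      chrom = truth$tads$chrom[1],
      start = round(mid - motif_w / 2),
      end = round(mid + motif_w / 2),
      name = sprintf("ctcf_decoy_%03d", seq_len(n_decoy)),
      score = runif(n_decoy, 0, 20),
      strand = sample(c("+", "-"), n_decoy, replace = TRUE)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      chrom = character(), start = double(), end = double(),
      name = character(), score = double(), strand = character()
    )
  }
  arrange(out, .data$start)
}

#' Simulate repeat, expression and subcompartment annotations
#'
#' Emits LINE/SINE repeat intervals whose per-TAD coverage depends on clique
#' membership, a per-gene expression table with a planted downward location
#' shift for genes inside planted-clique TADs, and subcompartment segments
#' with B2/B3 labels enriched over planted-clique footprints.
#'
#' @param truth A `tad_sim` object or its `truth` element.
#' @param line_frac_clique,line_frac_other Target LINE coverage fraction for
#'   planted-clique TADs and for all other segments.
#' @param expr_shift Downward shift (log2 units) of gene expression inside
#'   planted-clique TADs.
#' @param seed Integer seed.
#' @param tile_bp Repeat annotation granularity.
#' @param gene_per_bp Gene density (default 1 per 100 kb).
#'
#' @return List with tibbles `repeats` (BED4, `name` in LINE/SINE),
#'   `expression` (`gene_id`, `chrom`, `tss_pos`, `value`) and
#'   `subcompartments` (BED4, `name` in A1/A2/B1/B2/B3).
#' @export
simulate_annotations <- function(truth,
                                 line_frac_clique = 0.5,
                                 line_frac_other = 0.3,
                                 expr_shift = 1,
                                 seed = 1,
                                 tile_bp = 10000,
                                 gene_per_bp = 1 / 100000) {
  if (inherits(truth, "tad_sim")) truth <- truth$truth
  stopifnot(
    line_frac_clique >= 0, line_frac_clique <= 1,
    line_frac_other >= 0, line_frac_other <= 1
  )
  set.seed(seed)
  segs <- truth$tads

  repeats <- purrr::map(seq_len(nrow(segs)), function(t) {
    frac <- if (isTRUE(segs$in_planted_clique[t])) line_frac_clique else line_frac_other
    tile_starts <- seq(segs$start[t], segs$end[t] - 1, by = tile_bp)
    tile_ends <- pmin(tile_starts + tile_bp, segs$end[t])
    is_line <- runif(length(tile_starts)) < frac
    tibble(
      chrom = segs$chrom[t],
      start = tile_starts,
      end = tile_ends,
      name = ifelse(is_line, "LINE", "SINE")
    )
  }) %>% bind_rows()

  chrom_len <- max(segs$end)
  n_genes <- max(2L, round(chrom_len * gene_per_bp))
  tss <- sort(round(runif(n_genes, 0, chrom_len - 1)))
  idx <- findInterval(tss, segs$start)
  in_clique_tad <- segs$in_planted_clique[idx] %in% TRUE
  expression <- tibble(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    chrom = segs$chrom[1],
    tss_pos = tss,
    value = rnorm(n_genes, mean = 8 - expr_shift * in_clique_tad, sd = 2)
  )

  b_labels <- c("B2", "B3")
  other_labels <- c("A1", "A2", "B1", "B2", "B3")
  lab <- character(nrow(segs))
  for (t in seq_len(nrow(segs))) {
    lab[t] <- if (isTRUE(segs$in_planted_clique[t]) && runif(1) < 0.8) {
      sample(b_labels, 1)
    } else {
      sample(other_labels, 1, prob = c(0.3, 0.25, 0.15, 0.15, 0.15))
    }
  }
  subcompartments <- tibble(
    chrom = segs$chrom, start = segs$start, end = segs$end, name = lab
  )

  list(repeats = repeats, expression = expression, subcompartments = subcompartments)
}
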