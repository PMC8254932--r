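# Shared fixture builders and independent brute-force oracles.

# Random symmetric contact map with Poisson noise.
rand_contact_map <- function(n, res = 1000, lambda = 5, seed = 1, chrom = "chrT") {
  set.seed(seed)
  ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  contact_map(chrom, res, n, tibble::tibble(
    bin_i = ut[, 1] - 1L, bin_j = ut[, 2] - 1L,
    count = rpois(nrow(ut), lambda)
  ))
}

# Tiny segmentation from explicit bin extents (0-based bin spans, inclusive).
seg_from_bins <- function(spans, res, chrom = "chrT", domain = TRUE) {
  tibble::tibble(
    chrom = chrom,
    start = vapply(spans, function(s) s[1] * res, double(1)),
    end = vapply(spans, function(s) (s[2] + 1) * res, double(1)),
    tad_id = sprintf(ifelse(domain, "tad_%03d", "gap_%03d"), seq_along(spans)),
    is_domain = domain
  )
}

# Exhaustive maximal-clique enumeration over all vertex subsets (n <= 15).
brute_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  subsets <- list()
  is_complete <- function(v) {
    if (length(v) <= 1) return(TRUE)
    all(adj[v, v][upper.tri(matrix(0, length(v), length(v)))])
  }
  for (code in seq_len(2^n - 1)) {
    v <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (!is_complete(v)) next
    extendable <- any(vapply(setdiff(seq_len(n), v), function(u) {
      all(adj[u, v])
    }, logical(1)))
    if (!extendable) subsets[[length(subsets) + 1]] <- sort(nodes[v])
  }
  subsets[order(vapply(subsets, paste, character(1), collapse = "\r"))]
}

# Exhaustive best segmentation: recursively enumerate every set of disjoint
# candidate domains (>= min_bins bins), summing positive quality scores.
brute_best_segmentation <- function(q, n, min_bins = 2) {
  # q: matrix q[k, l] (1-based inclusive window), NA where invalid
  best <- function(from) {
    if (from > n) return(0)
    top <- best(from + 1) # leave bin `from` out of any domain
    for (l in (from + min_bins - 1):n) {
      if (l > n) break
      val <- q[from, l]
      if (!is.na(val) && val > 0) {
        cand <- val + best(l + 1)
        if (cand > top) top <- cand
      }
    }
    top
  }
  best(1)
}

# Base-pair bitmap coverage oracle for one interval against an annotation set.
bitmap_coverage <- function(tad_start, tad_end, ann) {
  bits <- logical(tad_end - tad_start)
  for (i in seq_len(nrow(ann))) {
    lo <- max(ann$start[i], tad_start)
    hi <- min(ann$end[i], tad_end)
    if (hi > lo) bits[(lo - tad_start + 1):(hi - tad_start)] <- TRUE
  }
  mean(bits)
}

# Graph fixture: edge list tibble from a compact string like "a-b,b-c".
edges_from_string <- function(s) {
  parts <- strsplit(strsplit(s, ",")[[1]], "-")
  tibble::tibble(
    tad_a = vapply(parts, `[`, character(1), 1),
    tad_b = vapply(parts, `[`, character(1), 2)
  )
}

# Small simulation config used by several suites (10 Mb keeps tests fast).
small_sim_config <- function(seed = 1, ...) {
  sim_config(chrom_length_bp = 10e6, clique_sizes = c(3), seed = seed, ...)
}
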