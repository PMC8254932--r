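# Per-category genomic characterization of TADs: aggregate contact heatmaps,
# CTCF motif convergence, annotation coverage, expression, subcompartments.

#' Nearest-neighbor matrix resize
#'
#' Resizes a square matrix to `size x size` by nearest-neighbor index
#' mapping: target cell `(r, c)` takes source cell
#' `(floor(r * m / size), floor(c * m / size))` (0-based).
#'
#' @param m Square numeric matrix.
#' @param size Target dimension (default 25).
#' @return A `size x size` matrix.
#' @export
resize_nearest <- function(m, size = 25) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 1)
  idx <- floor((seq_len(size) - 1) * nrow(m) / size) + 1L
  m[idx, idx, drop = FALSE]
}

# Dense intra-TAD contact block for one TAD (bins whose midpoint lies inside).
intra_tad_block <- function(dense, tad, resolution_bp) {
  b0 <- floor(tad$start / resolution_bp) + 1L
  b1 <- ceiling(tad$end / resolution_bp)
  dense[b0:b1, b0:b1, drop = FALSE]
}

#' Aggregate intra-TAD contact heatmap
#'
#' Rescales each TAD's intra-TAD contact matrix to a common 25 x 25 grid by
#' nearest-neighbor mapping and averages element-wise across TADs, producing
#' the mean contact profile of a TAD category.
#'
#' @param map A [contact_map()].
#' @param tads Tibble of TAD intervals (`chrom`, `start`, `end`, `tad_id`)
#'   on the map's chromosome; typically one clique-size category.
#' @param size Output grid size (default 25).
#' @return An `aggregate_heatmap` object: list with `matrix` (`size x size`),
#'   `n_tads`, `size`.
#' @export
aggregate_intra_tad_heatmap <- function(map, tads, size = 25) {
  if (nrow(tads) == 0) abort("no TADs in category")
  dense <- contact_dense(map)
  mats <- purrr::map(seq_len(nrow(tads)), function(t) {
    resize_nearest(intra_tad_block(dense, tads[t, ], map$resolution_bp), size)
  })
  avg <- Reduce(`+`, mats) / length(mats)
  structure(list(matrix = avg, n_tads = length(mats), size = size),
            class = "aggregate_heatmap")
}

#' @export
print.aggregate_heatmap <- function(x, ...) {
  cat(sprintf("<aggregate_heatmap> %dx%d over %d TADs, mean %.3f\n",
              x$size, x$size, x$n_tads, mean(x$matrix)))
  invisible(x)
}

# Decide a boundary's motif orientation: strand of the highest-score motif
# whose midpoint lies within [lo, hi] (ties: leftmost midpoint).
boundary_strand <- function(motifs, lo, hi) {
  mid <- (motifs$start + motifs$end) / 2
  hit <- which(mid >= lo & mid <= hi)
  if (length(hit) == 0) return(NA_character_)
  hit <- hit[order(-motifs$score[hit], mid[hit])]
  motifs$strand[hit[1]]
}

#' Convergent CTCF motif orientation at TAD boundaries
#'
#' A TAD is convergent when its boundary motifs point inward: the strongest
#' motif within `window_bp` inside the 5' boundary is on the forward strand
#' and the strongest motif within `window_bp` inside the 3' boundary is on
#' the reverse strand. Boundary windows extend into the domain only, so a
#' motif serving the adjacent TAD's boundary never decides this one; when
#' several motifs fall in a window, the highest-score motif decides that
#' boundary's orientation.
#'
#' @param tads Tibble of TAD intervals.
#' @param motifs Motif tibble (BED6 columns incl. `score`, `strand`).
#' @param window_bp Search window inside each boundary (default 50 kb, one
#'   bin at the default resolution).
#' @return Logical vector, one flag per row of `tads`.
#' @export
tad_is_convergent <- function(tads, motifs, window_bp = 50000) {
  stopifnot(window_bp > 0)
  vapply(seq_len(nrow(tads)), function(t) {
    m <- motifs[motifs$chrom == tads$chrom[t], , drop = FALSE]
    isTRUE(boundary_strand(m, tads$start[t], tads$start[t] + window_bp) == "+") &&
      isTRUE(boundary_strand(m, tads$end[t] - window_bp, tads$end[t]) == "-")
  }, logical(1))
}

#' Convergence enrichment per TAD category
#'
#' Computes the percentage of convergent TADs per clique-size category and
#' tests each category against the genome-wide convergent fraction `p0` with
#' a two-sided exact binomial test (doubled one-sided tail, capped at 1).
#'
#' @param assignments Clique statistics from [assign_clique_stats()].
#' @param tads Segmentation tibble supplying TAD intervals.
#' @param motifs Motif tibble.
#' @param window_bp Boundary window (see [tad_is_convergent()]).
#' @return Tibble per category (`category`, `n_tads`, `n_convergent`,
#'   `percent`, `p_value`) with the genome-wide fraction attached as
#'   attribute `p0`.
#' @export
convergence_enrichment <- function(assignments, tads, motifs, window_bp = 50000) {
  dat <- assignments %>%
    left_join(tads %>% select("tad_id", "chrom", "start", "end"), by = "tad_id")
  if (any(is.na(dat$start))) abort("every assigned TAD needs an interval in `tads`")
  dat$convergent <- tad_is_convergent(dat, motifs, window_bp)
  p0 <- mean(dat$convergent)
  out <- dat %>%
    group_by(.data$category) %>%
    summarise(
      n_tads = dplyr::n(),
      n_convergent = sum(.data$convergent),
      .groups = "drop"
    ) %>%
    mutate(
      percent = 100 * .data$n_convergent / .data$n_tads,
      p_value = purrr::map2_dbl(.data$n_convergent, .data$n_tads,
                                binom_two_sided, p0 = p0)
    )
  attr(out, "p0") <- p0
  out
}

# Two-sided exact binomial p-value by tail doubling, capped at 1.
binom_two_sided <- function(x, n, p0) {
  if (p0 <= 0) return(if (x == 0) 1 else 0)
  if (p0 >= 1) return(if (x == n) 1 else 0)
  lower <- pbinom(x, n, p0)
  upper <- pbinom(x - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Fraction of each TAD covered by an annotation
#'
#' Computes, per TAD, the base-pair fraction covered by the union of the
#' annotation intervals (overlapping annotation intervals are merged before
#' intersection, matching `bedtools coverage` semantics).
#'
#' @param tads Tibble of TAD intervals with `tad_id`.
#' @param annotation Tibble of intervals (`chrom`, `start`, `end`).
#' @return Tibble `tad_id`, `fraction`.
#' @export
interval_coverage <- function(tads, annotation) {
  merged <- merge_intervals(annotation)
  frac <- vapply(seq_len(nrow(tads)), function(t) {
    tad_iv <- tads[t, c("chrom", "start", "end")]
    intersect_bp(tad_iv, merged) / (tads$end[t] - tads$start[t])
  }, double(1))
  tibble(tad_id = tads$tad_id, fraction = frac)
}

#' Compare gene expression between clique and non-clique TADs
#'
#' Assigns each gene to the segment containing its TSS, splits genes into
#' clique TADs (maximal clique size >= 3) versus all other TADs, and runs a
#' two-sample two-sided Kolmogorov-Smirnov test.
#'
#' @param expression Tibble `gene_id`, `chrom`, `tss_pos`, `value`.
#' @param segmentation Segmentation tibble.
#' @param assignments Clique statistics from [assign_clique_stats()].
#' @return An `expression_comparison` object: `statistic`, `p_value`, and a
#'   per-class `summary` tibble.
#' @export
expression_compare <- function(expression, segmentation, assignments) {
  validate_segmentation(segmentation)
  k <- setNames(assignments$max_clique_size, assignments$tad_id)
  genes <- expression %>% filter(.data$chrom %in% segmentation$chrom)
  seg <- segmentation
  idx <- findInterval(genes$tss_pos, seg$start)
  inside <- idx > 0 & genes$tss_pos < seg$end[pmax(idx, 1)]
  genes <- genes[inside, , drop = FALSE]
  genes$tad_id <- seg$tad_id[idx[inside]]
  genes$in_clique <- unname(k[genes$tad_id]) >= 3
  genes$in_clique[is.na(genes$in_clique)] <- FALSE
  a <- genes$value[genes$in_clique]
  b <- genes$value[!genes$in_clique]
  if (length(a) < 2 || length(b) < 2) {
    abort("each class (clique / non-clique) needs at least 2 genes")
  }
  ks <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  structure(
    list(
      statistic = unname(ks$statistic),
      p_value = ks$p.value,
      summary = tibble(
        class = c("clique", "non_clique"),
        n_genes = c(length(a), length(b)),
        median = c(median(a), median(b)),
        mean = c(mean(a), mean(b))
      )
    ),
    class = "expression_comparison"
  )
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf("<expression_comparison> KS D = %.3f, p = %.3g\n",
              x$statistic, x$p_value))
  print(x$summary)
  invisible(x)
}

#' @method glance expression_comparison
#' @export
glance.expression_comparison <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value,
    n_clique = x$summary$n_genes[1], n_non_clique = x$summary$n_genes[2],
    median_clique = x$summary$median[1], median_non_clique = x$summary$median[2]
  )
}

#' Best subcompartment overlap per TAD
#'
#' For each TAD, computes the Jaccard index (intersection over union, in base
#' pairs) against every overlapping subcompartment segment and reports the
#' maximizing segment's label. With `per_label_union = TRUE` the JI is taken
#' against the union of all segments sharing a label instead.
#'
#' @param tads Tibble of TAD intervals with `tad_id`.
#' @param subcompartments Tibble `chrom`, `start`, `end`, `name` with labels
#'   A1/A2/B1/B2/B3(/B4).
#' @param per_label_union Compare against per-label merged footprints.
#' @return Tibble `tad_id`, `label` (NA when no overlap), `jaccard`.
#' @export
subcompartment_overlap <- function(tads, subcompartments, per_label_union = FALSE) {
  res <- purrr::map(seq_len(nrow(tads)), function(t) {
    tad_iv <- tads[t, c("chrom", "start", "end")]
    tad_len <- tads$end[t] - tads$start[t]
    best_label <- NA_character_
    best_ji <- 0
    if (per_label_union) {
      for (lab in sort(unique(subcompartments$name))) {
        segs <- merge_intervals(subcompartments[subcompartments$name == lab, ])
        inter <- intersect_bp(tad_iv, segs)
        if (inter > 0) {
          ji <- inter / (tad_len + total_bp(segs) - inter)
          if (ji > best_ji) {
            best_ji <- ji
            best_label <- lab
          }
        }
      }
    } else {
      sc <- subcompartments[subcompartments$chrom == tads$chrom[t], , drop = FALSE]
      ov <- sc[sc$start < tads$end[t] & sc$end > tads$start[t], , drop = FALSE]
      for (s in seq_len(nrow(ov))) {
        inter <- min(ov$end[s], tads$end[t]) - max(ov$start[s], tads$start[t])
        seg_len <- ov$end[s] - ov$start[s]
        ji <- inter / (tad_len + seg_len - inter)
        if (ji > best_ji) {
          best_ji <- ji
          best_label <- ov$name[s]
        }
      }
    }
    tibble(tad_id = tads$tad_id[t], label = best_label, jaccard = best_ji)
  })
  bind_rows(res)
}

#' Restrict TADs to the B compartment
#'
#' Convenience filter keyed on each TAD's best-overlap subcompartment label,
#' for rerunning any characterization on B-compartment TADs only.
#'
#' @param tads Tibble of TAD intervals with `tad_id`.
#' @param subcompartments Subcompartment segments (see
#'   [subcompartment_overlap()]).
#' @param labels Labels counted as B compartment.
#' @return The rows of `tads` whose best label is in `labels`.
#' @export
filter_b_compartment <- function(tads, subcompartments,
                                 labels = c("B1", "B2", "B3", "B4")) {
  ji <- subcompartment_overlap(tads, subcompartments)
  keep <- ji$tad_id[!is.na(ji$label) & ji$label %in% labels]
  tads %>% filter(.data$tad_id %in% keep)
}
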