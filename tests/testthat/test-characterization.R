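test_that("nearest-neighbor resize preserves constants and is identity at 25", {
  expect_equal(resize_nearest(matrix(7, 4, 4), 25), matrix(7, 25, 25))
  m <- matrix(runif(625), 25, 25)
  expect_equal(resize_nearest(m, 25), m)
})

test_that("the aggregate heatmap is the cell-wise mean of resized blocks", {
  res <- 100
  n <- 40
  map <- rand_contact_map(n, res = res, lambda = 8, seed = 21)
  tads <- seg_from_bins(list(c(0, 9), c(12, 28), c(30, 36)), res)
  hm <- aggregate_intra_tad_heatmap(map, tads)
  expect_equal(hm$n_tads, 3)

  dense <- contact_dense(map)
  resize_ref <- function(block, size = 25) {
    # independent index recomputation: target (r, c) <- source floor(r*m/size)
    m <- nrow(block)
    out <- matrix(0, size, size)
    for (r in 0:(size - 1)) for (c in 0:(size - 1)) {
      out[r + 1, c + 1] <- block[floor(r * m / size) + 1, floor(c * m / size) + 1]
    }
    out
  }
  blocks <- list(dense[1:10, 1:10], dense[13:29, 13:29], dense[31:37, 31:37])
  expected <- Reduce(`+`, lapply(blocks, resize_ref)) / 3
  expect_equal(hm$matrix, expected)

  expect_error(aggregate_intra_tad_heatmap(map, tads[0, ]), "no TADs")

  # a single 25-bin TAD: the aggregate equals the raw block exactly
  one <- seg_from_bins(list(c(5, 29)), res)
  hm1 <- aggregate_intra_tad_heatmap(map, one)
  expect_equal(hm1$matrix, dense[6:30, 6:30], ignore_attr = TRUE)
})

motif_row <- function(mid, strand, score = 10, chrom = "chrT") {
  tibble::tibble(chrom = chrom, start = mid - 10, end = mid + 9,
                 name = "m", score = score, strand = strand)
}

test_that("convergence requires a + motif at the start and a - at the end", {
  tad <- tibble::tibble(chrom = "chrT", start = 10000, end = 60000, tad_id = "t1")
  w <- 5000
  conv <- dplyr::bind_rows(motif_row(10500, "+"), motif_row(59000, "-"))
  expect_true(tad_is_convergent(tad, conv, w))
  div <- dplyr::bind_rows(motif_row(10500, "-"), motif_row(59000, "+"))
  expect_false(tad_is_convergent(tad, div, w))
  expect_false(tad_is_convergent(tad, motif_row(35000, "+"), w))
  # the highest-score motif decides a boundary shared by several motifs
  mixed <- dplyr::bind_rows(
    motif_row(10500, "+", score = 3), motif_row(11000, "-", score = 9),
    motif_row(59000, "-")
  )
  expect_false(tad_is_convergent(tad, mixed, w))
})

test_that("binomial enrichment matches closed forms and averages to p0", {
  # 0 convergent of 20 against p0 = 0.5: two-sided p = 2 * 0.5^20
  expect_equal(tadcliques:::binom_two_sided(0, 20, 0.5), 2 * 0.5^20)
  # observing the most probable outcome: doubled tail capped at 1
  expect_equal(tadcliques:::binom_two_sided(10, 20, 0.5), 1)

  set.seed(2)
  sim <- simulate_contact_map(sim_config(seed = 2))
  tads <- sim$truth$tads
  motifs <- simulate_ctcf_motifs(sim, seed = 2)
  g <- build_tad_graph(sim$truth$clique_edges,
                       nodes = tads$tad_id[tads$is_domain])
  stats <- assign_clique_stats(g)
  conv <- convergence_enrichment(stats, tads, motifs)
  p0 <- attr(conv, "p0")
  # category percentages, weighted by category sizes, average to p0 exactly
  expect_equal(sum(conv$percent / 100 * conv$n_tads) / sum(conv$n_tads), p0)
})

test_that("clique TADs are depleted of convergent motifs on the fixture", {
  sim <- simulate_contact_map(sim_config(seed = 1))
  tads <- sim$truth$tads
  motifs <- simulate_ctcf_motifs(sim, p_convergent_nonclique = 0.6,
                                 p_convergent_clique = 0.1, seed = 1)
  assignments <- tibble::tibble(
    tad_id = tads$tad_id[tads$is_domain],
    category = factor(ifelse(tads$in_planted_clique[tads$is_domain],
                             "clique", "non_clique"))
  )
  conv <- convergence_enrichment(assignments, tads, motifs)
  clique_row <- conv[conv$category == "clique", ]
  expect_lt(clique_row$percent / 100, attr(conv, "p0"))
  expect_lt(clique_row$p_value, 0.05)
})

test_that("interval coverage merges overlaps and matches a bitmap oracle", {
  tad <- tibble::tibble(chrom = "chrT", start = 0, end = 1000, tad_id = "t1")
  full <- tibble::tibble(chrom = "chrT", start = -50, end = 1200)
  expect_equal(interval_coverage(tad, full)$fraction, 1)

  overlapping <- tibble::tibble(chrom = "chrT", start = c(100, 150), end = c(200, 250))
  expect_equal(interval_coverage(tad, overlapping)$fraction, 0.15)

  set.seed(33)
  big <- tibble::tibble(chrom = "chrT", start = 0, end = 1e6, tad_id = "big")
  ann_start <- sort(sample.int(1.1e6, 200) - 5e4)
  ann <- tibble::tibble(chrom = "chrT", start = ann_start,
                        end = ann_start + sample.int(2e4, 200))
  expect_equal(
    interval_coverage(big, ann)$fraction,
    bitmap_coverage(0, 1e6, ann)
  )
})

test_that("expression comparison flags the planted shift and its direction", {
  sim <- simulate_contact_map(sim_config(seed = 3))
  ann <- simulate_annotations(sim, expr_shift = 1, seed = 3)
  tads <- sim$truth$tads
  g <- build_tad_graph(sim$truth$clique_edges,
                       nodes = tads$tad_id[tads$is_domain])
  stats <- assign_clique_stats(g)
  cmp <- expression_compare(ann$expression, tads, stats)
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$summary$median[cmp$summary$class == "clique"],
            cmp$summary$median[cmp$summary$class == "non_clique"])

  # identical samples: D = 0, p = 1 (same values in both classes)
  x <- rnorm(50)
  iv_c <- tads[tads$in_planted_clique, ][1, ]
  iv_o <- tads[!tads$in_planted_clique & tads$is_domain, ][1, ]
  expr_same <- tibble::tibble(
    gene_id = sprintf("g%d", 1:100), chrom = tads$chrom[1],
    tss_pos = c(
      seq(iv_c$start, iv_c$end - 1, length.out = 50),
      seq(iv_o$start, iv_o$end - 1, length.out = 50)
    ),
    value = c(x, x)
  )
  cmp_same <- expression_compare(expr_same, tads, stats)
  expect_equal(cmp_same$statistic, 0)
  expect_equal(cmp_same$p_value, 1)

  # disjoint supports: D = 1
  expr_disj <- expr_same
  expr_disj$value <- c(x, x + 100)
  expect_equal(expression_compare(expr_disj, tads, stats)$statistic, 1)

  expect_error(
    expression_compare(expr_same[c(1, 51), ], tads, stats),
    "at least 2 genes"
  )
})

test_that("subcompartment overlap reports the maximizing label and JI", {
  tad <- tibble::tibble(chrom = "chrT", start = 1000, end = 2000, tad_id = "t1")
  exact <- tibble::tibble(chrom = "chrT", start = 1000, end = 2000, name = "A1")
  expect_equal(subcompartment_overlap(tad, exact),
               tibble::tibble(tad_id = "t1", label = "A1", jaccard = 1))

  none <- tibble::tibble(chrom = "chrT", start = 5000, end = 6000, name = "B2")
  out <- subcompartment_overlap(tad, none)
  expect_equal(out$jaccard, 0)
  expect_true(is.na(out$label))

  # equal-length segment offset by half: JI = 500 / 1500 = 1/3
  half <- tibble::tibble(chrom = "chrT", start = 1500, end = 2500, name = "B1")
  expect_equal(subcompartment_overlap(tad, half)$jaccard, 1 / 3)

  both <- dplyr::bind_rows(half, tibble::tibble(
    chrom = "chrT", start = 900, end = 2000, name = "A2"
  ))
  best <- subcompartment_overlap(tad, both)
  expect_equal(best$label, "A2")
  expect_equal(best$jaccard, 1000 / 1100)
})

test_that("B-compartment restriction equals post-hoc filtering", {
  sim <- simulate_contact_map(sim_config(seed = 5))
  ann <- simulate_annotations(sim, seed = 5)
  tads <- sim$truth$tads[sim$truth$tads$is_domain, ]
  line <- ann$repeats[ann$repeats$name == "LINE", ]
  b_tads <- filter_b_compartment(tads, ann$subcompartments)
  expect_gt(nrow(b_tads), 0)
  cov_all <- interval_coverage(tads, line)
  cov_b <- interval_coverage(b_tads, line)
  expect_equal(cov_b, cov_all[cov_all$tad_id %in% b_tads$tad_id, ],
               ignore_attr = TRUE)
})

test_that("LINE enrichment direction is reproduced across seeds", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- sim_config(chrom_length_bp = 10e6, clique_sizes = c(3), seed = seed)
    sim <- simulate_contact_map(cfg)
    ann <- simulate_annotations(sim, seed = seed)
    tads <- sim$truth$tads[sim$truth$tads$is_domain, ]
    line <- ann$repeats[ann$repeats$name == "LINE", ]
    cov <- interval_coverage(tads, line)
    if (mean(cov$fraction[tads$in_planted_clique]) >
        mean(cov$fraction[!tads$in_planted_clique])) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})
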