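# Helper: tad_contacts object with equal-size TADs and chosen pair counts.
toy_tad_contacts <- function(counts, n_tads, res = 100, bins_per_tad = 2) {
  spans <- lapply(seq_len(n_tads) - 1, function(i) {
    c(i * bins_per_tad, (i + 1) * bins_per_tad - 1)
  })
  seg <- seg_from_bins(spans, res)
  structure(
    list(pairs = counts, segmentation = seg, chrom = "chrT",
         resolution_bp = res, total = sum(counts$count)),
    class = "tad_contacts"
  )
}

test_that("a single stratum's expected count is the arithmetic mean", {
  # 4 equally sized, equally spaced TADs: the three skip-one pairs all sit at
  # the same distance; counts {2,4,6} -> stratum mean 4
  counts <- tibble::tibble(
    tad_a = c("tad_001", "tad_002", "tad_001", "tad_002", "tad_003"),
    tad_b = c("tad_003", "tad_004", "tad_002", "tad_003", "tad_004"),
    count = c(2, 4, 10, 10, 10)
  )
  tc <- toy_tad_contacts(counts, n_tads = 4)
  # add the third eligible pair (tad_002, tad_004) via zero fill; then the
  # single-distance stratum holds counts {2, 4, 0}
  model <- fit_distance_expectation(tc, n_strata = 1)
  expect_equal(nrow(model$strata), 1)
  expect_equal(model$strata$mean_count, mean(c(2, 4, 0)))
  # equal-size TADs: expected count equals the stratum mean count
  expect_equal(
    expected_contacts(model, model$strata$lo * 1.0001, 2, 2),
    mean(c(2, 4, 0))
  )
})

test_that("strata means hover near the global mean when counts ignore distance", {
  set.seed(31)
  n_tads <- 40
  pairs <- t(utils::combn(n_tads, 2))
  counts <- tibble::tibble(
    tad_a = sprintf("tad_%03d", pairs[, 1]),
    tad_b = sprintf("tad_%03d", pairs[, 2]),
    count = rpois(nrow(pairs), 20)
  )
  tc <- toy_tad_contacts(counts, n_tads = n_tads)
  model <- fit_distance_expectation(tc, n_strata = 8)
  filled <- model$strata[model$strata$n_pairs >= 20, ]
  se <- sqrt(20 / filled$n_pairs)
  expect_true(all(abs(filled$mean_count - 20) < 4 * se))
})

test_that("empty interior strata inherit the nearest non-empty value", {
  # two clusters of TADs separated by a wide gap: pair distances are either
  # short or long, leaving interior strata empty
  res <- 100
  seg <- dplyr::bind_rows(
    seg_from_bins(list(c(0, 1), c(2, 3), c(4, 5)), res),
    seg_from_bins(list(c(6, 39)), res, domain = FALSE),
    seg_from_bins(list(c(40, 41), c(42, 43), c(44, 45)), res) %>%
      dplyr::mutate(tad_id = sprintf("tad_%03d", 4:6))
  )
  counts <- tibble::tibble(
    tad_a = c("tad_001", "tad_004", "tad_002"),
    tad_b = c("tad_003", "tad_006", "tad_005"),
    count = c(8, 2, 4)
  )
  tc <- structure(
    list(pairs = counts, segmentation = seg, chrom = "chrT",
         resolution_bp = res, total = sum(counts$count)),
    class = "tad_contacts"
  )
  model <- fit_distance_expectation(tc, n_strata = 12)
  expect_true(any(model$strata$n_pairs == 0)) # the gap really is empty
  expect_false(any(is.na(model$strata$mean_count)))
  expect_false(any(is.na(model$strata$rho)))
  filled <- which(model$strata$n_pairs > 0)
  empty <- which(model$strata$n_pairs == 0)
  for (s in empty) {
    nearest <- filled[which.min(abs(filled - s))]
    expect_equal(model$strata$rho[s], model$strata$rho[nearest])
  }
})

test_that("omega = 1 reduces to the central hypergeometric upper tail", {
  # closed-form cross-check at N=20, n_a=5, n_b=5, x=3
  expect_equal(
    nchg_pvalue(3, 5, 5, 20, 1),
    phyper(2, 5, 15, 5, lower.tail = FALSE),
    tolerance = 1e-12
  )
  set.seed(17)
  for (rep in 1:100) {
    N <- sample(50:10000, 1)
    n_a <- sample.int(N - 1, 1)
    n_b <- sample.int(N - 1, 1)
    lo <- max(0, n_a + n_b - N)
    hi <- min(n_a, n_b)
    x <- sample(lo:hi, 1)
    expect_equal(
      nchg_pvalue(x, n_a, n_b, N, 1),
      phyper(x - 1, n_a, N - n_a, n_b, lower.tail = FALSE),
      tolerance = 1e-9
    )
  }
})

test_that("noncentral tails match an external reference implementation", {
  # frozen values from scipy.stats.nchypergeom_fisher.sf(x - 1, N, n_a, n_b, omega)
  expect_equal(nchg_pvalue(7, 12, 15, 50, 2.5), 0.2483188482089993, tolerance = 1e-9)
  expect_equal(nchg_pvalue(3, 40, 30, 200, 0.5), 0.7274794221292646, tolerance = 1e-9)
  expect_equal(nchg_pvalue(10, 10, 12, 30, 8.0), 0.01674039554420559, tolerance = 1e-9)
})

test_that("tail probabilities behave like a normalized pmf over the support", {
  set.seed(23)
  for (rep in 1:20) {
    N <- sample(100:5000, 1)
    n_a <- sample.int(floor(N / 2), 1)
    n_b <- sample.int(floor(N / 2), 1)
    omega <- exp(runif(1, -2, 2))
    lo <- max(0, n_a + n_b - N)
    hi <- min(n_a, n_b)
    # whole support in the tail
    expect_equal(nchg_pvalue(lo, n_a, n_b, N, omega), 1, tolerance = 1e-12)
    # pmf reconstructed from successive tails sums to 1
    ys <- lo:hi
    tails <- nchg_pvalue(ys, n_a, n_b, N, omega)
    pmf <- c(tails[-length(tails)] - tails[-1], tails[length(tails)])
    expect_true(all(pmf >= -1e-12))
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    # monotone non-increasing in x
    expect_true(all(diff(tails) <= 1e-12))
  }
  expect_error(nchg_pvalue(5, 3, 3, 20, 1), "support")
  expect_error(nchg_pvalue(1, 3, 3, 20, -1), "positive")
})

test_that("BH q-values follow the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(5)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the fold filter vetoes unenriched pairs regardless of p-value", {
  sim <- simulate_contact_map(small_sim_config(seed = 8))
  tc <- aggregate_to_tads(sim$map, sim$truth$tads)
  pairs <- call_significant_interactions(tc, min_fold = 5)
  expect_false(any(pairs$significant & pairs$fold < 5))
  expect_false(any(pairs$significant & pairs$q_value >= 0.01))
  # a pair whose observed equals its expected (fold 1) can never pass
  expect_false(any(pairs$significant[abs(pairs$fold - 1) < 0.2]))
})

test_that("adjacent TADs and self-pairs are never tested", {
  sim <- simulate_contact_map(small_sim_config(seed = 9))
  tc <- aggregate_to_tads(sim$map, sim$truth$tads)
  pairs <- call_significant_interactions(tc)
  seg_ids <- sim$truth$tads$tad_id[sim$truth$tads$is_domain]
  ia <- match(pairs$tad_a, seg_ids)
  ib <- match(pairs$tad_b, seg_ids)
  expect_true(all(abs(ib - ia) >= 2))
})

test_that("planted clique edges are recovered on the true segmentation", {
  sim <- simulate_contact_map(sim_config(seed = 10))
  tc <- aggregate_to_tads(sim$map, sim$truth$tads)
  pairs <- call_significant_interactions(tc)
  sig <- pairs[pairs$significant, ]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted <- key(sim$truth$clique_edges$tad_a, sim$truth$clique_edges$tad_b)
  called <- key(sig$tad_a, sig$tad_b)
  expect_gte(sum(planted %in% called) / length(planted), 0.8)
  expect_gte(sum(called %in% planted) / length(called), 0.8)
})
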