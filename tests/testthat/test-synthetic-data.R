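test_that("distance decay of simulated counts matches the Poisson mean", {
  # beta = 0, gamma_c = 0: mean count at bin distance d must be L / (1 + d)
  cfg <- sim_config(
    chrom_length_bp = 10e6, intra_tad_boost = 0, clique_sizes = integer(0),
    clique_boost = 0, decay_exponent = 1, base_intensity = 50, seed = 7
  )
  sim <- simulate_contact_map(cfg)
  n <- sim$map$n_bins
  dense <- contact_dense(sim$map)
  for (d in c(0, 1, 5, 20, 80)) {
    obs <- dense[cbind(seq_len(n - d), seq_len(n - d) + d)]
    mu <- 50 / (1 + d)
    se <- sqrt(mu / length(obs))
    expect_lt(abs(mean(obs) - mu), 3 * se)
  }
})

test_that("no planted cliques means an empty planted edge set", {
  cfg <- sim_config(chrom_length_bp = 5e6, clique_sizes = integer(0), seed = 2)
  sim <- simulate_contact_map(cfg)
  expect_equal(nrow(sim$truth$clique_edges), 0)
  expect_false(any(sim$truth$tads$in_planted_clique))
})

test_that("identical config and seed reproduce the map bit for bit", {
  cfg <- small_sim_config(seed = 11)
  s1 <- simulate_contact_map(cfg)
  s2 <- simulate_contact_map(cfg)
  expect_identical(s1$map$contacts, s2$map$contacts)
  expect_identical(s1$truth$tads, s2$truth$tads)
  m1 <- simulate_ctcf_motifs(s1, seed = 5)
  m2 <- simulate_ctcf_motifs(s2, seed = 5)
  expect_identical(m1, m2)
  a1 <- simulate_annotations(s1, seed = 5)
  a2 <- simulate_annotations(s2, seed = 5)
  expect_identical(a1, a2)
})

test_that("planted clique members are pairwise linearly non-contiguous", {
  for (seed in 1:5) {
    sim <- simulate_contact_map(sim_config(seed = seed))
    dom_ids <- sim$truth$tads$tad_id[sim$truth$tads$is_domain]
    for (cl in sim$truth$cliques) {
      idx <- sort(match(cl, dom_ids))
      expect_true(all(diff(idx) >= 2))
    }
    # planted edges form complete subgraphs
    key <- paste(sim$truth$clique_edges$tad_a, sim$truth$clique_edges$tad_b)
    for (cl in sim$truth$cliques) {
      pairs <- utils::combn(sort(match(cl, dom_ids)), 2)
      expect_true(all(paste(dom_ids[pairs[1, ]], dom_ids[pairs[2, ]]) %in% key))
    }
  }
})

test_that("a chromosome too short for two TADs is rejected", {
  expect_error(
    simulate_contact_map(sim_config(chrom_length_bp = 300000)),
    "degenerate simulation"
  )
})

test_that("degenerate motif probabilities give all-or-nothing convergence", {
  sim <- simulate_contact_map(small_sim_config(seed = 3))
  tads <- sim$truth$tads[sim$truth$tads$is_domain, ]

  all_conv <- simulate_ctcf_motifs(sim, p_convergent_nonclique = 1,
                                   p_convergent_clique = 0, decoy_per_bp = 0,
                                   seed = 1)
  flags <- tad_is_convergent(tads, all_conv, window_bp = 50000)
  expect_true(all(flags[!tads$in_planted_clique]))
  expect_false(any(flags[tads$in_planted_clique]))

  none <- simulate_ctcf_motifs(sim, p_convergent_nonclique = 0,
                               p_convergent_clique = 0, decoy_per_bp = 0,
                               seed = 1)
  expect_equal(nrow(none), 0)
})

test_that("LINE coverage of planted-clique TADs tracks the requested fraction", {
  sim <- simulate_contact_map(sim_config(seed = 4))
  ann <- simulate_annotations(sim, line_frac_clique = 0.5,
                              line_frac_other = 0.3, seed = 4)
  tads <- sim$truth$tads[sim$truth$tads$is_domain, ]
  line <- ann$repeats[ann$repeats$name == "LINE", ]
  cov <- interval_coverage(tads, line)
  clique_cov <- cov$fraction[tads$in_planted_clique]
  other_cov <- cov$fraction[!tads$in_planted_clique]
  expect_gt(mean(clique_cov), 0.45)
  expect_lt(mean(clique_cov), 0.55)
  expect_gt(mean(clique_cov), mean(other_cov))
})

test_that("zero expression shift leaves the two gene classes indistinguishable", {
  sim <- simulate_contact_map(small_sim_config(seed = 5))
  tads <- sim$truth$tads
  in_clique <- function(ann) {
    idx <- findInterval(ann$expression$tss_pos, tads$start)
    tads$in_planted_clique[idx] %in% TRUE
  }
  n_sig <- 0
  for (seed in 1:20) {
    ann <- simulate_annotations(sim, expr_shift = 0, seed = seed)
    cl <- in_clique(ann)
    p <- suppressWarnings(
      ks.test(ann$expression$value[cl], ann$expression$value[!cl])$p.value
    )
    if (p < 0.01) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 1) # >= 95% of replicates non-significant
})

test_that("total simulated counts survive serialization round trip", {
  sim <- simulate_contact_map(small_sim_config(seed = 6))
  dir <- withr::local_tempdir()
  f_m <- file.path(dir, "x.matrix")
  f_b <- file.path(dir, "x.bed")
  write_contact_matrix(sim$map, f_m, f_b)
  trip <- read.table(f_m, sep = "\t")
  expect_equal(sum(trip$V3), contact_total(sim$map))
  back <- read_contact_matrix(f_m, f_b)
  expect_equal(back$contacts, sim$map$contacts)
})
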