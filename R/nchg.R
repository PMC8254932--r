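# Significance testing of TAD-TAD contacts under a distance-aware Fisher
# non-central hypergeometric (NCHG) model.

# Enumerate eligible TAD pairs: intra-chromosomal, linearly non-contiguous
# (self-pairs and consecutive tested segments excluded; gap-fillers do not
# break adjacency). Pairs with no observed contacts are kept with count 0.
eligible_pairs <- function(tc, include_gaps = FALSE) {
  stopifnot(inherits(tc, "tad_contacts"))
  seg <- tc$segmentation
  units <- if (include_gaps) seg else seg %>% filter(.data$is_domain)
  if (nrow(units) < 3) abort("need at least 3 tested segments to form non-adjacent pairs")

  # Margins over the full segmentation (row sums including the diagonal).
  long <- bind_rows(
    tc$pairs %>% select(tad = "tad_a", count = "count"),
    tc$pairs %>% filter(.data$tad_a != .data$tad_b) %>%
      select(tad = "tad_b", count = "count")
  ) %>%
    group_by(.data$tad) %>%
    summarise(n_tot = sum(.data$count), .groups = "drop")
  margins <- setNames(rep(0, nrow(seg)), seg$tad_id)
  margins[long$tad] <- long$n_tot

  zero_units <- units$tad_id[margins[units$tad_id] == 0]
  if (length(zero_units) > 0) {
    inform(sprintf("skipping %d zero-contact segment(s): %s",
                   length(zero_units), paste(utils::head(zero_units, 5), collapse = ", ")))
    units <- units %>% filter(!.data$tad_id %in% zero_units)
  }
  n_units <- nrow(units)
  if (n_units < 3) abort("fewer than 3 usable segments after dropping zero-contact ones")

  idx <- utils::combn(n_units, 2)
  keep <- idx[2, ] - idx[1, ] >= 2 # drop consecutive tested segments
  if (!any(keep)) abort("no eligible (non-adjacent) segment pairs")
  ia <- idx[1, keep]
  ib <- idx[2, keep]
  mid <- (units$start + units$end) / 2
  bins <- (units$end - units$start) / tc$resolution_bp

  counts <- tc$pairs
  key <- paste(counts$tad_a, counts$tad_b, sep = "\r")
  lut <- setNames(counts$count, key)
  x <- lut[paste(units$tad_id[ia], units$tad_id[ib], sep = "\r")]
  x[is.na(x)] <- 0

  tibble(
    tad_a = units$tad_id[ia],
    tad_b = units$tad_id[ib],
    observed = unname(x),
    distance_bp = abs(mid[ib] - mid[ia]),
    bins_a = bins[ia],
    bins_b = bins[ib],
    n_a = unname(margins[units$tad_id[ia]]),
    n_b = unname(margins[units$tad_id[ib]])
  )
}

#' Fit a distance-decay expectation model for TAD pairs
#'
#' Assigns eligible (non-adjacent) TAD pairs to log-spaced genomic-distance
#' strata by midpoint separation and records, per stratum, the mean observed
#' contact count and the mean contact count per bin pair (`rho`, the ratio of
#' summed counts to summed bin-pair numbers). The per-pair expected count is
#' `rho_d * bins_a * bins_b`, so TAD size is accounted for alongside distance.
#' Empty strata inherit the nearest non-empty stratum's values.
#'
#' @param tc A `tad_contacts` object from [aggregate_to_tads()].
#' @param n_strata Number of log-spaced distance strata (default 30).
#' @param include_gaps Test gap-filler segments like TADs (default `FALSE`).
#' @return A `distance_model` object with a `strata` tibble (`stratum`, `lo`,
#'   `hi`, `n_pairs`, `mean_count`, `rho`).
#' @export
fit_distance_expectation <- function(tc, n_strata = 30, include_gaps = FALSE) {
  ep <- eligible_pairs(tc, include_gaps = include_gaps)
  d <- ep$distance_bp
  lo <- min(d)
  hi <- max(d)
  if (lo == hi) {
    breaks <- c(lo * 0.999, hi * 1.001)
    n_strata <- 1L
  } else {
    breaks <- exp(seq(log(lo), log(hi), length.out = n_strata + 1))
    breaks[1] <- breaks[1] * 0.999
    breaks[n_strata + 1] <- breaks[n_strata + 1] * 1.001
  }
  stratum <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  agg <- tibble(
    stratum = stratum, count = ep$observed, bp = ep$bins_a * ep$bins_b
  ) %>%
    group_by(.data$stratum) %>%
    summarise(
      n_pairs = dplyr::n(),
      mean_count = mean(.data$count),
      rho = sum(.data$count) / sum(.data$bp),
      .groups = "drop"
    )
  strata <- tibble(
    stratum = seq_len(n_strata),
    lo = breaks[seq_len(n_strata)],
    hi = breaks[seq_len(n_strata) + 1]
  ) %>%
    left_join(agg, by = "stratum") %>%
    mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L))
  # fill empty strata from the nearest non-empty one
  filled <- which(strata$n_pairs > 0)
  if (length(filled) == 0) abort("no eligible pairs to fit the distance model")
  nearest <- filled[apply(abs(outer(strata$stratum, filled, "-")), 1, which.min)]
  strata$mean_count <- strata$mean_count[nearest]
  strata$rho <- strata$rho[nearest]

  structure(
    list(
      strata = strata, breaks = breaks,
      global_mean = mean(ep$observed), n_pairs = nrow(ep),
      include_gaps = include_gaps
    ),
    class = "distance_model"
  )
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("<distance_model> %d strata over %d pairs, global mean count %.2f\n",
              nrow(x$strata), x$n_pairs, x$global_mean))
  invisible(x)
}

#' Expected TAD-pair contact count under a fitted distance model
#'
#' @param model A `distance_model` from [fit_distance_expectation()].
#' @param distance_bp Midpoint separations.
#' @param bins_a,bins_b Sizes of the two TADs in bins.
#' @return Expected counts `rho_d * bins_a * bins_b`.
#' @export
expected_contacts <- function(model, distance_bp, bins_a, bins_b) {
  s <- findInterval(distance_bp, model$breaks, rightmost.closed = TRUE, all.inside = TRUE)
  model$strata$rho[s] * bins_a * bins_b
}

#' Upper-tail p-value of Fisher's non-central hypergeometric distribution
#'
#' Computes `P(X >= x)` for the Fisher non-central hypergeometric distribution
#' with pmf proportional to `choose(n_a, y) * choose(N - n_a, n_b - y) *
#' omega^y`, normalized explicitly over its support in log space so that
#' realistic chromosome-scale totals do not overflow. At `omega = 1` this is
#' the central hypergeometric upper tail.
#'
#' @param x Observed count (vectorized; recycled with the other arguments).
#' @param n_a,n_b Total contacts involving each TAD.
#' @param N Total contacts on the chromosome.
#' @param omega Odds parameter (> 0).
#' @return Upper-tail probabilities.
#' @export
nchg_pvalue <- function(x, n_a, n_b, N, omega) {
  unname(mapply(nchg_pvalue_one, x, n_a, n_b, N, omega))
}

nchg_pvalue_one <- function(x, n_a, n_b, N, omega) {
  if (!is.finite(omega) || omega <= 0) abort("omega must be positive")
  lo <- max(0, n_a + n_b - N)
  hi <- min(n_a, n_b)
  if (lo > hi) abort("empty support: check n_a, n_b, N")
  if (x < lo || x > hi) {
    abort(sprintf("x = %g outside the support [%g, %g]", x, lo, hi))
  }
  y <- lo:hi
  logw <- lchoose(n_a, y) + lchoose(N - n_a, n_b - y) + y * log(omega)
  denom <- logsumexp(logw)
  num <- logsumexp(logw[y >= x])
  exp(num - denom)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call significant TAD-TAD interactions
#'
#' Tests every eligible (linearly non-contiguous) TAD pair for contact
#' enrichment over the distance-decay expectation. The odds parameter is
#' `omega = E_ab * N / (n_a * n_b)` with `E_ab` the distance- and size-aware
#' expected count, so the test asks for more contacts than expected at this
#' distance given both TADs' interaction totals. P-values are BH-adjusted
#' over all tested pairs; a pair is significant when `q < fdr` and its
#' observed/expected fold reaches `min_fold`.
#'
#' @param tc A `tad_contacts` object.
#' @param model Optional pre-fitted `distance_model`; fitted from `tc` when
#'   `NULL`.
#' @param fdr False-discovery-rate threshold (default 0.01).
#' @param min_fold Minimum observed/expected enrichment (default 5).
#' @param n_strata Strata used when fitting the model here.
#' @param include_gaps Test gap-filler segments like TADs.
#' @return Tibble with one row per tested pair: `tad_a`, `tad_b`,
#'   `distance_bp`, `observed`, `expected`, `n_a`, `n_b`, `odds`, `p_value`,
#'   `q_value`, `fold`, `significant`.
#' @export
call_significant_interactions <- function(tc, model = NULL, fdr = 0.01,
                                          min_fold = 5, n_strata = 30,
                                          include_gaps = FALSE) {
  stopifnot(fdr > 0, fdr < 1, min_fold >= 0)
  if (is.null(model)) {
    model <- fit_distance_expectation(tc, n_strata = n_strata,
                                      include_gaps = include_gaps)
  }
  ep <- eligible_pairs(tc, include_gaps = include_gaps)
  N <- tc$total
  expected <- expected_contacts(model, ep$distance_bp, ep$bins_a, ep$bins_b)
  omega <- pmax(expected * N / (ep$n_a * ep$n_b), .Machine$double.xmin)
  p <- nchg_pvalue(ep$observed, ep$n_a, ep$n_b, N, omega)
  q <- bh_fdr(p)
  fold <- dplyr::case_when(
    expected > 0 ~ ep$observed / expected,
    ep$observed > 0 ~ Inf,
    TRUE ~ 0
  )
  ep %>%
    mutate(
      expected = expected,
      odds = omega,
      p_value = p,
      q_value = q,
      fold = fold,
      significant = .data$q_value < fdr & .data$fold >= min_fold
    ) %>%
    select("tad_a", "tad_b", "distance_bp", "observed", "expected",
           "n_a", "n_b", "odds", "p_value", "q_value", "fold", "significant")
}

#' @method tidy distance_model
#' @export
tidy.distance_model <- function(x, ...) {
  x$strata
}

#' @method glance distance_model
#' @export
glance.distance_model <- function(x, ...) {
  tibble(n_strata = nrow(x$strata), n_pairs = x$n_pairs,
         global_mean = x$global_mean)
}
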