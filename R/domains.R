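# Gamma-parameterized dynamic-programming TAD caller with gap-filling.
#
# The quality of a candidate domain [k, l] (bin indices, 0-based inclusive) is
#   q_gamma(k, l) = s(k, l) / d^gamma - mu_gamma(d),   d = l - k + 1,
# where s(k, l) sums contact counts over bin pairs i <= j inside the window
# and mu_gamma(d) is the mean of s / d^gamma over ALL length-d windows on the
# chromosome (global mean variant). The optimal segmentation maximizes the sum
# of positive-quality chosen domains; uncovered bins become gap-filler
# segments so the output always tiles the chromosome.

# Summed-area table of the dense symmetric matrix, for O(1) window sums.
window_sum_machinery <- function(map) {
  m <- contact_dense(map)
  n <- nrow(m)
  sat <- matrix(0, n + 1, n + 1)
  sat[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum)
  diag_cum <- c(0, cumsum(diag(m)))
  # s(k, l) for 1-based inclusive k..l: pairs i <= j within the block
  s_fun <- function(k, l) {
    block <- sat[cbind(l + 1, l + 1)] - sat[cbind(k, l + 1)] -
      sat[cbind(l + 1, k)] + sat[cbind(k, k)]
    (block + (diag_cum[l + 1] - diag_cum[k])) / 2
  }
  list(n = n, s = s_fun)
}

# Mean of s / d^gamma over all length-d windows, for d = 1..max_len.
window_length_means <- function(mach, gamma, max_len) {
  n <- mach$n
  vapply(seq_len(max_len), function(d) {
    starts <- seq_len(n - d + 1)
    mean(mach$s(starts, starts + d - 1)) / d^gamma
  }, double(1))
}

#' Domain quality score
#'
#' Scores candidate domains by their internal contact density relative to the
#' chromosome-wide mean for windows of the same length, scaled by
#' `length^gamma`. Vectorized over `start_bin`/`end_bin`.
#'
#' @param map A [contact_map()].
#' @param start_bin,end_bin 0-based inclusive bin indices, `start_bin <=
#'   end_bin`.
#' @param gamma Resolution parameter; larger values favor shorter domains.
#' @return Numeric vector of quality scores.
#' @export
domain_quality <- function(map, start_bin, end_bin, gamma = 1.2) {
  if (any(end_bin < start_bin)) abort("end_bin must be >= start_bin")
  if (any(start_bin < 0) || any(end_bin >= map$n_bins)) {
    abort("bin indices out of range")
  }
  mach <- window_sum_machinery(map)
  mu <- window_length_means(mach, gamma, max(end_bin - start_bin + 1))
  d <- end_bin - start_bin + 1
  mach$s(start_bin + 1, end_bin + 1) / d^gamma - mu[d]
}

#' Call TADs by dynamic programming
#'
#' Computes the segmentation maximizing the summed quality of chosen domains
#' (only positive-quality domains contribute), then fills unassigned bins
#' with gap segments so the output tiles the chromosome. Ties between equal
#' scores are broken toward the shorter domain.
#'
#' @param map A [contact_map()].
#' @param gamma Resolution parameter (default 1.2).
#' @param min_domain_bins Minimum domain length in bins (>= 2).
#' @param max_domain_bins Cap on domain length in bins; defaults to 2 Mb worth
#'   of bins, comfortably above the 0.2--1 Mb sizes typical of TADs.
#' @return Segmentation tibble: `chrom`, `start`, `end`, `tad_id`
#'   (`tad_NNN` for called domains, `gap_NNN` for fillers), `is_domain`.
#' @export
call_tads <- function(map, gamma = 1.2, min_domain_bins = 2,
                      max_domain_bins = NULL) {
  stopifnot(min_domain_bins >= 2, gamma >= 0, is.finite(gamma))
  n <- map$n_bins
  res <- map$resolution_bp
  max_domain_bins <- max_domain_bins %||% max(min_domain_bins, ceiling(2e6 / res))
  max_domain_bins <- min(max_domain_bins, n)
  if (n < min_domain_bins) {
    warn("chromosome shorter than the minimum domain size; returning one gap segment")
    return(tibble(
      chrom = map$chrom, start = 0, end = as.double(n) * res,
      tad_id = "gap_001", is_domain = FALSE
    ))
  }

  mach <- window_sum_machinery(map)
  mu <- window_length_means(mach, gamma, max_domain_bins)
  # q[d, k]: quality of window of length d starting at 1-based bin k
  q <- matrix(-Inf, max_domain_bins, n)
  for (d in seq_len(max_domain_bins)) {
    starts <- seq_len(n - d + 1)
    q[d, starts] <- mach$s(starts, starts + d - 1) / d^gamma - mu[d]
  }

  eps <- 1e-12
  opt <- numeric(n + 1) # opt[l+1] = best score over first l bins
  choice <- integer(n + 1) # 0 = gap bin, otherwise chosen domain length
  for (l in seq_len(n)) {
    best <- opt[l]
    pick <- 0L
    for (d in min_domain_bins:max_domain_bins) {
      if (d > l) break
      qd <- q[d, l - d + 1]
      if (qd > 0) {
        cand <- opt[l - d + 1] + qd
        if (cand > best + eps) {
          best <- cand
          pick <- d
        }
      }
    }
    opt[l + 1] <- best
    choice[l + 1] <- pick
  }

  # Backtrack into domain/gap runs.
  is_dom_bin <- logical(n)
  dom_start <- integer(0)
  dom_len <- integer(0)
  l <- n
  while (l > 0) {
    d <- choice[l + 1]
    if (d == 0L) {
      l <- l - 1
    } else {
      dom_start <- c(l - d + 1L, dom_start)
      dom_len <- c(d, dom_len)
      is_dom_bin[(l - d + 1):l] <- TRUE
      l <- l - d
    }
  }

  segs <- list()
  if (length(dom_start) > 0) {
    segs <- purrr::map2(dom_start, dom_len, function(s, d) {
      c(start = s - 1L, len = d, domain = 1L)
    })
  }
  gap_runs <- rle(is_dom_bin)
  pos <- 0L
  gaps <- list()
  for (r in seq_along(gap_runs$lengths)) {
    if (!gap_runs$values[r]) {
      gaps[[length(gaps) + 1]] <- c(start = pos, len = gap_runs$lengths[r], domain = 0L)
    }
    pos <- pos + gap_runs$lengths[r]
  }
  all_segs <- c(segs, gaps)
  all_segs <- all_segs[order(vapply(all_segs, `[[`, double(1), "start"))]

  out <- purrr::map(all_segs, function(s) {
    tibble(start_bin = s[["start"]], len = s[["len"]], is_domain = s[["domain"]] == 1)
  }) %>% bind_rows()
  out %>%
    mutate(
      chrom = map$chrom,
      start = as.double(.data$start_bin) * res,
      end = as.double(.data$start_bin + .data$len) * res,
      tad_id = dplyr::if_else(
        .data$is_domain,
        sprintf("tad_%03d", cumsum(.data$is_domain)),
        sprintf("gap_%03d", cumsum(!.data$is_domain))
      )
    ) %>%
    select("chrom", "start", "end", "tad_id", "is_domain")
}
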