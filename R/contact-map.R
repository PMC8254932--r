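#' Binned intra-chromosomal contact map
#'
#' A `contact_map` holds sparse symmetric contact counts for one chromosome at
#' a fixed bin resolution. Counts are stored upper-triangular (`bin_i <= bin_j`,
#' 0-based bin indices) and queried symmetrically.
#'
#' @param chrom Chromosome name.
#' @param resolution_bp Bin size in base pairs.
#' @param n_bins Number of bins on the chromosome.
#' @param contacts Tibble with integer columns `bin_i`, `bin_j` (0-based,
#'   `bin_i <= bin_j`) and non-negative `count`.
#'
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(chrom, resolution_bp, n_bins, contacts) {
  contacts <- as_tibble(contacts)
  stopifnot(all(c("bin_i", "bin_j", "count") %in% names(contacts)))
  if (nrow(contacts) > 0) {
    if (any(contacts$count < 0)) abort("contact counts must be non-negative")
    if (any(contacts$bin_i > contacts$bin_j)) {
      ij <- pmin(contacts$bin_i, contacts$bin_j)
      contacts$bin_j <- pmax(contacts$bin_i, contacts$bin_j)
      contacts$bin_i <- ij
    }
    if (any(contacts$bin_j >= n_bins) || any(contacts$bin_i < 0)) {
      abort("bin indices must lie in [0, n_bins)")
    }
    contacts <- contacts %>%
      group_by(.data$bin_i, .data$bin_j) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      arrange(.data$bin_i, .data$bin_j)
  }
  structure(
    list(
      chrom = chrom,
      resolution_bp = as.integer(resolution_bp),
      n_bins = as.integer(n_bins),
      contacts = contacts
    ),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %s: %d bins @ %d bp, %d non-zero pairs, total count %s\n",
    x$chrom, x$n_bins, x$resolution_bp, nrow(x$contacts),
    format(sum(x$contacts$count), big.mark = ",")
  ))
  invisible(x)
}

#' Total contact count of a map
#' @param map A [contact_map()].
#' @return Sum of all stored (upper-triangular) counts.
#' @export
contact_total <- function(map) {
  sum(map$contacts$count)
}

#' Dense symmetric matrix view of a contact map
#'
#' @param map A [contact_map()].
#' @return An `n_bins x n_bins` symmetric numeric matrix.
#' @export
contact_dense <- function(map) {
  n <- map$n_bins
  m <- matrix(0, n, n)
  if (nrow(map$contacts) > 0) {
    i <- map$contacts$bin_i + 1L
    j <- map$contacts$bin_j + 1L
    m[cbind(i, j)] <- map$contacts$count
    m[cbind(j, i)] <- map$contacts$count
  }
  m
}
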