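# Internal helpers shared across modules.

# Merge possibly-overlapping 0-based half-open intervals into a disjoint,
# sorted set. `x` is a tibble with chrom/start/end. Interval arithmetic is
# delegated to IRanges; coordinates cross the boundary as 1-based closed.
merge_intervals <- function(x) {
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  x %>%
    dplyr::group_split(.data$chrom) %>%
    purrr::map(function(g) {
      ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1, end = g$end))
      tibble(
        chrom = g$chrom[1],
        start = as.double(IRanges::start(ir) - 1),
        end = as.double(IRanges::end(ir))
      )
    }) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$start)
}

# Total base pairs in the intersection of two merged interval sets.
intersect_bp <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0) return(0)
  sum(vapply(chroms, function(ch) {
    ia <- a[a$chrom == ch, , drop = FALSE]
    ib <- b[b$chrom == ch, , drop = FALSE]
    ra <- IRanges::IRanges(start = ia$start + 1, end = ia$end)
    rb <- IRanges::IRanges(start = ib$start + 1, end = ib$end)
    ov <- IRanges::intersect(ra, rb)
    as.double(sum(IRanges::width(ov)))
  }, double(1)))
}

total_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Validate a segmentation tibble: sorted, non-overlapping, tiling per chrom.
validate_segmentation <- function(seg) {
  required <- c("chrom", "start", "end", "tad_id", "is_domain")
  missing <- setdiff(required, names(seg))
  if (length(missing) > 0) {
    abort(paste0("segmentation is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(seg$start >= seg$end)) abort("segmentation has empty or inverted segments")
  for (ch in unique(seg$chrom)) {
    g <- seg[seg$chrom == ch, ]
    if (is.unsorted(g$start)) abort("segmentation must be sorted by start")
    if (nrow(g) > 1 && any(g$start[-1] != g$end[-nrow(g)])) {
      abort("segmentation must tile the chromosome without gaps or overlaps")
    }
  }
  if (anyDuplicated(seg$tad_id)) abort("segmentation tad_id values must be unique")
  invisible(seg)
}
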