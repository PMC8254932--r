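# Readers/writers for the plain-text formats the pipeline touches.
# Coordinates are 0-based half-open everywhere inside the package (BED
# convention); HiC-Pro bin ids are 1-based in files and converted here at the
# boundary.

#' Read a HiC-Pro style contact matrix
#'
#' Reads a sparse triplet `.matrix` file (tab-separated `bin_i bin_j count`,
#' 1-based bin ids) together with its companion bin `.bed` file (0-based
#' half-open bins, 4th column the bin id). Entries are canonicalized to the
#' upper triangle; duplicate `(i,j)`/`(j,i)` records are summed.
#'
#' @param matrix_path Path to the triplet file.
#' @param bins_path Path to the companion bin BED file.
#' @return A [contact_map()].
#' @export
read_contact_matrix <- function(matrix_path, bins_path) {
  bins <- readr::read_tsv(
    bins_path,
    col_names = c("chrom", "start", "end", "bin_id"),
    col_types = "ciii", comment = "#", progress = FALSE
  )
  if (nrow(bins) == 0) abort("bin bed file is empty")
  if (length(unique(bins$chrom)) != 1) {
    abort("contact maps are per-chromosome; bin bed lists several chromosomes")
  }
  if (is.unsorted(bins$start, strictly = TRUE)) abort("bin bed must be sorted")
  res <- bins$end[1] - bins$start[1]
  n_bins <- nrow(bins)

  trip <- readr::read_tsv(
    matrix_path,
    col_names = c("bin_i", "bin_j", "count"),
    col_types = "iid", comment = "#", progress = FALSE
  )
  if (nrow(trip) > 0) {
    if (any(trip$count < 0)) abort("negative contact count in matrix file")
    bad <- setdiff(unique(c(trip$bin_i, trip$bin_j)), bins$bin_id)
    if (length(bad) > 0) {
      abort(sprintf("bin id %s in matrix file absent from bin bed", bad[1]))
    }
  }
  id_to_index <- setNames(seq_len(n_bins) - 1L, bins$bin_id)
  contacts <- tibble(
    bin_i = unname(id_to_index[as.character(trip$bin_i)]),
    bin_j = unname(id_to_index[as.character(trip$bin_j)]),
    count = trip$count
  )
  contact_map(bins$chrom[1], res, n_bins, contacts)
}

#' Write a contact map as a HiC-Pro style matrix/bed pair
#'
#' @param map A [contact_map()].
#' @param matrix_path,bins_path Output paths.
#' @return Invisibly, `map`.
#' @export
write_contact_matrix <- function(map, matrix_path, bins_path) {
  starts <- (seq_len(map$n_bins) - 1) * map$resolution_bp
  bins <- tibble(
    chrom = map$chrom, start = starts, end = starts + map$resolution_bp,
    bin_id = seq_len(map$n_bins)
  )
  readr::write_tsv(bins, bins_path, col_names = FALSE, progress = FALSE)
  trip <- map$contacts %>%
    mutate(bin_i = .data$bin_i + 1L, bin_j = .data$bin_j + 1L)
  readr::write_tsv(trip, matrix_path, col_names = FALSE, progress = FALSE)
  invisible(map)
}

#' Read a BED file
#'
#' Accepts BED3/BED4/BED6; returns the columns present. Coordinates stay
#' 0-based half-open. Malformed records abort with the offending line number.
#'
#' @param path Path to the BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1) {
    abort(sprintf("ragged BED file: line %d has a different column count",
                  line_no[which(lengths(fields) != lengths(fields)[1])[1]]))
  }
  if (ncol < 3) abort("BED file needs at least 3 columns")
  m <- do.call(rbind, fields)
  out <- tibble(
    chrom = m[, 1],
    start = as.double(m[, 2]),
    end = as.double(m[, 3])
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end | out$start < 0)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED interval at line %d", line_no[bad[1]]))
  }
  if (ncol >= 4) out$name <- m[, 4]
  if (ncol >= 5) out$score <- as.double(m[, 5])
  if (ncol >= 6) {
    out$strand <- m[, 6]
    bad <- which(!out$strand %in% c("+", "-", "."))
    if (length(bad) > 0) {
      abort(sprintf("invalid strand at line %d", line_no[bad[1]]))
    }
  }
  out
}

#' Write intervals as BED
#'
#' Writes whichever of `name`, `score`, `strand` are present (in BED column
#' order, padding intermediate columns when needed).
#'
#' @param x Tibble with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  has <- function(col) col %in% names(x)
  get_or <- function(col, default) if (has(col)) x[[col]] else default
  if (has("strand")) {
    cols <- c(cols, list(get_or("name", "."), get_or("score", 0), x$strand))
  } else if (has("score")) {
    cols <- c(cols, list(get_or("name", "."), x$score))
  } else if (has("name")) {
    cols <- c(cols, list(x$name))
  }
  df <- as.data.frame(cols, optional = TRUE)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(x)
}

#' Read / write a per-gene expression table
#'
#' Tab-separated with columns `gene_id`, `chrom`, `tss_pos`, `value`; lines
#' beginning `#` are ignored.
#'
#' @param path File path.
#' @return Tibble with the four columns.
#' @export
read_expression_table <- function(path) {
  readr::read_tsv(path, col_types = "ccdd", comment = "#", progress = FALSE,
                  col_names = c("gene_id", "chrom", "tss_pos", "value"), skip = 1)
}

#' @rdname read_expression_table
#' @param x Expression tibble to write.
#' @export
write_expression_table <- function(x, path) {
  readr::write_tsv(x[, c("gene_id", "chrom", "tss_pos", "value")], path,
                   progress = FALSE)
  invisible(x)
}

#' Read / write a TAD segmentation as BED4
#'
#' Gap-filler segments are flagged by the `gap_` name prefix.
#'
#' @param path File path.
#' @return Segmentation tibble (`chrom`, `start`, `end`, `tad_id`,
#'   `is_domain`).
#' @export
read_segmentation <- function(path) {
  bed <- read_bed(path)
  if (is.null(bed$name)) abort("segmentation BED needs a name column (BED4)")
  seg <- bed %>%
    rename(tad_id = "name") %>%
    mutate(is_domain = !startsWith(.data$tad_id, "gap_")) %>%
    select("chrom", "start", "end", "tad_id", "is_domain")
  validate_segmentation(seg)
  seg
}

#' @rdname read_segmentation
#' @param seg Segmentation tibble to write.
#' @export
write_segmentation <- function(seg, path) {
  validate_segmentation(seg)
  write_bed(seg %>% mutate(name = .data$tad_id) %>%
              select("chrom", "start", "end", "name"), path)
  invisible(seg)
}

#' Aggregate bin-level contacts to TAD-level contacts
#'
#' Each bin is assigned to the unique segment containing its midpoint; counts
#' are summed per unordered segment pair. Total counts are conserved exactly.
#'
#' @param map A [contact_map()].
#' @param segmentation Segmentation tibble tiling the map's chromosome.
#' @return A `tad_contacts` object: list with `pairs` (tibble `tad_a`,
#'   `tad_b`, `count`, canonical order), `segmentation`, `chrom`, `total`.
#' @export
aggregate_to_tads <- function(map, segmentation) {
  validate_segmentation(segmentation)
  seg <- segmentation %>% filter(.data$chrom == map$chrom)
  if (nrow(seg) == 0) abort("segmentation has no segments on the map's chromosome")
  mid <- ((seq_len(map$n_bins) - 1) + 0.5) * map$resolution_bp
  idx <- findInterval(mid, seg$start)
  outside <- idx == 0 | mid >= seg$end[pmax(idx, 1)]
  if (any(outside)) {
    abort(sprintf("bin midpoint %g falls outside the segmentation; it must tile the chromosome",
                  mid[which(outside)[1]]))
  }
  bin_tad <- seg$tad_id[idx]
  ord <- setNames(seq_len(nrow(seg)), seg$tad_id)

  contacts <- map$contacts
  ta <- bin_tad[contacts$bin_i + 1L]
  tb <- bin_tad[contacts$bin_j + 1L]
  flip <- ord[ta] > ord[tb]
  tmp <- ta[flip]; ta[flip] <- tb[flip]; tb[flip] <- tmp
  pairs <- tibble(tad_a = ta, tad_b = tb, count = contacts$count) %>%
    group_by(.data$tad_a, .data$tad_b) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(ord[.data$tad_a], ord[.data$tad_b])

  structure(
    list(pairs = pairs, segmentation = seg, chrom = map$chrom,
         resolution_bp = map$resolution_bp, total = sum(pairs$count)),
    class = "tad_contacts"
  )
}

#' @export
print.tad_contacts <- function(x, ...) {
  cat(sprintf(
    "<tad_contacts> %s: %d segments (%d domains), %d contact pairs, total %s\n",
    x$chrom, nrow(x$segmentation), sum(x$segmentation$is_domain),
    nrow(x$pairs), format(x$total, big.mark = ",")
  ))
  invisible(x)
}
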