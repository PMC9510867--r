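#' Genomic region tables (BED-style intervals)
#'
#' Regions are tibbles with columns `chrom`, `start`, `end` using 0-based
#' half-open coordinates, i.e. exactly the BED convention. Interval algebra
#' is delegated to GenomicRanges/IRanges.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`.
#' @return A region tibble.
#' @export
as_region_tbl <- function(df) {
  df <- tibble::as_tibble(df)[, c("chrom", "start", "end")]
  if (nrow(df) && any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop("region with start >= end at row ", bad)
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

regions_to_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
}

gr_to_regions <- function(gr) {
  as_region_tbl(tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  ))
}

#' Read a BED3+ file
#'
#' @param path Path to a BED file (plain text, tab-separated, no header).
#' @return A region tibble (0-based half-open, as in the file).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    stop("BED line with fewer than 3 fields in ", path)
  }
  df <- tibble::tibble(
    chrom = vapply(parts, `[[`, character(1), 1),
    start = as.numeric(vapply(parts, `[[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[[`, character(1), 3))
  )
  as_region_tbl(df)
}

#' Write regions as BED3
#' @param regions A region tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d", regions$chrom,
                   as.integer(regions$start), as.integer(regions$end))
  writeLines(lines, path)
  invisible(path)
}

#' Normalize a region set
#'
#' Merges overlapping and book-ended intervals per chromosome and sorts the
#' result. Idempotent; total covered bp is preserved except where overlap is
#' collapsed.
#'
#' @param regions A region tibble.
#' @return A normalized region tibble.
#' @export
normalize_regions <- function(regions) {
  regions <- as_region_tbl(regions)
  if (nrow(regions) == 0) return(regions)
  gr_to_regions(GenomicRanges::reduce(regions_to_gr(regions)))
}

#' Total covered base pairs of a region set
#' @param regions A region tibble.
#' @return Numeric scalar: union length in bp.
#' @export
regions_total_bp <- function(regions) {
  if (nrow(regions) == 0) return(0)
  sum(GenomicRanges::width(GenomicRanges::reduce(regions_to_gr(regions))))
}

#' Union / intersection / difference of two region sets
#'
#' All three return normalized region tibbles.
#'
#' @param a,b Region tibbles.
#' @return A region tibble.
#' @export
regions_union <- function(a, b) {
  normalize_regions(dplyr::bind_rows(as_region_tbl(a), as_region_tbl(b)))
}

#' @rdname regions_union
#' @export
regions_intersect <- function(a, b) {
  a <- as_region_tbl(a); b <- as_region_tbl(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  g <- align_gr(regions_to_gr(a), regions_to_gr(b))
  gr_to_regions(GenomicRanges::intersect(g$q, g$s))
}

#' @rdname regions_union
#' @export
regions_subtract <- function(a, b) {
  a <- as_region_tbl(a); b <- as_region_tbl(b)
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(normalize_regions(a))
  g <- align_gr(regions_to_gr(a), regions_to_gr(b))
  gr_to_regions(GenomicRanges::setdiff(g$q, g$s))
}

# put two GRanges on a shared seqlevel set so overlap queries across
# partially disjoint chromosome sets stay silent
align_gr <- function(q, s) {
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(s) <- lv
  list(q = q, s = s)
}

# logical vector: does the i-th query interval [start,end) (or point for
# start==end) intersect any region? Points use the base at `start`.
regions_overlap_any <- function(chrom, start, end, regions) {
  if (length(chrom) == 0) return(logical())
  if (nrow(regions) == 0) return(rep(FALSE, length(chrom)))
  qend <- ifelse(end > start, end, start + 1)
  g <- align_gr(GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, qend)),
                regions_to_gr(regions))
  IRanges::overlapsAny(g$q, g$s)
}
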