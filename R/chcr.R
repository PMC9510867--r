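#' Annotate haplotype-assembly support of high-confidence SVs
#'
#' Matches every high-confidence SV against the SV calls of the paternal
#' and the maternal haplotype assembly (under [match_pair()]) and fills the
#' `hap_support` column accordingly. A record matched in neither callset
#' gets empty `hap_support` and is later treated as discordant when CHCRs
#' are drawn.
#'
#' @param highconf SV tibble of high-confidence calls.
#' @param pat_calls,mat_calls SV tibbles called from the paternal and
#'   maternal haplotype assemblies.
#' @param params A [match_params()].
#' @return The `highconf` tibble with `hap_support` filled
#'   (`""`, `"paternal"`, `"maternal"` or `"maternal,paternal"`).
#' @export
annotate_hap_support <- function(highconf, pat_calls, mat_calls,
                                 params = preset_svmerge()) {
  pat_hit <- has_any_match(highconf, pat_calls, params)
  mat_hit <- has_any_match(highconf, mat_calls, params)
  hap <- character(nrow(highconf))
  hap[pat_hit & !mat_hit] <- "paternal"
  hap[!pat_hit & mat_hit] <- "maternal"
  hap[pat_hit & mat_hit] <- "maternal,paternal"
  highconf$hap_support <- hap
  highconf
}

# logical per query row: does any subject record match it?
has_any_match <- function(query, subject, params) {
  out <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(out)
  subject <- sort_sv_tbl(subject)
  by_chrom <- split(seq_len(nrow(subject)), subject$chrom)
  for (i in seq_len(nrow(query))) {
    idx <- by_chrom[[query$chrom[i]]]
    if (is.null(idx)) next
    ss <- subject$start[idx]
    lo <- findInterval(query$start[i] - params$max_dist - 1, ss) + 1
    hi <- findInterval(query$start[i] + params$max_dist, ss)
    if (lo > hi) next
    cand <- idx[lo:hi]
    out[i] <- any(match_pair(query[i, ], subject[cand, ], params))
  }
  out
}

#' Construct continuous high-confidence regions (CHCRs)
#'
#' Candidate regions are the haplotype-assembly coverage tracks (union of
#' paternal and maternal coverage by default). Every high-confidence SV
#' *without* haplotype-assembly support marks a discordance: a window of
#' `flank` bp on each side of it is excised from the candidate regions.
#' Surviving fragments shorter than `min_region` are dropped. Benchmark SVs
#' are the haplotype-supported high-confidence SVs wholly contained in a
#' surviving region.
#'
#' @param annotated SV tibble with `hap_support` filled (see
#'   [annotate_hap_support()]).
#' @param pat_cov,mat_cov Region tibbles of paternal/maternal assembly
#'   coverage.
#' @param flank Half-width in bp of the window excised around an
#'   unsupported SV (default 1000).
#' @param min_region Minimum surviving region length in bp (default 10000).
#' @param coverage_mode `"union"` (default) or `"intersect"`: how the two
#'   coverage tracks combine into candidate regions.
#' @return An object of class `benchmark_set`: a list with `chcrs` (tibble:
#'   `chcr_id`, `chrom`, `start`, `end`, `hap`, `n_svs`) and `svs` (SV
#'   tibble with a `chcr_id` column).
#' @export
build_chcrs <- function(annotated, pat_cov, mat_cov, flank = 1000,
                        min_region = 10000,
                        coverage_mode = c("union", "intersect")) {
  coverage_mode <- match.arg(coverage_mode)
  pat_cov <- normalize_regions(pat_cov)
  mat_cov <- normalize_regions(mat_cov)
  candidate <- if (coverage_mode == "union") {
    regions_union(pat_cov, mat_cov)
  } else {
    regions_intersect(pat_cov, mat_cov)
  }

  unsupported <- annotated[annotated$hap_support == "", , drop = FALSE]
  if (nrow(unsupported) > 0) {
    excise <- as_region_tbl(tibble::tibble(
      chrom = unsupported$chrom,
      start = pmax(0, unsupported$start - flank),
      end = pmax(unsupported$end, unsupported$start) + flank
    ))
    candidate <- regions_subtract(candidate, excise)
  }
  candidate <- candidate[candidate$end - candidate$start >= min_region, , drop = FALSE]

  supported <- annotated[annotated$hap_support != "", , drop = FALSE]
  chcr_id_of <- region_containing(supported, candidate)
  svs <- supported[!is.na(chcr_id_of), , drop = FALSE]
  svs$chcr_id <- chcr_id_of[!is.na(chcr_id_of)]

  hap <- character(nrow(candidate))
  if (nrow(candidate) > 0) {
    pat_ov <- regions_overlap_any(candidate$chrom, candidate$start, candidate$end, pat_cov)
    mat_ov <- regions_overlap_any(candidate$chrom, candidate$start, candidate$end, mat_cov)
    hap[pat_ov & !mat_ov] <- "paternal"
    hap[!pat_ov & mat_ov] <- "maternal"
    hap[pat_ov & mat_ov] <- "maternal,paternal"
  }
  chcrs <- tibble::tibble(
    chcr_id = paste0("chcr", seq_len(nrow(candidate))),
    chrom = candidate$chrom, start = candidate$start, end = candidate$end,
    hap = hap,
    n_svs = as.numeric(table(factor(svs$chcr_id,
                                    levels = paste0("chcr", seq_len(nrow(candidate))))))
  )
  svs <- sort_sv_tbl(svs)
  structure(list(chcrs = chcrs, svs = svs), class = "benchmark_set")
}

# id ("chcrN") of the region wholly containing each SV, NA when none;
# an INS is contained when its breakpoint base lies inside the region
region_containing <- function(svs, regions) {
  out <- rep(NA_character_, nrow(svs))
  if (nrow(svs) == 0 || nrow(regions) == 0) return(out)
  qend <- pmax(svs$end, svs$start + 1)
  g <- align_gr(GenomicRanges::GRanges(svs$chrom,
                                       IRanges::IRanges(svs$start + 1, qend)),
                regions_to_gr(regions))
  hits <- GenomicRanges::findOverlaps(g$q, g$s, type = "within")
  out[S4Vectors::queryHits(hits)] <- paste0("chcr", S4Vectors::subjectHits(hits))
  out
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat("<benchmark_set>", nrow(x$chcrs), "CHCRs spanning",
      format(sum(x$chcrs$end - x$chcrs$start), big.mark = ","), "bp |",
      nrow(x$svs), "benchmark SVs\n")
  invisible(x)
}

#' @export
glance.benchmark_set <- function(x, ...) {
  tibble::tibble(
    n_chcrs = nrow(x$chcrs),
    total_bp = sum(x$chcrs$end - x$chcrs$start),
    n_svs = nrow(x$svs),
    n_del = sum(x$svs$svtype == "DEL"),
    n_ins = sum(x$svs$svtype == "INS")
  )
}

#' Write / read a benchmark as truth VCF plus regions BED
#'
#' The standard distribution format of an SV benchmark: a truth VCF whose
#' records carry haplotype support in the `HAP` INFO key, and a BED of the
#' confident regions (4th column: haplotype coverage of the region).
#' [read_benchmark()] reconstructs the `benchmark_set` from the two files.
#'
#' @param bs A `benchmark_set`.
#' @param vcf_path,bed_path Output (or input) paths.
#' @return `emit_benchmark()`: invisibly, the two paths. `read_benchmark()`:
#'   a `benchmark_set`.
#' @export
emit_benchmark <- function(bs, vcf_path, bed_path) {
  write_sv_vcf(bs$svs, vcf_path)
  lines <- sprintf("%s\t%d\t%d\t%s", bs$chcrs$chrom,
                   as.integer(bs$chcrs$start), as.integer(bs$chcrs$end),
                   ifelse(bs$chcrs$hap == "", ".", bs$chcrs$hap))
  writeLines(lines, bed_path)
  invisible(c(vcf_path, bed_path))
}

#' @rdname emit_benchmark
#' @export
read_benchmark <- function(vcf_path, bed_path) {
  svs <- read_sv_vcf(vcf_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    chcrs <- tibble::tibble(chcr_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            hap = character(), n_svs = numeric())
    svs$chcr_id <- character(0)
    return(structure(list(chcrs = chcrs, svs = svs), class = "benchmark_set"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bed <- tibble::tibble(
    chrom = vapply(parts, `[[`, character(1), 1),
    start = as.numeric(vapply(parts, `[[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[[`, character(1), 3)),
    hap = vapply(parts, function(p) if (length(p) >= 4) p[[4]] else ".",
                 character(1))
  )
  bed <- bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
  regions <- as_region_tbl(bed[, c("chrom", "start", "end")])
  hap <- ifelse(bed$hap == ".", "", bed$hap)
  chcr_id_of <- region_containing(svs, regions)
  svs <- svs[!is.na(chcr_id_of), , drop = FALSE]
  svs$chcr_id <- chcr_id_of[!is.na(chcr_id_of)]
  chcrs <- tibble::tibble(
    chcr_id = paste0("chcr", seq_len(nrow(regions))),
    chrom = regions$chrom, start = regions$start, end = regions$end,
    hap = hap,
    n_svs = as.numeric(table(factor(svs$chcr_id,
                                    levels = paste0("chcr", seq_len(nrow(regions))))))
  )
  structure(list(chcrs = chcrs, svs = sort_sv_tbl(svs)), class = "benchmark_set")
}
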