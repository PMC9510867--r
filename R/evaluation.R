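#' Classify a test callset against a benchmark
#'
#' Test records lying outside every CHCR are ignored (the benchmark makes no
#' claim there). Within the regions, candidate (benchmark, test) pairs under
#' [match_pair()] are assigned one-to-one, greedily by breakpoint distance
#' (ties broken in favour of the longer test SV): each benchmark SV matches
#' at most one test record and vice versa. Matched benchmark SVs are TP,
#' unmatched benchmark SVs FN, and unmatched in-region test records FP.
#'
#' @param test SV tibble of the callset to score.
#' @param bench A `benchmark_set` (see [build_chcrs()]).
#' @param params A [match_params()]; defaults to the evaluation preset.
#' @return A list of class `sv_classification`: `tp_pairs` (tibble with
#'   `bench_id`, `test_id`, `distance`), `fp_records`, `fn_records` (SV
#'   tibbles), and `n_outside` (test records ignored as out-of-region).
#' @export
classify_calls <- function(test, bench, params = preset_truvari()) {
  regions <- bench$chcrs[, c("chrom", "start", "end")]
  inside <- !is.na(region_containing(test, as_region_tbl(regions)))
  test_in <- sort_sv_tbl(test[inside, , drop = FALSE])
  truth <- bench$svs

  cand <- candidate_pairs(truth, test_in, params)
  matched_truth <- rep(FALSE, nrow(truth))
  matched_test <- rep(FALSE, nrow(test_in))
  accepted <- logical(nrow(cand))
  if (nrow(cand) > 0) {
    ord <- order(cand$distance, -test_in$svlen[cand$test_row])
    cand <- cand[ord, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      bi <- cand$truth_row[r]; ti <- cand$test_row[r]
      if (!matched_truth[bi] && !matched_test[ti]) {
        matched_truth[bi] <- TRUE
        matched_test[ti] <- TRUE
        accepted[r] <- TRUE
      }
    }
  }
  cand <- cand[accepted, , drop = FALSE]

  tp_pairs <- tibble::tibble(
    bench_id = truth$id[cand$truth_row],
    test_id = test_in$id[cand$test_row],
    distance = cand$distance
  )
  structure(
    list(tp_pairs = tp_pairs,
         fp_records = test_in[!matched_test, , drop = FALSE],
         fn_records = truth[!matched_truth, , drop = FALSE],
         n_outside = sum(!inside)),
    class = "sv_classification"
  )
}

# all (truth_row, test_row) pairs satisfying match_pair, with start distance
candidate_pairs <- function(truth, test, params) {
  out <- tibble::tibble(truth_row = integer(), test_row = integer(),
                        distance = numeric())
  if (nrow(truth) == 0 || nrow(test) == 0) return(out)
  by_chrom <- split(seq_len(nrow(test)), test$chrom)
  rows_t <- integer(0); rows_s <- integer(0)
  for (i in seq_len(nrow(truth))) {
    idx <- by_chrom[[truth$chrom[i]]]
    if (is.null(idx)) next
    ss <- test$start[idx]
    lo <- findInterval(truth$start[i] - params$max_dist - 1, ss) + 1
    hi <- findInterval(truth$start[i] + params$max_dist, ss)
    if (lo > hi) next
    cand <- idx[lo:hi]
    ok <- match_pair(truth[i, ], test[cand, ], params)
    rows_t <- c(rows_t, rep(i, sum(ok)))
    rows_s <- c(rows_s, cand[ok])
  }
  tibble::tibble(
    truth_row = rows_t, test_row = rows_s,
    distance = abs(truth$start[rows_t] - test$start[rows_s])
  )
}

#' Precision, recall and F1 from TP/FP/FN counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2PR/(P+R)`; all defined as 0 when their denominator is 0.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @param stratum Optional stratum label column.
#' @return Tibble with columns `stratum` (if given), `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
#' @examples
#' compute_prf(8, 2, 2)
compute_prf <- function(tp, fp, fn, stratum = NULL) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  out <- tibble::tibble(tp = tp, fp = fp, fn = fn,
                        precision = precision, recall = recall, f1 = f1)
  if (!is.null(stratum)) out <- dplyr::bind_cols(tibble::tibble(stratum = stratum), out)
  out
}

#' Evaluate a callset against a benchmark
#'
#' Convenience wrapper around [classify_calls()] and [compute_prf()],
#' including per-svtype strata. Supports [generics::tidy()] (per-stratum
#' rows), [generics::glance()] (overall one-row summary) and
#' [ggplot2::autoplot()].
#'
#' @inheritParams classify_calls
#' @return An object of class `sv_eval`.
#' @export
evaluate_callset <- function(test, bench, params = preset_truvari()) {
  cls <- classify_calls(test, bench, params)
  truth <- bench$svs
  tp_type <- truth$svtype[match(cls$tp_pairs$bench_id, truth$id)]
  strata <- c("ALL", "DEL", "INS")
  res <- purrr::map_dfr(strata, function(s) {
    in_s <- function(types) if (s == "ALL") rep(TRUE, length(types)) else types == s
    compute_prf(
      tp = sum(in_s(tp_type)),
      fp = sum(in_s(cls$fp_records$svtype)),
      fn = sum(in_s(cls$fn_records$svtype)),
      stratum = s
    )
  })
  structure(list(result = res, classification = cls), class = "sv_eval")
}

#' @export
print.sv_eval <- function(x, ...) {
  cat("<sv_eval>\n")
  print(x$result)
  invisible(x)
}

#' @export
tidy.sv_eval <- function(x, ...) x$result

#' @export
glance.sv_eval <- function(x, ...) {
  x$result[x$result$stratum == "ALL", c("tp", "fp", "fn", "precision", "recall", "f1")]
}

#' @export
autoplot.sv_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$result,
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Benchmark evaluation") +
    ggplot2::theme_minimal()
}

#' F1 as a function of sequencing depth
#'
#' Evaluates one callset per depth against the benchmark and tabulates
#' precision/recall/F1 by depth, mirroring the depth-titration used to find
#' the saturation point of a platform.
#'
#' @param callsets_by_depth Named list of SV tibbles; names are numeric
#'   depths (e.g. `"5"`, `"11"`, `"20"`).
#' @param bench A `benchmark_set`.
#' @param params A [match_params()].
#' @return A tibble of class `sv_depth_curve` with columns `depth`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `f1`, sorted by depth.
#' @export
depth_curve <- function(callsets_by_depth, bench, params = preset_truvari()) {
  stopifnot(length(callsets_by_depth) >= 2, !is.null(names(callsets_by_depth)))
  depths <- as.numeric(names(callsets_by_depth))
  res <- purrr::map_dfr(seq_along(depths), function(i) {
    ev <- evaluate_callset(callsets_by_depth[[i]], bench, params)
    dplyr::bind_cols(tibble::tibble(depth = depths[i]), glance(ev))
  })
  res <- res[order(res$depth), , drop = FALSE]
  class(res) <- c("sv_depth_curve", class(res))
  res
}

#' @export
autoplot.sv_depth_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth, y = .data$f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Sequencing depth (x)", y = "F1 score",
                  title = "F1 vs sequencing depth") +
    ggplot2::theme_minimal()
}

#' Merge replicate callsets into a consensus
#'
#' Clusters calls across technical replicates (distance and type criteria
#' only, in the style of consensus mergers for short-read SV callers) and
#' keeps clusters supported by at least `min_support` distinct replicates
#' whose representative is at least `min_size` bp long. The default
#' parameters correspond to the consensus setting "1000 2 1 1 0 30"
#' (distance, support, type agreement, strand agreement, no duplicate
#' handling, minimum size); the strand flag is parsed but inert for
#' DEL/INS, which are strand-symmetric.
#'
#' @param replicates List of at least two SV tibbles.
#' @param max_dist Breakpoint distance cap in bp.
#' @param min_support Minimum number of distinct replicates per cluster.
#' @param same_type Require type agreement within a cluster?
#' @param same_strand Accepted for interface fidelity; ignored.
#' @param min_size Minimum representative svlen in bp.
#' @return The consensus SV tibble with an `n_replicates` column.
#' @export
merge_replicates <- function(replicates, max_dist = 1000, min_support = 2,
                             same_type = TRUE, same_strand = FALSE,
                             min_size = 30) {
  stopifnot(length(replicates) >= 2)
  labelled <- purrr::imap(replicates, function(cs, i) {
    cs$support <- paste0("rep", i)
    cs
  })
  params <- match_params(max_dist = max_dist, min_size_ratio = 1e-9,
                         min_recip_overlap = 0, max_divergence = 1,
                         require_same_type = same_type)
  merged <- cluster_merge(labelled, params = params,
                          priority = paste0("rep", seq_along(replicates)))
  merged$n_replicates <- support_size(merged$support)
  keep <- merged$n_replicates >= min_support & merged$svlen >= min_size
  out <- merged[keep, , drop = FALSE]
  out$support <- ""
  sort_sv_tbl(out)
}

#' Compare two SV benchmarks
#'
#' Reports how much of each benchmark the other recovers: the number of
#' shared SVs over all SVs, the intersection of the two region sets, and,
#' within the overlapping regions, the shared count plus each side's unique
#' count with per-side shared fractions
#' (`shared / (shared + unique_side)`).
#'
#' @param a,b `benchmark_set` objects.
#' @param params A [match_params()]; defaults to the merge preset.
#' @return A list of class `benchmark_comparison`: `shared_total`,
#'   `overlap_regions` (region tibble), `overlap_bp`, and `in_overlap`, a
#'   tibble with `shared`, `unique_a`, `unique_b`, `shared_frac_a`,
#'   `shared_frac_b`.
#' @export
compare_benchmarks <- function(a, b, params = preset_svmerge()) {
  shared_total <- sum(has_any_match(a$svs, b$svs, params))

  overlap <- regions_intersect(a$chcrs[, c("chrom", "start", "end")],
                               b$chcrs[, c("chrom", "start", "end")])
  overlap_bp <- regions_total_bp(overlap)

  a_in <- a$svs[!is.na(region_containing(a$svs, overlap)), , drop = FALSE]
  b_in <- b$svs[!is.na(region_containing(b$svs, overlap)), , drop = FALSE]
  a_hit <- has_any_match(a_in, b_in, params)
  b_hit <- has_any_match(b_in, a_in, params)
  shared <- sum(a_hit)
  unique_a <- sum(!a_hit)
  unique_b <- sum(!b_hit)
  in_overlap <- tibble::tibble(
    shared = shared, unique_a = unique_a, unique_b = unique_b,
    shared_frac_a = ifelse(shared + unique_a == 0, NA_real_,
                           shared / (shared + unique_a)),
    shared_frac_b = ifelse(shared + unique_b == 0, NA_real_,
                           shared / (shared + unique_b))
  )
  structure(
    list(shared_total = shared_total, overlap_regions = overlap,
         overlap_bp = overlap_bp, in_overlap = in_overlap),
    class = "benchmark_comparison"
  )
}

#' @export
print.benchmark_comparison <- function(x, ...) {
  cat("<benchmark_comparison>\n",
      "shared SVs (all):", x$shared_total, "\n",
      "overlap regions:", format(x$overlap_bp, big.mark = ","), "bp\n")
  print(x$in_overlap)
  invisible(x)
}

#' @export
tidy.benchmark_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(shared_total = x$shared_total, overlap_bp = x$overlap_bp),
    x$in_overlap
  )
}
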