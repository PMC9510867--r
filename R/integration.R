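#' Retention policy for high-confidence SV integration
#'
#' Encodes the two retention tiers applied to the merged multi-platform
#' callset: a call is kept when (a) it was detected by the anchor platform
#' (CCS alignment) and corroborated by at least one of the corroborating
#' platforms (CLR or ONT alignment), or (b) it is longer than
#' `long_sv_min_len` and supported by every long-SV platform (CCS assembly
#' and Bionano). Calls shorter than `min_svlen` are always dropped.
#'
#' @param anchor_label Platform whose detection anchors tier one.
#' @param corroborating_labels Platforms that can corroborate the anchor.
#' @param long_sv_min_len Strict lower bound (bp) for the long-SV tier.
#' @param long_sv_labels Platforms that must all support a long SV.
#' @param min_svlen Minimum SV length in bp.
#' @return An object of class `retention_policy`.
#' @export
retention_policy <- function(anchor_label = "CCS",
                             corroborating_labels = c("CLR", "ONT"),
                             long_sv_min_len = 1500,
                             long_sv_labels = c("ASM", "BN"),
                             min_svlen = 50) {
  stopifnot(long_sv_min_len > min_svlen)
  structure(
    list(anchor_label = anchor_label,
         corroborating_labels = corroborating_labels,
         long_sv_min_len = long_sv_min_len,
         long_sv_labels = long_sv_labels,
         min_svlen = min_svlen),
    class = "retention_policy"
  )
}

#' Remove SVs intersecting exclusion regions
#'
#' A deletion is removed when its span `[start, end)` intersects any
#' exclusion interval; an insertion when its breakpoint base does.
#' Exclusion regions are typically centromeres, telomeres, segmental
#' duplications and short tandem repeats, supplied as a BED file.
#'
#' @param svs An SV tibble.
#' @param excl A region tibble of exclusion intervals (normalized first).
#' @return A list with SV tibbles `kept` and `removed`; their union is the
#'   input.
#' @export
filter_excluded_regions <- function(svs, excl) {
  excl <- normalize_regions(excl)
  hit <- regions_overlap_any(svs$chrom, svs$start, svs$end, excl)
  list(kept = sort_sv_tbl(svs[!hit, , drop = FALSE]),
       removed = sort_sv_tbl(svs[hit, , drop = FALSE]))
}

#' Apply the tiered retention rules
#'
#' @param svs An SV tibble whose `support` column carries merged platform
#'   labels (see [cluster_merge()]).
#' @param policy A [retention_policy()].
#' @return The retained SV tibble, sorted.
#' @export
apply_retention_rules <- function(svs, policy = retention_policy()) {
  known <- unique(c(policy$anchor_label, policy$corroborating_labels,
                    policy$long_sv_labels))
  labels_present <- unique(unlist(support_list(svs$support)))
  bad <- setdiff(labels_present, known)
  if (length(bad) > 0) {
    stop("unknown platform label(s) in support: ", paste(bad, collapse = ", "))
  }
  supp <- support_list(svs$support)
  tier1 <- vapply(supp, function(s) {
    policy$anchor_label %in% s && length(intersect(s, policy$corroborating_labels)) > 0
  }, logical(1))
  tier2 <- svs$svlen > policy$long_sv_min_len &
    vapply(supp, function(s) all(policy$long_sv_labels %in% s), logical(1))
  keep <- svs$svlen >= policy$min_svlen & (tier1 | tier2)
  sort_sv_tbl(svs[keep, , drop = FALSE])
}

#' Build the high-confidence SV callset
#'
#' Composition of the three integration stages: cross-platform merge
#' ([cluster_merge()]), exclusion-region filtering
#' ([filter_excluded_regions()]) and tiered retention
#' ([apply_retention_rules()]). An audit table of per-stage record counts is
#' returned alongside the callset so every removal is accountable.
#'
#' @param callsets List of SV tibbles, one per platform/caller.
#' @param excl Region tibble of exclusion regions (may be empty).
#' @param params A [match_params()] for the merge stage.
#' @param policy A [retention_policy()].
#' @param priority Platform priority for merge representatives.
#' @return A list with elements `highconf` (SV tibble) and `audit` (tibble
#'   with columns `stage`, `n_in`, `n_kept`, `n_removed`).
#' @export
build_high_confidence <- function(callsets, excl = NULL,
                                  params = preset_svmerge(),
                                  policy = retention_policy(),
                                  priority = c("CCS", "CLR", "ONT", "ASM", "BN")) {
  if (is.data.frame(callsets)) callsets <- list(callsets)
  n_input <- sum(vapply(callsets, nrow, integer(1)))
  merged <- cluster_merge(callsets, params = params, priority = priority)

  if (is.null(excl)) {
    excl <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  }
  flt <- filter_excluded_regions(merged, excl)
  retained <- apply_retention_rules(flt$kept, policy)

  audit <- tibble::tibble(
    stage = c("merge", "exclusion_filter", "retention"),
    n_in = c(n_input, nrow(merged), nrow(flt$kept)),
    n_kept = c(nrow(merged), nrow(flt$kept), nrow(retained)),
    n_removed = n_in - n_kept
  )
  list(highconf = retained, audit = audit)
}
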