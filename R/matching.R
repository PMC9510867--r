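#' Matching parameters for pairwise SV comparison
#'
#' Bundles the thresholds under which two SV calls are considered the same
#' event: breakpoint distance, size ratio, reciprocal overlap (deletions),
#' and sequence divergence (insertions with base-resolved alleles).
#'
#' Two named presets cover the common cases:
#' * [preset_svmerge()] — merging calls across platforms: distance 1000 bp,
#'   size ratio 0.5, reciprocal overlap 0.5, divergence 0.2.
#' * [preset_truvari()] — benchmark evaluation: distance 500 bp, size ratio
#'   0.7, no reciprocal-overlap requirement, divergence 0.3.
#'
#' @param max_dist Maximum breakpoint (start) distance in bp.
#' @param min_size_ratio Minimum `min(svlen)/max(svlen)` in (0, 1].
#' @param min_recip_overlap Minimum reciprocal overlap for DEL pairs, in
#'   \[0, 1\].
#' @param max_divergence Maximum sequence divergence for INS pairs with both
#'   sequences present, in \[0, 1\].
#' @param require_same_type Must both records have the same `svtype`?
#' @return An object of class `match_params`.
#' @export
match_params <- function(max_dist = 1000, min_size_ratio = 0.5,
                         min_recip_overlap = 0.5, max_divergence = 0.2,
                         require_same_type = TRUE) {
  stopifnot(max_dist >= 0,
            min_size_ratio > 0, min_size_ratio <= 1,
            min_recip_overlap >= 0, min_recip_overlap <= 1,
            max_divergence >= 0, max_divergence <= 1)
  structure(
    list(max_dist = max_dist, min_size_ratio = min_size_ratio,
         min_recip_overlap = min_recip_overlap, max_divergence = max_divergence,
         require_same_type = require_same_type),
    class = "match_params"
  )
}

#' @rdname match_params
#' @export
preset_svmerge <- function() {
  match_params(max_dist = 1000, min_size_ratio = 0.5,
               min_recip_overlap = 0.5, max_divergence = 0.2)
}

#' @rdname match_params
#' @export
preset_truvari <- function() {
  match_params(max_dist = 500, min_size_ratio = 0.7,
               min_recip_overlap = 0, max_divergence = 0.3)
}

#' Sequence divergence between two alleles
#'
#' Levenshtein edit distance divided by the longer length; 0 when both
#' strings are empty. Symmetric. Vectorized over pairs.
#'
#' @param a,b Nucleotide strings (`ACGTN` alphabet, case-insensitive).
#' @return Numeric vector of divergences in \[0, 1\].
#' @export
#' @examples
#' sequence_divergence("ACGT", "ACGA") # 0.25
sequence_divergence <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ok <- grepl("^[ACGTN]*$", a) & grepl("^[ACGTN]*$", b)
  if (!all(ok)) stop("non-nucleotide characters in sequence")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  d <- mapply(function(x, y) utils::adist(x, y)[1, 1], a, b, USE.NAMES = FALSE)
  len <- pmax(nchar(a), nchar(b))
  ifelse(len == 0, 0, d / len)
}

#' Reciprocal overlap of two intervals
#'
#' `min(overlap/len_a, overlap/len_b)` for 0-based half-open intervals on
#' the same chromosome; 0 when disjoint or when either interval is empty.
#'
#' @param start_a,end_a,start_b,end_b Interval coordinates (vectorized).
#' @return Numeric vector of reciprocal overlaps in \[0, 1\].
#' @export
#' @examples
#' reciprocal_overlap(100, 600, 300, 800) # 0.6
reciprocal_overlap <- function(start_a, end_a, start_b, end_b) {
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  la <- end_a - start_a
  lb <- end_b - start_b
  ifelse(la <= 0 | lb <= 0, 0, pmin(ov / la, ov / lb))
}

#' Do two SV records describe the same event?
#'
#' All enabled criteria must pass (logical AND): same type (when
#' `require_same_type`), start distance within `max_dist`, size ratio at
#' least `min_size_ratio`, and — for DEL pairs — reciprocal overlap at least
#' `min_recip_overlap`; for INS pairs with both inserted sequences present,
#' sequence divergence at most `max_divergence`. Records on different
#' chromosomes never match. Symmetric in its two arguments. Vectorized
#' row-wise over two SV tables of equal length (or one of length 1).
#'
#' @param a,b SV tibbles (rows compared pairwise).
#' @param params A [match_params()] object.
#' @return Logical vector.
#' @export
match_pair <- function(a, b, params = match_params()) {
  n <- max(nrow(a), nrow(b))
  if (n == 0) return(logical())
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  stopifnot(nrow(a) == nrow(b))

  res <- a$chrom == b$chrom &
    abs(a$start - b$start) <= params$max_dist &
    pmin(a$svlen, b$svlen) / pmax(a$svlen, b$svlen) >= params$min_size_ratio
  if (params$require_same_type) res <- res & (a$svtype == b$svtype)

  del <- res & a$svtype == "DEL" & b$svtype == "DEL"
  if (any(del)) {
    ro <- reciprocal_overlap(a$start[del], a$end[del], b$start[del], b$end[del])
    res[del] <- ro >= params$min_recip_overlap
  }
  ins <- res & a$svtype == "INS" & b$svtype == "INS" &
    a$alt_seq != "" & b$alt_seq != ""
  if (any(ins)) {
    div <- sequence_divergence(a$alt_seq[ins], b$alt_seq[ins])
    res[ins] <- div <= params$max_divergence
  }
  res
}

#' Merge SV callsets by clustering matching records
#'
#' Deterministic greedy clustering in `(chrom, start)` order: each record
#' joins the first existing cluster whose seed record it matches under
#' [match_pair()], otherwise it seeds a new cluster. Anchoring matches on
#' the seed (not on every member) prevents unbounded transitive chaining,
#' which a plain distance criterion would otherwise permit. The reported
#' cluster representative is the member from the highest-priority platform
#' (ties broken by smallest start, then longest svlen); its `support`
#' becomes the union of all member platform labels and its genotype the
#' majority genotype of the members (ties give `"unknown"`).
#'
#' @param callsets A single SV tibble or a list of SV tibbles (one per
#'   platform/caller).
#' @param params A [match_params()] object.
#' @param priority Character vector ordering platform labels from most to
#'   least trusted; must cover every label present.
#' @param details If `TRUE`, also return the per-record cluster assignment.
#' @return The merged SV tibble with an `n_members` column; when
#'   `details = TRUE`, a list with elements `merged` and `assignments`
#'   (tibble: `id`, `support`, `cluster`).
#' @export
cluster_merge <- function(callsets, params = match_params(),
                          priority = c("CCS", "CLR", "ONT", "ASM", "BN"),
                          details = FALSE) {
  if (is.data.frame(callsets)) callsets <- list(callsets)
  all_svs <- dplyr::bind_rows(callsets)
  if (nrow(all_svs) == 0) {
    merged <- empty_sv_tbl()
    merged$n_members <- numeric()
    if (details) {
      return(list(merged = merged,
                  assignments = tibble::tibble(id = character(),
                                               support = character(),
                                               cluster = integer())))
    }
    return(merged)
  }
  labels_present <- unique(unlist(support_list(all_svs$support)))
  unknown <- setdiff(labels_present, priority)
  if (length(unknown) > 0) {
    stop("priority does not cover platform label(s): ",
         paste(unknown, collapse = ", "))
  }
  all_svs <- sort_sv_tbl(all_svs)

  cluster <- greedy_cluster(all_svs, params)
  n_clusters <- max(cluster, 0L)

  # representative per cluster: highest-priority platform, ties -> smallest
  # start, then longest svlen
  prio_rank <- vapply(support_list(all_svs$support), function(v) {
    m <- match(v, priority)
    if (length(m) == 0 || all(is.na(m))) length(priority) + 1L else min(m, na.rm = TRUE)
  }, integer(1))
  ord <- order(cluster, prio_rank, all_svs$start, -all_svs$svlen)
  rep_idx <- ord[!duplicated(cluster[ord])]
  rep_idx <- rep_idx[order(cluster[rep_idx])]

  merged <- all_svs[rep_idx, , drop = FALSE]
  supp_by_cluster <- split(all_svs$support, cluster)
  gt_by_cluster <- split(all_svs$genotype, cluster)
  keys <- as.character(seq_len(n_clusters))
  merged$support <- support_join(lapply(
    supp_by_cluster[keys], function(s) unlist(support_list(s))))
  merged$genotype <- vapply(gt_by_cluster[keys], majority_genotype, character(1))
  merged$n_members <- as.numeric(table(factor(cluster, levels = seq_len(n_clusters))))
  merged <- sort_sv_tbl(merged)
  if (!details) return(merged)
  list(merged = merged,
       assignments = tibble::tibble(id = all_svs$id,
                                    support = all_svs$support,
                                    cluster = cluster))
}

# Greedy seeded sweep over a (chrom, start)-sorted SV table: each record is
# matched against the seed record of every live cluster in creation order;
# clusters whose seed is more than max_dist behind the sweep position (or on
# an earlier chromosome) are retired, keeping the scan window small.
greedy_cluster <- function(svs, params) {
  n <- nrow(svs)
  cluster <- integer(n)
  if (n == 0) return(cluster)
  seed_idx <- integer(0)
  seed_start <- numeric(0)
  seed_chrom <- character(0)
  n_clusters <- 0L
  active_from <- 1L
  starts <- svs$start; chroms <- svs$chrom

  for (i in seq_len(n)) {
    while (active_from <= n_clusters &&
           (seed_chrom[active_from] != chroms[i] ||
              starts[i] - seed_start[active_from] > params$max_dist)) {
      active_from <- active_from + 1L
    }
    assigned <- 0L
    for (j in seq.int(active_from, length.out = n_clusters - active_from + 1L)) {
      if (match_pair(svs[i, ], svs[seed_idx[j], ], params)) {
        assigned <- j
        break
      }
    }
    if (assigned == 0L) {
      n_clusters <- n_clusters + 1L
      seed_idx[n_clusters] <- i
      seed_start[n_clusters] <- starts[i]
      seed_chrom[n_clusters] <- chroms[i]
      cluster[i] <- n_clusters
    } else {
      cluster[i] <- assigned
    }
  }
  cluster
}

majority_genotype <- function(g) {
  g <- g[g != "unknown"]
  if (length(g) == 0) return("unknown")
  tab <- sort(table(g), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("unknown")
  names(tab)[1]
}
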