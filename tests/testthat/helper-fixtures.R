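# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; heavyweight fixtures are memoised per test run.

make_sv <- function(chrom = "chr1", start = 1000, svtype = "DEL", svlen = 500,
                    id = "sv1", alt_seq = "", ref_seq = "", support = "",
                    genotype = "unknown") {
  as_sv_tbl(tibble::tibble(
    id = id, chrom = chrom, start = start,
    end = if (svtype == "DEL") start + svlen else start,
    svtype = svtype, svlen = svlen, alt_seq = alt_seq, ref_seq = ref_seq,
    support = support, genotype = genotype
  ))
}

# random SV table over a compact coordinate space (dense enough that clusters
# form), used for the brute-force equivalence checks
random_svs <- function(n, chroms = c("chr1", "chr2"), span = 2e5,
                       labels = c("CCS", "CLR", "ONT", "ASM", "BN")) {
  svtype <- sample(c("DEL", "INS"), n, replace = TRUE)
  svlen <- round(stats::runif(n, 50, 2000))
  start <- floor(stats::runif(n, 0, span))
  as_sv_tbl(tibble::tibble(
    id = sprintf("r%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = ifelse(svtype == "DEL", start + svlen, start),
    svtype = svtype, svlen = svlen,
    alt_seq = "", ref_seq = "",
    support = sample(labels, n, replace = TRUE),
    genotype = "unknown"
  ))
}

# O(n^2) clustering oracle: same greedy seeded-sweep rules as cluster_merge,
# but scanning every cluster without any windowing or retirement
oracle_cluster <- function(svs, params) {
  svs <- sort_sv_tbl(svs)
  n <- nrow(svs)
  cluster <- integer(n)
  seeds <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    if (length(seeds) > 0) {
      ok <- match_pair(svs[i, ], svs[seeds, , drop = FALSE], params)
      if (any(ok)) hit <- which(ok)[1]
    }
    if (hit == 0L) {
      seeds <- c(seeds, i)
      cluster[i] <- length(seeds)
    } else {
      cluster[i] <- hit
    }
  }
  cluster
}

# O(n*m) classification oracle: all matching pairs, greedy one-to-one by
# distance with ties to the longer test SV
oracle_classify <- function(test, bench_svs, regions, params) {
  inside <- rep(FALSE, nrow(test))
  for (i in seq_len(nrow(test))) {
    e <- max(test$end[i], test$start[i] + 1)
    inside[i] <- any(regions$chrom == test$chrom[i] &
                       regions$start <= test$start[i] & regions$end >= e)
  }
  test <- sort_sv_tbl(test[inside, , drop = FALSE])
  pairs <- NULL
  for (i in seq_len(nrow(bench_svs))) {
    ok <- if (nrow(test)) match_pair(bench_svs[i, ], test, params) else logical()
    if (any(ok)) {
      pairs <- rbind(pairs, data.frame(
        b = i, t = which(ok),
        d = abs(bench_svs$start[i] - test$start[ok]),
        tl = test$svlen[ok]))
    }
  }
  used_b <- logical(nrow(bench_svs)); used_t <- logical(nrow(test))
  tp <- 0
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$d, -pairs$tl), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      if (!used_b[pairs$b[r]] && !used_t[pairs$t[r]]) {
        used_b[pairs$b[r]] <- TRUE; used_t[pairs$t[r]] <- TRUE
        tp <- tp + 1
      }
    }
  }
  list(tp = tp, fp = sum(!used_t), fn = sum(!used_b))
}

# plain dynamic-programming Levenshtein distance
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  d <- matrix(0, length(a) + 1, length(b) + 1)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[length(a) + 1, length(b) + 1]
}

# enumerate canonical k-mers of a set of sequences by brute force
oracle_canonical_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    if (nchar(s) < k) next
    kmers <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    out <- c(out, pmin(kmers, revcomp(kmers)))
  }
  unique(out)
}

# the two-criterion multi-k vote, written straight from its definition
oracle_vote <- function(labels, min_agreeing = 2, basis = "decided_ks") {
  c_pat <- sum(labels == "paternal")
  c_mat <- sum(labels == "maternal")
  denom <- if (basis == "decided_ks") c_pat + c_mat else length(labels)
  for (side in c("paternal", "maternal")) {
    cx <- if (side == "paternal") c_pat else c_mat
    co <- if (side == "paternal") c_mat else c_pat
    if (cx >= min_agreeing && cx > denom / 2 && cx > co) return(side)
  }
  "unassigned"
}

# memoised mid-size trio pipeline fixture shared across test files
.fixture_cache <- new.env(parent = emptyenv())

small_trio_fixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  ref <- simulate_reference(length = 5e5, element_density = 60, seed = 101)
  trio <- simulate_trio(ref, sv_count = 80, seed = 102)
  sim <- simulate_platform_callsets(trio, seed = 103)
  asm <- simulate_hap_assembly(trio, seed = 104)
  .fixture_cache$small <- list(ref = ref, trio = trio, sim = sim, asm = asm)
  .fixture_cache$small
}

# the full-scale seeded trio fixture: 2 Mb reference, 300 planted SVs
big_trio_fixture <- function() {
  if (!is.null(.fixture_cache$big)) return(.fixture_cache$big)
  ref <- simulate_reference(length = 2e6, element_density = 50, seed = 201)
  trio <- simulate_trio(ref, sv_count = 300, seed = 202)
  sim <- simulate_platform_callsets(trio, seed = 203)
  asm <- simulate_hap_assembly(trio, seed = 204)
  .fixture_cache$big <- list(ref = ref, trio = trio, sim = sim, asm = asm)
  .fixture_cache$big
}

# two benchmark sets with a planted sharing structure, built directly from
# target counts: n_shared in-overlap shared pairs, per-side in-overlap
# uniques, per-side out-of-overlap SVs, and n_boundary cross-boundary pairs
# (an in-overlap SV of side A matching a side-B SV just outside the overlap)
two_benchmark_fixture <- function(n_shared, n_unique_a, n_unique_b,
                                  n_a_out, n_b_out, n_boundary = 0) {
  # Gb-scale region sets laid out over 100 Mb chromosomes (per-chromosome
  # coordinates stay well under 2^31):
  #   side A: c01-c14 full + c15 [0, 60 Mb)            -> 1.46 Gb
  #   side B: c02-c14 full + c15 [30, 100 Mb) + c16-c26 full + c27 [0, 40 Mb)
  #                                                     -> 2.51 Gb
  #   overlap: c02-c14 + c15 [30, 60 Mb)               -> 1.33 Gb
  Mb <- 1e6
  chrom_full <- function(ids) tibble::tibble(
    chrom = sprintf("c%02d", ids), start = 0, end = 100 * Mb)
  region_a <- dplyr::bind_rows(
    chrom_full(1:14),
    tibble::tibble(chrom = "c15", start = 0, end = 60 * Mb))
  region_b <- dplyr::bind_rows(
    chrom_full(2:14),
    tibble::tibble(chrom = "c15", start = 30 * Mb, end = 100 * Mb),
    chrom_full(16:26),
    tibble::tibble(chrom = "c27", start = 0, end = 40 * Mb))

  grid <- 1e4
  mk <- function(prefix, chrom, starts, svtype = "DEL") {
    n <- length(starts)
    as_sv_tbl(tibble::tibble(
      id = sprintf("%s_%s_%06d", prefix, chrom[1], seq_len(n)), chrom = chrom,
      start = starts, end = if (svtype == "DEL") starts + 100 else starts,
      svtype = svtype, svlen = 100))
  }
  # all in-overlap comparison SVs live on c02; out-of-overlap SVs on c01 (A)
  # and c16 (B); boundary pairs sit at the c15 overlap edge (60 Mb)
  shared_pos <- grid * seq_len(n_shared)
  ua_pos <- grid * n_shared + 3000 + grid * seq_len(max(0, n_unique_a - n_boundary))
  ub_pos <- grid * (n_shared + n_unique_a) + 6000 + grid * seq_len(n_unique_b)
  a_out_pos <- grid * seq_len(n_a_out)
  b_out_pos <- grid * seq_len(n_b_out - n_boundary)
  # boundary pairs, as insertions (no span, so reciprocal overlap does not
  # apply): the A mate just inside the overlap end, the B mate just outside,
  # every A mate within 1 kb of at least one B mate
  bd_a <- 60 * Mb - 100 - 50 * seq_len(n_boundary)
  bd_b <- 60 * Mb + 10 + 50 * seq_len(n_boundary)

  a_svs <- dplyr::bind_rows(
    mk("a", rep("c02", length(shared_pos)), shared_pos),
    mk("au", rep("c02", length(ua_pos)), ua_pos),
    mk("ao", rep("c01", length(a_out_pos)), a_out_pos),
    mk("ab", rep("c15", length(bd_a)), bd_a, svtype = "INS"))
  b_svs <- dplyr::bind_rows(
    mk("b", rep("c02", length(shared_pos)), shared_pos),
    mk("bu", rep("c02", length(ub_pos)), ub_pos),
    mk("bo", rep("c16", length(b_out_pos)), b_out_pos),
    mk("bb", rep("c15", length(bd_b)), bd_b, svtype = "INS"))
  bench <- function(svs, region) {
    svs$hap_support <- "paternal"
    build_chcrs(svs, region, region, flank = 0, min_region = 1)
  }
  list(a = bench(sort_sv_tbl(a_svs), region_a), b = bench(sort_sv_tbl(b_svs), region_b))
}

# trio-binning on the full-scale fixture (indices, reads, partition),
# memoised because it is by far the most expensive artefact
big_binning_fixture <- function() {
  if (!is.null(.fixture_cache$binning)) return(.fixture_cache$binning)
  fx <- big_trio_fixture()
  pol <- voting_policy()
  pat_seqs <- unlist(fx$trio$haplotypes[c("father_h1", "father_h2")])
  mat_seqs <- unlist(fx$trio$haplotypes[c("mother_h1", "mother_h2")])
  indices <- lapply(pol$k_values, function(k)
    build_kmer_index(pat_seqs, mat_seqs, k))
  indices_swapped <- lapply(pol$k_values, function(k)
    build_kmer_index(mat_seqs, pat_seqs, k))
  reads_tbl <- simulate_reads(fx$trio$haplotypes[c("child_pat", "child_mat")],
                              depth = 60, sub_error_rate = 0.01, seed = 205)
  reads <- stats::setNames(reads_tbl$seq, reads_tbl$read_id)
  part <- partition_reads(reads, indices, pol)
  .fixture_cache$binning <- list(
    policy = pol, indices = indices, indices_swapped = indices_swapped,
    reads_tbl = reads_tbl, reads = reads, part = part)
  .fixture_cache$binning
}
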