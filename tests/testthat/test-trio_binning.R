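test_that("parent-unique k-mer sets match brute-force enumeration", {
  # identical parents -> no unique k-mers
  idx <- build_kmer_index("ACGTACGTACGT", "ACGTACGTACGT", 5)
  expect_equal(unname(kmer_index_sizes(idx)), c(0, 0))

  idx <- build_kmer_index("AAAAA", "AAATA", 4)
  pat_oracle <- setdiff(oracle_canonical_kmers("AAAAA", 4),
                        oracle_canonical_kmers("AAATA", 4))
  mat_oracle <- setdiff(oracle_canonical_kmers("AAATA", 4),
                        oracle_canonical_kmers("AAAAA", 4))
  sizes <- kmer_index_sizes(idx)
  expect_equal(unname(sizes), c(length(pat_oracle), length(mat_oracle)))
  expect_true(all(kmer_index_contains(idx, pat_oracle, "paternal")))
  expect_true(all(kmer_index_contains(idx, mat_oracle, "maternal")))

  # random parents with planted SNVs, several k values
  set.seed(41)
  pat <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  mat_chars <- strsplit(pat, "")[[1]]
  snv_pos <- c(500, 1500, 2500)  # well separated: no overlapping k-windows
  for (p in snv_pos) {
    mat_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), mat_chars[p]), 1)
  }
  mat <- paste(mat_chars, collapse = "")
  for (k in c(7, 21)) {
    idx <- build_kmer_index(pat, mat, k)
    pat_oracle <- setdiff(oracle_canonical_kmers(pat, k),
                          oracle_canonical_kmers(mat, k))
    mat_oracle <- setdiff(oracle_canonical_kmers(mat, k),
                          oracle_canonical_kmers(pat, k))
    expect_equal(unname(kmer_index_sizes(idx)),
                 c(length(pat_oracle), length(mat_oracle)))
    expect_true(all(kmer_index_contains(idx, pat_oracle, "paternal")))
    expect_false(any(kmer_index_contains(idx, mat_oracle, "paternal")))
    # at k = 21 chance clashes are negligible, so the unique set is close to
    # k k-mers per SNV per parent (boundary losses only)
    if (k == 21) {
      expect_lt(abs(length(pat_oracle) - k * length(snv_pos)) /
                  (k * length(snv_pos)), 0.15)
    }
  }
  expect_error(build_kmer_index("ACGT", "ACGTA", 10), "shortest")
})

test_that("single-k voting counts markers and breaks ties to undecided", {
  idx <- build_kmer_index("AAAAAACGTACGTCCCCC", "AAAAATTGCAATGCCCCC", 5)
  reads <- c(pat_read = "AAAAAACGTACGTCCCCC",
             mat_read = "AAAAATTGCAATGCCCCC",
             no_marker = "GGGGGGGGGGGGGGGGGG")
  v <- vote_single_k(reads, idx)
  expect_equal(v$label[v$read_id == "pat_read"], "paternal")
  expect_gt(v$n_pat[v$read_id == "pat_read"], 0)
  expect_equal(v$n_mat[v$read_id == "pat_read"], 0)
  expect_equal(v$label[v$read_id == "mat_read"], "maternal")
  expect_equal(v$label[v$read_id == "no_marker"], "undecided")
  expect_equal(v$n_pat[v$read_id == "no_marker"], 0)
})

test_that("multi-k vote agrees with the rule oracle over all 3^5 vectors", {
  labs <- c("paternal", "maternal", "undecided")
  grid <- expand.grid(rep(list(labs), 5), stringsAsFactors = FALSE)
  mat <- as.matrix(grid)
  for (basis in c("decided_ks", "all_ks")) {
    pol <- voting_policy(majority_basis = basis)
    got <- vote_across_k(mat, pol)
    want <- apply(mat, 1, oracle_vote, min_agreeing = 2, basis = basis)
    expect_equal(got, unname(want))
  }
  # the printed examples of the rule
  expect_equal(vote_across_k(c("paternal", "paternal", rep("undecided", 3))),
               "paternal")
  expect_equal(vote_across_k(c("paternal", "paternal", "maternal",
                               "maternal", "undecided")), "unassigned")
  expect_equal(vote_across_k(c("paternal", rep("undecided", 4))), "unassigned")
})

test_that("read partitioning is accurate and label-symmetric on a small trio", {
  fx <- small_trio_fixture()
  trio <- fx$trio
  pol <- voting_policy()
  pat_seqs <- unlist(trio$haplotypes[c("father_h1", "father_h2")])
  mat_seqs <- unlist(trio$haplotypes[c("mother_h1", "mother_h2")])
  indices <- lapply(pol$k_values, function(k)
    build_kmer_index(pat_seqs, mat_seqs, k))
  reads_tbl <- simulate_reads(trio$haplotypes[c("child_pat", "child_mat")],
                              depth = 12, sub_error_rate = 0.01, seed = 42)
  reads <- stats::setNames(reads_tbl$seq, reads_tbl$read_id)
  part <- partition_reads(reads, indices, pol)

  expect_equal(sort(c(names(part$paternal), names(part$maternal),
                      names(part$unassigned))), sort(names(reads)))
  truth_lab <- ifelse(reads_tbl$hap == "child_pat", "paternal", "maternal")
  final <- part$report$final
  mis <- mean(final != "unassigned" & final != truth_lab)
  expect_lte(mis, 0.01)

  # swapping the parents swaps the bins exactly
  indices_sw <- lapply(pol$k_values, function(k)
    build_kmer_index(mat_seqs, pat_seqs, k))
  part_sw <- partition_reads(reads, indices_sw, pol)
  expect_equal(names(part_sw$paternal), names(part$maternal))
  expect_equal(names(part_sw$maternal), names(part$paternal))
  expect_equal(names(part_sw$unassigned), names(part$unassigned))

  # reads wholly inside the shared segment are predominantly unassigned
  shared <- reads_in_shared_region(reads_tbl, trio)
  if (sum(shared) >= 5) {
    expect_gt(mean(final[shared] == "unassigned"), 0.5)
  }

  # assigned fraction never grows as min_agreeing tightens
  fracs <- vapply(1:4, function(m) {
    p <- partition_reads(reads, indices, voting_policy(min_agreeing = m))
    attr(p$report, "assigned_fraction")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))

  # empty input
  empty <- partition_reads(stats::setNames(character(), character()),
                           indices, pol)
  expect_equal(length(empty$paternal), 0)
})
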