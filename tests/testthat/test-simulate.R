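test_that("generators are deterministic under a fixed seed", {
  r1 <- simulate_reference(length = 4e5, seed = 5)
  r2 <- simulate_reference(length = 4e5, seed = 5)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$elements, r2$elements)

  t1 <- simulate_trio(r1, sv_count = 30, seed = 6)
  t2 <- simulate_trio(r2, sv_count = 30, seed = 6)
  expect_identical(t1$haplotypes, t2$haplotypes)
  expect_identical(t1$svs, t2$svs)

  reads1 <- simulate_reads(t1$haplotypes["child_pat"], depth = 2, seed = 7)
  reads2 <- simulate_reads(t2$haplotypes["child_pat"], depth = 2, seed = 7)
  expect_identical(reads1, reads2)
})

test_that("element planting follows the requested density", {
  r0 <- simulate_reference(length = 1e5, element_density = 0, seed = 8)
  expect_equal(nrow(r0$elements), 0)

  r <- simulate_reference(length = 2e6, element_density = 50, seed = 9)
  lambda <- 50 * 2
  expect_gt(nrow(r$elements), lambda - 4 * sqrt(lambda))
  expect_lt(nrow(r$elements), lambda + 4 * sqrt(lambda))
  # planted copies resemble their library consensus
  alu <- r$elements[r$elements$family == "alu", ][1, ]
  copy <- substring(r$sequence, alu$start + 1, alu$end)
  expect_lt(sequence_divergence(copy, r$libraries$alu), 0.15)
})

test_that("SV sizes show the 300 bp and 6 kb element modes", {
  sizes <- sample_sv_sizes(5000, seed = 10)
  expect_true(all(sizes$size >= 50))
  modes <- sv_size_modes(sizes$size)
  expect_lt(abs(modes["small"] - 300) / 300, 0.10)
  expect_lt(abs(modes["large"] - 6000) / 6000, 0.10)
})

test_that("truth tables reconstruct the emitted haplotypes exactly", {
  ref <- simulate_reference(length = 4e5, seed = 11)
  trio <- simulate_trio(ref, sv_count = 40, seed = 12)
  for (h in c("father_h1", "mother_h2")) {
    rebuilt <- apply_variants(ref$sequence, trio$snvs[[h]],
                              trio$svs[trio$svs$haplotype == h, ])
    expect_identical(rebuilt, trio$haplotypes[[h]])
  }
  # sv_count = 0: haplotypes differ from the reference only by SNVs
  bare <- simulate_trio(ref, sv_count = 0, seed = 13)
  expect_equal(nchar(bare$haplotypes$father_h1), nchar(ref$sequence))
  expect_identical(bare$haplotypes$father_h1,
                   apply_variants(ref$sequence, bare$snvs$father_h1, NULL))
})

test_that("platform detection, jitter and length errors follow the profiles", {
  ref <- simulate_reference(length = 2e6, element_density = 30, seed = 14)
  trio <- simulate_trio(ref, sv_count = 260, spectrum = sv_spectrum(
    weights = c(background = 0.8, alu = 0.15, line = 0.05)), seed = 15)
  n_child <- sum(trio$svs$in_child)

  prof <- list(
    X = platform_profile("X", function(s) rep(0.8, length(s)),
                         function(s) rep(0.8, length(s)),
                         breakpoint_jitter_sd = 0, len_error_sd = 0,
                         fp_rate = 0),
    BNlike = platform_profile("BNlike", function(s) rep(1, length(s)),
                              function(s) rep(1, length(s)),
                              breakpoint_jitter_sd = 500, len_error_sd = 0,
                              fp_rate = 0, emits_sequence = FALSE)
  )
  sim <- simulate_platform_callsets(trio, prof, seed = 16)
  # binomial check on sensitivity 0.8
  frac <- mean(sim$bookkeeping$detected_X)
  se <- sqrt(0.8 * 0.2 / n_child)
  expect_lt(abs(frac - 0.8), 3 * se)
  # half-normal mean |offset| = sd * sqrt(2/pi), pooled to n ~ 1000 calls
  offs <- unlist(lapply(16:23, function(s) {
    calls <- simulate_platform_callsets(trio, prof, seed = s)$callsets$BNlike
    truth_start <- trio$svs$start[match(sub("^BNlike_", "", calls$id),
                                        trio$svs$id)]
    abs(calls$start - truth_start)
  }))
  expect_gte(length(offs), 1000)
  expect_lt(abs(mean(offs) - 500 * sqrt(2 / pi)) / (500 * sqrt(2 / pi)), 0.10)

  # perfect profiles reproduce the truth exactly
  perfect <- list(P = platform_profile("P", function(s) rep(1, length(s)),
                                       function(s) rep(1, length(s)),
                                       breakpoint_jitter_sd = 0,
                                       len_error_sd = 0, fp_rate = 0,
                                       seq_error_rate = 0))
  simp <- simulate_platform_callsets(trio, perfect, seed = 17)
  truth <- child_truth_svs(trio)
  expect_equal(simp$callsets$P$start, truth$start)
  expect_equal(simp$callsets$P$svlen, truth$svlen)
  expect_equal(simp$callsets$P$alt_seq, truth$alt_seq)
})

test_that("read simulation hits the requested depth and error rate", {
  ref <- simulate_reference(length = 2e5, seed = 18)
  trio <- simulate_trio(ref, sv_count = 20, seed = 19)
  haps <- trio$haplotypes[c("child_pat", "child_mat")]
  reads <- simulate_reads(haps, depth = 30, sub_error_rate = 0, seed = 20)
  G <- mean(nchar(unlist(haps)))
  expect_lt(abs(sum(reads$length) - 30 * G) / (30 * G), 0.05)
  # with zero error rate, reads are exact substrings of their haplotype
  i <- which.max(reads$length)
  expect_identical(reads$seq[i],
                   substring(haps[[reads$hap[i]]], reads$start[i] + 1,
                             reads$start[i] + reads$length[i]))

  noisy <- simulate_reads(haps, depth = 5, sub_error_rate = 0.01, seed = 21)
  mm <- 0; tot <- 0
  for (i in seq_len(nrow(noisy))) {
    orig <- substring(haps[[noisy$hap[i]]], noisy$start[i] + 1,
                      noisy$start[i] + noisy$length[i])
    a <- strsplit(noisy$seq[i], "")[[1]]
    b <- strsplit(orig, "")[[1]]
    mm <- mm + sum(a != b)
    tot <- tot + length(a)
  }
  se <- sqrt(0.01 * 0.99 / tot)
  expect_lt(abs(mm / tot - 0.01), 3 * se)
})
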