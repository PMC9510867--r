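test_that("haplotype support annotation reflects assembly matches", {
  hc <- dplyr::bind_rows(
    make_sv(start = 1000, svlen = 300, id = "a"),
    make_sv(start = 10000, svlen = 300, id = "b"),
    make_sv(start = 20000, svlen = 300, id = "c")
  )
  pat <- make_sv(start = 1005, svlen = 300, id = "p1")
  mat <- dplyr::bind_rows(make_sv(start = 1010, svlen = 295, id = "m1"),
                          make_sv(start = 10002, svlen = 300, id = "m2"))
  ann <- annotate_hap_support(hc, pat, mat)
  expect_equal(ann$hap_support[ann$id == "a"], "maternal,paternal")
  expect_equal(ann$hap_support[ann$id == "b"], "maternal")
  expect_equal(ann$hap_support[ann$id == "c"], "")
})

test_that("an unsupported SV splits coverage into two flanked CHCRs", {
  cov <- as_region_tbl(tibble::tibble(chrom = "chr1", start = 0, end = 100000))
  svs <- dplyr::bind_rows(
    make_sv(start = 20000, svtype = "INS", svlen = 300, id = "good"),
    make_sv(start = 50000, svtype = "INS", svlen = 300, id = "bad"),
    make_sv(start = 50500, svtype = "INS", svlen = 300, id = "victim")
  )
  svs$hap_support <- c("paternal", "", "paternal")
  bs <- build_chcrs(svs, cov, cov, flank = 1000, min_region = 10000)
  expect_equal(bs$chcrs$start, c(0, 51000))
  expect_equal(bs$chcrs$end, c(49000, 100000))
  # the supported SV inside the excised window is not a benchmark SV
  expect_setequal(bs$svs$id, "good")
  expect_true(all(bs$chcrs$hap == "maternal,paternal"))
})

test_that("benchmark soundness: no CHCR contains an unsupported call, and
           every benchmark SV lies in exactly one CHCR", {
  fx <- small_trio_fixture()
  hc <- build_high_confidence(fx$sim$callsets, excl = fx$trio$exclusion)
  ann <- annotate_hap_support(hc$highconf, fx$asm$pat_calls, fx$asm$mat_calls)
  bs <- build_chcrs(ann, fx$asm$pat_cov, fx$asm$mat_cov)

  expect_true(all(bs$svs$hap_support != ""))
  unsupported <- ann[ann$hap_support == "", ]
  for (i in seq_len(nrow(unsupported))) {
    inside <- bs$chcrs$chrom == unsupported$chrom[i] &
      bs$chcrs$start <= unsupported$start[i] &
      bs$chcrs$end > unsupported$start[i]
    expect_false(any(inside))
  }
  counts <- vapply(seq_len(nrow(bs$svs)), function(i) {
    sum(bs$chcrs$chrom == bs$svs$chrom[i] &
          bs$chcrs$start <= bs$svs$start[i] &
          bs$chcrs$end >= pmax(bs$svs$end[i], bs$svs$start[i] + 1))
  }, numeric(1))
  expect_true(all(counts == 1))

  cov_bp <- regions_total_bp(regions_union(fx$asm$pat_cov, fx$asm$mat_cov))
  expect_lte(sum(bs$chcrs$end - bs$chcrs$start), cov_bp)
})

test_that("haplotype support recovers the planted haplotype of origin", {
  fx <- small_trio_fixture()
  truth <- child_truth_svs(fx$trio)
  asm <- simulate_hap_assembly(fx$trio, sens = 1, jitter_sd = 0, seed = 51)
  ann <- annotate_hap_support(truth, asm$pat_calls, asm$mat_calls)
  origin <- fx$trio$svs$haplotype[match(ann$id, fx$trio$svs$id)]
  expected <- ifelse(origin == fx$trio$inherited[["father"]],
                     "paternal", "maternal")
  expect_gte(mean(ann$hap_support == expected), 0.99)
})

test_that("shrinking coverage never increases the benchmark SV count", {
  fx <- small_trio_fixture()
  hc <- build_high_confidence(fx$sim$callsets, excl = fx$trio$exclusion)
  ann <- annotate_hap_support(hc$highconf, fx$asm$pat_calls, fx$asm$mat_calls)
  full <- build_chcrs(ann, fx$asm$pat_cov, fx$asm$mat_cov)
  # drop the first coverage interval of each haplotype
  shrunk <- build_chcrs(ann, fx$asm$pat_cov[-1, ], fx$asm$mat_cov[-1, ])
  expect_lte(nrow(shrunk$svs), nrow(full$svs))
  # when every SV is supported, all in-coverage SVs are benchmark SVs
  all_supp <- ann
  all_supp$hap_support[all_supp$hap_support == ""] <- "paternal"
  bs_all <- build_chcrs(all_supp, fx$asm$pat_cov, fx$asm$mat_cov)
  in_cov <- !is.na(svbench:::region_containing(
    all_supp, regions_union(fx$asm$pat_cov, fx$asm$mat_cov)))
  expect_equal(nrow(bs_all$svs), sum(in_cov))
})

test_that("benchmark emit/read round-trips the set", {
  fx <- small_trio_fixture()
  hc <- build_high_confidence(fx$sim$callsets, excl = fx$trio$exclusion)
  ann <- annotate_hap_support(hc$highconf, fx$asm$pat_calls, fx$asm$mat_calls)
  bs <- build_chcrs(ann, fx$asm$pat_cov, fx$asm$mat_cov)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  bed <- withr::local_tempfile(fileext = ".bed")
  emit_benchmark(bs, vcf, bed)
  expect_equal(length(readLines(bed)), nrow(bs$chcrs))
  back <- read_benchmark(vcf, bed)
  cols <- c("id", "chrom", "start", "end", "svtype", "svlen", "hap_support",
            "chcr_id")
  expect_equal(as.data.frame(back$svs[cols]), as.data.frame(bs$svs[cols]),
               ignore_attr = TRUE)
  expect_equal(back$chcrs$start, bs$chcrs$start)
  expect_equal(back$chcrs$hap, bs$chcrs$hap)
  expect_equal(glance(back), glance(bs))

  # empty benchmark
  empty_bs <- build_chcrs(make_sv(start = 5e5)[0, ],
                          fx$asm$pat_cov[0, ], fx$asm$mat_cov[0, ])
  emit_benchmark(empty_bs, vcf, bed)
  back <- read_benchmark(vcf, bed)
  expect_equal(nrow(back$svs), 0)
  expect_equal(nrow(back$chcrs), 0)
})
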