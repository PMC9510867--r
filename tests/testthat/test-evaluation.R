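simple_bench <- function(svs, chrom = "chr1", span = 2e5) {
  svs$hap_support <- "paternal"
  cov <- as_region_tbl(tibble::tibble(chrom = chrom, start = 0, end = span))
  build_chcrs(svs, cov, cov, flank = 1000, min_region = 1000)
}

test_that("precision/recall/F1 arithmetic", {
  r <- compute_prf(8, 2, 2)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 0.8)
  expect_equal(r$f1, 0.8)
  z <- compute_prf(0, 0, 10)
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  r2 <- compute_prf(90, 10, 30)
  expect_equal(r2$precision, 0.9)
  expect_equal(r2$recall, 0.75)
  expect_equal(r2$f1, 0.8181818, tolerance = 1e-6)
})

test_that("classification of exact and empty test callsets", {
  set.seed(61)
  svs <- random_svs(40, chroms = "chr1")
  svs <- svs[!duplicated(floor(svs$start / 3000)), ]  # well separated
  bench <- simple_bench(svs)
  ev <- classify_calls(bench$svs, bench)
  expect_equal(nrow(ev$tp_pairs), nrow(bench$svs))
  expect_equal(nrow(ev$fp_records), 0)
  expect_equal(nrow(ev$fn_records), 0)

  ev0 <- classify_calls(empty_sv_tbl(), bench)
  expect_equal(nrow(ev0$tp_pairs), 0)
  expect_equal(nrow(ev0$fn_records), nrow(bench$svs))

  # out-of-region calls are ignored
  outside <- make_sv(chrom = "chr9", start = 1000, id = "far")
  ev1 <- classify_calls(dplyr::bind_rows(bench$svs, outside), bench)
  expect_equal(ev1$n_outside, 1)
  expect_equal(nrow(ev1$fp_records), 0)
})

test_that("classification matches the O(n*m) brute-force matcher", {
  p <- preset_truvari()
  set.seed(62)
  for (rep in 1:6) {
    truth <- random_svs(sample(50:150, 1))
    test <- random_svs(sample(50:150, 1))
    truth$hap_support <- "paternal"
    cov <- as_region_tbl(tibble::tibble(chrom = c("chr1", "chr2"),
                                        start = 0, end = 2.1e5))
    bench <- build_chcrs(truth, cov, cov, flank = 0, min_region = 1)
    got <- classify_calls(test, bench, p)
    want <- oracle_classify(test, bench$svs,
                            bench$chcrs[, c("chrom", "start", "end")], p)
    expect_equal(nrow(got$tp_pairs), want$tp)
    expect_equal(nrow(got$fp_records), want$fp)
    expect_equal(nrow(got$fn_records), want$fn)
    # conservation: tp + fn covers the whole benchmark
    expect_equal(nrow(got$tp_pairs) + nrow(got$fn_records), nrow(bench$svs))
  }
})

test_that("planted dropout and spurious rates are recovered", {
  set.seed(63)
  n <- 1000
  start <- sort(sample(seq(5000, 4e6, by = 3500), n))
  svs <- as_sv_tbl(tibble::tibble(
    id = sprintf("b%04d", 1:n), chrom = "chr1", start = start,
    end = start + 300, svtype = "DEL", svlen = 300))
  bench <- simple_bench(svs, span = 4.1e6)
  keep <- runif(n) > 0.10                      # 10% dropout
  test <- bench$svs[keep, ]
  n_fp <- round(sum(keep) * 0.05 / 0.95)       # 5% of test calls spurious
  fp_start <- seq(5000 + 1700, by = 3500, length.out = n_fp)
  fps <- as_sv_tbl(tibble::tibble(
    id = sprintf("fp%04d", 1:n_fp), chrom = "chr1", start = fp_start,
    end = fp_start + 100, svtype = "DEL", svlen = 100))
  ev <- glance(evaluate_callset(dplyr::bind_rows(test, fps), bench))
  expect_equal(ev$recall, 0.90, tolerance = 0.03)
  expect_equal(ev$precision, 0.95, tolerance = 0.03)
})

test_that("replicate consensus keeps well-supported, large-enough calls", {
  r1 <- dplyr::bind_rows(
    make_sv(start = 1000, svlen = 300, id = "a1"),
    make_sv(start = 9000, svlen = 40, id = "b1"),
    make_sv(start = 20000, svlen = 25, id = "c1"),
    make_sv(start = 30000, svlen = 500, id = "d1"))
  shift <- function(cs, by, tag) {
    cs$start <- cs$start + by
    cs$end <- cs$end + by
    cs$id <- sub("1$", tag, cs$id)
    cs
  }
  r2 <- shift(r1[-4, ], 50, "2")
  r3 <- shift(r1[-4, ], -30, "3")
  out <- merge_replicates(list(r1, r2, r3))
  expect_setequal(sub("[0-9]$", "", out$id), c("a", "b"))   # c too small, d 1/3
  expect_true(all(out$n_replicates == 3))

  # monotone non-increasing in min_support
  sizes <- vapply(1:3, function(m)
    nrow(merge_replicates(list(r1, r2, r3), min_support = m)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("depth curves are flat for identical callsets and F1-monotone under
           the saturating sensitivity model", {
  fx <- small_trio_fixture()
  hc <- build_high_confidence(fx$sim$callsets, excl = fx$trio$exclusion)
  ann <- annotate_hap_support(hc$highconf, fx$asm$pat_calls, fx$asm$mat_calls)
  bench <- build_chcrs(ann, fx$asm$pat_cov, fx$asm$mat_cov)

  flat <- depth_curve(list(`5` = fx$sim$callsets$CCS, `10` = fx$sim$callsets$CCS,
                           `20` = fx$sim$callsets$CCS), bench)
  expect_equal(length(unique(flat$f1)), 1)

  # sensitivity s(d) = 1 - exp(-d/d0): deeper callsets are supersets
  set.seed(64)
  truth <- bench$svs
  depths <- c(0, 3, 6, 11, 20)
  u <- runif(nrow(truth))
  by_depth <- lapply(depths, function(d) {
    truth[u < 1 - exp(-d / 5), , drop = FALSE]
  })
  names(by_depth) <- depths
  curve <- depth_curve(by_depth, bench)
  expect_equal(curve$f1[curve$depth == 0], 0)
  expect_true(all(diff(curve$f1) >= -1e-9))
  expect_s3_class(autoplot(curve), "ggplot")
})

test_that("benchmark comparison of a set with itself and with disjoint sets", {
  set.seed(65)
  svs <- random_svs(60, chroms = "chr1")
  svs <- svs[!duplicated(floor(svs$start / 3000)), ]
  bench <- simple_bench(svs)
  cmp <- compare_benchmarks(bench, bench)
  expect_equal(cmp$shared_total, nrow(bench$svs))
  expect_equal(cmp$in_overlap$unique_a, 0)
  expect_equal(cmp$in_overlap$unique_b, 0)
  expect_equal(cmp$in_overlap$shared_frac_a, 1)

  far <- svs
  far$chrom <- "chr9"
  bench_far <- simple_bench(far, chrom = "chr9")
  cmp2 <- compare_benchmarks(bench, bench_far)
  expect_equal(cmp2$overlap_bp, 0)
  expect_equal(cmp2$in_overlap$shared, 0)
})
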