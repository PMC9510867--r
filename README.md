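# svbench

Construction and use of haplotype-resolved structural-variant (SV)
benchmarks, as a tidyverse-style R package.

## What problem this solves

Different sequencing platforms (PacBio CCS and CLR, ONT, optical mapping)
and calling strategies (alignment- and assembly-based) disagree
substantially on large insertions and deletions. A usable gold standard
for a well-characterised sample therefore has two parts: **continuous
high-confidence regions (CHCRs)** in which the truth set claims to be
complete, and the **benchmark SV callset** inside them. Test callsets are
then scored only within the regions: matched benchmark SVs are TP,
unmatched benchmark SVs FN, unmatched in-region test calls FP, and

```
precision = TP/(TP+FP),  recall = TP/(TP+FN),  F1 = 2PR/(P+R).
```

svbench implements the full construction recipe for people building or
stress-testing such benchmarks:

* **SV model and I/O** — calls as plain tibbles (0-based half-open
  coordinates); VCF 4.2 and BED readers/writers; region algebra on
  GenomicRanges.
* **Matching and merging** — pairwise match predicates (breakpoint
  distance ≤ d, size ratio ≥ l, reciprocal overlap ≥ r for deletions,
  edit-distance divergence for sequence-resolved insertions; AND of all
  enabled criteria) and a deterministic greedy cluster merge across
  platforms with union-of-support bookkeeping.
* **Integration** — exclusion-region filtering plus two retention tiers:
  keep a call detected by CCS and corroborated by CLR or ONT, or longer
  than 1.5 kb and supported by both CCS assembly and optical mapping.
* **Trio-binning** — partition child long reads by parent-unique canonical
  k-mers at k = 21, 41, 51, 61, 81 with a two-criterion vote (≥ 2 k values
  agreeing, and a strict majority of decided k values). Rolling-hash k-mer
  machinery in C++ keeps 81-mers cheap.
* **CHCRs and benchmark** — anchor high-confidence calls on the two
  haplotype assemblies, excise ±1 kb windows around unsupported calls from
  the assembly-coverage tracks, and emit the benchmark as truth VCF +
  regions BED.
* **Evaluation** — Truvari-style one-to-one classification in regions,
  F1-vs-depth curves, SURVIVOR-style replicate consensus, benchmark-vs-
  benchmark comparison, and Sanger concordance scoring (type/length/
  breakpoint within 10 bp, long insertions uncertain).
* **Synthetic data** — seeded generators for a repeat-bearing reference
  (300 bp Alu-like and 6 kb LINE-like element families), a diploid trio
  with planted SVs/SNVs, per-platform corrupted callsets, and error-bearing
  long reads; every stage of the package is tested against this planted
  truth.

## A worked example

```r
library(svbench)

ref  <- simulate_reference(length = 5e5, element_density = 60, seed = 101)
trio <- simulate_trio(ref, sv_count = 80, seed = 102)
sim  <- simulate_platform_callsets(trio, seed = 103)   # CCS/CLR/ONT/ASM/BN
asm  <- simulate_hap_assembly(trio, seed = 104)

hc <- build_high_confidence(sim$callsets, excl = trio$exclusion)
hc$audit
#> # A tibble: 3 × 4
#>   stage             n_in n_kept n_removed
#>   <chr>            <int>  <int>     <int>
#> 1 merge              149     49       100
#> 2 exclusion_filter    49     45         4
#> 3 retention           45     31        14

ann   <- annotate_hap_support(hc$highconf, asm$pat_calls, asm$mat_calls)
bench <- build_chcrs(ann, asm$pat_cov, asm$mat_cov)
bench
#> <benchmark_set> 2 CHCRs spanning 498,000 bp | 30 benchmark SVs

glance(evaluate_callset(sim$callsets$CCS, bench))
#> # A tibble: 1 × 6
#>      tp    fp    fn precision recall    f1
#>   <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1    30     9     0     0.769      1 0.870
```

Reading the audit: 149 raw platform calls collapse to 49 merged events, 4
fall in exclusion regions, and 31 survive the cross-platform retention
tiers. Of those, 30 are reproduced by at least one haplotype assembly and
lie in a surviving CHCR — the benchmark. The CCS callset alone then scores
F1 = 0.870 against it: it finds every benchmark SV but also makes 9
in-region calls that match nothing (its excess calls were exactly what the
retention tiers filtered).

`autoplot()` methods exist for evaluations and depth curves, and
`tidy()`/`glance()` for every result object; `plot_size_spectrum()` shows
the 300 bp / 6 kb insertion-deletion size peaks of a callset.

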