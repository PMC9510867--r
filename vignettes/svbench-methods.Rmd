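---
title: "Building and using a haplotype-resolved SV benchmark with svbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and using a haplotype-resolved SV benchmark with svbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svbench)
library(dplyr)
```

## The problem

Structural variants (SVs) — here restricted to insertions and deletions of
at least 50 bp — are called with very different sensitivity and specificity
by different sequencing platforms and callers. A *benchmark* for a
well-characterised sample consists of two coupled artefacts: a set of
**continuous high-confidence regions** (CHCRs) within which the benchmark
claims to enumerate *all* true SVs, and the **benchmark callset** of those
SVs. Any test callset can then be scored inside the regions: matched
benchmark SVs are true positives, unmatched benchmark SVs false negatives,
and unmatched in-region test calls false positives; calls outside the
regions are ignored because the benchmark makes no claim there.

svbench implements the full construction recipe as composable,
tibble-in/tibble-out functions:

1. **Merge** per-platform callsets into one non-redundant set
   (`cluster_merge()`).
2. **Filter** calls in repeat-dominated exclusion regions
   (`filter_excluded_regions()`).
3. **Retain** only cross-platform-corroborated calls
   (`apply_retention_rules()`); steps 1–3 are wrapped by
   `build_high_confidence()`.
4. **Trio-bin** child long reads by parent-unique k-mers
   (`build_kmer_index()`, `partition_reads()`), the input to haplotype
   assembly (assembly itself is out of scope; its SV calls and coverage are
   consumed as VCF/BED).
5. **Anchor** the high-confidence calls on the haplotype assemblies and draw
   CHCRs (`annotate_hap_support()`, `build_chcrs()`).
6. **Evaluate** any callset against the result (`evaluate_callset()`,
   `depth_curve()`, `compare_benchmarks()`), and score Sanger validation
   experiments (`classify_concordance()`, `aggregate_rates()`).

A seeded synthetic trio generator (`simulate_reference()`,
`simulate_trio()`, `simulate_platform_callsets()`, `simulate_reads()`)
provides ground truth for every stage and is itself part of the tested
surface.

## Match predicates and merging

Two calls are the same event when **all** enabled criteria hold
(`match_pair()`):

* same type (DEL vs INS);
* start positions within `max_dist` (default 1 kb for merging);
* size ratio `min(l_a, l_b) / max(l_a, l_b) >= min_size_ratio` (default 0.5);
* deletions: reciprocal overlap
  `min(o/l_a, o/l_b) >= min_recip_overlap` (default 0.5);
* insertions with both inserted alleles present: edit-distance divergence
  `d(a, b) / max(|a|, |b|) <= max_divergence` (default 0.2, computed with
  `utils::adist`). Insertions have no genomic span, so reciprocal overlap
  does not apply; when a platform reports no sequence (optical mapping),
  the size-ratio criterion alone stands in.

The criteria combine by AND — the strictest reading — and distance is
measured between start coordinates, with the reciprocal-overlap criterion
constraining deletion ends. `preset_svmerge()` (1000/0.5/0.5/0.2) is the
merge setting; `preset_truvari()` (500/0.7/–/0.3) is the evaluation
setting, and both are plain `match_params()` objects the user can override
per callset.

Merging (`cluster_merge()`) is a greedy seeded sweep in `(chrom, start)`
order: each record joins the first existing cluster whose *seed* record it
matches, otherwise it seeds a new cluster. Anchoring on the seed keeps the
procedure deterministic and prevents transitive chaining (a chain of calls
each 1 kb apart will not collapse into one event). The reported
representative is the member from the most trusted platform
(CCS > CLR > ONT > ASM > BN by default — circular-consensus alignment
first, optical mapping last because it lacks base resolution), with ties
broken by smaller start then longer length; its support becomes the union
of member platforms and its genotype the member majority (ties →
unknown). The test suite checks the windowed implementation against a
brute-force all-pairs implementation of the same rules.

## Retention tiers

After merging and exclusion filtering, a call is kept when it is at least
50 bp and either

* tier 1: detected by CCS alignment **and** corroborated by CLR or ONT
  alignment, or
* tier 2: longer than 1.5 kb (strict) **and** supported by both the CCS
  assembly and optical mapping.

The tiers are an inclusive OR. Retention is monotone in support — adding a
platform can only help — which the suite checks by exhaustive enumeration
of all 2^5 support patterns at a short and a long size. Manual image review
of the remaining calls is not an algorithm and is deliberately not
emulated; the per-stage audit table returned by `build_high_confidence()`
is the machine-readable replacement.

## Trio-binning

Parent-unique k-mers are computed at five k values (21, 41, 51, 61, 81 bp)
from the parental sequences; k-mers are strand-collapsed (canonical form).
Internally a k-mer is identified by a 64-bit rolling hash of the window and
of its reverse complement, finalised and collapsed by minimum — this makes
index construction and read scanning O(1) per base regardless of k, which
is what makes 81-mers practical. At the fixture scale (~10^7 distinct
k-mers) hash collisions are vanishingly unlikely; the tests compare index
contents against brute-force string enumeration on small inputs.

Per read and per k, markers found in each parent-unique set are counted;
the k's verdict is the parent with the strictly larger count (ties, and
zero markers, are undecided — the simplest defensible per-k rule). The
verdicts are integrated by two criteria: at least two k values must agree,
and the agreeing count must exceed half of the *decided* k values. With
denominator "all five k" the first criterion would be implied by the
second, so the decided-k reading is the default; both are available via
`voting_policy(majority_basis=)`. Reads failing the vote are unassigned
and would conventionally feed both haplotype assemblies. Swapping the
parents swaps the bins exactly, and tightening `min_agreeing` can only
shrink the assigned fraction; both are asserted in the tests.

## CHCR construction

Candidate regions are the haplotype-assembly coverage tracks (union of
paternal and maternal by default; intersection by option — the source
material does not say which, and union is the more generous, clearly
flagged default). Every high-confidence SV that *no* haplotype assembly
reproduces marks a discordance: a ±1 kb window (`flank`) around it is
excised, and surviving fragments shorter than `min_region` (default 10 kb)
are dropped. The boundary rule is this package's mechanisation of
"regions supported by both the high-confidence calls and the
haplotype-resolved calls"; both parameters are explicit arguments.
Benchmark SVs are the haplotype-supported calls wholly contained in a
surviving region. By construction no CHCR contains an unsupported
high-confidence call, total CHCR length never exceeds coverage, and
shrinking coverage never adds benchmark SVs — all property-tested.

## Evaluation

`classify_calls()` performs one-to-one matching between benchmark and
in-region test calls: candidate pairs under the match predicate are
accepted greedily by breakpoint distance (ties favour the longer test
call), so one test call cannot absorb several benchmark SVs.
`compute_prf()` defines precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and
F1 `2PR/(P+R)`, each 0 on an empty denominator. `depth_curve()` evaluates
one callset per sequencing depth; `merge_replicates()` builds a replicate
consensus (distance and type only, minimum support 2, minimum size 30 bp —
the classic "1000 2 1 1 0 30" consensus setting; the strand flag is parsed
but inert for strand-symmetric DEL/INS). `compare_benchmarks()` reports
shared and per-side unique SV counts overall and within the intersection
of the two region sets, with per-side shared fractions
`shared / (shared + unique_side)`.

## Sanger concordance

Validation experiments are consumed as a TSV of per-site observations
(amplified, sequenced, observed type/length/breakpoint, genic or
intergenic). Three dimensions are scored against the targeted call — type
equality, length within 10 bp, breakpoint within 10 bp — and a dimension is
*uncertain* when its observation is missing or when the call is an
insertion longer than 500 bp, which a single Sanger read cannot traverse.
Rates exclude uncertain sites from the denominator (which can only raise a
rate relative to counting them as mismatches — property-tested).
Chromatogram processing and read alignment are instrument-bound and out of
scope; heterozygous double-peak loci should arrive already marked
uncertain.

## The synthetic trio

The generator emulates what the pipeline needs from real data, nothing
more:

* **Reference** (`simulate_reference()`): random backbone (GC 0.41) with
  planted copies of two small element libraries — an Alu-like 300 bp family
  and a LINE-like 6 kb family, each copy ~5% diverged from its consensus —
  at 50 copies/Mb (80:20 Alu:LINE).
* **Size spectrum** (`sv_spectrum()`): 45% uniform 50–1000 bp background,
  40% N(300, 25) Alu-like, 15% N(6000, 300) LINE-like; deletions of the
  element components preferentially remove planted copies, element
  insertions insert mutated library copies, so the characteristic 300 bp
  and 6 kb peaks emerge in both types.
* **Trio** (`simulate_trio()`): 300 SVs distributed over the four parental
  haplotypes of a 2 Mb genome, SNVs at 10^-3 per base per haplotype
  (plentiful parent-unique k-mers at every k), the child inheriting one
  haplotype per parent without recombination. Breakpoints are kept >= 2 kb
  apart and one 5% segment of the genome carries no variants at all, so
  both parents are locally identical there — the case in which binning
  should stay undecided. A few random intervals (~5%) act as exclusion
  regions.
* **Platform callsets** (`simulate_platform_callsets()`): per-SV Bernoulli
  detection with size- and type-dependent sensitivity, Gaussian breakpoint
  jitter and length error, and Poisson spurious calls placed away from
  truth breakpoints so the planted support pattern of every truth SV is
  unambiguous. The default profiles encode the qualitative platform
  contrasts (CCS 0.90 / CLR 0.80 / ONT 0.70 deletion sensitivity; CCS and
  CLR insertion sensitivity collapsing at LINE scale; ONT weaker on
  insertions than deletions; optical mapping blind below 1 kb, sequence-free,
  with 500 bp breakpoint noise). These numbers are configuration, not claims.
* **Reads** (`simulate_reads()`): uniform sampling, N(10 kb, 2 kb) lengths,
  substitution-only errors (1% default) — the consumers are k-mer
  membership tests, so indel errors add nothing at default settings (an
  error-rate parameter covers stress tests).

What the generator does *not* emulate — recombination, platform-specific
homopolymer error structure, segmental-duplication-scale repeats, optical
raw signal — bounds what green tests mean: they demonstrate the
correctness of the algorithms under the stated model, not field
performance on a human genome.

## Problem sizes and numerics

The shipped tests run the pipeline end-to-end on a 2 Mb / 300-SV trio with
60x child reads (the package's standard fixture scale; roughly a
1/1500-scale genome) and exercise the merge and evaluation engines against
brute-force oracles on dozens of random 50–250-record fixtures. Every
generator is deterministic under its `seed` argument. Coordinates are
0-based half-open internally (BED convention), converted at the VCF
boundary; interval algebra runs on GenomicRanges, whose 32-bit coordinates
are respected by laying Gb-scale synthetic region sets across 100 Mb
chromosomes. Degenerate inputs (empty callsets, empty regions, zero-length
intervals, reads without markers) all have defined, tested behaviour.

## A worked example

```{r example, eval = FALSE}
ref <- simulate_reference(length = 5e5, element_density = 60, seed = 101)
trio <- simulate_trio(ref, sv_count = 80, seed = 102)
sim <- simulate_platform_callsets(trio, seed = 103)
asm <- simulate_hap_assembly(trio, seed = 104)

hc <- build_high_confidence(sim$callsets, excl = trio$exclusion)
hc$audit
ann <- annotate_hap_support(hc$highconf, asm$pat_calls, asm$mat_calls)
bench <- build_chcrs(ann, asm$pat_cov, asm$mat_cov)
bench
glance(evaluate_callset(sim$callsets$CCS, bench))
autoplot(depth_curve(list(`5` = sim$callsets$ONT,
                          `20` = sim$callsets$CCS), bench))
```

## Known limitations

* Only insertions and deletions are modelled; inversions, duplications and
  translocations are out of scope, as is breakend algebra.
* Genotypes are carried from input VCFs and majority-voted across
  platforms; nothing is inferred from reads.
* Haplotype assembly itself (and assembly alignment) is consumed, not
  performed.
* The CHCR boundary rule (flank excision) is one reasonable mechanisation
  of a construction the source material describes only at the level of
  intent; its parameters are exposed rather than hidden.
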