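#' SV size spectrum for the synthetic generator
#'
#' Mixture of a uniform background and two mobile-element-like components:
#' a SINE-Alu-like component near 300 bp and a LINE-like component near
#' 6 kb, matching the characteristic bimodal size spectrum of human
#' insertion/deletion polymorphism.
#'
#' @param type_mix Fraction of insertions (the rest are deletions).
#' @param weights Named weights of the `background`, `alu` and `line`
#'   components; must sum to 1.
#' @param bg_min,bg_max Uniform background size range in bp.
#' @param alu_mean,alu_sd,line_mean,line_sd Normal size parameters of the
#'   two element components in bp.
#' @return An object of class `sv_spectrum`.
#' @export
sv_spectrum <- function(type_mix = 0.5,
                        weights = c(background = 0.45, alu = 0.40, line = 0.15),
                        bg_min = 50, bg_max = 1000,
                        alu_mean = 300, alu_sd = 25,
                        line_mean = 6000, line_sd = 300) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, bg_min >= 50,
            all(c("background", "alu", "line") %in% names(weights)))
  structure(
    list(type_mix = type_mix, weights = weights, bg_min = bg_min,
         bg_max = bg_max, alu_mean = alu_mean, alu_sd = alu_sd,
         line_mean = line_mean, line_sd = line_sd),
    class = "sv_spectrum"
  )
}

#' Draw SV sizes (and component labels) from a spectrum
#'
#' @param n Number of sizes.
#' @param spectrum An [sv_spectrum()].
#' @param seed Optional RNG seed.
#' @return Tibble with columns `size` (bp, always >= 50) and `component`.
#' @export
sample_sv_sizes <- function(n, spectrum = sv_spectrum(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample(names(spectrum$weights), n, replace = TRUE,
                 prob = spectrum$weights)
  size <- numeric(n)
  bg <- comp == "background"
  size[bg] <- round(stats::runif(sum(bg), spectrum$bg_min, spectrum$bg_max))
  alu <- comp == "alu"
  size[alu] <- round(stats::rnorm(sum(alu), spectrum$alu_mean, spectrum$alu_sd))
  line <- comp == "line"
  size[line] <- round(stats::rnorm(sum(line), spectrum$line_mean, spectrum$line_sd))
  tibble::tibble(size = pmax(50, size), component = comp)
}

#' Locate the two modes of an SV size distribution
#'
#' Kernel-density modes in the sub-kilobase window (100-1000 bp) and the
#' kilobase window (1-8 kb), the ranges in which the SINE-Alu and LINE
#' peaks live.
#'
#' @param sizes Numeric vector of SV sizes in bp.
#' @return Named numeric vector `c(small = ..., large = ...)`.
#' @export
sv_size_modes <- function(sizes) {
  mode_in <- function(lo, hi) {
    x <- sizes[sizes >= lo & sizes <= hi]
    if (length(x) < 10) return(NA_real_)
    d <- stats::density(x, from = lo, to = hi)
    d$x[which.max(d$y)]
  }
  c(small = mode_in(100, 1000), large = mode_in(1000, 8000))
}

random_dna <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of nucleotide strings
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a repeat-bearing reference sequence
#'
#' A random backbone into which copies of two small element libraries are
#' planted: an Alu-like ~300 bp family and a LINE-like ~6 kb family. Each
#' copy is the family consensus with ~5% substitutions, so copies are
#' near-identical but not exact. Fully deterministic under `seed`.
#'
#' @param length Reference length in bp (>= 100 kb recommended).
#' @param gc GC fraction of the backbone.
#' @param element_density Expected planted elements per Mb (Poisson);
#'   80% Alu-like, 20% LINE-like.
#' @param seed RNG seed.
#' @return A list of class `sim_reference`: `sequence` (single string),
#'   `elements` (tibble `chrom`, `start`, `end`, `family`), `libraries`
#'   (named list of consensus sequences), `length`, `chrom`.
#' @export
simulate_reference <- function(length = 2e6, gc = 0.41,
                               element_density = 50, seed = 1) {
  set.seed(seed)
  chrom <- "chr1"
  seq <- random_dna(length, gc)
  libraries <- list(alu = random_dna(300, 0.5), line = random_dna(6000, 0.45))

  n_elem <- stats::rpois(1, element_density * length / 1e6)
  fam <- sample(c("alu", "line"), n_elem, replace = TRUE, prob = c(0.8, 0.2))
  elements <- tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric(), family = character())
  if (n_elem > 0) {
    # place element copies without overlap by replacing backbone segments
    placed <- tibble::tibble(start = numeric(), end = numeric())
    starts <- ends <- numeric(n_elem)
    keep <- logical(n_elem)
    for (i in seq_len(n_elem)) {
      len_i <- nchar(libraries[[fam[i]]])
      for (try in 1:50) {
        s <- floor(stats::runif(1, 1000, length - len_i - 1000))
        if (!any(s < placed$end + 100 & s + len_i > placed$start - 100)) {
          placed <- dplyr::bind_rows(placed, tibble::tibble(start = s, end = s + len_i))
          starts[i] <- s; ends[i] <- s + len_i; keep[i] <- TRUE
          break
        }
      }
    }
    fam <- fam[keep]; starts <- starts[keep]; ends <- ends[keep]
    chars <- strsplit(seq, "")[[1]]
    for (i in seq_along(starts)) {
      copy <- mutate_sequences_cpp(libraries[[fam[i]]], 0.05)
      chars[(starts[i] + 1):ends[i]] <- strsplit(copy, "")[[1]]
    }
    seq <- paste(chars, collapse = "")
    ord <- order(starts)
    elements <- tibble::tibble(chrom = chrom, start = starts[ord],
                               end = ends[ord], family = fam[ord])
  }
  structure(list(sequence = seq, elements = elements, libraries = libraries,
                 length = length, chrom = chrom),
            class = "sim_reference")
}

#' Apply SNVs and SVs to a reference sequence
#'
#' SNV positions are 0-based reference coordinates and are applied first
#' (they do not shift coordinates); SVs are then applied from the highest
#' coordinate down. An insertion at `start` is placed before the 0-based
#' position `start`; a deletion removes `[start, end)`.
#'
#' @param sequence Reference string.
#' @param snvs Tibble with `pos` (0-based) and `alt` (single base); may be
#'   `NULL`.
#' @param svs SV tibble (only `start`, `end`, `svtype`, `svlen`, `alt_seq`
#'   are used); may be `NULL`.
#' @return The haplotype string.
#' @export
apply_variants <- function(sequence, snvs = NULL, svs = NULL) {
  if (!is.null(snvs) && nrow(snvs) > 0) {
    chars <- strsplit(sequence, "")[[1]]
    chars[snvs$pos + 1] <- snvs$alt
    sequence <- paste(chars, collapse = "")
  }
  if (is.null(svs) || nrow(svs) == 0) return(sequence)
  svs <- svs[order(svs$start), , drop = FALSE]
  pieces <- character(0)
  cursor <- 0
  for (i in seq_len(nrow(svs))) {
    pieces <- c(pieces, substring(sequence, cursor + 1, svs$start[i]))
    if (svs$svtype[i] == "INS") {
      pieces <- c(pieces, svs$alt_seq[i])
      cursor <- svs$start[i]
    } else {
      cursor <- svs$end[i]
    }
  }
  pieces <- c(pieces, substring(sequence, cursor + 1, nchar(sequence)))
  paste(pieces, collapse = "")
}

#' Simulate a diploid trio with planted SVs and SNVs
#'
#' Each of the four parental haplotypes receives its own SVs (drawn from
#' the size spectrum, preferring to delete planted elements or insert
#' mutated library copies for the element components) and its own SNVs.
#' The child inherits the first haplotype of each parent, without
#' recombination. One "shared" segment of the genome receives no variants
#' on any haplotype, so both parents are locally identical there — the
#' situation in which trio-binning is expected to stay undecided. SV start
#' positions are kept at least `min_gap` bp apart genome-wide so that every
#' planted event is unambiguous downstream.
#'
#' @param ref A `sim_reference` from [simulate_reference()].
#' @param sv_count Total SVs across the four parental haplotypes.
#' @param spectrum An [sv_spectrum()].
#' @param snv_rate Per-base SNV rate per haplotype.
#' @param shared_frac Fraction of the genome reserved as the variant-free
#'   shared segment.
#' @param exclusion_frac Approximate fraction of the genome covered by the
#'   simulated exclusion regions (repeat-like regions a real pipeline would
#'   mask).
#' @param min_gap Minimum distance in bp between SV breakpoints.
#' @param seed RNG seed.
#' @return A list of class `trio_truth`: `ref`, `haplotypes` (named list:
#'   father_h1/2, mother_h1/2, child_pat, child_mat), `svs` (truth tibble
#'   with `haplotype`, `component`, `in_child`), `snvs` (per-haplotype
#'   list), `shared_region`, `exclusion`, `inherited`.
#' @export
simulate_trio <- function(ref, sv_count = 300, spectrum = sv_spectrum(),
                          snv_rate = 1e-3, shared_frac = 0.05,
                          exclusion_frac = 0.05, min_gap = 2000, seed = 1) {
  set.seed(seed)
  L <- ref$length
  haps <- c("father_h1", "father_h2", "mother_h1", "mother_h2")
  shared <- tibble::tibble(chrom = ref$chrom,
                           start = floor(0.45 * L),
                           end = floor((0.45 + shared_frac) * L))

  sizes <- sample_sv_sizes(sv_count, spectrum)
  svtype <- ifelse(stats::runif(sv_count) < spectrum$type_mix, "INS", "DEL")
  haplotype <- sample(haps, sv_count, replace = TRUE)

  # global placement: spans at least min_gap apart, outside the shared segment
  acc_start <- numeric(0); acc_end <- numeric(0)
  blocked <- function(s, e) {
    any(s < acc_end + min_gap & e > acc_start - min_gap) ||
      (s < shared$end + min_gap && e > shared$start - min_gap)
  }
  elem_used <- rep(FALSE, nrow(ref$elements))
  out <- vector("list", sv_count)
  for (i in seq_len(sv_count)) {
    size <- sizes$size[i]
    comp <- sizes$component[i]
    placed <- FALSE
    start <- NA_real_
    if (svtype[i] == "DEL" && comp %in% c("alu", "line")) {
      # prefer deleting a planted element copy of the right family
      cand <- which(!elem_used & ref$elements$family == comp)
      for (j in sample(cand)) {
        s <- ref$elements$start[j]; e <- ref$elements$end[j]
        if (!blocked(s, e)) {
          start <- s; size <- e - s
          elem_used[j] <- TRUE
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      span <- if (svtype[i] == "DEL") size else 0
      for (try in 1:200) {
        s <- floor(stats::runif(1, 1000, L - span - 1000))
        if (!blocked(s, s + span)) {
          start <- s
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      stop("insufficient placeable space for ", sv_count, " SVs on a ",
           L, " bp reference")
    }
    end <- if (svtype[i] == "DEL") start + size else start
    acc_start <- c(acc_start, start); acc_end <- c(acc_end, end)
    alt_seq <- ""
    if (svtype[i] == "INS") {
      alt_seq <- if (comp %in% c("alu", "line")) {
        resize_seq(mutate_sequences_cpp(ref$libraries[[comp]], 0.05), size)
      } else {
        random_dna(size)
      }
    }
    ref_seq <- if (svtype[i] == "DEL") substring(ref$sequence, start + 1, end) else ""
    out[[i]] <- tibble::tibble(
      id = sprintf("truth%03d", i), chrom = ref$chrom, start = start,
      end = end, svtype = svtype[i], svlen = size, alt_seq = alt_seq,
      ref_seq = ref_seq, haplotype = haplotype[i], component = comp
    )
  }
  svs <- dplyr::bind_rows(out)
  if (nrow(svs) == 0) {
    svs <- tibble::tibble(
      id = character(), chrom = character(), start = numeric(),
      end = numeric(), svtype = character(), svlen = numeric(),
      alt_seq = character(), ref_seq = character(), haplotype = character(),
      component = character()
    )
  }

  # per-haplotype SNVs, never inside the shared segment
  snvs <- purrr::map(stats::setNames(haps, haps), function(h) {
    pos <- which(stats::runif(L) < snv_rate) - 1
    pos <- pos[pos < shared$start | pos >= shared$end]
    refbase <- substring(ref$sequence, pos + 1, pos + 1)
    alt <- vapply(refbase, function(b)
      sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1), character(1),
      USE.NAMES = FALSE)
    tibble::tibble(pos = pos, alt = alt)
  })

  haplotypes <- purrr::map(stats::setNames(haps, haps), function(h) {
    apply_variants(ref$sequence, snvs[[h]],
                   svs[svs$haplotype == h, , drop = FALSE])
  })
  inherited <- c(father = "father_h1", mother = "mother_h1")
  haplotypes$child_pat <- haplotypes[[inherited["father"]]]
  haplotypes$child_mat <- haplotypes[[inherited["mother"]]]
  svs$in_child <- svs$haplotype %in% inherited
  svs$genotype <- ifelse(svs$in_child, "het", "unknown")

  # exclusion regions: a few repeat-like intervals, independent of SVs
  n_excl <- 4
  excl_len <- exclusion_frac * L / n_excl
  excl_start <- sort(stats::runif(n_excl, 0, L - excl_len))
  exclusion <- normalize_regions(tibble::tibble(
    chrom = ref$chrom, start = floor(excl_start),
    end = floor(excl_start + excl_len)
  ))

  structure(
    list(ref = ref, haplotypes = haplotypes, svs = svs, snvs = snvs,
         shared_region = shared, exclusion = exclusion, inherited = inherited),
    class = "trio_truth"
  )
}

# truncate or pad a sequence to an exact target length
resize_seq <- function(seq, target) {
  n <- nchar(seq)
  if (n >= target) return(substring(seq, 1, target))
  paste0(seq, random_dna(target - n))
}

#' Child truth callset of a simulated trio
#'
#' The SVs carried by the child's two inherited haplotypes, as an SV tibble
#' in reference coordinates — the ground truth that platform callsets and
#' the integrated pipeline output are judged against.
#'
#' @param truth A `trio_truth`.
#' @return An SV tibble.
#' @export
child_truth_svs <- function(truth) {
  svs <- truth$svs[truth$svs$in_child, , drop = FALSE]
  as_sv_tbl(svs[, c("id", "chrom", "start", "end", "svtype", "svlen",
                    "alt_seq", "ref_seq", "genotype")])
}

#' Per-platform detection and error profile
#'
#' @param label Platform label (e.g. `"CCS"`).
#' @param sens_del,sens_ins Functions of SV size returning the detection
#'   probability for deletions/insertions.
#' @param breakpoint_jitter_sd SD in bp of the normal breakpoint error.
#' @param len_error_sd SD in bp of the normal length error.
#' @param fp_rate Expected spurious calls per Mb.
#' @param emits_sequence Does the platform report base-level alleles?
#' @param seq_error_rate Per-base substitution rate applied to reported
#'   insertion sequences.
#' @return An object of class `platform_profile`.
#' @export
platform_profile <- function(label, sens_del, sens_ins,
                             breakpoint_jitter_sd = 10, len_error_sd = 5,
                             fp_rate = 2, emits_sequence = TRUE,
                             seq_error_rate = 0.01) {
  structure(
    list(label = label, sens_del = sens_del, sens_ins = sens_ins,
         breakpoint_jitter_sd = breakpoint_jitter_sd,
         len_error_sd = len_error_sd, fp_rate = fp_rate,
         emits_sequence = emits_sequence, seq_error_rate = seq_error_rate),
    class = "platform_profile"
  )
}

#' Default five-platform profile set
#'
#' Emulates the qualitative contrasts between the platforms: CCS alignment
#' is the most sensitive small-SV detector but misses long (LINE-scale)
#' insertions, CLR behaves similarly with more breakpoint noise, ONT
#' detects deletions better than insertions, CCS assembly (ASM) sees all
#' size classes, and Bionano (BN) resolves nothing below 1 kb, reports no
#' base-level sequence and has coarse (sd 500 bp) breakpoints. The numeric
#' values are configuration, not claims about the real platforms.
#'
#' @return Named list of [platform_profile()] objects.
#' @export
default_platform_profiles <- function() {
  flat <- function(p) function(size) rep(p, length(size))
  ins_collapse <- function(p, p_long) function(size) ifelse(size >= 5000, p_long, p)
  bn_sens <- function(p) function(size) ifelse(size < 1000, 0, p)
  list(
    CCS = platform_profile("CCS", flat(0.90), ins_collapse(0.90, 0.20),
                           breakpoint_jitter_sd = 5, len_error_sd = 2,
                           fp_rate = 2, seq_error_rate = 0.002),
    CLR = platform_profile("CLR", flat(0.80), ins_collapse(0.80, 0.25),
                           breakpoint_jitter_sd = 20, len_error_sd = 10,
                           fp_rate = 2, seq_error_rate = 0.02),
    ONT = platform_profile("ONT", flat(0.70), flat(0.60),
                           breakpoint_jitter_sd = 30, len_error_sd = 15,
                           fp_rate = 2, seq_error_rate = 0.02),
    ASM = platform_profile("ASM", flat(0.85), flat(0.85),
                           breakpoint_jitter_sd = 5, len_error_sd = 2,
                           fp_rate = 1, seq_error_rate = 0.002),
    BN = platform_profile("BN", bn_sens(0.80), bn_sens(0.80),
                          breakpoint_jitter_sd = 500, len_error_sd = 100,
                          fp_rate = 1, emits_sequence = FALSE)
  )
}

#' Simulate per-platform callsets of the child genome
#'
#' Every child truth SV is detected independently per platform with the
#' profile's size- and type-dependent sensitivity; detected calls get
#' normally jittered breakpoints and perturbed lengths, and sequence-aware
#' platforms report the inserted allele with platform-level base errors.
#' Spurious calls are added at `fp_rate` per Mb, placed away from truth
#' breakpoints so the planted bookkeeping stays exact.
#'
#' @param truth A `trio_truth`.
#' @param profiles Named list of [platform_profile()] objects.
#' @param seed RNG seed.
#' @return A list: `callsets` (named list of SV tibbles), `bookkeeping`
#'   (tibble: truth `id`, per-platform `detected_*` flags,
#'   `planted_support`, `in_exclusion`, `eligible`).
#' @export
simulate_platform_callsets <- function(truth, profiles = default_platform_profiles(),
                                       seed = 1) {
  set.seed(seed)
  child <- truth$svs[truth$svs$in_child, , drop = FALSE]
  L <- truth$ref$length
  n <- nrow(child)

  detected <- matrix(FALSE, n, length(profiles),
                     dimnames = list(NULL, names(profiles)))
  callsets <- vector("list", length(profiles))
  names(callsets) <- names(profiles)
  fp_starts <- numeric(0)

  for (p in names(profiles)) {
    prof <- profiles[[p]]
    sens <- ifelse(child$svtype == "DEL",
                   prof$sens_del(child$svlen), prof$sens_ins(child$svlen))
    hit <- stats::runif(n) < sens
    detected[, p] <- hit
    calls <- child[hit, , drop = FALSE]
    m <- nrow(calls)
    if (m > 0) {
      jitter <- round(stats::rnorm(m, 0, prof$breakpoint_jitter_sd))
      dlen <- round(stats::rnorm(m, 0, prof$len_error_sd))
      svlen <- pmax(50, calls$svlen + dlen)
      start <- pmax(0, calls$start + jitter)
      calls <- tibble::tibble(
        id = paste0(p, "_", calls$id), chrom = calls$chrom,
        start = start,
        end = ifelse(calls$svtype == "DEL", start + svlen, start),
        svtype = calls$svtype, svlen = svlen,
        alt_seq = if (prof$emits_sequence) {
          ifelse(calls$svtype == "INS",
                 mutate_sequences_cpp(calls$alt_seq, prof$seq_error_rate), "")
        } else "",
        ref_seq = "", support = p, hap_support = "",
        genotype = calls$genotype
      )
    } else {
      calls <- empty_sv_tbl()
    }
    # spurious calls, kept >= 2 kb from every truth breakpoint and from
    # every other platform's spurious call, so each stays its own cluster
    n_fp <- stats::rpois(1, prof$fp_rate * L / 1e6)
    fps <- vector("list", n_fp)
    if (n_fp > 0) {
      for (f in seq_len(n_fp)) {
        size <- round(stats::runif(1, 50, 1000))
        type <- sample(c("DEL", "INS"), 1)
        for (try in 1:100) {
          s <- floor(stats::runif(1, 1000, L - size - 1000))
          if (all(abs(s - truth$svs$start) > 2000) &&
              (length(fp_starts) == 0 || all(abs(s - fp_starts) > 2000))) break
        }
        fp_starts <- c(fp_starts, s)
        fps[[f]] <- tibble::tibble(
          id = sprintf("%s_fp%03d", p, f), chrom = truth$ref$chrom,
          start = s, end = if (type == "DEL") s + size else s,
          svtype = type, svlen = size,
          alt_seq = if (prof$emits_sequence && type == "INS") random_dna(size) else "",
          ref_seq = "", support = p, hap_support = "", genotype = "unknown"
        )
      }
      calls <- dplyr::bind_rows(calls, dplyr::bind_rows(fps))
    }
    callsets[[p]] <- as_sv_tbl(calls)
  }

  planted_support <- support_join(apply(detected, 1, function(r)
    colnames(detected)[r], simplify = FALSE))
  in_excl <- regions_overlap_any(child$chrom, child$start, child$end,
                                 truth$exclusion)
  # generator-side eligibility under the default retention tiers; platforms
  # absent from the profile set count as never detecting
  det <- function(p) if (p %in% colnames(detected)) detected[, p] else rep(FALSE, n)
  tier1 <- det("CCS") & (det("CLR") | det("ONT"))
  tier2 <- child$svlen > 1500 & det("ASM") & det("BN")
  bookkeeping <- tibble::tibble(
    id = child$id, svtype = child$svtype, svlen = child$svlen,
    planted_support = planted_support
  )
  for (p in names(profiles)) bookkeeping[[paste0("detected_", p)]] <- detected[, p]
  bookkeeping$in_exclusion <- in_excl
  bookkeeping$eligible <- child$svlen >= 50 & (tier1 | tier2) & !in_excl

  list(callsets = callsets, bookkeeping = bookkeeping)
}

#' Simulate haplotype-assembly SV calls and coverage tracks
#'
#' Emulates what SV calling on the child's two assembled haplotypes yields:
#' nearly every truth SV of the inherited haplotype is recovered with tiny
#' breakpoint noise, and each haplotype's assembly covers the genome except
#' for a few random gaps.
#'
#' @param truth A `trio_truth`.
#' @param sens Per-SV recovery probability of each assembly.
#' @param jitter_sd Breakpoint noise SD in bp.
#' @param n_gaps,gap_size Number and size (bp) of coverage gaps per
#'   haplotype.
#' @param seed RNG seed.
#' @return A list: `pat_calls`, `mat_calls` (SV tibbles), `pat_cov`,
#'   `mat_cov` (region tibbles).
#' @export
simulate_hap_assembly <- function(truth, sens = 0.98, jitter_sd = 5,
                                  n_gaps = 3, gap_size = 2e4, seed = 1) {
  set.seed(seed)
  L <- truth$ref$length
  one_hap <- function(hap_name, label) {
    svs <- truth$svs[truth$svs$haplotype == hap_name, , drop = FALSE]
    hit <- stats::runif(nrow(svs)) < sens
    calls <- svs[hit, , drop = FALSE]
    jitter <- round(stats::rnorm(nrow(calls), 0, jitter_sd))
    start <- pmax(0, calls$start + jitter)
    as_sv_tbl(tibble::tibble(
      id = paste0(label, "_", calls$id), chrom = calls$chrom, start = start,
      end = ifelse(calls$svtype == "DEL", start + calls$svlen, start),
      svtype = calls$svtype, svlen = calls$svlen,
      alt_seq = calls$alt_seq, ref_seq = "", support = label,
      hap_support = "", genotype = calls$genotype
    ))
  }
  one_cov <- function() {
    gaps <- sort(stats::runif(n_gaps, 0, L - gap_size))
    regions_subtract(
      tibble::tibble(chrom = truth$ref$chrom, start = 0, end = L),
      tibble::tibble(chrom = truth$ref$chrom, start = floor(gaps),
                     end = floor(gaps + gap_size))
    )
  }
  list(pat_calls = one_hap(truth$inherited[["father"]], "hap_pat"),
       mat_calls = one_hap(truth$inherited[["mother"]], "hap_mat"),
       pat_cov = one_cov(), mat_cov = one_cov())
}

#' Simulate long reads from haplotype sequences
#'
#' Reads are sampled uniformly along each haplotype, with normal read
#' lengths and independent per-base substitution errors. `depth` is the
#' total depth over all supplied haplotypes relative to the haploid genome
#' length (so 60x over a diploid pair means 30x per haplotype). Each read
#' is labelled with its haplotype of origin for downstream accuracy
#' scoring.
#'
#' @param haps Named character vector (or list) of haplotype sequences.
#' @param depth Total sequencing depth.
#' @param read_length_mean,read_length_sd Normal read-length parameters in
#'   bp (truncated at 500 bp and at the haplotype end).
#' @param sub_error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @return Tibble with `read_id`, `hap` (origin), `start` (0-based, in
#'   haplotype coordinates), `length`, `seq`.
#' @export
simulate_reads <- function(haps, depth = 60, read_length_mean = 1e4,
                           read_length_sd = 2e3, sub_error_rate = 0.01,
                           seed = 1) {
  set.seed(seed)
  stopifnot(depth > 0)
  haps <- as.list(haps)
  hap_len <- vapply(haps, nchar, numeric(1))
  G <- mean(hap_len)
  total_bases <- depth * G
  per_hap <- total_bases / length(haps)
  out <- vector("list", length(haps))
  for (h in seq_along(haps)) {
    n_reads <- max(1, round(per_hap / read_length_mean))
    len <- pmax(500, round(stats::rnorm(n_reads, read_length_mean, read_length_sd)))
    start <- floor(stats::runif(n_reads, 0, pmax(1, hap_len[h] - len)))
    len <- pmin(len, hap_len[h] - start)
    seqs <- substring(haps[[h]], start + 1, start + len)
    seqs <- mutate_sequences_cpp(seqs, sub_error_rate)
    out[[h]] <- tibble::tibble(
      read_id = sprintf("%s_r%05d", names(haps)[h], seq_len(n_reads)),
      hap = names(haps)[h], start = start, length = len, seq = seqs
    )
  }
  dplyr::bind_rows(out)
}

#' Which reads come entirely from the shared (parent-identical) segment?
#'
#' Maps the shared reference segment into each child haplotype's coordinate
#' system (exact, since no variant is placed inside it) and flags reads
#' wholly contained in it.
#'
#' @param reads Read tibble from [simulate_reads()] over the child
#'   haplotypes.
#' @param truth A `trio_truth`.
#' @return Logical vector along the rows of `reads`.
#' @export
reads_in_shared_region <- function(reads, truth) {
  shared <- truth$shared_region
  hap_of <- c(child_pat = truth$inherited[["father"]],
              child_mat = truth$inherited[["mother"]])
  offset_at <- function(hap_name, pos) {
    svs <- truth$svs[truth$svs$haplotype == hap_name &
                       truth$svs$start <= pos, , drop = FALSE]
    sum(ifelse(svs$svtype == "INS", svs$svlen, -svs$svlen))
  }
  flag <- logical(nrow(reads))
  for (h in unique(reads$hap)) {
    hap_name <- if (h %in% names(hap_of)) hap_of[[h]] else h
    off <- offset_at(hap_name, shared$start)
    lo <- shared$start + off
    hi <- shared$end + off
    sel <- reads$hap == h
    flag[sel] <- reads$start[sel] >= lo & reads$start[sel] + reads$length[sel] <= hi
  }
  flag
}
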