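// Canonical k-mer hashing and parent-unique k-mer indices for trio-binning.
//
// K-mers are identified by a strand-collapsed 64-bit hash: a polynomial
// rolling hash is maintained for the forward window and for its reverse
// complement, each is passed through a splitmix64 finalizer, and the
// canonical identity is the minimum of the two. Rolling updates make the
// cost independent of k (k up to 81 is routine here), and collisions at
// the ~1e7 k-mer scale of the fixtures are vanishingly unlikely.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
using namespace Rcpp;

static const uint64_t BASE = 0x9E3779B97F4A7C15ULL; // odd -> invertible mod 2^64

static uint64_t base_inv() {
  // Newton iteration for the inverse of BASE modulo 2^64
  uint64_t x = BASE;
  for (int i = 0; i < 6; ++i) x *= 2 - BASE * x;
  return x;
}
static const uint64_t BASE_INV = base_inv();

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct KmerIndex {
  int k;
  std::unordered_set<uint64_t> pat;
  std::unordered_set<uint64_t> mat;
};

// visit the canonical hash of every valid k-mer window of seq
template <typename F>
static void for_each_canonical(const std::string& seq, int k, F fun) {
  const int n = (int)seq.size();
  if (n < k) return;
  uint64_t bk = 1; // BASE^(k-1)
  for (int i = 0; i < k - 1; ++i) bk *= BASE;

  uint64_t fwd = 0, rc = 0, pw = 1;
  int valid = 0; // length of current run of ACGT ending at position i
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; pw = 1; continue; }
    if (valid < k) {
      fwd = fwd * BASE + (uint64_t)c;
      rc += (uint64_t)(3 - c) * pw;
      pw *= BASE;
      ++valid;
    } else {
      int out = base_code(seq[i - k]);
      fwd = (fwd - (uint64_t)out * bk) * BASE + (uint64_t)c;
      rc = (rc - (uint64_t)(3 - out)) * BASE_INV + (uint64_t)(3 - c) * bk;
    }
    if (valid >= k) {
      uint64_t hf = mix64(fwd), hr = mix64(rc);
      fun(hf < hr ? hf : hr);
    }
  }
}

static void collect(const CharacterVector& seqs, int k,
                    std::unordered_set<uint64_t>& out) {
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for_each_canonical(s, k, [&](uint64_t h) { out.insert(h); });
  }
}

// [[Rcpp::export]]
SEXP kmer_index_build_cpp(CharacterVector paternal_seqs,
                          CharacterVector maternal_seqs, int k) {
  std::unordered_set<uint64_t> pat_all, mat_all;
  collect(paternal_seqs, k, pat_all);
  collect(maternal_seqs, k, mat_all);

  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  for (uint64_t h : pat_all)
    if (!mat_all.count(h)) idx->pat.insert(h);
  for (uint64_t h : mat_all)
    if (!pat_all.count(h)) idx->mat.insert(h);

  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector kmer_index_sizes_cpp(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return NumericVector::create((double)idx->pat.size(), (double)idx->mat.size());
}

// [[Rcpp::export]]
int kmer_index_k_cpp(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return idx->k;
}

// membership of exact length-k strings in one of the unique sets
// [[Rcpp::export]]
LogicalVector kmer_index_contains_cpp(SEXP xp, CharacterVector kmers,
                                      bool paternal) {
  XPtr<KmerIndex> idx(xp);
  const std::unordered_set<uint64_t>& set = paternal ? idx->pat : idx->mat;
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != idx->k) stop("k-mer of wrong length");
    bool found = false;
    for_each_canonical(s, idx->k, [&](uint64_t h) { found = set.count(h) > 0; });
    out[i] = found;
  }
  return out;
}

// per-read marker counts: columns n_pat, n_mat (k-mer occurrences found in
// each parent-unique set; every window counts, including repeats)
// [[Rcpp::export]]
NumericMatrix kmer_count_reads_cpp(SEXP xp, CharacterVector reads) {
  XPtr<KmerIndex> idx(xp);
  NumericMatrix out(reads.size(), 2);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    double np = 0, nm = 0;
    for_each_canonical(s, idx->k, [&](uint64_t h) {
      if (idx->pat.count(h)) ++np;
      else if (idx->mat.count(h)) ++nm;
    });
    out(i, 0) = np;
    out(i, 1) = nm;
  }
  return out;
}

// substitution errors at the given per-base rate, using R's RNG so results
// are reproducible under set.seed()
// [[Rcpp::export]]
CharacterVector mutate_sequences_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate) {
        int cur = base_code(s[j]);
        int sub = (int)(unif_rand() * 3);
        if (sub > 2) sub = 2;
        // pick uniformly among the three other bases
        int code = (cur < 0) ? sub : (sub + cur + 1) % 4;
        s[j] = bases[code];
      }
    }
    out[i] = s;
  }
  return out;
}
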