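// Seed-and-extend alignment core: k-mer index over the reference, exact-seed
// candidate lookup, ungapped full-length scoring. Kept in C++ because a 30x
// read set over a megabase-scale hybrid reference is millions of candidate
// comparisons.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static const char RC[4] = {'T', 'G', 'C', 'A'};

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  // kmer -> packed (contig << 40 | pos); forward strand only, reads are
  // queried in both orientations
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
};

// encode the k-mer starting at position i of s; returns false on non-ACGT
static inline bool encode_kmer(const std::string& s, size_t i, int k,
                               uint64_t& out) {
  uint64_t v = 0;
  for (int j = 0; j < k; ++j) {
    int c = base_code(s[i + j]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 11 || k > 31) stop("k must lie in [11, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  for (R_xlen_t ci = 0; ci < seqs.size(); ++ci) {
    std::string s = as<std::string>(seqs[ci]);
    idx->seqs.push_back(s);
    if ((int)s.size() < k) continue;
    uint64_t v = 0;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        size_t pos = i + 1 - k;
        idx->map[v].push_back(((uint64_t)ci << 40) | (uint64_t)pos);
      }
    }
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
IntegerVector cpp_index_positions(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector out(idx->seqs.size());
  for (auto& kv : idx->map)
    for (uint64_t packed : kv.second)
      out[(int)(packed >> 40)] += 1;
  return out;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return idx->k;
}

// [[Rcpp::export]]
IntegerVector cpp_contig_lengths(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector out(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i)
    out[i] = (int)idx->seqs[i].size();
  return out;
}

static inline int count_mismatches(const std::string& ref, size_t start,
                                   const std::string& read, int stop_at) {
  int mm = 0;
  for (size_t j = 0; j < read.size(); ++j) {
    if (ref[start + j] != read[j]) {
      if (++mm > stop_at) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List cpp_align_reads(SEXP xp, CharacterVector reads, int max_mismatch) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  R_xlen_t n = reads.size();
  IntegerVector out_contig(n), out_pos(n), out_score(n), out_nbest(n);
  IntegerVector out_strand(n);  // 0 = '+', 1 = '-'
  IntegerVector out_status(n);  // 0 unique, 1 ambiguous, 2 unmapped

  std::vector<uint64_t> cands;
  for (R_xlen_t ri = 0; ri < n; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int len = (int)fwd.size();
    if (len < k) stop("read length must be >= k");
    std::string rc(len, 'N');
    bool rc_ok = true;
    for (int j = 0; j < len; ++j) {
      int c = base_code(fwd[len - 1 - j]);
      if (c < 0) { rc_ok = false; break; }
      rc[j] = RC[c];
    }
    int offs[3] = {0, (len - k) / 2, len - k};
    cands.clear();
    for (int ori = 0; ori < 2; ++ori) {
      if (ori == 1 && !rc_ok) continue;
      const std::string& q = (ori == 0) ? fwd : rc;
      for (int s = 0; s < 3; ++s) {
        uint64_t key;
        if (!encode_kmer(q, offs[s], k, key)) continue;
        auto it = idx->map.find(key);
        if (it == idx->map.end()) continue;
        for (uint64_t packed : it->second) {
          int ci = (int)(packed >> 40);
          long pos = (long)(packed & ((1ULL << 40) - 1)) - offs[s];
          if (pos < 0 || pos + len > (long)idx->seqs[ci].size()) continue;
          cands.push_back(((uint64_t)ci << 42) | ((uint64_t)pos << 2) |
                          (uint64_t)ori);
        }
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best_mm = len + 1, n_best = 0;
    uint64_t best = 0;
    for (uint64_t cand : cands) {
      int ci = (int)(cand >> 42);
      size_t pos = (size_t)((cand >> 2) & ((1ULL << 40) - 1));
      int ori = (int)(cand & 3ULL);
      const std::string& q = (ori == 0) ? fwd : rc;
      int mm = count_mismatches(idx->seqs[ci], pos, q, best_mm);
      if (mm < best_mm) { best_mm = mm; n_best = 1; best = cand; }
      else if (mm == best_mm) ++n_best;
    }
    if (n_best == 0 || best_mm > max_mismatch) {
      out_status[ri] = 2;
      out_contig[ri] = NA_INTEGER; out_pos[ri] = NA_INTEGER;
      out_strand[ri] = NA_INTEGER;
      out_score[ri] = NA_INTEGER;
      out_nbest[ri] = n_best;
    } else {
      out_status[ri] = (n_best == 1) ? 0 : 1;
      out_contig[ri] = (int)(best >> 42) + 1;  // 1-based contig index
      out_pos[ri] = (int)((best >> 2) & ((1ULL << 40) - 1));
      out_strand[ri] = (int)(best & 3ULL);
      out_score[ri] = len - 2 * best_mm;
      out_nbest[ri] = n_best;
    }
  }
  return List::create(_["contig_idx"] = out_contig, _["pos"] = out_pos,
                      _["strand"] = out_strand, _["score"] = out_score,
                      _["n_best"] = out_nbest, _["status"] = out_status);
}

// Per-base A/C/G/T counts from reference-oriented read sequences.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int contig_len, IntegerVector pos,
                         CharacterVector seqs) {
  IntegerMatrix counts(4, contig_len);
  for (R_xlen_t i = 0; i < pos.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int p0 = pos[i];
    if (p0 < 0 || p0 + (int)s.size() > contig_len)
      stop("read interval outside contig");
    for (size_t j = 0; j < s.size(); ++j) {
      int c = base_code(s[j]);
      if (c >= 0) counts(c, p0 + j) += 1;
    }
  }
  return counts;
}
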