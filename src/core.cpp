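#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

// 2-bit encoding; -1 for non-ACGT
static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// encode q-mer starting at p; returns false if any non-ACGT base
static inline bool encode_kmer(const char *s, int q, uint64_t &key) {
  uint64_t k = 0;
  for (int i = 0; i < q; ++i) {
    int c = base2code(s[i]);
    if (c < 0) return false;
    k = (k << 2) | (uint64_t)c;
  }
  key = k;
  return true;
}

static inline int hamming_leq(const char *a, const char *b, int n, int maxmm) {
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i] && ++mm > maxmm) return mm;
  }
  return mm;
}

// ---------------------------------------------------------------------------
// Read repository: every read and its reverse complement as a linked pair,
// indexed by all q-mers for pigeonhole seed matching with mismatches.
// ---------------------------------------------------------------------------

struct Repo {
  std::vector<std::string> seqs;  // oriented sequences
  std::vector<int> mate;          // index of the paired orientation (self for palindromes)
  std::vector<char> active;
  int n_pairs;                    // number of molecules
  int q;                          // index q-mer size
  std::vector<uint64_t> bucket_start;  // size 4^q + 1
  std::vector<uint64_t> entries;       // packed id * 256 + offset
};

static void repo_index(Repo &R) {
  const uint64_t nb = 1ULL << (2 * R.q);
  std::vector<uint64_t> counts(nb + 1, 0);
  for (size_t id = 0; id < R.seqs.size(); ++id) {
    const std::string &s = R.seqs[id];
    int nk = (int)s.size() - R.q + 1;
    for (int off = 0; off < nk && off < 256; ++off) {
      uint64_t key;
      if (encode_kmer(s.c_str() + off, R.q, key)) counts[key + 1]++;
    }
  }
  for (uint64_t i = 1; i <= nb; ++i) counts[i] += counts[i - 1];
  R.bucket_start = counts;
  R.entries.resize(counts[nb]);
  std::vector<uint64_t> fill(counts.begin(), counts.end() - 1);
  for (size_t id = 0; id < R.seqs.size(); ++id) {
    const std::string &s = R.seqs[id];
    int nk = (int)s.size() - R.q + 1;
    for (int off = 0; off < nk && off < 256; ++off) {
      uint64_t key;
      if (encode_kmer(s.c_str() + off, R.q, key))
        R.entries[fill[key]++] = ((uint64_t)id << 8) | (uint64_t)off;
    }
  }
}

// [[Rcpp::export]]
SEXP repo_build_cpp(CharacterVector reads, int q) {
  Repo *R = new Repo();
  R->q = q;
  R->n_pairs = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string f = as<std::string>(reads[i]);
    std::string r = revcomp(f);
    int id = (int)R->seqs.size();
    if (f == r) {  // palindrome: one self-paired entry
      R->seqs.push_back(f);
      R->mate.push_back(id);
    } else {
      R->seqs.push_back(f);
      R->seqs.push_back(r);
      R->mate.push_back(id + 1);
      R->mate.push_back(id);
    }
    R->n_pairs++;
  }
  R->active.assign(R->seqs.size(), 1);
  repo_index(*R);
  XPtr<Repo> p(R, true);
  return p;
}

// [[Rcpp::export]]
List repo_status_cpp(SEXP ptr) {
  XPtr<Repo> R(ptr);
  int n_active = 0;
  for (char a : R->active) n_active += a;
  return List::create(_["n_oriented"] = (int)R->seqs.size(),
                      _["n_active"] = n_active,
                      _["n_pairs"] = R->n_pairs,
                      _["q"] = R->q);
}

// Find active oriented sequences containing a window matching `seed`
// with <= maxmm mismatches.  Returns, per hit, the leftmost matching window.
static void repo_matches(const Repo &R, const std::string &seed, int maxmm,
                         std::vector<std::pair<int,int> > &out) {
  const int slen = (int)seed.size();
  const int nparts = maxmm + 1;
  std::vector<std::pair<int,int> > raw;  // (id, window offset)
  for (int j = 0; j < nparts; ++j) {
    int poff = j * R.q;
    uint64_t key;
    if (!encode_kmer(seed.c_str() + poff, R.q, key)) continue;
    uint64_t b0 = R.bucket_start[key], b1 = R.bucket_start[key + 1];
    for (uint64_t e = b0; e < b1; ++e) {
      uint64_t packed = R.entries[e];
      int id = (int)(packed >> 8);
      int off = (int)(packed & 0xFF);
      if (!R.active[id]) continue;
      int w = off - poff;
      if (w < 0 || w + slen > (int)R.seqs[id].size()) continue;
      if (hamming_leq(R.seqs[id].c_str() + w, seed.c_str(), slen, maxmm) <= maxmm)
        raw.push_back(std::make_pair(id, w));
    }
  }
  std::sort(raw.begin(), raw.end());
  raw.erase(std::unique(raw.begin(), raw.end()), raw.end());
  // keep leftmost window per id
  out.clear();
  for (size_t i = 0; i < raw.size(); ++i)
    if (i == 0 || raw[i].first != raw[i - 1].first) out.push_back(raw[i]);
}

// [[Rcpp::export]]
IntegerVector repo_query_cpp(SEXP ptr, std::string seed, int max_mismatches) {
  XPtr<Repo> R(ptr);
  if ((int)seed.size() < R->q * (max_mismatches + 1))
    stop("seed shorter than q*(max_mismatches+1); index lookup incomplete");
  std::vector<std::pair<int,int> > hits;
  repo_matches(*R, seed, max_mismatches, hits);
  IntegerVector ids(hits.size());
  for (size_t i = 0; i < hits.size(); ++i) ids[i] = hits[i].first + 1;
  return ids;
}

// The overlap-consensus extension loop.  Mutates the repository (consumes
// reads).  Returns status, the extension string, per-base support, and the
// number of molecules consumed.
// [[Rcpp::export]]
List repo_extend_cpp(SEXP ptr, std::string upstream, std::string downstream,
                     int seed_len, int max_mismatches, int min_depth,
                     int max_extension, int term_overlap) {
  XPtr<Repo> R(ptr);
  if ((int)upstream.size() < seed_len) stop("upstream contig shorter than seed length");
  if (seed_len < R->q * (max_mismatches + 1))
    stop("seed length too short for the repository index");
  for (char c : upstream) if (base2code(c) < 0) stop("non-ACGT base in upstream contig");
  for (char c : downstream) if (base2code(c) < 0) stop("non-ACGT base in downstream contig");

  std::string growing = upstream;
  std::string ext;
  std::vector<int> support;
  int consumed = 0;
  std::string status = "cap_exceeded";

  const bool can_close = (int)downstream.size() >= term_overlap;
  std::vector<std::pair<int,int> > hits;

  for (;;) {
    // termination: tail of growing sequence reaches the downstream contig head
    if (can_close && (int)growing.size() >= term_overlap) {
      if (hamming_leq(growing.c_str() + growing.size() - term_overlap,
                      downstream.c_str(), term_overlap, max_mismatches)
          <= max_mismatches) {
        status = "closed";
        break;
      }
    }
    if ((int)ext.size() >= max_extension) { status = "cap_exceeded"; break; }

    const std::string seed = growing.substr(growing.size() - seed_len);
    repo_matches(*R, seed, max_mismatches, hits);

    int votes[4] = {0, 0, 0, 0};
    int total = 0;
    std::vector<int> exhausted;  // voters whose final base was recorded
    for (auto &h : hits) {
      const std::string &s = R->seqs[h.first];
      int bpos = h.second + seed_len;
      if (bpos >= (int)s.size()) continue;  // matched, but no following base
      int c = base2code(s[bpos]);
      if (c < 0) continue;
      votes[c]++; total++;
      if (bpos == (int)s.size() - 1) exhausted.push_back(h.first);
    }
    if (total < std::max(1, min_depth)) { status = "no_reads"; break; }
    int best = 0;
    for (int c = 1; c < 4; ++c) if (votes[c] > votes[best]) best = c;
    bool tie = false;
    for (int c = 0; c < 4; ++c) if (c != best && votes[c] == votes[best]) tie = true;
    if (tie) { status = "ambiguous_tie"; break; }

    // a read is consumed (with its complement) once its last base has been
    // recorded: it can contribute nothing further to the assembly
    for (int id : exhausted) {
      if (R->active[id]) {
        R->active[id] = 0;
        R->active[R->mate[id]] = 0;
        consumed++;
      }
    }
    const char bases[4] = {'A', 'C', 'G', 'T'};
    ext.push_back(bases[best]);
    growing.push_back(bases[best]);
    support.push_back(total);
  }

  return List::create(_["status"] = status,
                      _["extension"] = ext,
                      _["support"] = IntegerVector(support.begin(), support.end()),
                      _["reads_consumed"] = consumed);
}

// ---------------------------------------------------------------------------
// Short-read mapper: exact-seed pigeonhole index, ungapped alignment with a
// mismatch cap, MAQ-like random placement of equal-best hits.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List map_reads_cpp(std::string genome, CharacterVector reads,
                   int max_mismatches, int rng_seed, bool circular) {
  const int L = (int)genome.size();
  if (L == 0) stop("empty assembly");
  int maxrl = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    maxrl = std::max(maxrl, (int)LENGTH(STRING_ELT(reads, i)));
  std::string subject = genome;
  if (circular && maxrl > 1) subject += genome.substr(0, std::min(L, maxrl - 1));
  const int SL = (int)subject.size();

  const int nparts = max_mismatches + 1;

  // genome q-mer index; q = 9 keeps the table at 4^9 buckets and gives
  // complete <=3-mismatch lookup for reads of >= 36 bp
  int q = 9;

  const uint64_t nb = 1ULL << (2 * q);
  std::vector<uint32_t> counts(nb + 1, 0);
  int nk = SL - q + 1;
  for (int p = 0; p < nk; ++p) {
    uint64_t key;
    if (encode_kmer(subject.c_str() + p, q, key)) counts[key + 1]++;
  }
  for (uint64_t i = 1; i <= nb; ++i) counts[i] += counts[i - 1];
  std::vector<uint32_t> entries(counts[nb]);
  {
    std::vector<uint32_t> fill(counts.begin(), counts.end() - 1);
    for (int p = 0; p < nk; ++p) {
      uint64_t key;
      if (encode_kmer(subject.c_str() + p, q, key)) entries[fill[key]++] = (uint32_t)p;
    }
  }

  std::mt19937 rng((uint32_t)rng_seed);
  const R_xlen_t n = reads.size();
  IntegerVector pos(n), mm_out(n), nbest_out(n);
  LogicalVector fwd(n);
  IntegerVector depth(L);
  int n_mapped = 0;
  long long mapped_bases = 0;

  std::vector<std::pair<int,int> > cand;     // (position, strand 0/1)
  std::vector<std::pair<int,int> > bestset;

  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int rl = (int)rd.size();
    pos[i] = NA_INTEGER; mm_out[i] = NA_INTEGER; nbest_out[i] = 0; fwd[i] = true;
    if (rl < q * nparts || rl > L) continue;
    std::string rc = revcomp(rd);
    // pigeonhole: rl >= q*nparts guarantees each q-seed lies inside one of
    // the nparts disjoint read segments, so every <=max_mismatches placement
    // is found by at least one exact seed
    int best_mm = max_mismatches + 1;
    bestset.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &s = (strand == 0) ? rd : rc;
      cand.clear();
      for (int j = 0; j < nparts; ++j) {
        int soff = j * (rl / nparts);
        if (soff + q > rl) soff = rl - q;
        uint64_t key;
        if (!encode_kmer(s.c_str() + soff, q, key)) continue;
        for (uint32_t e = counts[key]; e < counts[key + 1]; ++e) {
          int p = (int)entries[e] - soff;
          if (p < 0 || p + rl > SL) continue;
          if (circular && p >= L) continue;  // canonical start in [0, L)
          cand.push_back(std::make_pair(p, strand));
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (auto &cp : cand) {
        int mm = hamming_leq(subject.c_str() + cp.first, s.c_str(), rl, max_mismatches);
        if (mm > max_mismatches) continue;
        if (mm < best_mm) { best_mm = mm; bestset.clear(); }
        if (mm == best_mm) bestset.push_back(cp);
      }
    }
    if (bestset.empty()) continue;
    size_t pick = 0;
    if (bestset.size() > 1) pick = rng() % bestset.size();
    int p = bestset[pick].first;
    pos[i] = p + 1;                        // 1-based
    fwd[i] = (bestset[pick].second == 0);
    mm_out[i] = best_mm;
    nbest_out[i] = (int)bestset.size();
    n_mapped++; mapped_bases += rl;
    for (int b = 0; b < rl; ++b) depth[(p + b) % L]++;
  }

  return List::create(_["pos"] = pos, _["forward"] = fwd,
                      _["mismatches"] = mm_out, _["n_best"] = nbest_out,
                      _["depth"] = depth, _["n_mapped"] = n_mapped,
                      _["mapped_bases"] = (double)mapped_bases);
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) { return revcomp(s); }

// Positions (1-based) where two equal-length strings differ.
// [[Rcpp::export]]
IntegerVector mismatch_positions_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  std::vector<int> out;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) out.push_back((int)i + 1);
  return IntegerVector(out.begin(), out.end());
}
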