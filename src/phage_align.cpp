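// Seed-and-extend sequence comparison kernels:
//  - map_reads_cpp:            exact k-mer seeding + ungapped extension of reads
//                              against a (possibly circular) genome
//  - anib_map_fragments_cpp:   k-mer seeding + windowed Smith-Waterman of genome
//                              fragments against a reference, both strands
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char base_comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = base_comp(r[i]);
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

// index every k-mer start position of s (skipping ambiguous bases)
static void build_kmer_index(const std::string &s, int k, KmerIndex &idx) {
  uint64_t key = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
}

// k-mer key at offset q of s, or false if ambiguous
static bool kmer_key_at(const std::string &s, int q, int k, uint64_t &key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[q + i]);
    if (c < 0) return false;
    key = (key << 2) | (uint64_t)c;
  }
  return true;
}

// [[Rcpp::export]]
List map_reads_cpp(std::string genome, CharacterVector reads, int k,
                   bool circular, double min_identity, int max_candidates) {
  const int L = (int)genome.size();
  if (L < k) stop("genome shorter than the seed k-mer");

  // longest read determines how far the circular extension must reach
  int max_rl = 0;
  for (int i = 0; i < reads.size(); ++i)
    max_rl = std::max(max_rl, (int)strlen(CHAR(STRING_ELT(reads, i))));
  if (max_rl >= L) stop("genome shorter than a read");

  std::string ref = genome;
  if (circular) ref += genome.substr(0, std::min(L, max_rl + k));
  KmerIndex idx;
  build_kmer_index(ref, k, idx);

  const int n = reads.size();
  IntegerVector out_pos(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);
  NumericVector out_identity(n, NA_REAL);
  LogicalVector out_mapped(n);

  std::unordered_map<int, int> votes;
  std::vector<std::pair<int, int> > cand;

  for (int ri = 0; ri < n; ++ri) {
    const std::string fwd = as<std::string>(reads[ri]);
    const int rl = (int)fwd.size();
    if (rl < k) { out_mapped[ri] = false; continue; }

    double best_id = -1.0;
    int best_pos = -1, best_strand = 0;
    const int need = (int)std::ceil(min_identity * rl);
    const int step = std::max(1, k / 3);

    for (int strand = 0; strand < 2; ++strand) {
      const std::string s = strand ? revcomp_str(fwd) : fwd;
      votes.clear();
      for (int q = 0; q <= rl - k; q += step) {
        uint64_t key;
        if (!kmer_key_at(s, q, k, key)) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        const std::vector<int> &pp = it->second;
        for (size_t z = 0; z < pp.size(); ++z) {
          int c = pp[z] - q;
          if (circular) { c %= L; if (c < 0) c += L; }
          else if (c < 0 || c + rl > L) continue;
          votes[c]++;
        }
      }
      if (votes.empty()) continue;
      cand.clear();
      for (std::unordered_map<int, int>::iterator it = votes.begin();
           it != votes.end(); ++it)
        cand.push_back(std::make_pair(it->first, it->second));
      std::sort(cand.begin(), cand.end(),
                [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                  if (a.second != b.second) return a.second > b.second;
                  return a.first < b.first;
                });
      const int ncand = std::min((int)cand.size(), max_candidates);
      for (int ci = 0; ci < ncand; ++ci) {
        const int pos = cand[ci].first;
        int matches = 0;
        if (circular) {
          for (int i = 0; i < rl; ++i) {
            int g = pos + i; if (g >= L) g -= L;
            if (genome[g] == s[i]) ++matches;
          }
        } else {
          for (int i = 0; i < rl; ++i)
            if (genome[pos + i] == s[i]) ++matches;
        }
        if (matches < need) continue;
        const double id = (double)matches / rl;
        if (id > best_id + 1e-12 ||
            (std::abs(id - best_id) <= 1e-12 && pos < best_pos)) {
          best_id = id; best_pos = pos; best_strand = strand;
        }
      }
    }

    if (best_id >= min_identity) {
      out_mapped[ri] = true;
      out_pos[ri] = best_pos;
      out_strand[ri] = best_strand ? "-" : "+";
      out_identity[ri] = best_id;
    } else {
      out_mapped[ri] = false;
    }
  }

  return List::create(_["pos"] = out_pos, _["strand"] = out_strand,
                      _["identity"] = out_identity, _["mapped"] = out_mapped);
}

// Smith-Waterman local alignment (linear gap cost) with traceback counts
static void sw_local(const std::string &q, const std::string &r, double match,
                     double mismatch, double gap, double &best_score,
                     int &matches, int &columns, int &query_consumed) {
  const int n = (int)q.size(), m = (int)r.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  best_score = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    const char qc = q[i - 1];
    unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      double v = prev[j - 1] + (qc == r[j - 1] ? match : mismatch);
      unsigned char t = 1;
      const double up = prev[j] - gap;
      if (up > v) { v = up; t = 2; }
      const double left = cur[j - 1] - gap;
      if (left > v) { v = left; t = 3; }
      if (v <= 0.0) { v = 0.0; t = 0; }
      cur[j] = v;
      tbrow[j] = t;
      if (v > best_score) { best_score = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  matches = 0; columns = 0; query_consumed = 0;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (t == 0) break;
    if (t == 1) {
      ++columns; ++query_consumed;
      if (q[i - 1] == r[j - 1]) ++matches;
      --i; --j;
    } else if (t == 2) {
      ++columns; ++query_consumed; --i;
    } else {
      ++columns; --j;
    }
  }
}

// [[Rcpp::export]]
DataFrame anib_map_fragments_cpp(std::string reference, CharacterVector fragments,
                                 int k, int band, double match, double mismatch,
                                 double gap) {
  const int m = (int)reference.size();
  KmerIndex idx;
  build_kmer_index(reference, k, idx);

  const int nf = fragments.size();
  NumericVector identity(nf, NA_REAL), aligned_fraction(nf, NA_REAL),
      score(nf, NA_REAL);
  CharacterVector strand(nf, NA_STRING);

  std::unordered_map<int, int> votes;

  for (int fi = 0; fi < nf; ++fi) {
    const std::string fwd = as<std::string>(fragments[fi]);
    const int fl = (int)fwd.size();
    if (fl < k) continue;

    double best_score = -1.0;
    int best_matches = 0, best_cols = 0, best_qcons = 0, best_strand = -1;

    for (int st = 0; st < 2; ++st) {
      const std::string s = st ? revcomp_str(fwd) : fwd;
      votes.clear();
      const int step = std::max(1, k / 2);
      for (int q = 0; q + k <= fl; q += step) {
        uint64_t key;
        if (!kmer_key_at(s, q, k, key)) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        const std::vector<int> &pp = it->second;
        for (size_t z = 0; z < pp.size(); ++z) votes[pp[z] - q]++;
      }
      if (votes.empty()) continue;
      int diag = 0, bestv = -1;
      for (std::unordered_map<int, int>::iterator it = votes.begin();
           it != votes.end(); ++it) {
        if (it->second > bestv ||
            (it->second == bestv && it->first < diag)) {
          bestv = it->second; diag = it->first;
        }
      }
      const int w0 = std::max(0, diag - band);
      const int w1 = std::min(m, diag + fl + band);
      if (w1 - w0 < k) continue;
      double sc; int ma, co, qc;
      sw_local(s, reference.substr(w0, w1 - w0), match, mismatch, gap, sc, ma,
               co, qc);
      if (sc > best_score) {
        best_score = sc; best_matches = ma; best_cols = co; best_qcons = qc;
        best_strand = st;
      }
    }

    if (best_strand >= 0 && best_cols > 0) {
      identity[fi] = 100.0 * best_matches / best_cols;
      aligned_fraction[fi] = (double)best_qcons / fl;
      score[fi] = best_score;
      strand[fi] = best_strand ? "-" : "+";
    }
  }

  return DataFrame::create(_["identity"] = identity,
                           _["aligned_fraction"] = aligned_fraction,
                           _["score"] = score, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
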