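#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int bcode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N and anything else breaks k-mer runs
  }
}

static inline char bcomp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default:  return 0;
  }
}

// [[Rcpp::export(rng = false)]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string o(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) {
      char c = bcomp(s[s.size() - 1 - i]);
      if (c == 0) stop("non-DNA character in sequence");
      o[i] = c;
    }
    out[r] = o;
  }
  return out;
}

// Exact k-mer matches between s1 and s2 (2-bit rolling hash, k <= 31, exact).
// Returns a 2-column matrix of 1-based start positions (pos1, pos2).
// When self = TRUE only matches with pos1 < pos2 are emitted and the trivial
// diagonal is skipped. K-mers occurring more than max_occ times in s1 are
// ignored (low-complexity guard).
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_kmer_matches(const std::string& s1, const std::string& s2,
                               int k, bool self, int max_occ = 100) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0;
  int run = 0;
  for (int p = 0; p < (int)s1.size(); ++p) {
    int c = bcode(s1[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[h].push_back(p - k + 1);
  }
  std::vector<int> o1, o2;
  h = 0; run = 0;
  for (int p = 0; p < (int)s2.size(); ++p) {
    int c = bcode(s2[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(h);
      if (it == idx.end()) continue;
      if ((int)it->second.size() > max_occ) continue;
      int j = p - k + 1;
      for (size_t t = 0; t < it->second.size(); ++t) {
        int i = it->second[t];
        if (self && i >= j) continue;
        o1.push_back(i + 1);
        o2.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(o1.size(), 2);
  for (size_t t = 0; t < o1.size(); ++t) {
    out(t, 0) = o1[t];
    out(t, 1) = o2[t];
  }
  return out;
}

// Ungapped extension of the seeded region s1[i1..i1+len0-1] ~ s2[i2..] in both
// directions with X-drop, followed by trimming: endpoints are pulled back to
// matching positions and shrunk until overall identity >= min_ident.
// Coordinates 1-based; returns ok = FALSE when nothing survives trimming.
// [[Rcpp::export(rng = false)]]
List cpp_extend_seed(const std::string& s1, const std::string& s2,
                     int i1, int i2, int len0, double min_ident,
                     int match, int mismatch, int xdrop) {
  int n1 = s1.size(), n2 = s2.size();
  int a = i1 - 1, b = i2 - 1;
  int e1 = a + len0 - 1, e2 = b + len0 - 1;
  if (a < 0 || b < 0 || e1 >= n1 || e2 >= n2) stop("seed out of range");

  long score = 0, best = 0;
  int bestoff = 0, off = 0;
  while (a - 1 - off >= 0 && b - 1 - off >= 0) {
    score += (s1[a - 1 - off] == s2[b - 1 - off]) ? match : mismatch;
    ++off;
    if (score > best) { best = score; bestoff = off; }
    if (best - score > xdrop) break;
  }
  int S1 = a - bestoff, S2 = b - bestoff;

  score = 0; best = 0; bestoff = 0; off = 0;
  while (e1 + 1 + off < n1 && e2 + 1 + off < n2) {
    score += (s1[e1 + 1 + off] == s2[e2 + 1 + off]) ? match : mismatch;
    ++off;
    if (score > best) { best = score; bestoff = off; }
    if (best - score > xdrop) break;
  }
  int E1 = e1 + bestoff;

  int len = E1 - S1 + 1;
  std::vector<char> ism(len);
  int mm = 0;
  for (int t = 0; t < len; ++t) {
    ism[t] = (s1[S1 + t] == s2[S2 + t]);
    if (!ism[t]) ++mm;
  }
  int lo = 0, hi = len - 1;
  while (lo <= hi && !ism[lo]) { --mm; ++lo; }
  while (hi >= lo && !ism[hi]) { --mm; --hi; }
  while (lo <= hi) {
    int L = hi - lo + 1;
    double ident = (double)(L - mm) / (double)L;
    if (ident >= min_ident) break;
    int dl = -1, dr = -1;
    for (int t = lo; t <= hi; ++t) if (!ism[t]) { dl = t - lo; break; }
    for (int t = hi; t >= lo; --t) if (!ism[t]) { dr = hi - t; break; }
    if (dl < 0) break;
    if (dl <= dr) lo = lo + dl + 1; else hi = hi - dr - 1;
    --mm;
    while (lo <= hi && !ism[lo]) { --mm; ++lo; }
    while (hi >= lo && !ism[hi]) { --mm; --hi; }
  }
  if (lo > hi) return List::create(_["ok"] = false);
  int mmf = 0;
  for (int t = lo; t <= hi; ++t) if (!ism[t]) ++mmf;
  return List::create(
    _["ok"] = true,
    _["start1"] = S1 + lo + 1, _["end1"] = S1 + hi + 1,
    _["start2"] = S2 + lo + 1, _["end2"] = S2 + hi + 1,
    _["mismatches"] = mmf, _["length"] = hi - lo + 1);
}

// Modal diagonal (subject_pos - pattern_pos, 0-based) of exact k-mer matches of
// pattern in subject, with votes summed over a +/- smooth window of diagonals.
// Returns c(diagonal, votes); votes = 0 when no k-mer matches.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_best_diagonal(const std::string& pattern,
                                const std::string& subject,
                                int k, int smooth = 20, int max_occ = 50) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0;
  int run = 0;
  for (int p = 0; p < (int)pattern.size(); ++p) {
    int c = bcode(pattern[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[h].push_back(p - k + 1);
  }
  std::unordered_map<int, int> diags;
  h = 0; run = 0;
  for (int p = 0; p < (int)subject.size(); ++p) {
    int c = bcode(subject[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(h);
      if (it == idx.end()) continue;
      if ((int)it->second.size() > max_occ) continue;
      int j = p - k + 1;
      for (size_t t = 0; t < it->second.size(); ++t)
        diags[j - it->second[t]] += 1;
    }
  }
  int bestd = 0, bestv = 0;
  for (std::unordered_map<int, int>::iterator it = diags.begin();
       it != diags.end(); ++it) {
    int v = 0;
    for (int d = it->first - smooth; d <= it->first + smooth; ++d) {
      std::unordered_map<int, int>::iterator jt = diags.find(d);
      if (jt != diags.end()) v += jt->second;
    }
    if (v > bestv || (v == bestv && it->first < bestd)) {
      bestv = v;
      bestd = it->first;
    }
  }
  IntegerVector out(2);
  out[0] = bestd; out[1] = bestv;
  return out;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void build_kmer_index(KmerIndex& idx, const std::string& s, int k) {
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0;
  int run = 0;
  for (int p = 0; p < (int)s.size(); ++p) {
    int c = bcode(s[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[h].push_back(p - k + 1);
  }
}

// Persistent k-mer index over a pattern, for repeated diagonal queries.
// [[Rcpp::export(rng = false)]]
SEXP cpp_kmer_index(const std::string& pattern, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  XPtr<KmerIndex> ptr(new KmerIndex(), true);
  build_kmer_index(*ptr, pattern, k);
  return ptr;
}

// As cpp_best_diagonal but against a prebuilt index of the pattern.
// [[Rcpp::export(rng = false)]]
IntegerVector cpp_best_diagonal_idx(SEXP index, const std::string& subject,
                                    int k, int smooth = 20, int max_occ = 50) {
  XPtr<KmerIndex> idx(index);
  std::unordered_map<int, int> diags;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0;
  int run = 0;
  for (int p = 0; p < (int)subject.size(); ++p) {
    int c = bcode(subject[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      KmerIndex::iterator it = idx->find(h);
      if (it == idx->end()) continue;
      if ((int)it->second.size() > max_occ) continue;
      int j = p - k + 1;
      for (size_t t = 0; t < it->second.size(); ++t)
        diags[j - it->second[t]] += 1;
    }
  }
  int bestd = 0, bestv = 0;
  for (std::unordered_map<int, int>::iterator it = diags.begin();
       it != diags.end(); ++it) {
    int v = 0;
    for (int d = it->first - smooth; d <= it->first + smooth; ++d) {
      std::unordered_map<int, int>::iterator jt = diags.find(d);
      if (jt != diags.end()) v += jt->second;
    }
    if (v > bestv || (v == bestv && it->first < bestd)) {
      bestv = v;
      bestd = it->first;
    }
  }
  IntegerVector out(2);
  out[0] = bestd; out[1] = bestv;
  return out;
}

// Banded semi-global edit distance: pattern aligned globally, subject ends
// free. `slack` bounds the deviation of the alignment diagonal from the
// [0, n - m] corridor. Returns the minimum edit distance (or a large value
// when no in-band alignment exists).
// [[Rcpp::export(rng = false)]]
int cpp_banded_semiglobal(const std::string& pattern,
                          const std::string& subject, int slack) {
  const int INF = 100000000;
  int m = pattern.size(), n = subject.size();
  if (m == 0) return 0;
  if (n == 0) return m;
  // cells stored per diagonal offset: (i, j) lives at t = j - i - lo + 1,
  // with lo/hi bounding j - i; sentinel columns 0 and w + 1 stay INF
  int lo = -slack;
  int hi = (n - m) + slack;
  if (hi < lo) { int t = lo; lo = hi; hi = t; }
  int w = hi - lo + 1;
  std::vector<int> prev(w + 2, INF), cur(w + 2, INF);
  for (int t = 1; t <= w; ++t) {
    int j = lo + t - 1;
    prev[t] = (j >= 0 && j <= n) ? 0 : INF;  // free subject prefix
  }
  for (int i = 1; i <= m; ++i) {
    char pc = pattern[i - 1];
    int jbase = i + lo;  // j at t = 1
    int tmin = std::max(1, 1 - jbase);          // j >= 0
    int tmax = std::min(w, n - jbase + 1);      // j <= n
    if (tmin > tmax) return INF;
    for (int t = 1; t < tmin; ++t) cur[t] = INF;
    for (int t = tmax + 1; t <= w; ++t) cur[t] = INF;
    int t = tmin;
    if (jbase + t - 1 == 0) {  // j == 0: deletions only
      cur[t] = prev[t + 1] + 1;
      ++t;
    }
    const char* sub = subject.c_str();
    for (; t <= tmax; ++t) {
      int v = prev[t] + (pc == sub[jbase + t - 2] ? 0 : 1);
      int up = prev[t + 1] + 1;
      if (up < v) v = up;
      int left = cur[t - 1] + 1;
      if (left < v) v = left;
      cur[t] = v;
    }
    std::swap(prev, cur);
  }
  int best = INF;
  int jbase = m + lo;
  for (int t = 1; t <= w; ++t) {
    int j = jbase + t - 1;
    if (j >= 0 && j <= n && prev[t] < best) best = prev[t];
  }
  return best;
}

// Apply a nanopore-like error model (substitutions / insertions / deletions at
// the given per-base rates) to each sequence. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector seqs, double sub, double ins,
                                 double del) {
  static const char* bases = "ACGT";
  int n = seqs.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string o;
    o.reserve((size_t)(s.size() * 1.1) + 8);
    for (size_t i = 0; i < s.size(); ++i) {
      double u = unif_rand();
      if (u < sub) {
        int ci = bcode(s[i]);
        int alt = (int)(unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        o.push_back(ci < 0 ? 'N' : bases[(ci + 1 + alt) % 4]);
      } else if (u < sub + ins) {
        o.push_back(s[i]);
        int nb = (int)(unif_rand() * 4.0);
        if (nb > 3) nb = 3;
        o.push_back(bases[nb]);
      } else if (u < sub + ins + del) {
        // deleted
      } else {
        o.push_back(s[i]);
      }
    }
    out[r] = o;
  }
  return out;
}
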