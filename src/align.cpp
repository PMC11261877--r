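#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Banded ends-free (overlap) pairwise alignment with linear gap penalties.
//
// Terminal gaps are free and are not part of the reported alignment: the
// returned aligned strings cover only the aligned core, so identity computed
// as matches / columns excludes terminal-gap columns by construction.
//
// band < 0 disables banding (full dynamic programme). Otherwise cells are
// restricted to diagonals j - i in [min(0, m-n) - band, max(0, m-n) + band],
// which covers the corridor between the main diagonals of the two sequence
// ends; high-identity alignments never leave it for band >> expected indels.
//
// Tie-breaking is fixed (diagonal > up > left; end cell scanned from the
// bottom-right corner outward) so results are deterministic.
// [[Rcpp::export]]
List align_overlap_cpp(std::string a, std::string b,
                       int match, int mismatch, int gap, int band) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  const long NEG = -1000000000L;

  int lo, hi;
  if (band < 0 || band >= std::max(n, m)) {
    lo = -n;
    hi = m;
  } else {
    lo = std::min(0, m - n) - band;
    hi = std::max(0, m - n) + band;
    if (lo < -n) lo = -n;
    if (hi > m) hi = m;
  }
  const int W = hi - lo + 1;

  std::vector<long> H((size_t)(n + 1) * W, NEG);
  std::vector<unsigned char> TB((size_t)(n + 1) * W, 0);
  // TB codes: 0 = origin (free start), 1 = diagonal, 2 = up (gap in b),
  //           3 = left (gap in a)

  auto idx = [&](int i, int j) { return (size_t)i * W + (size_t)(j - i - lo); };
  auto inband = [&](int i, int j) {
    int d = j - i;
    return d >= lo && d <= hi;
  };

  for (int j = 0; j <= m; ++j) if (inband(0, j)) H[idx(0, j)] = 0;
  for (int i = 0; i <= n; ++i) if (inband(i, 0)) H[idx(i, 0)] = 0;

  for (int i = 1; i <= n; ++i) {
    int jmin = std::max(1, i + lo);
    int jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      long best = NEG;
      unsigned char t = 0;
      if (inband(i - 1, j - 1) && H[idx(i - 1, j - 1)] > NEG) {
        long s = H[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
        if (s > best) { best = s; t = 1; }
      }
      if (inband(i - 1, j) && H[idx(i - 1, j)] > NEG) {
        long s = H[idx(i - 1, j)] + gap;
        if (s > best) { best = s; t = 2; }
      }
      if (inband(i, j - 1) && H[idx(i, j - 1)] > NEG) {
        long s = H[idx(i, j - 1)] + gap;
        if (s > best) { best = s; t = 3; }
      }
      if (t != 0 && best > H[idx(i, j)]) {
        H[idx(i, j)] = best;
        TB[idx(i, j)] = t;
      }
    }
  }

  // Best end cell over last row / last column (free trailing gaps); scan
  // from (n, m) outward with strict improvement so ties resolve nearest the
  // corner.
  long best = NEG;
  int bi = -1, bj = -1;
  for (int i = n; i >= 0; --i) {
    if (inband(i, m) && H[idx(i, m)] > best) { best = H[idx(i, m)]; bi = i; bj = m; }
  }
  for (int j = m; j >= 0; --j) {
    if (inband(n, j) && H[idx(n, j)] > best) { best = H[idx(n, j)]; bi = n; bj = j; }
  }

  std::string aa, bb;
  long matches = 0, cols = 0;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    unsigned char t = TB[idx(i, j)];
    if (t == 0) break;
    if (t == 1) {
      aa.push_back(a[i - 1]);
      bb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (t == 2) {
      aa.push_back(a[i - 1]);
      bb.push_back('-');
      --i;
    } else {
      aa.push_back('-');
      bb.push_back(b[j - 1]);
      --j;
    }
    ++cols;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  double identity = cols > 0 ? 100.0 * (double)matches / (double)cols : 0.0;

  return List::create(
    _["a_aln"] = aa,
    _["b_aln"] = bb,
    _["score"] = (double)best,
    _["matches"] = (double)matches,
    _["columns"] = (double)cols,
    _["identity"] = identity,
    _["a_start"] = i,   // 0-based start of aligned core in a
    _["b_start"] = j
  );
}

static void encode_kmers(const std::string &s, int k,
                         std::vector<int> &out) {
  unsigned int code = 0, mask = (1u << (2 * k)) - 1u;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: v = -1;
    }
    if (v < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (unsigned int)v) & mask;
    if (++run >= k) out.push_back((int)code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// Sorted distinct k-mer codes of a sequence (k <= 15); cache these per
// centroid so repeated prescreens avoid re-sorting.
// [[Rcpp::export]]
IntegerVector kmer_set_cpp(std::string s, int k) {
  std::vector<int> v;
  encode_kmers(s, k, v);
  return wrap(v);
}

// Containment of sorted k-mer set `q` in sorted set `s`.
// [[Rcpp::export]]
double kmer_containment_sorted_cpp(IntegerVector q, IntegerVector s) {
  if (q.size() == 0) return 0.0;
  R_xlen_t i = 0, j = 0, shared = 0;
  while (i < q.size() && j < s.size()) {
    if (q[i] == s[j]) { ++shared; ++i; ++j; }
    else if (q[i] < s[j]) ++i;
    else ++j;
  }
  return (double)shared / (double)q.size();
}

// Count of distinct k-mers of `query` also present in `subject`, divided by
// the number of distinct k-mers of `query`. Cheap prescreen for the greedy
// clusterer: pairs below a containment cutoff cannot reach a high identity
// threshold and are skipped without alignment.
// [[Rcpp::export]]
double kmer_containment_cpp(std::string query, std::string subject, int k) {
  int nq = (int) query.size(), ns = (int) subject.size();
  if (nq < k || ns < k) return 0.0;
  auto encode = [&](const std::string &s, std::vector<unsigned int> &out) {
    unsigned int code = 0, mask = (1u << (2 * k)) - 1u;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int v;
      switch (s[i]) {
        case 'A': v = 0; break;
        case 'C': v = 1; break;
        case 'G': v = 2; break;
        case 'T': v = 3; break;
        default: v = -1;
      }
      if (v < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (unsigned int)v) & mask;
      if (++run >= k) out.push_back(code);
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  };
  std::vector<unsigned int> kq, ks;
  encode(query, kq);
  encode(subject, ks);
  if (kq.empty()) return 0.0;
  size_t i = 0, j = 0, shared = 0;
  while (i < kq.size() && j < ks.size()) {
    if (kq[i] == ks[j]) { ++shared; ++i; ++j; }
    else if (kq[i] < ks[j]) ++i;
    else ++j;
  }
  return (double)shared / (double)kq.size();
}
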