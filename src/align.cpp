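#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Banded global alignment with affine gaps (Gotoh, three states).
// A gap of length L costs gap_open + gap_ext * L, i.e. opening a gap
// charges gap_open + gap_ext for its first base.  This matches the
// Biostrings::pairwiseAlignment() convention so the two can be compared
// column for column on the same scoring scheme.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b,
                  int match = 1, int mismatch = -1,
                  int gap_open = 2, int gap_ext = 1,
                  int band = 0, bool free_b_ends = false) {
  const long n = (long)a.size();
  const long m = (long)b.size();

  if (n == 0 || m == 0) {
    std::string ga(m, '-'), gb(n, '-');
    return List::create(_["a"] = a + ga, _["b"] = gb + b,
                        _["score"] = NA_INTEGER);
  }

  if (band <= 0) band = 32;
  long dlo = std::min(0L, m - n) - band;
  long dhi = std::max(0L, m - n) + band;
  if (dlo < -n) dlo = -n;
  if (dhi > m) dhi = m;
  const long W = dhi - dlo + 1;

  // scores: two rolling rows per state; traceback: full byte matrices
  std::vector<int> Mprev(W, NEG), Xprev(W, NEG), Yprev(W, NEG);
  std::vector<int> Mcur(W, NEG), Xcur(W, NEG), Ycur(W, NEG);
  // traceback codes: predecessor state 0=M,1=X,2=Y; 3 = boundary/none
  std::vector<uint8_t> tbM((n + 1) * W, 3), tbX((n + 1) * W, 3),
      tbY((n + 1) * W, 3);

  // row i = 0
  {
    long k0 = 0 - 0 - dlo;  // j = 0
    if (k0 >= 0 && k0 < W) Mprev[k0] = 0;
    for (long j = 1; j <= m; ++j) {
      long k = j - dlo;
      if (k < 0 || k >= W) break;
      Yprev[k] = free_b_ends ? 0 : -(gap_open + gap_ext * (int)j);
      tbY[0 * W + k] = (j == 1) ? 0 : 2;
    }
  }

  for (long i = 1; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG);
    std::fill(Xcur.begin(), Xcur.end(), NEG);
    std::fill(Ycur.begin(), Ycur.end(), NEG);
    long jlo = std::max(0L, i + dlo);
    long jhi = std::min(m, i + dhi);
    for (long j = jlo; j <= jhi; ++j) {
      long k = j - i - dlo;
      uint8_t *tM = &tbM[i * W + k], *tX = &tbX[i * W + k],
              *tY = &tbY[i * W + k];
      if (j == 0) {
        Xcur[k] = -(gap_open + gap_ext * (int)i);
        *tX = (i == 1) ? 0 : 1;
        continue;
      }
      // M state: diagonal, same k in previous row
      {
        int best = Mprev[k]; uint8_t from = 0;
        if (Xprev[k] > best) { best = Xprev[k]; from = 1; }
        if (Yprev[k] > best) { best = Yprev[k]; from = 2; }
        if (best > NEG) {
          char ca = a[i - 1], cb = b[j - 1];
          int s = (ca == cb) ? match : mismatch;
          Mcur[k] = best + s;
          *tM = from;
        }
      }
      // X state: gap in b (consume a[i-1]); from (i-1, j) = prev row, k+1
      if (k + 1 < W) {
        int vm = (Mprev[k + 1] > NEG) ? Mprev[k + 1] - gap_open - gap_ext : NEG;
        int vx = (Xprev[k + 1] > NEG) ? Xprev[k + 1] - gap_ext : NEG;
        int vy = (Yprev[k + 1] > NEG) ? Yprev[k + 1] - gap_open - gap_ext : NEG;
        int best = vm; uint8_t from = 0;
        if (vx > best) { best = vx; from = 1; }
        if (vy > best) { best = vy; from = 2; }
        if (best > NEG) { Xcur[k] = best; *tX = from; }
      }
      // Y state: gap in a (consume b[j-1]); from (i, j-1) = same row, k-1
      if (k - 1 >= 0) {
        int vm = (Mcur[k - 1] > NEG) ? Mcur[k - 1] - gap_open - gap_ext : NEG;
        int vx = (Xcur[k - 1] > NEG) ? Xcur[k - 1] - gap_open - gap_ext : NEG;
        int vy = (Ycur[k - 1] > NEG) ? Ycur[k - 1] - gap_ext : NEG;
        int best = vm; uint8_t from = 0;
        if (vx > best) { best = vx; from = 1; }
        if (vy > best) { best = vy; from = 2; }
        if (best > NEG) { Ycur[k] = best; *tY = from; }
      }
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  long kend = m - n - dlo;
  long jend = m;
  int best = NEG; uint8_t state = 0;
  if (free_b_ends) {
    // trailing subject gaps are free: best cell anywhere in last row
    long jlo = std::max(0L, n + dlo);
    long jhi = std::min(m, n + dhi);
    for (long j = jlo; j <= jhi; ++j) {
      long k = j - n - dlo;
      if (Mprev[k] > best) { best = Mprev[k]; state = 0; jend = j; }
      if (Xprev[k] > best) { best = Xprev[k]; state = 1; jend = j; }
      if (Yprev[k] > best) { best = Yprev[k]; state = 2; jend = j; }
    }
  } else {
    if (kend < 0 || kend >= W)
      stop("band too narrow for sequence length difference");
    best = Mprev[kend]; state = 0;
    if (Xprev[kend] > best) { best = Xprev[kend]; state = 1; }
    if (Yprev[kend] > best) { best = Yprev[kend]; state = 2; }
  }
  if (best <= NEG)
    stop("no alignment found within band; increase band width");

  // traceback
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  long i = n, j = jend;
  for (long jj = m; jj > jend; --jj) {  // free trailing subject bases
    ga.push_back('-'); gb.push_back(b[jj - 1]);
  }
  while (i > 0 || j > 0) {
    long k = j - i - dlo;
    uint8_t from;
    if (state == 0) {
      from = tbM[i * W + k];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      from = tbX[i * W + k];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i;
    } else {
      from = tbY[i * W + k];
      ga.push_back('-');
      gb.push_back(b[j - 1]);
      --j;
    }
    if (i == 0 && j == 0) break;
    state = from;
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = best);
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

static void kmer_positions(const std::string &s, int k,
                           std::unordered_map<uint64_t, long> &map) {
  // value = 0-based position of the unique occurrence, or -1 if repeated
  const long n = (long)s.size();
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0;
  int valid = 0;
  for (long i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      long pos = i - k + 1;
      auto it = map.find(kmer);
      if (it == map.end()) map.emplace(kmer, pos);
      else it->second = -1;
    }
  }
}

// Maximal runs of k-mers unique in both sequences and matching at
// consistent offsets; returned as a matrix [q0, s0, len] (0-based).
// [[Rcpp::export]]
IntegerMatrix cpp_find_anchors(std::string q, std::string s, int k = 15) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::unordered_map<uint64_t, long> mq, ms;
  kmer_positions(q, k, mq);
  kmer_positions(s, k, ms);

  std::vector<std::pair<long, long>> hits;
  for (auto &kv : mq) {
    if (kv.second < 0) continue;
    auto it = ms.find(kv.first);
    if (it == ms.end() || it->second < 0) continue;
    hits.emplace_back(kv.second, it->second);
  }
  std::sort(hits.begin(), hits.end());

  std::vector<long> q0, s0, len;
  for (size_t i = 0; i < hits.size(); ++i) {
    if (!q0.empty() &&
        hits[i].first == q0.back() + len.back() - k + 1 &&
        hits[i].second - hits[i].first == s0.back() - q0.back()) {
      len.back() += 1;  // extend run by one base
    } else {
      q0.push_back(hits[i].first);
      s0.push_back(hits[i].second);
      len.push_back(k);
    }
  }
  IntegerMatrix out(q0.size(), 3);
  for (size_t i = 0; i < q0.size(); ++i) {
    out(i, 0) = (int)q0[i];
    out(i, 1) = (int)s0[i];
    out(i, 2) = (int)len[i];
  }
  colnames(out) = CharacterVector::create("q0", "s0", "len");
  return out;
}
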