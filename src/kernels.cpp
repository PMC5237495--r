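#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Blockwise q-gram rotation search.
//
// Scans all m rotations of x against fixed y. Both strings are partitioned
// into beta blocks by the floor partition; per block we keep the signed
// q-gram count difference (x-block minus y-block) in a hash map together with
// the running L1 norm. Advancing the rotation by one shifts every x-block
// window one position to the right (circularly), so exactly one q-gram leaves
// and one enters per block: O(beta * q) work per rotation.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_best_rotation(std::string x, std::string y, int beta, int q) {
  const long long m = (long long)x.size(), n = (long long)y.size();
  if (m < q || n < q) stop("strings shorter than q");
  if (beta < 1) stop("beta must be >= 1");

  int code[256];
  std::fill(code, code + 256, -1);
  int sigma = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    unsigned char c = x[i];
    if (code[c] < 0) code[c] = sigma++;
  }
  for (size_t i = 0; i < y.size(); ++i) {
    unsigned char c = y[i];
    if (code[c] < 0) code[c] = sigma++;
  }
  if (q * std::log2((double)std::max(sigma, 2)) > 61.0)
    stop("q too large for this alphabet");

  std::vector<long long> bx(beta + 1), by(beta + 1);
  for (int j = 0; j <= beta; ++j) {
    bx[j] = (long long)j * m / beta;
    by[j] = (long long)j * n / beta;
  }
  for (int j = 0; j < beta; ++j)
    if (bx[j + 1] - bx[j] < q || by[j + 1] - by[j] < q)
      stop("a block is shorter than q");

  std::vector< std::unordered_map<uint64_t, int> > cnt(beta);
  long long total = 0;

  auto upd = [&](int j, uint64_t v, int delta) {
    std::unordered_map<uint64_t, int> &mp = cnt[j];
    std::unordered_map<uint64_t, int>::iterator it = mp.find(v);
    int c = (it == mp.end()) ? 0 : it->second;
    total -= std::llabs((long long)c);
    c += delta;
    total += std::llabs((long long)c);
    if (c == 0) {
      if (it != mp.end()) mp.erase(it);
    } else if (it != mp.end()) {
      it->second = c;
    } else {
      mp.emplace(v, c);
    }
  };
  auto gramX = [&](long long s) {
    uint64_t v = 0;
    for (int t = 0; t < q; ++t)
      v = v * (uint64_t)sigma + (uint64_t)code[(unsigned char)x[(s + t) % m]];
    return v;
  };
  auto gramY = [&](long long s) {
    uint64_t v = 0;
    for (int t = 0; t < q; ++t)
      v = v * (uint64_t)sigma + (uint64_t)code[(unsigned char)y[s + t]];
    return v;
  };

  for (int j = 0; j < beta; ++j) {
    for (long long s = bx[j]; s <= bx[j + 1] - q; ++s) upd(j, gramX(s), +1);
    for (long long s = by[j]; s <= by[j + 1] - q; ++s) upd(j, gramY(s), -1);
  }

  long long best = total;
  long long bestR = 0;
  for (long long r = 1; r < m; ++r) {
    for (int j = 0; j < beta; ++j) {
      long long lx = bx[j + 1] - bx[j];
      upd(j, gramX((r - 1 + bx[j]) % m), -1);          // q-gram leaving
      upd(j, gramX((r + bx[j] + lx - q) % m), +1);     // q-gram entering
    }
    if (total < best) { best = total; bestR = r; }
  }
  return List::create(Named("r") = (int)bestR,
                      Named("distance") = (double)best);
}

// ---------------------------------------------------------------------------
// Unit-cost edit distance: Myers bit-vector algorithm, blocked for strings
// longer than the 64-bit machine word.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_edit_myers(std::string a, std::string b) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  const int W = 64;
  const int nb = (m + W - 1) / W;

  std::vector<uint64_t> Peq((size_t)256 * nb, 0);
  for (int i = 0; i < m; ++i)
    Peq[(size_t)(unsigned char)a[i] * nb + i / W] |= 1ULL << (i % W);

  std::vector<uint64_t> Pv(nb, ~0ULL), Mv(nb, 0ULL);
  long long score = m;
  const uint64_t hbLast = 1ULL << ((m - 1) % W);

  for (int j = 0; j < n; ++j) {
    const unsigned char c = b[j];
    int hin = 1;  // top boundary row of the global DP: D[0][j] = j
    for (int blk = 0; blk < nb; ++blk) {
      uint64_t Pv0 = Pv[blk], Mv0 = Mv[blk];
      uint64_t Eq = Peq[(size_t)c * nb + blk];
      const uint64_t Xv = Eq | Mv0;
      if (hin < 0) Eq |= 1ULL;
      const uint64_t Xh = (((Eq & Pv0) + Pv0) ^ Pv0) | Eq;
      uint64_t Ph = Mv0 | ~(Xh | Pv0);
      uint64_t Mh = Pv0 & Xh;
      const uint64_t HB = (blk == nb - 1) ? hbLast : (1ULL << 63);
      int hout = 0;
      if (Ph & HB) hout = 1;
      else if (Mh & HB) hout = -1;
      Ph <<= 1; Mh <<= 1;
      if (hin < 0) Mh |= 1ULL;
      else if (hin > 0) Ph |= 1ULL;
      Pv[blk] = Mh | ~(Xv | Ph);
      Mv[blk] = Ph & Xv;
      hin = hout;
      if (blk == nb - 1) score += hout;
    }
  }
  return (double)score;
}

// ---------------------------------------------------------------------------
// Weighted edit distance: textbook dynamic programme with configurable
// substitution and indel costs (matches cost 0).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_edit_dp(std::string a, std::string b, double subCost,
                   double indelCost) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j * indelCost;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * indelCost;
    for (int j = 1; j <= n; ++j) {
      double d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : subCost);
      double v = prev[j] + indelCost;
      double h = cur[j - 1] + indelCost;
      cur[j] = std::min(d, std::min(v, h));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// ---------------------------------------------------------------------------
// Global alignment score with affine gaps (Gotoh), score only. A gap of
// length k costs gapOpen + k * gapExtend (both <= 0). Sequences arrive as
// 0-based integer codes indexing the similarity matrix.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_gotoh_score(IntegerVector a, IntegerVector b, NumericMatrix sim,
                       double gapOpen, double gapExtend) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  // rolling rows: S = previous row of best scores, Ix = previous row of the
  // "gap in b" state (vertical), Iy tracked along the current row.
  std::vector<double> Sprev(n + 1), Scur(n + 1), IxPrev(n + 1), IxCur(n + 1);
  Sprev[0] = 0.0;
  IxPrev[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    Sprev[j] = gapOpen + j * gapExtend;
    IxPrev[j] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    IxCur[0] = gapOpen + i * gapExtend;
    Scur[0] = IxCur[0];
    double Iy = NEG;
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const double ix = std::max(Sprev[j] + gapOpen + gapExtend,
                                 IxPrev[j] + gapExtend);
      Iy = std::max(Scur[j - 1] + gapOpen + gapExtend, Iy + gapExtend);
      const double diag = Sprev[j - 1] + sim(ai, b[j - 1]);
      double s = diag;
      if (ix > s) s = ix;
      if (Iy > s) s = Iy;
      IxCur[j] = ix;
      Scur[j] = s;
    }
    std::swap(Sprev, Scur);
    std::swap(IxPrev, IxCur);
  }
  return Sprev[n];
}

// ---------------------------------------------------------------------------
// Profile-profile global alignment on a precomputed column-pair score matrix
// p (nA x nB). Linear mode: gap columns cost gA (gap inserted into profile A,
// i.e. a B column consumed alone) or gB (gap into B) per column, the literal
// profile recurrence. Affine mode: Gotoh states with open gA/gB and extend
// eA/eB. Returns the score and, unless scoreOnly, the forward list of moves:
// 1 = both advance (column pairing), 2 = A column against gap inserted into
// B, 3 = B column against gap inserted into A.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix p, double gA, double gB, bool affine,
                       double eA, double eB, bool scoreOnly) {
  const int nA = p.nrow(), nB = p.ncol();
  const double NEG = -1e30;
  const size_t sz = (size_t)(nA + 1) * (nB + 1);
  std::vector<double> S(sz);
  std::vector<uint8_t> ptrS, ptrX, ptrY;
  std::vector<double> Ix, Iy;
  if (!scoreOnly) ptrS.resize(sz);
  auto at = [nB](int i, int j) { return (size_t)i * (nB + 1) + j; };

  if (!affine) {
    S[at(0, 0)] = 0.0;
    for (int i = 1; i <= nA; ++i) {
      S[at(i, 0)] = i * gB;
      if (!scoreOnly) ptrS[at(i, 0)] = 2;
    }
    for (int j = 1; j <= nB; ++j) {
      S[at(0, j)] = j * gA;
      if (!scoreOnly) ptrS[at(0, j)] = 3;
    }
    for (int i = 1; i <= nA; ++i) {
      for (int j = 1; j <= nB; ++j) {
        const double diag = S[at(i - 1, j - 1)] + p(i - 1, j - 1);
        const double up = S[at(i - 1, j)] + gB;
        const double left = S[at(i, j - 1)] + gA;
        double s = diag;
        uint8_t c = 1;
        if (up > s) { s = up; c = 2; }
        if (left > s) { s = left; c = 3; }
        S[at(i, j)] = s;
        if (!scoreOnly) ptrS[at(i, j)] = c;
      }
    }
    if (scoreOnly)
      return List::create(Named("score") = S[at(nA, nB)]);
    // traceback
    std::vector<int> ops;
    ops.reserve(nA + nB);
    int i = nA, j = nB;
    while (i > 0 || j > 0) {
      uint8_t c = ptrS[at(i, j)];
      ops.push_back(c);
      if (c == 1) { --i; --j; }
      else if (c == 2) { --i; }
      else { --j; }
    }
    std::reverse(ops.begin(), ops.end());
    return List::create(Named("score") = S[at(nA, nB)],
                        Named("ops") = wrap(ops));
  }

  // affine (Gotoh) mode
  Ix.resize(sz); Iy.resize(sz);
  if (!scoreOnly) { ptrX.resize(sz); ptrY.resize(sz); }
  S[at(0, 0)] = 0.0; Ix[at(0, 0)] = NEG; Iy[at(0, 0)] = NEG;
  for (int i = 1; i <= nA; ++i) {
    Ix[at(i, 0)] = gB + i * eB;
    S[at(i, 0)] = Ix[at(i, 0)];
    Iy[at(i, 0)] = NEG;
    if (!scoreOnly) { ptrS[at(i, 0)] = 2; ptrX[at(i, 0)] = (i == 1) ? 0 : 1; }
  }
  for (int j = 1; j <= nB; ++j) {
    Iy[at(0, j)] = gA + j * eA;
    S[at(0, j)] = Iy[at(0, j)];
    Ix[at(0, j)] = NEG;
    if (!scoreOnly) { ptrS[at(0, j)] = 3; ptrY[at(0, j)] = (j == 1) ? 0 : 1; }
  }
  for (int i = 1; i <= nA; ++i) {
    for (int j = 1; j <= nB; ++j) {
      const double openX = S[at(i - 1, j)] + gB + eB;
      const double extX = Ix[at(i - 1, j)] + eB;
      const double ix = std::max(openX, extX);
      const double openY = S[at(i, j - 1)] + gA + eA;
      const double extY = Iy[at(i, j - 1)] + eA;
      const double iy = std::max(openY, extY);
      const double diag = S[at(i - 1, j - 1)] + p(i - 1, j - 1);
      double s = diag;
      uint8_t c = 1;
      if (ix > s) { s = ix; c = 2; }
      if (iy > s) { s = iy; c = 3; }
      S[at(i, j)] = s; Ix[at(i, j)] = ix; Iy[at(i, j)] = iy;
      if (!scoreOnly) {
        ptrS[at(i, j)] = c;
        ptrX[at(i, j)] = (openX >= extX) ? 0 : 1;
        ptrY[at(i, j)] = (openY >= extY) ? 0 : 1;
      }
    }
  }
  if (scoreOnly)
    return List::create(Named("score") = S[at(nA, nB)]);
  std::vector<int> ops;
  ops.reserve(nA + nB);
  int i = nA, j = nB;
  int state = 0;  // 0 = S, 1 = Ix, 2 = Iy
  while (i > 0 || j > 0) {
    if (state == 0) {
      uint8_t c = ptrS[at(i, j)];
      if (c == 1) { ops.push_back(1); --i; --j; }
      else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back(2);
      uint8_t c = ptrX[at(i, j)];
      --i;
      if (c == 0) state = 0;
    } else {
      ops.push_back(3);
      uint8_t c = ptrY[at(i, j)];
      --j;
      if (c == 0) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(Named("score") = S[at(nA, nB)],
                      Named("ops") = wrap(ops));
}
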