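// Banded CYK for covariance-model search.
//
// States are numbered in guide-tree preorder, so every transition goes to a
// higher state index (inserts self-loop, handled by iterating d upward).
// alpha[v][j][d] is the best bit score of state v generating the subsequence
// of length d ending at 1-based position j. Length bands per state come from
// the consensus span of the state's subtree plus configurable slack.
//
// Type codes: 0=S 1=D 2=E 3=ML 4=MR 5=MP 6=IL 7=IR 8=B

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cfloat>
using namespace Rcpp;

static const double NEG = -1e30;

struct CM {
  int S;
  const int *type, *cOff, *cN, *cIdx, *bL, *bR, *dmin, *dmax;
  const double *cSc, *escS, *escP;
};

static inline double escSinglet(const CM &cm, int v, int x) {
  if (x >= 4) return 0.0;                   // N at null
  return cm.escS[v * 4 + x];
}
static inline double escPair(const CM &cm, int v, int xl, int xr) {
  if (xl >= 4 || xr >= 4) return 0.0;
  return cm.escP[v * 16 + xl * 4 + xr];
}

// ragged alpha indexing
template <typename T>
struct Alpha {
  std::vector<T> a;
  std::vector<size_t> off;
  std::vector<int> dmin, dmax, w;
  int L;
  void init(const CM &cm, int L_) {
    L = L_;
    off.resize(cm.S); dmin.resize(cm.S); dmax.resize(cm.S); w.resize(cm.S);
    size_t tot = 0;
    for (int v = 0; v < cm.S; ++v) {
      dmin[v] = cm.dmin[v]; dmax[v] = cm.dmax[v];
      w[v] = dmax[v] - dmin[v] + 1;
      off[v] = tot;
      tot += (size_t)w[v] * (L + 1);
    }
    a.assign(tot, (T)NEG);
  }
  inline double get(int v, int j, int d) const {
    if (d < dmin[v] || d > dmax[v]) return NEG;
    return a[off[v] + (size_t)j * w[v] + (d - dmin[v])];
  }
  inline void set(int v, int j, int d, double val) {
    a[off[v] + (size_t)j * w[v] + (d - dmin[v])] = (T)val;
  }
};

template <typename T>
static void fill(const CM &cm, Alpha<T> &A, const int *x, int L) {
  A.init(cm, L);
  std::vector<T> buf;
  for (int j = 0; j <= L; ++j) {
    for (int v = cm.S - 1; v >= 0; --v) {
      int t = cm.type[v];
      int lo = A.dmin[v], hi = std::min(A.dmax[v], j);
      if (lo > hi) continue;
      T *row = &A.a[A.off[v] + (size_t)j * A.w[v]];
      if (t == 2) {                         // E: d == 0 only
        if (lo == 0) row[0] = 0.0;
        continue;
      }
      if (t == 8) {                         // B
        int lv = cm.bL[v], rv = cm.bR[v];
        for (int d = lo; d <= hi; ++d) {
          double best = NEG;
          int d2lo = std::max(A.dmin[rv], d - std::min(A.dmax[lv], j - 0));
          int d2hi = std::min(d - A.dmin[lv], A.dmax[rv]);
          for (int d2 = std::max(0, d2lo); d2 <= d2hi; ++d2) {
            int dl = d - d2;
            if (dl > j - d2) continue;      // left part cannot reach past 1
            double s = A.get(lv, j - d2, dl) + A.get(rv, j, d2);
            if (s > best) best = s;
          }
          if (best > NEG / 2) row[d - lo + (lo - A.dmin[v])] = best;
        }
        continue;
      }
      // emission-dependent offsets: delta = consumed length, jc = child j
      int delta, jc;
      bool pairEmit = false, leftEmit = false, rightEmit = false;
      if (t == 0 || t == 1) { delta = 0; jc = j; }
      else if (t == 3 || t == 6) { delta = 1; jc = j; leftEmit = true; }
      else if (t == 4 || t == 7) { delta = 1; jc = j - 1; rightEmit = true; }
      else { delta = 2; jc = j - 1; pairEmit = true; }
      if (jc < 0) continue;
      int dlo = std::max(lo, delta), dhi = hi;
      if (dlo > dhi) continue;
      buf.assign(dhi - dlo + 1, (T)NEG);
      double selfTs = NEG;                  // IL self-loop (same j, d-1)
      for (int k = 0; k < cm.cN[v]; ++k) {
        int y = cm.cIdx[cm.cOff[v] + k];
        double ts = cm.cSc[cm.cOff[v] + k];
        if (y == v && leftEmit) { selfTs = ts; continue; }
        const T *crow = &A.a[A.off[y] + (size_t)jc * A.w[y]];
        T tsT = (T)ts;
        int cdlo = std::max(dlo, A.dmin[y] + delta);
        int cdhi = std::min(dhi, A.dmax[y] + delta);
        const T *src = crow + (cdlo - delta - A.dmin[y]);
        T *dst = buf.data() + (cdlo - dlo);
        int nn = cdhi - cdlo + 1;
        for (int q = 0; q < nn; ++q)
          dst[q] = std::max(dst[q], (T)(tsT + src[q]));
      }
      if (pairEmit) {
        int xr = x[j - 1];
        for (int d = dlo; d <= dhi; ++d) {
          if (buf[d - dlo] <= NEG / 2) continue;
          row[d - A.dmin[v]] = buf[d - dlo] + (T)escPair(cm, v, x[j - d], xr);
        }
      } else if (leftEmit) {
        for (int d = dlo; d <= dhi; ++d) {   // ascending: self-loop reads d-1
          double cand = buf[d - dlo];
          if (selfTs > NEG / 2 && d - 1 >= A.dmin[v] && d - 1 <= A.dmax[v]) {
            double prev = row[d - 1 - A.dmin[v]];
            if (prev > NEG / 2 && selfTs + prev > cand)
              cand = selfTs + prev;
          }
          if (cand <= NEG / 2) continue;
          row[d - A.dmin[v]] = (T)(cand + escSinglet(cm, v, x[j - d]));
        }
      } else if (rightEmit) {
        T e = (T)((j >= 1) ? escSinglet(cm, v, x[j - 1]) : 0.0);
        for (int d = dlo; d <= dhi; ++d) {
          if (buf[d - dlo] <= NEG / 2) continue;
          row[d - A.dmin[v]] = buf[d - dlo] + e;
        }
      } else {
        for (int d = dlo; d <= dhi; ++d) {
          if (buf[d - dlo] <= NEG / 2) continue;
          row[d - A.dmin[v]] = buf[d - dlo];
        }
      }
    }
  }
}

static CM unpack(const IntegerVector &type, const IntegerVector &cOff,
                 const IntegerVector &cN, const IntegerVector &cIdx,
                 const NumericVector &cSc, const NumericVector &escS,
                 const NumericVector &escP, const IntegerVector &bL,
                 const IntegerVector &bR, const IntegerVector &dmin,
                 const IntegerVector &dmax) {
  CM cm;
  cm.S = type.size();
  cm.type = INTEGER(type); cm.cOff = INTEGER(cOff); cm.cN = INTEGER(cN);
  cm.cIdx = INTEGER(cIdx); cm.bL = INTEGER(bL); cm.bR = INTEGER(bR);
  cm.dmin = INTEGER(dmin); cm.dmax = INTEGER(dmax);
  cm.cSc = REAL(cSc); cm.escS = REAL(escS); cm.escP = REAL(escP);
  return cm;
}

// Best-scoring parse end/length per start position; returns starts with
// root score >= thresh.
// [[Rcpp::export(name = ".cm_scan")]]
DataFrame cm_scan(IntegerVector type, IntegerVector cOff, IntegerVector cN,
                  IntegerVector cIdx, NumericVector cSc, NumericVector escS,
                  NumericVector escP, IntegerVector bL, IntegerVector bR,
                  IntegerVector dmin, IntegerVector dmax, IntegerVector seq,
                  double thresh) {
  CM cm = unpack(type, cOff, cN, cIdx, cSc, escS, escP, bL, bR, dmin, dmax);
  int L = seq.size();
  Alpha<float> A;
  fill(cm, A, INTEGER(seq), L);
  std::vector<double> bestScore(L + 1, NEG);
  std::vector<int> bestEnd(L + 1, 0);
  for (int j = 1; j <= L; ++j) {
    for (int d = std::max(1, A.dmin[0]); d <= std::min(j, A.dmax[0]); ++d) {
      double s = A.get(0, j, d);
      int i = j - d + 1;
      if (s > bestScore[i]) { bestScore[i] = s; bestEnd[i] = j; }
    }
  }
  std::vector<int> starts, ends; std::vector<double> scores;
  for (int i = 1; i <= L; ++i) {
    if (bestScore[i] >= thresh) {
      starts.push_back(i); ends.push_back(bestEnd[i]);
      scores.push_back(bestScore[i]);
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["score"] = scores);
}

// Global alignment of the full sequence to the model, with traceback.
// [[Rcpp::export(name = ".cm_align")]]
List cm_align(IntegerVector type, IntegerVector cOff, IntegerVector cN,
              IntegerVector cIdx, NumericVector cSc, NumericVector escS,
              NumericVector escP, IntegerVector bL, IntegerVector bR,
              IntegerVector dmin, IntegerVector dmax, IntegerVector seq) {
  CM cm = unpack(type, cOff, cN, cIdx, cSc, escS, escP, bL, bR, dmin, dmax);
  int L = seq.size();
  const int *x = INTEGER(seq);
  Alpha<double> A;
  fill(cm, A, x, L);
  double sc = A.get(0, L, L);
  std::vector<int> tbState, tbI, tbJ;
  if (sc > NEG / 2) {
    // explicit stack of (v, j, d)
    std::vector<std::array<int,3>> stack;
    stack.push_back({0, L, L});
    const double tol = 1e-6;
    while (!stack.empty()) {
      auto c = stack.back(); stack.pop_back();
      int v = c[0], j = c[1], d = c[2];
      int i = j - d + 1;
      tbState.push_back(v + 1); tbI.push_back(i); tbJ.push_back(j);
      double cur = A.get(v, j, d);
      int t = cm.type[v];
      if (t == 2) continue;                       // E
      if (t == 8) {                               // B
        int lv = cm.bL[v], rv = cm.bR[v];
        bool done = false;
        for (int d2 = 0; d2 <= d && !done; ++d2) {
          double s = A.get(lv, j - d2, d - d2) + A.get(rv, j, d2);
          if (s > NEG / 2 && std::abs(s - cur) < tol) {
            stack.push_back({rv, j, d2});
            stack.push_back({lv, j - d2, d - d2});
            done = true;
          }
        }
        if (!done) stop("traceback failure at bifurcation");
        continue;
      }
      double e = 0.0; int nj = j, nd = d;
      if (t == 3 || t == 6) { e = escSinglet(cm, v, x[i - 1]); nd = d - 1; }
      else if (t == 4 || t == 7) { e = escSinglet(cm, v, x[j - 1]); nj = j - 1; nd = d - 1; }
      else if (t == 5) { e = escPair(cm, v, x[i - 1], x[j - 1]); nj = j - 1; nd = d - 2; }
      bool done = false;
      for (int k = 0; k < cm.cN[v] && !done; ++k) {
        int y = cm.cIdx[cm.cOff[v] + k];
        double s = e + cm.cSc[cm.cOff[v] + k] + A.get(y, nj, nd);
        if (s > NEG / 2 && std::abs(s - cur) < tol) {
          stack.push_back({y, nj, nd});
          done = true;
        }
      }
      if (!done) stop("traceback failure at state %d", v + 1);
    }
  }
  return List::create(_["score"] = sc, _["state"] = tbState,
                      _["i"] = tbI, _["j"] = tbJ);
}
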