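#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Three-state affine-gap alignment (Gotoh). Sequences arrive as 1-based
// integer indices into the substitution matrix. A gap of length L costs
// gapOpen + L * gapExtend (open charged once, extend per gap character);
// terminal gaps are penalized in global mode. Tie-break everywhere:
// diagonal (M), then gap-in-b (X, consumes a), then gap-in-a (Y).

static const double NEG_INF = -1e30;

enum State { ST_M = 0, ST_X = 1, ST_Y = 2, ST_START = 3 };

// pick best of (m, x, y) with tie order M > X > Y
static inline int argbest(double m, double x, double y) {
  if (m >= x && m >= y) return ST_M;
  if (x >= y) return ST_X;
  return ST_Y;
}

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gapOpen, double gapExtend, bool local) {
  const int n = a.size(), m = b.size();
  const double go = gapOpen, ge = gapExtend;
  const size_t W = (size_t)(m + 1);
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<unsigned char> tM((n + 1) * W, ST_START),
      tX((n + 1) * W, ST_START), tY((n + 1) * W, ST_START);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (local) {
      M[i * W] = 0.0;  // free start
    } else {
      X[i * W] = -(go + i * ge);
      tX[i * W] = (i == 1) ? ST_M : ST_X;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (local) {
      M[j] = 0.0;
    } else {
      Y[j] = -(go + j * ge);
      tY[j] = (j == 1) ? ST_M : ST_Y;
    }
  }

  double best = 0.0;
  int bi = 0, bj = 0;  // local best cell (state M)

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      const double s = S(a[i - 1] - 1, b[j - 1] - 1);
      // match state
      int src = argbest(M[d], X[d], Y[d]);
      double bp = (src == ST_M ? M[d] : (src == ST_X ? X[d] : Y[d]));
      double v = bp + s;
      if (local && v <= 0.0) {
        M[c] = 0.0;
        tM[c] = ST_START;
      } else if (local && src == ST_M && bp <= 0.0) {
        // alignment starts at this column (the predecessor M value is the
        // free start / an empty restart, never part of the alignment)
        M[c] = v;
        tM[c] = ST_START;
      } else {
        M[c] = v;
        tM[c] = (unsigned char)src;
      }
      if (local && M[c] > best) {  // strictly greater: earliest cell wins ties
        best = M[c];
        bi = i;
        bj = j;
      }
      // gap in b (consume a)
      {
        double fm = M[u] - go - ge, fx = X[u] - ge, fy = Y[u] - go - ge;
        int sx = argbest(fm, fx, fy);
        X[c] = (sx == ST_M ? fm : (sx == ST_X ? fx : fy));
        tX[c] = (unsigned char)sx;
      }
      // gap in a (consume b)
      {
        double fm = M[l] - go - ge, fx = X[l] - go - ge, fy = Y[l] - ge;
        int sy = argbest(fm, fx, fy);
        Y[c] = (sy == ST_M ? fm : (sy == ST_X ? fx : fy));
        tY[c] = (unsigned char)sy;
      }
    }
  }

  int i, j, st;
  double score;
  if (local) {
    if (best <= 0.0) {  // empty alignment
      return List::create(_["score"] = 0.0, _["ai"] = IntegerVector(0),
                          _["bi"] = IntegerVector(0), _["a_start"] = 0,
                          _["a_end"] = 0, _["b_start"] = 0, _["b_end"] = 0);
    }
    i = bi;
    j = bj;
    st = ST_M;
    score = best;
  } else {
    const size_t c = (size_t)n * W + m;
    st = argbest(M[c], X[c], Y[c]);
    score = (st == ST_M ? M[c] : (st == ST_X ? X[c] : Y[c]));
    i = n;
    j = m;
  }

  std::vector<int> ra, rb;  // reversed aligned indices, 0 = gap
  int aEnd = 0, bEnd = 0, aStart = 0, bStart = 0;
  if (local) {
    aEnd = i;
    bEnd = j;
  }
  while (true) {
    if (!local && i == 0 && j == 0) break;
    const size_t c = (size_t)i * W + j;
    if (st == ST_M) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      int prev = tM[c];
      --i;
      --j;
      if (local && prev == ST_START) break;
      st = prev;
    } else if (st == ST_X) {
      ra.push_back(a[i - 1]);
      rb.push_back(0);
      int prev = tX[c];
      --i;
      st = prev;
    } else {
      ra.push_back(0);
      rb.push_back(b[j - 1]);
      int prev = tY[c];
      --j;
      st = prev;
    }
  }
  if (local) {
    aStart = i + 1;
    bStart = j + 1;
  } else {
    aStart = n > 0 ? 1 : 0;
    bStart = m > 0 ? 1 : 0;
    aEnd = n;
    bEnd = m;
  }
  const int L = (int)ra.size();
  IntegerVector ai(L), biv(L);
  for (int k = 0; k < L; ++k) {
    ai[k] = ra[L - 1 - k];
    biv[k] = rb[L - 1 - k];
  }
  return List::create(_["score"] = score, _["ai"] = ai, _["bi"] = biv,
                      _["a_start"] = aStart, _["a_end"] = aEnd,
                      _["b_start"] = bStart, _["b_end"] = bEnd);
}

// Profile-profile global alignment for progressive MSA. `ca`/`cb` are
// K x L residue-count matrices (gap counts excluded); `nRowsA`/`nRowsB`
// the number of rows in each profile. Column-column score is the
// sum-of-pairs substitution score between residue counts; inserting a gap
// column against a profile column charges open and extend per crossing
// row pair (residue count of the consumed column times the rows of the
// gapped profile), approximating the induced sum-of-pairs gap cost, so
// gaps opposite gappy columns are cheap. Tie-break as in align_pair_cpp.
// [[Rcpp::export]]
List align_profiles_cpp(NumericMatrix ca, NumericMatrix cb, NumericMatrix S,
                        double gapOpen, double gapExtend, double nRowsA,
                        double nRowsB) {
  const int K = ca.nrow();
  const int n = ca.ncol(), m = cb.ncol();
  const double go = gapOpen, ge = gapExtend;

  std::vector<double> nresA(n, 0.0), nresB(m, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) nresA[i] += ca(k, i);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) nresB[j] += cb(k, j);

  // SB = S %*% cb  (K x m)
  std::vector<double> SB((size_t)K * m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int k2 = 0; k2 < K; ++k2) {
      const double c = cb(k2, j);
      if (c != 0.0)
        for (int k1 = 0; k1 < K; ++k1) SB[(size_t)k1 * m + j] += S(k1, k2) * c;
    }

  const size_t W = (size_t)(m + 1);
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<unsigned char> tM((n + 1) * W, ST_START),
      tX((n + 1) * W, ST_START), tY((n + 1) * W, ST_START);
  M[0] = 0.0;
  {
    double acc = 0.0;
    for (int i = 1; i <= n; ++i) {
      acc += ge * nresA[i - 1] * nRowsB;
      X[i * W] = -(go * nresA[0] * nRowsB + acc);
      tX[i * W] = (i == 1) ? ST_M : ST_X;
    }
    acc = 0.0;
    for (int j = 1; j <= m; ++j) {
      acc += ge * nresB[j - 1] * nRowsA;
      Y[j] = -(go * nresB[0] * nRowsA + acc);
      tY[j] = (j == 1) ? ST_M : ST_Y;
    }
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double cv = ca(k, i - 1);
        if (cv != 0.0) s += cv * SB[(size_t)k * m + (j - 1)];
      }
      int src = argbest(M[d], X[d], Y[d]);
      M[c] = (src == ST_M ? M[d] : (src == ST_X ? X[d] : Y[d])) + s;
      tM[c] = (unsigned char)src;
      {
        const double pen = ge * nresA[i - 1] * nRowsB;
        const double open = go * nresA[i - 1] * nRowsB;
        double fm = M[u] - open - pen, fx = X[u] - pen, fy = Y[u] - open - pen;
        int sx = argbest(fm, fx, fy);
        X[c] = (sx == ST_M ? fm : (sx == ST_X ? fx : fy));
        tX[c] = (unsigned char)sx;
      }
      {
        const double pen = ge * nresB[j - 1] * nRowsA;
        const double open = go * nresB[j - 1] * nRowsA;
        double fm = M[l] - open - pen, fx = X[l] - open - pen, fy = Y[l] - pen;
        int sy = argbest(fm, fx, fy);
        Y[c] = (sy == ST_M ? fm : (sy == ST_X ? fx : fy));
        tY[c] = (unsigned char)sy;
      }
    }
  }

  const size_t cNM = (size_t)n * W + m;
  int st = argbest(M[cNM], X[cNM], Y[cNM]);
  double score = (st == ST_M ? M[cNM] : (st == ST_X ? X[cNM] : Y[cNM]));
  int i = n, j = m;
  std::vector<int> ia, ib;  // reversed column mapping, 0 = gap column
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    if (st == ST_M) {
      ia.push_back(i);
      ib.push_back(j);
      st = tM[c];
      --i;
      --j;
    } else if (st == ST_X) {
      ia.push_back(i);
      ib.push_back(0);
      st = tX[c];
      --i;
    } else {
      ia.push_back(0);
      ib.push_back(j);
      st = tY[c];
      --j;
    }
  }
  const int L = (int)ia.size();
  IntegerVector idxA(L), idxB(L);
  for (int k = 0; k < L; ++k) {
    idxA[k] = ia[L - 1 - k];
    idxB[k] = ib[L - 1 - k];
  }
  return List::create(_["score"] = score, _["idxA"] = idxA, _["idxB"] = idxB);
}
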