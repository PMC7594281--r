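#include <Rcpp.h>
#include <deque>
#include <complex>
using namespace Rcpp;

// q: integer matrix, 0 outside the mask, 1..L inside.

// Symmetric co-occurrence counts for pixel pairs at offset (dr, dc); pairs
// with either pixel outside the mask are excluded. Each pair counted in both
// orders, so the matrix is symmetric by construction.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerMatrix q, int L, int dr, int dc) {
  int nr = q.nrow(), nc = q.ncol();
  NumericMatrix out(L, L);
  for (int r = 0; r < nr; ++r) {
    int r2 = r + dr;
    if (r2 < 0 || r2 >= nr) continue;
    for (int c = 0; c < nc; ++c) {
      int c2 = c + dc;
      if (c2 < 0 || c2 >= nc) continue;
      int a = q(r, c), b = q(r2, c2);
      if (a > 0 && b > 0) {
        out(a - 1, b - 1) += 1.0;
        out(b - 1, a - 1) += 1.0;
      }
    }
  }
  return out;
}

// Run-length counts along direction (dr, dc): maximal collinear sequences of
// equal-level in-mask pixels. Row i = gray level, column j = run length j+1.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerMatrix q, int L, int dr, int dc) {
  int nr = q.nrow(), nc = q.ncol();
  int maxlen = nr > nc ? nr : nc;
  NumericMatrix out(L, maxlen);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int v = q(r, c);
      if (v <= 0) continue;
      // start of a run only if the predecessor is out of image/mask or differs
      int rp = r - dr, cp = c - dc;
      bool start = rp < 0 || rp >= nr || cp < 0 || cp >= nc || q(rp, cp) != v;
      if (!start) continue;
      int len = 1, rn = r + dr, cn = c + dc;
      while (rn >= 0 && rn < nr && cn >= 0 && cn < nc && q(rn, cn) == v) {
        ++len; rn += dr; cn += dc;
      }
      out(v - 1, len - 1) += 1.0;
    }
  }
  return out;
}

// 8-connected zone labelling; returns for each zone its level and size as a
// two-column matrix (level, size). BFS flood fill per unvisited pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_zones(IntegerMatrix q) {
  int nr = q.nrow(), nc = q.ncol();
  std::vector<int> lev, siz;
  std::vector<bool> seen((size_t)nr * nc, false);
  std::deque<int> queue;
  const int drs[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dcs[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int v = q(r, c);
      size_t idx = (size_t)c * nr + r;
      if (v <= 0 || seen[idx]) continue;
      seen[idx] = true;
      queue.clear();
      queue.push_back((int)idx);
      int size = 0;
      while (!queue.empty()) {
        int cur = queue.front(); queue.pop_front();
        ++size;
        int cr = cur % nr, cc = cur / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = cr + drs[k], c2 = cc + dcs[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          size_t i2 = (size_t)c2 * nr + r2;
          if (!seen[i2] && q(r2, c2) == v) {
            seen[i2] = true;
            queue.push_back((int)i2);
          }
        }
      }
      lev.push_back(v); siz.push_back(size);
    }
  }
  IntegerMatrix out((int)lev.size(), 2);
  for (size_t i = 0; i < lev.size(); ++i) {
    out((int)i, 0) = lev[i];
    out((int)i, 1) = siz[i];
  }
  return out;
}

// Neighborhood gray-tone difference parts: for each level i, n_i = number of
// in-mask pixels of level i having at least one in-mask 8-neighbor, and
// s_i = sum over those pixels of |i - mean(in-mask neighbors)|.
// [[Rcpp::export]]
List cpp_ngtdm_parts(IntegerMatrix q, int L) {
  int nr = q.nrow(), nc = q.ncol();
  NumericVector n(L), s(L);
  const int drs[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dcs[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int v = q(r, c);
      if (v <= 0) continue;
      double sum = 0.0; int cnt = 0;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + drs[k], c2 = c + dcs[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int w = q(r2, c2);
        if (w > 0) { sum += w; ++cnt; }
      }
      if (cnt == 0) continue;  // isolated pixel: excluded
      n[v - 1] += 1.0;
      s[v - 1] += std::abs((double)v - sum / cnt);
    }
  }
  return List::create(_["n"] = n, _["s"] = s);
}

// Valid-mode separable complex correlation: the caller pads the image
// (reflect) by the kernel half-width; kc runs along columns (x offsets),
// kr along rows (y offsets). out(r,c) = sum_{dy,dx} img(r+dy, c+dx) kr[dy] kc[dx].
// [[Rcpp::export]]
ComplexMatrix cpp_sepconv_valid(NumericMatrix img, ComplexVector kr, ComplexVector kc) {
  int nr = img.nrow(), nc = img.ncol();
  int lr = kr.size(), lc = kc.size();
  int orows = nr - lr + 1, ocols = nc - lc + 1;
  if (orows <= 0 || ocols <= 0) stop("kernel larger than padded image");
  const double* im = REAL(img);
  // pass 1: along columns (horizontal); kernel tap outermost so the inner
  // loop runs down contiguous column memory
  std::vector<double> tre((size_t)nr * ocols, 0.0), tim((size_t)nr * ocols, 0.0);
  for (int k = 0; k < lc; ++k) {
    double wr = kc[k].r, wi = kc[k].i;
    for (int c = 0; c < ocols; ++c) {
      const double* src = im + (size_t)(c + k) * nr;
      double* dre = &tre[(size_t)c * nr];
      double* dim = &tim[(size_t)c * nr];
      for (int r = 0; r < nr; ++r) {
        dre[r] += src[r] * wr;
        dim[r] += src[r] * wi;
      }
    }
  }
  // pass 2: along rows (vertical)
  ComplexMatrix out(orows, ocols);
  std::vector<double> ore((size_t)orows), oim((size_t)orows);
  for (int c = 0; c < ocols; ++c) {
    std::fill(ore.begin(), ore.end(), 0.0);
    std::fill(oim.begin(), oim.end(), 0.0);
    const double* cre = &tre[(size_t)c * nr];
    const double* cim = &tim[(size_t)c * nr];
    for (int k = 0; k < lr; ++k) {
      double wr = kr[k].r, wi = kr[k].i;
      const double* sre = cre + k;
      const double* sim = cim + k;
      for (int r = 0; r < orows; ++r) {
        ore[r] += sre[r] * wr - sim[r] * wi;
        oim[r] += sre[r] * wi + sim[r] * wr;
      }
    }
    for (int r = 0; r < orows; ++r) {
      Rcomplex z; z.r = ore[r]; z.i = oim[r];
      out(r, c) = z;
    }
  }
  return out;
}
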