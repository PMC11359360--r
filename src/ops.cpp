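#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Hot loops work on raw column pointers of the N x 3 coordinate matrices
// (column-major: x, y, z columns are contiguous).

// Greedy farthest-point sampling. coords: N x 3; m picks; start: 1-based
// index of the first pick. Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix coords, int m, int start) {
  const int n = coords.nrow();
  if (m > n) stop("cannot sample more points than available");
  if (start < 1 || start > n) stop("start index out of range");
  const double *X = coords.begin(), *Y = X + n, *Z = Y + n;
  IntegerVector out(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  out[0] = cur + 1;
  for (int j = 1; j < m; ++j) {
    const double cx = X[cur], cy = Y[cur], cz = Z[cur];
    int argmax = 0;
    double best = -1.0;
    for (int i = 0; i < n; ++i) {
      const double dx = X[i] - cx, dy = Y[i] - cy, dz = Z[i] - cz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > best) {
        best = mind[i];
        argmax = i;
      }
    }
    cur = argmax;
    out[j] = cur + 1;
  }
  return out;
}

// Ball query with nearest-first ordering. For each centroid (1-based rows
// of coords named by cidx) return up to K neighbours within radius, sorted
// by distance; if fewer than K lie in the ball the nearest in-ball point
// (the centroid itself is always in the ball at distance 0) is repeated.
// Returns a K x M 1-based index matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_ball_group(NumericMatrix coords, IntegerVector cidx,
                             double radius, int K) {
  const int n = coords.nrow(), m = cidx.size();
  const double *X = coords.begin(), *Y = X + n, *Z = Y + n;
  const double r2 = radius * radius;
  IntegerMatrix out(K, m);
  int *O = out.begin();
  std::vector<std::pair<double, int> > cand;
  cand.reserve(n);
  for (int j = 0; j < m; ++j) {
    const int c = cidx[j] - 1;
    const double cx = X[c], cy = Y[c], cz = Z[c];
    cand.clear();
    for (int i = 0; i < n; ++i) {
      const double dx = X[i] - cx, dy = Y[i] - cy, dz = Z[i] - cz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d <= r2) cand.push_back(std::make_pair(d, i));
    }
    const int take = std::min((int)cand.size(), K);
    std::partial_sort(cand.begin(), cand.begin() + take, cand.end());
    int *col = O + (size_t)j * K;
    for (int k = 0; k < K; ++k)
      col[k] = (k < take ? cand[k].second : cand[0].second) + 1;
  }
  return out;
}

// Mean distance of every point to its k nearest neighbours (self excluded).
// [[Rcpp::export]]
NumericVector cpp_knn_meandist(NumericMatrix coords, int k) {
  const int n = coords.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  const double *X = coords.begin(), *Y = X + n, *Z = Y + n;
  NumericVector out(n);
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    const double cx = X[i], cy = Y[i], cz = Z[i];
    for (int j = 0; j < n; ++j) {
      const double dx = X[j] - cx, dy = Y[j] - cy, dz = Z[j] - cz;
      d[j] = dx * dx + dy * dy + dz * dz;
    }
    d[i] = R_PosInf;  // exclude self
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::sqrt(d[j]);
    out[i] = s / k;
  }
  return out;
}

// Three nearest reference points for every query point; used by the
// inverse-distance feature interpolation of the decoder. Returns 3 x nq
// 1-based indices and the matching distances (references repeated when
// fewer than 3 exist).
// [[Rcpp::export]]
List cpp_three_nn(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  const double *QX = query.begin(), *QY = QX + nq, *QZ = QY + nq;
  const double *RX = ref.begin(), *RY = RX + nr, *RZ = RY + nr;
  IntegerMatrix idx(3, nq);
  NumericMatrix dist(3, nq);
  for (int i = 0; i < nq; ++i) {
    const double cx = QX[i], cy = QY[i], cz = QZ[i];
    double b0 = R_PosInf, b1 = R_PosInf, b2 = R_PosInf;
    int i0 = 0, i1 = 0, i2 = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = RX[j] - cx, dy = RY[j] - cy, dz = RZ[j] - cz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < b0) {
        b2 = b1; i2 = i1;
        b1 = b0; i1 = i0;
        b0 = d; i0 = j;
      } else if (d < b1) {
        b2 = b1; i2 = i1;
        b1 = d; i1 = j;
      } else if (d < b2) {
        b2 = d; i2 = j;
      }
    }
    if (nr < 2) { b1 = b0; i1 = i0; }
    if (nr < 3) { b2 = b1; i2 = i1; }
    idx(0, i) = i0 + 1; idx(1, i) = i1 + 1; idx(2, i) = i2 + 1;
    dist(0, i) = std::sqrt(b0);
    dist(1, i) = std::sqrt(b1);
    dist(2, i) = std::sqrt(b2);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Nearest single reference point for each query point (label back-mapping).
// [[Rcpp::export]]
IntegerVector cpp_nearest(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  const double *QX = query.begin(), *QY = QX + nq, *QZ = QY + nq;
  const double *RX = ref.begin(), *RY = RX + nr, *RZ = RY + nr;
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double cx = QX[i], cy = QY[i], cz = QZ[i];
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < nr; ++j) {
      const double dx = RX[j] - cx, dy = RY[j] - cy, dz = RZ[j] - cz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) {
        best = d;
        arg = j;
      }
    }
    out[i] = arg + 1;
  }
  return out;
}

// Scatter-add of gradient columns back to source columns: for the backward
// pass of a column gather. grad: C x L, idx: length L of 1-based source
// columns; returns C x n with column j = sum of grad columns gathered from j.
// [[Rcpp::export]]
NumericMatrix cpp_scatter_add_cols(NumericMatrix grad, IntegerVector idx,
                                   int n) {
  const int C = grad.nrow(), L = grad.ncol();
  NumericMatrix out(C, n);
  double *O = out.begin();
  const double *G = grad.begin();
  for (int j = 0; j < L; ++j) {
    double *oc = O + (size_t)(idx[j] - 1) * C;
    const double *gc = G + (size_t)j * C;
    for (int c = 0; c < C; ++c) oc[c] += gc[c];
  }
  return out;
}
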