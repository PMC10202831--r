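#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nearest neighbor of each query point (px, py) among reference points
// (qx, qy). Ties in distance are broken toward the lowest reference index.
// Returns 1-based indices (NA when the reference set is empty) and the
// Euclidean distances (R_PosInf when empty).
// [[Rcpp::export]]
List nn_pairs_cpp(NumericVector px, NumericVector py,
                  NumericVector qx, NumericVector qy) {
  const int n = px.size();
  const int m = qx.size();
  IntegerVector idx(n, NA_INTEGER);
  NumericVector dist(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int besti = -1;
    const double xi = px[i], yi = py[i];
    for (int j = 0; j < m; ++j) {
      const double dx = qx[j] - xi, dy = qy[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; besti = j; }
    }
    if (besti >= 0) { idx[i] = besti + 1; dist[i] = std::sqrt(best); }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// 3D variant used when detections carry z coordinates.
// [[Rcpp::export]]
List nn_pairs3_cpp(NumericVector px, NumericVector py, NumericVector pz,
                   NumericVector qx, NumericVector qy, NumericVector qz) {
  const int n = px.size();
  const int m = qx.size();
  IntegerVector idx(n, NA_INTEGER);
  NumericVector dist(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int besti = -1;
    for (int j = 0; j < m; ++j) {
      const double dx = qx[j] - px[i], dy = qy[j] - py[i], dz = qz[j] - pz[i];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; besti = j; }
    }
    if (besti >= 0) { idx[i] = besti + 1; dist[i] = std::sqrt(best); }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// For each query point, whether any reference point lies within radius r
// (inclusive). Early exit keeps the randomization-null loop cheap.
// [[Rcpp::export]]
LogicalVector any_within_cpp(NumericVector px, NumericVector py,
                             NumericVector qx, NumericVector qy, double r) {
  const int n = px.size();
  const int m = qx.size();
  const double r2 = r * r;
  LogicalVector hit(n, false);
  for (int i = 0; i < n; ++i) {
    const double xi = px[i], yi = py[i];
    for (int j = 0; j < m; ++j) {
      const double dx = qx[j] - xi, dy = qy[j] - yi;
      if (dx * dx + dy * dy <= r2) { hit[i] = true; break; }
    }
  }
  return hit;
}
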