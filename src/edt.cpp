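#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared distance transform (lower envelope of parabolas), with
// support for infinite heights (lines that contain no seed cell yet).
static void dt1d(const std::vector<double>& f, std::vector<double>& out,
                 int n, std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) q0++;
  if (q0 == n) {
    for (int q = 0; q < n; q++) out[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double s = ((f[q] + (double)q * q) -
                (f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) -
           (f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    out[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in grid units) from every cell of a
// d-dimensional array to the nearest TRUE cell. Infinite if mask is empty.
// [[Rcpp::export]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int d = dims.size();
  long long N = 1;
  for (int k = 0; k < d; k++) N *= dims[k];
  NumericVector out(N);
  for (long long i = 0; i < N; i++) out[i] = mask[i] ? 0.0 : INF;

  int maxdim = 0;
  for (int k = 0; k < d; k++) if (dims[k] > maxdim) maxdim = dims[k];
  std::vector<double> line(maxdim), res(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);

  long long stride = 1;
  for (int k = 0; k < d; k++) {
    int n = dims[k];
    long long nLines = N / n;
    for (long long l = 0; l < nLines; l++) {
      // base index of this line: interleave the remaining axes
      long long lo = l % stride;
      long long hi = l / stride;
      long long base = lo + hi * stride * n;
      for (int q = 0; q < n; q++) line[q] = out[base + (long long)q * stride];
      dt1d(line, res, n, v, z);
      for (int q = 0; q < n; q++) out[base + (long long)q * stride] = res[q];
    }
    stride *= n;
  }
  return out;
}
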