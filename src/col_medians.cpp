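#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of each column of a channels x samples matrix, without the
// memory overhead of apply(); used by the common median reference on
// long recordings (64 x millions of samples).
// [[Rcpp::export]]
NumericVector col_medians_cpp(const NumericMatrix& x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  const int k = nr / 2;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double m = buf[k];
    if (nr % 2 == 0) {
      // even count: mean of the two central order statistics
      double lo = *std::max_element(buf.begin(), buf.begin() + k);
      m = (m + lo) / 2.0;
    }
    out[j] = m;
  }
  return out;
}

// Subtract a per-column offset from every row, writing into a fresh
// matrix (keeps R copy-on-modify semantics for the caller).
// [[Rcpp::export]]
NumericMatrix sweep_cols_cpp(const NumericMatrix& x, const NumericVector& offset) {
  const int nr = x.nrow(), nc = x.ncol();
  if (offset.size() != nc) stop("offset length must equal ncol(x)");
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double o = offset[j];
    for (int i = 0; i < nr; ++i) out(i, j) = x(i, j) - o;
  }
  return out;
}
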