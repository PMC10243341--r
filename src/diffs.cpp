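#include <Rcpp.h>

using namespace Rcpp;

// Forward difference with replicate (Neumann) boundary along dimension
// k (1-based) of a 3-D array: out[i] = x[i+1] - x[i], last slice 0.
// [[Rcpp::export]]
NumericVector diff_fwd_cpp(NumericVector x, IntegerVector dims, int k) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(x.size());
  const double *px = x.begin();
  double *po = out.begin();
  if (k == 1) {
    for (R_xlen_t j = 0; j < (R_xlen_t)n2 * n3; ++j) {
      const double *c = px + j * n1;
      double *o = po + j * n1;
      for (int i = 0; i < n1 - 1; ++i) o[i] = c[i + 1] - c[i];
      o[n1 - 1] = 0.0;
    }
  } else if (k == 2) {
    for (int m = 0; m < n3; ++m) {
      const double *c = px + (R_xlen_t)m * n1 * n2;
      double *o = po + (R_xlen_t)m * n1 * n2;
      for (int j = 0; j < n2 - 1; ++j)
        for (int i = 0; i < n1; ++i)
          o[i + j * n1] = c[i + (j + 1) * n1] - c[i + j * n1];
      for (int i = 0; i < n1; ++i) o[i + (n2 - 1) * n1] = 0.0;
    }
  } else {
    const R_xlen_t sl = (R_xlen_t)n1 * n2;
    for (int m = 0; m < n3 - 1; ++m)
      for (R_xlen_t i = 0; i < sl; ++i)
        po[i + m * sl] = px[i + (m + 1) * sl] - px[i + m * sl];
    for (R_xlen_t i = 0; i < sl; ++i) po[i + (R_xlen_t)(n3 - 1) * sl] = 0.0;
  }
  out.attr("dim") = dims;
  return out;
}

// Negative adjoint of diff_fwd_cpp along dimension k:
// out[1] = p[1]; out[i] = p[i] - p[i-1]; out[n] = -p[n-1].
// [[Rcpp::export]]
NumericVector div_1d_cpp(NumericVector p, IntegerVector dims, int k) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(p.size());
  const double *pp = p.begin();
  double *po = out.begin();
  if ((k == 1 && n1 == 1) || (k == 2 && n2 == 1) || (k == 3 && n3 == 1)) {
    out.attr("dim") = dims;
    return out;
  }
  if (k == 1) {
    for (R_xlen_t j = 0; j < (R_xlen_t)n2 * n3; ++j) {
      const double *c = pp + j * n1;
      double *o = po + j * n1;
      o[0] = c[0];
      for (int i = 1; i < n1 - 1; ++i) o[i] = c[i] - c[i - 1];
      o[n1 - 1] = -c[n1 - 2];
    }
  } else if (k == 2) {
    for (int m = 0; m < n3; ++m) {
      const double *c = pp + (R_xlen_t)m * n1 * n2;
      double *o = po + (R_xlen_t)m * n1 * n2;
      for (int i = 0; i < n1; ++i) o[i] = c[i];
      for (int j = 1; j < n2 - 1; ++j)
        for (int i = 0; i < n1; ++i)
          o[i + j * n1] = c[i + j * n1] - c[i + (j - 1) * n1];
      for (int i = 0; i < n1; ++i)
        o[i + (n2 - 1) * n1] = -c[i + (n2 - 2) * n1];
    }
  } else {
    const R_xlen_t sl = (R_xlen_t)n1 * n2;
    for (R_xlen_t i = 0; i < sl; ++i) po[i] = pp[i];
    for (int m = 1; m < n3 - 1; ++m)
      for (R_xlen_t i = 0; i < sl; ++i)
        po[i + m * sl] = pp[i + m * sl] - pp[i + (m - 1) * sl];
    for (R_xlen_t i = 0; i < sl; ++i)
      po[i + (R_xlen_t)(n3 - 1) * sl] = -pp[i + (R_xlen_t)(n3 - 2) * sl];
  }
  out.attr("dim") = dims;
  return out;
}
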