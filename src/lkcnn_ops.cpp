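// Hot inner kernels of the LKCNN training step. The matrix products stay in
// R (BLAS); these kernels cover the memory-bound pieces: im2col gather,
// col2im scatter-add, 1-D max pooling, ReLU, dropout masks (drawn from R's
// RNG so set.seed() governs them), and the Adam update.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".gather_cols_cpp")]]
NumericMatrix gather_cols_cpp(NumericMatrix X, IntegerVector idx) {
  const int B = X.nrow(), M = idx.size();
  NumericMatrix out(B, M);
  const double *xp = X.begin();
  double *op = out.begin();
  for (int m = 0; m < M; ++m) {
    const double *src = xp + (size_t)(idx[m] - 1) * B;
    std::copy(src, src + B, op + (size_t)m * B);
  }
  return out;
}

// [[Rcpp::export(name = ".scatter_cols_cpp")]]
NumericMatrix scatter_cols_cpp(NumericMatrix dP, IntegerVector idx, int N) {
  const int B = dP.nrow(), M = idx.size();
  NumericMatrix out(B, N);
  const double *pp = dP.begin();
  double *op = out.begin();
  for (int m = 0; m < M; ++m) {
    double *dst = op + (size_t)(idx[m] - 1) * B;
    const double *src = pp + (size_t)m * B;
    for (int b = 0; b < B; ++b) dst[b] += src[b];
  }
  return out;
}

// X viewed as (B, L, F); pools length pairs (2*j-1, 2*j) -> Lp = L/2
// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
List maxpool2_fwd_cpp(NumericVector X, int B, int L, int F) {
  const int Lp = L / 2;
  NumericVector Y((size_t)B * Lp * F);
  LogicalVector take1((size_t)B * Lp * F);
  const double *xp = X.begin();
  double *yp = Y.begin();
  int *tp = take1.begin();
  for (int f = 0; f < F; ++f) {
    for (int j = 0; j < Lp; ++j) {
      const double *c1 = xp + ((size_t)f * L + 2 * j) * B;
      const double *c2 = c1 + B;
      double *yo = yp + ((size_t)f * Lp + j) * B;
      int *to = tp + ((size_t)f * Lp + j) * B;
      for (int b = 0; b < B; ++b) {
        if (c1[b] >= c2[b]) {  // ties take the earlier sample
          yo[b] = c1[b];
          to[b] = 1;
        } else {
          yo[b] = c2[b];
          to[b] = 0;
        }
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(B, Lp, F);
  return List::create(_["Y"] = Y, _["take1"] = take1, _["L"] = L,
                      _["Lp"] = Lp);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
NumericVector maxpool2_bwd_cpp(NumericVector dY, LogicalVector take1, int B,
                               int L, int F) {
  const int Lp = L / 2;
  NumericVector dX((size_t)B * L * F);
  const double *gp = dY.begin();
  const int *tp = take1.begin();
  double *op = dX.begin();
  for (int f = 0; f < F; ++f) {
    for (int j = 0; j < Lp; ++j) {
      const double *gi = gp + ((size_t)f * Lp + j) * B;
      const int *ti = tp + ((size_t)f * Lp + j) * B;
      double *o1 = op + ((size_t)f * L + 2 * j) * B;
      double *o2 = o1 + B;
      for (int b = 0; b < B; ++b) {
        if (ti[b]) o1[b] = gi[b]; else o2[b] = gi[b];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(B, L, F);
  return dX;
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector Z) {
  NumericVector Y = clone(Z);
  for (double &v : Y) if (v < 0) v = 0;
  Y.attr("dim") = Z.attr("dim");
  return Y;
}

// dZ = dY * (Y > 0), using the forward output as the mask
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector dY, NumericVector Y) {
  NumericVector out = clone(dY);
  const double *yp = Y.begin();
  double *op = out.begin();
  const size_t n = out.size();
  for (size_t i = 0; i < n; ++i) if (yp[i] <= 0) op[i] = 0;
  out.attr("dim") = dY.attr("dim");
  return out;
}

// inverted dropout mask from R's RNG stream
// [[Rcpp::export(name = ".dropout_mask_cpp")]]
NumericVector dropout_mask_cpp(int n, double rate) {
  NumericVector out(n);
  const double keep = 1.0 - rate;
  const double inv = 1.0 / keep;
  for (int i = 0; i < n; ++i) out[i] = (unif_rand() < keep) ? inv : 0.0;
  return out;
}

// one Adam step over the flattened parameter blocks; returns fresh vectors
// (R copy-on-write safe)
// [[Rcpp::export(name = ".adam_step_cpp")]]
List adam_step_cpp(List par, List grad, List m, List v, int t, double lr,
                   double beta1, double beta2, double eps) {
  const int K = par.size();
  List par2(K), m2(K), v2(K);
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (int k = 0; k < K; ++k) {
    NumericVector p = par[k], g = grad[k], mk = m[k], vk = v[k];
    const int n = p.size();
    NumericVector pn(n), mn(n), vn(n);
    for (int i = 0; i < n; ++i) {
      mn[i] = beta1 * mk[i] + (1 - beta1) * g[i];
      vn[i] = beta2 * vk[i] + (1 - beta2) * g[i] * g[i];
      pn[i] = p[i] - lr * (mn[i] / bc1) / (std::sqrt(vn[i] / bc2) + eps);
    }
    pn.attr("dim") = p.attr("dim");
    par2[k] = pn;
    m2[k] = mn;
    v2[k] = vn;
  }
  par2.names() = par.names();
  m2.names() = m.names();
  v2.names() = v.names();
  return List::create(_["par"] = par2, _["m"] = m2, _["v"] = v2);
}
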