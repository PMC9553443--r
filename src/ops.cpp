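// Hot numerical kernels for the autodiff tape: multi-head attention
// forward/backward, 1-D convolution gather/scatter, and row-wise layer
// normalisation.  Only inner loops live here; the tape structure and all
// model logic stay in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// rows: list of 1-based row index vectors (one per sequence, NULL-free);
// returns Z (same shape as Q) and the cached attention weights per
// (sequence, head).
// [[Rcpp::export]]
List cpp_attention_fwd(const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const List& rows, int n_heads,
                       double scl) {
  const int d = Q.n_cols;
  const int dk = d / n_heads;
  arma::mat Z(Q.n_rows, d, arma::fill::zeros);
  const int B = rows.size();
  List cache(B);
  for (int b = 0; b < B; ++b) {
    IntegerVector rb = rows[b];
    const int T = rb.size();
    arma::uvec idx(T);
    for (int t = 0; t < T; ++t) idx[t] = rb[t] - 1;
    arma::mat Qb = Q.rows(idx), Kb = K.rows(idx), Vb = V.rows(idx);
    arma::mat Zb(T, d);
    List Pb(n_heads);
    for (int h = 0; h < n_heads; ++h) {
      arma::span ch(h * dk, (h + 1) * dk - 1);
      arma::mat S = Qb.cols(ch) * Kb.cols(ch).t() * scl;
      S.each_col() -= arma::max(S, 1);
      arma::mat P = arma::exp(S);
      P.each_col() /= arma::sum(P, 1);
      Zb.cols(ch) = P * Vb.cols(ch);
      Pb[h] = P;
    }
    Z.rows(idx) = Zb;
    cache[b] = Pb;
  }
  return List::create(Named("Z") = Z, Named("P") = cache);
}

// [[Rcpp::export]]
List cpp_attention_bwd(const arma::mat& dZ, const arma::mat& Q,
                       const arma::mat& K, const arma::mat& V,
                       const List& rows, const List& cache, int n_heads,
                       double scl) {
  const int d = Q.n_cols;
  const int dk = d / n_heads;
  arma::mat dQ(Q.n_rows, d, arma::fill::zeros);
  arma::mat dK(Q.n_rows, d, arma::fill::zeros);
  arma::mat dV(Q.n_rows, d, arma::fill::zeros);
  const int B = rows.size();
  for (int b = 0; b < B; ++b) {
    IntegerVector rb = rows[b];
    const int T = rb.size();
    arma::uvec idx(T);
    for (int t = 0; t < T; ++t) idx[t] = rb[t] - 1;
    arma::mat Qb = Q.rows(idx), Kb = K.rows(idx), Vb = V.rows(idx);
    arma::mat dZb = dZ.rows(idx);
    arma::mat dQb(T, d, arma::fill::zeros), dKb(T, d, arma::fill::zeros),
        dVb(T, d, arma::fill::zeros);
    List Pb = cache[b];
    for (int h = 0; h < n_heads; ++h) {
      arma::span ch(h * dk, (h + 1) * dk - 1);
      arma::mat P = Pb[h];
      arma::mat dZh = dZb.cols(ch);
      arma::mat dP = dZh * Vb.cols(ch).t();
      dVb.cols(ch) = P.t() * dZh;
      arma::mat dS = P % (dP.each_col() - arma::sum(dP % P, 1));
      dQb.cols(ch) = dS * Kb.cols(ch) * scl;
      dKb.cols(ch) = dS.t() * Qb.cols(ch) * scl;
    }
    dQ.rows(idx) = dQb;
    dK.rows(idx) = dKb;
    dV.rows(idx) = dVb;
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK,
                      Named("dV") = dV);
}

// im2col gather: idx is (n_out x k), 1-based rows of x, 0 = zero pad
// [[Rcpp::export]]
NumericMatrix cpp_conv_gather(const NumericMatrix& x,
                              const IntegerMatrix& idx) {
  const int n = idx.nrow(), k = idx.ncol(), C = x.ncol();
  NumericMatrix X2(n, k * C);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < C; ++c) {
      const int outc = j * C + c;
      for (int i = 0; i < n; ++i) {
        const int r = idx(i, j);
        X2(i, outc) = (r == 0) ? 0.0 : x(r - 1, c);
      }
    }
  }
  return X2;
}

// scatter-add of the im2col gradient back onto the input rows
// [[Rcpp::export]]
NumericMatrix cpp_conv_scatter(const NumericMatrix& dX2,
                               const IntegerMatrix& idx, int nr) {
  const int n = idx.nrow(), k = idx.ncol();
  const int C = dX2.ncol() / k;
  NumericMatrix G(nr, C);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < C; ++c) {
      const int inc = j * C + c;
      for (int i = 0; i < n; ++i) {
        const int r = idx(i, j);
        if (r != 0) G(r - 1, c) += dX2(i, inc);
      }
    }
  }
  return G;
}

// scatter-add rows of g into an (nr x C) zero matrix at 1-based idx
// (0 entries dropped); the backward of a row gather
// [[Rcpp::export]]
NumericMatrix cpp_row_scatter(const NumericMatrix& g,
                              const IntegerVector& idx, int nr) {
  const int n = g.nrow(), C = g.ncol();
  NumericMatrix G(nr, C);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < n; ++i) {
      const int r = idx[i];
      if (r != 0) G(r - 1, c) += g(i, c);
    }
  }
  return G;
}

// weighted two-point scatter-add: backward of linear row interpolation
// [[Rcpp::export]]
NumericMatrix cpp_interp_scatter(const NumericMatrix& g,
                                 const IntegerVector& i1,
                                 const IntegerVector& i2,
                                 const NumericVector& w, int nr) {
  const int n = g.nrow(), C = g.ncol();
  NumericMatrix G(nr, C);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < n; ++i) {
      const double gv = g(i, c);
      if (i1[i] != 0) G(i1[i] - 1, c) += gv * w[i];
      if (i2[i] != 0) G(i2[i] - 1, c) += gv * (1.0 - w[i]);
    }
  }
  return G;
}

// gather rows with zero row for idx 0 (forward of tp_rows / embedding)
// [[Rcpp::export]]
NumericMatrix cpp_row_gather(const NumericMatrix& x,
                             const IntegerVector& idx) {
  const int n = idx.size(), C = x.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < n; ++i) {
      const int r = idx[i];
      out(i, c) = (r == 0) ? 0.0 : x(r - 1, c);
    }
  }
  return out;
}

// weighted two-point gather (forward of linear row interpolation)
// [[Rcpp::export]]
NumericMatrix cpp_interp_gather(const NumericMatrix& x,
                                const IntegerVector& i1,
                                const IntegerVector& i2,
                                const NumericVector& w) {
  const int n = i1.size(), C = x.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < n; ++i) {
      double v = 0.0;
      if (i1[i] != 0) v += x(i1[i] - 1, c) * w[i];
      if (i2[i] != 0) v += x(i2[i] - 1, c) * (1.0 - w[i]);
      out(i, c) = v;
    }
  }
  return out;
}

// layer norm forward: returns normalised rows and the inverse sd per row
// [[Rcpp::export]]
List cpp_layernorm_fwd(const NumericMatrix& x, double eps) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix xn(n, C);
  NumericVector isd(n);
  for (int i = 0; i < n; ++i) {
    double mu = 0.0;
    for (int c = 0; c < C; ++c) mu += x(i, c);
    mu /= C;
    double va = 0.0;
    for (int c = 0; c < C; ++c) {
      const double d = x(i, c) - mu;
      va += d * d;
    }
    va /= C;
    const double s = 1.0 / std::sqrt(va + eps);
    isd[i] = s;
    for (int c = 0; c < C; ++c) xn(i, c) = (x(i, c) - mu) * s;
  }
  return List::create(Named("xn") = xn, Named("isd") = isd);
}

// layer norm backward wrt the input (affine handled in R)
// [[Rcpp::export]]
NumericMatrix cpp_layernorm_bwd(const NumericMatrix& dxn,
                                const NumericMatrix& xn,
                                const NumericVector& isd) {
  const int n = dxn.nrow(), C = dxn.ncol();
  NumericMatrix dx(n, C);
  for (int i = 0; i < n; ++i) {
    double m1 = 0.0, m2 = 0.0;
    for (int c = 0; c < C; ++c) {
      m1 += dxn(i, c);
      m2 += dxn(i, c) * xn(i, c);
    }
    m1 /= C;
    m2 /= C;
    for (int c = 0; c < C; ++c) {
      dx(i, c) = isd[i] * (dxn(i, c) - m1 - xn(i, c) * m2);
    }
  }
  return dx;
}

// row-wise softmax with global-shift stability
// [[Rcpp::export]]
NumericMatrix cpp_softmax_rows(const NumericMatrix& x) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix P(n, C);
  for (int i = 0; i < n; ++i) {
    double mx = x(i, 0);
    for (int c = 1; c < C; ++c) mx = std::max(mx, x(i, c));
    double s = 0.0;
    for (int c = 0; c < C; ++c) {
      const double e = std::exp(x(i, c) - mx);
      P(i, c) = e;
      s += e;
    }
    for (int c = 0; c < C; ++c) P(i, c) /= s;
  }
  return P;
}

// in-place Adam update: val, m, s are modified directly (they are owned by
// the parameter store and no live tape needs the old values once the step
// runs); g is the clipped gradient, c1/c2 the bias corrections.
// [[Rcpp::export]]
void cpp_adam(NumericMatrix val, NumericMatrix m, NumericMatrix s,
              const NumericMatrix& g, double lr, double b1, double b2,
              double eps, double c1, double c2, double scale) {
  const R_xlen_t n = val.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] * scale;
    m[i] = b1 * m[i] + (1.0 - b1) * gi;
    s[i] = b2 * s[i] + (1.0 - b2) * gi * gi;
    val[i] -= lr * (m[i] / c1) / (std::sqrt(s[i] / c2) + eps);
  }
}
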