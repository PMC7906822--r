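// Performance-critical primitives of the convolution stack: temporal
// convolution via im2col + GEMM, per-map batch normalization, leaky-ReLU
// and 1xp max pooling, each with its exact backward pass. Activations are
// (R, T, M) arrays: rows = batch*channels, cols = time, slices = feature
// maps. R arrays are accessed through raw pointers (no copies); Armadillo
// matrices are non-owning views used only for the GEMM calls.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static IntegerVector dims3(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  return d;
}

// gather the padded k-tap neighbourhoods: Xc is (R*T, k*Min)
static void im2col_fill(const double* A, int R, int T, int Min, int k,
                        int pad_left, arma::mat& Xc) {
  Xc.zeros();
  for (int s = 0; s < k; ++s) {
    for (int m = 0; m < Min; ++m) {
      double* dst0 = Xc.colptr((size_t)s * Min + m);
      const double* Am = A + (size_t)m * R * T;
      for (int t = 0; t < T; ++t) {
        const int src_t = t + s - pad_left;  // same padding, stride 1
        if (src_t < 0 || src_t >= T) continue;
        std::memcpy(dst0 + (size_t)t * R, Am + (size_t)src_t * R,
                    R * sizeof(double));
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(const NumericVector& A, const arma::mat& W,
                       const arma::vec& b, int pad_left) {
  IntegerVector d = dims3(A);
  const int R = d[0], T = d[1], Min = d[2];
  const int k = W.n_rows / Min, Mout = W.n_cols;
  arma::mat Xc((size_t)R * T, (size_t)k * Min);
  im2col_fill(A.begin(), R, T, Min, k, pad_left, Xc);
  NumericVector Y((size_t)R * T * Mout);
  arma::mat Yv(Y.begin(), (size_t)R * T, Mout, false, true);
  Yv = Xc * W;
  Yv.each_row() += b.t();
  Y.attr("dim") = IntegerVector::create(R, T, Mout);
  return Y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const NumericVector& dY, const NumericVector& A,
              const arma::mat& W, int pad_left) {
  IntegerVector d = dims3(A);
  const int R = d[0], T = d[1], Min = d[2];
  const int k = W.n_rows / Min, Mout = W.n_cols;
  arma::mat Xc((size_t)R * T, (size_t)k * Min);
  im2col_fill(A.begin(), R, T, Min, k, pad_left, Xc);
  const arma::mat dYv(const_cast<double*>(dY.begin()), (size_t)R * T, Mout,
                      false, true);
  arma::mat dW = Xc.t() * dYv;
  arma::vec db = arma::sum(dYv, 0).t();
  arma::mat dXc = dYv * W.t();
  NumericVector dA((size_t)R * T * Min);  // zero-initialized
  double* dAp = dA.begin();
  for (int s = 0; s < k; ++s) {
    for (int m = 0; m < Min; ++m) {
      const double* src0 = dXc.colptr((size_t)s * Min + m);
      double* dAm = dAp + (size_t)m * R * T;
      for (int t = 0; t < T; ++t) {
        const int src_t = t + s - pad_left;
        if (src_t < 0 || src_t >= T) continue;
        double* dst = dAm + (size_t)src_t * R;
        const double* src = src0 + (size_t)t * R;
        for (int r = 0; r < R; ++r) dst[r] += src[r];
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(R, T, Min);
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(const NumericVector& A, const NumericVector& gamma,
            const NumericVector& beta, const NumericVector& rmean,
            const NumericVector& rvar, bool train, double momentum,
            double eps) {
  IntegerVector d = dims3(A);
  const size_t N = (size_t)d[0] * d[1];
  const int M = d[2];
  NumericVector Y(N * M), mu(M), invstd(M), new_mean(clone(rmean)),
      new_var(clone(rvar));
  for (int m = 0; m < M; ++m) {
    const double* x = A.begin() + N * m;
    double mean_m, var_m;
    if (train) {
      double s = 0, s2 = 0;
      for (size_t i = 0; i < N; ++i) { s += x[i]; s2 += x[i] * x[i]; }
      mean_m = s / N;
      var_m = s2 / N - mean_m * mean_m;
      new_mean[m] = (1 - momentum) * rmean[m] + momentum * mean_m;
      new_var[m] = (1 - momentum) * rvar[m] + momentum * var_m;
    } else {
      mean_m = rmean[m];
      var_m = rvar[m];
    }
    mu[m] = mean_m;
    invstd[m] = 1.0 / std::sqrt(var_m + eps);
    const double a = gamma[m] * invstd[m];
    const double c = beta[m] - a * mean_m;
    double* y = Y.begin() + N * m;
    for (size_t i = 0; i < N; ++i) y[i] = a * x[i] + c;
  }
  Y.attr("dim") = d;
  return List::create(_["Y"] = Y, _["mu"] = mu, _["invstd"] = invstd,
                      _["mean"] = new_mean, _["var"] = new_var);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(const NumericVector& dY, const NumericVector& A,
            const NumericVector& mu, const NumericVector& invstd,
            const NumericVector& gamma, bool train) {
  IntegerVector d = dims3(A);
  const size_t N = (size_t)d[0] * d[1];
  const int M = d[2];
  NumericVector dA(N * M), dgamma(M), dbeta(M);
  for (int m = 0; m < M; ++m) {
    const double* x = A.begin() + N * m;
    const double* dy = dY.begin() + N * m;
    double* dx = dA.begin() + N * m;
    double s1 = 0, s2 = 0;
    for (size_t i = 0; i < N; ++i) {
      s1 += dy[i];
      s2 += dy[i] * (x[i] - mu[m]) * invstd[m];
    }
    dbeta[m] = s1;
    dgamma[m] = s2;
    const double a = gamma[m] * invstd[m];
    if (train) {
      const double c1 = s1 / N, c2 = s2 / N;
      for (size_t i = 0; i < N; ++i) {
        const double xh = (x[i] - mu[m]) * invstd[m];
        dx[i] = a * (dy[i] - c1 - xh * c2);
      }
    } else {
      for (size_t i = 0; i < N; ++i) dx[i] = a * dy[i];
    }
  }
  dA.attr("dim") = d;
  return List::create(_["dA"] = dA, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd(const NumericVector& A, double slope) {
  NumericVector Y(A.size());
  const double* a = A.begin();
  double* y = Y.begin();
  const size_t n = A.size();
  for (size_t i = 0; i < n; ++i) y[i] = a[i] > 0 ? a[i] : slope * a[i];
  Y.attr("dim") = A.attr("dim");
  return Y;
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd(const NumericVector& dY, const NumericVector& A,
                        double slope) {
  NumericVector dA(dY.size());
  const double* a = A.begin();
  const double* dy = dY.begin();
  double* dx = dA.begin();
  const size_t n = dY.size();
  for (size_t i = 0; i < n; ++i) dx[i] = a[i] > 0 ? dy[i] : slope * dy[i];
  dA.attr("dim") = dY.attr("dim");
  return dA;
}

// [[Rcpp::export(name = ".pool_fwd")]]
List pool_fwd(const NumericVector& A, int p) {
  IntegerVector d = dims3(A);
  const int R = d[0], T = d[1], M = d[2], T2 = T / p;
  NumericVector Y((size_t)R * T2 * M);
  IntegerVector amax((size_t)R * T2 * M);
  for (int m = 0; m < M; ++m) {
    const double* Am = A.begin() + (size_t)m * R * T;
    double* Ym = Y.begin() + (size_t)m * R * T2;
    int* Xm = amax.begin() + (size_t)m * R * T2;
    for (int t2 = 0; t2 < T2; ++t2) {
      const double* col0 = Am + (size_t)t2 * p * R;
      double* yc = Ym + (size_t)t2 * R;
      int* xc = Xm + (size_t)t2 * R;
      for (int r = 0; r < R; ++r) {
        double best = col0[r];
        int arg = 0;
        for (int s = 1; s < p; ++s) {
          const double v = col0[(size_t)s * R + r];
          if (v > best) { best = v; arg = s; }   // ties keep the first
        }
        yc[r] = best;
        xc[r] = arg;
      }
    }
  }
  Y.attr("dim") = IntegerVector::create(R, T2, M);
  amax.attr("dim") = IntegerVector::create(R, T2, M);
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export(name = ".pool_bwd")]]
NumericVector pool_bwd(const NumericVector& dY, const IntegerVector& amax,
                       int p, int T) {
  IntegerVector d = dims3(dY);
  const int R = d[0], T2 = d[1], M = d[2];
  NumericVector dA((size_t)R * T * M);
  for (int m = 0; m < M; ++m) {
    const double* dYm = dY.begin() + (size_t)m * R * T2;
    const int* Xm = amax.begin() + (size_t)m * R * T2;
    double* dAm = dA.begin() + (size_t)m * R * T;
    for (int t2 = 0; t2 < T2; ++t2) {
      for (int r = 0; r < R; ++r) {
        const size_t i = (size_t)t2 * R + r;
        dAm[(size_t)(t2 * p + Xm[i]) * R + r] = dYm[i];
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(R, T, M);
  return dA;
}
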