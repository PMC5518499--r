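#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM (hinge loss, L2 regularization) solved in the dual by
// coordinate descent. The bias is absorbed as an augmented constant feature
// (linear) or an additive +1 kernel term (kernelized), so the box constraint
// 0 <= alpha_i <= C is the only constraint and single-variable updates are
// exact. Randomized sweep order draws from R's RNG, so results are
// reproducible under set.seed().

static int draw_index(int k) {
  int j = (int)std::floor(unif_rand() * k);
  if (j >= k) j = k - 1;
  return j;
}

// [[Rcpp::export(name = ".svm_dcd_linear")]]
List svm_dcd_linear(NumericMatrix X, NumericVector y, double C,
                    double tol, int max_iter) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d + 1, 0.0);       // last entry = bias weight
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qd(n);               // diagonal of Q = x_i.x_i (augmented)
  for (int i = 0; i < n; ++i) {
    double s = 1.0;                        // augmented constant feature
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qd[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int iter = 0; iter < max_iter; ++iter) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = draw_index(i + 1);
      std::swap(idx[i], idx[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = idx[t];
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (PG != 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - G / qd[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
        w[d] += delta;
      }
    }
    if (max_pg < tol) break;
  }
  NumericVector wv(d);
  for (int j = 0; j < d; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv, _["b"] = w[d], _["alpha"] = alpha);
}

// Kernelized variant: K is the raw n x n kernel matrix; +1 is added inside
// to absorb the bias. Decision value for a point z is
// sum_j alpha_j y_j (K(x_j, z) + 1).
// [[Rcpp::export(name = ".svm_dcd_kernel")]]
NumericVector svm_dcd_kernel(NumericMatrix K, NumericVector y, double C,
                             double tol, int max_iter) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  std::vector<double> f(n, 0.0);           // f_i = sum_j alpha_j y_j (K_ij + 1)
  std::vector<double> qd(n);
  for (int i = 0; i < n; ++i) qd[i] = K(i, i) + 1.0;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int iter = 0; iter < max_iter; ++iter) {
    for (int i = n - 1; i > 0; --i) {
      int j = draw_index(i + 1);
      std::swap(idx[i], idx[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = idx[t];
      double G = y[i] * f[i] - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (PG != 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - G / qd[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        for (int j = 0; j < n; ++j) f[j] += delta * (K(i, j) + 1.0);
      }
    }
    if (max_pg < tol) break;
  }
  return wrap(alpha);
}
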