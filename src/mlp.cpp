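#include <Rcpp.h>
using namespace Rcpp;

// Single-hidden-layer perceptron with logistic activations, trained by
// online backpropagation with momentum:
//   w <- w + eta * delta_j * x_ji + alpha * dw(n-1)
// Two output units (one per class, one-hot targets, squared-error deltas).
// Weight init and everything downstream draw from R's RNG, so training is
// reproducible under set.seed(). Instances are visited in a fixed order;
// stochasticity enters only through initialization.

static inline double sigmoid(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// [[Rcpp::export(name = ".mlp_train")]]
List mlp_train(NumericMatrix X, NumericMatrix T, int n_hidden,
               double eta, double momentum, int epochs) {
  int n = X.nrow(), d = X.ncol(), h = n_hidden, k = T.ncol();
  // W1: h x (d+1) (last column bias); W2: k x (h+1)
  NumericMatrix W1(h, d + 1), W2(k, h + 1);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j <= d; ++j) W1(i, j) = unif_rand() - 0.5;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j <= h; ++j) W2(i, j) = unif_rand() - 0.5;
  NumericMatrix dW1(h, d + 1), dW2(k, h + 1);   // previous updates (momentum)

  std::vector<double> hid(h), out(k), dout(k), dhid(h);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < n; ++r) {
      // forward
      for (int i = 0; i < h; ++i) {
        double v = W1(i, d);
        for (int j = 0; j < d; ++j) v += W1(i, j) * X(r, j);
        hid[i] = sigmoid(v);
      }
      for (int i = 0; i < k; ++i) {
        double v = W2(i, h);
        for (int j = 0; j < h; ++j) v += W2(i, j) * hid[j];
        out[i] = sigmoid(v);
      }
      // backward deltas
      for (int i = 0; i < k; ++i)
        dout[i] = (T(r, i) - out[i]) * out[i] * (1.0 - out[i]);
      for (int j = 0; j < h; ++j) {
        double s = 0.0;
        for (int i = 0; i < k; ++i) s += W2(i, j) * dout[i];
        dhid[j] = hid[j] * (1.0 - hid[j]) * s;
      }
      // update with momentum
      for (int i = 0; i < k; ++i) {
        for (int j = 0; j < h; ++j) {
          double dw = eta * dout[i] * hid[j] + momentum * dW2(i, j);
          W2(i, j) += dw; dW2(i, j) = dw;
        }
        double dwb = eta * dout[i] + momentum * dW2(i, h);
        W2(i, h) += dwb; dW2(i, h) = dwb;
      }
      for (int i = 0; i < h; ++i) {
        for (int j = 0; j < d; ++j) {
          double dw = eta * dhid[i] * X(r, j) + momentum * dW1(i, j);
          W1(i, j) += dw; dW1(i, j) = dw;
        }
        double dwb = eta * dhid[i] + momentum * dW1(i, d);
        W1(i, d) += dwb; dW1(i, d) = dwb;
      }
    }
  }
  return List::create(_["W1"] = W1, _["W2"] = W2);
}

// [[Rcpp::export(name = ".mlp_forward")]]
NumericMatrix mlp_forward(NumericMatrix X, NumericMatrix W1, NumericMatrix W2) {
  int n = X.nrow(), d = X.ncol(), h = W1.nrow(), k = W2.nrow();
  NumericMatrix out(n, k);
  std::vector<double> hid(h);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < h; ++i) {
      double v = W1(i, d);
      for (int j = 0; j < d; ++j) v += W1(i, j) * X(r, j);
      hid[i] = sigmoid(v);
    }
    for (int i = 0; i < k; ++i) {
      double v = W2(i, h);
      for (int j = 0; j < h; ++j) v += W2(i, j) * hid[j];
      out(r, i) = sigmoid(v);
    }
  }
  return out;
}
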