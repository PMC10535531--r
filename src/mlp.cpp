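// Minimal multilayer-perceptron regressor: ReLU hidden layers, linear output,
// Adam optimizer on mean-absolute-error loss, early stopping on a validation
// split. Self-contained RNG (mt19937 + Box-Muller, own Fisher-Yates) so a
// given seed reproduces training bit-for-bit on any platform.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937 gen;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint32_t seed) : gen(seed) {}
  double unif() {
    // uniform in (0, 1)
    return (static_cast<double>(gen()) + 0.5) / 4294967296.0;
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    spare = r * std::sin(2.0 * M_PI * v);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * v);
  }
  void shuffle(arma::uvec& idx) {
    for (arma::uword i = idx.n_elem - 1; i > 0; --i) {
      arma::uword j = gen() % (i + 1);
      std::swap(idx[i], idx[j]);
    }
  }
};

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

// forward pass, inputs as columns; returns activations per layer
arma::rowvec forward(const Net& net, const arma::mat& A0,
                     std::vector<arma::mat>* acts = nullptr) {
  arma::mat A = A0;
  if (acts) acts->push_back(A);
  const size_t L = net.W.size();
  for (size_t l = 0; l < L; ++l) {
    arma::mat Z = net.W[l] * A;
    Z.each_col() += net.b[l];
    if (l + 1 < L) {
      A = arma::clamp(Z, 0.0, arma::datum::inf);  // ReLU
    } else {
      A = Z;  // linear output
    }
    if (acts) acts->push_back(A);
  }
  return arma::rowvec(A.row(0));
}

double val_mae(const Net& net, const arma::mat& Xv, const arma::vec& yv) {
  if (Xv.n_cols == 0) return NA_REAL;
  arma::rowvec pred = forward(net, Xv);
  return arma::mean(arma::abs(pred.t() - yv));
}

}  // namespace

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                   const arma::mat& X_val, const arma::vec& y_val,
                   IntegerVector hidden, int batch_size, double lr,
                   int max_epochs, int patience, int seed) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (n == 0 || p == 0) stop("empty training data");
  if (!X.is_finite() || !y.is_finite()) stop("non-finite training data");

  std::vector<arma::uword> sizes;
  sizes.push_back(p);
  for (int h : hidden) sizes.push_back(static_cast<arma::uword>(h));
  sizes.push_back(1);
  const size_t L = sizes.size() - 1;

  Rng rng(static_cast<uint32_t>(seed));
  Net net;
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    double sd = std::sqrt(2.0 / static_cast<double>(sizes[l]));  // He init
    arma::mat W(sizes[l + 1], sizes[l]);
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = sd * rng.norm();
    net.W.push_back(W);
    net.b.push_back(arma::vec(sizes[l + 1], arma::fill::zeros));
    mW[l] = arma::mat(arma::size(W), arma::fill::zeros);
    vW[l] = arma::mat(arma::size(W), arma::fill::zeros);
    mb[l] = arma::vec(sizes[l + 1], arma::fill::zeros);
    vb[l] = arma::vec(sizes[l + 1], arma::fill::zeros);
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  const arma::mat Xt = X.t();        // features as rows, samples as columns
  const arma::mat Xvt = X_val.t();
  arma::uvec order = arma::regspace<arma::uvec>(0, n - 1);

  Net best = net;
  double best_mae = std::numeric_limits<double>::infinity();
  int stall = 0, epochs_run = 0;
  long t_adam = 0;
  std::vector<double> history;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    rng.shuffle(order);
    for (arma::uword start = 0; start < n;
         start += static_cast<arma::uword>(batch_size)) {
      arma::uword end = std::min(n, start + static_cast<arma::uword>(batch_size));
      arma::uvec bidx = order.subvec(start, end - 1);
      arma::mat A0 = Xt.cols(bidx);
      arma::vec yb = y.elem(bidx);
      const double bn = static_cast<double>(bidx.n_elem);

      std::vector<arma::mat> acts;
      forward(net, A0, &acts);

      // MAE gradient at the linear output
      arma::mat dZ = arma::sign(acts[L] - yb.t()) / bn;
      ++t_adam;
      const double bc1 = 1.0 - std::pow(beta1, t_adam);
      const double bc2 = 1.0 - std::pow(beta2, t_adam);
      for (size_t l = L; l-- > 0;) {
        arma::mat dW = dZ * acts[l].t();
        arma::vec db = arma::sum(dZ, 1);
        if (l > 0) {
          arma::mat dA = net.W[l].t() * dZ;
          dZ = dA % arma::conv_to<arma::mat>::from(acts[l] > 0.0);
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * dW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(dW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * db;
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(db);
        net.W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
        net.b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
    }
    epochs_run = epoch + 1;
    double mae = val_mae(net, Xvt, y_val);
    history.push_back(mae);
    if (std::isfinite(mae) && mae < best_mae - 1e-9) {
      best_mae = mae;
      best = net;
      stall = 0;
    } else {
      ++stall;
      if (stall >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (!std::isfinite(best_mae)) best = net;  // no validation set supplied

  List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = best.W[l];
    bl[l] = best.b[l];
  }
  return List::create(_["weights"] = Wl, _["biases"] = bl,
                      _["best_val_mae"] = best_mae,
                      _["epochs_run"] = epochs_run,
                      _["val_history"] = history);
}

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
arma::vec mlp_predict_cpp(List weights, List biases, const arma::mat& X) {
  Net net;
  for (int l = 0; l < weights.size(); ++l) {
    net.W.push_back(as<arma::mat>(weights[l]));
    net.b.push_back(as<arma::vec>(biases[l]));
  }
  if (net.W.front().n_cols != X.n_cols) stop("feature count mismatch");
  arma::rowvec pred = forward(net, X.t());
  return pred.t();
}
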