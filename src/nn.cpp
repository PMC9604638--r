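// Small fully connected network (two hidden ReLU layers, sigmoid output)
// trained with minibatch Adam on binary cross-entropy. All randomness
// (weight initialization, epoch shuffles) is supplied from R so training is
// reproducible under R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  mat W1, W2, W3;
  rowvec b1, b2, b3;
};

Net net_from_list(const Rcpp::List& w) {
  Net n;
  n.W1 = Rcpp::as<mat>(w["W1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]);
  n.W3 = Rcpp::as<mat>(w["W3"]);
  n.b1 = Rcpp::as<rowvec>(w["b1"]);
  n.b2 = Rcpp::as<rowvec>(w["b2"]);
  n.b3 = Rcpp::as<rowvec>(w["b3"]);
  return n;
}

Rcpp::List net_to_list(const Net& n) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
      Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
      Rcpp::Named("W3") = n.W3, Rcpp::Named("b3") = n.b3);
}

mat relu(const mat& z) { return clamp(z, 0.0, datum::inf); }

mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// forward pass; returns activations needed for backprop
void forward(const Net& n, const mat& X, mat& a1, mat& a2, vec& p) {
  a1 = relu(X * n.W1 + repmat(n.b1, X.n_rows, 1));
  a2 = relu(a1 * n.W2 + repmat(n.b2, a1.n_rows, 1));
  p = vectorise(sigmoid(a2 * n.W3 + repmat(n.b3, a2.n_rows, 1)));
}

double bce(const vec& p, const vec& y) {
  vec q = clamp(p, 1e-12, 1.0 - 1e-12);
  return -mean(y % log(q) + (1.0 - y) % log(1.0 - q));
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_nn_forward_prob(const Rcpp::List& weights,
                                        const arma::mat& X) {
  Net n = net_from_list(weights);
  mat a1, a2;
  vec p;
  forward(n, X, a1, a2, p);
  return Rcpp::wrap(p);
}

// [[Rcpp::export]]
arma::mat cpp_nn_hidden(const Rcpp::List& weights, const arma::mat& X) {
  Net n = net_from_list(weights);
  mat a1, a2;
  vec p;
  forward(n, X, a1, a2, p);
  return a2;
}

// Train with Adam + early stopping on validation BCE. 'shuffles' is an
// epochs x n integer matrix of 1-based row orders drawn from R's RNG.
// Returns the best (lowest validation loss) weights and the loss history.
// [[Rcpp::export]]
Rcpp::List cpp_nn_train(const Rcpp::List& weights, const arma::mat& X,
                        const arma::vec& y, const arma::mat& Xval,
                        const arma::vec& yval,
                        const arma::imat& shuffles, double lr, int batch,
                        int patience, double l2, bool freeze_first) {
  Net n = net_from_list(weights);
  Net best = n;
  const int n_obs = X.n_rows;
  const int epochs = shuffles.n_rows;

  // Adam state
  Net m, v;
  m.W1 = zeros(size(n.W1)); m.W2 = zeros(size(n.W2)); m.W3 = zeros(size(n.W3));
  m.b1 = zeros<rowvec>(n.b1.n_elem); m.b2 = zeros<rowvec>(n.b2.n_elem);
  m.b3 = zeros<rowvec>(n.b3.n_elem);
  v = m;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<double> train_hist, val_hist;
  double best_val = datum::inf;
  int bad = 0;

  mat a1, a2;
  vec p;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int start = 0; start < n_obs; start += batch) {
      int stop = std::min(start + batch - 1, n_obs - 1);
      uvec idx(stop - start + 1);
      for (int i = start; i <= stop; ++i)
        idx(i - start) = (uword)(shuffles(ep, i) - 1);
      mat Xb = X.rows(idx);
      vec yb = y(idx);
      forward(n, Xb, a1, a2, p);
      double nb = (double)Xb.n_rows;

      vec dz3 = (p - yb) / nb;
      mat gW3 = a2.t() * dz3 + l2 * n.W3;
      rowvec gb3(1);
      gb3(0) = accu(dz3);
      mat da2 = dz3 * n.W3.t();
      mat dz2 = da2 % (a2 > 0);
      mat gW2 = a1.t() * dz2 + l2 * n.W2;
      rowvec gb2 = sum(dz2, 0);
      mat da1 = dz2 * n.W2.t();
      mat dz1 = da1 % (a1 > 0);
      mat gW1 = Xb.t() * dz1 + l2 * n.W1;
      rowvec gb1 = sum(dz1, 0);

      ++step;
      double c1 = 1.0 - std::pow(beta1, (double)step);
      double c2 = 1.0 - std::pow(beta2, (double)step);
      auto adam = [&](mat& W, mat& mW, mat& vW, const mat& g) {
        mW = beta1 * mW + (1 - beta1) * g;
        vW = beta2 * vW + (1 - beta2) * square(g);
        W -= lr * (mW / c1) / (sqrt(vW / c2) + eps);
      };
      auto adam_b = [&](rowvec& b, rowvec& mb, rowvec& vb, const rowvec& g) {
        mb = beta1 * mb + (1 - beta1) * g;
        vb = beta2 * vb + (1 - beta2) * square(g);
        b -= lr * (mb / c1) / (sqrt(vb / c2) + eps);
      };
      if (!freeze_first) {
        adam(n.W1, m.W1, v.W1, gW1);
        adam_b(n.b1, m.b1, v.b1, gb1);
      }
      adam(n.W2, m.W2, v.W2, gW2);
      adam(n.W3, m.W3, v.W3, gW3);
      adam_b(n.b2, m.b2, v.b2, gb2);
      adam_b(n.b3, m.b3, v.b3, gb3);
    }
    forward(n, X, a1, a2, p);
    train_hist.push_back(bce(p, y));
    forward(n, Xval, a1, a2, p);
    double vl = bce(p, yval);
    val_hist.push_back(vl);
    if (vl < best_val - 1e-7) {
      best_val = vl;
      best = n;
      bad = 0;
    } else if (++bad >= patience) {
      break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = net_to_list(best),
      Rcpp::Named("val_loss") = best_val,
      Rcpp::Named("train_history") = train_hist,
      Rcpp::Named("val_history") = val_hist,
      Rcpp::Named("epochs_run") = (int)val_hist.size());
}
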