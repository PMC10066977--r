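// Dense multilayer perceptron regressor with RMSprop, used to recover shunt
// from the ten bedside features.  Features are z-scored by the R caller;
// this file only fits weights.  Fully deterministic given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_mlp_train(const arma::mat& X, const arma::vec& y,
                   int hidden_layers, int units, int epochs, int batch_size,
                   double lr, double rho, double eps, double lr_decay, int seed,
                   const arma::mat& Xval, const arma::vec& yval) {
  const int n = X.n_rows, p = X.n_cols;
  const int L = hidden_layers + 1;            // weight matrices incl. output
  std::mt19937 rng(static_cast<unsigned>(seed));

  std::vector<arma::mat> W(L), cW(L);
  std::vector<arma::rowvec> b(L), cb(L);
  for (int l = 0; l < L; ++l) {
    int fan_in = (l == 0) ? p : units;
    int fan_out = (l == L - 1) ? 1 : units;
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    W[l].set_size(fan_in, fan_out);
    for (arma::uword j = 0; j < W[l].n_elem; ++j) W[l](j) = U(rng);
    b[l] = arma::rowvec(fan_out, arma::fill::zeros);
    cW[l] = arma::mat(fan_in, fan_out, arma::fill::zeros);
    cb[l] = arma::rowvec(fan_out, arma::fill::zeros);
  }

  auto forward = [&](const arma::mat& Xb, std::vector<arma::mat>& A) {
    A[0] = Xb;
    for (int l = 0; l < L; ++l) {
      arma::mat Z = A[l] * W[l];
      Z.each_row() += b[l];
      if (l < L - 1) Z = arma::clamp(Z, 0.0, arma::datum::inf);  // ReLU
      A[l + 1] = Z;
    }
  };

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  int nb = (n + batch_size - 1) / batch_size;
  NumericVector loss_hist(epochs), val_hist(epochs);
  std::vector<arma::mat> A(L + 1);

  double lr_ep = lr;
  for (int ep = 0; ep < epochs; ++ep) {
    if (ep > 0) lr_ep *= lr_decay;
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0; long ep_n = 0;
    for (int bi = 0; bi < nb; ++bi) {
      int s = bi * batch_size;
      int e = std::min(n, s + batch_size);
      arma::uvec rows(e - s);
      for (int i = s; i < e; ++i) rows(i - s) = idx[i];
      arma::mat Xb = X.rows(rows);
      arma::vec yb = y.elem(rows);
      int m = e - s;

      forward(Xb, A);
      arma::mat delta = (A[L] - yb) * (2.0 / m);   // dMSE/dyhat
      ep_loss += arma::accu(arma::square(A[L] - yb));
      ep_n += m;

      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = A[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<arma::mat>::from(A[l] > 0.0);
        }
        cW[l] = rho * cW[l] + (1.0 - rho) * arma::square(gW);
        cb[l] = rho * cb[l] + (1.0 - rho) * arma::square(gb);
        W[l] -= lr_ep * gW / (arma::sqrt(cW[l]) + eps);
        b[l] -= lr_ep * gb / (arma::sqrt(cb[l]) + eps);
      }
    }
    loss_hist[ep] = ep_loss / ep_n;
    if (Xval.n_rows > 0) {
      forward(Xval, A);
      val_hist[ep] = arma::accu(arma::square(A[L] - yval)) / Xval.n_rows;
    } else val_hist[ep] = NA_REAL;
    if (!std::isfinite(loss_hist[ep]))
      stop("non-finite training loss at epoch %d", ep + 1);
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) { Wout[l] = wrap(W[l]); bout[l] = wrap(b[l]); }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["loss"] = loss_hist, _["val_loss"] = val_hist);
}

// [[Rcpp::export]]
arma::vec cpp_mlp_predict(List weights, List biases, const arma::mat& X) {
  int L = weights.size();
  arma::mat A = X;
  for (int l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(weights[l]);
    arma::rowvec b = as<arma::rowvec>(biases[l]);
    A = A * W;
    A.each_row() += b;
    if (l < L - 1) A = arma::clamp(A, 0.0, arma::datum::inf);
  }
  return A.col(0);
}
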