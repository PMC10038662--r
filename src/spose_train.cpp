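// Projected-Adam trainer for the sparse positive similarity embedding.
//
// The objective is the mean cross-entropy of observed odd-one-out choices
// under the pairwise-dot-product softmax model, plus an L1 penalty
// lambda * sum(W) / n_objects (weights are non-negative, so |w| = w).
// After every Adam update the weights are projected onto the non-negative
// orthant.  Minibatch order is reshuffled each epoch with a Mersenne
// Twister seeded from R, so runs are bit-reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Weights are handled internally in transposed form (dims x objects) so each
// object's vector is a contiguous column.

// softmax over the three pairwise dot products; returns p_ab, p_ac, p_bc
inline void pair_probs(const arma::mat& Wt, int a, int b, int c,
                       double& p_ab, double& p_ac, double& p_bc) {
  const double s_ab = arma::dot(Wt.unsafe_col(a), Wt.unsafe_col(b));
  const double s_ac = arma::dot(Wt.unsafe_col(a), Wt.unsafe_col(c));
  const double s_bc = arma::dot(Wt.unsafe_col(b), Wt.unsafe_col(c));
  const double m = std::max(s_ab, std::max(s_ac, s_bc));
  const double e_ab = std::exp(s_ab - m);
  const double e_ac = std::exp(s_ac - m);
  const double e_bc = std::exp(s_bc - m);
  const double z = e_ab + e_ac + e_bc;
  p_ab = e_ab / z; p_ac = e_ac / z; p_bc = e_bc / z;
}

// mean cross-entropy of the observed choices (transposed weights)
double mean_ce_t(const arma::mat& Wt, const IntegerVector& a,
               const IntegerVector& b, const IntegerVector& c,
               const IntegerVector& choice) {
  const int n = a.size();
  double ce = 0.0;
  for (int t = 0; t < n; ++t) {
    double p_ab, p_ac, p_bc;
    pair_probs(Wt, a[t], b[t], c[t], p_ab, p_ac, p_bc);
    const double p_obs = (choice[t] == c[t]) ? p_ab
                       : (choice[t] == b[t]) ? p_ac : p_bc;
    ce -= std::log(std::max(p_obs, 1e-300));
  }
  return ce / n;
}

// accumulate the cross-entropy gradient of one trial into G (transposed)
inline void accumulate_grad(const arma::mat& Wt, arma::mat& G,
                            int a, int b, int c, int choice) {
  double p_ab, p_ac, p_bc;
  pair_probs(Wt, a, b, c, p_ab, p_ac, p_bc);
  const double g_ab = p_ab - (choice == c ? 1.0 : 0.0);
  const double g_ac = p_ac - (choice == b ? 1.0 : 0.0);
  const double g_bc = p_bc - (choice == a ? 1.0 : 0.0);
  const int d = Wt.n_rows;
  const double* wa = Wt.colptr(a);
  const double* wb = Wt.colptr(b);
  const double* wc = Wt.colptr(c);
  double* ga = G.colptr(a);
  double* gb = G.colptr(b);
  double* gc = G.colptr(c);
  for (int k = 0; k < d; ++k) {
    ga[k] += g_ab * wb[k] + g_ac * wc[k];
    gb[k] += g_ab * wa[k] + g_bc * wc[k];
    gc[k] += g_ac * wa[k] + g_bc * wb[k];
  }
}

}  // namespace

// [[Rcpp::export]]
double cpp_spose_ce(const arma::mat& W, IntegerVector a, IntegerVector b,
                    IntegerVector c, IntegerVector choice) {
  return mean_ce_t(W.t(), a, b, c, choice);
}

// [[Rcpp::export]]
arma::mat cpp_spose_grad(const arma::mat& W, IntegerVector a, IntegerVector b,
                         IntegerVector c, IntegerVector choice,
                         double lambda) {
  const arma::mat Wt = W.t();
  arma::mat G(Wt.n_rows, Wt.n_cols, arma::fill::zeros);
  const int n = a.size();
  for (int t = 0; t < n; ++t)
    accumulate_grad(Wt, G, a[t], b[t], c[t], choice[t]);
  G /= static_cast<double>(n);
  const double pen = lambda / static_cast<double>(W.n_rows);
  G += pen * arma::conv_to<arma::mat>::from(Wt > 0.0);
  return G.t();
}

// [[Rcpp::export]]
List cpp_spose_train(const arma::mat& W0,
                     IntegerVector a, IntegerVector b, IntegerVector c,
                     IntegerVector choice,
                     IntegerVector va, IntegerVector vb, IntegerVector vc,
                     IntegerVector vchoice,
                     double lambda, double lr, double beta1, double beta2,
                     double eps, int batch_size, int max_epochs,
                     int patience, double val_tol, int shuffle_seed) {
  arma::mat W = W0.t();  // dims x objects internally
  arma::mat M(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat V(W.n_rows, W.n_cols, arma::fill::zeros);
  const int n_trials = a.size();
  const double pen = lambda / static_cast<double>(W.n_cols);
  const bool has_val = va.size() > 0;

  std::mt19937 rng(static_cast<unsigned int>(shuffle_seed));
  std::vector<int> order(n_trials);
  for (int i = 0; i < n_trials; ++i) order[i] = i;

  std::vector<double> train_loss, val_loss;
  double best_val = std::numeric_limits<double>::infinity();
  int stall = 0;
  long step = 0;
  int epochs_run = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n_trials; start += batch_size) {
      const int end = std::min(start + batch_size, n_trials);
      const int bs = end - start;
      arma::mat G(W.n_rows, W.n_cols, arma::fill::zeros);
      double batch_ce = 0.0;
      for (int t = start; t < end; ++t) {
        const int i = order[t];
        double p_ab, p_ac, p_bc;
        pair_probs(W, a[i], b[i], c[i], p_ab, p_ac, p_bc);
        const double p_obs = (choice[i] == c[i]) ? p_ab
                           : (choice[i] == b[i]) ? p_ac : p_bc;
        batch_ce -= std::log(std::max(p_obs, 1e-300));
        accumulate_grad(W, G, a[i], b[i], c[i], choice[i]);
      }
      // fused penalty + Adam update + projection, single pass over elements
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, static_cast<double>(step));
      const double bc2 = 1.0 - std::pow(beta2, static_cast<double>(step));
      const double inv_bs = 1.0 / static_cast<double>(bs);
      double* w = W.memptr();
      double* g = G.memptr();
      double* m = M.memptr();
      double* v = V.memptr();
      const arma::uword n_elem = W.n_elem;
      double w_sum = 0.0;
      bool finite = true;
      for (arma::uword e = 0; e < n_elem; ++e) {
        double ge = g[e] * inv_bs + (w[e] > 0.0 ? pen : 0.0);
        if (!std::isfinite(ge)) { finite = false; break; }
        m[e] = beta1 * m[e] + (1.0 - beta1) * ge;
        v[e] = beta2 * v[e] + (1.0 - beta2) * ge * ge;
        double we = w[e] - lr * (m[e] / bc1) / (std::sqrt(v[e] / bc2) + eps);
        w[e] = we < 0.0 ? 0.0 : we;
        w_sum += w[e];
      }
      if (!finite)
        stop("Non-finite gradient at epoch %d; training diverged.", epoch + 1);

      epoch_loss += batch_ce / bs + pen * w_sum;
      ++n_batches;
    }
    epochs_run = epoch + 1;
    train_loss.push_back(epoch_loss / n_batches);
    if (!std::isfinite(train_loss.back()))
      stop("Non-finite loss at epoch %d; training diverged.", epochs_run);

    if (has_val) {
      const double vce = mean_ce_t(W, va, vb, vc, vchoice);
      val_loss.push_back(vce);
      if (vce < best_val - val_tol) {
        best_val = vce;
        stall = 0;
      } else {
        if (++stall >= patience) break;
      }
      if (vce < best_val) best_val = vce;
    }
  }

  return List::create(_["weights"] = W.t(),
                      _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss,
                      _["epochs_run"] = epochs_run);
}
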