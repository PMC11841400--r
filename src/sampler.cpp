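#include <Rcpp.h>
using namespace Rcpp;

// log of the logistic sigmoid, numerically stable
static inline double log_sigmoid(double x) {
  if (x < 0.0) return x - log1p(std::exp(x));
  return -log1p(std::exp(-x));
}

// Bernoulli log-likelihood contribution of scenario i
static inline double loglik_term(int y, double bm, double bt, double tau) {
  double q = (bm - bt) / tau;
  return log_sigmoid(y == 1 ? q : -q);
}

// log prior kernel of the belonging threshold (normalizing constants drop
// out of the Metropolis ratio); support [0,1] is enforced by the proposal
static inline double bt_log_prior_kernel(double bt, int type, double mu,
                                         double sigma) {
  if (type == 1) {
    double z = (bt - mu) / sigma;
    return -0.5 * z * z;
  }
  return 0.0; // uniform
}

// Component-wise random-walk Metropolis over (bt, bm_1..bm_n).
// Proposals leaving [0,1] are rejected (the priors' support).  Uses R's RNG
// so results are reproducible under set.seed().  Returns a matrix with
// n_chains * (n_iter - n_warmup) rows (chain-major blocks) and 1 + n
// columns (bt first).
// [[Rcpp::export]]
NumericMatrix sample_rater_cpp(IntegerVector y, NumericVector mu,
                               NumericVector sigma, double tau,
                               int bt_prior_type, double bt_prior_mu,
                               double bt_prior_sigma, int n_chains,
                               int n_iter, int n_warmup, double prop_sd,
                               int sweeps_per_iter) {
  int n = y.size();
  int n_keep = n_iter - n_warmup;
  NumericMatrix out(n_chains * n_keep, n + 1);
  RNGScope scope;

  for (int c = 0; c < n_chains; ++c) {
    // overdispersed initialization
    double bt = unif_rand();
    std::vector<double> bm(n), lp_bm(n), ll(n);
    for (int i = 0; i < n; ++i) {
      double b = mu[i] + 0.5 * (unif_rand() - 0.5);
      if (b < 0.02) b = 0.02;
      if (b > 0.98) b = 0.98;
      bm[i] = b;
      double z = (b - mu[i]) / sigma[i];
      lp_bm[i] = -0.5 * z * z;
      ll[i] = loglik_term(y[i], b, bt, tau);
    }
    double lp_bt = bt_log_prior_kernel(bt, bt_prior_type, bt_prior_mu,
                                       bt_prior_sigma);

    for (int it = 0; it < n_iter; ++it) {
      for (int s = 0; s < sweeps_per_iter; ++s) {
        // update bt
        double bt_new = bt + prop_sd * norm_rand();
        if (bt_new >= 0.0 && bt_new <= 1.0) {
          double lp_bt_new = bt_log_prior_kernel(bt_new, bt_prior_type,
                                                 bt_prior_mu, bt_prior_sigma);
          double delta = lp_bt_new - lp_bt;
          std::vector<double> ll_new(n);
          for (int i = 0; i < n; ++i) {
            ll_new[i] = loglik_term(y[i], bm[i], bt_new, tau);
            delta += ll_new[i] - ll[i];
          }
          if (delta >= 0.0 || unif_rand() < std::exp(delta)) {
            bt = bt_new;
            lp_bt = lp_bt_new;
            ll = ll_new;
          }
        }
        // update each bm
        for (int i = 0; i < n; ++i) {
          double b_new = bm[i] + prop_sd * norm_rand();
          if (b_new < 0.0 || b_new > 1.0) continue;
          double z = (b_new - mu[i]) / sigma[i];
          double lp_new = -0.5 * z * z;
          double ll_new = loglik_term(y[i], b_new, bt, tau);
          double delta = (lp_new - lp_bm[i]) + (ll_new - ll[i]);
          if (delta >= 0.0 || unif_rand() < std::exp(delta)) {
            bm[i] = b_new;
            lp_bm[i] = lp_new;
            ll[i] = ll_new;
          }
        }
      }
      if (it >= n_warmup) {
        int row = c * n_keep + (it - n_warmup);
        out(row, 0) = bt;
        for (int i = 0; i < n; ++i) out(row, i + 1) = bm[i];
      }
    }
  }
  return out;
}
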