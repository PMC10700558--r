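#include <Rcpp.h>
using namespace Rcpp;

// Per-trial response probabilities of the two observers.
//
// The belief state (mu, tau) is carried across stimuli and trials; it depends
// only on the stimulus sequence, never on the choices, so the q-series can be
// computed once per parameter vector and reused for likelihoods and for
// simulation.
//
// u1, u2 : stimulus features (already on the model scale)
// r      : per-trial precision ratio pi_u / pi_x (ignored for the static model)
// pi_u   : sensory precision
// b      : response bias on the erf-argument scale
// dynamic: 1 for the learning observer (M1), 0 for the static control (M0)
// mu0, tau0 : initial belief state (M1 only)
//
// Returns q = P(answer "first stimulus higher") per trial, plus the belief
// trajectory for diagnostics.
// [[Rcpp::export]]
List cpp_trial_q(NumericVector u1, NumericVector u2, NumericVector r,
                 double pi_u, double b, int dynamic,
                 double mu0, double tau0) {
  int n = u1.size();
  NumericVector q(n), mu_pre(n), tau1v(n), tau2v(n), mu1v(n), mu2v(n);
  double mu = mu0, tau = tau0;
  const double sqrt2 = M_SQRT2;
  for (int t = 0; t < n; ++t) {
    double R;
    if (dynamic) {
      mu_pre[t] = mu;
      double tau1 = 1.0 - 1.0 / (1.0 + tau + r[t]);
      double mu1 = mu + tau1 * (u1[t] - mu);
      double tau2 = 1.0 - 1.0 / (1.0 + tau1 + r[t]);
      double mu2 = mu1 + tau2 * (u2[t] - mu1);
      double alpha = std::sqrt(pi_u / (2.0 * (tau1 + tau2)));
      R = alpha * (mu1 - mu2);
      tau1v[t] = tau1; tau2v[t] = tau2; mu1v[t] = mu1; mu2v[t] = mu2;
      mu = mu2; tau = tau2;
    } else {
      R = 0.5 * std::sqrt(pi_u) * (u1[t] - u2[t]);
      mu_pre[t] = NA_REAL;
    }
    // 0.5 * (1 + erf(z)) == pnorm(z * sqrt(2))
    q[t] = R::pnorm((R + b) * sqrt2, 0.0, 1.0, 1, 0);
  }
  return List::create(_["q"] = q, _["mu_pre"] = mu_pre,
                      _["tau1"] = tau1v, _["tau2"] = tau2v,
                      _["mu1"] = mu1v, _["mu2"] = mu2v,
                      _["mu_end"] = mu, _["tau_end"] = tau);
}
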