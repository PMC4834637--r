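// Sparse Bayesian (automatic relevance determination) logistic regression by
// constructive marginal-likelihood maximization. Each weight carries a
// Gaussian prior N(0, 1/alpha_i); the Laplace approximation turns the
// logistic likelihood into a local Gaussian one (IRLS working responses),
// under which the per-feature sparsity statistics
//   s_i = phi_i' C_{-i}^-1 phi_i,   q_i = phi_i' C_{-i}^-1 t_hat
// (C_{-i} the model covariance with feature i excluded) determine the
// evidence-optimal precision: alpha_i = s_i^2 / (q_i^2 - s_i) when
// q_i^2 > s_i, infinite otherwise. The model starts from the bias-only
// configuration and repeatedly (a) re-estimates precisions of in-model
// features, (b) deletes features whose optimal precision is infinite
// (weights exactly zero), and (c) adds the out-of-model feature with the
// largest positive evidence gain. The bias rides on a fixed broad prior and
// is never deleted. This bottom-up search reaches the sparse evidence
// optimum that top-down precision updates miss: starting all features broad
// lets the model latch onto training noise, a local maximum in which
// irrelevant features retain finite precision.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double softplus(const double x) {
  return (x > 30.0) ? x : std::log1p(std::exp(x));
}

static double penalized_nll(const vec &eta, const vec &y, const vec &aa,
                            const vec &wa) {
  double ll = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i)
    ll += y(i) * eta(i) - softplus(eta(i));
  return -ll + 0.5 * dot(aa, square(wa));
}

// Penalized-logistic Newton (IRLS with backtracking) at fixed precisions.
static void laplace_fit(const mat &Pa, const vec &y, const vec &aa, vec &wa,
                        const int max_newton) {
  vec eta = Pa * wa;
  for (int nt = 0; nt < max_newton; ++nt) {
    const vec p = 1.0 / (1.0 + exp(-eta));
    const vec g = Pa.t() * (y - p) - aa % wa;
    const vec b = clamp(p % (1.0 - p), 1e-10, datum::inf);
    mat H = Pa.t() * (Pa.each_col() % b);
    H.diag() += aa;
    const vec delta = solve(H, g, solve_opts::likely_sympd);
    const double obj0 = penalized_nll(eta, y, aa, wa);
    double step = 1.0;
    vec wn, etan;
    for (;;) {
      wn = wa + step * delta;
      etan = Pa * wn;
      if (penalized_nll(etan, y, aa, wn) <= obj0 + 1e-12 || step < 1e-6)
        break;
      step *= 0.5;
    }
    wa = wn;
    eta = etan;
    if (max(abs(step * delta)) < 1e-8) break;
  }
}

// [[Rcpp::export(name = ".ard_logistic_cpp")]]
Rcpp::List ard_logistic_cpp(const arma::mat &Phi, const arma::vec &y,
                            const int bias_index, const double alpha_bias,
                            const int max_iter, const double tol,
                            const double prune_threshold, const int max_newton,
                            const double add_gain_tol) {
  const uword n = Phi.n_rows, mtot = Phi.n_cols;
  const uword bias = (uword)bias_index;  // 0-based column of the constant
  vec alpha(mtot);
  alpha.fill(datum::inf);
  alpha(bias) = alpha_bias;
  vec w = zeros<vec>(mtot);
  std::vector<uword> active;  // excludes the bias; bias handled separately
  int it = 0;
  bool conv = false;

  for (it = 1; it <= max_iter; ++it) {
    // ---- Laplace refit on the current configuration
    uvec cols(active.size() + 1);
    for (size_t j = 0; j < active.size(); ++j) cols(j) = active[j];
    cols(active.size()) = bias;
    mat Pa = Phi.cols(cols);
    vec aa = alpha(cols);
    vec wa = w(cols);
    laplace_fit(Pa, y, aa, wa, max_newton);
    w.zeros();
    w(cols) = wa;

    // ---- local Gaussian (IRLS) quantities
    const vec eta = Pa * wa;
    const vec p = 1.0 / (1.0 + exp(-eta));
    const vec b = clamp(p % (1.0 - p), 1e-10, datum::inf);
    const vec r = b % eta + (y - p);  // = B t_hat
    mat H = Pa.t() * (Pa.each_col() % b);
    H.diag() += aa;
    const mat Sigma = inv_sympd(H);

    // ---- sparsity statistics for every feature
    const mat U = Pa.each_col() % b;       // B Phi_A
    const mat G = U.t() * Phi;             // k x m
    const mat T = Sigma * G;
    const rowvec Sraw = sum(square(Phi) % repmat(b, 1, mtot), 0) -
                        sum(G % T, 0);
    const vec PhiTr = Phi.t() * r;
    const vec Qraw = PhiTr - G.t() * (Sigma * (Pa.t() * r));

    // ---- actions
    bool deleted = false, added = false;
    double max_rel = 0.0;
    std::vector<uword> keep;
    keep.reserve(active.size());
    for (const uword i : active) {
      const double denom = std::max(alpha(i) - Sraw(i), 1e-12);
      const double s = alpha(i) * Sraw(i) / denom;
      const double q = alpha(i) * Qraw(i) / denom;
      if (q * q <= s) {
        deleted = true;           // evidence-optimal precision is infinite
        alpha(i) = datum::inf;
        w(i) = 0.0;
        continue;
      }
      const double anew = s * s / (q * q - s);
      if (anew > prune_threshold) {
        deleted = true;
        alpha(i) = datum::inf;
        w(i) = 0.0;
        continue;
      }
      const double rel = std::abs(anew - alpha(i)) / alpha(i);
      if (rel > max_rel) max_rel = rel;
      alpha(i) = anew;
      keep.push_back(i);
    }
    active = keep;

    double best_gain = add_gain_tol;
    sword best_i = -1;
    if (!deleted) {  // stats are stale right after a deletion
      for (uword i = 0; i < mtot; ++i) {
        if (i == bias || std::isfinite(alpha(i))) continue;
        const double S = Sraw(i), Q = Qraw(i);
        if (S <= 0.0 || Q * Q <= S) continue;
        const double gain = 0.5 * ((Q * Q - S) / S + std::log(S / (Q * Q)));
        if (gain > best_gain) {
          best_gain = gain;
          best_i = (sword)i;
        }
      }
      if (best_i >= 0) {
        const double S = Sraw((uword)best_i), Q = Qraw((uword)best_i);
        alpha((uword)best_i) = S * S / (Q * Q - S);
        active.push_back((uword)best_i);
        added = true;
      }
    }

    if (!deleted && !added && max_rel < tol) {
      conv = true;
      break;
    }
  }

  // ---- final Laplace fit and evidence on the converged configuration
  uvec cols(active.size() + 1);
  for (size_t j = 0; j < active.size(); ++j) cols(j) = active[j];
  cols(active.size()) = bias;
  mat Pa = Phi.cols(cols);
  vec aa = alpha(cols);
  vec wa = w(cols);
  laplace_fit(Pa, y, aa, wa, max_newton);
  w.zeros();
  w(cols) = wa;
  const vec eta = Pa * wa;
  double loglik = 0.0;
  for (uword i = 0; i < n; ++i) loglik += y(i) * eta(i) - softplus(eta(i));
  const vec p = 1.0 / (1.0 + exp(-eta));
  const vec b = clamp(p % (1.0 - p), 1e-10, datum::inf);
  mat H = Pa.t() * (Pa.each_col() % b);
  H.diag() += aa;
  const mat R = chol(H);
  const double evidence = loglik - 0.5 * dot(aa, square(wa)) +
                          0.5 * sum(log(aa)) - sum(log(R.diag()));

  uvec active_out(active.size() + 1);
  for (size_t j = 0; j < active.size(); ++j) active_out(j) = active[j];
  active_out(active.size()) = bias;
  vec alpha_out = alpha;
  return Rcpp::List::create(
      Rcpp::Named("weights") = w, Rcpp::Named("alphas") = alpha_out,
      Rcpp::Named("active") = sort(active_out) + 1,
      Rcpp::Named("iterations") = it, Rcpp::Named("converged") = conv,
      Rcpp::Named("evidence") = evidence);
}
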