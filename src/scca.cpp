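// Core alternating solver for L1-regularized sparse CCA on the cross-product
// matrix S = X1' X2 (columns of X1, X2 standardized upstream). Each canonical
// component maximizes v1' S v2 subject to ||v|| <= 1 and ||v||_1 <= c; the
// solved component is deflated from S by rank-1 subtraction.
//
// All matrix arithmetic here is written as plain fixed-order loops rather
// than BLAS calls: selection decisions downstream depend on exact zero
// patterns and argmax choices, and optimized BLAS kernels can change their
// reduction order with buffer alignment, flipping near-tied bifurcations
// between otherwise identical runs. The matrices are small (p1 ~ 10), so
// the scalar loops cost nothing.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// y = M v, fixed accumulation order
static void matvec(const mat &M, const vec &v, vec &y) {
  const uword nr = M.n_rows, nc = M.n_cols;
  y.zeros(nr);
  for (uword j = 0; j < nc; ++j) {
    const double vj = v(j);
    if (vj == 0.0) continue;
    const double *col = M.colptr(j);
    for (uword i = 0; i < nr; ++i) y(i) += col[i] * vj;
  }
}

// y = M' v, fixed accumulation order
static void tmatvec(const mat &M, const vec &v, vec &y) {
  const uword nr = M.n_rows, nc = M.n_cols;
  y.set_size(nc);
  for (uword j = 0; j < nc; ++j) {
    const double *col = M.colptr(j);
    double acc = 0.0;
    for (uword i = 0; i < nr; ++i) acc += col[i] * v(i);
    y(j) = acc;
  }
}

static double dot_fixed(const vec &a, const vec &b) {
  double acc = 0.0;
  for (uword i = 0; i < a.n_elem; ++i) acc += a(i) * b(i);
  return acc;
}

static double norm2_fixed(const vec &a) {
  double acc = 0.0;
  for (uword i = 0; i < a.n_elem; ++i) acc += a(i) * a(i);
  return std::sqrt(acc);
}

static double norm1_fixed(const vec &a) {
  double acc = 0.0;
  for (uword i = 0; i < a.n_elem; ++i) acc += std::abs(a(i));
  return acc;
}

// Project a onto {v : ||v||_2 = 1, ||v||_1 <= c} by soft-thresholding with
// the smallest threshold (bisection) that meets the L1 bound. c >= 1 keeps
// the constraint feasible (any unit-L2 vector has L1 >= 1).
static vec l1l2_project_cpp(const vec &a, const double c, bool &all_zero) {
  all_zero = false;
  const double n2 = norm2_fixed(a);
  if (n2 <= 0.0) {
    all_zero = true;
    return zeros<vec>(a.n_elem);
  }
  vec v = a / n2;
  if (norm1_fixed(v) <= c) return v;
  double lo = 0.0, hi = max(abs(a));
  vec s(a.n_elem);
  for (int i = 0; i < 60; ++i) {
    const double mid = 0.5 * (lo + hi);
    for (uword k = 0; k < a.n_elem; ++k) {
      const double m = std::abs(a(k)) - mid;
      s(k) = m > 0.0 ? (a(k) > 0.0 ? m : -m) : 0.0;
    }
    const double sn2 = norm2_fixed(s);
    if (sn2 <= 0.0 || norm1_fixed(s) / sn2 <= c)
      hi = mid;
    else
      lo = mid;
  }
  for (uword k = 0; k < a.n_elem; ++k) {
    const double m = std::abs(a(k)) - hi;
    s(k) = m > 0.0 ? (a(k) > 0.0 ? m : -m) : 0.0;
  }
  // entries surviving only at machine-noise level are not support: the
  // float L1/L2 ratio test cannot see a coordinate 1e-16 of the largest,
  // and whether it survives would depend on rounding order
  double mx = 0.0;
  for (uword k = 0; k < a.n_elem; ++k) mx = std::max(mx, std::abs(s(k)));
  for (uword k = 0; k < a.n_elem; ++k)
    if (std::abs(s(k)) <= 1e-12 * mx) s(k) = 0.0;
  const double sn2 = norm2_fixed(s);
  if (sn2 <= 0.0) {
    // Threshold collapsed everything (ties at the maximum); fall back to a
    // single coordinate at the first argmax, which satisfies L1 = L2 = 1.
    vec out = zeros<vec>(a.n_elem);
    const uword i = index_max(abs(a));
    out(i) = (a(i) >= 0.0) ? 1.0 : -1.0;
    return out;
  }
  return s / sn2;
}

// [[Rcpp::export(name = ".scca_core_cpp")]]
Rcpp::List scca_core_cpp(const arma::mat &S, const double c1, const double c2,
                         const int q, const int max_iter, const double tol,
                         const int power_steps) {
  const uword p1 = S.n_rows, p2 = S.n_cols;
  mat V1 = zeros<mat>(p1, q), V2 = zeros<mat>(p2, q);
  vec d = zeros<vec>(q);
  ivec iters = zeros<ivec>(q);
  Rcpp::LogicalVector converged(q);
  mat W = S;  // deflated working copy
  vec tmp1(p1), tmp2(p2);

  for (int k = 0; k < q; ++k) {
    double fro = 0.0;
    for (uword j = 0; j < p2; ++j)
      for (uword i = 0; i < p1; ++i) fro += W(i, j) * W(i, j);
    if (std::sqrt(fro) < 1e-12) { converged[k] = true; continue; }

    // Initialize v2 at the leading right singular direction (plain power
    // steps on W'W from the deterministic column-norm profile).
    vec v2(p2);
    for (uword j = 0; j < p2; ++j) {
      double acc = 0.0;
      for (uword i = 0; i < p1; ++i) acc += W(i, j) * W(i, j);
      v2(j) = std::sqrt(acc);
    }
    double n2 = norm2_fixed(v2);
    if (n2 <= 0.0) { converged[k] = true; continue; }
    v2 /= n2;
    for (int s = 0; s < power_steps; ++s) {
      matvec(W, v2, tmp1);
      tmatvec(W, tmp1, tmp2);
      const double tn = norm2_fixed(tmp2);
      if (tn <= 0.0) break;
      v2 = tmp2 / tn;
    }
    if (v2(index_max(abs(v2))) < 0.0) v2 = -v2;  // sign convention

    vec v1 = zeros<vec>(p1);
    double obj = 0.0, obj_prev = datum::inf;
    bool zero_flag = false, conv = false;
    int it = 0;
    for (it = 1; it <= max_iter; ++it) {
      matvec(W, v2, tmp1);
      v1 = l1l2_project_cpp(tmp1, c1, zero_flag);
      if (zero_flag) break;
      tmatvec(W, v1, tmp2);
      v2 = l1l2_project_cpp(tmp2, c2, zero_flag);
      if (zero_flag) break;
      matvec(W, v2, tmp1);
      obj = dot_fixed(v1, tmp1);
      if (std::abs(obj - obj_prev) < tol * std::max(1.0, std::abs(obj_prev))) {
        conv = true;
        break;
      }
      obj_prev = obj;
    }
    if (zero_flag) { converged[k] = true; iters(k) = it; continue; }
    matvec(W, v2, tmp1);
    d(k) = dot_fixed(v1, tmp1);
    V1.col(k) = v1;
    V2.col(k) = v2;
    iters(k) = it;
    converged[k] = conv;
    for (uword j = 0; j < p2; ++j) {
      const double f = d(k) * v2(j);
      if (f == 0.0) continue;
      for (uword i = 0; i < p1; ++i) W(i, j) -= v1(i) * f;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("v1") = V1, Rcpp::Named("v2") = V2,
      Rcpp::Named("canonical_values") = d, Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = converged);
}
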