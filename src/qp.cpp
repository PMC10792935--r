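// Active-set quadratic programming for shape-constrained smoothing splines.
//
// Solves  min_x (1/2) x'Gx + c'x  s.t.  Cx >= 0  with G positive definite.
// The constant vector is always feasible for the monotonicity constraint
// sets built by this package (every row annihilates constants), so the
// solver starts there with an empty working set and proceeds by the
// textbook primal active-set iteration: equality-constrained subproblems
// in the null space of the working rows, blocking-constraint line search,
// and Lagrange-multiplier tests for optimality.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Solve A x = b for symmetric positive (semi-)definite A.  Cholesky when
// possible; otherwise an eigendecomposition with machine-precision
// clamping, which keeps the tiny-but-genuine eigenvalues that arise for
// very small smoothing factors (A = roughness kernel + tiny ridge).
bool solve_spd(mat& out, const mat& A, const mat& B) {
  mat R;
  if (chol(R, A)) {
    out = solve(trimatu(R), solve(trimatl(R.t()), B));
    return true;
  }
  vec d;
  mat V;
  if (!eig_sym(d, V, A)) return false;
  double floor_ = std::abs(d.max()) * 1e-14 + datum::eps;
  d = clamp(d, floor_, datum::inf);
  mat VtB = V.t() * B;
  VtB.each_col() /= d;
  out = V * VtB;
  return true;
}

// Orthonormal null-space basis of C (empty C -> identity).
mat null_basis(const mat& C, unsigned int n) {
  if (C.n_rows == 0) return eye<mat>(n, n);
  mat Z = null(C);
  if (Z.n_rows == 0) Z.set_size(n, 0);
  return Z;
}

struct QPResult {
  vec x;
  std::vector<unsigned int> working;
  bool converged;
  int iterations;
};

QPResult qp_solve(const mat& G, const vec& cvec, const mat& C,
                  const vec& x0, int maxit,
                  const std::vector<unsigned int>& ws0 =
                      std::vector<unsigned int>()) {
  const unsigned int n = G.n_rows;
  const unsigned int m = C.n_rows;
  QPResult res;
  res.x = x0;
  res.converged = false;
  res.iterations = 0;

  std::vector<bool> in_ws(m, false);
  std::vector<unsigned int> ws;   // working set (row indices into C)
  for (unsigned int j : ws0) {
    // warm start: keep rows the start point satisfies as equalities
    if (j < m && std::abs(dot(C.row(j), res.x)) <=
                     1e-8 * (1.0 + norm(res.x, "inf"))) {
      ws.push_back(j);
      in_ws[j] = true;
    }
  }

  const double ptol = 1e-11;
  const double mtol = 1e-9;

  for (int iter = 0; iter < maxit; ++iter) {
    res.iterations = iter + 1;
    vec g = G * res.x + cvec;

    mat CW(ws.size(), n);
    for (size_t j = 0; j < ws.size(); ++j) CW.row(j) = C.row(ws[j]);
    mat Z = null_basis(CW, n);

    vec p(n, fill::zeros);
    if (Z.n_cols > 0) {
      mat ZGZ = Z.t() * G * Z;
      mat q;
      if (!solve_spd(q, ZGZ, -(Z.t() * g))) break;
      p = Z * q;
    }

    double pscale = 1.0 + norm(res.x, "inf");
    // stationarity: a negligible step, or a step whose predicted
    // objective decrease -(g'p + p'Gp/2) is below rounding noise (the
    // step-norm test alone is unreachable for badly conditioned G)
    double obj = 0.5 * dot(res.x, G * res.x) + dot(cvec, res.x);
    double pred = -(dot(g, p) + 0.5 * dot(p, G * p));
    if (norm(p, "inf") <= ptol * pscale ||
        pred <= 1e-14 * (1.0 + std::abs(obj))) {
      if (ws.empty()) { res.converged = true; break; }
      // multipliers: least-squares solution of CW' * lam = g
      vec lam;
      bool ok = solve(lam, CW.t(), g, solve_opts::no_approx);
      if (!ok) lam = pinv(CW.t()) * g;
      double gscale = 1.0 + norm(g, "inf");
      uword worst = 0;
      double worst_val = -mtol * gscale;
      bool found = false;
      for (uword j = 0; j < lam.n_elem; ++j) {
        if (lam(j) < worst_val) { worst_val = lam(j); worst = j; found = true; }
      }
      if (!found) { res.converged = true; break; }
      in_ws[ws[worst]] = false;
      ws.erase(ws.begin() + worst);
    } else {
      // step length limited by blocking constraints
      double alpha = 1.0;
      int blocking = -1;
      for (unsigned int j = 0; j < m; ++j) {
        if (in_ws[j]) continue;
        double cp = dot(C.row(j), p);
        if (cp < -1e-13 * pscale) {
          double cx = dot(C.row(j), res.x);
          if (cx < 0) cx = 0;
          double aj = cx / (-cp);  // cx >= 0, cp < 0
          if (aj < alpha) { alpha = aj; blocking = (int)j; }
        }
      }
      res.x += alpha * p;
      if (blocking >= 0) { in_ws[blocking] = true; ws.push_back((unsigned)blocking); }
      else if (alpha >= 1.0) {
        // full step taken with no blocking constraint: loop once more to
        // test optimality / multipliers
        continue;
      }
    }
  }
  res.working = ws;
  return res;
}

// active rows at solution: |C_j x| <= tol * (1 + max|x|)
std::vector<unsigned int> active_rows(const mat& C, const vec& x, double tol) {
  std::vector<unsigned int> act;
  double scale = 1.0 + norm(x, "inf");
  for (uword j = 0; j < C.n_rows; ++j) {
    if (std::abs(dot(C.row(j), x)) <= tol * scale) act.push_back((unsigned)j);
  }
  return act;
}

}  // namespace

// [[Rcpp::export(name = ".qp_active_set_cpp")]]
Rcpp::List qp_active_set_cpp(const arma::mat& G, const arma::vec& cvec,
                             const arma::mat& Cmat, const arma::vec& x0,
                             double tol_active, int maxit) {
  QPResult r = qp_solve(G, cvec, Cmat, x0, maxit);
  std::vector<unsigned int> act = active_rows(Cmat, r.x, tol_active);
  Rcpp::IntegerVector act1(act.size());
  for (size_t i = 0; i < act.size(); ++i) act1[i] = (int)act[i] + 1;
  return Rcpp::List::create(
      Rcpp::Named("a") = r.x,
      Rcpp::Named("active_rows") = act1,
      Rcpp::Named("converged") = r.converged,
      Rcpp::Named("iterations") = r.iterations);
}

// Full lambda-grid sweep for one shape spec: for each lambda build the QP,
// solve it, determine the active set, its null-space basis Z and the
// modified GCV score
//   n * ||W(a - y)||^2 / (Tr(I - rho * A_lambda))^2,
//   A_lambda = 2 (lambda/n) Z (Z' G Z)^-1 Z' W'W.
// Returns the best (minimal-mGCV) fit; ties keep the smaller lambda.
// [[Rcpp::export(name = ".fit_sweep_cpp")]]
Rcpp::List fit_sweep_cpp(const arma::mat& K, const arma::vec& w,
                         const arma::vec& y, const arma::mat& Cmat,
                         const arma::vec& lambdas, double rho,
                         double tol_active, int maxit) {
  const unsigned int n = K.n_rows;
  const unsigned int L = lambdas.n_elem;
  vec w2 = square(w);
  mat W2 = diagmat(w2);
  vec x0(n);
  x0.fill(mean(y));
  vec xprev = x0;
  std::vector<unsigned int> wsprev;
  bool have_prev = false;

  vec mgcv(L);
  mgcv.fill(datum::inf);
  vec wrss(L);
  wrss.fill(datum::nan);
  Rcpp::LogicalVector ok(L);

  double best = datum::inf;
  int best_i = -1;
  vec best_a;
  std::vector<unsigned int> best_act;

  for (unsigned int l = 0; l < L; ++l) {
    double lam = lambdas(l);
    mat G = 2.0 * (K + (lam / n) * W2);
    vec cvec = -2.0 * (lam / n) * (w2 % y);
    // warm start from the previous (smaller) lambda's solution, which
    // is feasible for the same constraint set
    QPResult r = have_prev ? qp_solve(G, cvec, Cmat, xprev, maxit, wsprev)
                           : qp_solve(G, cvec, Cmat, x0, maxit);
    ok[l] = r.converged;
    if (!r.converged) continue;
    xprev = r.x;
    wsprev = r.working;
    have_prev = true;

    std::vector<unsigned int> act = active_rows(Cmat, r.x, tol_active);
    mat CA(act.size(), n);
    for (size_t j = 0; j < act.size(); ++j) CA.row(j) = Cmat.row(act[j]);
    mat Z = null_basis(CA, n);

    vec resid = w % (r.x - y);
    double rss = dot(resid, resid);
    wrss(l) = rss;

    double score = datum::inf;
    if (Z.n_cols > 0) {
      mat ZGZ = Z.t() * G * Z;
      mat ZW2Z = Z.t() * W2 * Z;
      mat Minv_N;
      if (solve_spd(Minv_N, ZGZ, ZW2Z)) {
        double trA = 2.0 * (lam / n) * trace(Minv_N);
        double denom = (double)n - rho * trA;
        if (denom > 0) score = n * rss / (denom * denom);
      }
    }
    mgcv(l) = score;
    if (score < best) {
      best = score;
      best_i = (int)l;
      best_a = r.x;
      best_act = act;
    }
  }

  Rcpp::IntegerVector act1(best_act.size());
  for (size_t i = 0; i < best_act.size(); ++i) act1[i] = (int)best_act[i] + 1;
  return Rcpp::List::create(
      Rcpp::Named("best_index") = best_i + 1,  // 0 if none converged/finite
      Rcpp::Named("a") = (best_i >= 0) ? Rcpp::wrap(best_a)
                                       : Rcpp::wrap(Rcpp::NumericVector(0)),
      Rcpp::Named("active_rows") = act1,
      Rcpp::Named("mgcv") = mgcv,
      Rcpp::Named("wrss") = wrss,
      Rcpp::Named("converged") = ok);
}
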