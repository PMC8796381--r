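// Dense bounded-variable two-phase primal simplex.
//
// Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
// with lb/ub possibly infinite.  Designed for steady-state metabolic LPs:
// m (metabolites) and n (reactions) up to a few hundred, coefficients O(1),
// bounds O(1000).  Full-tableau updates, Dantzig pricing with a Bland's-rule
// fallback against cycling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const int AT_LB = 0, AT_UB = 1, FREE = 2, BASIC = 3;

struct Tableau {
  mat D;                 // B^{-1} [A | I_art], m x N
  vec xB;                // values of basic variables
  std::vector<int> basis;    // column index basic in each row
  std::vector<int> status;   // per-column status
  vec lb, ub;            // per-column bounds (incl. artificials)
  int m, n, N;           // rows, structural cols, total cols
};

// Value of a nonbasic column.
inline double nb_value(const Tableau& T, int j) {
  if (T.status[j] == AT_LB) return T.lb[j];
  if (T.status[j] == AT_UB) return T.ub[j];
  return 0.0;  // FREE
}

// One simplex phase on cost vector cc (minimization).  Returns:
//  0 optimal, 1 unbounded, 2 iteration limit.
int run_phase(Tableau& T, const vec& cc, double tol_opt, double tol_piv,
              int max_iter, int bland_after) {
  const int m = T.m, N = T.N;
  for (int iter = 0; iter < max_iter; ++iter) {
    bool bland = iter >= bland_after;

    // reduced costs: rc = cc - D' * cc_B
    vec cB(m);
    for (int i = 0; i < m; ++i) cB[i] = cc[T.basis[i]];
    rowvec y = cB.t() * T.D;

    // entering column
    int e = -1, dir = 0;
    double best = tol_opt;
    for (int j = 0; j < N; ++j) {
      if (T.status[j] == BASIC) continue;
      if (T.lb[j] == T.ub[j]) continue;  // fixed, cannot move
      double rc = cc[j] - y[j];
      double viol = 0.0;
      int d = 0;
      if (T.status[j] == AT_LB && rc < -tol_opt) { viol = -rc; d = +1; }
      else if (T.status[j] == AT_UB && rc > tol_opt) { viol = rc; d = -1; }
      else if (T.status[j] == FREE && std::abs(rc) > tol_opt) {
        viol = std::abs(rc); d = rc < 0 ? +1 : -1;
      }
      if (d != 0) {
        if (bland) { e = j; dir = d; break; }
        if (viol > best) { best = viol; e = j; dir = d; }
      }
    }
    if (e < 0) return 0;  // optimal

    // ratio test along +dir * column e
    vec w = T.D.col(e);
    double step = datum::inf;
    int leave = -1, leave_to = AT_LB;
    // entering variable's own opposite bound
    if (std::isfinite(T.ub[e]) && std::isfinite(T.lb[e]))
      step = T.ub[e] - T.lb[e];
    for (int i = 0; i < m; ++i) {
      double wi = dir * w[i];
      int bi = T.basis[i];
      double lim = datum::inf;
      int to = AT_LB;
      if (wi > tol_piv) {                     // basic value decreases
        if (std::isfinite(T.lb[bi])) { lim = (T.xB[i] - T.lb[bi]) / wi; to = AT_LB; }
      } else if (wi < -tol_piv) {             // basic value increases
        if (std::isfinite(T.ub[bi])) { lim = (T.ub[bi] - T.xB[i]) / (-wi); to = AT_UB; }
      } else continue;
      if (lim < -1e-11) lim = 0.0;
      bool better;
      if (bland)
        better = lim < step - 1e-12 ||
                 (lim < step + 1e-12 && (leave < 0 || bi < T.basis[leave]));
      else
        better = lim < step - 1e-12 ||
                 (lim < step + 1e-12 && (leave < 0 || std::abs(w[i]) > std::abs(w[leave])));
      if (better) { step = lim; leave = i; leave_to = to; }
    }

    if (!std::isfinite(step)) return 1;  // unbounded

    if (leave < 0) {
      // bound flip of the entering variable
      T.xB -= (dir * step) * w;
      T.status[e] = (T.status[e] == AT_LB) ? AT_UB : AT_LB;
      continue;
    }

    // pivot: e enters, basis[leave] exits to bound leave_to
    double enter_val = nb_value(T, e) + dir * step;
    for (int i = 0; i < m; ++i)
      if (i != leave) T.xB[i] -= dir * step * w[i];
    int out = T.basis[leave];
    T.status[out] = std::isfinite(T.lb[out]) || std::isfinite(T.ub[out])
                        ? leave_to : FREE;
    double piv = T.D(leave, e);
    T.D.row(leave) /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = T.D(i, e);
      if (f != 0.0) T.D.row(i) -= f * T.D.row(leave);
    }
    T.basis[leave] = e;
    T.status[e] = BASIC;
    T.xB[leave] = enter_val;
  }
  return 2;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat& A, const arma::vec& b,
                         const arma::vec& c, const arma::vec& lb,
                         const arma::vec& ub, bool maximize,
                         double tol_feas = 1e-9, double tol_opt = 1e-9,
                         int max_iter = 0) {
  const int m = A.n_rows, n = A.n_cols;
  const int N = n + m;
  if (max_iter <= 0) max_iter = 200 * (N + 10);
  const int bland_after = 40 * (N + 10);
  const double tol_piv = 1e-10;

  Tableau T;
  T.m = m; T.n = n; T.N = N;
  T.lb.set_size(N); T.ub.set_size(N);
  T.status.assign(N, AT_LB);
  T.basis.resize(m);

  // start nonbasic structurals at the finite bound nearest zero
  vec x0(n, fill::zeros);
  for (int j = 0; j < n; ++j) {
    T.lb[j] = lb[j]; T.ub[j] = ub[j];
    if (std::isfinite(lb[j])) { T.status[j] = AT_LB; x0[j] = lb[j]; }
    else if (std::isfinite(ub[j])) { T.status[j] = AT_UB; x0[j] = ub[j]; }
    else { T.status[j] = FREE; x0[j] = 0.0; }
  }

  // residual, row signs chosen so artificials start >= 0
  vec r = b - A * x0;
  mat Asigned = A;
  vec bsigned = b;
  T.D.set_size(m, N);
  for (int i = 0; i < m; ++i) {
    double s = (r[i] < 0) ? -1.0 : 1.0;
    T.D.submat(i, 0, i, n - 1) = s * Asigned.row(i);
    bsigned[i] *= s;
    r[i] *= s;
  }
  T.D.cols(n, N - 1).zeros();
  for (int i = 0; i < m; ++i) {
    int aj = n + i;
    T.D(i, aj) = 1.0;
    T.lb[aj] = 0.0; T.ub[aj] = datum::inf;
    T.basis[i] = aj;
    T.status[aj] = BASIC;
  }
  T.xB = r;

  // phase 1: drive artificials to zero
  vec c1(N, fill::zeros);
  c1.subvec(n, N - 1).ones();
  int rc1 = run_phase(T, c1, tol_opt, tol_piv, max_iter, bland_after);
  double art = 0.0;
  for (int i = 0; i < m; ++i)
    if (T.basis[i] >= n) art += std::abs(T.xB[i]);
  for (int j = n; j < N; ++j)
    if (T.status[j] != BASIC) art += nb_value(T, j);
  double scale = std::max(1.0, norm(b, "inf"));
  if (rc1 == 2)
    return Rcpp::List::create(Rcpp::Named("status") = "iteration_limit");
  if (art > tol_feas * scale * 1e3 + 1e-7)
    return Rcpp::List::create(Rcpp::Named("status") = "infeasible");

  // fix artificials at zero for phase 2
  for (int j = n; j < N; ++j) {
    T.lb[j] = 0.0; T.ub[j] = 0.0;
    if (T.status[j] != BASIC) T.status[j] = AT_LB;
  }

  vec c2(N, fill::zeros);
  for (int j = 0; j < n; ++j) c2[j] = maximize ? -c[j] : c[j];
  int rc2 = run_phase(T, c2, tol_opt, tol_piv, max_iter, bland_after);
  if (rc2 == 1)
    return Rcpp::List::create(Rcpp::Named("status") = "unbounded");
  if (rc2 == 2)
    return Rcpp::List::create(Rcpp::Named("status") = "iteration_limit");

  // assemble primal solution
  vec x(n, fill::zeros);
  for (int j = 0; j < n; ++j)
    if (T.status[j] != BASIC) x[j] = nb_value(T, j);
  for (int i = 0; i < m; ++i)
    if (T.basis[i] < n) x[T.basis[i]] = T.xB[i];
  double obj = dot(c, x);

  return Rcpp::List::create(Rcpp::Named("status") = "optimal",
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = x);
}
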