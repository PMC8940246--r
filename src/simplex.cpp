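// Bounded-variable two-phase primal simplex for the LP
//
//   maximize  c'x   subject to  A x = b,  l <= x <= u
//
// used as the flux-balance backend.  Problem sizes here are small (tens to a
// few hundred columns), so the basis inverse is held densely and updated by
// an explicit pivot; it is refactorized periodically for stability.
//
// Status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Tableau {
  mat A;            // m x N (structural + artificial columns)
  vec b;            // right-hand side (length m)
  vec c;            // current phase objective (length N)
  vec lo, hi;       // variable bounds (length N)
  vec x;            // current values (length N)
  uvec basis;       // m basic column indices
  std::vector<bool> in_basis;
  mat Binv;         // basis inverse
  int m, N;
  double tol;

  void refactor() {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = A.col(basis[i]);
    Binv = inv(B);
  }

  // recompute basic variable values from nonbasic ones: xB = Binv (b - N xN)
  void recompute_basics() {
    vec rhs = b - A * x;
    for (int i = 0; i < m; ++i) rhs += A.col(basis[i]) * x(basis[i]);
    vec xb = Binv * rhs;
    for (int i = 0; i < m; ++i) x(basis[i]) = xb(i);
  }
};

// One simplex phase: optimize t.c over current feasible point.
// Returns 0 optimal, 2 unbounded, 3 iteration limit.
int simplex_phase(Tableau &t, int max_iter) {
  int iters_since_refactor = 0;
  bool bland = false;
  int stall = 0;
  double last_obj = dot(t.c, t.x);

  for (int iter = 0; iter < max_iter; ++iter) {
    if (iters_since_refactor >= 60) { t.refactor(); t.recompute_basics(); iters_since_refactor = 0; }

    // reduced costs d = c_N - N' y, y = Binv' c_B
    vec cb(t.m);
    for (int i = 0; i < t.m; ++i) cb(i) = t.c(t.basis[i]);
    vec y = t.Binv.t() * cb;

    // choose entering variable
    int enter = -1, dir = 0;  // dir +1: increase, -1: decrease
    double best = t.tol;
    for (int j = 0; j < t.N; ++j) {
      if (t.in_basis[j]) continue;
      if (t.lo(j) == t.hi(j)) continue;  // fixed
      double dj = t.c(j) - dot(t.A.col(j), y);
      bool at_lo = std::isfinite(t.lo(j)) && t.x(j) <= t.lo(j) + 1e-11;
      bool at_hi = std::isfinite(t.hi(j)) && t.x(j) >= t.hi(j) - 1e-11;
      bool free_var = !at_lo && !at_hi;
      int cand_dir = 0;
      if ((at_lo || free_var) && dj > t.tol) cand_dir = +1;
      else if ((at_hi || free_var) && dj < -t.tol) cand_dir = -1;
      if (cand_dir != 0) {
        double score = std::fabs(dj);
        if (bland) { enter = j; dir = cand_dir; break; }
        if (score > best) { best = score; enter = j; dir = cand_dir; }
      }
    }
    if (enter < 0) return 0;  // optimal

    // direction of basic variables: xB changes by -dir * w * step, w = Binv A_enter
    vec w = t.Binv * t.A.col(enter);

    // ratio test
    double limit = INF;       // max step for entering variable
    int leave = -1;           // index into basis
    double leave_bound = 0.0;
    // entering variable's own bound range
    double own_range = INF;
    if (dir > 0 && std::isfinite(t.hi(enter))) own_range = t.hi(enter) - t.x(enter);
    if (dir < 0 && std::isfinite(t.lo(enter))) own_range = t.x(enter) - t.lo(enter);
    limit = own_range;

    for (int i = 0; i < t.m; ++i) {
      double wi = dir * w(i);
      int bi = t.basis[i];
      if (wi > 1e-11) {  // basic decreases toward its lower bound
        if (std::isfinite(t.lo(bi))) {
          double r = (t.x(bi) - t.lo(bi)) / wi;
          if (r < limit - 1e-12) { limit = r; leave = i; leave_bound = t.lo(bi); }
        }
      } else if (wi < -1e-11) {  // basic increases toward its upper bound
        if (std::isfinite(t.hi(bi))) {
          double r = (t.x(bi) - t.hi(bi)) / wi;
          if (r < limit - 1e-12) { limit = r; leave = i; leave_bound = t.hi(bi); }
        }
      }
    }

    if (!std::isfinite(limit)) return 2;  // unbounded
    if (limit < 0) limit = 0;

    // apply step
    t.x(enter) += dir * limit;
    for (int i = 0; i < t.m; ++i) t.x(t.basis[i]) -= dir * w(i) * limit;

    if (leave >= 0) {
      // basis change
      int out = t.basis[leave];
      t.x(out) = leave_bound;  // snap exactly
      t.in_basis[out] = false;
      t.in_basis[enter] = true;
      t.basis[leave] = enter;
      // pivot update of Binv: row ops so that Binv*A_enter = e_leave
      double piv = w(leave);
      if (std::fabs(piv) < 1e-12) { t.basis[leave] = enter; t.refactor(); }
      else {
        rowvec prow = t.Binv.row(leave) / piv;
        for (int i = 0; i < t.m; ++i) {
          if (i == leave) continue;
          t.Binv.row(i) -= w(i) * prow;
        }
        t.Binv.row(leave) = prow;
      }
      ++iters_since_refactor;
    }
    // else: bound flip, basis unchanged

    double obj = dot(t.c, t.x);
    if (std::fabs(obj - last_obj) < 1e-13) { if (++stall > 2 * (t.N + t.m)) bland = true; }
    else { stall = 0; bland = false; }
    last_obj = obj;
  }
  return 3;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat &A, const arma::vec &b,
                         const arma::vec &c, const arma::vec &lb,
                         const arma::vec &ub, double tol = 1e-9,
                         int max_iter = 20000) {
  int m = A.n_rows, n = A.n_cols;
  Tableau t;
  t.m = m; t.N = n + m; t.tol = tol; t.b = b;
  t.A.set_size(m, t.N);
  t.A.cols(0, n - 1) = A;
  t.A.cols(n, t.N - 1) = eye(m, m);
  t.lo.set_size(t.N); t.hi.set_size(t.N);
  t.x.zeros(t.N);
  t.in_basis.assign(t.N, false);

  for (int j = 0; j < n; ++j) {
    t.lo(j) = lb(j); t.hi(j) = ub(j);
    // start nonbasic structurals at the finite bound of smallest magnitude
    double v;
    if (std::isfinite(lb(j)) && std::isfinite(ub(j)))
      v = (std::fabs(lb(j)) <= std::fabs(ub(j))) ? lb(j) : ub(j);
    else if (std::isfinite(lb(j))) v = lb(j);
    else if (std::isfinite(ub(j))) v = ub(j);
    else v = 0.0;
    t.x(j) = v;
  }

  // artificial variables absorb the residual; their sign fixes their bounds
  vec resid = b;
  for (int j = 0; j < n; ++j) if (t.x(j) != 0.0) resid -= A.col(j) * t.x(j);
  t.basis.set_size(m);
  vec c1 = zeros(t.N);
  for (int i = 0; i < m; ++i) {
    int aj = n + i;
    t.basis[i] = aj;
    t.in_basis[aj] = true;
    t.x(aj) = resid(i);
    if (resid(i) >= 0) { t.lo(aj) = 0; t.hi(aj) = INF; c1(aj) = -1.0; }
    else { t.lo(aj) = -INF; t.hi(aj) = 0; c1(aj) = 1.0; }
  }
  t.Binv = eye(m, m);

  // phase 1: drive artificials to zero
  t.c = c1;
  int st = simplex_phase(t, max_iter);
  double infeas = 0;
  for (int i = 0; i < m; ++i) infeas += std::fabs(t.x(n + i));
  if (st == 3 || infeas > std::max(1e-7, tol * 100)) {
    return Rcpp::List::create(Rcpp::Named("status") = (st == 3 ? 3 : 1),
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = Rcpp::NumericVector(0));
  }
  // fix artificials at zero for phase 2
  for (int i = 0; i < m; ++i) { t.lo(n + i) = 0; t.hi(n + i) = 0; t.x(n + i) = 0; }
  t.recompute_basics();

  // phase 2
  t.c = zeros(t.N);
  t.c.head(n) = c;
  st = simplex_phase(t, max_iter);
  if (st == 2 || st == 3) {
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = Rcpp::NumericVector(0));
  }

  vec xs = t.x.head(n);
  // clip tiny bound violations from floating point
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(lb(j)) && xs(j) < lb(j)) xs(j) = lb(j);
    if (std::isfinite(ub(j)) && xs(j) > ub(j)) xs(j) = ub(j);
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("objective") = dot(c, xs),
                            Rcpp::Named("x") = xs);
}
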