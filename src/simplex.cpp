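// Dense bounded-variable two-phase revised simplex.
//
// Solves   min c'x   s.t.  A x = b,  lb <= x <= ub
// which is the shape of every LP in this package: flux balance analysis
// (S v = 0 with flux bounds) and the minimum-|v| refinement used by the
// synthetic-lethality search. Models of this class are small and dense
// (tens to a few hundred rows), so a dense factor-per-iteration simplex
// is simpler and fast enough; no sparse machinery is needed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double INF = std::numeric_limits<double>::infinity();

namespace {

struct Tableau {
  mat A;          // m x N (structural + artificial columns)
  vec b, lb, ub, x;
  uvec basis;     // m basic variable indices
  std::vector<int> state; // nonbasic state: 0 basic, 1 at lb, 2 at ub, 3 free at value
  umat dummy;
};

// One simplex phase on the current basis. Returns 0 optimal, 1 unbounded,
// 2 iteration limit.
int simplex_phase(Tableau& T, const vec& cost, int max_iter, double tol) {
  const uword m = T.A.n_rows, N = T.A.n_cols;
  int iter = 0;
  const int bland_after = std::max(200, (int)(20 * (m + N)));
  while (true) {
    if (++iter > max_iter) return 2;
    bool bland = iter > bland_after;

    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = T.A.col(T.basis(i));
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB(i) = cost(T.basis(i));
    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 2;

    // pricing
    int q = -1, qdir = 0; double best = tol;
    for (uword j = 0; j < N; ++j) {
      if (T.state[j] == 0) continue;
      double dj = cost(j) - dot(y, T.A.col(j));
      double viol = 0; int dir = 0;
      if (T.state[j] == 1 && dj < -tol) { viol = -dj; dir = +1; }
      else if (T.state[j] == 2 && dj > tol) { viol = dj; dir = -1; }
      else if (T.state[j] == 3 && std::fabs(dj) > tol) { viol = std::fabs(dj); dir = dj < 0 ? +1 : -1; }
      if (dir != 0 && (viol > best || (bland && q < 0))) {
        q = (int)j; qdir = dir; best = viol;
        if (bland) break;
      }
    }
    if (q < 0) return 0; // optimal

    vec w;
    if (!solve(w, B, T.A.col(q), solve_opts::no_approx)) return 2;

    // ratio test: entering moves by t in direction qdir
    double tmax = INF; int leave = -1; int leave_to = 0; // 1 -> lb, 2 -> ub
    double range = T.ub(q) - T.lb(q);
    if (std::isfinite(range)) tmax = range; // bound flip limit
    for (uword i = 0; i < m; ++i) {
      double wi = qdir * w(i);
      uword bi = T.basis(i);
      if (wi > tol) {
        if (std::isfinite(T.lb(bi))) {
          double t = (T.x(bi) - T.lb(bi)) / wi;
          if (t < tmax - 1e-12 || (t <= tmax && leave < 0)) { tmax = t; leave = (int)i; leave_to = 1; }
        }
      } else if (wi < -tol) {
        if (std::isfinite(T.ub(bi))) {
          double t = (T.ub(bi) - T.x(bi)) / (-wi);
          if (t < tmax - 1e-12 || (t <= tmax && leave < 0)) { tmax = t; leave = (int)i; leave_to = 2; }
        }
      }
    }
    if (!std::isfinite(tmax)) return 1; // unbounded

    if (tmax < 0) tmax = 0;
    // update basic values
    for (uword i = 0; i < m; ++i) T.x(T.basis(i)) -= qdir * w(i) * tmax;
    T.x(q) += qdir * tmax;

    if (leave < 0) {
      // bound flip: entering hit its opposite bound, basis unchanged
      T.state[q] = qdir > 0 ? 2 : 1;
    } else {
      uword out = T.basis(leave);
      T.state[out] = leave_to;
      T.x(out) = leave_to == 1 ? T.lb(out) : T.ub(out);
      T.basis(leave) = q;
      T.state[q] = 0;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".lp_simplex")]]
Rcpp::List lp_simplex(const arma::mat& A, const arma::vec& b,
                      const arma::vec& c, const arma::vec& lb,
                      const arma::vec& ub, bool maximize = false,
                      int max_iter = 50000, double tol = 1e-9) {
  const uword m = A.n_rows, n = A.n_cols;
  if (b.n_elem != m || c.n_elem != n || lb.n_elem != n || ub.n_elem != n)
    Rcpp::stop("inconsistent LP dimensions");
  for (uword j = 0; j < n; ++j)
    if (lb(j) > ub(j) + 1e-12)
      Rcpp::stop("lower bound exceeds upper bound for variable %d", (int)j + 1);

  Tableau T;
  const uword N = n + m;
  T.A.set_size(m, N);
  T.A.cols(0, n - 1) = A;
  T.b = b;
  T.lb.set_size(N); T.ub.set_size(N); T.x.set_size(N);
  T.state.assign(N, 1);
  T.basis.set_size(m);

  // start structurals at a finite bound (or 0 if free)
  for (uword j = 0; j < n; ++j) {
    T.lb(j) = lb(j); T.ub(j) = ub(j);
    if (std::isfinite(lb(j)))      { T.x(j) = lb(j); T.state[j] = 1; }
    else if (std::isfinite(ub(j))) { T.x(j) = ub(j); T.state[j] = 2; }
    else                           { T.x(j) = 0.0;   T.state[j] = 3; }
  }
  // artificial basis absorbing the residual
  vec r = b - T.A.cols(0, n - 1) * T.x.subvec(0, n - 1);
  for (uword i = 0; i < m; ++i) {
    uword j = n + i;
    vec e = zeros<vec>(m);
    e(i) = r(i) >= 0 ? 1.0 : -1.0;
    T.A.col(j) = e;
    T.lb(j) = 0.0; T.ub(j) = INF;
    T.x(j) = std::fabs(r(i));
    T.basis(i) = j;
    T.state[j] = 0;
  }

  // phase 1: drive artificials to zero
  vec c1 = zeros<vec>(N);
  c1.subvec(n, N - 1).fill(1.0);
  int st = simplex_phase(T, c1, max_iter, tol);
  double infeas = accu(T.x.subvec(n, N - 1));
  std::string status;
  double scale = std::max(1.0, norm(b, "inf"));
  if (st == 2) status = "iteration_limit";
  else if (infeas > 1e-7 * scale) status = "infeasible";
  else {
    // phase 2: real objective, artificials pinned at zero
    for (uword j = n; j < N; ++j) { T.ub(j) = 0.0; T.x(j) = 0.0; if (T.state[j] != 0) T.state[j] = 1; }
    vec c2 = zeros<vec>(N);
    c2.subvec(0, n - 1) = maximize ? vec(-c) : c;
    st = simplex_phase(T, c2, max_iter, tol);
    status = st == 0 ? "optimal" : (st == 1 ? "unbounded" : "iteration_limit");
  }

  vec x = T.x.subvec(0, n - 1);
  double obj = dot(c, x);
  return Rcpp::List::create(
    Rcpp::Named("status") = status,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("x") = Rcpp::NumericVector(x.begin(), x.end()));
}
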