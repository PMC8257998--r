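// Bounded-variable two-phase primal simplex for the community flux LPs.
//
// Solves   min c'x   s.t.  A x = b,  lb <= x <= ub
// with a dense tableau, explicit variable-bound handling (no bound rows),
// bound-flip pivots, a Dantzig rule with Bland fallback for anti-cycling,
// a singleton-column crash basis, periodic LU refactorization of the
// tableau against the original data (the dense tableau drifts over long
// degenerate runs), post-optimality verification, and warm-started
// re-solves: an instance keeps its basis between calls, so successive FVA
// objectives on the same model start primal-feasible and skip phase 1.
//
// Scale target: a few hundred rows/columns per community model; dense
// storage is deliberate.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

class SimplexLP {
public:
  int m, n, nt;                 // rows, real columns, total (+ artificials)
  std::vector<double> A;        // original m x n, row-major
  std::vector<double> b;
  std::vector<double> lb, ub;   // length nt
  std::vector<double> art_sign; // artificial column k = art_sign[k] * e_k
  std::vector<double> T;        // tableau m x nt: B^{-1} [A | Art]
  std::vector<double> xB;       // basic variable values, length m
  std::vector<int> basis;       // row -> column basic in that row
  std::vector<int> vstat;       // 0 nonbasic at lb, 1 nonbasic at ub, 2 basic
  bool have_basis, phase1_done;
  double tol;
  int refactor_every, since_refactor;

  SimplexLP(const NumericMatrix& A_, const NumericVector& b_,
            const NumericVector& lb_, const NumericVector& ub_)
    : m(A_.nrow()), n(A_.ncol()), nt(A_.nrow() + A_.ncol()),
      have_basis(false), phase1_done(false), tol(1e-9),
      refactor_every(120), since_refactor(0) {
    A.resize((size_t)m * n);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j) A[(size_t)i * n + j] = A_(i, j);
    b.assign(b_.begin(), b_.end());
    lb.assign(lb_.begin(), lb_.end());
    ub.assign(ub_.begin(), ub_.end());
    lb.resize(nt, 0.0);
    ub.resize(nt, INF);
    art_sign.assign(m, 1.0);
    T.assign((size_t)m * nt, 0.0);
    xB.assign(m, 0.0);
    basis.assign(m, 0);
    vstat.assign(nt, 0);
  }

  double nb_value(int j) const { return vstat[j] == 1 ? ub[j] : lb[j]; }

  double col_entry(int j, int i) const {  // original column j, row i
    if (j < n) return A[(size_t)i * n + j];
    return (j - n == i) ? art_sign[i] : 0.0;
  }

  // ---- initial basis: singleton-column crash, artificials elsewhere ----
  // warm = true keeps the current nonbasic bound pattern (and demotes
  // basic variables to their nearest bound), so a restart after numerical
  // trouble resumes near the point already reached instead of replaying
  // the failed trajectory.
  void init_basis(bool warm = false) {
    if (!warm) {
      for (int j = 0; j < n; ++j) {
        if (std::isfinite(lb[j])) vstat[j] = 0;
        else if (std::isfinite(ub[j])) vstat[j] = 1;
        else stop("simplex: every variable needs at least one finite bound");
      }
    } else {
      for (int i = 0; i < m; ++i) {
        int j = basis[i];
        if (j >= n) continue;
        bool lo_ok = std::isfinite(lb[j]), hi_ok = std::isfinite(ub[j]);
        if (lo_ok && (!hi_ok || xB[i] - lb[j] <= ub[j] - xB[i]))
          vstat[j] = 0;
        else vstat[j] = 1;
      }
      for (int k = 0; k < m; ++k) if (vstat[n + k] == 2) vstat[n + k] = 0;
    }
    for (int k = 0; k < m; ++k) { vstat[n + k] = 0; lb[n + k] = 0.0; ub[n + k] = INF; }

    // residual r = b - A x_N with every real column nonbasic at its bound
    std::vector<double> r(b);
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      const double* Ai = &A[(size_t)i * n];
      for (int j = 0; j < n; ++j) s += Ai[j] * nb_value(j);
      r[i] -= s;
    }
    // find singleton columns (one nonzero, magnitude ~1) per row
    std::vector<int> srow(n, -1);
    std::vector<double> scoef(n, 0.0);
    for (int j = 0; j < n; ++j) {
      int row = -1; bool single = true;
      for (int i = 0; i < m; ++i) {
        double a = A[(size_t)i * n + j];
        if (a != 0.0) {
          if (row >= 0) { single = false; break; }
          row = i; scoef[j] = a;
        }
      }
      if (single && row >= 0 && std::fabs(scoef[j]) > 0.5) srow[j] = row;
    }
    std::vector<int> chosen(m, -1);
    for (int j = 0; j < n; ++j) {
      int i = srow[j];
      if (i < 0 || chosen[i] >= 0) continue;
      double val = nb_value(j) + r[i] / scoef[j];
      if (val >= lb[j] - tol && val <= ub[j] + tol) chosen[i] = j;
    }
    for (int i = 0; i < m; ++i) {
      if (chosen[i] >= 0) {
        basis[i] = chosen[i];
        vstat[chosen[i]] = 2;
      } else {
        art_sign[i] = (r[i] >= 0.0) ? 1.0 : -1.0;
        basis[i] = n + i;
        vstat[n + i] = 2;
      }
    }
    have_basis = true;
    phase1_done = false;
    if (!refactor()) stop("simplex: singular crash basis");
  }

  // ---- LU refactorization of the tableau from original data ----
  // Returns false if the basis matrix is numerically singular or the
  // recomputed basic solution violates bounds by more than 1e-5.
  bool refactor() {
    // build B (column i = original column basis[i]), factor with
    // partial pivoting: PB = LU
    std::vector<double> B((size_t)m * m);
    for (int i = 0; i < m; ++i)
      for (int k = 0; k < m; ++k)
        B[(size_t)i * m + k] = col_entry(basis[k], i);
    std::vector<int> piv(m);
    for (int k = 0; k < m; ++k) piv[k] = k;
    for (int k = 0; k < m; ++k) {
      int p = k; double best = std::fabs(B[(size_t)k * m + k]);
      for (int i = k + 1; i < m; ++i) {
        double v = std::fabs(B[(size_t)i * m + k]);
        if (v > best) { best = v; p = i; }
      }
      if (best < 1e-11) return false;
      if (p != k) {
        for (int j = 0; j < m; ++j)
          std::swap(B[(size_t)k * m + j], B[(size_t)p * m + j]);
        std::swap(piv[k], piv[p]);
      }
      double d = B[(size_t)k * m + k];
      for (int i = k + 1; i < m; ++i) {
        double f = B[(size_t)i * m + k] / d;
        B[(size_t)i * m + k] = f;
        if (f != 0.0)
          for (int j = k + 1; j < m; ++j)
            B[(size_t)i * m + j] -= f * B[(size_t)k * m + j];
      }
    }
    std::vector<double> y(m), Tcol((size_t)m * nt);
    auto solveB = [&](std::vector<double>& rhs) {
      for (int k = 0; k < m; ++k) y[k] = rhs[piv[k]];
      for (int k = 0; k < m; ++k)
        for (int i = k + 1; i < m; ++i) y[i] -= B[(size_t)i * m + k] * y[k];
      for (int k = m - 1; k >= 0; --k) {
        for (int j = k + 1; j < m; ++j) y[k] -= B[(size_t)k * m + j] * y[j];
        y[k] /= B[(size_t)k * m + k];
      }
      rhs = y;
    };
    std::vector<double> cbuf(m);
    for (int j = 0; j < nt; ++j) {
      bool nz = false;
      for (int i = 0; i < m; ++i) {
        cbuf[i] = col_entry(j, i);
        if (cbuf[i] != 0.0) nz = true;
      }
      if (nz) solveB(cbuf);
      for (int i = 0; i < m; ++i) Tcol[(size_t)i * nt + j] = cbuf[i];
    }
    // xB = B^{-1} (b - sum_{nonbasic j} A_j x_j)
    std::vector<double> rhs(b);
    for (int j = 0; j < nt; ++j) {
      if (vstat[j] == 2) continue;
      double xj = nb_value(j);
      if (xj != 0.0)
        for (int i = 0; i < m; ++i) rhs[i] -= col_entry(j, i) * xj;
    }
    solveB(rhs);
    double viol = 0.0;
    for (int i = 0; i < m; ++i) {
      double v = rhs[i];
      double lo = lb[basis[i]], hi = ub[basis[i]];
      if (v < lo) viol = std::max(viol, lo - v);
      if (v > hi) viol = std::max(viol, v - hi);
    }
    if (viol > 1e-5) return false;
    for (int i = 0; i < m; ++i) {
      double v = rhs[i];
      double lo = lb[basis[i]], hi = ub[basis[i]];
      xB[i] = std::min(std::max(v, lo), hi);
    }
    T.swap(Tcol);
    since_refactor = 0;
    return true;
  }

  // infinity-norm residual of the current solution on the original system
  double current_residual() const {
    std::vector<double> x(nt);
    for (int j = 0; j < nt; ++j) x[j] = nb_value(j);
    for (int i = 0; i < m; ++i) x[basis[i]] = xB[i];
    double res = 0.0;
    for (int i = 0; i < m; ++i) {
      double s = -b[i];
      const double* Ai = &A[(size_t)i * n];
      for (int j = 0; j < n; ++j) s += Ai[j] * x[j];
      s += art_sign[i] * x[n + i];
      res = std::max(res, std::fabs(s));
    }
    return res;
  }

  void reduced_costs(const std::vector<double>& cv,
                     std::vector<double>& d) const {
    for (int j = 0; j < nt; ++j) d[j] = cv[j];
    for (int i = 0; i < m; ++i) {
      double ci = cv[basis[i]];
      if (ci != 0.0) {
        const double* Ti = &T[(size_t)i * nt];
        for (int j = 0; j < nt; ++j) d[j] -= ci * Ti[j];
      }
    }
  }

  int pick_entering(const std::vector<double>& d, bool bland) const {
    int e = -1; double best = 1e-7;
    for (int j = 0; j < nt; ++j) {
      if (vstat[j] == 2 || lb[j] == ub[j]) continue;
      double viol = (vstat[j] == 0) ? -d[j] : d[j];
      if (viol > (bland ? 1e-7 : best)) {
        e = j;
        if (bland) return e;
        best = viol;
      }
    }
    return e;
  }

  // One simplex pass. Returns 0 optimal-candidate, 2 unbounded,
  // 3 iteration limit, 4 refactorization failure (restart needed).
  int iterate(const std::vector<double>& cv) {
    const int max_iter = 50000, bland_after = 10000;
    std::vector<double> d(nt);
    for (int it = 0; it < max_iter; ++it) {
      if (since_refactor >= refactor_every) {
        if (!refactor()) return 4;
      }
      reduced_costs(cv, d);
      int e = pick_entering(d, it >= bland_after);
      if (e < 0) return 0;
      double dir = (vstat[e] == 0) ? 1.0 : -1.0;

      double tmax = ub[e] - lb[e];
      int r = -1; double rlim = INF, rpiv = 0.0;
      for (int i = 0; i < m; ++i) {
        double a = T[(size_t)i * nt + e] * dir;
        double lim;
        if (a > tol)       lim = (xB[i] - lb[basis[i]]) / a;
        else if (a < -tol) lim = (ub[basis[i]] - xB[i]) / (-a);
        else continue;
        if (!std::isfinite(lim)) continue;
        if (lim < 0) lim = 0;
        double win = 1e-9 + 1e-7 * std::fabs(rlim);
        if (lim < rlim - win ||
            (lim < rlim + win && std::fabs(a) > std::fabs(rpiv))) {
          rlim = std::min(lim, rlim); r = i; rpiv = T[(size_t)i * nt + e];
        }
      }
      double t = std::min(tmax, rlim);
      if (!std::isfinite(t)) return 2;

      if (r < 0 || tmax <= rlim) {          // bound flip
        for (int i = 0; i < m; ++i)
          xB[i] -= T[(size_t)i * nt + e] * dir * t;
        vstat[e] = 1 - vstat[e];
        continue;
      }
      int lv = basis[r];
      double a_r = T[(size_t)r * nt + e] * dir;
      vstat[lv] = (a_r > 0) ? 0 : 1;
      for (int i = 0; i < m; ++i)
        if (i != r) xB[i] -= T[(size_t)i * nt + e] * dir * t;
      double enter_val = nb_value(e) + dir * t;
      double piv = T[(size_t)r * nt + e];
      double* Tr = &T[(size_t)r * nt];
      double inv = 1.0 / piv;
      for (int j = 0; j < nt; ++j) Tr[j] *= inv;
      for (int i = 0; i < m; ++i) {
        if (i == r) continue;
        double f = T[(size_t)i * nt + e];
        if (f != 0.0) {
          double* Ti = &T[(size_t)i * nt];
          for (int j = 0; j < nt; ++j) Ti[j] -= f * Tr[j];
        }
      }
      basis[r] = e;
      vstat[e] = 2;
      xB[r] = enter_val;
      ++since_refactor;
    }
    return 3;
  }

  double artificial_mass() const {
    double s = 0.0;
    for (int i = 0; i < m; ++i) if (basis[i] >= n) s += xB[i];
    for (int k = 0; k < m; ++k)
      if (vstat[n + k] != 2) s += nb_value(n + k);
    return s;
  }

  // status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
  List solve(const NumericVector& c_, bool maximize) {
    std::vector<double> cv(nt, 0.0);
    for (int j = 0; j < n; ++j) cv[j] = maximize ? -c_[j] : c_[j];
    std::vector<double> d(nt);

    int restarts = 0, unbounded_seen = 0;
    bool warm_restart = false;
    for (int round = 0; round < 20; ++round) {
      if (!have_basis) { init_basis(warm_restart); warm_restart = true; }
      if (!phase1_done) {
        std::vector<double> c1(nt, 0.0);
        bool need = false;
        for (int k = 0; k < m; ++k)
          if (vstat[n + k] == 2 || xB_of(n + k) != 0.0) need = true;
        for (int k = 0; k < m; ++k) c1[n + k] = 1.0;
        if (need && artificial_mass() > 1e-9) {
          int st = iterate(c1);
          if (st == 4 || !refactor()) {
            if (++restarts > 6) return result(cv, 3, maximize);
            have_basis = false;
            continue;
          }
          if (st == 3) return result(cv, 3, maximize);
          if (artificial_mass() > 1e-7) return result(cv, 1, maximize);
        }
        for (int k = 0; k < m; ++k) ub[n + k] = 0.0;
        phase1_done = true;
      }
      int st = iterate(cv);
      if (st == 4) {
        if (++restarts > 6) return result(cv, 3, maximize);
        have_basis = false; phase1_done = false;
        for (int k = 0; k < m; ++k) ub[n + k] = INF;
        continue;
      }
      if (st == 3) return result(cv, 3, maximize);
      if (st == 2) {
        // verify the unbounded ray on a refactored tableau
        if (++unbounded_seen >= 2) return result(cv, 2, maximize);
        if (!refactor()) {
          if (++restarts > 6) return result(cv, 3, maximize);
          have_basis = false; phase1_done = false;
          for (int k = 0; k < m; ++k) ub[n + k] = INF;
        }
        continue;
      }
      // accept immediately when the tableau is provably fresh or the
      // solution already satisfies the original system; refactor and
      // re-verify otherwise
      if (since_refactor == 0 || current_residual() < 1e-8)
        return result(cv, 0, maximize);
      if (!refactor()) {
        if (++restarts > 6) return result(cv, 3, maximize);
        have_basis = false; phase1_done = false;
        for (int k = 0; k < m; ++k) ub[n + k] = INF;
        continue;
      }
      reduced_costs(cv, d);
      if (pick_entering(d, false) < 0) return result(cv, 0, maximize);
    }
    return result(cv, 3, maximize);
  }

  double xB_of(int j) const {
    for (int i = 0; i < m; ++i) if (basis[i] == j) return xB[i];
    return nb_value(j);
  }

  // Update the bounds of real column j. The basis is preserved when the
  // current point remains feasible (the usual case when bounds are
  // tightened up to the current value or relaxed); otherwise it is
  // invalidated and the next solve re-initializes warm.
  void set_bound(int j, double lo, double hi) {
    if (j < 0 || j >= n) stop("simplex: bound index out of range");
    if (lo > hi) stop("simplex: lower bound exceeds upper bound");
    double old_val = (vstat[j] == 2) ? xB_of(j) : nb_value(j);
    lb[j] = lo; ub[j] = hi;
    if (!have_basis) return;
    bool ok = true;
    if (vstat[j] == 2) {
      ok = (old_val >= lo - 1e-9) && (old_val <= hi + 1e-9);
    } else {
      if (!std::isfinite(nb_value(j)))
        vstat[j] = 1 - vstat[j];
      double dlt = nb_value(j) - old_val;
      if (!std::isfinite(dlt)) ok = false;
      else if (dlt != 0.0) {
        for (int i = 0; i < m; ++i)
          xB[i] -= T[(size_t)i * nt + j] * dlt;
        for (int i = 0; i < m && ok; ++i)
          if (xB[i] < lb[basis[i]] - 1e-9 || xB[i] > ub[basis[i]] + 1e-9)
            ok = false;
      }
    }
    if (!ok) {
      have_basis = false;
      phase1_done = false;
      for (int k = 0; k < m; ++k) ub[n + k] = INF;
    }
  }

  List result(const std::vector<double>& cv, int status, bool maximize) {
    std::vector<double> xt(nt);
    for (int j = 0; j < nt; ++j) xt[j] = nb_value(j);
    for (int i = 0; i < m; ++i) xt[basis[i]] = xB[i];
    NumericVector x(n);
    double obj = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] = xt[j];
      obj += cv[j] * xt[j];
    }
    if (maximize) obj = -obj;
    double res = 0.0;
    for (int i = 0; i < m; ++i) {
      double s = -b[i] + art_sign[i] * xt[n + i];
      const double* Ai = &A[(size_t)i * n];
      for (int j = 0; j < n; ++j) s += Ai[j] * xt[j];
      res = std::max(res, std::fabs(s));
    }
    return List::create(_["status"] = status, _["objective"] = obj,
                        _["x"] = x, _["residual"] = res);
  }
};

// [[Rcpp::export(name = ".lp_instance")]]
SEXP lp_instance_cpp(NumericMatrix A, NumericVector b,
                     NumericVector lb, NumericVector ub) {
  if (b.size() != A.nrow() || lb.size() != A.ncol() || ub.size() != A.ncol())
    stop("simplex: dimension mismatch");
  XPtr<SimplexLP> p(new SimplexLP(A, b, lb, ub), true);
  return p;
}

// [[Rcpp::export(name = ".lp_optimize")]]
List lp_optimize_cpp(SEXP ptr, NumericVector c, bool maximize) {
  XPtr<SimplexLP> p(ptr);
  if (c.size() != p->n) stop("simplex: objective length mismatch");
  return p->solve(c, maximize);
}

// [[Rcpp::export(name = ".lp_set_bound")]]
void lp_set_bound_cpp(SEXP ptr, int j, double lo, double hi) {
  XPtr<SimplexLP> p(ptr);
  p->set_bound(j - 1, lo, hi);   // 1-based from R
}
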