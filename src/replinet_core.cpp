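// Fixed-step march for the networked replicator model.
//
// The right-hand side is the per-node replicator field plus a transport term
// (none / linear velocity / delayed survival-weighted).  The main scheme is
// the two-stage Gauss-Legendre implicit Runge-Kutta method (order 4) in
// predictor-corrector form: explicit Euler predictors at the two Gauss
// abscissae, then fixed-point iteration of the stage equations until
// max(||k1 - k1c||, ||k2 - k2c||) < eps.  Explicit and implicit Euler
// baselines share the same right-hand side.  A cubic Hermite history of
// accepted steps provides dense output for delay lookups; queries at or
// before t0 return the initial state, queries past the newest accepted time
// extend the last segment's cubic.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Model {
  int N = 0, n = 0;
  bool shared = true;
  std::vector<std::vector<double>> A;     // payoff matrices, row-major n*n
  std::vector<std::vector<int>> nbrs;     // transport neighbor lists
  std::vector<std::vector<double>> nu_e;  // per (i, j-slot) velocity
  std::vector<std::vector<double>> w_e;   // per (i, j-slot) exp(-p*tau)
  std::vector<std::vector<double>> tau_e; // per (i, j-slot) travel time
  int kind = 0;         // 0 none, 1 linear, 2 delayed
  int formulation = 0;  // 0 printed, 1 departure
};

struct History {
  double t0 = 0.0, dt = 0.0;
  std::vector<std::vector<double>> states, derivs;  // per accepted step

  const std::vector<double>& initial() const { return states.front(); }

  // Hermite dense output; `out` has size N*n
  void query(double t, std::vector<double>& out) const {
    if (t <= t0) { out = states.front(); return; }
    long k = (long)std::floor((t - t0) / dt + 1e-12);
    // derivs can lag states by one entry while the newest accepted point's
    // right-hand side is being evaluated; only fully closed segments are used
    long last = (long)derivs.size() - 1;
    if (k > last - 1) k = last - 1;
    if (k < 0) k = 0;
    double tk = t0 + k * dt;
    double s = (t - tk) / dt;
    double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
    double h10 = s * (1 - s) * (1 - s);
    double h01 = s * s * (3 - 2 * s);
    double h11 = s * s * (s - 1);
    const std::vector<double>& y0 = states[k];
    const std::vector<double>& y1 = states[k + 1];
    const std::vector<double>& d0 = derivs[k];
    const std::vector<double>& d1 = derivs[k + 1];
    size_t m = y0.size();
    out.resize(m);
    for (size_t q = 0; q < m; ++q) {
      out[q] = h00 * y0[q] + h10 * dt * d0[q] + h01 * y1[q] + h11 * dt * d1[q];
    }
  }
};

// out = full RHS at (t, y); scratch avoids reallocations for delay lookups
void eval_rhs(const Model& M, const History* H, double t,
              const std::vector<double>& y, std::vector<double>& out,
              std::vector<double>& scratch) {
  const int N = M.N, n = M.n;
  out.assign((size_t)N * n, 0.0);
  for (int i = 0; i < N; ++i) {
    const std::vector<double>& A = M.shared ? M.A[0] : M.A[i];
    const double* xi = &y[(size_t)i * n];
    double phi = 0.0;
    std::vector<double> f(n, 0.0);
    for (int k = 0; k < n; ++k) {
      double fk = 0.0;
      for (int l = 0; l < n; ++l) fk += A[(size_t)k * n + l] * xi[l];
      f[k] = fk;
      phi += xi[k] * fk;
    }
    double* oi = &out[(size_t)i * n];
    for (int k = 0; k < n; ++k) oi[k] = xi[k] * (f[k] - phi);
  }
  if (M.kind == 1) {  // linear
    for (int i = 0; i < N; ++i) {
      double* oi = &out[(size_t)i * n];
      const double* xi = &y[(size_t)i * n];
      for (size_t s = 0; s < M.nbrs[i].size(); ++s) {
        int j = M.nbrs[i][s];
        double nu = M.nu_e[i][s];
        const double* xj = &y[(size_t)j * n];
        for (int k = 0; k < n; ++k) oi[k] += nu * (xj[k] - xi[k]);
      }
    }
  } else if (M.kind == 2) {  // delayed
    for (int i = 0; i < N; ++i) {
      double* oi = &out[(size_t)i * n];
      const double* xi = &y[(size_t)i * n];
      for (size_t s = 0; s < M.nbrs[i].size(); ++s) {
        int j = M.nbrs[i][s];
        double w = M.w_e[i][s];
        double tau = M.tau_e[i][s];
        H->query(t - tau, scratch);
        if (M.formulation == 0) {
          const double* xj_now = &y[(size_t)j * n];
          const double* xi_del = &scratch[(size_t)i * n];
          for (int k = 0; k < n; ++k) oi[k] += w * (xj_now[k] - xi_del[k]);
        } else {
          const double* xj_del = &scratch[(size_t)j * n];
          for (int k = 0; k < n; ++k) oi[k] += w * (xj_del[k] - xi[k]);
        }
      }
    }
  }
}

double diff_norm2(const std::vector<double>& a, const std::vector<double>& b) {
  double s = 0.0;
  for (size_t q = 0; q < a.size(); ++q) {
    double d = a[q] - b[q];
    s += d * d;
  }
  return std::sqrt(s);
}

Model build_model(const List& model) {
  Model M;
  M.N = as<int>(model["N"]);
  M.n = as<int>(model["n"]);
  M.shared = as<bool>(model["shared"]);
  List As = model["payoffs"];
  for (int q = 0; q < As.size(); ++q) {
    NumericMatrix A(As[q]);
    std::vector<double> a((size_t)M.n * M.n);
    for (int r = 0; r < M.n; ++r)
      for (int c = 0; c < M.n; ++c) a[(size_t)r * M.n + c] = A(r, c);
    M.A.push_back(std::move(a));
  }
  IntegerMatrix W(as<IntegerMatrix>(model["neighbor_matrix"]));
  NumericMatrix nu(as<NumericMatrix>(model["nu"]));
  NumericMatrix p(as<NumericMatrix>(model["p"]));
  NumericMatrix tau(as<NumericMatrix>(model["tau"]));
  M.kind = as<int>(model["kind"]);
  M.formulation = as<int>(model["formulation"]);
  M.nbrs.resize(M.N);
  M.nu_e.resize(M.N);
  M.w_e.resize(M.N);
  M.tau_e.resize(M.N);
  for (int i = 0; i < M.N; ++i) {
    for (int j = 0; j < M.N; ++j) {
      if (W(i, j) == 1) {
        M.nbrs[i].push_back(j);
        M.nu_e[i].push_back(nu(i, j));
        M.w_e[i].push_back(std::exp(-p(i, j) * tau(i, j)));
        M.tau_e[i].push_back(tau(i, j));
      }
    }
  }
  return M;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_integrate")]]
List cpp_integrate(List model, NumericMatrix x0, double dt, int n_steps,
                   double eps, int max_iters, int method, int stride,
                   double guard_tol) {
  Model M = build_model(model);
  const int N = M.N, n = M.n;
  const size_t dim = (size_t)N * n;
  if (x0.nrow() != N || x0.ncol() != n) stop("x0 has the wrong shape");

  const double c1 = 0.5 - std::sqrt(3.0) / 6.0;
  const double c2 = 0.5 + std::sqrt(3.0) / 6.0;
  const double a11 = 0.25, a12 = 0.25 - std::sqrt(3.0) / 6.0;
  const double a21 = 0.25 + std::sqrt(3.0) / 6.0, a22 = 0.25;

  std::vector<double> y(dim);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < n; ++k) y[(size_t)i * n + k] = x0(i, k);

  History H;
  H.t0 = 0.0;
  H.dt = dt;
  const bool delayed = (M.kind == 2);
  const History* Hp = delayed ? &H : nullptr;

  std::vector<double> f_n(dim), scratch, k1(dim), k2(dim), k1c(dim), k2c(dim);
  std::vector<double> Y1(dim), Y2(dim), ynew(dim);

  int n_stored = n_steps / stride + 1;
  NumericVector states((R_xlen_t)n_stored * N * n);
  states.attr("dim") = IntegerVector::create(n_stored, N, n);
  NumericVector times(n_stored);
  auto store = [&](int slot, double t, const std::vector<double>& v) {
    times[slot] = t;
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < n; ++k)
        states[(R_xlen_t)slot + (R_xlen_t)n_stored * (i + (R_xlen_t)N * k)] =
            v[(size_t)i * n + k];
  };

  double max_dev = 0.0, min_coord = R_PosInf;
  auto monitor = [&](const std::vector<double>& v, double t) {
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < n; ++k) {
        double val = v[(size_t)i * n + k];
        s += val;
        if (val < min_coord) min_coord = val;
      }
      double dev = std::fabs(s - 1.0);
      if (dev > max_dev) max_dev = dev;
    }
    if (max_dev > guard_tol) {
      stop("simplex drift %g exceeds guard tolerance %g at t = %g; "
           "the step size is too large for this configuration",
           max_dev, guard_tol, t);
    }
  };

  if (delayed) H.states.push_back(y);  // queries at t <= t0 hit this entry
  eval_rhs(M, Hp, 0.0, y, f_n, scratch);
  if (delayed) H.derivs.push_back(f_n);
  store(0, 0.0, y);
  monitor(y, 0.0);

  long total_iters = 0;
  int max_used = 0;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    if (method == 0) {  // GL4 P-(EC)^k
      for (size_t q = 0; q < dim; ++q) {
        Y1[q] = y[q] + c1 * dt * f_n[q];
        Y2[q] = y[q] + c2 * dt * f_n[q];
      }
      eval_rhs(M, Hp, t + c1 * dt, Y1, k1, scratch);
      eval_rhs(M, Hp, t + c2 * dt, Y2, k2, scratch);
      int it = 0;
      double res = R_PosInf;
      while (it < max_iters) {
        for (size_t q = 0; q < dim; ++q) {
          Y1[q] = y[q] + dt * (a11 * k1[q] + a12 * k2[q]);
          Y2[q] = y[q] + dt * (a21 * k1[q] + a22 * k2[q]);
        }
        eval_rhs(M, Hp, t + c1 * dt, Y1, k1c, scratch);
        eval_rhs(M, Hp, t + c2 * dt, Y2, k2c, scratch);
        res = std::max(diff_norm2(k1, k1c), diff_norm2(k2, k2c));
        k1.swap(k1c);
        k2.swap(k2c);
        ++it;
        if (res < eps) break;
      }
      total_iters += it;
      if (it > max_used) max_used = it;
      if (res >= eps) {
        stop("corrector did not reach tolerance %g in %d iterations "
             "(residual %g at t = %g); reduce dt", eps, max_iters, res, t);
      }
      for (size_t q = 0; q < dim; ++q)
        ynew[q] = y[q] + 0.5 * dt * (k1[q] + k2[q]);
    } else if (method == 1) {  // explicit Euler
      for (size_t q = 0; q < dim; ++q) ynew[q] = y[q] + dt * f_n[q];
    } else {  // implicit Euler, fixed-point to eps
      for (size_t q = 0; q < dim; ++q) ynew[q] = y[q] + dt * f_n[q];
      int it = 0;
      double res = R_PosInf;
      while (it < max_iters) {
        eval_rhs(M, Hp, t + dt, ynew, k1, scratch);
        res = 0.0;
        for (size_t q = 0; q < dim; ++q) {
          double z = y[q] + dt * k1[q];
          double d = z - ynew[q];
          res += d * d;
          ynew[q] = z;
        }
        res = std::sqrt(res);
        ++it;
        if (res < eps) break;
      }
      total_iters += it;
      if (res >= eps) {
        stop("implicit Euler solve did not converge (residual %g at t = %g)",
             res, t);
      }
    }

    y.swap(ynew);
    double t1 = (step + 1) * dt;
    if (delayed) H.states.push_back(y);
    eval_rhs(M, Hp, t1, y, f_n, scratch);  // derivative at the accepted point
    if (delayed) H.derivs.push_back(f_n);
    monitor(y, t1);
    if ((step + 1) % stride == 0) store((step + 1) / stride, t1, y);
  }

  return List::create(
      _["times"] = times, _["states"] = states,
      _["total_corrector_iters"] = (double)total_iters,
      _["max_corrector_iters_used"] = max_used,
      _["max_simplex_deviation"] = max_dev,
      _["min_coordinate"] = min_coord);
}
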