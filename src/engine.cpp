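// Overdamped Langevin dynamics and (bias-exchange) metadynamics on analytic
// landscapes.  Units: nm, ns, kJ/mol; kB = 0.0083145 kJ/mol/K.
//
// Bias bookkeeping: every deposited kernel is recorded exactly (center, time);
// for the per-step force the accumulated bias is cached on a dense 1D grid per
// biased replica (value + analytic derivative, linear interpolation).  The
// kernel list is the authoritative record used by the R-level free-energy
// readout.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0083145;

// ---- analytic landscapes ---------------------------------------------------
// id 1: double_well, par = (h);            U = h (x^2 - 1)^2           (1D)
// id 2: two_basin_2d, par = (h, ky);       U = h (x^2 - 1)^2 + ky/2 y^2
// id 3: multi_basin_2d, par = (kconf, A1,x1,y1,w1, A2,x2,y2,w2, ...):
//       U = kconf/2 (x^2+y^2) - sum_i A_i exp(-((x-xi)^2+(y-yi)^2)/(2 wi^2))

static double land_energy(int id, const NumericVector& p, const double* x) {
  if (id == 1) {
    double a = x[0] * x[0] - 1.0;
    return p[0] * a * a;
  } else if (id == 2) {
    double a = x[0] * x[0] - 1.0;
    return p[0] * a * a + 0.5 * p[1] * x[1] * x[1];
  } else if (id == 3) {
    double u = 0.5 * p[0] * (x[0] * x[0] + x[1] * x[1]);
    int nw = (p.size() - 1) / 4;
    for (int i = 0; i < nw; ++i) {
      double A = p[1 + 4 * i], cx = p[2 + 4 * i], cy = p[3 + 4 * i],
             w = p[4 + 4 * i];
      double dx = x[0] - cx, dy = x[1] - cy;
      u -= A * std::exp(-(dx * dx + dy * dy) / (2.0 * w * w));
    }
    return u;
  }
  stop("unknown landscape id");
}

static void land_grad(int id, const NumericVector& p, const double* x,
                      double* g) {
  if (id == 1) {
    g[0] = 4.0 * p[0] * x[0] * (x[0] * x[0] - 1.0);
  } else if (id == 2) {
    g[0] = 4.0 * p[0] * x[0] * (x[0] * x[0] - 1.0);
    g[1] = p[1] * x[1];
  } else if (id == 3) {
    g[0] = p[0] * x[0];
    g[1] = p[0] * x[1];
    int nw = (p.size() - 1) / 4;
    for (int i = 0; i < nw; ++i) {
      double A = p[1 + 4 * i], cx = p[2 + 4 * i], cy = p[3 + 4 * i],
             w = p[4 + 4 * i];
      double dx = x[0] - cx, dy = x[1] - cy;
      double e = A * std::exp(-(dx * dx + dy * dy) / (2.0 * w * w)) / (w * w);
      g[0] += e * dx;
      g[1] += e * dy;
    }
  } else {
    stop("unknown landscape id");
  }
}

// [[Rcpp::export]]
NumericVector landscape_energy_cpp(int id, NumericVector par, NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericVector out(n);
  std::vector<double> x(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = X(i, j);
    out[i] = land_energy(id, par, x.data());
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix landscape_gradient_cpp(int id, NumericVector par,
                                     NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericMatrix out(n, d);
  std::vector<double> x(d), g(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = X(i, j);
    land_grad(id, par, x.data(), g.data());
    for (int j = 0; j < d; ++j) out(i, j) = g[j];
  }
  return out;
}

// ---- grid-cached 1D bias ---------------------------------------------------
struct BiasGrid {
  double lo, hi, dx;
  int n;
  std::vector<double> v, dv;  // value and derivative at nodes
  void init(double lo_, double hi_, int n_) {
    lo = lo_; hi = hi_; n = n_;
    dx = (hi - lo) / (n - 1);
    v.assign(n, 0.0);
    dv.assign(n, 0.0);
  }
  void deposit(double c, double sigma, double w) {
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int i = 0; i < n; ++i) {
      double s = lo + i * dx, d = s - c;
      double e = w * std::exp(-d * d * inv2s2);
      v[i] += e;
      dv[i] += -e * d / (sigma * sigma);
    }
  }
  double value(double s) const {
    if (s <= lo) return v[0];
    if (s >= hi) return v[n - 1];
    double t = (s - lo) / dx;
    int i = (int)t;
    double f = t - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
  }
  double deriv(double s) const {
    if (s <= lo || s >= hi) return 0.0;
    double t = (s - lo) / dx;
    int i = (int)t;
    double f = t - i;
    return dv[i] * (1.0 - f) + dv[i + 1] * f;
  }
};

// ---- plain Langevin run ----------------------------------------------------
// [[Rcpp::export]]
NumericMatrix run_langevin_cpp(int id, NumericVector par, NumericVector x0,
                               double dt, int n_steps, int out_stride,
                               double temperature, double friction) {
  int d = x0.size();
  int n_out = n_steps / out_stride;
  NumericMatrix trace(n_out, d);
  std::vector<double> x(d), g(d);
  for (int j = 0; j < d; ++j) x[j] = x0[j];
  double amp = std::sqrt(2.0 * KB * temperature * dt / friction);
  RNGScope scope;
  int k = 0;
  for (int t = 1; t <= n_steps; ++t) {
    land_grad(id, par, x.data(), g.data());
    for (int j = 0; j < d; ++j)
      x[j] += -(dt / friction) * g[j] + amp * norm_rand();
    if (t % out_stride == 0) {
      for (int j = 0; j < d; ++j) trace(k, j) = x[j];
      ++k;
    }
  }
  return trace;
}

// ---- single-replica 1D metadynamics with flatness stopping -----------------
// Deposits hills every tau_steps; every check_steps computes the bias growth
// over the window on the region [flat_lo, flat_hi] and stops once the
// relative RMS deviation of the growth from uniform stays below flat_tol for
// n_consec consecutive windows (or max_steps is reached).
// [[Rcpp::export]]
List run_metad_cpp(int id, NumericVector par, double x0, double dt,
                   int tau_steps, int max_steps, int out_stride,
                   double sigma, double height, double temperature,
                   double friction, double grid_lo, double grid_hi, int grid_n,
                   int check_steps, double flat_tol, double flat_lo,
                   double flat_hi, int n_consec, int extra_steps) {
  BiasGrid bias;
  bias.init(grid_lo, grid_hi, grid_n);
  std::vector<double> centers, times;
  double x = x0, g;
  double amp = std::sqrt(2.0 * KB * temperature * dt / friction);
  std::vector<double> trace;
  std::vector<double> vprev;
  int i_lo = (int)std::ceil((flat_lo - grid_lo) / bias.dx);
  int i_hi = (int)std::floor((flat_hi - grid_lo) / bias.dx);
  for (int i = i_lo; i <= i_hi; ++i) vprev.push_back(0.0);
  RNGScope scope;
  int consec = 0, t = 0, stop_at = -1;
  bool flat = false;
  for (t = 1; t <= max_steps; ++t) {
    if (stop_at > 0 && t > stop_at) { --t; break; }
    land_grad(id, par, &x, &g);
    double f = -g - bias.deriv(x);
    x += (dt / friction) * f + amp * norm_rand();
    if (t % tau_steps == 0) {
      bias.deposit(x, sigma, height);
      centers.push_back(x);
      times.push_back(t * dt);
    }
    if (t % out_stride == 0) trace.push_back(x);
    if (t % check_steps == 0) {
      double mg = 0.0;
      int m = i_hi - i_lo + 1;
      std::vector<double> gr(m);
      for (int i = 0; i < m; ++i) {
        gr[i] = bias.v[i_lo + i] - vprev[i];
        vprev[i] = bias.v[i_lo + i];
        mg += gr[i];
      }
      mg /= m;
      double ss = 0.0;
      for (int i = 0; i < m; ++i) ss += (gr[i] - mg) * (gr[i] - mg);
      double rel = (mg > 0) ? std::sqrt(ss / m) / mg : R_PosInf;
      consec = (rel < flat_tol) ? consec + 1 : 0;
      if (consec >= n_consec && !flat) {
        flat = true;
        stop_at = t + extra_steps;  // keep depositing through the
                                    // averaging window
      }
    }
  }
  int n_steps_done = std::min(t, max_steps);
  return List::create(
      _["centers"] = NumericVector(centers.begin(), centers.end()),
      _["times"] = NumericVector(times.begin(), times.end()),
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["n_steps"] = n_steps_done, _["flat"] = flat);
}

// ---- bias-exchange metadynamics -------------------------------------------
// bias_dim[r] is the 0-based coordinate the CV of replica r projects onto, or
// -1 for a neutral (unbiased) replica.  Exchanges: at every exchange time a
// uniformly chosen replica pair attempts a coordinate swap under the
// Metropolis-like criterion on the two walkers' bias energies.
// [[Rcpp::export]]
List run_bemd_cpp(int id, NumericVector par, NumericMatrix x0,
                  IntegerVector bias_dim, NumericVector sigma, double height,
                  double dt, int tau_steps, int exch_steps, int total_steps,
                  int out_stride, double temperature, double friction,
                  NumericVector grid_lo, NumericVector grid_hi, int grid_n) {
  int nrep = x0.nrow(), d = x0.ncol();
  std::vector<std::vector<double>> x(nrep, std::vector<double>(d));
  for (int r = 0; r < nrep; ++r)
    for (int j = 0; j < d; ++j) x[r][j] = x0(r, j);
  std::vector<BiasGrid> bias(nrep);
  std::vector<std::vector<double>> centers(nrep), times(nrep);
  for (int r = 0; r < nrep; ++r)
    if (bias_dim[r] >= 0) bias[r].init(grid_lo[r], grid_hi[r], grid_n);
  double amp = std::sqrt(2.0 * KB * temperature * dt / friction);
  double beta = 1.0 / (KB * temperature);
  int n_out = total_steps / out_stride;
  // traces: one matrix per replica, n_out x d
  std::vector<NumericMatrix> traces;
  for (int r = 0; r < nrep; ++r) traces.push_back(NumericMatrix(n_out, d));
  std::vector<double> ex_time;
  std::vector<int> ex_a, ex_b, ex_acc;
  std::vector<double> g(d);
  RNGScope scope;
  int k = 0;
  for (int t = 1; t <= total_steps; ++t) {
    for (int r = 0; r < nrep; ++r) {
      land_grad(id, par, x[r].data(), g.data());
      int bd = bias_dim[r];
      for (int j = 0; j < d; ++j) {
        double f = -g[j];
        if (bd == j) f -= bias[r].deriv(x[r][j]);
        x[r][j] += (dt / friction) * f + amp * norm_rand();
      }
    }
    if (t % tau_steps == 0) {
      for (int r = 0; r < nrep; ++r) {
        int bd = bias_dim[r];
        if (bd >= 0) {
          bias[r].deposit(x[r][bd], sigma[r], height);
          centers[r].push_back(x[r][bd]);
          times[r].push_back(t * dt);
        }
      }
    }
    if (exch_steps > 0 && t % exch_steps == 0 && nrep >= 2) {
      int a = (int)(unif_rand() * nrep);
      if (a >= nrep) a = nrep - 1;
      int b = a;
      while (b == a) {
        b = (int)(unif_rand() * nrep);
        if (b >= nrep) b = nrep - 1;
      }
      double va_a = 0, va_b = 0, vb_b = 0, vb_a = 0;
      if (bias_dim[a] >= 0) {
        va_a = bias[a].value(x[a][bias_dim[a]]);
        va_b = bias[a].value(x[b][bias_dim[a]]);
      }
      if (bias_dim[b] >= 0) {
        vb_b = bias[b].value(x[b][bias_dim[b]]);
        vb_a = bias[b].value(x[a][bias_dim[b]]);
      }
      double delta = beta * (va_a + vb_b - va_b - vb_a);
      int acc = (delta >= 0) ? 1 : (unif_rand() < std::exp(delta) ? 1 : 0);
      if (acc) std::swap(x[a], x[b]);
      ex_time.push_back(t * dt);
      ex_a.push_back(a + 1);
      ex_b.push_back(b + 1);
      ex_acc.push_back(acc);
    }
    if (t % out_stride == 0) {
      for (int r = 0; r < nrep; ++r)
        for (int j = 0; j < d; ++j) traces[r](k, j) = x[r][j];
      ++k;
    }
  }
  List tr(nrep), ke(nrep);
  for (int r = 0; r < nrep; ++r) {
    tr[r] = traces[r];
    ke[r] = List::create(
        _["centers"] = NumericVector(centers[r].begin(), centers[r].end()),
        _["times"] = NumericVector(times[r].begin(), times[r].end()));
  }
  return List::create(
      _["traces"] = tr, _["kernels"] = ke,
      _["exchange"] = DataFrame::create(
          _["time"] = NumericVector(ex_time.begin(), ex_time.end()),
          _["a"] = IntegerVector(ex_a.begin(), ex_a.end()),
          _["b"] = IntegerVector(ex_b.begin(), ex_b.end()),
          _["accepted"] = IntegerVector(ex_acc.begin(), ex_acc.end())));
}
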