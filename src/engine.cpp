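#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-time centered-space diffusion with no-flux (mirror) boundaries.
// lam = D * dt_sub / dx^2 per sub-step; nsub sub-steps are taken.
// [[Rcpp::export]]
NumericMatrix ftcs_diffuse_cpp(NumericMatrix f, double lam, int nsub) {
  int n = f.nrow(), m = f.ncol();
  std::vector<double> av(f.begin(), f.end()), bv(n * m);
  double *a = av.data(), *b = bv.data();
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < m; ++j) {
      const double *c = a + (size_t)j * n;
      const double *l = (j > 0) ? c - n : c;       // mirror boundary
      const double *r = (j < m - 1) ? c + n : c;
      double *o = b + (size_t)j * n;
      // top and bottom rows (mirrored vertical neighbor)
      o[0] = c[0] + lam * (c[0] + c[1] + l[0] + r[0] - 4.0 * c[0]);
      o[n - 1] = c[n - 1] + lam * (c[n - 2] + c[n - 1] + l[n - 1] +
                                   r[n - 1] - 4.0 * c[n - 1]);
      for (int i = 1; i < n - 1; ++i)
        o[i] = c[i] + lam * (c[i - 1] + c[i + 1] + l[i] + r[i] - 4.0 * c[i]);
    }
    std::swap(a, b);
  }
  NumericMatrix out(n, m);
  std::copy(a, a + (size_t)n * m, out.begin());
  return out;
}

// Lsr parameter column order shared with the R engine.
enum LsrP { K_SYNTH, V_YDGG, BASAL, K_BASAL, K_PHOS, K_PK, D_AP,
            V_IND, K_IND, A0, A_M, K2, HILL_N, D_M, K_TR, D_T, NLSRP };

static inline double hill_frac(double Ap, double k2, double n) {
  if (Ap <= 0.0) return 0.0;
  double r = Ap / k2;
  if (r > 1e12) return 1.0;
  double rn = std::pow(r, n);
  return rn / (1.0 + rn);
}

// Derivatives of one element group: pool concentration C plus 4 states per
// cell. y layout: [C, Ai_1, Ap_1, M_1, T_1, Ai_2, ...].
static void lsr_group_deriv(const std::vector<double> &y,
                            std::vector<double> &d,
                            const NumericMatrix &par,
                            const std::vector<int> &cells,
                            double vr) {
  double C = y[0];
  d[0] = 0.0;
  for (size_t k = 0; k < cells.size(); ++k) {
    int c = cells[k];
    size_t i = 1 + 4 * k;
    double Ai = y[i], Ap = y[i + 1], M = y[i + 2], T = y[i + 3];
    double exp_ = par(c, V_YDGG) * Ai;
    double bas = par(c, BASAL) * C / (par(c, K_BASAL) + C);
    double ind = par(c, V_IND) * T * C / (par(c, K_IND) + C);
    double kp = par(c, K_PHOS) + par(c, K_PK) * T;
    double hill = hill_frac(Ap, par(c, K2), par(c, HILL_N));
    d[0] += vr * (exp_ - bas - ind);
    d[i]     = par(c, K_SYNTH) - exp_ + bas + ind - kp * Ai;
    d[i + 1] = kp * Ai - par(c, D_AP) * Ap;
    d[i + 2] = par(c, A0) + par(c, A_M) * hill - par(c, D_M) * M;
    d[i + 3] = par(c, K_TR) * M - par(c, D_T) * T;
  }
}

// Adaptive Heun integration of one element group over dt (minutes).
// Steps producing a negative state are rejected and retried smaller
// (never clipped, so mole balance is preserved).
static void integrate_group(std::vector<double> &y,
                            const NumericMatrix &par,
                            const std::vector<int> &cells,
                            double vr, double dt,
                            double rtol, double atol) {
  size_t ns = y.size();
  std::vector<double> d0(ns), d1(ns), ye(ns), yh(ns);
  double t = 0.0, h = dt;
  const double hmin = dt * 1e-8;
  int guard = 0;
  while (t < dt * (1.0 - 1e-12)) {
    if (++guard > 2000000) stop("lsr engine step: sub-step limit exceeded");
    if (h > dt - t) h = dt - t;
    lsr_group_deriv(y, d0, par, cells, vr);
    bool bad = false;
    for (size_t i = 0; i < ns; ++i) {
      ye[i] = y[i] + h * d0[i];
      if (ye[i] < 0.0) { bad = true; break; }
    }
    double err = 0.0;
    if (!bad) {
      lsr_group_deriv(ye, d1, par, cells, vr);
      for (size_t i = 0; i < ns; ++i) {
        yh[i] = y[i] + 0.5 * h * (d0[i] + d1[i]);
        if (yh[i] < 0.0) { bad = true; break; }
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yh[i]));
        double e = std::fabs(yh[i] - ye[i]) / sc;
        if (e > err) err = e;
      }
    }
    if (bad || err > 1.0) {
      // jump toward the error-implied step size; plain halving when the
      // rejection came from a negativity excursion
      double shrink = bad ? 0.5 : std::max(0.2, 0.9 / std::sqrt(err));
      h *= shrink;
      if (h < hmin) stop("lsr engine step: step size underflow");
      continue;
    }
    y = yh;
    t += h;
    double grow = (err > 1e-12) ? 0.9 / std::sqrt(err) : 4.0;
    if (grow > 4.0) grow = 4.0;
    if (grow < 0.2) grow = 0.2;
    h *= grow;
  }
}

// Advance all Lsr cells by one engine step, coupled to their grid elements.
// states: ncell x 4 (Ai, Ap, M, T); par: ncell x 16 (column order above);
// elem: 0-based linear element index per cell; field: n x n (uM).
// vol_ratio = cell volume / element volume. Returns list(states, field).
// [[Rcpp::export]]
List lsr_cells_step_cpp(NumericMatrix states, NumericMatrix par,
                        IntegerVector elem, NumericMatrix field,
                        double vol_ratio, double dt_min,
                        double rtol = 2e-4, double atol = 1e-8) {
  int ncell = states.nrow();
  if (par.ncol() != NLSRP) stop("lsr parameter matrix has wrong column count");
  NumericMatrix st = clone(states);
  NumericMatrix fld = clone(field);
  // group cells by element
  std::map<int, std::vector<int> > groups;
  for (int c = 0; c < ncell; ++c) groups[elem[c]].push_back(c);
  for (std::map<int, std::vector<int> >::iterator it = groups.begin();
       it != groups.end(); ++it) {
    const std::vector<int> &cells = it->second;
    std::vector<double> y(1 + 4 * cells.size());
    y[0] = fld[it->first];
    for (size_t k = 0; k < cells.size(); ++k)
      for (int s = 0; s < 4; ++s) y[1 + 4 * k + s] = st(cells[k], s);
    integrate_group(y, par, cells, vol_ratio, dt_min, rtol, atol);
    fld[it->first] = y[0];
    for (size_t k = 0; k < cells.size(); ++k)
      for (int s = 0; s < 4; ++s) st(cells[k], s) = y[1 + 4 * k + s];
  }
  return List::create(_["states"] = st, _["field"] = fld);
}

// Advance all LuxIR cells by one engine step, coupled to their elements.
// states: ncell x 3 (AHL_in, t_since [-1 = never crossed], r_basal).
// lp: threshold, r_max, ramp, conductivity, degradation.
// [[Rcpp::export]]
List lux_cells_step_cpp(NumericMatrix states, NumericVector lp,
                        IntegerVector elem, NumericMatrix field,
                        double vol_ratio, double dt_min, int nsub = 4) {
  double threshold = lp[0], r_max = lp[1], ramp = lp[2],
         cond = lp[3], degr = lp[4];
  int ncell = states.nrow();
  NumericMatrix st = clone(states);
  NumericMatrix fld = clone(field);
  std::map<int, std::vector<int> > groups;
  for (int c = 0; c < ncell; ++c) groups[elem[c]].push_back(c);
  double h = dt_min / nsub;
  for (std::map<int, std::vector<int> >::iterator it = groups.begin();
       it != groups.end(); ++it) {
    const std::vector<int> &cells = it->second;
    double C = fld[it->first];
    for (int s = 0; s < nsub; ++s) {
      double dC = 0.0;
      for (size_t k = 0; k < cells.size(); ++k) {
        int c = cells[k];
        double A = st(c, 0), ts = st(c, 1), rb = st(c, 2);
        double rate = rb;
        if (ts >= 0.0) {
          double frac = ts / ramp; if (frac > 1.0) frac = 1.0;
          rate = rb + (r_max - rb) * frac;
        }
        double flux = cond * (A - C);           // uM/min leaving the cell
        double Anew = A + h * (rate - flux - degr * A);
        if (Anew < 0.0) Anew = 0.0;
        dC += vol_ratio * flux * h;
        if (ts >= 0.0) ts += h;
        else if (Anew > threshold) ts = 0.0;
        st(c, 0) = Anew;
        st(c, 1) = ts;
      }
      C += dC;
      if (C < 0.0) C = 0.0;
    }
    fld[it->first] = C;
  }
  return List::create(_["states"] = st, _["field"] = fld);
}

// Sequential acceptance of proposed swim moves under the per-element
// density cap. Positions already reflected into the domain. counts is the
// current per-element occupancy (modified on a clone). 0-based linear
// element index = i + n * j with i = floor(x/dx), j = floor(y/dx).
// [[Rcpp::export]]
List apply_moves_cpp(NumericVector x, NumericVector y,
                     NumericVector px, NumericVector py,
                     IntegerMatrix counts, double dx, int cap) {
  int ncell = x.size(), n = counts.nrow();
  NumericVector nx = clone(x), ny = clone(y);
  IntegerMatrix ct = clone(counts);
  for (int c = 0; c < ncell; ++c) {
    int i0 = std::min(std::max((int)std::floor(x[c] / dx), 0), n - 1);
    int j0 = std::min(std::max((int)std::floor(y[c] / dx), 0), n - 1);
    int i1 = std::min(std::max((int)std::floor(px[c] / dx), 0), n - 1);
    int j1 = std::min(std::max((int)std::floor(py[c] / dx), 0), n - 1);
    if (i0 == i1 && j0 == j1) { nx[c] = px[c]; ny[c] = py[c]; continue; }
    if (ct(i1, j1) >= cap) continue;           // rejected: stay put
    ct(i0, j0) -= 1;
    ct(i1, j1) += 1;
    nx[c] = px[c];
    ny[c] = py[c];
  }
  return List::create(_["x"] = nx, _["y"] = ny, _["counts"] = ct);
}
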