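#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// logistic transfer: fmax / (1 + exp(-gain * (x - half)))
static inline double logis(double x, double gain, double half, double fmax) {
  return fmax / (1.0 + std::exp(-gain * (x - half)));
}

// threshold power law: gain * max(x - thresh, 0)^expo
static inline double tpl(double x, double gain, double thresh, double expo) {
  double u = x - thresh;
  return u > 0.0 ? gain * std::pow(u, expo) : 0.0;
}

// Heun (explicit trapezoidal) integration of the r-a model
//   tau_r dr/dt = -r + R_inf(w r - b a + drive(t) + xi(t))
//   tau_a da/dt = -a + A_inf(r)
// xi and drive are piecewise constant on the dt grid (precomputed noise).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_ra(NumericVector xi, NumericVector drive, double dt,
                              double w, double b,
                              double tau_r, double tau_a,
                              double rg, double rh, double rm,
                              double ag, double ah, double am,
                              double r0, double a0) {
  int n = xi.size();
  NumericMatrix out(n + 1, 2);
  double r = r0, a = a0;
  out(0, 0) = r; out(0, 1) = a;
  for (int i = 0; i < n; ++i) {
    double in0 = w * r - b * a + drive[i] + xi[i];
    double dr1 = (-r + logis(in0, rg, rh, rm)) / tau_r;
    double da1 = (-a + logis(r, ag, ah, am)) / tau_a;
    double rp = r + dt * dr1, ap = a + dt * da1;
    double in1 = w * rp - b * ap + drive[i] + xi[i];
    double dr2 = (-rp + logis(in1, rg, rh, rm)) / tau_r;
    double da2 = (-ap + logis(rp, ag, ah, am)) / tau_a;
    r += 0.5 * dt * (dr1 + dr2);
    a += 0.5 * dt * (da1 + da2);
    if (!std::isfinite(r) || !std::isfinite(a))
      stop("simulation diverged (non-finite state) at step %d", i + 1);
    out(i + 1, 0) = r; out(i + 1, 1) = a;
  }
  return out;
}

// Heun integration of the adapting inhibition-stabilized network
//   tau_e dre/dt = -re + Re(wee re - wei ri - b a + drive_e + xi_e)
//   tau_i dri/dt = -ri + Ri(wie re - wii ri + drive_i + xi_i)
//   tau_a da/dt  = -a + A_inf(re)
// Transfer functions Re, Ri are threshold power laws; A_inf is logistic.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_ei(NumericVector xi_e, NumericVector xi_i,
                              NumericVector drive_e, NumericVector drive_i,
                              double dt,
                              double wee, double wei, double wie, double wii,
                              double b, double tau_e, double tau_i, double tau_a,
                              double eg, double eth, double eex,
                              double ig, double ith, double iex,
                              double ag, double ah, double am,
                              double re0, double ri0, double a0,
                              double r_cap) {
  int n = xi_e.size();
  NumericMatrix out(n + 1, 3);
  double re = re0, ri = ri0, a = a0;
  out(0, 0) = re; out(0, 1) = ri; out(0, 2) = a;
  for (int i = 0; i < n; ++i) {
    double d1e = (-re + tpl(wee * re - wei * ri - b * a + drive_e[i] + xi_e[i],
                            eg, eth, eex)) / tau_e;
    double d1i = (-ri + tpl(wie * re - wii * ri + drive_i[i] + xi_i[i],
                            ig, ith, iex)) / tau_i;
    double d1a = (-a + logis(re, ag, ah, am)) / tau_a;
    double pe = re + dt * d1e, pi = ri + dt * d1i, pa = a + dt * d1a;
    double d2e = (-pe + tpl(wee * pe - wei * pi - b * pa + drive_e[i] + xi_e[i],
                            eg, eth, eex)) / tau_e;
    double d2i = (-pi + tpl(wie * pe - wii * pi + drive_i[i] + xi_i[i],
                            ig, ith, iex)) / tau_i;
    double d2a = (-pa + logis(pe, ag, ah, am)) / tau_a;
    re += 0.5 * dt * (d2e + d1e);
    ri += 0.5 * dt * (d2i + d1i);
    a  += 0.5 * dt * (d2a + d1a);
    if (re > r_cap) re = r_cap;
    if (ri > r_cap) ri = r_cap;
    if (!std::isfinite(re) || !std::isfinite(ri) || !std::isfinite(a))
      stop("simulation diverged (non-finite state) at step %d", i + 1);
    out(i + 1, 0) = re; out(i + 1, 1) = ri; out(i + 1, 2) = a;
  }
  return out;
}

// One sweep of the dip computation: points (xs[j], ylo[j]) in ascending xs,
// lower convex hull grown left to right; dev[j] = max over k <= j of
// (yhi[k] - hull_j(xs[k])), i.e. sup deviation of the empirical CDF above
// the greatest convex minorant of the prefix ending at j.
static std::vector<double> gcm_dev_sweep(const std::vector<double>& xs,
                                         const std::vector<double>& ylo,
                                         const std::vector<double>& yhi) {
  int n = xs.size();
  std::vector<double> dev(n);
  std::vector<int> hull; hull.reserve(n);
  std::vector<double> segmax; segmax.reserve(n);  // cumulative max along hull
  hull.push_back(0);
  segmax.push_back(yhi[0] - ylo[0]);
  dev[0] = segmax[0];
  for (int i = 1; i < n; ++i) {
    // pop while the last hull point is not strictly below line (prev -> i)
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull.back();
      long double cr = (long double)(xs[b] - xs[a]) * (ylo[i] - ylo[a]) -
                       (long double)(ylo[b] - ylo[a]) * (xs[i] - xs[a]);
      if (cr <= 0) { hull.pop_back(); segmax.pop_back(); } else break;
    }
    int a = hull.back();
    double m = 0.0;
    double dx = xs[i] - xs[a];
    for (int k = a; k <= i; ++k) {
      double hv = dx > 0 ? ylo[a] + (ylo[i] - ylo[a]) * (xs[k] - xs[a]) / dx
                         : std::min(ylo[a], ylo[i]);
      double d = yhi[k] - hv;
      if (d > m) m = d;
    }
    double cum = segmax.empty() ? m : std::max(m, segmax.back());
    hull.push_back(i);
    segmax.push_back(cum);
    dev[i] = cum;
  }
  return dev;
}

// Hartigan-type dip statistic: half the smallest, over candidate modes m, of
// the larger of (a) the sup deviation of the ECDF above its greatest convex
// minorant on [x_1, x_m] and (b) the sup deviation below its least concave
// majorant on [x_m, x_n]. x must be sorted ascending.
// [[Rcpp::export]]
double cpp_dip(NumericVector x) {
  int n = x.size();
  if (n < 4) return 0.0;
  if (x[n - 1] == x[0]) return 0.0;  // degenerate constant sample
  std::vector<double> xs(n), ylo(n), yhi(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[i];
    ylo[i] = (double)i / n;        // F(x_i^-)
    yhi[i] = (double)(i + 1) / n;  // F(x_i)
  }
  std::vector<double> dl = gcm_dev_sweep(xs, ylo, yhi);
  // mirror both axes: least concave majorant of suffix becomes a gcm sweep
  std::vector<double> xs2(n), ylo2(n), yhi2(n);
  for (int t = 0; t < n; ++t) {
    int j = n - 1 - t;
    xs2[t] = -xs[j];
    ylo2[t] = -yhi[j];
    yhi2[t] = -ylo[j];
  }
  std::vector<double> du_rev = gcm_dev_sweep(xs2, ylo2, yhi2);
  double best = R_PosInf;
  for (int m = 0; m < n; ++m) {
    double d = std::max(dl[m], du_rev[n - 1 - m]);
    if (d < best) best = d;
  }
  return 0.5 * best;
}
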