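#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-passage densities of a time-inhomogeneous Brownian motion
//   dX = mu(t) dt + sigma(t) dW,  X(0) = 0,
// between constant bounds +theta_up and -theta_lo, via the two-boundary
// Volterra integral equations of the second kind.
//
// The process is mapped to a standard Brownian motion B(s) in variance time
// s(t) = int sigma^2 du with curved boundaries U(s) = theta_up - M(t(s)),
// L(s) = -theta_lo - M(t(s)), M(t) = int mu du.  In that clock the kernel is
//   Psi(c_i, s_i | y, r) = phi((c_i - y)/sqrt(ds)) / sqrt(ds)
//                          * ( slope_i / 2 - (c_i - y) / (2 ds) )
// with ds = s_i - r and slope_i the (discrete) boundary slope at s_i.  The
// diagonal kernel vanishes in the limit r -> s_i for the discrete slope,
// so the trapezoidal discretization is explicit.
//
// Inputs: s, M on the (real-time) grid; outputs densities per unit s.

static inline double kern(double ci, double slope_i, double y, double ds) {
  if (ds <= 1e-14) return 0.0;
  double z = (ci - y) / std::sqrt(ds);
  double f = std::exp(-0.5 * z * z) / std::sqrt(2.0 * M_PI * ds);
  return f * (0.5 * slope_i - (ci - y) / (2.0 * ds));
}

// [[Rcpp::export]]
List volterra_fpt_cpp(NumericVector s, NumericVector M,
                      double theta_up, double theta_lo, int nx = 201) {
  int n = s.size();
  NumericVector U(n), L(n), g1(n), g2(n);
  for (int i = 0; i < n; ++i) {
    U[i] = theta_up - M[i];
    L[i] = -theta_lo - M[i];
  }
  // discrete boundary slopes in s (identical for both boundaries here,
  // kept separate in case of asymmetric generalizations)
  NumericVector dU(n, 0.0), dL(n, 0.0);
  for (int i = 1; i < n; ++i) {
    double ds = s[i] - s[i - 1];
    if (ds > 1e-14) {
      dU[i] = (U[i] - U[i - 1]) / ds;
      dL[i] = (L[i] - L[i - 1]) / ds;
    }
  }
  g1[0] = 0.0;
  g2[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double si = s[i];
    double sum1 = 0.0, sum2 = 0.0;
    for (int j = 1; j < i; ++j) {
      // trapezoid weight on the nonuniform s grid (interior nodes)
      double w = 0.5 * (s[j + 1] - s[j - 1]);
      if (w <= 0) continue;
      double k1u = kern(U[i], dU[i], U[j], si - s[j]);
      double k1l = kern(U[i], dU[i], L[j], si - s[j]);
      double k2u = kern(L[i], dL[i], U[j], si - s[j]);
      double k2l = kern(L[i], dL[i], L[j], si - s[j]);
      sum1 += w * (g1[j] * k1u + g2[j] * k1l);
      sum2 += w * (g1[j] * k2u + g2[j] * k2l);
    }
    double psi10 = kern(U[i], dU[i], 0.0, si);
    double psi20 = kern(L[i], dL[i], 0.0, si);
    double a = -2.0 * psi10 + 2.0 * sum1;
    double b = 2.0 * psi20 - 2.0 * sum2;
    g1[i] = a > 0 ? a : 0.0;
    g2[i] = b > 0 ? b : 0.0;
  }
  // survived density at the deadline and the mass with X(T) > 0
  double S = s[n - 1];
  double surv_tot = 0.0, surv_pos = 0.0;
  if (S > 1e-14) {
    double lo = L[n - 1], hi = U[n - 1];
    double x0 = -M[n - 1];  // B-value where X = 0
    if (x0 < lo) x0 = lo;
    if (x0 > hi) x0 = hi;
    NumericVector xg(nx), px(nx);
    for (int m = 0; m < nx; ++m)
      xg[m] = lo + (hi - lo) * m / (nx - 1.0);
    for (int m = 0; m < nx; ++m) {
      double x = xg[m];
      double p = std::exp(-0.5 * x * x / S) / std::sqrt(2.0 * M_PI * S);
      for (int j = 1; j < n - 1; ++j) {
        double w = 0.5 * (s[j + 1] - s[j - 1]);
        double ds = S - s[j];
        if (w <= 0 || ds <= 1e-14) continue;
        double zu = (x - U[j]) / std::sqrt(ds);
        double zl = (x - L[j]) / std::sqrt(ds);
        double fu = std::exp(-0.5 * zu * zu) / std::sqrt(2.0 * M_PI * ds);
        double fl = std::exp(-0.5 * zl * zl) / std::sqrt(2.0 * M_PI * ds);
        p -= w * (g1[j] * fu + g2[j] * fl);
      }
      px[m] = p > 0 ? p : 0.0;
    }
    double dx = (hi - lo) / (nx - 1.0);
    for (int m = 0; m < nx - 1; ++m) {
      double seg = 0.5 * (px[m] + px[m + 1]) * dx;
      surv_tot += seg;
      // portion of the segment above x0 (X > 0)
      if (xg[m + 1] <= x0) continue;
      if (xg[m] >= x0) {
        surv_pos += seg;
      } else {
        double frac = (xg[m + 1] - x0) / dx;
        double pm = px[m] + (px[m + 1] - px[m]) * (1.0 - frac);
        surv_pos += 0.5 * (pm + px[m + 1]) * (xg[m + 1] - x0);
      }
    }
  }
  return List::create(_["g_up"] = g1, _["g_lo"] = g2,
                      _["surv_tot"] = surv_tot, _["surv_pos"] = surv_pos);
}
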