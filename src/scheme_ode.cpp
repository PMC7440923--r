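// Adaptive Cash-Karp Runge-Kutta integration of the coupled
// folding-binding-catalysis scheme
//   EU <-> EF <-> ES -> EF + P
// with stoichiometric depletion of substrate (S) and cofactor (N).
// State vector: (EU, EF, ES, S, N, P), all molar.
// No stiff solver is available offline, so the fast binding relaxation
// is handled by adaptive explicit stepping with tight tolerances; the
// stiffness ratio of the regimes used here (<= ~1e5) keeps this cheap.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void rhs(const double *y, double *dy,
                       double k1, double km1, double k2, double km2,
                       double kcat, bool clampS) {
  const double EU = y[0], EF = y[1], ES = y[2], S = y[3];
  const double fold = k1 * EU - km1 * EF;
  const double bind = k2 * EF * S - km2 * ES;
  const double cat = kcat * ES;
  dy[0] = -fold;
  dy[1] = fold - bind + cat;
  dy[2] = bind - cat;
  dy[3] = clampS ? 0.0 : -bind;
  dy[4] = -cat;
  dy[5] = cat;
}

// [[Rcpp::export(name = ".scheme_ode_cpp")]]
NumericMatrix scheme_ode_cpp(NumericVector y0, NumericVector times,
                             double k1, double km1, double k2, double km2,
                             double kcat, bool clampS,
                             double rtol, double atol,
                             double max_steps) {
  if (y0.size() != 6) stop("state vector must have length 6");
  const int nt = times.size();
  NumericMatrix out(nt, 6);

  // Cash-Karp 4(5) tableau
  static const double a2 = 1.0 / 5, a3 = 3.0 / 10, a4 = 3.0 / 5,
                      a5 = 1.0, a6 = 7.0 / 8;
  static const double b21 = 1.0 / 5;
  static const double b31 = 3.0 / 40, b32 = 9.0 / 40;
  static const double b41 = 3.0 / 10, b42 = -9.0 / 10, b43 = 6.0 / 5;
  static const double b51 = -11.0 / 54, b52 = 5.0 / 2, b53 = -70.0 / 27,
                      b54 = 35.0 / 27;
  static const double b61 = 1631.0 / 55296, b62 = 175.0 / 512,
                      b63 = 575.0 / 13824, b64 = 44275.0 / 110592,
                      b65 = 253.0 / 4096;
  static const double c1 = 37.0 / 378, c3 = 250.0 / 621, c4 = 125.0 / 594,
                      c6 = 512.0 / 1771;
  static const double dc1 = c1 - 2825.0 / 27648,
                      dc3 = c3 - 18575.0 / 48384,
                      dc4 = c4 - 13525.0 / 55296,
                      dc5 = -277.0 / 14336, dc6 = c6 - 1.0 / 4;
  (void)a2; (void)a3; (void)a4; (void)a5; (void)a6;

  double y[6], yt[6], k[6][6], yerr[6], ynew[6];
  for (int i = 0; i < 6; ++i) y[i] = y0[i];

  double t = times[0];
  for (int i = 0; i < 6; ++i) out(0, i) = y[i];

  // initial step: a fraction of the fastest timescale
  double rate_scale = k1 + km1 + km2 + kcat + k2 * std::max(y[3], 1e-30);
  double h = (rate_scale > 0) ? 0.01 / rate_scale
                              : (times[nt - 1] - times[0]) / 1000.0;
  long steps = 0;

  for (int it = 1; it < nt; ++it) {
    const double t_end = times[it];
    while (t < t_end) {
      if (++steps > (long)max_steps)
        stop("ODE integration exceeded max_steps (rtol=%g, atol=%g)",
             rtol, atol);
      bool clipped = false;
      double hs = h;
      if (t + hs > t_end) { hs = t_end - t; clipped = true; }

      rhs(y, k[0], k1, km1, k2, km2, kcat, clampS);
      for (int i = 0; i < 6; ++i) yt[i] = y[i] + hs * b21 * k[0][i];
      rhs(yt, k[1], k1, km1, k2, km2, kcat, clampS);
      for (int i = 0; i < 6; ++i)
        yt[i] = y[i] + hs * (b31 * k[0][i] + b32 * k[1][i]);
      rhs(yt, k[2], k1, km1, k2, km2, kcat, clampS);
      for (int i = 0; i < 6; ++i)
        yt[i] = y[i] + hs * (b41 * k[0][i] + b42 * k[1][i] + b43 * k[2][i]);
      rhs(yt, k[3], k1, km1, k2, km2, kcat, clampS);
      for (int i = 0; i < 6; ++i)
        yt[i] = y[i] + hs * (b51 * k[0][i] + b52 * k[1][i] +
                             b53 * k[2][i] + b54 * k[3][i]);
      rhs(yt, k[4], k1, km1, k2, km2, kcat, clampS);
      for (int i = 0; i < 6; ++i)
        yt[i] = y[i] + hs * (b61 * k[0][i] + b62 * k[1][i] +
                             b63 * k[2][i] + b64 * k[3][i] +
                             b65 * k[4][i]);
      rhs(yt, k[5], k1, km1, k2, km2, kcat, clampS);

      double errmax = 0.0;
      for (int i = 0; i < 6; ++i) {
        ynew[i] = y[i] + hs * (c1 * k[0][i] + c3 * k[2][i] +
                               c4 * k[3][i] + c6 * k[5][i]);
        yerr[i] = hs * (dc1 * k[0][i] + dc3 * k[2][i] + dc4 * k[3][i] +
                        dc5 * k[4][i] + dc6 * k[5][i]);
        const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(ynew[i]));
        const double e = std::fabs(yerr[i]) / sc;
        if (e > errmax) errmax = e;
      }

      if (errmax <= 1.0) {
        t += hs;
        for (int i = 0; i < 6; ++i) y[i] = std::max(ynew[i], 0.0);
        double fac = (errmax > 0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
        if (fac > 5.0) fac = 5.0;
        if (!clipped) h = hs * fac;
        else h = std::max(h, hs * fac);
      } else {
        double fac = 0.9 * std::pow(errmax, -0.25);
        if (fac < 0.1) fac = 0.1;
        h = hs * fac;
      }
    }
    for (int i = 0; i < 6; ++i) out(it, i) = y[i];
  }
  colnames(out) = CharacterVector::create("E_U", "E_F", "ES", "S", "N",
                                          "P");
  return out;
}
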