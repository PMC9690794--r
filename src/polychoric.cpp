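#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// Upper-quadrant probability P(X > dh, Y > dk) of the standard bivariate
// normal with correlation r.  Genz's BVND scheme: Gauss-Legendre quadrature
// on the tetrachoric series for |r| < 0.925, and the stable tail expansion
// otherwise.  Absolute accuracy ~ 1e-14.
static double bvnu(double dh, double dk, double r) {
  static const double xs[3][10] = {
    {0.9324695142031521, 0.6612093864662645, 0.2386191860831969,
     0, 0, 0, 0, 0, 0, 0},
    {0.9815606342467192, 0.9041172563704749, 0.7699026741943047,
     0.5873179542866175, 0.3678314989981802, 0.1252334085114689,
     0, 0, 0, 0},
    {0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
     0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
     0.5108670019508271, 0.3737060887154195, 0.2277858511416451,
     0.07652652113349734}};
  static const double ws[3][10] = {
    {0.1713244923791704, 0.3607615730481386, 0.4679139345726910,
     0, 0, 0, 0, 0, 0, 0},
    {0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
     0.2031674267230659, 0.2334925365383548, 0.2491470458134028,
     0, 0, 0, 0},
    {0.01761400713915212, 0.04060142980038694, 0.06267204833410907,
     0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
     0.1316886384491766, 0.1420961093183820, 0.1491729864726037,
     0.1527533871307258}};
  const double twopi = 6.283185307179586;
  int ng, lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { ng = 0; lg = 3; }
  else if (ar < 0.75) { ng = 1; lg = 6; }
  else                { ng = 2; lg = 10; }

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    if (ar > 0.0) {
      double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * xs[ng][i] + 1.0) / 2.0);
          bvn += ws[ng][i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        double sp = std::sqrt(twopi) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double x2 = a * (is * xs[ng][i] + 1.0);
          double xsq = x2 * x2;
          double rs = std::sqrt(1.0 - xsq);
          double asr1 = -(bs / xsq + hk) / 2.0;
          if (asr1 > -100.0) {
            double sp = 1.0 + c * xsq * (1.0 + d * xsq);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a * ws[ng][i] * std::exp(asr1) * (ep - sp);
          }
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0.0) bvn += phid(-std::max(h, k));
    else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return std::max(0.0, std::min(1.0, bvn));
}

// CDF P(X <= h, Y <= k); infinite arguments are allowed.
// [[Rcpp::export]]
double pbvnorm_cpp(double h, double k, double rho) {
  if (!std::isfinite(h) || !std::isfinite(k)) {
    if (h <= -40.0 || k <= -40.0) return 0.0;
    if (!std::isfinite(h) && h > 0) return phid(std::min(k, 40.0));
    if (!std::isfinite(k) && k > 0) return phid(std::min(h, 40.0));
    return 0.0;
  }
  return bvnu(-h, -k, rho);
}

// Negative log-likelihood of a two-way contingency table under the bivariate
// normal copula: `tab` is the R x C table of pair counts, `a` and `b` the
// finite inner thresholds (lengths R-1 and C-1).  Cell probabilities are
// floored at 1e-12 so sparse cells do not produce -Inf.
// [[Rcpp::export]]
double polychoric_nll_cpp(const arma::mat& tab, const arma::vec& a,
                          const arma::vec& b, double rho) {
  const int R = tab.n_rows, C = tab.n_cols;
  // cumulative CDF at threshold grid, with -Inf / +Inf borders
  arma::mat F(R + 1, C + 1);
  for (int i = 0; i <= R; i++) {
    double ai = (i == 0) ? -INFINITY : (i == R ? INFINITY : a(i - 1));
    for (int j = 0; j <= C; j++) {
      double bj = (j == 0) ? -INFINITY : (j == C ? INFINITY : b(j - 1));
      if (i == 0 || j == 0) F(i, j) = 0.0;
      else if (i == R && j == C) F(i, j) = 1.0;
      else if (i == R) F(i, j) = phid(bj);
      else if (j == C) F(i, j) = phid(ai);
      else F(i, j) = pbvnorm_cpp(ai, bj, rho);
    }
  }
  double nll = 0.0;
  for (int i = 0; i < R; i++) {
    for (int j = 0; j < C; j++) {
      if (tab(i, j) > 0) {
        double p = F(i + 1, j + 1) - F(i, j + 1) - F(i + 1, j) + F(i, j);
        if (p < 1e-12) p = 1e-12;
        nll -= tab(i, j) * std::log(p);
      }
    }
  }
  return nll;
}
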