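// Bivariate standard-normal rectangle probabilities for the polychoric
// likelihood. The CDF uses the Drezner-Wesolowsky / Genz Gauss-Legendre
// scheme (double precision, |rho| up to 1), so no external distribution
// library is needed in the hot loop.
#include <Rcpp.h>
using namespace Rcpp;

static double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// P(X > dh, Y > dk) for standard bivariate normal with correlation r.
static double bvnu(double dh, double dk, double r) {
  static const double w1[] = {0.1713244923791705, 0.3607615730481384,
                              0.4679139345726904};
  static const double x1[] = {0.9324695142031522, 0.6612093864662647,
                              0.2386191860831970};
  static const double w2[] = {0.04717533638651177, 0.1069393259953183,
                              0.1600783285433464,  0.2031674267230659,
                              0.2334925365383547,  0.2491470458134029};
  static const double x2[] = {0.9815606342467191, 0.9041172563704750,
                              0.7699026741943050, 0.5873179542866171,
                              0.3678314989981802, 0.1252334085114692};
  static const double w3[] = {0.01761400713915212, 0.04060142980038694,
                              0.06267204833410906, 0.08327674157670475,
                              0.1019301198172404,  0.1181945319615184,
                              0.1316886384491766,  0.1420961093183821,
                              0.1491729864726037,  0.1527533871307259};
  static const double x3[] = {0.9931285991850949, 0.9639719272779138,
                              0.9122344282513259, 0.8391169718222188,
                              0.7463319064601508, 0.6360536807265150,
                              0.5108670019508271, 0.3737060887154196,
                              0.2277858511416451, 0.07652652113349733};
  const double twopi = 6.283185307179586;
  const double *w, *x;
  int ng;
  if (std::fabs(r) < 0.3)      { ng = 3;  w = w1; x = x1; }
  else if (std::fabs(r) < 0.75){ ng = 6;  w = w2; x = x2; }
  else                         { ng = 10; w = w3; x = x3; }

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (std::fabs(r) < 0.925) {
    if (std::fabs(r) > 0) {
      double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
      for (int i = 0; i < ng; ++i) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
          bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (std::fabs(r) < 1) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr2 = -(bs / as + hk) / 2.0;
      if (asr2 > -100.0)
        bvn = a * std::exp(asr2) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < ng; ++i) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr3 = -(bs / xs + hk) / 2.0;
          if (asr3 > -100.0) {
            bvn += a * w[i] * std::exp(asr3) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
          }
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return bvn;
}

// P(X <= h, Y <= k)
static double phi2(double h, double k, double r) {
  if (h <= -37.0 || k <= -37.0) return 0.0;
  if (h >= 37.0) return phid(k);
  if (k >= 37.0) return phid(h);
  return bvnu(-h, -k, r);
}

// [[Rcpp::export(name = ".pbvnorm_cpp")]]
NumericVector pbvnorm_cpp(NumericVector h, NumericVector k, NumericVector r) {
  const int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = phi2(h[i], k[i], r[i]);
  return out;
}

// Negative log-likelihood of a two-way ordinal contingency table under the
// latent bivariate-normal model with fixed thresholds (two-step polychoric).
// tx, ty: interior thresholds (finite, increasing).
// [[Rcpp::export(name = ".polychoric_negll_cpp")]]
double polychoric_negll_cpp(const NumericMatrix& tab, const NumericVector& tx,
                            const NumericVector& ty, double rho) {
  const int R = tab.nrow(), C = tab.ncol();
  std::vector<double> ax(R + 1), ay(C + 1);
  ax[0] = -40.0; ax[R] = 40.0;
  ay[0] = -40.0; ay[C] = 40.0;
  for (int i = 1; i < R; ++i) ax[i] = tx[i - 1];
  for (int j = 1; j < C; ++j) ay[j] = ty[j - 1];
  // corner CDF values
  std::vector<double> F((R + 1) * (C + 1));
  for (int i = 0; i <= R; ++i)
    for (int j = 0; j <= C; ++j)
      F[i * (C + 1) + j] = phi2(ax[i], ay[j], rho);
  double nll = 0.0;
  for (int i = 0; i < R; ++i) {
    for (int j = 0; j < C; ++j) {
      double nij = tab(i, j);
      if (nij <= 0) continue;
      double pij = F[(i + 1) * (C + 1) + (j + 1)] - F[i * (C + 1) + (j + 1)] -
                   F[(i + 1) * (C + 1) + j] + F[i * (C + 1) + j];
      if (pij < 1e-300) pij = 1e-300;
      nll -= nij * std::log(pij);
    }
  }
  return nll;
}
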