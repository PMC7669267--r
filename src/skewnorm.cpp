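// Skew-normal negative log-likelihood and gradient, parametrised as
// (xi, log omega, alpha). Hot path of the permutation null, where the
// likelihood is evaluated millions of times.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2 = 0.6931471805599453;
static const double HALF_LOG_2PI = 0.9189385332046727;

// [[Rcpp::export(name = ".snNllCpp")]]
double snNllCpp(NumericVector par, NumericVector x) {
  const double xi = par[0], lomega = par[1], alpha = par[2];
  const double omega = std::exp(lomega);
  const int n = x.size();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double z = (x[i] - xi) / omega;
    nll -= LOG2 - lomega - 0.5 * z * z - HALF_LOG_2PI +
           R::pnorm(alpha * z, 0.0, 1.0, 1, 1);
  }
  return nll;
}

// [[Rcpp::export(name = ".snNllGradCpp")]]
NumericVector snNllGradCpp(NumericVector par, NumericVector x) {
  const double xi = par[0], lomega = par[1], alpha = par[2];
  const double omega = std::exp(lomega);
  const int n = x.size();
  double gxi = 0.0, gw = 0.0, ga = 0.0;
  for (int i = 0; i < n; ++i) {
    const double z = (x[i] - xi) / omega;
    const double t = alpha * z;
    // inverse Mills ratio phi(t)/Phi(t), stable in the left tail
    const double zeta = std::exp(R::dnorm(t, 0.0, 1.0, 1) -
                                 R::pnorm(t, 0.0, 1.0, 1, 1));
    gxi += -z + alpha * zeta;
    gw += -z * z + alpha * z * zeta;
    ga += -z * zeta;
  }
  return NumericVector::create(gxi / omega, n + gw, ga);
}
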