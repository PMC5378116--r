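// Fast evaluation of the segregating-sites log-PMF for one sampling state
// across a vector of loci. Mirrors the log-space signed-mixture assembly of
// the R reference kernel, but rewrites every factor of the form
//   e^{lambda*tau} * P[Pois(beta*tau) <= s]
// as e^{-theta*tau} * sum_{l<=s} (beta*tau)^l / l!, whose logarithm is a
// sum of moderate-magnitude terms: the naive form cancels two huge
// exponents when a population size approaches zero (beta ~ 1/a), and the
// rounding noise of that cancellation is large enough to mislead the
// optimiser.

#include <Rcpp.h>
#include <Rmath.h>
using namespace Rcpp;

// log( sum_{l<=s} x^l / l! )  (the Poisson CDF without its e^-x factor)
static double log_pois_sum(int s, double x) {
  if (x <= 0.0 || s == 0) return 0.0;
  if (x <= 500.0 && s <= 400) {
    // direct series; bounded by e^500, no overflow
    double term = 1.0, sum = 1.0;
    for (int l = 1; l <= s; ++l) {
      term *= x / l;
      sum += term;
    }
    return std::log(sum);
  }
  double sd = std::sqrt(x);
  if (s < x - 12.0 * sd) {
    // terms increase up to l = s: sum downward from the dominant term
    double corr = 1.0, term = 1.0;
    for (int l = s; l >= 1; --l) {
      term *= l / x;
      corr += term;
      if (term < corr * 1e-17) break;
    }
    return s * std::log(x) - R::lgammafn(s + 1.0) + std::log(corr);
  }
  // bulk or upper tail: the CDF is not tiny, so its log is moderate and
  // x + log CDF involves no large cancellation
  return x + R::ppois(s, x, 1, 1);
}

// log( sum_{l>s} x^l / l! ), valid when s sits above the bulk (x/(s+2) < 1)
static double log_pois_sum_upper(int s, double x) {
  if (x <= 0.0) return R_NegInf;
  double term = 1.0, sum = 1.0;
  for (int l = s + 2; l < s + 100000; ++l) {
    term *= x / l;
    sum += term;
    if (term < sum * 1e-17) break;
  }
  return (s + 1) * std::log(x) - R::lgammafn(s + 2.0) + std::log(sum);
}

// log of the upper Poisson tail, log P[Pois(x) > s]
static inline double log_pois_sf(int s, double x) {
  if (x <= 0.0) return R_NegInf;
  if (x > 500.0 || s > 300) return R::ppois(s, x, 0, 1);
  double lterm = (s + 1) * std::log(x) - R::lgammafn(s + 2.0);
  double term = std::exp(lterm), sum = term;
  if (sum == 0.0) return R::ppois(s, x, 0, 1);
  for (int l = s + 2; l < s + 2000; ++l) {
    term *= x / l;
    sum += term;
    if (term < sum * 1e-17) break;
  }
  return -x + std::log(sum);
}

// log(exp(la) - exp(lb)) for la >= lb
static inline double log_diff_exp(double la, double lb) {
  if (!(la > lb)) return R_NegInf;
  if (lb == R_NegInf) return la;
  return la + log1p(-std::exp(lb - la));
}

// [[Rcpp::export(name = ".segsites_logpmf_cpp")]]
NumericVector segsites_logpmf_cpp(IntegerVector s, NumericVector theta,
                                  NumericVector Ai, NumericVector lam,
                                  double ci, double a,
                                  double tau1, double tau0,
                                  double smig_delta, double log_siso) {
  const int n = s.size();
  const double delta = tau0 - tau1;
  const bool has_iso = R_finite(ci) && tau1 > 0.0;
  const bool has_mig = delta > 0.0;
  const bool has_anc = smig_delta > 0.0;
  const double log_smig = has_anc ? std::log(smig_delta) : R_NegInf;

  NumericVector out(n);
  double logs[5], sgns[5];

  for (int k = 0; k < n; ++k) {
    const int sk = s[k];
    const double th = theta[k];
    int nt = 0;

    if (has_iso) {
      double x = ci * th;
      logs[nt] = sk * std::log(x / (1.0 + x)) - log1p(x) +
        log_pois_sf(sk, (1.0 / ci + th) * tau1);
      sgns[nt++] = 1.0;
    }
    if (has_mig) {
      for (int j = 0; j < 3; ++j) {
        const double A = Ai[j];
        if (A == 0.0) continue;
        const double l = lam[j];
        const double beta = l + th;
        // e^{l*tau1} * [CDF(s; beta*tau1) - CDF(s; beta*tau0)] expressed
        // through e^{-theta*tau} factors (all exponents moderate). Deep in
        // the upper tail both CDFs are ~1 and their difference cancels, so
        // the complement (survival) difference is used there instead.
        const double x0 = beta * tau0, x1 = beta * tau1;
        double ld;
        if ((double) sk > x0) {
          double up0 = -th * tau0 - l * delta + log_pois_sum_upper(sk, x0);
          double up1 = (tau1 > 0.0)
            ? -th * tau1 + log_pois_sum_upper(sk, x1) : R_NegInf;
          ld = log_diff_exp(up0, up1);
        } else {
          double t1term = (tau1 > 0.0)
            ? -th * tau1 + log_pois_sum(sk, x1) : 0.0;
          double t0term = -th * tau0 - l * delta + log_pois_sum(sk, x0);
          ld = log_diff_exp(t1term, t0term);
        }
        logs[nt] = std::log(std::fabs(A)) + log_siso + std::log(l) -
          std::log(beta) + sk * std::log(th / beta) + ld;
        sgns[nt++] = (A > 0.0) ? 1.0 : -1.0;
      }
    }
    if (has_anc) {
      double x = a * th;
      logs[nt] = log_siso + log_smig +
        sk * std::log(x / (1.0 + x)) - log1p(x) -
        th * tau0 + log_pois_sum(sk, (1.0 / a + th) * tau0);
      sgns[nt++] = 1.0;
    }

    double m = R_NegInf;
    for (int t = 0; t < nt; ++t) if (logs[t] > m) m = logs[t];
    if (m == R_NegInf) { out[k] = R_NegInf; continue; }
    double r = 0.0, gross = 0.0;
    for (int t = 0; t < nt; ++t) {
      double e = std::exp(logs[t] - m);
      r += sgns[t] * e;
      gross += e;
    }
    if (r < 0.0) {
      double tol = 1e-12 * std::max(gross, 1.0);
      if (r < -tol)
        stop("catastrophic cancellation in segregating-sites PMF");
      r = 0.0;
    }
    double v = m + std::log(r);
    if (v > 0.0) {
      if (v > 1e-6)
        stop("precision loss in segregating-sites PMF (log-probability > 0)");
      v = 0.0;
    }
    out[k] = v;
  }
  return out;
}
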