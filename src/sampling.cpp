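#include <Rcpp.h>
using namespace Rcpp;

// Multivariate hypergeometric sample: draw k items without replacement from
// a pool with per-category counts `pool`, by chained univariate
// hypergeometric draws. Uses R's RNG, so results are reproducible under
// set.seed(). Caller guarantees sum(pool) and k fit in the integer range
// accepted by rhyper.
// [[Rcpp::export(name = ".mvhyper_cpp")]]
NumericVector mvhyper_cpp(NumericVector pool, double k) {
  int n = pool.size();
  NumericVector out(n);
  double remaining = 0.0;
  for (int i = 0; i < n; ++i) remaining += pool[i];
  double k_rem = k > remaining ? remaining : k;
  for (int i = 0; i < n && k_rem > 0; ++i) {
    remaining -= pool[i];
    double x;
    if (remaining <= 0) {
      x = k_rem;
    } else {
      x = ::Rf_rhyper(pool[i], remaining, k_rem);
    }
    out[i] = x;
    k_rem -= x;
  }
  return out;
}

// One PCR cycle for a vector of molecule/fragment counts: each copy is
// duplicated with its category's probability, i.e. x += Binomial(x, rate).
// [[Rcpp::export(name = ".pcr_cycle_cpp")]]
NumericVector pcr_cycle_cpp(NumericVector counts, NumericVector rate) {
  int n = counts.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = counts[i];
    if (x <= 0) { out[i] = 0; continue; }
    double r = rate[i];
    if (x > 1073741824.0) { // 2^30: normal approximation of the binomial
      double m = x * r;
      double add = ::Rf_fround(::Rf_rnorm(m, std::sqrt(m * (1.0 - r))), 0);
      if (add < 0) add = 0;
      out[i] = x + add;
    } else {
      out[i] = x + ::Rf_rbinom(x, r);
    }
  }
  return out;
}

// Beta-Poisson log-likelihood for one gene: sum over unique counts y (with
// multiplicities w) of the closed-form marginal pmf at effective synthesis
// rate se = s * f,
//   P(y) = se^y/y! * B(kon+y, koff)/B(kon, koff) * e^{-se}
//          * 1F1(koff; kon+koff+y; se),
// the confluent hypergeometric series summed in log space.
// [[Rcpp::export(name = ".betapois_loglik_cpp")]]
double betapois_loglik_cpp(NumericVector y, NumericVector w,
                           double kon, double koff, double se) {
  int n = y.size();
  double a = kon + koff;
  int k_max = (int)std::ceil(se + 10.0 * std::sqrt(se) + 30.0);
  // shared series coefficients: log (koff)_k + k log(se) - log k!
  std::vector<double> lk(k_max);
  double acc = 0.0, lse = std::log(se);
  for (int k = 1; k <= k_max; ++k) {
    acc += std::log(koff + k - 1.0) + lse - std::log((double)k);
    lk[k - 1] = acc;
  }
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double yy = y[i];
    double lg_ay = ::Rf_lgammafn(a + yy);
    // logsumexp over k of lk[k] - (lgamma(a+y+k) - lgamma(a+y)), plus the
    // k = 0 term (= 0); running pochhammer avoids lgamma in the loop
    double m = 0.0, ssum = 1.0, lpoch = 0.0;
    for (int k = 1; k <= k_max; ++k) {
      lpoch += std::log(a + yy + k - 1.0);
      double lt = lk[k - 1] - lpoch;
      if (lt > m) { ssum = ssum * std::exp(m - lt) + 1.0; m = lt; }
      else ssum += std::exp(lt - m);
      if (lt < m - 40.0 && k > (int)se) break;  // tail is negligible
    }
    double l1f1 = m + std::log(ssum);
    double lpmf = yy * lse - ::Rf_lgammafn(yy + 1.0) +
      ::Rf_lgammafn(kon + yy) - ::Rf_lgammafn(kon) +
      ::Rf_lgammafn(a) - lg_ay - se + l1f1;
    total += w[i] * lpmf;
  }
  return total;
}
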