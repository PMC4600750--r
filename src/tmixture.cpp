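#include <Rcpp.h>
using namespace Rcpp;

// Q-function for degrees of freedom given E-step sufficient statistics from
// the latent-Gamma representation of the t distribution
static inline double df_qfun(double nu, double tau_sum, double s_elog, double s_e) {
  return tau_sum * (nu / 2.0 * std::log(nu / 2.0) - R::lgammafn(nu / 2.0)) +
         nu / 2.0 * (s_elog - s_e);
}

// golden-section maximisation of df_qfun on [lo, hi]
static double df_maximise(double tau_sum, double s_elog, double s_e,
                          double lo, double hi) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = df_qfun(c, tau_sum, s_elog, s_e);
  double fd = df_qfun(d, tau_sum, s_elog, s_e);
  for (int i = 0; i < 40 && (b - a) > 1e-2; ++i) {
    if (fc > fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = df_qfun(c, tau_sum, s_elog, s_e);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = df_qfun(d, tau_sum, s_elog, s_e);
    }
  }
  return (a + b) / 2.0;
}

// (MAP-)EM for the three-component location-scale Student's-t mixture from
// one fixed starting point; mirrors the reference R implementation.  With
// shared_dispersion all components share one scale and one df; alpha is a
// Dirichlet prior on the weights (all ones = maximum likelihood).  The
// reported trace is the EM objective: observed-data log-likelihood plus the
// log weight prior.
// [[Rcpp::export(name = ".tmix_em_cpp")]]
List tmix_em_cpp(NumericVector y, NumericVector weight0, NumericVector loc0,
                 NumericVector scale0, NumericVector df0, NumericVector alpha,
                 bool shared_dispersion, int max_iter, double tol,
                 double df_lo, double df_hi, double scale_floor) {
  const int n = y.size(), K = 3;
  std::vector<double> w(weight0.begin(), weight0.end());
  std::vector<double> loc(loc0.begin(), loc0.end());
  std::vector<double> scale(scale0.begin(), scale0.end());
  std::vector<double> df(df0.begin(), df0.end());

  std::vector<double> tau(n * K), u(n * K), elog(n * K);
  std::vector<double> obj_trace;
  obj_trace.reserve(64);
  double obj_old = R_NegInf, ll = R_NegInf;
  bool converged = false;
  int it = 0;

  while (it < max_iter) {
    ++it;
    // E-step; per-component constants hoisted out of the data loop
    double cst[3], lw[3], dgam[3];
    for (int k = 0; k < K; ++k) {
      cst[k] = R::lgammafn((df[k] + 1.0) / 2.0) - R::lgammafn(df[k] / 2.0) -
               0.5 * std::log(M_PI * df[k]) - std::log(scale[k]);
      lw[k] = (w[k] > 0.0) ? std::log(w[k]) : R_NegInf;
      dgam[k] = R::digamma((df[k] + 1.0) / 2.0);
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double lj[3], mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double z2 = (y[i] - loc[k]) / scale[k];
        z2 *= z2;
        double l_z = std::log1p(z2 / df[k]);
        lj[k] = lw[k] + cst[k] - (df[k] + 1.0) / 2.0 * l_z;
        if (lj[k] > mx) mx = lj[k];
        u[i * K + k] = (df[k] + 1.0) / (df[k] + z2);
        elog[i * K + k] = dgam[k] - std::log(df[k] / 2.0) - l_z;
      }
      double den = 0.0;
      for (int k = 0; k < K; ++k) den += std::exp(lj[k] - mx);
      ll += mx + std::log(den);
      for (int k = 0; k < K; ++k) tau[i * K + k] = std::exp(lj[k] - mx) / den;
    }
    double lprior = 0.0;
    for (int k = 0; k < K; ++k)
      if (alpha[k] != 1.0 && w[k] > 0.0) lprior += (alpha[k] - 1.0) * std::log(w[k]);
    double obj = ll + lprior;
    obj_trace.push_back(obj);
    if (R_FINITE(obj_old) && std::fabs(obj - obj_old) <= tol * (std::fabs(obj_old) + 1e-12)) {
      converged = true;
      break;
    }
    obj_old = obj;

    // M-step
    double tsum[3];
    for (int k = 0; k < K; ++k) {
      double ts = 0.0, tu_sum = 0.0, tuy = 0.0;
      for (int i = 0; i < n; ++i) {
        double t = tau[i * K + k], uu = u[i * K + k];
        ts += t; tu_sum += t * uu; tuy += t * uu * y[i];
      }
      tsum[k] = ts;
      if (tu_sum > 1e-12) loc[k] = tuy / tu_sum;
    }
    if (shared_dispersion) {
      double ss = 0.0, s_elog = 0.0, s_e = 0.0;
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < n; ++i) {
          double d = y[i] - loc[k];
          double t = tau[i * K + k];
          ss += t * u[i * K + k] * d * d;
          s_elog += t * elog[i * K + k];
          s_e += t * u[i * K + k];
        }
      double sc = std::max(std::sqrt(ss / n), scale_floor);
      double nu = df_maximise((double)n, s_elog, s_e, df_lo, df_hi);
      for (int k = 0; k < K; ++k) { scale[k] = sc; df[k] = nu; }
    } else {
      for (int k = 0; k < K; ++k) {
        if (tsum[k] < 1e-10) continue;
        double ss = 0.0, s_elog = 0.0, s_e = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = y[i] - loc[k];
          double t = tau[i * K + k];
          ss += t * u[i * K + k] * d * d;
          s_elog += t * elog[i * K + k];
          s_e += t * u[i * K + k];
        }
        scale[k] = std::max(std::sqrt(ss / tsum[k]), scale_floor);
        df[k] = df_maximise(tsum[k], s_elog, s_e, df_lo, df_hi);
      }
    }
    double wsum = 0.0;
    for (int k = 0; k < K; ++k) {
      w[k] = tsum[k] + alpha[k] - 1.0;
      if (w[k] < 0.0) w[k] = 0.0;
      wsum += w[k];
    }
    for (int k = 0; k < K; ++k) w[k] /= wsum;
  }

  return List::create(
    _["weight"] = NumericVector(w.begin(), w.end()),
    _["loc"] = NumericVector(loc.begin(), loc.end()),
    _["scale"] = NumericVector(scale.begin(), scale.end()),
    _["df"] = NumericVector(df.begin(), df.end()),
    _["loglik"] = ll,
    _["objective_trace"] = NumericVector(obj_trace.begin(), obj_trace.end()),
    _["n_iter"] = it,
    _["converged"] = converged);
}
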