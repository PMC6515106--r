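#include <Rcpp.h>
using namespace Rcpp;

// Disallowed transitions/states use a large negative constant rather than
// -Inf so sums stay well-defined doubles.
static const double LOG_ZERO = -1e30;
static const double LOGDENS_FLOOR = -1e10;

// Per-state diagonal-Gaussian-mixture log densities.
// X: T x D, means/vars: Ctot x D stacked components, logw: Ctot,
// offsets: S+1 (0-based component ranges per state). Returns S x T.
// [[Rcpp::export]]
NumericMatrix gmm_logdens_cpp(NumericMatrix X, NumericMatrix means,
                              NumericMatrix vars, NumericVector logw,
                              IntegerVector offsets) {
  const int T = X.nrow(), D = X.ncol(), S = offsets.size() - 1;
  NumericMatrix out(S, T);
  const double l2pi = std::log(2.0 * M_PI);
  // per-component normalization constants
  const int C = means.nrow();
  std::vector<double> cnorm(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int d = 0; d < D; ++d) s += std::log(vars(c, d));
    cnorm[c] = logw[c] - 0.5 * (D * l2pi + s);
  }
  for (int t = 0; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf, acc = 0.0;
      const int c0 = offsets[s], c1 = offsets[s + 1];
      if (c1 - c0 == 1) {
        double q = 0.0;
        for (int d = 0; d < D; ++d) {
          const double z = X(t, d) - means(c0, d);
          q += z * z / vars(c0, d);
        }
        acc = cnorm[c0] - 0.5 * q;
      } else {
        // log-sum-exp over components
        std::vector<double> vals(c1 - c0);
        for (int c = c0; c < c1; ++c) {
          double q = 0.0;
          for (int d = 0; d < D; ++d) {
            const double z = X(t, d) - means(c, d);
            q += z * z / vars(c, d);
          }
          vals[c - c0] = cnorm[c] - 0.5 * q;
          if (vals[c - c0] > best) best = vals[c - c0];
        }
        double se = 0.0;
        for (double v : vals) se += std::exp(v - best);
        acc = best + std::log(se);
      }
      out(s, t) = std::max(acc, LOGDENS_FLOOR);
    }
  }
  return out;
}

// Sparse-transition Viterbi. logobs: S x T (already masked for label/task
// constraints), loginit: S, preds: list of 0-based predecessor vectors per
// state, logtrans: matching log transition probabilities. Ties go to the
// lowest state index (strict > comparisons, ascending scan order).
// [[Rcpp::export]]
List viterbi_cpp(NumericMatrix logobs, NumericVector loginit, List preds,
                 List logtrans) {
  const int S = logobs.nrow(), T = logobs.ncol();
  if (T == 0) return List::create(_["path"] = IntegerVector(0),
                                  _["logp"] = R_NegInf);
  NumericMatrix delta(S, T);
  IntegerMatrix psi(S, T);
  for (int s = 0; s < S; ++s) {
    double v = loginit[s] + logobs(s, 0);
    delta(s, 0) = (v < LOG_ZERO) ? LOG_ZERO : v;
    psi(s, 0) = -1;
  }
  std::vector<IntegerVector> pv(S);
  std::vector<NumericVector> tv(S);
  for (int s = 0; s < S; ++s) {
    pv[s] = as<IntegerVector>(preds[s]);
    tv[s] = as<NumericVector>(logtrans[s]);
  }
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = -std::numeric_limits<double>::infinity();
      int arg = 0;
      const IntegerVector &p = pv[s];
      const NumericVector &w = tv[s];
      for (int k = 0; k < p.size(); ++k) {
        const double v = delta(p[k], t - 1) + w[k];
        if (v > best) { best = v; arg = p[k]; }
      }
      double v = best + logobs(s, t);
      delta(s, t) = (v < LOG_ZERO) ? LOG_ZERO : v;
      psi(s, t) = arg;
    }
  }
  int last = 0;
  double best = delta(0, T - 1);
  for (int s = 1; s < S; ++s) {
    if (delta(s, T - 1) > best) { best = delta(s, T - 1); last = s; }
  }
  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  return List::create(_["path"] = path, _["logp"] = best);
}
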