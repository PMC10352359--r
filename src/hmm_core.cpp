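#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward over a concatenation of independent segments.
// logb: n x K matrix of (expected) log emission densities.
// seg_start/seg_end: 0-based half-open row ranges, one per segment; the chain
// restarts from the initial distribution at every segment start.
// Returns posteriors gamma (n x K), summed expected transition counts xi
// (K x K), summed first-row posteriors (K), and the total log normalizer.
// [[Rcpp::export]]
List fb_core(const NumericMatrix& logb,
             const IntegerVector& seg_start,
             const IntegerVector& seg_end,
             const NumericVector& log_init,
             const NumericMatrix& log_trans) {
  const int n = logb.nrow(), K = logb.ncol(), S = seg_start.size();
  NumericMatrix gamma(n, K);
  NumericMatrix xi(K, K);
  NumericVector init_counts(K);
  double loglik = 0.0;

  std::vector<double> init(K), trans(K * K);
  for (int k = 0; k < K; ++k) init[k] = std::exp(log_init[k]);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) trans[j * K + k] = std::exp(log_trans(j, k));

  std::vector<double> b;        // scaled emission probs for current segment
  std::vector<double> alpha;    // scaled forward variables
  std::vector<double> cvec;     // per-row normalizers
  std::vector<double> beta_next(K), beta_cur(K), tmp(K);
  const double* lb = &logb(0, 0);            // column-major, stride n
  double* gm = &gamma(0, 0);
  double* xp = &xi(0, 0);

  for (int s = 0; s < S; ++s) {
    const int t0 = seg_start[s], t1 = seg_end[s];
    const int T = t1 - t0;
    if (T <= 0) stop("empty segment in forward-backward");
    b.assign((size_t)T * K, 0.0);
    alpha.assign((size_t)T * K, 0.0);
    cvec.assign(T, 0.0);

    // emission probs scaled by rowwise max to avoid underflow
    for (int t = 0; t < T; ++t) {
      double m = lb[t0 + t];
      for (int k = 1; k < K; ++k) m = std::max(m, lb[(size_t)k * n + t0 + t]);
      for (int k = 0; k < K; ++k)
        b[(size_t)t * K + k] = std::exp(lb[(size_t)k * n + t0 + t] - m);
      cvec[t] = m;   // temporarily store the max; folded into loglik below
    }

    // forward pass with per-row normalization
    double c;
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = init[k] * b[k];
      alpha[k] = v;
      c += v;
    }
    if (!(c > 0.0) || !std::isfinite(c)) stop("numerical failure in forward pass (t = 1)");
    for (int k = 0; k < K; ++k) alpha[k] /= c;
    loglik += std::log(c) + cvec[0];

    for (int t = 1; t < T; ++t) {
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j)
          acc += alpha[(size_t)(t - 1) * K + j] * trans[j * K + k];
        double v = acc * b[(size_t)t * K + k];
        alpha[(size_t)t * K + k] = v;
        c += v;
      }
      if (!(c > 0.0) || !std::isfinite(c))
        stop("numerical failure in forward pass (t = %d)", t + 1);
      for (int k = 0; k < K; ++k) alpha[(size_t)t * K + k] /= c;
      loglik += std::log(c) + cvec[t];
      cvec[t] = c;   // keep scaled normalizer for the backward pass
    }

    // backward pass; gamma and xi accumulation
    for (int k = 0; k < K; ++k) beta_next[k] = 1.0;
    for (int k = 0; k < K; ++k)
      gm[(size_t)k * n + t1 - 1] = alpha[(size_t)(T - 1) * K + k];
    for (int t = T - 2; t >= 0; --t) {
      const double cn = cvec[t + 1];
      for (int k = 0; k < K; ++k)
        tmp[k] = b[(size_t)(t + 1) * K + k] * beta_next[k] / cn;
      double gsum = 0.0;
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        const double aj = alpha[(size_t)t * K + j];
        const double* trj = &trans[(size_t)j * K];
        double* xij = &xp[j];   // xi row j, stride K in column-major K x K
        for (int k = 0; k < K; ++k) {
          const double w = trj[k] * tmp[k];
          xij[(size_t)k * K] += aj * w;
          acc += w;
        }
        beta_cur[j] = acc;
        gm[(size_t)j * n + t0 + t] = aj * acc;
        gsum += aj * acc;
      }
      // guard tiny drift; gamma rows are renormalized exactly
      if (gsum > 0.0)
        for (int j = 0; j < K; ++j) gm[(size_t)j * n + t0 + t] /= gsum;
      std::swap(beta_next, beta_cur);
    }
    for (int k = 0; k < K; ++k) init_counts[k] += gm[(size_t)k * n + t0];
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["init_counts"] = init_counts, _["loglik"] = loglik);
}

// Viterbi decoding per segment (log space). Returns 1-based state labels and
// the summed log probability of the returned joint path(s).
// [[Rcpp::export]]
List viterbi_core(const NumericMatrix& logb,
                  const IntegerVector& seg_start,
                  const IntegerVector& seg_end,
                  const NumericVector& log_init,
                  const NumericMatrix& log_trans) {
  const int n = logb.nrow(), K = logb.ncol(), S = seg_start.size();
  IntegerVector path(n);
  double logp_total = 0.0;

  for (int s = 0; s < S; ++s) {
    const int t0 = seg_start[s], t1 = seg_end[s];
    const int T = t1 - t0;
    std::vector<double> delta_prev(K), delta_cur(K);
    std::vector<int> back((size_t)T * K, 0);

    for (int k = 0; k < K; ++k) delta_prev[k] = log_init[k] + logb(t0, k);
    for (int t = 1; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta_prev[0] + log_trans(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          const double v = delta_prev[j] + log_trans(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta_cur[k] = best + logb(t0 + t, k);
        back[(size_t)t * K + k] = arg;
      }
      std::swap(delta_prev, delta_cur);
    }
    int arg = 0;
    double best = delta_prev[0];
    for (int k = 1; k < K; ++k)
      if (delta_prev[k] > best) { best = delta_prev[k]; arg = k; }
    logp_total += best;
    path[t1 - 1] = arg + 1;
    for (int t = T - 1; t >= 1; --t) {
      arg = back[(size_t)t * K + arg];
      path[t0 + t - 1] = arg + 1;
    }
  }
  return List::create(_["path"] = path, _["logp"] = logp_total);
}
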