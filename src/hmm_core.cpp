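#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward for a sticky HMM: from state j the chain stays with
// probability `e` and otherwise redraws a state from the prior `prior`
// (so trans(j,k) = e*1[j==k] + (1-e)*prior[k]; rows sum to 1). The prior
// also serves as the initial distribution; a prior concentrated near the
// diploid state breaks the exact aliasing between (state, tumour-fraction)
// combinations that produce identical emission means. Emissions arrive as a
// B x K matrix of log densities; `starts` flags the first observation of
// each independent chain (one per chromosome). Returns the total
// log-likelihood and the per-observation posterior state probabilities.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logE, LogicalVector starts, double e,
            NumericVector prior) {
  const int B = logE.nrow(), K = logE.ncol();
  NumericMatrix alpha(B, K), beta(B, K), gamma(B, K);
  NumericVector scale(B);
  double loglik = 0.0;

  // emission densities, shifted per row for stability
  NumericMatrix dens(B, K);
  NumericVector shift(B);
  for (int b = 0; b < B; ++b) {
    double m = logE(b, 0);
    for (int k = 1; k < K; ++k) if (logE(b, k) > m) m = logE(b, k);
    shift[b] = m;
    for (int k = 0; k < K; ++k) dens(b, k) = std::exp(logE(b, k) - m);
  }

  for (int b = 0; b < B; ++b) {
    double s = 0.0;
    if (starts[b]) {
      for (int k = 0; k < K; ++k) { alpha(b, k) = prior[k] * dens(b, k); s += alpha(b, k); }
    } else {
      for (int k = 0; k < K; ++k) {
        // rows of alpha sum to 1, so the redraw mass is just (1-e)*prior
        double pred = e * alpha(b - 1, k) + (1.0 - e) * prior[k];
        alpha(b, k) = pred * dens(b, k);
        s += alpha(b, k);
      }
    }
    scale[b] = s;
    loglik += std::log(s) + shift[b];
    for (int k = 0; k < K; ++k) alpha(b, k) /= s;
  }

  for (int b = B - 1; b >= 0; --b) {
    if (b == B - 1 || starts[b + 1]) {
      for (int k = 0; k < K; ++k) beta(b, k) = 1.0;
    } else {
      double S = 0.0;
      double v[64];
      for (int k = 0; k < K; ++k) { v[k] = dens(b + 1, k) * beta(b + 1, k); S += prior[k] * v[k]; }
      for (int k = 0; k < K; ++k)
        beta(b, k) = ((1.0 - e) * S + e * v[k]) / scale[b + 1];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(b, k) = alpha(b, k) * beta(b, k); s += gamma(b, k); }
    for (int k = 0; k < K; ++k) gamma(b, k) /= s;
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma);
}

// Viterbi MAP state path under the same sticky transition structure.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logE, LogicalVector starts, double e,
                          NumericVector prior) {
  const int B = logE.nrow(), K = logE.ncol();
  NumericMatrix delta(B, K);
  IntegerMatrix psi(B, K);
  IntegerVector path(B);

  for (int b = 0; b < B; ++b) {
    if (starts[b]) {
      for (int k = 0; k < K; ++k) { delta(b, k) = std::log(prior[k]) + logE(b, k); psi(b, k) = -1; }
    } else {
      for (int k = 0; k < K; ++k) {
        const double lstay = std::log(e + (1.0 - e) * prior[k]);
        const double lswitch = std::log((1.0 - e) * prior[k]);
        double best = R_NegInf; int arg = 0;
        for (int j = 0; j < K; ++j) {
          double v = delta(b - 1, j) + (j == k ? lstay : lswitch);
          if (v > best + 1e-12) { best = v; arg = j; }
        }
        delta(b, k) = best + logE(b, k);
        psi(b, k) = arg;
      }
    }
  }
  // backtrack chain by chain
  int b = B - 1;
  while (b >= 0) {
    int end = b;
    double best = R_NegInf; int arg = 0;
    for (int k = 0; k < K; ++k)
      if (delta(end, k) > best + 1e-12) { best = delta(end, k); arg = k; }
    path[end] = arg;
    int bb = end;
    while (!starts[bb]) { path[bb - 1] = psi(bb, path[bb]); --bb; }
    b = bb - 1;
  }
  return path;  // 0-based state indices
}
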