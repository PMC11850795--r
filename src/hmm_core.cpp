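#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step over concatenated sequences.
// logdens: T_total x K matrix of per-observation emission log-densities.
// starts: 0-based start index of each sequence; lengths: its length.
// Returns total log-likelihood, posterior state probabilities (gamma),
// summed expected transition counts (xi_sum) and summed first-step gamma.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericMatrix logdens, IntegerVector starts,
                   IntegerVector lengths, NumericMatrix A, NumericVector pi) {
  const int K = logdens.ncol();
  const int S = starts.size();
  NumericMatrix gamma(logdens.nrow(), K);
  NumericMatrix xi_sum(K, K);
  NumericVector pi_sum(K);
  double loglik = 0.0;

  for (int s = 0; s < S; ++s) {
    const int off = starts[s];
    const int T = lengths[s];
    NumericMatrix alpha(T, K), beta(T, K), b(T, K);
    NumericVector c(T);

    for (int t = 0; t < T; ++t) {
      double m = logdens(off + t, 0);
      for (int k = 1; k < K; ++k) m = std::max(m, logdens(off + t, k));
      for (int k = 0; k < K; ++k) b(t, k) = std::exp(logdens(off + t, k) - m);
      c[t] = m;  // reuse c to stash the max temporarily
    }
    NumericVector logb_max = clone(c);

    // forward with per-step normalisation
    double norm = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * b(0, k); norm += alpha(0, k); }
    if (norm <= 0) stop("forward pass underflow at t = 0");
    for (int k = 0; k < K; ++k) alpha(0, k) /= norm;
    c[0] = norm;
    for (int t = 1; t < T; ++t) {
      norm = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * A(j, k);
        alpha(t, k) = acc * b(t, k);
        norm += alpha(t, k);
      }
      if (norm <= 0) stop("forward pass underflow");
      for (int k = 0; k < K; ++k) alpha(t, k) /= norm;
      c[t] = norm;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + logb_max[t];

    // backward, same scaling constants
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) acc += A(k, j) * b(t + 1, j) * beta(t + 1, j);
        beta(t, k) = acc / c[t + 1];
      }
    }

    for (int t = 0; t < T; ++t) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        gamma(off + t, k) = alpha(t, k) * beta(t, k);
        tot += gamma(off + t, k);
      }
      for (int k = 0; k < K; ++k) gamma(off + t, k) /= tot;
    }
    for (int k = 0; k < K; ++k) pi_sum[k] += gamma(off, k);
    for (int t = 0; t < T - 1; ++t) {
      for (int j = 0; j < K; ++j) {
        for (int k = 0; k < K; ++k) {
          xi_sum(j, k) += alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k) / c[t + 1];
        }
      }
    }
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum, _["pi_sum"] = pi_sum);
}

// Log-space Viterbi for one sequence; ties go to the lowest state index.
// Returns the 1-based most probable state path and its joint log probability.
// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericMatrix logdens, NumericMatrix A, NumericVector pi) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG_INF = -std::numeric_limits<double>::infinity();

  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi[k] > 0 ? std::log(pi[k]) : NEG_INF) + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = NEG_INF; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double lA = A(j, k) > 0 ? std::log(A(j, k)) : NEG_INF;
        double v = delta(t - 1, j) + lA;
        if (v > best) { best = v; arg = j; }  // strict >: lowest index wins ties
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = NEG_INF; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return List::create(_["path"] = path, _["logprob"] = best);
}
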