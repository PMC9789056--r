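#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for microbial source tracking with an Unknown
// component. Each of the N sink reads carries a latent source assignment
// z_i in {1..S, Unknown}. Known-source taxon distributions are fixed at
// their smoothed empirical frequencies,
//   phi_s(t) = (y_st + alpha1) / (Y_s + alpha1 * T),
// while the Unknown source's distribution is learned from the reads
// currently assigned to it,
//   phi_U(t) = (u_t^-i + alpha2 * N) / (U^-i + alpha2 * N * T).
// The mixing proportions are collapsed out, leaving the env-count prior
// beta in the conditional
//   P(z_i = v | .) propto phi_v(t_i) * (n_v^-i + beta).
// Uses R's RNG so results are reproducible under set.seed().
//
// sink_counts:  taxon counts of the sink (length T)
// source_counts: S x T matrix of known-source taxon counts
// returns: ndraws x (S + 1) matrix of mixing-proportion draws
//          (last column = Unknown), recorded every `delay` sweeps
//          after `burnin` sweeps.
// [[Rcpp::export(name = ".gibbs_chain")]]
NumericMatrix gibbs_chain(IntegerVector sink_counts,
                         IntegerMatrix source_counts,
                         double alpha1, double alpha2, double beta,
                         int burnin, int ndraws, int delay) {
  const int T = sink_counts.size();
  const int S = source_counts.nrow();
  const int V = S + 1;
  if (source_counts.ncol() != T)
    stop("source matrix and sink vector disagree on taxon count");

  long N = 0;
  for (int t = 0; t < T; ++t) {
    if (sink_counts[t] < 0) stop("negative sink count");
    N += sink_counts[t];
  }
  if (N == 0) stop("zero-depth sink");

  // expand sink into reads
  std::vector<int> read_taxon((size_t)N);
  {
    size_t k = 0;
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < sink_counts[t]; ++c) read_taxon[k++] = t;
  }

  // fixed smoothed taxon probabilities for known sources
  std::vector<double> phi((size_t)S * T);
  for (int s = 0; s < S; ++s) {
    double tot = 0;
    for (int t = 0; t < T; ++t) {
      if (source_counts(s, t) < 0) stop("negative source count");
      tot += source_counts(s, t);
    }
    const double denom = tot + alpha1 * T;
    for (int t = 0; t < T; ++t)
      phi[(size_t)s * T + t] = (source_counts(s, t) + alpha1) / denom;
  }

  const double a2n = alpha2 * (double)N;
  const double a2nT = a2n * T;

  std::vector<int> z((size_t)N);
  std::vector<double> env(V, 0.0);     // reads per env
  std::vector<double> u(T, 0.0);       // unknown-assigned reads per taxon
  double U = 0.0;

  // random initial assignment
  for (size_t i = 0; i < (size_t)N; ++i) {
    int v = (int)(unif_rand() * V);
    if (v >= V) v = V - 1;
    z[i] = v;
    env[v] += 1.0;
    if (v == S) { u[read_taxon[i]] += 1.0; U += 1.0; }
  }

  NumericMatrix draws(ndraws, V);
  std::vector<double> prob(V);
  const int total_sweeps = burnin + ndraws * delay;
  int recorded = 0;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (size_t i = 0; i < (size_t)N; ++i) {
      const int t = read_taxon[i];
      const int old = z[i];
      env[old] -= 1.0;
      if (old == S) { u[t] -= 1.0; U -= 1.0; }

      double tot = 0.0;
      for (int s = 0; s < S; ++s) {
        prob[s] = phi[(size_t)s * T + t] * (env[s] + beta);
        tot += prob[s];
      }
      prob[S] = ((u[t] + a2n) / (U + a2nT)) * (env[S] + beta);
      tot += prob[S];

      double r = unif_rand() * tot;
      int v = 0;
      double acc = prob[0];
      while (r > acc && v < V - 1) { ++v; acc += prob[v]; }

      z[i] = v;
      env[v] += 1.0;
      if (v == S) { u[t] += 1.0; U += 1.0; }
    }
    if (sweep >= burnin && (sweep - burnin + 1) % delay == 0 && recorded < ndraws) {
      for (int v = 0; v < V; ++v) draws(recorded, v) = env[v] / (double)N;
      ++recorded;
    }
  }
  return draws;
}
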