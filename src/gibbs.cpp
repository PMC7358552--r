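#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for Bayesian microbial source tracking.
//
// Each sink read n (of taxon t_n) carries a latent source assignment
// z_n in {1..V known sources, unknown}. The full conditional is
//   P(z_n = v | .) propto [(m_{t,v} + alpha_v) / (m_{.,v} + alpha_v * T)]
//                       * (n_v^{-n} + beta)
// where for known sources m counts source reads plus currently assigned
// sink reads (prior alpha_known) and for the unknown source only
// currently assigned sink reads (prior alpha_unknown); n_v^{-n} is the
// number of sink reads currently assigned to v excluding read n.
// Retained draws are the assignment fractions at every `delay`-th sweep
// after `burnin`, pooled over restarts. Uses R's RNG.
//
// sink: length-T taxon counts of the sink; sources: T x V count matrix.
// [[Rcpp::export]]
NumericMatrix cpp_source_gibbs(const IntegerVector& sink,
                               const NumericMatrix& sources,
                               double alpha_known, double alpha_unknown,
                               double beta_prior, int restarts, int burnin,
                               int draws_per_restart, int delay) {
  const int T = sink.size();
  const int V = sources.ncol();   // known sources
  const int VU = V + 1;           // + unknown
  std::vector<int> rtax;
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < sink[t]; ++c) rtax.push_back(t);
  const int N = rtax.size();
  std::vector<double> stot(V, 0.0);
  for (int v = 0; v < V; ++v)
    for (int t = 0; t < T; ++t) stot[v] += sources(t, v);

  NumericMatrix draws(restarts * draws_per_restart, VU);
  std::vector<int> z(N);
  std::vector<std::vector<int> > m(VU, std::vector<int>(T));
  std::vector<int> nv(VU);
  std::vector<double> p(VU);
  int drow = 0;
  for (int r = 0; r < restarts; ++r) {
    std::fill(nv.begin(), nv.end(), 0);
    for (int v = 0; v < VU; ++v) std::fill(m[v].begin(), m[v].end(), 0);
    for (int n = 0; n < N; ++n) {
      int v = (int)(unif_rand() * VU);
      if (v >= VU) v = VU - 1;
      z[n] = v; nv[v]++; m[v][rtax[n]]++;
    }
    const int sweeps = burnin + delay * draws_per_restart;
    int taken = 0;
    for (int s = 1; s <= sweeps; ++s) {
      for (int n = 0; n < N; ++n) {
        const int t = rtax[n], v0 = z[n];
        nv[v0]--; m[v0][t]--;
        double tot = 0.0;
        for (int v = 0; v < V; ++v) {
          const double num = sources(t, v) + m[v][t] + alpha_known;
          const double den = stot[v] + nv[v] + alpha_known * T;
          p[v] = num / den * (nv[v] + beta_prior);
          tot += p[v];
        }
        p[V] = (m[V][t] + alpha_unknown) / (nv[V] + alpha_unknown * T) *
               (nv[V] + beta_prior);
        tot += p[V];
        double u = unif_rand() * tot;
        int v = 0;
        double acc = p[0];
        while (u > acc && v < VU - 1) { acc += p[++v]; }
        z[n] = v; nv[v]++; m[v][t]++;
      }
      if (s > burnin && (s - burnin) % delay == 0 &&
          taken < draws_per_restart) {
        for (int v = 0; v < VU; ++v)
          draws(drow, v) = double(nv[v]) / double(N);
        ++drow; ++taken;
      }
    }
  }
  return draws;
}
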