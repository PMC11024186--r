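#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation on a
// document-term count matrix (subjects x taxa). Posterior-mean estimates of
// theta and beta are averaged over the post-burn-in sweeps. The RNG is a
// self-contained mt19937_64 stream so that a given seed reproduces the chain
// bit-for-bit regardless of R's RNG state.

static inline double unif01(std::mt19937_64 &rng) {
  // 53-bit uniform in [0, 1)
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

// joint collapsed log p(w, z | alpha, eta), up to constants shared across sweeps
static double joint_loglik(const std::vector<int> &ndt,
                           const std::vector<int> &ntw,
                           const std::vector<int> &nt,
                           const std::vector<int> &nd,
                           int M, int T, int B, double alpha, double eta) {
  double ll = 0.0;
  for (int d = 0; d < M; ++d) {
    for (int t = 0; t < T; ++t) ll += std::lgamma(ndt[d * T + t] + alpha);
    ll -= std::lgamma(nd[d] + T * alpha);
  }
  for (int t = 0; t < T; ++t) {
    for (int w = 0; w < B; ++w) ll += std::lgamma(ntw[t * B + w] + eta);
    ll -= std::lgamma(nt[t] + B * eta);
  }
  return ll;
}

// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerMatrix counts, int T, double alpha, double eta,
                   int n_iter, int burnin, int seed) {
  const int M = counts.nrow(), B = counts.ncol();
  if (T < 1) stop("T must be >= 1");
  if (n_iter <= burnin) stop("n_iter must exceed burnin");

  // token expansion
  std::vector<int> tok_d, tok_w;
  for (int d = 0; d < M; ++d)
    for (int w = 0; w < B; ++w)
      for (int k = 0; k < counts(d, w); ++k) { tok_d.push_back(d); tok_w.push_back(w); }
  const int N = (int)tok_d.size();
  if (N == 0) stop("count table has no reads");

  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 88172645463325252ULL);

  std::vector<int> z(N), ndt(M * T, 0), ntw(T * B, 0), nt(T, 0), nd(M, 0);
  for (int n = 0; n < N; ++n) {
    int t = (int)(unif01(rng) * T); if (t >= T) t = T - 1;
    z[n] = t;
    ++ndt[tok_d[n] * T + t]; ++ntw[t * B + tok_w[n]]; ++nt[t]; ++nd[tok_d[n]];
  }

  std::vector<double> prob(T), theta_sum(M * T, 0.0), beta_sum(T * B, 0.0);
  std::vector<double> ll_trace;
  ll_trace.reserve(n_iter);
  const double Beta_eta = B * eta, T_alpha = T * alpha;
  int n_samples = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int n = 0; n < N; ++n) {
      const int d = tok_d[n], w = tok_w[n], old = z[n];
      --ndt[d * T + old]; --ntw[old * B + w]; --nt[old];
      double tot = 0.0;
      for (int t = 0; t < T; ++t) {
        prob[t] = (ndt[d * T + t] + alpha) *
                  (ntw[t * B + w] + eta) / (nt[t] + Beta_eta);
        tot += prob[t];
      }
      double u = unif01(rng) * tot, acc = 0.0;
      int t_new = T - 1;
      for (int t = 0; t < T; ++t) { acc += prob[t]; if (u < acc) { t_new = t; break; } }
      z[n] = t_new;
      ++ndt[d * T + t_new]; ++ntw[t_new * B + w]; ++nt[t_new];
    }
    ll_trace.push_back(joint_loglik(ndt, ntw, nt, nd, M, T, B, alpha, eta));
    if (it >= burnin) {
      ++n_samples;
      for (int d = 0; d < M; ++d)
        for (int t = 0; t < T; ++t)
          theta_sum[d * T + t] += (ndt[d * T + t] + alpha) / (nd[d] + T_alpha);
      for (int t = 0; t < T; ++t)
        for (int w = 0; w < B; ++w)
          beta_sum[t * B + w] += (ntw[t * B + w] + eta) / (nt[t] + Beta_eta);
    }
  }

  NumericMatrix theta(M, T), beta(T, B);
  for (int d = 0; d < M; ++d)
    for (int t = 0; t < T; ++t) theta(d, t) = theta_sum[d * T + t] / n_samples;
  for (int t = 0; t < T; ++t) {
    double rs = 0.0;
    for (int w = 0; w < B; ++w) { beta(t, w) = beta_sum[t * B + w] / n_samples; rs += beta(t, w); }
    for (int w = 0; w < B; ++w) beta(t, w) /= rs; // renormalise fp drift
  }
  // renormalise theta rows as well
  for (int d = 0; d < M; ++d) {
    double rs = 0.0;
    for (int t = 0; t < T; ++t) rs += theta(d, t);
    for (int t = 0; t < T; ++t) theta(d, t) /= rs;
  }

  return List::create(_["theta"] = theta, _["beta"] = beta,
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["n_samples"] = n_samples, _["n_tokens"] = N);
}
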