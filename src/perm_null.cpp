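#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass permutation null for the per-state mean read count of every OTU.
//
// counts_t: P x S integer matrix (OTUs x samples; transposed for cache
//           locality), state: length-S 0-based state codes, obs_mean: P x K
//           observed per-state means, strata: length-S 0-based stratum codes
//           (all zero = unrestricted shuffling).
//
// Pass 1 shuffles the state labels n_perm times (Fisher-Yates within each
// stratum, driven by R's RNG so set.seed() controls it), records every
// permuted label vector, and accumulates the running sum and sum of squares
// of the per-state means. Pass 2 replays the stored labels to count, per
// (OTU, state), permutations whose mean deviates from the null mean by at
// least as much as the observed mean (two-sided empirical p numerator).
// The null s.d. uses the population denominator n_perm, matching exact
// enumeration over all label assignments as n_perm grows.
// [[Rcpp::export(rng = true)]]
List perm_null_kernel(const IntegerMatrix counts_t,
                      const IntegerVector state,
                      const NumericMatrix obs_mean,
                      const IntegerVector strata,
                      const int n_states,
                      const int n_perm) {
  const int P = counts_t.nrow(), S = counts_t.ncol();
  const int K = n_states;
  if (state.size() != S || strata.size() != S)
    stop("label length does not match sample count");

  std::vector<double> n_per_state(K, 0.0);
  for (int s = 0; s < S; ++s) n_per_state[state[s]] += 1.0;
  for (int k = 0; k < K; ++k)
    if (n_per_state[k] < 1) stop("every state needs at least one sample");

  // sample indices grouped by stratum
  int n_strata = 0;
  for (int s = 0; s < S; ++s) n_strata = std::max(n_strata, strata[s] + 1);
  std::vector< std::vector<int> > groups(n_strata);
  for (int s = 0; s < S; ++s) groups[strata[s]].push_back(s);

  std::vector<unsigned char> labels((size_t)n_perm * S);
  std::vector<double> sum(P * K, 0.0), sumsq(P * K, 0.0);
  std::vector<double> acc(P * K);
  std::vector<int> lab(state.begin(), state.end());
  const int *cnt = INTEGER(counts_t);

  for (int t = 0; t < n_perm; ++t) {
    for (size_t g = 0; g < groups.size(); ++g) {
      std::vector<int> &idx = groups[g];
      for (int i = (int)idx.size() - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(lab[idx[i]], lab[idx[j]]);
      }
    }
    unsigned char *rec = &labels[(size_t)t * S];
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      rec[s] = (unsigned char)lab[s];
      double *a = &acc[(size_t)lab[s] * P];
      const int *c = cnt + (size_t)s * P;
      for (int p = 0; p < P; ++p) a[p] += c[p];
    }
    for (int k = 0; k < K; ++k) {
      const double nk = n_per_state[k];
      for (int p = 0; p < P; ++p) {
        double m = acc[(size_t)k * P + p] / nk;
        sum[(size_t)k * P + p] += m;
        sumsq[(size_t)k * P + p] += m * m;
      }
    }
    if ((t & 1023) == 0) checkUserInterrupt();
  }

  NumericMatrix null_mean(P, K), null_sd(P, K);
  for (int k = 0; k < K; ++k)
    for (int p = 0; p < P; ++p) {
      double m = sum[(size_t)k * P + p] / n_perm;
      double v = sumsq[(size_t)k * P + p] / n_perm - m * m;
      null_mean(p, k) = m;
      null_sd(p, k) = v > 0 ? std::sqrt(v) : 0.0;
    }

  IntegerMatrix exceed(P, K);
  std::vector<double> thr(P * K);
  for (int k = 0; k < K; ++k)
    for (int p = 0; p < P; ++p)
      thr[(size_t)k * P + p] =
        std::fabs(obs_mean(p, k) - null_mean(p, k)) - 1e-12;

  for (int t = 0; t < n_perm; ++t) {
    const unsigned char *rec = &labels[(size_t)t * S];
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      double *a = &acc[(size_t)rec[s] * P];
      const int *c = cnt + (size_t)s * P;
      for (int p = 0; p < P; ++p) a[p] += c[p];
    }
    for (int k = 0; k < K; ++k) {
      const double nk = n_per_state[k];
      for (int p = 0; p < P; ++p) {
        double m = acc[(size_t)k * P + p] / nk;
        if (std::fabs(m - null_mean(p, k)) >= thr[(size_t)k * P + p])
          ++exceed(p, k);
      }
    }
    if ((t & 1023) == 0) checkUserInterrupt();
  }

  return List::create(_["null_mean"] = null_mean,
                      _["null_sd"] = null_sd,
                      _["exceed"] = exceed);
}
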