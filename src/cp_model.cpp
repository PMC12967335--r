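#include <Rcpp.h>
using namespace Rcpp;

// Block tallies over the full symmetric matrix (both triangles, diagonal
// included). g holds the 0-based loci-group id per bin, -1 for masked bins.
static void tally_blocks(const NumericMatrix &Y, const IntegerVector &g,
                         int Kp1, std::vector<double> &N,
                         std::vector<double> &S, std::vector<double> &sum,
                         std::vector<double> &sum2) {
  const int n = Y.nrow();
  std::fill(N.begin(), N.end(), 0.0);
  std::fill(S.begin(), S.end(), 0.0);
  std::fill(sum.begin(), sum.end(), 0.0);
  std::fill(sum2.begin(), sum2.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    const int gj = g[j];
    if (gj < 0) continue;
    for (int i = 0; i < n; ++i) {
      const int gi = g[i];
      if (gi < 0) continue;
      const int b = gi * Kp1 + gj;
      N[b] += 1.0;
      const double y = Y(i, j);
      if (y != 0.0) {
        S[b] += 1.0;
        sum[b] += y;
        sum2[b] += y * y;
      }
    }
  }
}

// Log-posterior up to an additive constant: Bernoulli block term plus the
// plug-in Gaussian term -(1/(2*sigma2)) * sum_kl S_kl * V_kl, where
// S*V = sum2 - sum^2/S (population variance of nonzero entries).
static double lp_from_tallies(const std::vector<double> &N,
                              const std::vector<double> &S,
                              const std::vector<double> &sum,
                              const std::vector<double> &sum2,
                              int Kp1, double sigma2) {
  double bern = 0.0, gauss = 0.0;
  const int nb = Kp1 * Kp1;
  for (int b = 0; b < nb; ++b) {
    const double Nb = N[b], Sb = S[b];
    if (Nb <= 0.0) continue;
    const double r = Sb / Nb;
    if (Sb > 0.0) bern += Sb * std::log(r);
    if (Nb - Sb > 0.0) bern += (Nb - Sb) * std::log(1.0 - r);
    if (Sb > 1.0) gauss += sum2[b] - sum[b] * sum[b] / Sb;
  }
  double lp = bern;
  if (sigma2 > 0.0) lp -= gauss / (2.0 * sigma2);
  return lp;
}

// Map sorted change-point positions (1-based gap indices) to per-bin group
// ids, keeping masked bins at -1.
static void groups_from_pos(const std::vector<int> &pos, const LogicalVector &mask,
                            int n, IntegerVector &g) {
  int grp = 0;
  size_t next = 0;
  for (int b = 0; b < n; ++b) {
    while (next < pos.size() && pos[next] == b) { ++grp; ++next; }
    g[b] = mask[b] ? grp : -1;
  }
}

// TRUE iff every loci group contains at least one unmasked bin.
static bool state_valid(const std::vector<int> &pos, const LogicalVector &mask,
                        int n, int Kp1, IntegerVector &scratch) {
  groups_from_pos(pos, mask, n, scratch);
  std::vector<int> cnt(Kp1, 0);
  for (int b = 0; b < n; ++b)
    if (scratch[b] >= 0) cnt[scratch[b]]++;
  for (int k = 0; k < Kp1; ++k)
    if (cnt[k] == 0) return false;
  return true;
}

// [[Rcpp::export]]
List cpp_block_tallies(NumericMatrix Y, IntegerVector g, int Kp1) {
  std::vector<double> N(Kp1 * Kp1), S(Kp1 * Kp1), sum(Kp1 * Kp1),
      sum2(Kp1 * Kp1);
  tally_blocks(Y, g, Kp1, N, S, sum, sum2);
  NumericMatrix Nm(Kp1, Kp1), Sm(Kp1, Kp1), summ(Kp1, Kp1), sum2m(Kp1, Kp1);
  for (int k = 0; k < Kp1; ++k)
    for (int l = 0; l < Kp1; ++l) {
      Nm(k, l) = N[k * Kp1 + l];
      Sm(k, l) = S[k * Kp1 + l];
      summ(k, l) = sum[k * Kp1 + l];
      sum2m(k, l) = sum2[k * Kp1 + l];
    }
  return List::create(_["N"] = Nm, _["S"] = Sm, _["sum"] = summ,
                      _["sum2"] = sum2m);
}

// [[Rcpp::export]]
double cpp_log_posterior(NumericMatrix Y, IntegerVector g, int Kp1,
                         double sigma2) {
  std::vector<double> N(Kp1 * Kp1), S(Kp1 * Kp1), sum(Kp1 * Kp1),
      sum2(Kp1 * Kp1);
  tally_blocks(Y, g, Kp1, N, S, sum, sum2);
  return lp_from_tallies(N, S, sum, sum2, Kp1, sigma2);
}

// Metropolis-Hastings over change-point configurations with exactly K ones.
// Proposal: move one uniformly chosen occupied gap to a uniformly chosen
// unoccupied gap (symmetric). Proposals that would leave a loci group with
// only masked bins are rejected in place. Uses R's RNG, so the chain is
// reproducible under set.seed().
// [[Rcpp::export]]
List cpp_mh_sample(NumericMatrix Y, LogicalVector mask, IntegerVector init_pos,
                   int n_iter, double sigma2) {
  const int n = Y.nrow();
  const int K = init_pos.size();
  const int Kp1 = K + 1;
  RNGScope scope;

  std::vector<int> pos(init_pos.begin(), init_pos.end());
  std::sort(pos.begin(), pos.end());

  IntegerVector g(n), scratch(n);
  if (!state_valid(pos, mask, n, Kp1, scratch))
    stop("initial change-point state leaves a loci group fully masked");
  groups_from_pos(pos, mask, n, g);

  std::vector<double> N(Kp1 * Kp1), S(Kp1 * Kp1), sum(Kp1 * Kp1),
      sum2(Kp1 * Kp1);
  tally_blocks(Y, g, Kp1, N, S, sum, sum2);
  double lp = lp_from_tallies(N, S, sum, sum2, Kp1, sigma2);

  IntegerMatrix states(n_iter, K);
  NumericVector log_posts(n_iter);
  LogicalVector accepted(n_iter);

  std::vector<char> occupied(n, 0);  // gap p occupied, p in 1..n-1
  for (int k = 0; k < K; ++k) occupied[pos[k]] = 1;
  const int n_gaps = n - 1;
  const int n_free = n_gaps - K;

  for (int k = 0; k < K; ++k) states(0, k) = pos[k];
  log_posts[0] = lp;
  accepted[0] = NA_LOGICAL;

  std::vector<int> prop(K);
  for (int it = 1; it < n_iter; ++it) {
    bool acc = false;
    if (n_free > 0) {
      // uniformly chosen occupied slot and free gap
      int ko = (int)(unif_rand() * K);
      if (ko >= K) ko = K - 1;
      int fo = (int)(unif_rand() * n_free);
      if (fo >= n_free) fo = n_free - 1;
      int target = -1, seen = 0;
      for (int p = 1; p <= n_gaps; ++p) {
        if (!occupied[p]) {
          if (seen == fo) { target = p; break; }
          ++seen;
        }
      }
      prop = pos;
      prop[ko] = target;
      std::sort(prop.begin(), prop.end());
      if (state_valid(prop, mask, n, Kp1, scratch)) {
        // scratch already holds the proposed grouping
        tally_blocks(Y, scratch, Kp1, N, S, sum, sum2);
        const double lp_new = lp_from_tallies(N, S, sum, sum2, Kp1, sigma2);
        if (lp_new >= lp || unif_rand() < std::exp(lp_new - lp)) {
          const int old = pos[ko];
          occupied[old] = 0;
          occupied[target] = 1;
          pos = prop;
          lp = lp_new;
          acc = true;
        }
      }
    }
    for (int k = 0; k < K; ++k) states(it, k) = pos[k];
    log_posts[it] = lp;
    accepted[it] = acc;
  }

  return List::create(_["states"] = states, _["log_posts"] = log_posts,
                      _["accepted"] = accepted);
}
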