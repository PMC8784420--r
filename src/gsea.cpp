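#include <Rcpp.h>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov-like running sum over a ranked list.
// `weights` are |score|^w for the list in rank order; `hit` marks gene-set
// members. Hits step up by weight/N_R, misses step down by 1/(N - k).
// ES is the running-sum value of maximum magnitude (first such position).
static double running_es(const NumericVector& weights,
                         const std::vector<int>& hit, int n, int k) {
  double nr = 0.0;
  for (int i = 0; i < n; ++i) if (hit[i]) nr += weights[i];
  const double miss = 1.0 / (double)(n - k);
  double cur = 0.0, best = 0.0;
  for (int i = 0; i < n; ++i) {
    cur += hit[i] ? weights[i] / nr : -miss;
    // largest magnitude wins; an exact magnitude tie prefers the positive
    // deviation (the convention of preranked GSEA implementations)
    if (std::fabs(cur) > std::fabs(best) ||
        (std::fabs(cur) == std::fabs(best) && cur > best)) best = cur;
  }
  return best;
}

// [[Rcpp::export(name = ".gsea_perm")]]
List gsea_perm(NumericVector weights, LogicalVector hits, int n_perm) {
  const int n = weights.size();
  int k = 0;
  std::vector<int> hit(n);
  for (int i = 0; i < n; ++i) { hit[i] = hits[i] ? 1 : 0; k += hit[i]; }
  if (k == 0 || k == n)
    stop("need at least one hit and one miss in the ranked list");

  const double es_obs = running_es(weights, hit, n, k);

  NumericVector es_null(n_perm);
  std::vector<int> perm(hit);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle of hit labels using R's RNG (seeded from R)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    es_null[b] = running_es(weights, perm, n, k);
  }
  return List::create(_["es"] = es_obs, _["es_null"] = es_null);
}

// [[Rcpp::export(name = ".gsea_es")]]
double gsea_es(NumericVector weights, LogicalVector hits) {
  const int n = weights.size();
  int k = 0;
  std::vector<int> hit(n);
  for (int i = 0; i < n; ++i) { hit[i] = hits[i] ? 1 : 0; k += hit[i]; }
  if (k == 0) stop("gene set does not overlap the ranked list");
  if (k == n) return 1.0;
  return running_es(weights, hit, n, k);
}
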