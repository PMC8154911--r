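#include <Rcpp.h>
using namespace Rcpp;

// Draw `k` distinct indices in [0, m) as the prefix of a partial
// Fisher-Yates shuffle of a reusable index array; O(k) per draw. The array is
// deliberately not restored between draws: a partial Fisher-Yates of any
// fixed arrangement yields a uniform k-subset. Uses R's RNG, so results are
// reproducible under set.seed().
static inline void draw_distinct(std::vector<int> &perm, int m, int k,
                                 std::vector<int> &out) {
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (m - i));
    if (j >= m) j = m - 1; // guard against unif_rand() returning 1.0
    std::swap(perm[i], perm[j]);
    out[i] = perm[i];
  }
}

// Null distribution of the mean patristic distance of `n_pairs` distinct
// species pairs drawn uniformly (without replacement within a draw) from the
// pool's pair list. `dvec` is the upper triangle of the pool's distance
// matrix.
// [[Rcpp::export]]
NumericVector mpd_null_pairs_cpp(NumericVector dvec, int n_pairs, int n_draws) {
  int m = dvec.size();
  if (n_pairs > m) stop("n_pairs exceeds the number of available pairs");
  std::vector<int> perm(m);
  for (int i = 0; i < m; ++i) perm[i] = i;
  std::vector<int> pick(n_pairs);
  NumericVector out(n_draws);
  for (int d = 0; d < n_draws; ++d) {
    draw_distinct(perm, m, n_pairs, pick);
    double s = 0.0;
    for (int i = 0; i < n_pairs; ++i) s += dvec[pick[i]];
    out[d] = s / n_pairs;
  }
  return out;
}

// Group-resampling null: each draw picks a random subset of `group_size`
// species from the pool of `n` (rows of `dmat`), then averages `n_pairs`
// distinct pairs drawn uniformly within that subset (all pairs if the subset
// has at most `n_pairs` of them) - i.e. the null group is processed exactly
// like the observed group.
// [[Rcpp::export]]
NumericVector mpd_null_groups_cpp(NumericMatrix dmat, int group_size,
                                  int n_pairs, int n_draws) {
  int n = dmat.nrow();
  if (group_size > n) stop("group_size exceeds the pool");
  long npair_group = (long)group_size * (group_size - 1) / 2;
  int k = (npair_group <= n_pairs) ? (int)npair_group : n_pairs;

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::vector<int> grp(group_size);
  std::vector<int> pairperm(npair_group);
  for (long i = 0; i < npair_group; ++i) pairperm[i] = (int)i;
  std::vector<int> pick(k);

  // decode table: pair index -> (a, b) within the group
  std::vector<int> pa(npair_group), pb(npair_group);
  {
    long idx = 0;
    for (int a = 0; a < group_size - 1; ++a)
      for (int b = a + 1; b < group_size; ++b) { pa[idx] = a; pb[idx] = b; ++idx; }
  }

  NumericVector out(n_draws);
  for (int d = 0; d < n_draws; ++d) {
    draw_distinct(perm, n, group_size, grp);
    draw_distinct(pairperm, (int)npair_group, k, pick);
    double s = 0.0;
    for (int i = 0; i < k; ++i) {
      int p = pick[i];
      s += dmat(grp[pa[p]], grp[pb[p]]);
    }
    out[d] = s / k;
  }
  return out;
}
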