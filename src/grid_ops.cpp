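#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 8- or 4-connected component labeling of a binary grid (BFS flood fill).
// Labels are consecutive positive integers in scan order of patch seeds.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& x, int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int> > offs;
  offs.push_back(std::make_pair(-1, 0));
  offs.push_back(std::make_pair(1, 0));
  offs.push_back(std::make_pair(0, -1));
  offs.push_back(std::make_pair(0, 1));
  if (connectivity == 8) {
    offs.push_back(std::make_pair(-1, -1));
    offs.push_back(std::make_pair(-1, 1));
    offs.push_back(std::make_pair(1, -1));
    offs.push_back(std::make_pair(1, 1));
  }
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(j * nr + i);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        int ci = cur % nr, cj = cur / nr;
        for (size_t k = 0; k < offs.size(); ++k) {
          int ni = ci + offs[k].first, nj = cj + offs[k].second;
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (x(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(nj * nr + ni);
          }
        }
      }
    }
  }
  return lab;
}

// Greedy ordering of candidate pixels for the cluster / scatter allocation
// strategies. Repeatedly picks the candidate with the largest (cluster) or
// smallest (scatter) number of high-canopy pixels in its Moore
// neighbourhood, breaking ties uniformly at random with R's RNG; a picked
// candidate immediately becomes high canopy, so neighbour counts are
// dynamic. Implemented with count buckets (counts are bounded by 8) and
// lazy deletion, giving near-linear behaviour.
//
// cand_idx: 0-based linear indices (column-major) of candidate pixels.
// high0:    initial high-canopy indicator grid.
// maximize: true for cluster, false for scatter.
// dynamic_counts: if false, neighbour counts are precomputed once.
// Returns the candidate indices (0-based into cand_idx) in pick order.
// [[Rcpp::export(name = ".greedy_order")]]
IntegerVector greedy_order(const IntegerVector& cand_idx,
                           const LogicalMatrix& high0,
                           bool maximize,
                           bool dynamic_counts) {
  const int nr = high0.nrow(), nc = high0.ncol();
  const int n = cand_idx.size();
  std::vector<char> high(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      high[j * nr + i] = high0(i, j) ? 1 : 0;

  std::vector<int> cand_of_cell(nr * nc, -1); // cell -> candidate slot
  for (int k = 0; k < n; ++k) cand_of_cell[cand_idx[k]] = k;

  // Moore-neighbour high-canopy counts per candidate
  std::vector<int> cnt(n, 0);
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int k = 0; k < n; ++k) {
    int ci = cand_idx[k] % nr, cj = cand_idx[k] / nr;
    int c = 0;
    for (int m = 0; m < 8; ++m) {
      int ni = ci + di[m], nj = cj + dj[m];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (high[nj * nr + ni]) ++c;
    }
    cnt[k] = c;
  }

  // buckets by count (0..8), lazy deletion
  std::vector< std::vector<int> > bucket(9);
  for (int k = 0; k < n; ++k) bucket[cnt[k]].push_back(k);
  std::vector<char> taken(n, 0);

  IntegerVector order(n);
  for (int pick = 0; pick < n; ++pick) {
    int b = -1;
    if (maximize) {
      for (int c = 8; c >= 0; --c) {
        // purge stale entries (taken, or count changed since insertion)
        std::vector<int>& bk = bucket[c];
        while (!bk.empty()) {
          int k = bk.back();
          if (taken[k] || cnt[k] != c) bk.pop_back(); else break;
        }
        if (!bk.empty()) { b = c; break; }
      }
    } else {
      for (int c = 0; c <= 8; ++c) {
        std::vector<int>& bk = bucket[c];
        while (!bk.empty()) {
          int k = bk.back();
          if (taken[k] || cnt[k] != c) bk.pop_back(); else break;
        }
        if (!bk.empty()) { b = c; break; }
      }
    }
    // uniform tie-break among live members of the best bucket
    std::vector<int>& bk = bucket[b];
    std::vector<int> live;
    std::vector<int> keep;
    keep.reserve(bk.size());
    for (size_t t = 0; t < bk.size(); ++t) {
      int k = bk[t];
      if (!taken[k] && cnt[k] == b) { live.push_back(k); keep.push_back(k); }
    }
    bk.swap(keep);
    int chosen = live[(int)(unif_rand() * live.size()) % live.size()];
    taken[chosen] = 1;
    order[pick] = chosen;

    if (dynamic_counts) {
      int cell = cand_idx[chosen];
      if (!high[cell]) {
        high[cell] = 1;
        int ci = cell % nr, cj = cell / nr;
        for (int m = 0; m < 8; ++m) {
          int ni = ci + di[m], nj = cj + dj[m];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          int k = cand_of_cell[nj * nr + ni];
          if (k >= 0 && !taken[k]) {
            ++cnt[k];
            bucket[cnt[k]].push_back(k);
          }
        }
      }
    }
  }
  return order;
}
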