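// Branch-mode site frequency spectrum: for every edge, the genetic span
// (excluding spacer gaps) times the branch length is added to the class
// given by the number of samples subtending the child over that interval.
// Multiplying by a mutation rate per Morgan per generation gives the
// expected infinite-sites SFS conditional on the genealogy.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>

using namespace Rcpp;

static double glen_cc(const std::vector<double>& cs,
                      const std::vector<double>& ce, double l, double r) {
  if (r <= l) return 0.0;
  double s = 0;
  size_t i = std::upper_bound(ce.begin(), ce.end(), l) - ce.begin();
  for (; i < cs.size() && cs[i] < r; ++i) {
    double a = std::max(l, cs[i]), b = std::min(r, ce[i]);
    if (b > a) s += b - a;
  }
  return s;
}

typedef std::map<double, int> Prof;  // piecewise-constant descendant counts

static void prof_add(Prof& p, double l, double r, int cnt, double axis) {
  if (p.empty()) {
    p[0.0] = 0;
    p[axis] = 0;
  }
  auto split = [&](double x) {
    auto it = p.lower_bound(x);
    if (it != p.end() && it->first == x) return it;
    --it;
    return p.insert(it, {x, it->second});
  };
  auto itl = split(l), itr = split(r);
  for (auto it = itl; it != itr; ++it) it->second += cnt;
}

// [[Rcpp::export]]
NumericVector cpp_branch_sfs(NumericVector node_time, IntegerVector node_flags,
                             NumericVector edge_left, NumericVector edge_right,
                             IntegerVector edge_parent,
                             IntegerVector edge_child,
                             NumericVector chrom_start,
                             NumericVector chrom_end) {
  int nn = node_time.size();
  std::vector<double> cs(chrom_start.begin(), chrom_start.end());
  std::vector<double> ce(chrom_end.begin(), chrom_end.end());
  double axis = ce.back();

  int n_samples = 0;
  std::vector<Prof> prof(nn);
  for (int v = 0; v < nn; ++v)
    if ((node_flags[v] & 1) && node_time[v] == 0) {
      prof_add(prof[v], 0.0, axis, 1, axis);
      ++n_samples;
    }

  std::vector<int> eord(edge_left.size());
  for (size_t i = 0; i < eord.size(); ++i) eord[i] = (int)i;
  std::stable_sort(eord.begin(), eord.end(), [&](int a, int b) {
    return node_time[edge_parent[a]] < node_time[edge_parent[b]];
  });

  NumericVector sfs(n_samples);  // classes 1 .. n (n kept for diagnostics)
  for (int e : eord) {
    int p = edge_parent[e], c = edge_child[e];
    double l = edge_left[e], r = edge_right[e];
    double blen = node_time[p] - node_time[c];
    Prof& pc = prof[c];
    if (pc.empty()) continue;
    auto it = pc.lower_bound(l);
    if (it == pc.end() || it->first > l) --it;
    for (; it != pc.end() && it->first < r; ++it) {
      double pl = std::max(l, it->first);
      auto nx = std::next(it);
      double pr = std::min(r, nx == pc.end() ? axis : nx->first);
      int cnt = it->second;
      if (pr <= pl || cnt <= 0) continue;
      if (cnt <= n_samples)
        sfs[cnt - 1] += glen_cc(cs, ce, pl, pr) * blen;
      prof_add(prof[p], pl, pr, cnt, axis);
    }
  }
  return sfs;
}
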