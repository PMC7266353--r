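// Multi-locus statistics computed from recorded node/edge tables.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

typedef std::pair<double, double> Iv;
typedef std::vector<Iv> IList;  // sorted, disjoint

static IList iv_intersect(const IList& a, const IList& b) {
  IList out;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    double l = std::max(a[i].first, b[j].first);
    double r = std::min(a[i].second, b[j].second);
    if (r > l) out.push_back({l, r});
    if (a[i].second < b[j].second)
      ++i;
    else
      ++j;
  }
  return out;
}

static IList iv_union(const IList& a, const IList& b) {
  IList m;
  m.reserve(a.size() + b.size());
  std::merge(a.begin(), a.end(), b.begin(), b.end(), std::back_inserter(m));
  IList out;
  for (auto& iv : m) {
    if (!out.empty() && iv.first <= out.back().second)
      out.back().second = std::max(out.back().second, iv.second);
    else
      out.push_back(iv);
  }
  return out;
}

static IList iv_subtract(const IList& a, const IList& b) {
  IList out;
  size_t j = 0;
  for (auto& iv : a) {
    double cur = iv.first;
    while (j < b.size() && b[j].second <= cur) ++j;
    size_t k = j;
    while (cur < iv.second) {
      if (k >= b.size() || b[k].first >= iv.second) {
        out.push_back({cur, iv.second});
        break;
      }
      if (b[k].first > cur) out.push_back({cur, b[k].first});
      cur = std::max(cur, b[k].second);
      ++k;
    }
  }
  return out;
}

// non-spacer genetic length of [l, r) given chromosome intervals
static double glen_chrom(const std::vector<double>& cs,
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

// ---------------------------------------------------------------------------
// IBD: maximal intervals over which a sample pair's MRCA node is constant,
// with MRCA time <= max_gen.  Nodes are processed in increasing time order;
// the first node to contain both samples at a point is their MRCA there, and
// later (older) nodes cannot reclaim it.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ibd_segments(NumericVector node_time, IntegerVector node_flags,
                      NumericVector edge_left, NumericVector edge_right,
                      IntegerVector edge_parent, IntegerVector edge_child,
                      double max_gen, double min_cm,
                      NumericVector chrom_start, NumericVector chrom_end) {
  int nn = node_time.size();
  std::vector<double> cs(chrom_start.begin(), chrom_start.end());
  std::vector<double> ce(chrom_end.begin(), chrom_end.end());
  double axis = ce.back();

  // descent intervals per (node, sample)
  std::vector<std::unordered_map<int, IList>> D(nn);
  for (int v = 0; v < nn; ++v)
    if ((node_flags[v] & 1) && node_time[v] == 0)
      D[v][v] = IList{{0.0, axis}};

  // order relevant edges by parent time (children strictly younger, so a
  // child's descent set is complete before any of its parents is reached)
  std::vector<int> eord;
  for (int e = 0; e < edge_left.size(); ++e)
    if (node_time[edge_parent[e]] <= max_gen) eord.push_back(e);
  std::stable_sort(eord.begin(), eord.end(), [&](int a, int b) {
    if (node_time[edge_parent[a]] != node_time[edge_parent[b]])
      return node_time[edge_parent[a]] < node_time[edge_parent[b]];
    return edge_parent[a] < edge_parent[b];
  });
  for (int e : eord) {
    int p = edge_parent[e], c = edge_child[e];
    IList win{{edge_left[e], edge_right[e]}};
    for (auto& kv : D[c]) {
      IList piece = iv_intersect(kv.second, win);
      if (piece.empty()) continue;
      IList& tgt = D[p][kv.first];
      tgt = tgt.empty() ? piece : iv_union(tgt, piece);
    }
  }

  // nodes in increasing time; claim MRCA intervals lowest-first
  std::vector<int> nord;
  for (int v = 0; v < nn; ++v)
    if (node_time[v] > 0 && node_time[v] <= max_gen && !D[v].empty())
      nord.push_back(v);
  std::stable_sort(nord.begin(), nord.end(), [&](int a, int b) {
    return node_time[a] < node_time[b];
  });

  std::unordered_map<long long, IList> claimed;
  std::vector<int> out_a, out_b, out_m;
  std::vector<double> out_l, out_r, out_t, out_cm;
  std::vector<int> samp;
  for (int v : nord) {
    samp.clear();
    for (auto& kv : D[v]) samp.push_back(kv.first);
    if (samp.size() < 2) continue;
    std::sort(samp.begin(), samp.end());
    for (size_t i = 0; i < samp.size(); ++i)
      for (size_t j = i + 1; j < samp.size(); ++j) {
        int a = samp[i], b = samp[j];
        IList I = iv_intersect(D[v][a], D[v][b]);
        if (I.empty()) continue;
        long long key = (long long)a * nn + b;
        auto cl = claimed.find(key);
        IList nw = (cl == claimed.end()) ? I : iv_subtract(I, cl->second);
        if (nw.empty()) continue;
        // IBD segments are reported per chromosome: an interval spanning a
        // spacer gap becomes one record on each side
        for (auto& iv : nw) {
          size_t ci =
              std::upper_bound(ce.begin(), ce.end(), iv.first) - ce.begin();
          for (; ci < cs.size() && cs[ci] < iv.second; ++ci) {
            double pl = std::max(iv.first, cs[ci]);
            double pr = std::min(iv.second, ce[ci]);
            double cm = 100.0 * (pr - pl);
            if (cm >= min_cm && cm > 0) {
              out_a.push_back(a);
              out_b.push_back(b);
              out_l.push_back(pl);
              out_r.push_back(pr);
              out_m.push_back(v);
              out_t.push_back(node_time[v]);
              out_cm.push_back(cm);
            }
          }
        }
        claimed[key] = (cl == claimed.end()) ? I : iv_union(cl->second, nw);
      }
  }
  return List::create(_["sample_a"] = wrap(out_a), _["sample_b"] = wrap(out_b),
                      _["left"] = wrap(out_l), _["right"] = wrap(out_r),
                      _["mrca"] = wrap(out_m), _["tmrca"] = wrap(out_t),
                      _["length_cm"] = wrap(out_cm));
}

// ---------------------------------------------------------------------------
// Ancestry fractions: propagate each sample's genome upward until it hits a
// census node recorded at census_time; fraction = migrant-census span / L.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_census_fractions(NumericVector node_time,
                                   IntegerVector node_population,
                                   IntegerVector node_flags,
                                   NumericVector edge_left,
                                   NumericVector edge_right,
                                   IntegerVector edge_parent,
                                   IntegerVector edge_child, double census_time,
                                   int source_pop, NumericVector chrom_start,
                                   NumericVector chrom_end) {
  int nn = node_time.size();
  std::vector<double> cs(chrom_start.begin(), chrom_start.end());
  std::vector<double> ce(chrom_end.begin(), chrom_end.end());
  double axis = ce.back();
  double L = glen_chrom(cs, ce, 0.0, axis);

  std::vector<std::vector<int>> by_child(nn);
  for (int e = 0; e < edge_left.size(); ++e)
    by_child[edge_child[e]].push_back(e);
  // edges per child sorted by left for the coverage sweep
  for (auto& v : by_child)
    std::sort(v.begin(), v.end(), [&](int a, int b) {
      return edge_left[a] < edge_left[b];
    });

  std::vector<int> samples;
  for (int v = 0; v < nn; ++v)
    if ((node_flags[v] & 1) && node_time[v] == 0) samples.push_back(v);

  NumericVector frac(samples.size());
  struct Piece {
    double l, r;
    int node;
  };
  std::vector<Piece> stack;
  for (size_t si = 0; si < samples.size(); ++si) {
    double migrant = 0;
    stack.clear();
    stack.push_back({0.0, axis, samples[si]});
    while (!stack.empty()) {
      Piece p = stack.back();
      stack.pop_back();
      int v = p.node;
      if ((node_flags[v] & 2) &&
          std::abs(node_time[v] - census_time) < 1e-9) {
        if (node_population[v] == source_pop)
          migrant += glen_chrom(cs, ce, p.l, p.r);
        continue;
      }
      double covered = p.l;
      for (int e : by_child[v]) {
        double l = std::max(p.l, edge_left[e]);
        double r = std::min(p.r, edge_right[e]);
        if (r <= l) continue;
        if (l > covered && glen_chrom(cs, ce, covered, l) > 1e-12)
          stop("genome interval not attributable to a census ancestor; "
               "run the simulation with census recording enabled");
        stack.push_back({l, r, edge_parent[e]});
        covered = std::max(covered, r);
      }
      if (covered < p.r && glen_chrom(cs, ce, covered, p.r) > 1e-12)
        stop("genome interval not attributable to a census ancestor; "
             "run the simulation with census recording enabled");
    }
    frac[si] = migrant / L;
  }
  return frac;
}

// ---------------------------------------------------------------------------
// Derived-allele carriers: samples below a given node at a given position.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_site_carriers(NumericVector node_time, IntegerVector node_flags,
                       NumericVector edge_left, NumericVector edge_right,
                       IntegerVector edge_parent, IntegerVector edge_child,
                       NumericVector site_pos, IntegerVector site_node) {
  int nn = node_time.size();
  std::vector<std::vector<int>> by_parent(nn);
  for (int e = 0; e < edge_left.size(); ++e)
    by_parent[edge_parent[e]].push_back(e);

  List out(site_pos.size());
  std::vector<int> stack, carriers;
  for (int s = 0; s < site_pos.size(); ++s) {
    double x = site_pos[s];
    carriers.clear();
    stack.clear();
    stack.push_back(site_node[s]);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if ((node_flags[v] & 1) && node_time[v] == 0) {
        carriers.push_back(v);
        continue;
      }
      for (int e : by_parent[v])
        if (edge_left[e] <= x && x < edge_right[e])
          stack.push_back(edge_child[e]);
    }
    std::sort(carriers.begin(), carriers.end());
    out[s] = wrap(carriers);
  }
  return out;
}
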