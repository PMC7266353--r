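// Backwards-in-time genealogy engines over ancestral segments.
//
// Both engines share the same state: a set of extant lineages, each a sorted
// list of disjoint ancestral segments tagged with the genealogy node whose
// ancestry they carry, plus a genome-wide overlap counter giving, at every
// point, the number of extant lineages ancestral to that point.  When a
// common-ancestor event drives the counter to 1 at a point, that point has
// reached its grand MRCA and is pruned from the merged lineage (the MRCA node
// itself is recorded).  All randomness comes from R's RNG so set.seed()
// controls every draw.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Seg {
  double l, r;
  int node;
};
typedef std::vector<Seg> SegList;

struct Lin {
  SegList segs;
  int pop;
};

// Append a segment, coalescing with the previous one when contiguous and
// carrying the same node.
static inline void push_seg(SegList& out, double l, double r, int node) {
  if (r <= l) return;
  if (!out.empty() && out.back().node == node && out.back().r == l) {
    out.back().r = r;
  } else {
    out.push_back({l, r, node});
  }
}

// ---------------------------------------------------------------------------
// Genetic map: chromosomes live on one concatenated axis, with optional
// spacer gaps between them (used as recombining distance by the Hudson
// engine, skipped entirely by the DTWF meiosis model).
// ---------------------------------------------------------------------------
struct GMap {
  std::vector<double> cs, ce;  // per-chromosome [start, end) on the axis
  double axis_len = 0;

  void init(const NumericVector& start, const NumericVector& end) {
    cs.assign(start.begin(), start.end());
    ce.assign(end.begin(), end.end());
    axis_len = ce.back();
  }
  // non-spacer genetic length within [l, r)
  double glen(double l, double r) const {
    if (r <= l) return 0.0;
    double s = 0;
    size_t i = std::upper_bound(ce.begin(), ce.end(), l) - ce.begin();
    for (; i < cs.size() && cs[i] < r; ++i) {
      double a = std::max(l, cs[i]), b = std::min(r, ce[i]);
      if (b > a) s += b - a;
    }
    return s;
  }
  // map a genetic offset u in (0, glen(l, r)) to an axis coordinate
  double gpos(double l, double r, double u) const {
    size_t i = std::upper_bound(ce.begin(), ce.end(), l) - ce.begin();
    for (; i < cs.size() && cs[i] < r; ++i) {
      double a = std::max(l, cs[i]), b = std::min(r, ce[i]);
      double w = b - a;
      if (w <= 0) continue;
      if (u < w) return a + u;
      u -= w;
    }
    return std::nextafter(r, 0.0);
  }
  double total_glen() const { return glen(0.0, axis_len); }
};

// ---------------------------------------------------------------------------
// Fenwick tree over per-lineage-slot recombination mass (Hudson engine).
// ---------------------------------------------------------------------------
struct Fenwick {
  std::vector<double> v;
  int n = 0;
  void build(const std::vector<double>& mass) {
    n = std::max((int)(2 * mass.size()), 1024);  // headroom for new slots
    v.assign(n + 1, 0.0);
    for (size_t i = 0; i < mass.size(); ++i) add((int)i, mass[i]);
  }
  void add(int i, double d) {
    for (++i; i <= n; i += i & (-i)) v[i] += d;
  }
  double total() const {
    double s = 0;
    for (int i = n; i > 0; i -= i & (-i)) s += v[i];
    return s;
  }
  // smallest 0-based i with prefix-sum(0..i) >= u
  int find(double u) const {
    int pos = 0, logn = 0;
    while ((2 << logn) <= n) ++logn;
    for (int pw = 1 << logn; pw > 0; pw >>= 1) {
      int npos = pos + pw;
      if (npos <= n && v[npos] < u) {
        u -= v[npos];
        pos = npos;
      }
    }
    return pos;  // first index whose cumulative mass reaches u
  }
};

// ---------------------------------------------------------------------------
// Meiosis: Poisson crossovers along the (non-spacer) genetic length of a
// span, a fair phase coin, and an independent assortment coin at every
// chromosome boundary inside the span.
// ---------------------------------------------------------------------------
struct Switch {
  double x;
  int type;  // 0 = crossover (flip), 1 = chromosome boundary (fresh coin)
  bool operator<(const Switch& o) const { return x < o.x; }
};

static void draw_switches(const GMap& map, double sl, double sr,
                          std::vector<Switch>& sw) {
  sw.clear();
  double gl = map.glen(sl, sr);
  if (gl > 0) {
    for (;;) {
      int nb = (int)R::rpois(gl);
      sw.clear();
      for (int i = 0; i < nb; ++i)
        sw.push_back({map.gpos(sl, sr, unif_rand() * gl), 0});
      std::sort(sw.begin(), sw.end());
      bool dup = false;
      for (size_t i = 1; i < sw.size(); ++i)
        if (sw[i].x == sw[i - 1].x) dup = true;
      if (!dup) break;  // duplicate breakpoints are redrawn (probability ~0)
    }
  }
  for (size_t c = 0; c + 1 < map.ce.size(); ++c)
    if (map.ce[c] > sl && map.ce[c] < sr) sw.push_back({map.ce[c], 1});
  std::sort(sw.begin(), sw.end());
}

// Split a lineage's segments onto the two parental haplotypes.
static void split_by_switches(const SegList& segs,
                              const std::vector<Switch>& sw, int phase,
                              SegList& A, SegList& B) {
  A.clear();
  B.clear();
  int h = phase;
  size_t k = 0;
  for (const Seg& s : segs) {
    double cur = s.l;
    while (k < sw.size() && sw[k].x <= cur) {
      h = sw[k].type == 0 ? 1 - h : (unif_rand() < 0.5 ? 0 : 1);
      ++k;
    }
    while (cur < s.r) {
      double nxt = (k < sw.size() && sw[k].x < s.r) ? sw[k].x : s.r;
      push_seg(h == 0 ? A : B, cur, nxt, s.node);
      cur = nxt;
      if (k < sw.size() && sw[k].x == cur) {
        h = sw[k].type == 0 ? 1 - h : (unif_rand() < 0.5 ? 0 : 1);
        ++k;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Engine
// ---------------------------------------------------------------------------
struct Event {
  double time;
  int kind;  // 0 = size_change, 1 = growth_change, 2 = pulse
  int a, b;  // population / (dest, source)
  double x;  // new size, new rate, or pulse fraction
};

class Engine {
 public:
  GMap map;
  int npop = 1;
  std::vector<double> N0, alpha, t0;
  std::vector<std::vector<double>> mig;
  std::vector<double> migrow;
  bool any_mig = false;
  std::vector<Event> events;
  size_t next_event = 0;

  bool record_tables = true, keep_coal = false, record_trace = true;
  double stop_time = INF;

  double t = 0;
  std::vector<Lin> lins;
  std::vector<double> mass;  // per-slot span mass (Hudson recombination rate)
  std::vector<int> free_slots;
  std::vector<std::vector<int>> members;  // slots per population
  std::vector<int> lin_pos;               // index of slot within its pop list
  long n_extant = 0;
  Fenwick fen;
  bool fen_live = false;

  std::map<double, int> ov;  // genome-wide overlap counter (piecewise const.)

  // node / edge tables
  std::vector<double> ntime;
  std::vector<int> npopv, nflags;
  std::vector<double> el, er;
  std::vector<int> ep, ec;
  int next_node = 0;

  std::vector<double> trace_gen, trace_cnt;
  bool fully_coalesced = false;
  unsigned long n_events = 0;
  double n_rec = 0, n_ca = 0, n_mig = 0;

  // ---- bookkeeping -------------------------------------------------------
  int new_node(double time, int pop, int flags) {
    int id = next_node++;
    if (record_tables) {
      ntime.push_back(time);
      npopv.push_back(pop);
      nflags.push_back(flags);
    }
    return id;
  }
  void push_edge(double l, double r, int parent, int child) {
    el.push_back(l);
    er.push_back(r);
    ep.push_back(parent);
    ec.push_back(child);
  }
  int alloc_slot() {
    if (!free_slots.empty()) {
      int s = free_slots.back();
      free_slots.pop_back();
      return s;
    }
    lins.push_back(Lin());
    mass.push_back(0.0);
    lin_pos.push_back(-1);
    return (int)lins.size() - 1;
  }
  void set_mass(int slot, double m) {
    if (fen_live) {
      if ((int)lins.size() > fen.n) fen.build(mass);  // capacity grew
      fen.add(slot, m - mass[slot]);
    }
    mass[slot] = m;
  }
  int insert_lineage(SegList&& segs, int pop) {
    int s = alloc_slot();
    lins[s].segs = std::move(segs);
    lins[s].pop = pop;
    set_mass(s, lins[s].segs.back().r - lins[s].segs.front().l);
    lin_pos[s] = (int)members[pop].size();
    members[pop].push_back(s);
    ++n_extant;
    return s;
  }
  void remove_lineage(int s) {
    int pop = lins[s].pop, pos = lin_pos[s];
    int last = members[pop].back();
    members[pop][pos] = last;
    lin_pos[last] = pos;
    members[pop].pop_back();
    set_mass(s, 0.0);
    lins[s].segs.clear();
    free_slots.push_back(s);
    --n_extant;
  }
  void move_lineage(int s, int to) {
    int pop = lins[s].pop, pos = lin_pos[s];
    int last = members[pop].back();
    members[pop][pos] = last;
    lin_pos[last] = pos;
    members[pop].pop_back();
    lins[s].pop = to;
    lin_pos[s] = (int)members[to].size();
    members[to].push_back(s);
  }
  double pop_size_at(int i, double tt) const {
    return N0[i] * std::exp(-alpha[i] * (tt - t0[i]));
  }

  // ---- overlap counter ---------------------------------------------------
  std::map<double, int>::iterator ov_split(double x) {
    auto it = ov.lower_bound(x);
    if (it != ov.end() && it->first == x) return it;
    --it;
    return ov.insert(it, {x, it->second});
  }
  // decrement counter by (k - 1) over [l, r) where k children overlapped;
  // returns kept (non-pruned) pieces
  void ov_coalesce(double l, double r, int dec,
                   std::vector<std::pair<double, double>>& kept) {
    auto itl = ov_split(l);
    auto itr = ov_split(r);
    for (auto it = itl; it != itr; ++it) {
      int nv = it->second - dec;
      if (!keep_coal && nv <= 1) {
        it->second = 0;
      } else {
        it->second = nv < 1 ? 1 : nv;
        kept.push_back({it->first, std::next(it)->first});
      }
    }
    // squash equal-valued neighbours touching [l, r]
    auto first = itl;
    if (first != ov.begin()) --first;
    auto it = first;
    while (it != ov.end()) {
      auto nx = std::next(it);
      if (nx == ov.end() || nx->first > r) break;
      if (nx->second == it->second)
        ov.erase(nx);
      else
        it = nx;
    }
  }

  // ---- merging -----------------------------------------------------------
  // Fast path: merge exactly two sorted seglists with a two-pointer sweep
  // (the only case the Hudson engine ever produces, and the common DTWF one).
  SegList merge_two(const SegList& A, const SegList& B, double tt, int pop) {
    SegList out;
    out.reserve(A.size() + B.size());
    int anc = -1;
    size_t i = 0, j = 0;
    double al = 0, ar = 0, bl = 0, br = 0;
    int an = 0, bn = 0;
    bool hasA = false, hasB = false;
    auto loadA = [&] {
      if (i < A.size()) {
        al = A[i].l; ar = A[i].r; an = A[i].node; ++i; hasA = true;
      } else {
        hasA = false;
      }
    };
    auto loadB = [&] {
      if (j < B.size()) {
        bl = B[j].l; br = B[j].r; bn = B[j].node; ++j; hasB = true;
      } else {
        hasB = false;
      }
    };
    loadA();
    loadB();
    std::vector<std::pair<double, double>> kept;
    while (hasA || hasB) {
      if (!hasB || (hasA && ar <= bl)) {
        push_seg(out, al, ar, an);
        loadA();
        continue;
      }
      if (!hasA || (hasB && br <= al)) {
        push_seg(out, bl, br, bn);
        loadB();
        continue;
      }
      // overlapping pieces coalesce on [l, r)
      double l = std::max(al, bl), r = std::min(ar, br);
      if (al < l) push_seg(out, al, l, an);
      if (bl < l) push_seg(out, bl, l, bn);
      if (anc < 0) anc = new_node(tt, pop, 0);
      if (record_tables) {
        push_edge(l, r, anc, an);
        push_edge(l, r, anc, bn);
      }
      kept.clear();
      ov_coalesce(l, r, 1, kept);
      for (auto& kp : kept) push_seg(out, kp.first, kp.second, anc);
      if (ar > r) al = r; else loadA();
      if (br > r) bl = r; else loadB();
    }
    return out;
  }

  // Merge the seglists of >= 1 children at time tt in population pop.
  // Records one ancestor node (lazily) plus edges over overlapped intervals.
  SegList merge_children(std::vector<SegList>& ch, double tt, int pop) {
    if (ch.size() == 2) return merge_two(ch[0], ch[1], tt, pop);
    struct Ev {
      double x;
      int node;
      bool open;
    };
    std::vector<Ev> evs;
    size_t tot = 0;
    for (auto& c : ch) tot += c.size();
    evs.reserve(2 * tot);
    for (auto& c : ch)
      for (auto& s : c) {
        evs.push_back({s.l, s.node, true});
        evs.push_back({s.r, s.node, false});
      }
    std::sort(evs.begin(), evs.end(), [](const Ev& a, const Ev& b) {
      return a.x < b.x || (a.x == b.x && !a.open && b.open);
    });
    SegList out;
    std::vector<int> active;
    std::vector<std::pair<double, double>> kept;
    int anc = -1;
    size_t i = 0;
    while (i < evs.size()) {
      double x = evs[i].x;
      while (i < evs.size() && evs[i].x == x) {
        if (evs[i].open)
          active.push_back(evs[i].node);
        else
          active.erase(std::find(active.begin(), active.end(), evs[i].node));
        ++i;
      }
      if (i >= evs.size() || active.empty()) continue;
      double xr = evs[i].x;
      if (xr <= x) continue;
      if (active.size() == 1) {
        push_seg(out, x, xr, active[0]);
      } else {
        if (anc < 0) anc = new_node(tt, pop, 0);
        if (record_tables)
          for (int c : active) push_edge(x, xr, anc, c);
        kept.clear();
        ov_coalesce(x, xr, (int)active.size() - 1, kept);
        for (auto& kp : kept) push_seg(out, kp.first, kp.second, anc);
      }
    }
    return out;
  }

  // ---- demographic events ------------------------------------------------
  void apply_event(const Event& e, double census_time) {
    if (e.kind == 0) {  // size_change
      N0[e.a] = e.x;
      t0[e.a] = e.time;
    } else if (e.kind == 1) {  // growth_change
      N0[e.a] = pop_size_at(e.a, e.time);
      alpha[e.a] = e.x;
      t0[e.a] = e.time;
    } else {  // pulse: dest -> source with probability f, then census
      std::vector<int> snap = members[e.a];
      for (int s : snap)
        if (unif_rand() < e.x) move_lineage(s, e.b);
      if (record_tables) {
        for (int p = 0; p < npop; ++p)
          for (int s : members[p]) {
            int cn = new_node(census_time, p, 2);
            for (Seg& sg : lins[s].segs) {
              push_edge(sg.l, sg.r, cn, sg.node);
              sg.node = cn;
            }
          }
      }
    }
  }

  void record_gen(long g) {
    trace_gen.push_back((double)g);
    trace_cnt.push_back((double)n_extant);
  }
  void advance_time(double tt) {
    if (record_trace) {
      long g0 = (long)std::floor(t) + 1, g1 = (long)std::floor(tt);
      if (tt == std::floor(tt)) --g1;  // count at an integer time is recorded
                                       // once the time is strictly passed
      for (long g = g0; g <= g1; ++g) record_gen(g);
    }
    t = tt;
  }

  // ---- Hudson phase ------------------------------------------------------
  void run_hudson() {
    if (!fen_live) {
      fen.build(mass);
      fen_live = true;
    }
    while (n_extant > 0 && t < stop_time) {
      double R = fen.total();
      double M = 0;
      if (any_mig)
        for (int i = 0; i < npop; ++i) M += members[i].size() * migrow[i];
      double t_rec = R > 0 ? t + exp_rand() / R : INF;
      double t_mig = M > 0 ? t + exp_rand() / M : INF;
      double t_ca = INF;
      int ca_pop = -1;
      for (int i = 0; i < npop; ++i) {
        double k = (double)members[i].size();
        if (k < 2) continue;
        double B = k * (k - 1) / (4.0 * pop_size_at(i, t));
        double E = exp_rand(), s;
        if (alpha[i] == 0.0) {
          s = E / B;
        } else {
          double z = 1.0 + alpha[i] * E / B;
          s = z > 0 ? std::log(z) / alpha[i] : INF;
        }
        if (t + s < t_ca) {
          t_ca = t + s;
          ca_pop = i;
        }
      }
      double tev = std::min(t_rec, std::min(t_mig, t_ca));
      double tnext =
          next_event < events.size() ? events[next_event].time : INF;
      double tstop = std::min(stop_time, tnext);
      if (tev >= tstop) {
        if (!std::isfinite(tstop)) break;  // nothing can ever happen again
        advance_time(tstop);
        if (next_event < events.size() && events[next_event].time == tstop) {
          apply_event(events[next_event], tstop);
          ++next_event;
        }
        if (t >= stop_time) break;
        continue;
      }
      advance_time(tev);
      if (tev == t_rec) {
        do_recomb(R);
        ++n_rec;
      } else if (tev == t_ca) {
        do_ca(ca_pop);
        ++n_ca;
      } else {
        do_migration(M);
        ++n_mig;
      }
      if ((++n_events & 0xfffff) == 0) Rcpp::checkUserInterrupt();
    }
    if (n_extant == 0) fully_coalesced = true;
  }

  void do_recomb(double R) {
    int s;
    do {
      s = fen.find(unif_rand() * R);
    } while (lins[s].segs.empty());
    SegList& sg = lins[s].segs;
    double a = sg.front().l, b = sg.back().r;
    double bp;
    do {
      bp = a + unif_rand() * (b - a);
    } while (bp <= a || bp >= b);
    // split at bp; copy out whichever side has fewer segments
    size_t i = 0;
    while (i < sg.size() && sg[i].r <= bp) ++i;
    bool cut = i < sg.size() && sg[i].l < bp;  // bp inside segment i
    size_t nleft = i + (cut ? 1 : 0);
    size_t nright = sg.size() - i;
    SegList other;
    if (nleft <= nright) {  // copy out the left part
      other.assign(sg.begin(), sg.begin() + (cut ? i + 1 : i));
      if (cut) {
        other.back().r = bp;
        sg.erase(sg.begin(), sg.begin() + i);
        sg.front().l = bp;
      } else {
        sg.erase(sg.begin(), sg.begin() + i);
      }
    } else {  // copy out the right part
      other.assign(sg.begin() + i, sg.end());
      if (cut) {
        other.front().l = bp;
        sg.resize(i + 1);
        sg.back().r = bp;
      } else {
        sg.resize(i);
      }
    }
    set_mass(s, sg.back().r - sg.front().l);
    insert_lineage(std::move(other), lins[s].pop);
  }

  void do_ca(int pop) {
    long k = (long)members[pop].size();
    long i1 = (long)(unif_rand() * k);
    if (i1 >= k) i1 = k - 1;
    long i2 = (long)(unif_rand() * (k - 1));
    if (i2 >= k - 1) i2 = k - 2;
    if (i2 >= i1) ++i2;
    int s1 = members[pop][i1], s2 = members[pop][i2];
    SegList c1 = std::move(lins[s1].segs);
    SegList c2 = std::move(lins[s2].segs);
    lins[s1].segs.clear();
    lins[s2].segs.clear();
    remove_lineage(s1);
    remove_lineage(s2);
    SegList merged = merge_two(c1, c2, t, pop);
    if (!merged.empty()) insert_lineage(std::move(merged), pop);
  }

  void do_migration(double M) {
    double u = unif_rand() * M;
    for (int i = 0; i < npop; ++i) {
      double ki = (double)members[i].size();
      if (ki == 0) continue;
      for (int j = 0; j < npop; ++j) {
        if (j == i || mig[i][j] == 0) continue;
        double w = ki * mig[i][j];
        if (u < w) {
          long idx = (long)(unif_rand() * ki);
          if (idx >= (long)ki) idx = (long)ki - 1;
          move_lineage(members[i][idx], j);
          return;
        }
        u -= w;
      }
    }
  }

  // ---- DTWF phase --------------------------------------------------------
  void run_dtwf(double until) {
    std::vector<int> snap;
    std::vector<Switch> sw;
    SegList hapA, hapB;
    // bucket key -> per-haplotype lists of contributed seglists
    std::unordered_map<long long, std::array<std::vector<SegList>, 2>> buckets;
    while (n_extant > 0 && t < until && t < stop_time) {
      double tn = t + 1;
      // an event at time g acts on the generation-g lineages, i.e. at the
      // start of the step from t = g to t = g + 1 (so a pulse marks the
      // ancestors g meioses above the samples, and their parents are drawn
      // from the source population)
      while (next_event < events.size() && events[next_event].time < tn) {
        apply_event(events[next_event], tn - 0.5);
        ++next_event;
      }
      // migration
      if (any_mig) {
        for (int i = 0; i < npop; ++i) {
          if (migrow[i] == 0) continue;
          snap = members[i];
          for (int s : snap) {
            double u = unif_rand();
            for (int j = 0; j < npop; ++j) {
              if (j == i) continue;
              if (u < mig[i][j]) {
                move_lineage(s, j);
                break;
              }
              u -= mig[i][j];
            }
          }
        }
      }
      // parent choice + meiosis
      buckets.clear();
      for (int i = 0; i < npop; ++i) {
        double Ni = std::round(pop_size_at(i, tn));
        if (Ni < 1) Ni = 1;
        for (int s : members[i]) {
          long long parent = (long long)(unif_rand() * Ni);
          if (parent >= (long long)Ni) parent = (long long)Ni - 1;
          const SegList& sg = lins[s].segs;
          draw_switches(map, sg.front().l, sg.back().r, sw);
          int phase = unif_rand() < 0.5 ? 0 : 1;
          split_by_switches(sg, sw, phase, hapA, hapB);
          long long key = ((long long)i << 44) | parent;
          auto& bk = buckets[key];
          if (!hapA.empty()) bk[0].push_back(hapA);
          if (!hapB.empty()) bk[1].push_back(hapB);
        }
      }
      // clear extant state, then rebuild from buckets
      for (int i = 0; i < npop; ++i) {
        for (int s : members[i]) {
          set_mass(s, 0.0);
          lins[s].segs.clear();
          free_slots.push_back(s);
        }
        members[i].clear();
      }
      n_extant = 0;
      for (auto& kv : buckets) {
        int pop = (int)(kv.first >> 44);
        for (int h = 0; h < 2; ++h) {
          std::vector<SegList>& contrib = kv.second[h];
          if (contrib.empty()) continue;
          if (contrib.size() == 1) {
            insert_lineage(std::move(contrib[0]), pop);
          } else {
            SegList merged = merge_children(contrib, tn, pop);
            if (!merged.empty()) insert_lineage(std::move(merged), pop);
          }
        }
      }
      t = tn;
      if (record_trace) record_gen((long)tn);
      if (((long)tn & 0x3ff) == 0) Rcpp::checkUserInterrupt();
    }
    if (n_extant == 0) fully_coalesced = true;
  }
};

// ---------------------------------------------------------------------------
// Entry point
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(List cfg) {
  Engine eng;
  eng.map.init(cfg["chrom_start"], cfg["chrom_end"]);
  NumericVector N0 = cfg["N0"], alpha = cfg["alpha"];
  eng.npop = N0.size();
  eng.N0.assign(N0.begin(), N0.end());
  eng.alpha.assign(alpha.begin(), alpha.end());
  eng.t0.assign(eng.npop, 0.0);
  NumericMatrix mg = cfg["migration"];
  eng.mig.assign(eng.npop, std::vector<double>(eng.npop, 0.0));
  eng.migrow.assign(eng.npop, 0.0);
  for (int i = 0; i < eng.npop; ++i)
    for (int j = 0; j < eng.npop; ++j)
      if (i != j) {
        eng.mig[i][j] = mg(i, j);
        eng.migrow[i] += mg(i, j);
        if (mg(i, j) > 0) eng.any_mig = true;
      }
  List evl = cfg["events"];
  for (int i = 0; i < evl.size(); ++i) {
    List e = evl[i];
    Event ev;
    ev.time = as<double>(e["time"]);
    std::string kind = as<std::string>(e["kind"]);
    if (kind == "size_change") {
      ev.kind = 0;
      ev.a = as<int>(e["population"]);
      ev.b = 0;
      ev.x = as<double>(e["value"]);
    } else if (kind == "growth_change") {
      ev.kind = 1;
      ev.a = as<int>(e["population"]);
      ev.b = 0;
      ev.x = as<double>(e["value"]);
    } else {
      ev.kind = 2;
      ev.a = as<int>(e["dest"]);
      ev.b = as<int>(e["source"]);
      ev.x = as<double>(e["fraction"]);
    }
    eng.events.push_back(ev);
  }
  std::stable_sort(eng.events.begin(), eng.events.end(),
                   [](const Event& a, const Event& b) { return a.time < b.time; });
  eng.record_tables = as<bool>(cfg["record_tables"]);
  eng.keep_coal = as<bool>(cfg["keep_coalesced"]);
  eng.record_trace = as<bool>(cfg["record_trace"]);
  eng.stop_time = as<double>(cfg["stop_time"]);
  int model = as<int>(cfg["model"]);  // 0 hudson, 1 dtwf, 2 hybrid
  double switch_time = as<double>(cfg["switch_time"]);

  // samples
  IntegerVector samples = cfg["samples"];
  eng.members.assign(eng.npop, std::vector<int>());
  long ntot = 0;
  for (int i = 0; i < eng.npop; ++i) ntot += samples[i];
  eng.ov[0.0] = (int)ntot;
  eng.ov[eng.map.axis_len] = 0;
  for (int i = 0; i < eng.npop; ++i)
    for (int s = 0; s < samples[i]; ++s) {
      int nd = eng.new_node(0.0, i, 1);
      SegList sg;
      sg.push_back({0.0, eng.map.axis_len, nd});
      eng.insert_lineage(std::move(sg), i);
    }
  if (eng.record_trace) eng.record_gen(0);

  if (model == 0) {
    eng.run_hudson();
  } else if (model == 1) {
    eng.run_dtwf(INF);
  } else {
    eng.run_dtwf(switch_time);
    if (eng.n_extant > 0 && eng.t < eng.stop_time) eng.run_hudson();
  }

  // finalize edges: sort by (parent time, parent, child, left), squash
  size_t ne = eng.el.size();
  std::vector<size_t> ord(ne);
  for (size_t i = 0; i < ne; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    double ta = eng.ntime[eng.ep[a]], tb = eng.ntime[eng.ep[b]];
    if (ta != tb) return ta < tb;
    if (eng.ep[a] != eng.ep[b]) return eng.ep[a] < eng.ep[b];
    if (eng.ec[a] != eng.ec[b]) return eng.ec[a] < eng.ec[b];
    return eng.el[a] < eng.el[b];
  });
  std::vector<double> fl, fr;
  std::vector<int> fp, fc;
  for (size_t k = 0; k < ne; ++k) {
    size_t i = ord[k];
    if (!fp.empty() && fp.back() == eng.ep[i] && fc.back() == eng.ec[i] &&
        fr.back() == eng.el[i]) {
      fr.back() = eng.er[i];
    } else {
      fl.push_back(eng.el[i]);
      fr.push_back(eng.er[i]);
      fp.push_back(eng.ep[i]);
      fc.push_back(eng.ec[i]);
    }
  }

  return List::create(
      _["node_time"] = wrap(eng.ntime), _["node_population"] = wrap(eng.npopv),
      _["node_flags"] = wrap(eng.nflags), _["edge_left"] = wrap(fl),
      _["edge_right"] = wrap(fr), _["edge_parent"] = wrap(fp),
      _["edge_child"] = wrap(fc), _["trace_gen"] = wrap(eng.trace_gen),
      _["trace_count"] = wrap(eng.trace_cnt),
      _["fully_coalesced"] = eng.fully_coalesced, _["end_time"] = eng.t,
      _["n_extant"] = (double)eng.n_extant,
      _["n_recomb_events"] = eng.n_rec, _["n_ca_events"] = eng.n_ca,
      _["n_migration_events"] = eng.n_mig);
}

// ---------------------------------------------------------------------------
// Forward gene-dropping through an explicit pedigree (oracle support).
// Founder haplotypes are labelled uniquely; every transmission uses the same
// meiosis model as the DTWF engine (Poisson crossovers + independent
// chromosome assortment), so comparisons against the engines are about
// genealogy, not about the recombination model.
// ---------------------------------------------------------------------------

// pieces of `h` inside the mask intervals, preserving labels
static void restrict_to(const SegList& h, const SegList& mask, SegList& out) {
  size_t i = 0, j = 0;
  while (i < h.size() && j < mask.size()) {
    double l = std::max(h[i].l, mask[j].l);
    double r = std::min(h[i].r, mask[j].r);
    if (r > l) push_seg(out, l, r, h[i].node);
    if (h[i].r < mask[j].r)
      ++i;
    else
      ++j;
  }
}

static SegList gamete(const GMap& map, const SegList& h1, const SegList& h2) {
  SegList full{{0.0, map.axis_len, 0}};
  std::vector<Switch> sw;
  draw_switches(map, 0.0, map.axis_len, sw);
  int phase = unif_rand() < 0.5 ? 0 : 1;
  SegList maskA, maskB;
  split_by_switches(full, sw, phase, maskA, maskB);
  SegList out;
  restrict_to(h1, maskA, out);
  SegList part2;
  restrict_to(h2, maskB, part2);
  out.insert(out.end(), part2.begin(), part2.end());
  std::sort(out.begin(), out.end(),
            [](const Seg& a, const Seg& b) { return a.l < b.l; });
  // squash touching pieces with equal labels
  SegList sq;
  for (auto& s : out) push_seg(sq, s.l, s.r, s.node);
  return sq;
}

// pedigree: list over generations 0..G-1; element t is an n_t x 2 integer
// matrix of (father, mother) indices (1-based) into generation t+1.
// n_founders individuals at generation G get haplotype labels 2i-1, 2i.

// [[Rcpp::export]]
DataFrame cpp_gene_drop(NumericVector chrom_start, NumericVector chrom_end,
                        List pedigree, int n_founders) {
  GMap map;
  map.init(chrom_start, chrom_end);
  int G = pedigree.size();
  std::vector<std::array<SegList, 2>> cur(n_founders), nxt;
  for (int i = 0; i < n_founders; ++i) {
    cur[i][0].push_back({0.0, map.axis_len, 2 * i + 1});
    cur[i][1].push_back({0.0, map.axis_len, 2 * i + 2});
  }
  for (int t = G - 1; t >= 0; --t) {
    IntegerMatrix par = pedigree[t];
    int n = par.nrow();
    nxt.assign(n, std::array<SegList, 2>());
    for (int i = 0; i < n; ++i) {
      int f = par(i, 0) - 1, m = par(i, 1) - 1;
      nxt[i][0] = gamete(map, cur[f][0], cur[f][1]);
      nxt[i][1] = gamete(map, cur[m][0], cur[m][1]);
    }
    cur.swap(nxt);
  }
  std::vector<int> oi, oh, olab;
  std::vector<double> ol, orr;
  for (size_t i = 0; i < cur.size(); ++i)
    for (int h = 0; h < 2; ++h)
      for (auto& s : cur[i][h]) {
        oi.push_back((int)i + 1);
        oh.push_back(h + 1);
        ol.push_back(s.l);
        orr.push_back(s.r);
        olab.push_back(s.node);
      }
  return DataFrame::create(_["individual"] = wrap(oi), _["haplotype"] = wrap(oh),
                           _["left"] = wrap(ol), _["right"] = wrap(orr),
                           _["founder_hap"] = wrap(olab));
}

// Expose the meiosis primitives for distribution-level tests.

// [[Rcpp::export]]
List cpp_draw_meiosis(NumericVector chrom_start, NumericVector chrom_end,
                      double l, double r) {
  GMap map;
  map.init(chrom_start, chrom_end);
  std::vector<Switch> sw;
  draw_switches(map, l, r, sw);
  int phase = unif_rand() < 0.5 ? 0 : 1;
  std::vector<double> bps;
  for (auto& s : sw)
    if (s.type == 0) bps.push_back(s.x);
  return List::create(_["breakpoints"] = wrap(bps), _["phase"] = phase);
}

// [[Rcpp::export]]
List cpp_split_meiosis(NumericVector chrom_start, NumericVector chrom_end,
                       NumericVector seg_left, NumericVector seg_right,
                       IntegerVector seg_node) {
  GMap map;
  map.init(chrom_start, chrom_end);
  SegList segs;
  for (int i = 0; i < seg_left.size(); ++i)
    segs.push_back({seg_left[i], seg_right[i], seg_node[i]});
  std::vector<Switch> sw;
  draw_switches(map, segs.front().l, segs.back().r, sw);
  int phase = unif_rand() < 0.5 ? 0 : 1;
  SegList A, B;
  split_by_switches(segs, sw, phase, A, B);
  auto tab = [](const SegList& s) {
    NumericVector l(s.size()), r(s.size());
    IntegerVector nd(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
      l[i] = s[i].l;
      r[i] = s[i].r;
      nd[i] = s[i].node;
    }
    return DataFrame::create(_["left"] = l, _["right"] = r, _["node"] = nd);
  };
  return List::create(_["A"] = tab(A), _["B"] = tab(B), _["phase"] = phase);
}
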