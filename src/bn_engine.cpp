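// Intervention-aware BDeu scoring and DAG structure search.
//
// Data layout: states is an (n_nodes x n_samples) integer matrix of 0-based
// states; clamped marks (node, sample) cells fixed by a knockout. A clamped
// sample is excluded from that node's own family counts but still serves as
// a parent observation for its children (interventional likelihood).
//
// Structures are vectors of parent bitmasks (<= 64 nodes). Family scores are
// cached per (node, parent-mask); the cache is shared across restarts, so
// repeated evaluations are exact re-reads, never re-computations.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <map>
#include <set>
#include <unordered_map>
#include <vector>

using namespace Rcpp;
typedef uint64_t mask_t;

static inline int popcount64(mask_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

struct Scorer {
  const IntegerMatrix states;
  const LogicalMatrix clamped;
  const IntegerVector arity;
  double ess;
  int n, N;
  std::vector<std::unordered_map<mask_t, double> > cache;

  Scorer(IntegerMatrix st, LogicalMatrix cl, IntegerVector ar, double e)
      : states(st), clamped(cl), arity(ar), ess(e) {
    n = states.nrow();
    N = states.ncol();
    cache.resize(n);
  }

  double family(int v, mask_t pmask) {
    std::unordered_map<mask_t, double>::iterator it = cache[v].find(pmask);
    if (it != cache[v].end()) return it->second;
    std::vector<int> ps;
    for (int u = 0; u < n; ++u)
      if ((pmask >> u) & 1) ps.push_back(u);
    long q = 1;
    for (size_t i = 0; i < ps.size(); ++i) q *= arity[ps[i]];
    int r = arity[v];
    std::vector<int> cnt((size_t)q * r, 0);
    for (int s = 0; s < N; ++s) {
      if (clamped(v, s)) continue;
      long j = 0, mult = 1;
      for (size_t i = 0; i < ps.size(); ++i) {
        j += mult * states(ps[i], s);
        mult *= arity[ps[i]];
      }
      cnt[(size_t)j * r + states(v, s)]++;
    }
    double aj = ess / (double)q;
    double ajk = ess / ((double)q * r);
    double sc = 0.0;
    for (long j = 0; j < q; ++j) {
      int Nj = 0;
      for (int k = 0; k < r; ++k) Nj += cnt[(size_t)j * r + k];
      if (Nj == 0) continue;
      sc += std::lgamma(aj) - std::lgamma(aj + Nj);
      for (int k = 0; k < r; ++k) {
        int c = cnt[(size_t)j * r + k];
        if (c > 0) sc += std::lgamma(ajk + c) - std::lgamma(ajk);
      }
    }
    cache[v][pmask] = sc;
    return sc;
  }
};

// is there a directed path from `from` to `to`?
static bool has_path(const std::vector<mask_t>& pa, int n, int from, int to) {
  if (from == to) return true;
  mask_t visited = 0, frontier = ((mask_t)1) << from;
  while (frontier) {
    visited |= frontier;
    mask_t next = 0;
    for (int w = 0; w < n; ++w) {
      if ((visited >> w) & 1) continue;
      // w is a child of any frontier node?
      if (pa[w] & frontier) next |= ((mask_t)1) << w;
    }
    if ((next >> to) & 1) return true;
    frontier = next;
  }
  return false;
}

struct Move {
  int type;  // 0 add u->v, 1 delete u->v, 2 reverse u->v (to v->u)
  int u, v;
};

struct TopK {
  size_t capacity;
  // ordered worst-first: (score, structure); dedup by structure
  std::set<std::pair<double, std::vector<mask_t> > > heap;
  std::set<std::vector<mask_t> > members;

  TopK(size_t k) : capacity(k) {}

  void offer(double score, const std::vector<mask_t>& pa) {
    if (heap.size() >= capacity && score <= heap.begin()->first) return;
    if (members.count(pa)) return;
    heap.insert(std::make_pair(score, pa));
    members.insert(pa);
    if (heap.size() > capacity) {
      members.erase(heap.begin()->second);
      heap.erase(heap.begin());
    }
  }
};

struct Search {
  Scorer& scorer;
  const IntegerVector role;  // 0 free, 1 root-only, 2 leaf-only
  int max_par;
  int n;
  std::vector<mask_t> pa;
  double cur;
  TopK& topk;

  Search(Scorer& sc, IntegerVector ro, int mp, TopK& tk)
      : scorer(sc), role(ro), max_par(mp), n(sc.n), topk(tk) {
    pa.assign(n, 0);
    cur = full_score();
  }

  double full_score() {
    double s = 0;
    for (int v = 0; v < n; ++v) s += scorer.family(v, pa[v]);
    return s;
  }

  void reset_random(int init_edges) {
    pa.assign(n, 0);
    for (int t = 0; t < init_edges; ++t) {
      int u = (int)(R::unif_rand() * n);
      int v = (int)(R::unif_rand() * n);
      if (u >= n) u = n - 1;
      if (v >= n) v = n - 1;
      if (u == v) continue;
      if (role[u] == 2 || role[v] == 1) continue;
      if ((pa[v] >> u) & 1) continue;
      if (popcount64(pa[v]) >= max_par) continue;
      if (has_path(pa, n, v, u)) continue;
      pa[v] |= ((mask_t)1) << u;
    }
    cur = full_score();
    topk.offer(cur, pa);
  }

  void legal_moves(std::vector<Move>& out) {
    out.clear();
    for (int u = 0; u < n; ++u) {
      for (int v = 0; v < n; ++v) {
        if (u == v) continue;
        bool edge = (pa[v] >> u) & 1;
        if (edge) {
          Move d = {1, u, v};
          out.push_back(d);
          // reverse u->v into v->u
          if (role[v] != 2 && role[u] != 1 &&
              popcount64(pa[u]) < max_par) {
            std::vector<mask_t> tmp = pa;
            tmp[v] &= ~(((mask_t)1) << u);
            if (!has_path(tmp, n, u, v)) {
              Move r = {2, u, v};
              out.push_back(r);
            }
          }
        } else {
          if (role[u] == 2 || role[v] == 1) continue;
          if (popcount64(pa[v]) >= max_par) continue;
          if (has_path(pa, n, v, u)) continue;
          Move a = {0, u, v};
          out.push_back(a);
        }
      }
    }
  }

  double delta(const Move& m) {
    mask_t bu = ((mask_t)1) << m.u;
    mask_t bv = ((mask_t)1) << m.v;
    switch (m.type) {
      case 0:
        return scorer.family(m.v, pa[m.v] | bu) - scorer.family(m.v, pa[m.v]);
      case 1:
        return scorer.family(m.v, pa[m.v] & ~bu) - scorer.family(m.v, pa[m.v]);
      default:
        return scorer.family(m.v, pa[m.v] & ~bu) - scorer.family(m.v, pa[m.v]) +
               scorer.family(m.u, pa[m.u] | bv) - scorer.family(m.u, pa[m.u]);
    }
  }

  void apply(const Move& m) {
    mask_t bu = ((mask_t)1) << m.u;
    mask_t bv = ((mask_t)1) << m.v;
    if (m.type == 0) {
      pa[m.v] |= bu;
    } else if (m.type == 1) {
      pa[m.v] &= ~bu;
    } else {
      pa[m.v] &= ~bu;
      pa[m.u] |= bv;
    }
  }

  // offer the neighbour reached by m without applying it
  void offer_neighbour(const Move& m, double nscore) {
    std::vector<mask_t> tmp = pa;
    mask_t bu = ((mask_t)1) << m.u;
    mask_t bv = ((mask_t)1) << m.v;
    if (m.type == 0) {
      tmp[m.v] |= bu;
    } else if (m.type == 1) {
      tmp[m.v] &= ~bu;
    } else {
      tmp[m.v] &= ~bu;
      tmp[m.u] |= bv;
    }
    topk.offer(nscore, tmp);
  }

  void greedy() {
    std::vector<Move> moves;
    for (;;) {
      legal_moves(moves);
      double best = 0.0;
      int besti = -1;
      for (size_t i = 0; i < moves.size(); ++i) {
        double d = delta(moves[i]);
        offer_neighbour(moves[i], cur + d);
        if (d > best + 1e-10) {
          best = d;
          besti = (int)i;
        }
      }
      if (besti < 0) break;
      apply(moves[besti]);
      cur += best;
    }
  }

  void anneal(double t0, double cooling, int moves_per_temp, int n_temps) {
    std::vector<Move> moves;
    if (t0 <= 0) {
      // self-scaling start: spread of random-move deltas from here
      legal_moves(moves);
      if (moves.empty()) return;
      double sum = 0, sum2 = 0;
      int m = 100;
      for (int i = 0; i < m; ++i) {
        int k = (int)(R::unif_rand() * moves.size());
        if ((size_t)k >= moves.size()) k = (int)moves.size() - 1;
        double d = delta(moves[k]);
        sum += d;
        sum2 += d * d;
      }
      double var = sum2 / m - (sum / m) * (sum / m);
      t0 = var > 0 ? std::sqrt(var) : 1.0;
    }
    double T = t0;
    for (int t = 0; t < n_temps; ++t) {
      for (int k = 0; k < moves_per_temp; ++k) {
        legal_moves(moves);
        if (moves.empty()) return;
        int idx = (int)(R::unif_rand() * moves.size());
        if ((size_t)idx >= moves.size()) idx = (int)moves.size() - 1;
        double d = delta(moves[idx]);
        offer_neighbour(moves[idx], cur + d);
        if (d > 0 || R::unif_rand() < std::exp(d / T)) {
          apply(moves[idx]);
          cur += d;
          topk.offer(cur, pa);
        }
      }
      T *= cooling;
    }
  }
};

// [[Rcpp::export]]
double cpp_family_score(IntegerMatrix states, LogicalMatrix clamped,
                        IntegerVector arity, int node,
                        IntegerVector parents, double ess) {
  Scorer sc(states, clamped, arity, ess);
  mask_t pmask = 0;
  for (int i = 0; i < parents.size(); ++i)
    pmask |= ((mask_t)1) << (parents[i] - 1);
  return sc.family(node - 1, pmask);
}

// [[Rcpp::export]]
List cpp_learn(IntegerMatrix states, LogicalMatrix clamped,
               IntegerVector arity, IntegerVector role, double ess,
               int max_in_degree, std::string strategy, int restarts,
               double sa_initial_temp, double sa_cooling,
               int moves_per_temp, int n_temps, int top_k) {
  int n = states.nrow();
  if (n < 1) stop("zero nodes");
  if (n > 64) stop("engine supports at most 64 nodes");
  Scorer scorer(states, clamped, arity, ess);
  TopK topk((size_t)top_k);
  Search search(scorer, role, max_in_degree, topk);

  bool do_greedy = strategy == "greedy" || strategy == "greedy_plus_sa";
  bool do_sa = strategy == "sa" || strategy == "greedy_plus_sa";

  for (int rep = 0; rep < restarts; ++rep) {
    search.reset_random(rep == 0 ? 0 : n);  // first restart from empty graph
    if (do_greedy) search.greedy();
    if (do_sa) {
      search.anneal(sa_initial_temp, sa_cooling, moves_per_temp, n_temps);
      if (do_greedy) search.greedy();
    }
    Rcpp::checkUserInterrupt();
  }

  // export best-first
  int k = (int)topk.heap.size();
  NumericVector scores(k);
  List structures(k);
  int i = 0;
  for (std::set<std::pair<double, std::vector<mask_t> > >::reverse_iterator
           it = topk.heap.rbegin();
       it != topk.heap.rend(); ++it, ++i) {
    scores[i] = it->first;
    int ne = 0;
    for (int v = 0; v < n; ++v) ne += popcount64(it->second[v]);
    IntegerMatrix edges(ne, 2);
    int e = 0;
    for (int v = 0; v < n; ++v)
      for (int u = 0; u < n; ++u)
        if ((it->second[v] >> u) & 1) {
          edges(e, 0) = u + 1;
          edges(e, 1) = v + 1;
          ++e;
        }
    structures[i] = edges;
  }
  return List::create(Named("scores") = scores,
                      Named("structures") = structures);
}
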