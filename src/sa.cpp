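// Simulated-annealing modularity maximisation on an undirected simple
// graph. Move set per temperature: f*S^2 single-node reassignments and
// f*S collective proposals (merge of two modules or split of one), with
// Metropolis acceptance exp(dQ/T). Deterministic given an integer seed:
// randomness comes from a local splitmix64 stream, never from R's RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SARng {
  uint64_t s;
  explicit SARng(uint32_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

struct State {
  int n;
  double L;                           // edge count
  const std::vector<std::vector<int>>& adj;
  std::vector<double> deg;            // node degree
  std::vector<int> memb;              // node -> community id
  std::vector<double> lin, dtot;      // per community: internal edges, degree sum
  std::vector<std::vector<int>> members;
  std::vector<int> pos;               // node position inside members[c]
  std::vector<int> active;            // active community ids
  std::vector<int> active_pos;        // community id -> index in active (-1 if empty)
  double Q;

  State(int n_, double L_, const std::vector<std::vector<int>>& adj_)
    : n(n_), L(L_), adj(adj_), deg(n_), memb(n_), lin(n_, 0.0), dtot(n_, 0.0),
      members(n_), pos(n_), active_pos(n_, -1), Q(0.0) {
    for (int v = 0; v < n; ++v) deg[v] = (double)adj[v].size();
    for (int v = 0; v < n; ++v) {
      memb[v] = v;
      dtot[v] = deg[v];
      members[v].push_back(v);
      pos[v] = 0;
      active_pos[v] = (int)active.size();
      active.push_back(v);
    }
    Q = recompute();
  }

  double recompute() const {
    if (L <= 0) return 0.0;
    std::vector<double> l2(n, 0.0), d2(n, 0.0);
    for (int v = 0; v < n; ++v) {
      d2[memb[v]] += deg[v];
      for (int u : adj[v]) if (memb[u] == memb[v] && u > v) l2[memb[v]] += 1.0;
    }
    double q = 0.0;
    for (int c = 0; c < n; ++c) {
      double ds = d2[c] / (2.0 * L);
      q += l2[c] / L - ds * ds;
    }
    return q;
  }

  int links_to(int v, int c) const {
    int e = 0;
    for (int u : adj[v]) if (memb[u] == c) ++e;
    return e;
  }

  // dQ of moving v from its community a to community b (a != b)
  double dq_move(int v, int b, int& e_va, int& e_vb) const {
    int a = memb[v];
    e_va = links_to(v, a);
    e_vb = links_to(v, b);
    double k = deg[v];
    return (e_vb - e_va) / L + k * (dtot[a] - dtot[b] - k) / (2.0 * L * L);
  }

  void deactivate(int c) {
    int idx = active_pos[c];
    int last = active.back();
    active[idx] = last;
    active_pos[last] = idx;
    active.pop_back();
    active_pos[c] = -1;
  }

  void activate(int c) {
    active_pos[c] = (int)active.size();
    active.push_back(c);
  }

  void move_node(int v, int b, int e_va, int e_vb, double dq) {
    int a = memb[v];
    lin[a] -= e_va; lin[b] += e_vb;
    dtot[a] -= deg[v]; dtot[b] += deg[v];
    // remove from members[a]
    int idx = pos[v];
    int last = members[a].back();
    members[a][idx] = last;
    pos[last] = idx;
    members[a].pop_back();
    // append to members[b]
    pos[v] = (int)members[b].size();
    members[b].push_back(v);
    memb[v] = b;
    if (members[a].empty()) deactivate(a);
    Q += dq;
  }

  int free_community() const {
    // any id with no members; active_pos == -1 marks empty
    for (int c = 0; c < n; ++c) if (active_pos[c] == -1) return c;
    return -1;
  }

  // edges between communities a and b
  double edges_between(int a, int b) const {
    const std::vector<int>& small = members[a].size() <= members[b].size()
      ? members[a] : members[b];
    int other = (members[a].size() <= members[b].size()) ? b : a;
    double e = 0.0;
    for (int v : small) for (int u : adj[v]) if (memb[u] == other) e += 1.0;
    return e;
  }

};

} // namespace

// [[Rcpp::export(name = ".sa_anneal")]]
List sa_anneal(int n, IntegerVector edge_from, IntegerVector edge_to,
               double T0, double cooling, double f, int seed,
               bool check = false) {
  if (cooling <= 0.0 || cooling >= 1.0) stop("cooling factor must be in (0, 1)");
  if (f <= 0.0) stop("moves-per-temperature factor must be positive");
  int m = edge_from.size();
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < m; ++e) {
    int a = edge_from[e], b = edge_to[e];
    if (a < 0 || a >= n || b < 0 || b >= n) stop("edge endpoint out of range");
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  if (m == 0) {
    IntegerVector memb(n);
    for (int v = 0; v < n; ++v) memb[v] = v + 1;
    return List::create(_["membership"] = memb, _["modularity"] = 0.0,
                        _["temperatures"] = 0, _["max_check_err"] = 0.0,
                        _["T0"] = T0);
  }

  State st(n, (double)m, adj);
  SARng rng((uint32_t)seed);

  // auto temperature: start hot relative to the typical |dQ| of random
  // single moves so the chain can leave any initial configuration; the
  // floor keeps small sparse graphs from freezing into local optima
  if (!R_finite(T0) || T0 <= 0.0) {
    double acc = 0.0; int cnt = 0;
    int trials = std::min(1000, 20 * n);
    for (int t = 0; t < trials; ++t) {
      int v = rng.unif_int(n);
      int b = st.active[rng.unif_int((int)st.active.size())];
      if (b == st.memb[v]) continue;
      int e_va, e_vb;
      double dq = st.dq_move(v, b, e_va, e_vb);
      if (dq < 0) { acc += -dq; ++cnt; }
    }
    T0 = cnt > 0 ? 8.0 * (acc / cnt) : 0.05;
    if (T0 < 0.05) T0 = 0.05;
  }

  std::vector<int> best_memb = st.memb;
  double best_q = st.Q;
  double max_err = 0.0;
  double T = T0;
  int stall = 0, temps = 0;
  const int max_temps = 20000;
  std::vector<int> grp(n, 0);  // scratch for split proposals

  while (temps < max_temps && T > 1e-12) {
    ++temps;
    int S = (int)st.active.size();
    long nsingle = (long)std::ceil(f * (double)S * (double)S);
    long ncoll = (long)std::ceil(f * (double)S);
    long proposed = 0, accepted = 0;

    for (long it = 0; it < nsingle; ++it) {
      int v = rng.unif_int(n);
      if ((int)st.active.size() < 2) break;
      int b = st.active[rng.unif_int((int)st.active.size())];
      if (b == st.memb[v]) continue;
      ++proposed;
      int e_va, e_vb;
      double dq = st.dq_move(v, b, e_va, e_vb);
      if (dq > 0 || rng.unif() < std::exp(dq / T)) {
        st.move_node(v, b, e_va, e_vb, dq);
        ++accepted;
        if (check) {
          double err = std::fabs(st.Q - st.recompute());
          if (err > max_err) max_err = err;
        }
        if (st.Q > best_q) { best_q = st.Q; best_memb = st.memb; }
      }
    }

    for (long it = 0; it < ncoll; ++it) {
      int Sa = (int)st.active.size();
      bool do_merge = (Sa >= 2) && (rng.unif() < 0.5);
      if (do_merge) {
        int ai = rng.unif_int(Sa), bi = rng.unif_int(Sa);
        if (ai == bi) continue;
        int a = st.active[ai], b = st.active[bi];
        ++proposed;
        double e_ab = st.edges_between(a, b);
        double dq = e_ab / st.L
          - st.dtot[a] * st.dtot[b] / (2.0 * st.L * st.L);
        if (dq > 0 || rng.unif() < std::exp(dq / T)) {
          // manual merge keeping Q consistent
          st.lin[a] += st.lin[b] + e_ab;
          st.dtot[a] += st.dtot[b];
          std::vector<int> bm = st.members[b];
          for (int v : bm) {
            st.memb[v] = a;
            st.pos[v] = (int)st.members[a].size();
            st.members[a].push_back(v);
          }
          st.members[b].clear();
          st.lin[b] = 0.0; st.dtot[b] = 0.0;
          st.deactivate(b);
          st.Q += dq;
          ++accepted;
          if (check) {
            double err = std::fabs(st.Q - st.recompute());
            if (err > max_err) max_err = err;
          }
          if (st.Q > best_q) { best_q = st.Q; best_memb = st.memb; }
        }
      } else {
        // split proposal: random bisection of one module, refined by
        // greedy single-node passes within the bisection, then Metropolis
        int c = st.active[rng.unif_int(Sa)];
        int sz = (int)st.members[c].size();
        if (sz < 2) continue;
        int cnew = st.free_community();
        if (cnew < 0) continue;
        ++proposed;
        for (int v : st.members[c]) grp[v] = (int)(rng.next() & 1u);
        double d0 = 0.0, d1 = 0.0;
        for (int v : st.members[c]) (grp[v] ? d1 : d0) += st.deg[v];
        for (int pass = 0; pass < 3; ++pass) {
          bool moved = false;
          for (int v : st.members[c]) {
            int e0 = 0, e1 = 0;
            for (int u : st.adj[v]) if (st.memb[u] == c)
              (grp[u] ? e1 : e0) += 1;
            double k = st.deg[v];
            double dq_loc;
            if (grp[v] == 0)
              dq_loc = (e1 - e0) / st.L + k * (d0 - d1 - k) / (2.0 * st.L * st.L);
            else
              dq_loc = (e0 - e1) / st.L + k * (d1 - d0 - k) / (2.0 * st.L * st.L);
            if (dq_loc > 1e-15) {
              if (grp[v] == 0) { grp[v] = 1; d0 -= k; d1 += k; }
              else { grp[v] = 0; d1 -= k; d0 += k; }
              moved = true;
            }
          }
          if (!moved) break;
        }
        if (d0 == 0.0 || d1 == 0.0) continue; // degenerate bisection
        int n1 = 0;
        for (int v : st.members[c]) n1 += grp[v];
        if (n1 == 0 || n1 == sz) continue;
        double e01 = 0.0;
        for (int v : st.members[c]) if (grp[v] == 0)
          for (int u : st.adj[v]) if (st.memb[u] == c && grp[u] == 1) e01 += 1.0;
        double dq = -e01 / st.L + d0 * d1 / (2.0 * st.L * st.L);
        if (dq > 0 || rng.unif() < std::exp(dq / T)) {
          // execute split: move group-1 members into cnew
          double l1 = 0.0;
          std::vector<int> movers;
          for (int v : st.members[c]) if (grp[v] == 1) movers.push_back(v);
          for (int v : movers) for (int u : st.adj[v])
            if (st.memb[u] == c && grp[u] == 1 && u > v) l1 += 1.0;
          st.activate(cnew);
          for (int v : movers) {
            int idx = st.pos[v];
            int last = st.members[c].back();
            st.members[c][idx] = last;
            st.pos[last] = idx;
            st.members[c].pop_back();
            st.pos[v] = (int)st.members[cnew].size();
            st.members[cnew].push_back(v);
            st.memb[v] = cnew;
          }
          st.lin[cnew] = l1;
          st.lin[c] -= l1 + e01;
          st.dtot[cnew] = d1;
          st.dtot[c] -= d1;
          st.Q += dq;
          ++accepted;
          if (check) {
            double err = std::fabs(st.Q - st.recompute());
            if (err > max_err) max_err = err;
          }
          if (st.Q > best_q) { best_q = st.Q; best_memb = st.memb; }
        }
      }
    }

    double rate = proposed > 0 ? (double)accepted / (double)proposed : 0.0;
    if (rate < 0.001) ++stall; else stall = 0;
    if (stall >= 3) break;
    T *= cooling;
  }

  // compact labels to 1..S by first appearance
  std::vector<int> relab(n, 0);
  int next_id = 0;
  IntegerVector memb_out(n);
  for (int v = 0; v < n; ++v) {
    int c = best_memb[v];
    if (relab[c] == 0) relab[c] = ++next_id;
    memb_out[v] = relab[c];
  }
  // recompute Q of the best partition from scratch for reporting
  State fin(n, (double)m, adj);
  fin.memb = best_memb;
  double q_best = fin.recompute();

  return List::create(_["membership"] = memb_out, _["modularity"] = q_best,
                      _["temperatures"] = temps, _["max_check_err"] = max_err,
                      _["T0"] = T0);
}
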