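// Constrained simulated-annealing modularity maximization for directed
// weighted networks. Move units are single nodes or locked bilateral
// pairs (both members always reassigned together). Each temperature
// stage runs unit-move proposals followed by cluster-merge proposals,
// both accepted by a metropolis rule on the exact incremental dQ.
//
// Adjacency convention: A(i, j) = weight from node j to node i, so the
// modularity null term pairs the receiver's in-strength with the
// sender's out-strength. Self-loops are always within-cluster and are
// carried through every incremental update unchanged.
//
// RNG is a self-contained PCG32 seeded from the caller, so a run is a
// pure function of (network, pairing, schedule, seed) independent of
// R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

struct Pcg32 {
  uint64_t state, inc;
  explicit Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += 0x853c49e6748fea9bULL + seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

class Annealer {
public:
  int n;                       // nodes
  const NumericMatrix A;
  std::vector<double> s_in, s_out;
  double w;
  int n_units;
  std::vector<std::vector<int>> units;   // unit -> member nodes (1 or 2)
  std::vector<int> unit_of;              // node -> unit
  std::vector<int> label;                // node -> cluster (0..n_units-1)
  std::vector<std::vector<int>> members; // cluster -> nodes
  std::vector<double> sin_c, sout_c;     // per-cluster strength sums
  double Q;                              // current modularity

  Annealer(const NumericMatrix& A_, const IntegerVector& partner)
    : A(A_) {
    n = A.nrow();
    s_in.assign(n, 0.0); s_out.assign(n, 0.0); w = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double a = A(i, j);
        s_in[i] += a; s_out[j] += a; w += a;
      }
    unit_of.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      if (unit_of[i] >= 0) continue;
      std::vector<int> u; u.push_back(i);
      int p = partner[i];
      if (p >= 0) u.push_back(p);
      int id = (int)units.size();
      for (int m : u) unit_of[m] = id;
      units.push_back(u);
    }
    n_units = (int)units.size();
    label.assign(n, 0);
    members.assign(n_units, {});
    sin_c.assign(n_units, 0.0);
    sout_c.assign(n_units, 0.0);
  }

  void assign_random(Pcg32& rng) {
    for (auto& m : members) m.clear();
    std::fill(sin_c.begin(), sin_c.end(), 0.0);
    std::fill(sout_c.begin(), sout_c.end(), 0.0);
    for (int u = 0; u < n_units; ++u) {
      int c = rng.below(n_units);
      for (int node : units[u]) {
        label[node] = c;
        members[c].push_back(node);
        sin_c[c] += s_in[node];
        sout_c[c] += s_out[node];
      }
    }
    Q = full_q();
  }

  double full_q() const {
    double q = 0.0;
    for (int c = 0; c < n_units; ++c) {
      if (members[c].empty()) continue;
      double intra = 0.0;
      for (int i : members[c])
        for (int j : members[c]) intra += A(i, j);
      q += intra - sin_c[c] * sout_c[c] / w;
    }
    return q / w;
  }

  // combined in+out weight between unit u's nodes and cluster c,
  // excluding the unit's own members
  double link_unit_cluster(int u, int c) const {
    double l = 0.0;
    for (int m : members[c]) {
      if (unit_of[m] == u) continue;
      for (int node : units[u]) l += A(node, m) + A(m, node);
    }
    return l;
  }

  double dq_move(int u, int from, int to) const {
    if (from == to) return 0.0;
    double si_u = 0.0, so_u = 0.0;
    for (int node : units[u]) { si_u += s_in[node]; so_u += s_out[node]; }
    double dqw = link_unit_cluster(u, to) - link_unit_cluster(u, from)
      - (si_u * sout_c[to] + so_u * sin_c[to]) / w
      + (si_u * (sout_c[from] - so_u) + so_u * (sin_c[from] - si_u)) / w;
    return dqw / w;
  }

  void apply_move(int u, int from, int to) {
    for (int node : units[u]) {
      auto& mv = members[from];
      mv.erase(std::find(mv.begin(), mv.end(), node));
      members[to].push_back(node);
      label[node] = to;
      sin_c[from] -= s_in[node]; sout_c[from] -= s_out[node];
      sin_c[to] += s_in[node]; sout_c[to] += s_out[node];
    }
  }

  double dq_merge(int c, int d) const {
    double l = 0.0;
    for (int i : members[c])
      for (int j : members[d]) l += A(i, j) + A(j, i);
    return (l - (sin_c[c] * sout_c[d] + sout_c[c] * sin_c[d]) / w) / w;
  }

  void apply_merge(int into, int from) {
    for (int node : members[from]) {
      label[node] = into;
      members[into].push_back(node);
    }
    members[from].clear();
    sin_c[into] += sin_c[from]; sout_c[into] += sout_c[from];
    sin_c[from] = 0.0; sout_c[from] = 0.0;
  }

  std::vector<int> nonempty() const {
    std::vector<int> out;
    for (int c = 0; c < n_units; ++c)
      if (!members[c].empty()) out.push_back(c);
    return out;
  }

  int separated_pairs() const {
    int sep = 0;
    for (const auto& u : units)
      if (u.size() == 2 && label[u[0]] != label[u[1]]) ++sep;
    return sep;
  }
};

static bool metropolis(double dq, double T, Pcg32& rng) {
  if (dq >= 0) return true;
  return rng.unif() < std::exp(dq / T);
}

// [[Rcpp::export(name = ".cpp_anneal")]]
List cpp_anneal(NumericMatrix A, IntegerVector partner,
                double T0, double cool, int node_moves_factor,
                double T_min, int stall_limit, double seed) {
  Annealer ann(A, partner);
  if (ann.w <= 0) stop("total weight must be positive");
  Pcg32 rng((uint64_t)seed);
  ann.assign_random(rng);

  // temperature calibration: probe negative-dQ magnitudes from the
  // random start so initial acceptance of a median bad move is ~1/2
  if (T0 <= 0) {
    std::vector<double> neg;
    for (int t = 0; t < 100; ++t) {
      int u = rng.below(ann.n_units);
      int v = rng.below(ann.n_units);
      int to = ann.label[ann.units[v][0]];
      double dq = ann.dq_move(u, ann.label[ann.units[u][0]], to);
      if (dq < 0) neg.push_back(-dq);
    }
    if (neg.empty()) {
      T0 = 0.05;
    } else {
      std::sort(neg.begin(), neg.end());
      T0 = neg[neg.size() / 2] / std::log(2.0);
      if (T0 <= 0 || !std::isfinite(T0)) T0 = 0.05;
    }
  }

  if (T_min <= 0) T_min = T0 / 1000.0;
  int node_moves = std::max(1, node_moves_factor * ann.n_units);
  double best_q = ann.Q;
  std::vector<int> best_label = ann.label;
  std::vector<double> q_trace, acc_trace;
  std::vector<int> sep_trace;

  // One cooling cycle of unit-level metropolis moves. Targets are
  // uniform over all cluster slots: empty slots act as fresh clusters,
  // so new clusters can nucleate at any time.
  auto node_cycle = [&](double T_start) {
    double T = T_start;
    int stall = 0;
    while (T > T_min) {
      int accepted = 0, proposed = 0;
      for (int m = 0; m < node_moves; ++m) {
        int u = rng.below(ann.n_units);
        int from = ann.label[ann.units[u][0]];
        int to = rng.below(ann.n_units);
        if (to == from) continue;
        ++proposed;
        double dq = ann.dq_move(u, from, to);
        if (metropolis(dq, T, rng)) {
          ann.apply_move(u, from, to);
          ann.Q += dq;
          ++accepted;
          if (ann.Q > best_q) { best_q = ann.Q; best_label = ann.label; }
        }
      }
      // kill incremental drift and keep the trace exact
      ann.Q = ann.full_q();
      if (ann.Q > best_q) { best_q = ann.Q; best_label = ann.label; }
      int sep = ann.separated_pairs();
      if (sep != 0) stop("internal error: bilateral pair separated during annealing");
      sep_trace.push_back(sep);
      if (!q_trace.empty() && best_q <= q_trace.back() + 1e-12) ++stall; else stall = 0;
      q_trace.push_back(best_q);
      acc_trace.push_back(proposed > 0 ? (double)accepted / proposed : 0.0);
      if (stall >= stall_limit) break;
      T *= cool;
    }
  };

  // Cluster-level metropolis merging at the stop temperature: after a
  // node-level optimum is reached, merging whole clusters can still
  // raise Q; run sweeps until a full sweep accepts nothing.
  auto merge_phase = [&]() {
    bool any = true;
    while (any) {
      any = false;
      std::vector<int> live = ann.nonempty();
      int sweeps = (int)live.size();
      for (int m = 0; m < sweeps && (int)live.size() >= 2; ++m) {
        int ci = rng.below((int)live.size());
        int di = rng.below((int)live.size());
        if (ci == di) continue;
        int c = live[ci], d = live[di];
        double dq = ann.dq_merge(c, d);
        if (metropolis(dq, T_min, rng)) {
          ann.apply_merge(c, d);
          ann.Q += dq;
          if (dq > 0) any = true;
          live = ann.nonempty();
          if (ann.Q > best_q) { best_q = ann.Q; best_label = ann.label; }
        }
      }
      ann.Q = ann.full_q();
      if (ann.Q > best_q) { best_q = ann.Q; best_label = ann.label; }
    }
  };

  // Alternate node-level cooling cycles with cluster-merge phases until
  // a full alternation no longer improves the best solution; reheats
  // shrink geometrically.
  const int max_alt = 6;
  double T_start = T0;
  for (int alt = 0; alt < max_alt; ++alt) {
    double before = best_q;
    node_cycle(T_start);
    merge_phase();
    if (best_q <= before + 1e-12) break;
    T_start = std::max(T_start * 0.25, T_min * 30.0);
  }

  return List::create(
    _["assign"] = IntegerVector(best_label.begin(), best_label.end()),
    _["best_q"] = best_q,
    _["q_trace"] = NumericVector(q_trace.begin(), q_trace.end()),
    _["acceptance_trace"] = NumericVector(acc_trace.begin(), acc_trace.end()),
    _["sep_trace"] = IntegerVector(sep_trace.begin(), sep_trace.end()),
    _["n_stages"] = (int)q_trace.size(),
    _["T0"] = T0);
}
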