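// Simulated-annealing sampler over injective node mappings V1 -> V2 with
// incremental (delta) scoring for the EC, S3 and node-similarity objectives.
// All randomness flows through a private mt19937_64 stream so runs are
// bit-reproducible for a given seed on any platform.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
using namespace Rcpp;

namespace {

enum Obj { OBJ_EC = 0, OBJ_S3 = 1, OBJ_NODESIM = 2 };

struct SAState {
  std::vector<std::vector<int> > adj1, adj2;  // sorted adjacency, 0-based
  int n1, n2, m1;
  int obj;
  const double *sim;  // n1 x n2 column-major, or NULL
  std::vector<int> a;        // alignment: g1 node -> g2 node
  std::vector<int> rev;      // g2 node -> g1 node or -1
  std::vector<char> used;    // g2 node in image?
  std::vector<int> freev;    // unused g2 nodes
  std::vector<int> free_pos; // position of g2 node in freev, -1 if used
  long long c;   // conserved edges
  long long i2;  // G2 edges induced on the image
  double S;      // sum of pair similarities

  bool adj2_has(int x, int y) const {
    const std::vector<int> &nb = adj2[x];
    return std::binary_search(nb.begin(), nb.end(), y);
  }
  double simval(int u, int q) const { return sim[(size_t)q * n1 + u]; }

  void init_counters() {
    c = 0; i2 = 0; S = 0.0;
    for (int u = 0; u < n1; ++u) {
      for (size_t j = 0; j < adj1[u].size(); ++j) {
        int w = adj1[u][j];
        if (w > u && adj2_has(a[u], a[w])) ++c;
      }
      if (obj == OBJ_NODESIM) S += simval(u, a[u]);
    }
    for (int x = 0; x < n2; ++x) {
      if (!used[x]) continue;
      for (size_t j = 0; j < adj2[x].size(); ++j) {
        int y = adj2[x][j];
        if (y > x && used[y]) ++i2;
      }
    }
  }

  double score_from(long long cc, long long ii2, double SS) const {
    switch (obj) {
      case OBJ_EC: return (double)cc / (double)m1;
      case OBJ_S3: {
        double den = (double)m1 + (double)ii2 - (double)cc;
        if (den <= 0) stop("S3 denominator is zero");
        return (double)cc / den;
      }
      default: return SS / (double)n1;
    }
  }
  double score() const { return score_from(c, i2, S); }

  // swap images of u and v: returns counter deltas
  void delta_swap(int u, int v, long long &dc, double &dS) const {
    dc = 0; dS = 0.0;
    int au = a[u], av = a[v];
    for (size_t j = 0; j < adj1[u].size(); ++j) {
      int w = adj1[u][j];
      if (w == v) continue;
      dc -= adj2_has(au, a[w]);
      dc += adj2_has(av, a[w]);
    }
    for (size_t j = 0; j < adj1[v].size(); ++j) {
      int w = adj1[v][j];
      if (w == u) continue;
      dc -= adj2_has(av, a[w]);
      dc += adj2_has(au, a[w]);
    }
    if (obj == OBJ_NODESIM)
      dS = simval(u, av) + simval(v, au) - simval(u, au) - simval(v, av);
  }

  // remap u to unused q
  void delta_change(int u, int q, long long &dc, long long &di2, double &dS) const {
    dc = 0; di2 = 0; dS = 0.0;
    int au = a[u];
    for (size_t j = 0; j < adj1[u].size(); ++j) {
      int w = adj1[u][j];
      dc -= adj2_has(au, a[w]);
      dc += adj2_has(q, a[w]);
    }
    long long old_deg = 0, new_deg = 0;
    for (size_t j = 0; j < adj2[au].size(); ++j) old_deg += used[adj2[au][j]];
    for (size_t j = 0; j < adj2[q].size(); ++j) new_deg += used[adj2[q][j]];
    if (adj2_has(q, au)) --new_deg;  // au leaves the image
    di2 = new_deg - old_deg;
    if (obj == OBJ_NODESIM) dS = simval(u, q) - simval(u, au);
  }

  void apply_swap(int u, int v, long long dc, double dS) {
    std::swap(a[u], a[v]);
    rev[a[u]] = u; rev[a[v]] = v;
    c += dc; S += dS;
  }

  void apply_change(int u, int q, long long dc, long long di2, double dS) {
    int au = a[u];
    used[au] = 0; used[q] = 1;
    rev[au] = -1; rev[q] = u;
    // q leaves the free list, au enters at q's slot
    int pos = free_pos[q];
    freev[pos] = au;
    free_pos[au] = pos;
    free_pos[q] = -1;
    a[u] = q;
    c += dc; i2 += di2; S += dS;
  }
};

struct RNG {
  std::mt19937_64 eng;
  explicit RNG(std::uint64_t seed) : eng(seed) {}
  double u01() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(eng() % (std::uint64_t)n); }
};

std::vector<std::vector<int> > as_adj(List adj_list) {
  int n = adj_list.size();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_list[i];
    adj[i].assign(nb.begin(), nb.end());
    std::sort(adj[i].begin(), adj[i].end());
  }
  return adj;
}

SAState make_state(List adj1, List adj2, int m1, int obj, NumericMatrix sim,
                   IntegerVector init) {
  SAState st;
  st.adj1 = as_adj(adj1);
  st.adj2 = as_adj(adj2);
  st.n1 = (int)st.adj1.size();
  st.n2 = (int)st.adj2.size();
  st.m1 = m1;
  st.obj = obj;
  st.sim = (obj == OBJ_NODESIM) ? REAL(sim) : (double *)0;
  if (obj == OBJ_NODESIM && (sim.nrow() != st.n1 || sim.ncol() != st.n2))
    stop("similarity matrix must be n1 x n2");
  if ((int)init.size() != st.n1) stop("initial alignment has wrong length");
  st.a.assign(init.begin(), init.end());
  st.rev.assign(st.n2, -1);
  st.used.assign(st.n2, 0);
  for (int u = 0; u < st.n1; ++u) {
    int q = st.a[u];
    if (q < 0 || q >= st.n2 || st.used[q]) stop("initial alignment not injective");
    st.used[q] = 1;
    st.rev[q] = u;
  }
  st.free_pos.assign(st.n2, -1);
  for (int x = 0; x < st.n2; ++x)
    if (!st.used[x]) {
      st.free_pos[x] = (int)st.freev.size();
      st.freev.push_back(x);
    }
  st.init_counters();
  return st;
}

struct Move {
  int type;  // 0 swap, 1 change
  int u, v, q;
  long long dc, di2;
  double dS, delta;
};

Move propose(SAState &st, RNG &rng) {
  Move mv;
  mv.di2 = 0; mv.dS = 0.0;
  bool can_change = st.n1 < st.n2;
  bool do_change = can_change && rng.below(2) == 1;
  if (do_change) {
    mv.type = 1;
    mv.u = rng.below(st.n1);
    mv.q = st.freev[rng.below((int)st.freev.size())];
    mv.v = -1;
    st.delta_change(mv.u, mv.q, mv.dc, mv.di2, mv.dS);
  } else {
    mv.type = 0;
    mv.u = rng.below(st.n1);
    mv.v = rng.below(st.n1 - 1);
    if (mv.v >= mv.u) ++mv.v;
    mv.q = -1;
    st.delta_swap(mv.u, mv.v, mv.dc, mv.dS);
  }
  double before = st.score();
  double after = st.score_from(st.c + mv.dc, st.i2 + mv.di2, st.S + mv.dS);
  mv.delta = after - before;
  return mv;
}

void apply_move(SAState &st, const Move &mv) {
  if (mv.type == 0) st.apply_swap(mv.u, mv.v, mv.dc, mv.dS);
  else st.apply_change(mv.u, mv.q, mv.dc, mv.di2, mv.dS);
}

}  // namespace

// [[Rcpp::export]]
List sa_anneal_cpp(List adj1, List adj2, int m1, int obj, NumericMatrix sim,
                   IntegerVector init, double iterations, double t_initial,
                   double t_final, int seed) {
  SAState st = make_state(adj1, adj2, m1, obj, sim, init);
  RNG rng((std::uint64_t)(std::uint32_t)seed);
  long long iters = (long long)iterations;
  if (iters < 1) stop("iterations must be >= 1");
  if (!(t_initial >= t_final) || !(t_final > 0))
    stop("need t_initial >= t_final > 0");
  double ratio = (iters > 1) ? std::pow(t_final / t_initial, 1.0 / (double)(iters - 1)) : 1.0;
  double T = t_initial;
  double best = st.score();
  long long accepted = 0;
  for (long long it = 0; it < iters; ++it) {
    Move mv = propose(st, rng);
    if (mv.delta >= 0 || rng.u01() < std::exp(mv.delta / T)) {
      apply_move(st, mv);
      ++accepted;
      double sc = st.score();
      if (sc > best) best = sc;
    }
    T *= ratio;
  }
  // from-scratch verification of the cached counters
  SAState chk = make_state(adj1, adj2, m1, obj, sim,
                           IntegerVector(st.a.begin(), st.a.end()));
  double cached = st.score(), fresh = chk.score();
  if (std::fabs(cached - fresh) > 1e-9) stop("cached score drifted from truth");
  return List::create(_["alignment"] = IntegerVector(st.a.begin(), st.a.end()),
                      _["final_score"] = fresh,
                      _["best_score"] = best,
                      _["accepted_moves"] = (double)accepted,
                      _["proposed_moves"] = (double)iters);
}

// Random walk that applies every proposed move, recording each delta; used
// to calibrate the temperature schedule.
// [[Rcpp::export]]
NumericVector sa_probe_cpp(List adj1, List adj2, int m1, int obj,
                           NumericMatrix sim, IntegerVector init,
                           int n_moves, int seed) {
  SAState st = make_state(adj1, adj2, m1, obj, sim, init);
  RNG rng((std::uint64_t)(std::uint32_t)seed);
  NumericVector out(n_moves);
  for (int i = 0; i < n_moves; ++i) {
    Move mv = propose(st, rng);
    out[i] = mv.delta;
    apply_move(st, mv);
  }
  return out;
}

// Single proposal from a given state (no move applied).
// [[Rcpp::export]]
List sa_propose_cpp(List adj1, List adj2, int m1, int obj, NumericMatrix sim,
                    IntegerVector align, int seed) {
  SAState st = make_state(adj1, adj2, m1, obj, sim, align);
  RNG rng((std::uint64_t)(std::uint32_t)seed);
  Move mv = propose(st, rng);
  return List::create(_["type"] = (mv.type == 0) ? "swap" : "change",
                      _["u"] = mv.u, _["v"] = mv.v, _["q"] = mv.q,
                      _["delta"] = mv.delta);
}

// Audit: for n random moves compare the incremental delta against a
// from-scratch recomputation after applying the move; returns the largest
// absolute discrepancy observed.
// [[Rcpp::export]]
double sa_delta_audit_cpp(List adj1, List adj2, int m1, int obj,
                          NumericMatrix sim, IntegerVector init,
                          int n_moves, int seed) {
  SAState st = make_state(adj1, adj2, m1, obj, sim, init);
  RNG rng((std::uint64_t)(std::uint32_t)seed);
  double worst = 0.0;
  for (int i = 0; i < n_moves; ++i) {
    double before = st.score();
    Move mv = propose(st, rng);
    apply_move(st, mv);
    SAState chk = make_state(adj1, adj2, m1, obj, sim,
                             IntegerVector(st.a.begin(), st.a.end()));
    double full_delta = chk.score() - before;
    worst = std::max(worst, std::fabs(full_delta - mv.delta));
  }
  return worst;
}
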