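// Graphlet-degree-vector machinery: enumeration of connected induced
// subgraphs on up to 4 or 5 nodes (ESU) and classification of the touched
// node into automorphism orbits.  The orbit registry is built at run time
// from first principles: graphlets are connected graphs on 2..k nodes up to
// isomorphism, ordered by (node count, edge count, descending degree
// sequence, canonical adjacency bits); orbits within a graphlet are node
// classes under the automorphism group, ordered by (degree, canonical
// position).  On <=4 nodes this reproduces the standard 15-orbit indexing
// (orbit 0 = edge end, 1/2 = path end/mid, 3 = triangle, ... 14 = K4).
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <map>
#include <set>
using namespace Rcpp;

namespace {

typedef std::uint32_t mask_t;   // upper-triangle adjacency bits, <=10 bits

inline int pair_bit(int i, int j, int r) {
  if (i > j) std::swap(i, j);
  // index of pair (i,j), i<j, in row-major upper triangle
  return i * r - i * (i + 1) / 2 + (j - i - 1);
}

inline bool has_edge(mask_t m, int i, int j, int r) {
  return (m >> pair_bit(i, j, r)) & 1u;
}

bool is_connected(mask_t m, int r) {
  std::vector<int> stack(1, 0);
  std::vector<bool> seen(r, false);
  seen[0] = true;
  int nseen = 1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (int u = 0; u < r; ++u)
      if (u != v && !seen[u] && has_edge(m, u, v, r)) {
        seen[u] = true; ++nseen; stack.push_back(u);
      }
  }
  return nseen == r;
}

void all_perms(int r, std::vector<std::vector<int> > &out) {
  std::vector<int> p(r);
  for (int i = 0; i < r; ++i) p[i] = i;
  do { out.push_back(p); } while (std::next_permutation(p.begin(), p.end()));
}

mask_t apply_perm(mask_t m, const std::vector<int> &p, int r) {
  mask_t out = 0;
  for (int i = 0; i < r; ++i)
    for (int j = i + 1; j < r; ++j)
      if (has_edge(m, i, j, r)) out |= mask_t(1) << pair_bit(p[i], p[j], r);
  return out;
}

// canonical form = minimum permuted mask; canon position of each node =
// minimum image over permutations achieving the canonical form (an
// automorphism-orbit invariant)
struct CanonInfo {
  mask_t canon;
  std::vector<int> node_pos;  // per original node
};

CanonInfo canonicalize(mask_t m, int r, const std::vector<std::vector<int> > &perms) {
  CanonInfo ci;
  ci.canon = ~mask_t(0);
  ci.node_pos.assign(r, r);
  for (size_t k = 0; k < perms.size(); ++k) {
    mask_t pm = apply_perm(m, perms[k], r);
    if (pm < ci.canon) {
      ci.canon = pm;
      ci.node_pos.assign(r, r);
      for (int v = 0; v < r; ++v) ci.node_pos[v] = perms[k][v];
    } else if (pm == ci.canon) {
      for (int v = 0; v < r; ++v)
        ci.node_pos[v] = std::min(ci.node_pos[v], perms[k][v]);
    }
  }
  return ci;
}

struct Orbit {
  int graphlet;     // global graphlet index
  int r, medges;
  int degree;       // degree of touched node inside the graphlet
  int canon_pos;    // orbit invariant within the graphlet
  mask_t gmask;     // canonical graphlet mask
  int rep_node;     // representative touched node in canonical labelling
  int dep_count;    // number of orbits affecting this one (incl. itself)
};

struct Registry {
  int k;
  std::vector<Orbit> orbits;
  // lookup: per size r (2..k), per raw mask, per local node -> orbit id (-1 if n/a)
  std::vector<std::vector<std::vector<int> > > lookup;
};

struct GraphletRec {
  int r, medges;
  std::vector<int> degseq_desc;
  mask_t canon;
  bool operator<(const GraphletRec &o) const {
    if (r != o.r) return r < o.r;
    if (medges != o.medges) return medges < o.medges;
    if (degseq_desc != o.degseq_desc) return degseq_desc < o.degseq_desc;
    return canon < o.canon;
  }
};

int popcount32(mask_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

Registry build_registry(int k) {
  Registry reg;
  reg.k = k;
  std::vector<std::vector<std::vector<int> > > perms_by_r(k + 1);
  for (int r = 2; r <= k; ++r) all_perms(r, perms_by_r[r]);

  // collect canonical representatives
  std::vector<GraphletRec> reps;
  for (int r = 2; r <= k; ++r) {
    int nbits = r * (r - 1) / 2;
    std::set<mask_t> seen;
    for (mask_t m = 0; m < (mask_t(1) << nbits); ++m) {
      if (!is_connected(m, r)) continue;
      CanonInfo ci = canonicalize(m, r, perms_by_r[r]);
      if (seen.count(ci.canon)) continue;
      seen.insert(ci.canon);
      GraphletRec g;
      g.r = r; g.medges = popcount32(ci.canon); g.canon = ci.canon;
      g.degseq_desc.assign(r, 0);
      for (int i = 0; i < r; ++i)
        for (int j = 0; j < r; ++j)
          if (i != j && has_edge(ci.canon, i, j, r)) g.degseq_desc[i]++;
      std::sort(g.degseq_desc.rbegin(), g.degseq_desc.rend());
      reps.push_back(g);
    }
  }
  std::sort(reps.begin(), reps.end());

  // orbits per graphlet, ordered by (degree, canon position)
  std::map<std::pair<mask_t, int>, std::map<int, int> > orbit_id_by_graphlet_pos;
  for (size_t gi = 0; gi < reps.size(); ++gi) {
    const GraphletRec &g = reps[gi];
    CanonInfo ci = canonicalize(g.canon, g.r, perms_by_r[g.r]);
    std::map<int, std::pair<int, int> > classes;  // canon_pos -> (degree, rep node)
    for (int v = 0; v < g.r; ++v) {
      int deg = 0;
      for (int u = 0; u < g.r; ++u)
        if (u != v && has_edge(g.canon, u, v, g.r)) ++deg;
      if (!classes.count(ci.node_pos[v]))
        classes[ci.node_pos[v]] = std::make_pair(deg, v);
    }
    std::vector<std::pair<std::pair<int, int>, std::pair<int, int> > > ordered;
    for (std::map<int, std::pair<int, int> >::iterator it = classes.begin();
         it != classes.end(); ++it)
      ordered.push_back(std::make_pair(
          std::make_pair(it->second.first, it->first),
          std::make_pair(it->first, it->second.second)));
    std::sort(ordered.begin(), ordered.end());
    for (size_t oi = 0; oi < ordered.size(); ++oi) {
      Orbit o;
      o.graphlet = (int)gi;
      o.r = g.r; o.medges = g.medges;
      o.degree = ordered[oi].first.first;
      o.canon_pos = ordered[oi].second.first;
      o.gmask = g.canon;
      o.rep_node = ordered[oi].second.second;
      o.dep_count = 0;
      orbit_id_by_graphlet_pos[std::make_pair(g.canon, o.canon_pos)][g.r] =
          (int)reg.orbits.size();
      reg.orbits.push_back(o);
    }
  }

  // lookup tables: raw mask + local node -> orbit id
  reg.lookup.assign(k + 1, std::vector<std::vector<int> >());
  for (int r = 2; r <= k; ++r) {
    int nbits = r * (r - 1) / 2;
    reg.lookup[r].assign(size_t(1) << nbits, std::vector<int>());
    for (mask_t m = 0; m < (mask_t(1) << nbits); ++m) {
      if (!is_connected(m, r)) continue;
      CanonInfo ci = canonicalize(m, r, perms_by_r[r]);
      std::vector<int> ids(r, -1);
      for (int v = 0; v < r; ++v) {
        std::map<std::pair<mask_t, int>, std::map<int, int> >::iterator it =
            orbit_id_by_graphlet_pos.find(std::make_pair(ci.canon, ci.node_pos[v]));
        ids[v] = it->second[r];
      }
      reg.lookup[r][m] = ids;
    }
  }

  // dependency counts: transitive closure of the single-node-removal relation
  int no = (int)reg.orbits.size();
  std::vector<std::set<int> > deps(no);
  for (int i = 0; i < no; ++i) {
    deps[i].insert(i);
    const Orbit &o = reg.orbits[i];
    if (o.r == 2) continue;
    for (int u = 0; u < o.r; ++u) {
      if (u == o.rep_node) continue;
      // induced subgraph with u removed
      std::vector<int> keep;
      for (int v = 0; v < o.r; ++v) if (v != u) keep.push_back(v);
      int rr = o.r - 1;
      mask_t sub = 0;
      for (int a = 0; a < rr; ++a)
        for (int b = a + 1; b < rr; ++b)
          if (has_edge(o.gmask, keep[a], keep[b], o.r))
            sub |= mask_t(1) << pair_bit(a, b, rr);
      if (!is_connected(sub, rr)) continue;
      int local_touch = 0;
      for (int a = 0; a < rr; ++a) if (keep[a] == o.rep_node) local_touch = a;
      int j = reg.lookup[rr][sub][local_touch];
      deps[i].insert(deps[j].begin(), deps[j].end());  // j < i (fewer nodes)
    }
  }
  for (int i = 0; i < no; ++i) reg.orbits[i].dep_count = (int)deps[i].size();
  return reg;
}

Registry &registry(int k) {
  static Registry reg4, reg5;
  if (k == 4) {
    if (reg4.orbits.empty()) reg4 = build_registry(4);
    return reg4;
  }
  if (reg5.orbits.empty()) reg5 = build_registry(5);
  return reg5;
}

// ESU (Wernicke) enumeration of connected induced subgraphs of size s
struct ESU {
  const std::vector<std::vector<int> > &adj;
  int n, smin, smax;
  const Registry &reg;
  IntegerMatrix &counts;

  ESU(const std::vector<std::vector<int> > &adj_, int smin_, int smax_,
      const Registry &reg_, IntegerMatrix &counts_)
      : adj(adj_), n((int)adj_.size()), smin(smin_), smax(smax_),
        reg(reg_), counts(counts_) {}

  void record(std::vector<int> &sub) {
    int r = (int)sub.size();
    std::vector<int> s(sub);
    std::sort(s.begin(), s.end());
    mask_t m = 0;
    for (int a = 0; a < r; ++a) {
      const std::vector<int> &na = adj[s[a]];
      for (int b = a + 1; b < r; ++b)
        if (std::binary_search(na.begin(), na.end(), s[b]))
          m |= mask_t(1) << pair_bit(a, b, r);
    }
    const std::vector<int> &ids = reg.lookup[r][m];
    for (int a = 0; a < r; ++a) counts(s[a], ids[a])++;
  }

  void extend(std::vector<int> &sub, std::vector<int> &ext, int root) {
    int r = (int)sub.size();
    if (r >= smin && r <= smax) record(sub);
    if (r == smax) return;
    std::vector<int> ext2;
    for (size_t i = 0; i < ext.size(); ++i) {
      int w = ext[i];
      ext2.clear();
      for (size_t j = i + 1; j < ext.size(); ++j) ext2.push_back(ext[j]);
      // exclusive neighbourhood of w
      for (size_t j = 0; j < adj[w].size(); ++j) {
        int u = adj[w][j];
        if (u <= root) continue;
        bool in_sub = false, in_ext = false;
        for (size_t t = 0; t < sub.size(); ++t) if (sub[t] == u) { in_sub = true; break; }
        if (in_sub) continue;
        for (size_t t = 0; t < ext.size(); ++t) if (ext[t] == u) { in_ext = true; break; }
        if (in_ext) continue;
        bool nb_sub = false;  // u adjacent to sub \ {w}? then not exclusive
        for (size_t t = 0; t < sub.size(); ++t)
          if (std::binary_search(adj[u].begin(), adj[u].end(), sub[t])) { nb_sub = true; break; }
        if (!nb_sub) ext2.push_back(u);
      }
      sub.push_back(w);
      extend(sub, ext2, root);
      sub.pop_back();
    }
  }

  void run() {
    for (int v = 0; v < n; ++v) {
      std::vector<int> sub(1, v), ext;
      for (size_t j = 0; j < adj[v].size(); ++j)
        if (adj[v][j] > v) ext.push_back(adj[v][j]);
      extend(sub, ext, v);
    }
  }
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

}  // namespace

// [[Rcpp::export]]
IntegerMatrix gdv_counts_cpp(List adj_list, int max_nodes) {
  if (max_nodes != 4 && max_nodes != 5)
    stop("max_graphlet_nodes must be 4 or 5");
  Registry &reg = registry(max_nodes);
  std::vector<std::vector<int> > adj = as_adj(adj_list);
  IntegerMatrix counts((int)adj.size(), (int)reg.orbits.size());
  ESU esu(adj, 2, max_nodes, reg, counts);
  esu.run();
  return counts;
}

// [[Rcpp::export]]
DataFrame gdv_orbit_info_cpp(int max_nodes) {
  if (max_nodes != 4 && max_nodes != 5)
    stop("max_graphlet_nodes must be 4 or 5");
  Registry &reg = registry(max_nodes);
  int no = (int)reg.orbits.size();
  IntegerVector orbit(no), graphlet(no), nodes(no), edges(no), degree(no), dep(no);
  for (int i = 0; i < no; ++i) {
    orbit[i] = i;
    graphlet[i] = reg.orbits[i].graphlet;
    nodes[i] = reg.orbits[i].r;
    edges[i] = reg.orbits[i].medges;
    degree[i] = reg.orbits[i].degree;
    dep[i] = reg.orbits[i].dep_count;
  }
  return DataFrame::create(_["orbit"] = orbit, _["graphlet"] = graphlet,
                           _["nodes"] = nodes, _["edges"] = edges,
                           _["degree"] = degree, _["dependencies"] = dep);
}
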