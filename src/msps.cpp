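// Compiled kernels: the exhaustive small-instance oracle and the bottom-up
// configuration DP over a rooted binary tree decomposition.
//
// Conventions shared with the R side:
//  * vertices are integers 0..nv-1 (R passes 1-based, converted here);
//  * a configuration of a bag with terminal list T (sorted) is packed into a
//    64-bit key, 4 bits per slot, 2 slots per terminal (in/out for directed
//    graphs, two symmetric slots for undirected ones);
//    slot values: 0..7 = index into T of the pointed-to terminal,
//                 14 = used but no terminal reachable ("NONE"),
//                 15 = slot unused;
//  * undirected slot pairs are stored sorted ascending, so symmetric
//    duplicates collapse to one key.

#include <Rcpp.h>
#include <cstdint>
#include <functional>
#include <vector>
#include <unordered_map>

using namespace Rcpp;

static const int VAL_NONE = 14;
static const int VAL_UNUSED = 15;
static const int MAX_B = 12;   // max bag size
static const int MAX_T = 8;    // max terminals per bag (64-bit key)

static inline int nib(uint64_t key, int slot) {
  return (int)((key >> (4 * slot)) & 0xF);
}
static inline void setnib(uint64_t &key, int slot, int val) {
  key |= ((uint64_t)val) << (4 * slot);
}

// ---------------------------------------------------------------------------
// Union-find on a small fixed array
struct UF {
  int p[MAX_B + 2];
  void init(int n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void un(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

// ---------------------------------------------------------------------------
// Exhaustive oracle: enumerate degree-feasible edge subsets.
//
// score(S) = sum of weights of covered vertices - c * (#components of S)
//          + sum over uncovered v of max(0, w(v) - c)
// Enumeration order excludes each edge before including it, so on ties the
// first (smaller) selection is kept.

struct BFState {
  int nv, m;
  bool directed;
  double c;
  const double *w;
  std::vector<int> efrom, eto;
  std::vector<int> indeg, outdeg;         // usage counters
  std::vector<int> chosen;
  double best;
  std::vector<int> bestEdges;
  double singletonBase;                   // sum max(0, w - c) over all v
};

static void bf_eval(BFState &st) {
  // components + covered vertices of the chosen subset
  std::vector<int> parent(st.nv);
  for (int i = 0; i < st.nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<char> covered(st.nv, 0);
  for (int ei : st.chosen) {
    int a = st.efrom[ei], b = st.eto[ei];
    covered[a] = covered[b] = 1;
    int ra = find(a), rb = find(b);
    if (ra != rb) parent[ra] = rb;
  }
  double sc = 0;
  for (int v = 0; v < st.nv; ++v)
    if (covered[v]) sc += st.w[v];
  int ncomp = 0;
  std::vector<char> seen(st.nv, 0);
  for (int v = 0; v < st.nv; ++v) {
    if (!covered[v]) continue;
    int r = find(v);
    if (!seen[r]) { seen[r] = 1; ++ncomp; }
  }
  sc -= st.c * ncomp;
  for (int v = 0; v < st.nv; ++v)
    if (!covered[v] && st.w[v] > st.c) sc += st.w[v] - st.c;
  if (sc > st.best + 1e-12) {
    st.best = sc;
    st.bestEdges = st.chosen;
  }
}

static void bf_rec(BFState &st, int idx) {
  if (idx == st.m) { bf_eval(st); return; }
  // exclude first
  bf_rec(st, idx + 1);
  int a = st.efrom[idx], b = st.eto[idx];
  bool ok;
  if (st.directed) ok = (st.outdeg[a] == 0 && st.indeg[b] == 0);
  else ok = (st.outdeg[a] + st.indeg[a] < 2 && st.outdeg[b] + st.indeg[b] < 2);
  if (ok) {
    if (st.directed) { st.outdeg[a]++; st.indeg[b]++; }
    else { st.outdeg[a]++; st.indeg[b]++; }   // outdeg+indeg = degree
    st.chosen.push_back(idx);
    bf_rec(st, idx + 1);
    st.chosen.pop_back();
    st.outdeg[a]--; st.indeg[b]--;
  }
}

// [[Rcpp::export]]
List cpp_bruteforce(int nv, NumericVector w, IntegerMatrix edges,
                    bool directed, double c) {
  BFState st;
  st.nv = nv;
  st.m = edges.nrow();
  st.directed = directed;
  st.c = c;
  st.w = REAL(w);
  st.efrom.resize(st.m); st.eto.resize(st.m);
  for (int i = 0; i < st.m; ++i) {
    st.efrom[i] = edges(i, 0) - 1;
    st.eto[i] = edges(i, 1) - 1;
  }
  st.indeg.assign(nv, 0);
  st.outdeg.assign(nv, 0);
  st.best = R_NegInf;
  bf_rec(st, 0);
  IntegerVector out(st.bestEdges.size());
  for (size_t i = 0; i < st.bestEdges.size(); ++i) out[i] = st.bestEdges[i] + 1;
  return List::create(_["score"] = st.best, _["edges"] = out);
}

// ---------------------------------------------------------------------------
// Treewidth DP

struct Entry {
  double score;
  int c1, c2;         // indices into child tables (-1 for leaves)
  uint32_t smask;     // selected assigned-edge subset
};

struct BagTable {
  std::vector<uint64_t> keys;              // insertion order (deterministic)
  std::vector<Entry> ents;
  std::unordered_map<uint64_t, int> index;
  int upsert(uint64_t key, double score, int c1, int c2, uint32_t smask) {
    auto it = index.find(key);
    if (it == index.end()) {
      index.emplace(key, (int)keys.size());
      keys.push_back(key);
      ents.push_back({score, c1, c2, smask});
      return (int)keys.size() - 1;
    }
    if (score > ents[it->second].score) {
      ents[it->second] = {score, c1, c2, smask};
    }
    return it->second;
  }
};

// number of slot-pointer components among used terminals of a packed config
static int config_components(uint64_t key, int t) {
  UF uf; uf.init(t);
  bool used[MAX_T];
  for (int j = 0; j < t; ++j) {
    int a = nib(key, 2 * j), b = nib(key, 2 * j + 1);
    used[j] = (a != VAL_UNUSED) || (b != VAL_UNUSED);
    if (a <= 7) uf.un(j, a);
    if (b <= 7) uf.un(j, b);
  }
  int n = 0;
  bool seen[MAX_T] = {false};
  for (int j = 0; j < t; ++j) {
    if (!used[j]) continue;
    int r = uf.find(j);
    if (!seen[r]) { seen[r] = true; ++n; }
  }
  return n;
}

// enumerate degree-feasible subsets of the bag's assigned edges
static void enum_smasks(const std::vector<std::pair<int,int>> &ed, bool directed,
                        int b, std::vector<uint32_t> &out) {
  int m = (int)ed.size();
  std::vector<int> indeg(b, 0), outdeg(b, 0), deg(b, 0);
  std::function<void(int, uint32_t)> rec = [&](int idx, uint32_t mask) {
    if (idx == m) { out.push_back(mask); return; }
    rec(idx + 1, mask);
    int a = ed[idx].first, v = ed[idx].second;
    bool ok = directed ? (outdeg[a] == 0 && indeg[v] == 0)
                       : (deg[a] < 2 && deg[v] < 2);
    if (ok) {
      outdeg[a]++; indeg[v]++; deg[a]++; deg[v]++;
      rec(idx + 1, mask | (1u << idx));
      outdeg[a]--; indeg[v]--; deg[a]--; deg[v]--;
    }
  };
  rec(0, 0u);
}

// Working extended configuration over the current bag (directed view)
struct DirSlots {
  int8_t inOrig[MAX_B], outOrig[MAX_B];    // 0 unused, 1 left, 2 right, 3 bag
  int8_t inTgt[MAX_B], outTgt[MAX_B];      // local index or -1 (= NONE)
};
// Undirected view: up to two symmetric records per vertex
struct UndSlots {
  int8_t orig[MAX_B][2];
  int8_t tgt[MAX_B][2];
  int8_t n[MAX_B];
};

class TwSolver {
public:
  int nv;
  std::vector<double> w;
  bool directed;
  double c;
  int nb;
  std::vector<std::vector<int>> bagv, term, eidx, kids;
  std::vector<std::pair<int,int>> edges;   // global 0-based
  int root;
  std::vector<BagTable> tables;
  std::vector<long long> combos;           // diagnostics

  // ---- per-bag scratch
  int b, t;
  std::vector<int> localOf;                // global -> local (or -1)
  bool isTerm[MAX_B];
  int termIdx[MAX_B];

  void solve_bag(int x);
  void solve_bag_directed(int x, int k1, int k2,
                          const std::vector<int> &T1loc, const std::vector<int> &T2loc,
                          const std::vector<std::pair<int,int>> &ledges,
                          const std::vector<uint32_t> &smasks);
  void solve_bag_undirected(int x, int k1, int k2,
                            const std::vector<int> &T1loc, const std::vector<int> &T2loc,
                            const std::vector<std::pair<int,int>> &ledges,
                            const std::vector<uint32_t> &smasks);
};

// chase pointers backwards/forwards through non-terminal bag vertices
// (directed case); returns encoded slot value.
static int chase_dir(const DirSlots &E, const bool *isTerm, const int *termIdx,
                     int start, bool backward, int b) {
  int u = backward ? E.inTgt[start] : E.outTgt[start];
  int steps = 0;
  while (true) {
    if (u < 0) return VAL_NONE;
    if (isTerm[u]) return termIdx[u];
    if (++steps > b + 1) stop("internal error: pointer chase did not terminate");
    int orig = backward ? E.inOrig[u] : E.outOrig[u];
    if (orig == 0) return VAL_NONE;        // path starts/ends at u outside T
    u = backward ? E.inTgt[u] : E.outTgt[u];
  }
}

void TwSolver::solve_bag(int x) {
  const std::vector<int> &kx = kids[x];
  b = (int)bagv[x].size();
  t = (int)term[x].size();
  if (b > MAX_B) stop("bag with more than %d vertices is not supported", MAX_B);
  if (t > MAX_T) stop("bag with more than %d terminals is not supported", MAX_T);
  if (kx.empty()) {
    if (b != 0) stop("internal error: nonempty leaf bag in preprocessed decomposition");
    tables[x].upsert(0u, 0.0, -1, -1, 0u);
    combos[x] = 1;
    return;
  }
  if (kx.size() != 2) stop("internal error: bag with one child");
  int k1 = kx[0], k2 = kx[1];

  localOf.assign(nv, -1);
  for (int i = 0; i < b; ++i) localOf[bagv[x][i]] = i;
  for (int i = 0; i < b; ++i) { isTerm[i] = false; termIdx[i] = -1; }
  for (int j = 0; j < t; ++j) {
    int li = localOf[term[x][j]];
    isTerm[li] = true; termIdx[li] = j;
  }
  std::vector<int> T1loc, T2loc;
  for (int v : term[k1]) {
    if (localOf[v] < 0) stop("internal error: child terminal not in parent bag");
    T1loc.push_back(localOf[v]);
  }
  for (int v : term[k2]) {
    if (localOf[v] < 0) stop("internal error: child terminal not in parent bag");
    T2loc.push_back(localOf[v]);
  }
  std::vector<std::pair<int,int>> ledges;
  for (int ei : eidx[x]) {
    int a = localOf[edges[ei].first], v = localOf[edges[ei].second];
    if (a < 0 || v < 0) stop("internal error: assigned edge endpoint not in bag");
    ledges.push_back({a, v});
  }
  if ((int)ledges.size() > 25) stop("too many edges assigned to a single bag");
  std::vector<uint32_t> smasks;
  enum_smasks(ledges, directed, b, smasks);

  if (directed) solve_bag_directed(x, k1, k2, T1loc, T2loc, ledges, smasks);
  else solve_bag_undirected(x, k1, k2, T1loc, T2loc, ledges, smasks);
}

void TwSolver::solve_bag_directed(int x, int k1, int k2,
                                  const std::vector<int> &T1loc,
                                  const std::vector<int> &T2loc,
                                  const std::vector<std::pair<int,int>> &ledges,
                                  const std::vector<uint32_t> &smasks) {
  BagTable &tab1 = tables[k1], &tab2 = tables[k2];
  int t1 = (int)T1loc.size(), t2 = (int)T2loc.size();
  std::vector<int> comp1(tab1.keys.size()), comp2(tab2.keys.size());
  for (size_t i = 0; i < tab1.keys.size(); ++i)
    comp1[i] = config_components(tab1.keys[i], t1);
  for (size_t i = 0; i < tab2.keys.size(); ++i)
    comp2[i] = config_components(tab2.keys[i], t2);

  long long ncomb = 0;
  DirSlots E0, E1, E;
  for (size_t i1 = 0; i1 < tab1.keys.size(); ++i1) {
    uint64_t key1 = tab1.keys[i1];
    double s1 = tab1.ents[i1].score;
    // fill from child 1 (cannot conflict with itself)
    for (int v = 0; v < b; ++v) { E0.inOrig[v] = 0; E0.outOrig[v] = 0; }
    for (int j = 0; j < t1; ++j) {
      int v = T1loc[j];
      int vin = nib(key1, 2 * j), vout = nib(key1, 2 * j + 1);
      if (vin != VAL_UNUSED) {
        E0.inOrig[v] = 1; E0.inTgt[v] = (vin == VAL_NONE) ? -1 : (int8_t)T1loc[vin];
      }
      if (vout != VAL_UNUSED) {
        E0.outOrig[v] = 1; E0.outTgt[v] = (vout == VAL_NONE) ? -1 : (int8_t)T1loc[vout];
      }
    }
    for (size_t i2 = 0; i2 < tab2.keys.size(); ++i2) {
      uint64_t key2 = tab2.keys[i2];
      double s2 = tab2.ents[i2].score;
      E1 = E0;
      bool ok = true;
      for (int j = 0; j < t2 && ok; ++j) {
        int v = T2loc[j];
        int vin = nib(key2, 2 * j), vout = nib(key2, 2 * j + 1);
        if (vin != VAL_UNUSED) {
          if (E1.inOrig[v]) { ok = false; break; }
          E1.inOrig[v] = 2; E1.inTgt[v] = (vin == VAL_NONE) ? -1 : (int8_t)T2loc[vin];
        }
        if (vout != VAL_UNUSED) {
          if (E1.outOrig[v]) { ok = false; break; }
          E1.outOrig[v] = 2; E1.outTgt[v] = (vout == VAL_NONE) ? -1 : (int8_t)T2loc[vout];
        }
      }
      if (!ok) { ncomb += (long long)smasks.size(); continue; }
      double s12 = s1 + s2 + c * (comp1[i1] + comp2[i2]);
      for (uint32_t smask : smasks) {
        ++ncomb;
        E = E1;
        bool okv = true;
        uint32_t mm = smask;
        while (mm) {
          int e = __builtin_ctz(mm); mm &= mm - 1;
          int a = ledges[e].first, v = ledges[e].second;
          if (E.outOrig[a] || E.inOrig[v]) { okv = false; break; }
          E.outOrig[a] = 3; E.outTgt[a] = (int8_t)v;
          E.inOrig[v] = 3; E.inTgt[v] = (int8_t)a;
        }
        if (!okv) continue;
        // weight delta + components over the bag
        double sc = s12;
        UF uf; uf.init(b);
        bool used[MAX_B];
        for (int v = 0; v < b; ++v) {
          bool uL = (E.inOrig[v] == 1) || (E.outOrig[v] == 1);
          bool uR = (E.inOrig[v] == 2) || (E.outOrig[v] == 2);
          bool uB = (E.inOrig[v] == 3) || (E.outOrig[v] == 3);
          used[v] = uL || uR || uB;
          if (uB && !uL && !uR) sc += w[bagv[x][v]];
          if (uL && uR) sc -= w[bagv[x][v]];
          if (E.inOrig[v] && E.inTgt[v] >= 0) uf.un(v, E.inTgt[v]);
          if (E.outOrig[v] && E.outTgt[v] >= 0) uf.un(v, E.outTgt[v]);
        }
        int ncompX = 0;
        { bool seen[MAX_B] = {false};
          for (int v = 0; v < b; ++v) {
            if (!used[v]) continue;
            int r = uf.find(v);
            if (!seen[r]) { seen[r] = true; ++ncompX; }
          } }
        sc -= c * ncompX;
        // reduce to the parent configuration
        uint64_t key = 0;
        for (int j = 0; j < t; ++j) {
          int v = localOf[term[x][j]];
          int vin = E.inOrig[v] ? chase_dir(E, isTerm, termIdx, v, true, b)
                                : VAL_UNUSED;
          int vout = E.outOrig[v] ? chase_dir(E, isTerm, termIdx, v, false, b)
                                  : VAL_UNUSED;
          setnib(key, 2 * j, vin);
          setnib(key, 2 * j + 1, vout);
        }
        tables[x].upsert(key, sc, (int)i1, (int)i2, smask);
      }
    }
  }
  combos[x] = ncomb;
}

// undirected chase: start at terminal vertex 'start', following its record r
static int chase_und(const UndSlots &E, const bool *isTerm, const int *termIdx,
                     int start, int r, int b) {
  int o = E.orig[start][r];
  int u = E.tgt[start][r];
  int prev = start;
  int steps = 0;
  while (true) {
    if (u < 0) return VAL_NONE;
    if (isTerm[u]) return termIdx[u];
    if (++steps > b + 1) stop("internal error: pointer chase did not terminate");
    int back = -1;
    for (int s = 0; s < E.n[u]; ++s)
      if (E.orig[u][s] == o && E.tgt[u][s] == prev) { back = s; break; }
    if (back < 0) stop("internal error: reciprocal pointer missing in chase");
    if (E.n[u] < 2) return VAL_NONE;       // path ends at u
    int fwd = 1 - back;
    o = E.orig[u][fwd];
    int nxt = E.tgt[u][fwd];
    prev = u;
    u = nxt;
  }
}

void TwSolver::solve_bag_undirected(int x, int k1, int k2,
                                    const std::vector<int> &T1loc,
                                    const std::vector<int> &T2loc,
                                    const std::vector<std::pair<int,int>> &ledges,
                                    const std::vector<uint32_t> &smasks) {
  BagTable &tab1 = tables[k1], &tab2 = tables[k2];
  int t1 = (int)T1loc.size(), t2 = (int)T2loc.size();
  std::vector<int> comp1(tab1.keys.size()), comp2(tab2.keys.size());
  for (size_t i = 0; i < tab1.keys.size(); ++i)
    comp1[i] = config_components(tab1.keys[i], t1);
  for (size_t i = 0; i < tab2.keys.size(); ++i)
    comp2[i] = config_components(tab2.keys[i], t2);

  long long ncomb = 0;
  UndSlots E0, E1, E;
  for (size_t i1 = 0; i1 < tab1.keys.size(); ++i1) {
    uint64_t key1 = tab1.keys[i1];
    double s1 = tab1.ents[i1].score;
    for (int v = 0; v < b; ++v) E0.n[v] = 0;
    for (int j = 0; j < t1; ++j) {
      int v = T1loc[j];
      for (int s = 0; s < 2; ++s) {
        int val = nib(key1, 2 * j + s);
        if (val == VAL_UNUSED) continue;
        E0.orig[v][E0.n[v]] = 1;
        E0.tgt[v][E0.n[v]] = (val == VAL_NONE) ? -1 : (int8_t)T1loc[val];
        E0.n[v]++;
      }
    }
    for (size_t i2 = 0; i2 < tab2.keys.size(); ++i2) {
      uint64_t key2 = tab2.keys[i2];
      double s2 = tab2.ents[i2].score;
      E1 = E0;
      bool ok = true;
      for (int j = 0; j < t2 && ok; ++j) {
        int v = T2loc[j];
        for (int s = 0; s < 2; ++s) {
          int val = nib(key2, 2 * j + s);
          if (val == VAL_UNUSED) continue;
          if (E1.n[v] >= 2) { ok = false; break; }
          E1.orig[v][E1.n[v]] = 2;
          E1.tgt[v][E1.n[v]] = (val == VAL_NONE) ? -1 : (int8_t)T2loc[val];
          E1.n[v]++;
        }
      }
      if (!ok) { ncomb += (long long)smasks.size(); continue; }
      double s12 = s1 + s2 + c * (comp1[i1] + comp2[i2]);
      for (uint32_t smask : smasks) {
        ++ncomb;
        E = E1;
        bool okv = true;
        uint32_t mm = smask;
        while (mm) {
          int e = __builtin_ctz(mm); mm &= mm - 1;
          int a = ledges[e].first, v = ledges[e].second;
          if (E.n[a] >= 2 || E.n[v] >= 2) { okv = false; break; }
          E.orig[a][E.n[a]] = 3; E.tgt[a][E.n[a]] = (int8_t)v; E.n[a]++;
          E.orig[v][E.n[v]] = 3; E.tgt[v][E.n[v]] = (int8_t)a; E.n[v]++;
        }
        if (!okv) continue;
        double sc = s12;
        UF uf; uf.init(b);
        bool used[MAX_B];
        for (int v = 0; v < b; ++v) {
          bool uL = false, uR = false, uB = false;
          for (int s = 0; s < E.n[v]; ++s) {
            if (E.orig[v][s] == 1) uL = true;
            else if (E.orig[v][s] == 2) uR = true;
            else uB = true;
            if (E.tgt[v][s] >= 0) uf.un(v, E.tgt[v][s]);
          }
          used[v] = E.n[v] > 0;
          if (uB && !uL && !uR) sc += w[bagv[x][v]];
          if (uL && uR) sc -= w[bagv[x][v]];
        }
        int ncompX = 0;
        { bool seen[MAX_B] = {false};
          for (int v = 0; v < b; ++v) {
            if (!used[v]) continue;
            int r = uf.find(v);
            if (!seen[r]) { seen[r] = true; ++ncompX; }
          } }
        sc -= c * ncompX;
        uint64_t key = 0;
        for (int j = 0; j < t; ++j) {
          int v = localOf[term[x][j]];
          int vals[2] = {VAL_UNUSED, VAL_UNUSED};
          for (int s = 0; s < E.n[v]; ++s)
            vals[s] = chase_und(E, isTerm, termIdx, v, s, b);
          if (vals[0] > vals[1]) std::swap(vals[0], vals[1]);   // canonical
          setnib(key, 2 * j, vals[0]);
          setnib(key, 2 * j + 1, vals[1]);
        }
        tables[x].upsert(key, sc, (int)i1, (int)i2, smask);
      }
    }
  }
  combos[x] = ncomb;
}

// [[Rcpp::export]]
List cpp_solve_tw(int nv, NumericVector w, bool directed, IntegerMatrix edges,
                  List bags, List children, int root, List terminals,
                  List bag_edges, double c) {
  TwSolver S;
  S.nv = nv;
  S.w.assign(REAL(w), REAL(w) + nv);
  S.directed = directed;
  S.c = c;
  S.nb = bags.size();
  S.root = root - 1;
  S.bagv.resize(S.nb); S.term.resize(S.nb); S.eidx.resize(S.nb);
  S.kids.resize(S.nb);
  for (int i = 0; i < S.nb; ++i) {
    IntegerVector bv = bags[i];
    for (int v : bv) S.bagv[i].push_back(v - 1);
    IntegerVector tv = terminals[i];
    for (int v : tv) S.term[i].push_back(v - 1);
    IntegerVector ev = bag_edges[i];
    for (int e : ev) S.eidx[i].push_back(e - 1);
    IntegerVector kv = children[i];
    for (int k : kv) S.kids[i].push_back(k - 1);
  }
  int m = edges.nrow();
  for (int i = 0; i < m; ++i)
    S.edges.push_back({edges(i, 0) - 1, edges(i, 1) - 1});
  S.tables.resize(S.nb);
  S.combos.assign(S.nb, 0);

  // iterative post-order from the root
  std::vector<int> order;
  std::vector<int> stack = {S.root};
  while (!stack.empty()) {
    int x = stack.back(); stack.pop_back();
    order.push_back(x);
    for (int k : S.kids[x]) stack.push_back(k);
  }
  for (auto it = order.rbegin(); it != order.rend(); ++it) S.solve_bag(*it);

  // answer: the single empty configuration at the root
  BagTable &rt = S.tables[S.root];
  if (S.term[S.root].size() != 0)
    stop("internal error: root bag has terminals");
  auto it = rt.index.find(0u);
  if (it == rt.index.end()) stop("internal error: root configuration missing");
  int rootIdx = it->second;
  double best = rt.ents[rootIdx].score;

  // traceback: collect selected assigned edges down the tree
  std::vector<int> selected;
  std::function<void(int, int)> walk = [&](int x, int entIdx) {
    const Entry &e = S.tables[x].ents[entIdx];
    uint32_t mm = e.smask;
    while (mm) {
      int b = __builtin_ctz(mm); mm &= mm - 1;
      selected.push_back(S.eidx[x][b] + 1);
    }
    if (!S.kids[x].empty()) {
      walk(S.kids[x][0], e.c1);
      walk(S.kids[x][1], e.c2);
    }
  };
  walk(S.root, rootIdx);

  IntegerVector selv(selected.begin(), selected.end());
  IntegerVector dbag(S.nb), dsize(S.nb), dterm(S.nb), dconf(S.nb);
  NumericVector dcomb(S.nb);
  for (int i = 0; i < S.nb; ++i) {
    dbag[i] = i + 1;
    dsize[i] = (int)S.bagv[i].size();
    dterm[i] = (int)S.term[i].size();
    dconf[i] = (int)S.tables[i].keys.size();
    dcomb[i] = (double)S.combos[i];
  }
  DataFrame diag = DataFrame::create(
      _["bag"] = dbag, _["bag_size"] = dsize, _["n_terminals"] = dterm,
      _["n_configs"] = dconf, _["n_extended"] = dcomb);
  return List::create(_["score"] = best, _["edges"] = selv,
                      _["diagnostics"] = diag);
}
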