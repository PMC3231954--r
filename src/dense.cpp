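// Core search kernels: maximal gamma-dense, mu-enriched quasi-clique
// enumeration, the exhaustive reference enumerator, bitmap module registries
// and the maximality filter. Vertices are 0-based here; R wrappers convert.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <map>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rational thresholds.  gamma and mu arrive as exact fractions p/q so that
// degree/enrichment comparisons are integer cross-multiplications; `strict_`
// models "just above p/q" (used for the boundary gamma = 1/2 regime).
// ---------------------------------------------------------------------------
struct Rat {
  long long p, q;
  bool strict_;
};

// minimal integer k with k >= (p/q)*m, or k > (p/q)*m when strict
static inline long long rat_min(const Rat& r, long long m) {
  if (m <= 0) return 0;
  long long num = r.p * m;
  if (r.strict_) return num / r.q + 1;
  return (num + r.q - 1) / r.q;
}

// count >= (p/q) * s  (enrichment test; never strict: mu in (0,1])
static inline bool mu_ok(long long count, long long s, const Rat& mu) {
  return count * mu.q >= mu.p * s;
}

// ---------------------------------------------------------------------------
// Fixed-width bitset helpers (W 64-bit words per row)
// ---------------------------------------------------------------------------
static inline void bs_set(uint64_t* b, int v) { b[v >> 6] |= 1ull << (v & 63); }
static inline void bs_clear(uint64_t* b, int v) { b[v >> 6] &= ~(1ull << (v & 63)); }
static inline bool bs_test(const uint64_t* b, int v) {
  return (b[v >> 6] >> (v & 63)) & 1ull;
}
static inline long long bs_popc_and(const uint64_t* a, const uint64_t* b, int W) {
  long long s = 0;
  for (int w = 0; w < W; ++w) s += __builtin_popcountll(a[w] & b[w]);
  return s;
}

// ---------------------------------------------------------------------------
// Module registries.  A registry answers "is some already-registered module a
// superset of this vertex set?" by AND-ing per-vertex membership bitsets.
// ---------------------------------------------------------------------------
struct ModIndex {
  size_t nreg = 0;     // modules registered so far (ids 0..nreg-1)
  size_t maxsize = 0;  // largest registered module (quick superset refusal)
  virtual ~ModIndex() {}
  virtual void reg(const std::vector<int>& vs) = 0;
  virtual bool superset(const std::vector<int>& vs) const = 0;
  virtual std::map<int, int> bit_counts() const = 0;
};

// Flat registry: one plain bitset per vertex, full-width AND.
struct FlatIndex : ModIndex {
  std::vector<std::vector<uint64_t>> rows;  // rows[v] bit i = v in module i

  void reg(const std::vector<int>& vs) {
    size_t bit = nreg++;
    size_t w = bit >> 6;
    uint64_t m = 1ull << (bit & 63);
    for (int v : vs) {
      if ((size_t)v >= rows.size()) rows.resize(v + 1);
      auto& r = rows[v];
      if (r.size() <= w) r.resize(w + 1, 0);
      r[w] |= m;
    }
    if (vs.size() > maxsize) maxsize = vs.size();
  }

  bool superset(const std::vector<int>& vs) const {
    if (nreg == 0 || vs.empty() || vs.size() > maxsize) return false;
    size_t minw = SIZE_MAX;
    for (int v : vs) {
      if ((size_t)v >= rows.size() || rows[v].empty()) return false;
      minw = std::min(minw, rows[v].size());
    }
    for (size_t w = 0; w < minw; ++w) {
      uint64_t acc = ~0ull;
      for (int v : vs) {
        acc &= rows[v][w];
        if (!acc) break;
      }
      if (acc) return true;
    }
    return false;
  }

  std::map<int, int> bit_counts() const {
    std::map<int, int> out;
    for (size_t v = 0; v < rows.size(); ++v) {
      int c = 0;
      for (uint64_t w : rows[v]) c += __builtin_popcountll(w);
      if (c) out[(int)v] = c;
    }
    return out;
  }
};

// Hierarchical registry: level 0 is the plain byte-addressed bitset; each
// higher level summarizes one byte of the level below with a single bit
// (1 = byte nonzero).  A level is added whenever the current top level grows
// beyond one byte, so the top is always a single byte and AND queries descend
// only into byte ranges whose summary AND is nonzero.
struct HierIndex : ModIndex {
  // lv[v][level] = byte array; missing trailing bytes are zero
  std::vector<std::vector<std::vector<uint8_t>>> lv;
  int nlevels = 1;

  static int levels_for(size_t nreg) {
    int nl = 1;
    size_t b = (nreg + 7) / 8;  // bytes at base level
    while (b > 1) {
      b = (b + 7) / 8;
      ++nl;
    }
    return nl;
  }

  static std::vector<uint8_t> summarize(const std::vector<uint8_t>& lower) {
    std::vector<uint8_t> up((lower.size() + 7) / 8, 0);
    for (size_t i = 0; i < lower.size(); ++i)
      if (lower[i]) up[i >> 3] |= (uint8_t)(1u << (i & 7));
    return up;
  }

  void reg(const std::vector<int>& vs) {
    size_t bit = nreg++;
    int need = levels_for(nreg);
    if (need > nlevels) {  // grow: summarize the current top for every vertex
      for (auto& rows : lv) {
        if (rows.empty()) continue;
        while ((int)rows.size() < need) rows.push_back(summarize(rows.back()));
      }
      nlevels = need;
    }
    for (int v : vs) {
      if ((size_t)v >= lv.size()) lv.resize(v + 1);
      auto& rows = lv[v];
      if (rows.empty()) rows.resize(nlevels);
      for (int l = 0; l < nlevels; ++l) {
        size_t bidx = bit >> (3 * l);       // bit index at level l
        size_t byi = bidx >> 3;             // byte index at level l
        if (rows[l].size() <= byi) rows[l].resize(byi + 1, 0);
        rows[l][byi] |= (uint8_t)(1u << (bidx & 7));
      }
    }
    if (vs.size() > maxsize) maxsize = vs.size();
  }

  bool check_byte(const std::vector<int>& vs, int level, size_t b) const {
    uint8_t acc = 0xFF;
    for (int v : vs) {
      const auto& arr = lv[v][level];
      uint8_t x = (b < arr.size()) ? arr[b] : 0;
      acc &= x;
      if (!acc) return false;
    }
    if (level == 0) return true;
    while (acc) {
      int j = __builtin_ctz(acc);
      acc &= (uint8_t)(acc - 1);
      if (check_byte(vs, level - 1, b * 8 + j)) return true;
    }
    return false;
  }

  bool superset(const std::vector<int>& vs) const {
    if (nreg == 0 || vs.empty() || vs.size() > maxsize) return false;
    for (int v : vs)
      if ((size_t)v >= lv.size() || lv[v].empty()) return false;
    return check_byte(vs, nlevels - 1, 0);
  }

  std::map<int, int> bit_counts() const {
    std::map<int, int> out;
    for (size_t v = 0; v < lv.size(); ++v) {
      if (lv[v].empty()) continue;
      int c = 0;
      for (uint8_t b : lv[v][0]) c += __builtin_popcount((unsigned)b);
      if (c) out[(int)v] = c;
    }
    return out;
  }
};

static ModIndex* make_index(int kind) {  // 0 none, 1 flat, 2 hierarchical
  if (kind == 1) return new FlatIndex();
  if (kind == 2) return new HierIndex();
  return nullptr;
}

// ---------------------------------------------------------------------------
// The backtracking enumerator.
//
// Search tree: set-enumeration over an ordered candidate array.  At a node
// (S, C) the children extend S by C[i] with candidate set
// {C[j] : j > i} /\ N2(C[i]); i.e. the first candidate in the array is always
// the next vertex considered.  Pruning at each node, to a fixed point:
//   P1  candidates stay within distance 2 of every member of S (maintained
//       by the N2 intersections at child construction),
//   P3  drop v in C unless s_a(v)+c_a(v) >= ceil(gamma*(|S|+c_a(v))),
//   P4  abandon extension when |S/\Q|+|C/\Q| < mu*(|S|+|C/\Q|); drop any
//       non-query v whose addition would force that violation.
//   P2  stop expanding when some v in S has
//       s_a(v)+c_a(v) < ceil(gamma*(|S|-1+c_a(v))).
// A node also backtracks when a registered module already contains S u C.
// Emission (after the children) registers S when it is gamma-dense,
// mu-enriched, at least min_size large and not covered by a registered
// module; global maximality is finally enforced by the maximality filter.
// ---------------------------------------------------------------------------
struct Enumerator {
  int n, W;
  std::vector<uint64_t> adj;  // n*W adjacency bitsets
  std::vector<uint64_t> inQ;  // W
  Rat g, mu;
  int min_size;
  bool p2, p3, p4;
  ModIndex* idx;

  std::vector<std::vector<uint64_t>> n2;  // lazy distance-<=2 bitsets
  std::vector<char> n2done;

  std::vector<int> S;
  std::vector<uint64_t> Sbits;
  long long sq = 0;  // |S /\ Q|
  long long nodes = 0;

  std::vector<std::vector<int>> out;  // emitted candidate modules (sorted)

  const uint64_t* A(int v) const { return &adj[(size_t)v * W]; }

  const std::vector<uint64_t>& n2bits(int v) {
    if (!n2done[v]) {
      auto& b = n2[v];
      b.assign(W, 0);
      const uint64_t* av = A(v);
      for (int w = 0; w < W; ++w) b[w] |= av[w];
      for (int w = 0; w < W; ++w) {
        uint64_t word = av[w];
        while (word) {
          int u = (w << 6) + __builtin_ctzll(word);
          word &= word - 1;
          const uint64_t* au = A(u);
          for (int k = 0; k < W; ++k) b[k] |= au[k];
        }
      }
      bs_set(b.data(), v);
      n2done[v] = 1;
    }
    return n2[v];
  }

  void try_emit() {
    if ((int)S.size() < min_size) return;
    if (!mu_ok(sq, (long long)S.size(), mu)) return;
    long long need = rat_min(g, (long long)S.size() - 1);
    for (int v : S)
      if (bs_popc_and(A(v), Sbits.data(), W) < need) return;
    std::vector<int> m(S);
    std::sort(m.begin(), m.end());
    if (idx) {
      if (idx->superset(m)) return;  // already inside a discovered module
      idx->reg(m);
    }
    out.push_back(std::move(m));
  }

  void node(std::vector<int> C) {
    ++nodes;
    if ((nodes & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    std::vector<uint64_t> Cb(W, 0);
    for (int v : C) bs_set(Cb.data(), v);

    // --- prune to fixed point ---
    bool enrich_dead = false;
    bool changed = true;
    while (changed) {
      changed = false;
      long long cq = bs_popc_and(Cb.data(), inQ.data(), W);
      if (p4 && !mu_ok(sq + cq, (long long)S.size() + cq, mu)) {
        enrich_dead = true;  // no extension from C can be mu-enriched
        break;
      }
      for (size_t i = 0; i < C.size();) {
        int v = C[i];
        long long sa = bs_popc_and(A(v), Sbits.data(), W);
        long long ca = bs_popc_and(A(v), Cb.data(), W);
        bool drop = false;
        if (p3 && sa + ca < rat_min(g, (long long)S.size() + ca)) drop = true;
        if (!drop && p4 && !bs_test(inQ.data(), v) &&
            !mu_ok(sq + cq, (long long)S.size() + 1 + cq, mu))
          drop = true;
        if (drop) {
          bs_clear(Cb.data(), v);
          C.erase(C.begin() + i);
          changed = true;
        } else {
          ++i;
        }
      }
    }

    if (enrich_dead) {
      try_emit();
      return;
    }
    if ((int)(S.size() + C.size()) < min_size) return;

    // registered-superset backtrack (covers the emission duplicate check
    // too when C is empty)
    if (idx && !C.empty()) {
      std::vector<int> sc;
      sc.reserve(S.size() + C.size());
      sc.insert(sc.end(), S.begin(), S.end());
      sc.insert(sc.end(), C.begin(), C.end());
      std::sort(sc.begin(), sc.end());
      if (idx->superset(sc)) return;
    }

    // P2: no gamma-dense supergraph achievable from C
    if (p2 && !C.empty()) {
      for (int v : S) {
        long long sa = bs_popc_and(A(v), Sbits.data(), W);
        long long ca = bs_popc_and(A(v), Cb.data(), W);
        if (sa + ca < rat_min(g, (long long)S.size() - 1 + ca)) {
          try_emit();
          return;
        }
      }
    }

    for (size_t i = 0; i < C.size(); ++i) {
      int v = C[i];
      const std::vector<uint64_t>& nv = n2bits(v);
      std::vector<int> Cc;
      for (size_t j = i + 1; j < C.size(); ++j)
        if (bs_test(nv.data(), C[j])) Cc.push_back(C[j]);
      S.push_back(v);
      bs_set(Sbits.data(), v);
      bool vq = bs_test(inQ.data(), v);
      if (vq) ++sq;
      node(std::move(Cc));
      S.pop_back();
      bs_clear(Sbits.data(), v);
      if (vq) --sq;
    }
    try_emit();
  }

  void run(const std::vector<int>& seeds) {
    for (int v0 : seeds) {
      S.assign(1, v0);
      Sbits.assign(W, 0);
      bs_set(Sbits.data(), v0);
      sq = bs_test(inQ.data(), v0) ? 1 : 0;
      std::vector<int> C;
      const auto& nv = n2bits(v0);
      for (int w = 0; w < W; ++w) {
        uint64_t word = nv[w];
        while (word) {
          int u = (w << 6) + __builtin_ctzll(word);
          word &= word - 1;
          if (u != v0) C.push_back(u);
        }
      }
      node(std::move(C));
    }
  }
};

// ---------------------------------------------------------------------------
// exported kernels
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_enumerate(int n, IntegerVector ei, IntegerVector ej,
                   IntegerVector query0, long long gp, long long gq,
                   bool gstrict, long long mp, long long mq, int min_size,
                   bool use_p2, bool use_p3, bool use_p4, int index_kind) {
  Enumerator E;
  E.n = n;
  E.W = (n + 63) / 64;
  E.adj.assign((size_t)n * E.W, 0);
  for (int k = 0; k < ei.size(); ++k) {
    int a = ei[k], b = ej[k];
    if (a == b) continue;
    bs_set(&E.adj[(size_t)a * E.W], b);
    bs_set(&E.adj[(size_t)b * E.W], a);
  }
  E.inQ.assign(E.W, 0);
  for (int k = 0; k < query0.size(); ++k) bs_set(E.inQ.data(), query0[k]);
  E.g = {gp, gq, gstrict};
  E.mu = {mp, mq, false};
  E.min_size = min_size;
  E.p2 = use_p2;
  E.p3 = use_p3;
  E.p4 = use_p4;
  E.n2.resize(n);
  E.n2done.assign(n, 0);
  ModIndex* idx = make_index(index_kind);
  E.idx = idx;

  std::vector<int> seeds(query0.begin(), query0.end());
  std::sort(seeds.begin(), seeds.end());
  E.run(seeds);
  delete idx;

  List mods(E.out.size());
  for (size_t i = 0; i < E.out.size(); ++i) {
    IntegerVector m(E.out[i].size());
    for (size_t j = 0; j < E.out[i].size(); ++j) m[j] = E.out[i][j] + 1;
    mods[i] = m;
  }
  return List::create(_["modules"] = mods, _["nodes"] = (double)E.nodes);
}

// Deduplicate and drop every set strictly contained in another; returns the
// 1-based indices (into `mods`) of the surviving sets.
// [[Rcpp::export]]
IntegerVector cpp_maximality_filter(List mods) {
  int m = mods.size();
  std::vector<std::vector<int>> sets(m);
  int maxv = -1;
  for (int i = 0; i < m; ++i) {
    IntegerVector s = mods[i];
    sets[i].assign(s.begin(), s.end());
    std::sort(sets[i].begin(), sets[i].end());
    if (!sets[i].empty()) maxv = std::max(maxv, sets[i].back());
  }
  // dedupe, keeping first occurrence
  std::vector<int> order;
  {
    std::map<std::vector<int>, int> seen;
    for (int i = 0; i < m; ++i)
      if (seen.insert({sets[i], i}).second) order.push_back(i);
  }
  // inverted index over the deduped sets
  FlatIndex fx;
  std::vector<int> ids;  // registry position -> original index
  for (int i : order) {
    fx.reg(sets[i]);
    ids.push_back(i);
  }
  std::vector<int> keep;
  for (size_t r = 0; r < order.size(); ++r) {
    const std::vector<int>& A = sets[order[r]];
    // AND the rows of A's members; any set bit other than r means a superset
    size_t minw = SIZE_MAX;
    bool empty = false;
    for (int v : A) {
      if ((size_t)v >= fx.rows.size() || fx.rows[v].empty()) {
        empty = true;
        break;
      }
      minw = std::min(minw, fx.rows[v].size());
    }
    if (empty) continue;  // cannot happen: A registered itself
    bool dominated = false;
    for (size_t w = 0; w < minw && !dominated; ++w) {
      uint64_t acc = ~0ull;
      for (int v : A) {
        acc &= fx.rows[v][w];
        if (!acc) break;
      }
      if (w == (r >> 6)) acc &= ~(1ull << (r & 63));  // mask own id
      if (acc) dominated = true;
    }
    if (!dominated) keep.push_back(order[r] + 1);
  }
  return IntegerVector(keep.begin(), keep.end());
}

// Exhaustive reference enumerator over all vertex subsets (n <= 22).
// Independent of the backtracking search: no pruning, no registry.
// [[Rcpp::export]]
List cpp_brute_force(int n, IntegerVector ei, IntegerVector ej,
                     IntegerVector query0, long long gp, long long gq,
                     bool gstrict, long long mp, long long mq, int min_size) {
  if (n > 22) stop("exhaustive enumeration refused for n > 22 vertices");
  Rat g{gp, gq, gstrict}, mu{mp, mq, false};
  std::vector<uint32_t> adjm(n, 0);
  for (int k = 0; k < ei.size(); ++k) {
    int a = ei[k], b = ej[k];
    if (a == b) continue;
    adjm[a] |= 1u << b;
    adjm[b] |= 1u << a;
  }
  uint32_t qmask = 0;
  for (int k = 0; k < query0.size(); ++k) qmask |= 1u << query0[k];

  std::vector<uint32_t> kept;
  uint32_t top = (n == 32) ? 0xFFFFFFFFu : ((1u << n) - 1);
  for (uint32_t mask = 1; mask <= top; ++mask) {
    int s = __builtin_popcount(mask);
    if (s < min_size) continue;
    if (!mu_ok(__builtin_popcount(mask & qmask), s, mu)) continue;
    long long need = rat_min(g, s - 1);
    bool ok = true;
    uint32_t rest = mask;
    while (rest && ok) {
      int v = __builtin_ctz(rest);
      rest &= rest - 1;
      if (__builtin_popcount(adjm[v] & mask) < (int)need) ok = false;
    }
    if (ok) kept.push_back(mask);
    if ((mask & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // maximality among all kept feasible sets (feasibility is not
  // anti-monotone, so every kept set must be compared)
  size_t k = kept.size();
  std::vector<std::vector<uint64_t>> rows(n);
  size_t kw = (k + 63) / 64;
  for (int v = 0; v < n; ++v) rows[v].assign(kw, 0);
  for (size_t i = 0; i < k; ++i) {
    uint32_t rest = kept[i];
    while (rest) {
      int v = __builtin_ctz(rest);
      rest &= rest - 1;
      rows[v][i >> 6] |= 1ull << (i & 63);
    }
  }
  std::vector<std::vector<int>> final_sets;
  for (size_t i = 0; i < k; ++i) {
    bool dominated = false;
    for (size_t w = 0; w < kw && !dominated; ++w) {
      uint64_t acc = ~0ull;
      uint32_t rest = kept[i];
      while (rest) {
        int v = __builtin_ctz(rest);
        rest &= rest - 1;
        acc &= rows[v][w];
        if (!acc) break;
      }
      if (w == (i >> 6)) acc &= ~(1ull << (i & 63));
      if (acc) dominated = true;
    }
    if (!dominated) {
      std::vector<int> s;
      uint32_t rest = kept[i];
      while (rest) {
        int v = __builtin_ctz(rest);
        rest &= rest - 1;
        s.push_back(v + 1);
      }
      final_sets.push_back(std::move(s));
    }
  }
  // deterministic order: size descending, then lexicographic
  std::sort(final_sets.begin(), final_sets.end(),
            [](const std::vector<int>& a, const std::vector<int>& b) {
              if (a.size() != b.size()) return a.size() > b.size();
              return a < b;
            });
  List outl(final_sets.size());
  for (size_t i = 0; i < final_sets.size(); ++i)
    outl[i] = IntegerVector(final_sets[i].begin(), final_sets[i].end());
  return outl;
}

// ---------------------------------------------------------------------------
// standalone registry handles (for direct use and testing)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_index_new(int kind) {
  ModIndex* p = make_index(kind);
  if (!p) stop("unknown index kind");
  XPtr<ModIndex> xp(p, true);
  return xp;
}

// [[Rcpp::export]]
int cpp_index_register(SEXP xp, IntegerVector vertices0) {
  XPtr<ModIndex> p(xp);
  std::vector<int> vs(vertices0.begin(), vertices0.end());
  std::sort(vs.begin(), vs.end());
  p->reg(vs);
  return (int)p->nreg - 1;
}

// [[Rcpp::export]]
bool cpp_index_superset(SEXP xp, IntegerVector vertices0) {
  XPtr<ModIndex> p(xp);
  std::vector<int> vs(vertices0.begin(), vertices0.end());
  std::sort(vs.begin(), vs.end());
  return p->superset(vs);
}

// [[Rcpp::export]]
int cpp_index_count(SEXP xp) {
  XPtr<ModIndex> p(xp);
  return (int)p->nreg;
}

// [[Rcpp::export]]
DataFrame cpp_index_bit_counts(SEXP xp) {
  XPtr<ModIndex> p(xp);
  std::map<int, int> bc = p->bit_counts();
  IntegerVector v(bc.size()), c(bc.size());
  int i = 0;
  for (auto& kv : bc) {
    v[i] = kv.first + 1;
    c[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["vertex"] = v, _["n_modules"] = c);
}
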