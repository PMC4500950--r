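#include <Rcpp.h>
#include <unordered_set>
#include <map>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Colored triad machinery.
//
// A colored triad class is encoded as a single integer
//   code = adjcode * 64 + colorcode
// where adjcode packs the 6 off-diagonal adjacency bits in the fixed pair
// order (1,2),(1,3),(2,1),(2,3),(3,1),(3,2) (first pair most significant)
// and colorcode = c1*16 + c2*4 + c3 with colors in 0..3. The canonical code
// of a triple is the minimum over the 6 node permutations; because adjcode
// dominates the encoding, minimisation restricts the coloring to the
// automorphisms of the canonical structure.

static const int PERMS[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
static const int PAIRS[6][2] = {{0,1},{0,2},{1,0},{1,2},{2,0},{2,1}};

static inline long long ekey(int u, int v, long long n) {
  return (long long)u * n + v;
}

static int canon_code(const bool adj[3][3], const int col[3], int *perm_out) {
  int best = INT_MAX, bestp = 0;
  for (int p = 0; p < 6; ++p) {
    int a = 0;
    for (int k = 0; k < 6; ++k)
      a = (a << 1) | (adj[PERMS[p][PAIRS[k][0]]][PERMS[p][PAIRS[k][1]]] ? 1 : 0);
    int c = col[PERMS[p][0]] * 16 + col[PERMS[p][1]] * 4 + col[PERMS[p][2]];
    int code = a * 64 + c;
    if (code < best) { best = code; bestp = p; }
  }
  if (perm_out) *perm_out = bestp;
  return best;
}

// Census of weakly connected induced 3-node subgraphs with node colors.
// Nodes 0-based; colors in 0..3; self-loops in the input are ignored.
// Each connected triple {a<b<c} is visited exactly once: from its
// lexicographically smallest adjacent (undirected) pair.
// [[Rcpp::export]]
List triad_census_colored_cpp(int n, IntegerVector from, IntegerVector to,
                              IntegerVector colors, bool keep_instances) {
  std::unordered_set<long long> eset, uset;
  std::vector<std::vector<int>> nbr(n);
  int m = from.size();
  for (int i = 0; i < m; ++i) {
    int u = from[i], v = to[i];
    if (u == v) continue;
    eset.insert(ekey(u, v, n));
    int a = std::min(u, v), b = std::max(u, v);
    if (uset.insert(ekey(a, b, n)).second) {
      nbr[a].push_back(b);
      nbr[b].push_back(a);
    }
  }
  for (int i = 0; i < n; ++i) std::sort(nbr[i].begin(), nbr[i].end());

  std::map<int, int> counts;
  std::vector<int> inst_code, inst_a, inst_b, inst_c;

  std::vector<int> third;
  for (int u = 0; u < n; ++u) {
    for (size_t iv = 0; iv < nbr[u].size(); ++iv) {
      int v = nbr[u][iv];
      if (v <= u) continue;
      third.clear();
      std::set_union(nbr[u].begin(), nbr[u].end(),
                     nbr[v].begin(), nbr[v].end(), std::back_inserter(third));
      for (size_t iw = 0; iw < third.size(); ++iw) {
        int w = third[iw];
        if (w <= u || w == v) continue;
        if (w < v && uset.count(ekey(u, w, n))) continue;  // pair (u,w) is smaller
        int t[3] = {u, v, w};
        bool adj[3][3];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            adj[i][j] = (i != j) && eset.count(ekey(t[i], t[j], n));
        int col[3] = {colors[u], colors[v], colors[w]};
        int perm;
        int code = canon_code(adj, col, &perm);
        counts[code] += 1;
        if (keep_instances) {
          inst_code.push_back(code);
          inst_a.push_back(t[PERMS[perm][0]]);
          inst_b.push_back(t[PERMS[perm][1]]);
          inst_c.push_back(t[PERMS[perm][2]]);
        }
      }
    }
  }

  int k = counts.size();
  IntegerVector out_code(k), out_count(k);
  int i = 0;
  for (std::map<int, int>::iterator it = counts.begin(); it != counts.end(); ++it) {
    out_code[i] = it->first;
    out_count[i] = it->second;
    ++i;
  }
  List res = List::create(_["code"] = out_code, _["count"] = out_count);
  if (keep_instances) {
    res["inst_code"] = wrap(inst_code);
    res["inst_n1"] = wrap(inst_a);
    res["inst_n2"] = wrap(inst_b);
    res["inst_n3"] = wrap(inst_c);
  }
  return res;
}

// Canonical colored code of a single triple (used for cross-checks).
// [[Rcpp::export]]
int canon_code_cpp(LogicalMatrix adjacency, IntegerVector colors) {
  bool adj[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      adj[i][j] = (i != j) && adjacency(i, j);
  int col[3] = {colors[0], colors[1], colors[2]};
  return canon_code(adj, col, 0);
}

// Degree- and target-state-preserving randomization by constrained double
// edge swaps. Single (non-mutual) edges are swapped with single edges,
// mutual dyads with mutual dyads, so the count of every two-node subgraph
// (single edge, mutual pair) is preserved alongside in/out degrees and each
// source's per-state target counts. Swaps that would create a self-loop, a
// duplicate edge, or convert a single edge into a mutual pair are rejected.
// Self-loops in the input are left untouched and returned unchanged.
// [[Rcpp::export]]
List swap_randomize_cpp(int n, IntegerVector from, IntegerVector to,
                        IntegerVector colors, int n_attempts) {
  std::unordered_set<long long> eset;
  int m = from.size();
  std::vector<int> loops_u;
  for (int i = 0; i < m; ++i) {
    if (from[i] == to[i]) { loops_u.push_back(from[i]); continue; }
    eset.insert(ekey(from[i], to[i], n));
  }
  std::vector<std::pair<int,int> > singles, dyads;
  for (std::unordered_set<long long>::iterator it = eset.begin(); it != eset.end(); ++it) {
    int u = (int)(*it / n), v = (int)(*it % n);
    if (eset.count(ekey(v, u, n))) {
      if (u < v) dyads.push_back(std::make_pair(u, v));
    } else {
      singles.push_back(std::make_pair(u, v));
    }
  }

  int ns = singles.size(), nd = dyads.size();
  int accepted = 0;
  for (int a = 0; a < n_attempts; ++a) {
    if (ns + nd < 2) break;
    int pick = (int)(unif_rand() * (ns + nd));
    if (pick >= ns + nd) pick = ns + nd - 1;
    if (pick < ns) {
      if (ns < 2) continue;
      int i = (int)(unif_rand() * ns); if (i >= ns) i = ns - 1;
      int j = (int)(unif_rand() * ns); if (j >= ns) j = ns - 1;
      if (i == j) continue;
      int u = singles[i].first, v = singles[i].second;
      int x = singles[j].first, y = singles[j].second;
      if (colors[v] != colors[y]) continue;
      if (v == y || u == y || x == v) continue;
      if (eset.count(ekey(u, y, n)) || eset.count(ekey(x, v, n))) continue;
      if (eset.count(ekey(y, u, n)) || eset.count(ekey(v, x, n))) continue;
      eset.erase(ekey(u, v, n)); eset.erase(ekey(x, y, n));
      eset.insert(ekey(u, y, n)); eset.insert(ekey(x, v, n));
      singles[i] = std::make_pair(u, y);
      singles[j] = std::make_pair(x, v);
      ++accepted;
    } else {
      if (nd < 2) continue;
      int i = (int)(unif_rand() * nd); if (i >= nd) i = nd - 1;
      int j = (int)(unif_rand() * nd); if (j >= nd) j = nd - 1;
      if (i == j) continue;
      int u = dyads[i].first, v = dyads[i].second;
      int x = dyads[j].first, y = dyads[j].second;
      if (unif_rand() < 0.5) std::swap(x, y);
      // (u<->v, x<->y) -> (u<->y, x<->v): u and x exchange partners
      if (colors[v] != colors[y] || colors[u] != colors[x]) continue;
      if (u == y || x == v || u == x || v == y) continue;
      if (eset.count(ekey(u, y, n)) || eset.count(ekey(y, u, n))) continue;
      if (eset.count(ekey(x, v, n)) || eset.count(ekey(v, x, n))) continue;
      eset.erase(ekey(u, v, n)); eset.erase(ekey(v, u, n));
      eset.erase(ekey(x, y, n)); eset.erase(ekey(y, x, n));
      eset.insert(ekey(u, y, n)); eset.insert(ekey(y, u, n));
      eset.insert(ekey(x, v, n)); eset.insert(ekey(v, x, n));
      dyads[i] = std::make_pair(std::min(u, y), std::max(u, y));
      dyads[j] = std::make_pair(std::min(x, v), std::max(x, v));
      ++accepted;
    }
  }

  int mm = eset.size() + loops_u.size();
  IntegerVector of(mm), ot(mm);
  int i = 0;
  for (std::unordered_set<long long>::iterator it = eset.begin(); it != eset.end(); ++it) {
    of[i] = (int)(*it / n); ot[i] = (int)(*it % n); ++i;
  }
  for (size_t l = 0; l < loops_u.size(); ++l) { of[i] = loops_u[l]; ot[i] = loops_u[l]; ++i; }
  return List::create(_["from"] = of, _["to"] = ot, _["accepted"] = accepted);
}
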