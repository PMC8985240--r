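// Exact maximum common connected substructure search.
//
// Backtracking over pairs of compatible atoms: a mapping is grown only
// through bonds present (and compatible) in both molecules, so the common
// substructure is connected by construction. Explored extension pairs are
// forbidden in later sibling branches, which enumerates every maximal
// common connected subgraph once; a simple upper bound on the achievable
// score prunes the search. Exact for the molecule sizes the package
// accepts (a hard size guard is enforced on the R side).

#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

namespace {

struct Mol {
  int n;
  std::vector<int> elem;
  std::vector<int> chg;
  // adjacency: neighbor index and bond order (1,2,3; 4 = aromatic)
  std::vector<std::vector<std::pair<int, int>>> adj;
};

Mol build_mol(const IntegerVector& elem, const IntegerVector& chg,
              const IntegerMatrix& bonds) {
  Mol m;
  m.n = elem.size();
  m.elem.assign(elem.begin(), elem.end());
  m.chg.assign(chg.begin(), chg.end());
  m.adj.resize(m.n);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int a = bonds(k, 0) - 1, b = bonds(k, 1) - 1, o = bonds(k, 2);
    m.adj[a].push_back(std::make_pair(b, o));
    m.adj[b].push_back(std::make_pair(a, o));
  }
  return m;
}

struct Search {
  const Mol* A;
  const Mol* B;
  bool charge_sensitive;
  bool bond_exact;
  bool count_bonds;  // feature unit atoms+bonds

  std::vector<int> mapA, mapB;        // current mapping (-1 = unmapped)
  std::vector<std::pair<int, int>> order;  // pairs in addition order
  int cur_atoms, cur_edges;

  int best_score, best_atoms, best_edges;
  std::vector<std::pair<int, int>> best_mapping;  // sorted by A index

  bool atom_ok(int i, int j) const {
    if (A->elem[i] != B->elem[j]) return false;
    if (charge_sensitive && A->chg[i] != B->chg[j]) return false;
    return true;
  }
  bool bond_ok(int oa, int ob) const {
    if (!bond_exact) return true;
    return oa == ob;
  }

  int score() const { return count_bonds ? cur_atoms + cur_edges : cur_atoms; }

  // number of compatible common edges gained by adding (u,v)
  int gained_edges(int u, int v) const {
    int g = 0;
    for (size_t k = 0; k < A->adj[u].size(); ++k) {
      int x = A->adj[u][k].first, oa = A->adj[u][k].second;
      if (mapA[x] < 0) continue;
      int y = mapA[x];
      for (size_t l = 0; l < B->adj[v].size(); ++l) {
        if (B->adj[v][l].first == y && bond_ok(oa, B->adj[v][l].second)) {
          ++g;
          break;
        }
      }
    }
    return g;
  }

  void consider_best() {
    int s = score();
    if (s < best_score) return;
    std::vector<std::pair<int, int>> sorted(order);
    std::sort(sorted.begin(), sorted.end());
    if (s > best_score || sorted < best_mapping || best_mapping.empty()) {
      best_score = s;
      best_atoms = cur_atoms;
      best_edges = cur_edges;
      best_mapping = sorted;
    }
  }

  void extend(std::vector<std::vector<bool>>& forbidden) {
    consider_best();
    // candidate extension pairs: adjacent to the mapped core in both graphs
    std::vector<std::pair<int, int>> cands;
    if (cur_atoms == 0) {
      for (int i = 0; i < A->n; ++i)
        for (int j = 0; j < B->n; ++j)
          if (!forbidden[i][j] && atom_ok(i, j))
            cands.push_back(std::make_pair(i, j));
    } else {
      std::vector<bool> seen(A->n, false);
      for (size_t t = 0; t < order.size(); ++t) {
        int x = order[t].first, y = order[t].second;
        for (size_t k = 0; k < A->adj[x].size(); ++k) {
          int u = A->adj[x][k].first, oa = A->adj[x][k].second;
          if (mapA[u] >= 0) continue;
          for (size_t l = 0; l < B->adj[y].size(); ++l) {
            int v = B->adj[y][l].first, ob = B->adj[y][l].second;
            if (mapB[v] >= 0) continue;
            if (forbidden[u][v]) continue;
            if (!atom_ok(u, v)) continue;
            if (!bond_ok(oa, ob)) continue;
            cands.push_back(std::make_pair(u, v));
          }
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    }
    if (cands.empty()) return;

    // upper bound: every remaining candidate atom adds at most 1 (+ degree
    // bound on new common edges when counting bonds)
    int remA = A->n - cur_atoms, remB = B->n - cur_atoms;
    int rem = remA < remB ? remA : remB;
    int per_atom = count_bonds ? 5 : 1;  // organic degree <= 4
    if (score() + rem * per_atom < best_score) return;

    std::vector<std::pair<int, int>> locally_forbidden;
    for (size_t c = 0; c < cands.size(); ++c) {
      int u = cands[c].first, v = cands[c].second;
      if (forbidden[u][v]) continue;
      int g = gained_edges(u, v);
      mapA[u] = v;
      mapB[v] = u;
      order.push_back(std::make_pair(u, v));
      cur_atoms += 1;
      cur_edges += g;
      extend(forbidden);
      cur_edges -= g;
      cur_atoms -= 1;
      order.pop_back();
      mapA[u] = -1;
      mapB[v] = -1;
      forbidden[u][v] = true;
      locally_forbidden.push_back(cands[c]);
    }
    for (size_t c = 0; c < locally_forbidden.size(); ++c)
      forbidden[locally_forbidden[c].first][locally_forbidden[c].second] = false;
  }
};

}  // namespace

// [[Rcpp::export(name = ".mcs_search")]]
List mcs_search(IntegerVector elemA, IntegerVector chgA, IntegerMatrix bondsA,
                IntegerVector elemB, IntegerVector chgB, IntegerMatrix bondsB,
                bool charge_sensitive, bool bond_exact, bool count_bonds) {
  Mol A = build_mol(elemA, chgA, bondsA);
  Mol B = build_mol(elemB, chgB, bondsB);
  Search s;
  s.A = &A;
  s.B = &B;
  s.charge_sensitive = charge_sensitive;
  s.bond_exact = bond_exact;
  s.count_bonds = count_bonds;
  s.mapA.assign(A.n, -1);
  s.mapB.assign(B.n, -1);
  s.cur_atoms = s.cur_edges = 0;
  s.best_score = 0;
  s.best_atoms = s.best_edges = 0;
  std::vector<std::vector<bool>> forbidden(A.n, std::vector<bool>(B.n, false));
  s.extend(forbidden);

  IntegerMatrix mapping(s.best_mapping.size(), 2);
  for (size_t k = 0; k < s.best_mapping.size(); ++k) {
    mapping(k, 0) = s.best_mapping[k].first + 1;
    mapping(k, 1) = s.best_mapping[k].second + 1;
  }
  return List::create(_["atoms"] = s.best_atoms, _["edges"] = s.best_edges,
                      _["score"] = s.best_score, _["mapping"] = mapping);
}
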