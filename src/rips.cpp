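// Vietoris-Rips persistence in dimensions 0 and 1 from a dense distance
// matrix. H0 via union-find over the edge filtration; H1 via GF(2)
// boundary-matrix reduction of the triangle columns (pivot rows are edges in
// filtration order), the standard dimension-by-dimension scheme.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Edge {
  double w;
  int i, j;   // 0-based vertex ids, i < j
};

struct Tri {
  double w;       // filtration value = max of the three edge weights
  int e1, e2, e3; // sorted filtration-order edge indices, e1 < e2 < e3
};

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

// symmetric difference of two sorted int vectors (GF(2) column addition)
void sym_diff(std::vector<int> &a, const std::vector<int> &b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  a.swap(out);
}

} // namespace

// [[Rcpp::export]]
List rips_pairs_cpp(NumericMatrix D, double R) {
  const int n = D.nrow();

  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (D(i, j) <= R) edges.push_back({D(i, j), i, j});

  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge &a, const Edge &b) {
                     if (a.w != b.w) return a.w < b.w;
                     if (a.i != b.i) return a.i < b.i;
                     return a.j < b.j;
                   });
  const int m = (int)edges.size();

  // edge index lookup (filtration order) by vertex pair
  std::vector<std::vector<int>> eidx(n, std::vector<int>(n, -1));
  for (int e = 0; e < m; ++e) {
    eidx[edges[e].i][edges[e].j] = e;
    eidx[edges[e].j][edges[e].i] = e;
  }

  // ---- H0: union-find; merging edges are deaths, others create cycles ----
  UnionFind uf(n);
  std::vector<double> h0_death;
  std::vector<bool> creator(m, false);
  for (int e = 0; e < m; ++e) {
    if (uf.unite(edges[e].i, edges[e].j))
      h0_death.push_back(edges[e].w);
    else
      creator[e] = true;
  }
  int n_inf_h0 = 0;
  for (int v = 0; v < n; ++v)
    if (uf.find(v) == v) ++n_inf_h0;

  // ---- H1: reduce the triangle boundary matrix ----
  std::vector<Tri> tris;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (D(i, j) > R) continue;
      for (int k = j + 1; k < n; ++k) {
        if (D(i, k) > R || D(j, k) > R) continue;
        int a = eidx[i][j], b = eidx[i][k], c = eidx[j][k];
        int lo = std::min(a, std::min(b, c));
        int hi = std::max(a, std::max(b, c));
        int mid = a + b + c - lo - hi;
        double w = std::max(D(i, j), std::max(D(i, k), D(j, k)));
        tris.push_back({w, lo, mid, hi});
      }
    }
  std::stable_sort(tris.begin(), tris.end(),
                   [](const Tri &a, const Tri &b) {
                     if (a.w != b.w) return a.w < b.w;
                     return a.e3 != b.e3 ? a.e3 < b.e3
                          : (a.e2 != b.e2 ? a.e2 < b.e2 : a.e1 < b.e1);
                   });

  std::vector<int> pivot_col(m, -1);           // edge row -> column owning it
  std::vector<std::vector<int>> cols(tris.size());
  std::vector<double> h1_birth, h1_death;
  std::vector<char> paired(m, 0);

  for (size_t t = 0; t < tris.size(); ++t) {
    std::vector<int> col = {tris[t].e1, tris[t].e2, tris[t].e3};
    while (!col.empty()) {
      int piv = col.back();
      int owner = pivot_col[piv];
      if (owner < 0) break;
      sym_diff(col, cols[owner]);
    }
    if (!col.empty()) {
      int piv = col.back();
      pivot_col[piv] = (int)t;
      cols[t] = col;
      double birth = edges[piv].w;
      double death = tris[t].w;
      if (death > birth) { // drop zero-persistence pairs
        h1_birth.push_back(birth);
        h1_death.push_back(death);
      }
      paired[piv] = 1;
    }
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // creator edges never killed by a triangle within the filtration
  std::vector<double> h1_inf_birth;
  for (int e = 0; e < m; ++e)
    if (creator[e] && !paired[e]) h1_inf_birth.push_back(edges[e].w);

  return List::create(
      _["h0_death"] = h0_death,
      _["n_inf_h0"] = n_inf_h0,
      _["h1_birth"] = h1_birth,
      _["h1_death"] = h1_death,
      _["h1_inf_birth"] = h1_inf_birth);
}
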