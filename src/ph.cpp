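#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---- helpers ---------------------------------------------------------------

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  }
};

// Enumerate the 1- and 2-skeleton of a Vietoris-Rips complex: all edges with
// length <= max_eps (closed balls), and all triangles whose three edges are
// present. Simplex value = max pairwise distance. Output is sorted by
// (value, lexicographic vertex tuple) so it is directly a filtration order.
// [[Rcpp::export]]
List cpp_vr_skeleton(NumericVector x, NumericVector y, double max_eps,
                     int max_dim) {
  const int n = x.size();
  std::vector<int> ei, ej;
  std::vector<double> ev;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d <= max_eps) { ei.push_back(i); ej.push_back(j); ev.push_back(d); }
    }
  }
  const int m = ei.size();
  std::vector<int> ord(m);
  for (int k = 0; k < m; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ev[a] != ev[b]) return ev[a] < ev[b];
    if (ei[a] != ei[b]) return ei[a] < ei[b];
    return ej[a] < ej[b];
  });
  IntegerMatrix edges(m, 2);
  NumericVector edge_values(m);
  for (int k = 0; k < m; ++k) {
    edges(k, 0) = ei[ord[k]] + 1;
    edges(k, 1) = ej[ord[k]] + 1;
    edge_values[k] = ev[ord[k]];
  }

  IntegerMatrix tri(0, 3);
  NumericVector tri_values(0);
  if (max_dim >= 2 && m > 0) {
    // adjacency with distances, neighbours sorted by index
    std::vector<std::vector<std::pair<int, double>>> adj(n);
    for (int k = 0; k < m; ++k) {
      int a = edges(k, 0) - 1, b = edges(k, 1) - 1;
      adj[a].push_back({b, edge_values[k]});
      adj[b].push_back({a, edge_values[k]});
    }
    for (int i = 0; i < n; ++i)
      std::sort(adj[i].begin(), adj[i].end());
    std::vector<int> ti, tj, tk;
    std::vector<double> tv;
    for (int k = 0; k < m; ++k) {
      int a = edges(k, 0) - 1, b = edges(k, 1) - 1;
      double dab = edge_values[k];
      // common neighbours c > b ensures each triangle once (a < b < c)
      size_t pa = 0, pb = 0;
      const auto &na = adj[a], &nb = adj[b];
      while (pa < na.size() && pb < nb.size()) {
        if (na[pa].first < nb[pb].first) ++pa;
        else if (na[pa].first > nb[pb].first) ++pb;
        else {
          int c = na[pa].first;
          if (c > b) {
            double v = std::max(dab, std::max(na[pa].second, nb[pb].second));
            ti.push_back(a); tj.push_back(b); tk.push_back(c); tv.push_back(v);
          }
          ++pa; ++pb;
        }
      }
    }
    const int t = ti.size();
    std::vector<int> tord(t);
    for (int q = 0; q < t; ++q) tord[q] = q;
    std::sort(tord.begin(), tord.end(), [&](int a, int b) {
      if (tv[a] != tv[b]) return tv[a] < tv[b];
      if (ti[a] != ti[b]) return ti[a] < ti[b];
      if (tj[a] != tj[b]) return tj[a] < tj[b];
      return tk[a] < tk[b];
    });
    tri = IntegerMatrix(t, 3);
    tri_values = NumericVector(t);
    for (int q = 0; q < t; ++q) {
      tri(q, 0) = ti[tord[q]] + 1;
      tri(q, 1) = tj[tord[q]] + 1;
      tri(q, 2) = tk[tord[q]] + 1;
      tri_values[q] = tv[tord[q]];
    }
  }
  return List::create(_["edges"] = edges, _["edge_values"] = edge_values,
                      _["triangles"] = tri, _["triangle_values"] = tri_values);
}

// Dimension-0 persistence by union-find with the elder rule. Vertices carry
// their own birth values (0 for VR, R - |x - mu| for the radial filtration);
// edges must arrive sorted by (value, lexicographic vertex pair). On a merge
// the component with the larger birth dies; ties are broken so that the
// component containing the smaller minimum vertex index survives.
// [[Rcpp::export]]
NumericMatrix cpp_ph0(NumericVector vertex_values, IntegerMatrix edges,
                      NumericVector edge_values) {
  const int n = vertex_values.size();
  const int m = edges.nrow();
  UnionFind uf(n);
  std::vector<double> birth(n);
  std::vector<int> minv(n);
  for (int i = 0; i < n; ++i) { birth[i] = vertex_values[i]; minv[i] = i; }
  std::vector<double> bb, dd;
  for (int k = 0; k < m; ++k) {
    int ra = uf.find(edges(k, 0) - 1);
    int rb = uf.find(edges(k, 1) - 1);
    if (ra == rb) continue;
    // decide survivor: smaller birth; tie -> smaller min vertex index
    int surv = ra, dead = rb;
    if (birth[rb] < birth[ra] ||
        (birth[rb] == birth[ra] && minv[rb] < minv[ra])) {
      surv = rb; dead = ra;
    }
    bb.push_back(birth[dead]);
    dd.push_back(edge_values[k]);
    uf.parent[dead] = surv;
    if (minv[dead] < minv[surv]) minv[surv] = minv[dead];
  }
  // survivors get infinite bars
  for (int i = 0; i < n; ++i) {
    if (uf.find(i) == i) {
      bb.push_back(birth[i]);
      dd.push_back(R_PosInf);
    }
  }
  NumericMatrix out(bb.size(), 2);
  for (size_t k = 0; k < bb.size(); ++k) {
    out(k, 0) = bb[k];
    out(k, 1) = dd[k];
  }
  colnames(out) = CharacterVector::create("birth", "death");
  return out;
}

// Dimension-1 persistence: reduction of the triangle boundary matrix over
// GF(2). Edges and triangles must be in filtration order. Positive edges
// (those closing a cycle in the union-find sweep) that are never a pivot of
// a reduced triangle column give infinite bars.
// [[Rcpp::export]]
NumericMatrix cpp_ph1(int n_vertices, IntegerMatrix edges,
                      NumericVector edge_values, IntegerMatrix triangles,
                      NumericVector triangle_values) {
  const int m = edges.nrow();
  const int t = triangles.nrow();
  // positive edges via union-find
  UnionFind uf(n_vertices);
  std::vector<bool> positive(m, false);
  // map (a,b) -> edge filtration index for triangle boundary lookup
  std::vector<std::vector<std::pair<int, int>>> eidx(n_vertices);
  for (int k = 0; k < m; ++k) {
    int a = uf.find(edges(k, 0) - 1), b = uf.find(edges(k, 1) - 1);
    if (a == b) positive[k] = true; else uf.parent[a] = b;
    eidx[edges(k, 0) - 1].push_back({edges(k, 1) - 1, k});
  }
  for (int i = 0; i < n_vertices; ++i) std::sort(eidx[i].begin(), eidx[i].end());
  auto edge_of = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    const auto &v = eidx[a];
    auto it = std::lower_bound(v.begin(), v.end(), std::make_pair(b, -1));
    return it->second;
  };

  std::vector<int> low2col(m, -1);
  std::vector<std::vector<int>> cols;
  std::vector<double> bb, dd;
  std::vector<bool> paired(m, false);
  std::vector<int> col, tmp;
  for (int q = 0; q < t; ++q) {
    int a = triangles(q, 0) - 1, b = triangles(q, 1) - 1, c = triangles(q, 2) - 1;
    col = {edge_of(a, b), edge_of(a, c), edge_of(b, c)};
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int p = col.back();
      if (low2col[p] < 0) break;
      const std::vector<int> &other = cols[low2col[p]];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(), other.begin(),
                                    other.end(), std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      int p = col.back();
      low2col[p] = cols.size();
      cols.push_back(col);
      paired[p] = true;
      bb.push_back(edge_values[p]);
      dd.push_back(triangle_values[q]);
    }
  }
  for (int k = 0; k < m; ++k) {
    if (positive[k] && !paired[k]) {
      bb.push_back(edge_values[k]);
      dd.push_back(R_PosInf);
    }
  }
  NumericMatrix out(bb.size(), 2);
  for (size_t k = 0; k < bb.size(); ++k) {
    out(k, 0) = bb[k];
    out(k, 1) = dd[k];
  }
  colnames(out) = CharacterVector::create("birth", "death");
  return out;
}

// Connected-component labels (1-based, ordered by smallest vertex index).
// [[Rcpp::export]]
IntegerVector cpp_components(int n_vertices, IntegerMatrix edges) {
  UnionFind uf(n_vertices);
  for (int k = 0; k < edges.nrow(); ++k) {
    int a = uf.find(edges(k, 0) - 1), b = uf.find(edges(k, 1) - 1);
    if (a != b) uf.parent[a] = b;
  }
  std::vector<int> label(n_vertices, 0);
  IntegerVector out(n_vertices);
  int next = 0;
  for (int i = 0; i < n_vertices; ++i) {
    int r = uf.find(i);
    if (label[r] == 0) label[r] = ++next;
    out[i] = label[r];
  }
  return out;
}
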