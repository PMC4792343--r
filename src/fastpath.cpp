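// Compiled kernels for the per-step hot path: gathering rod segments from
// the edge list, walking cell boundary loops, shoelace areas and area
// gradients.  These operate directly on the R-side representation (lists
// of edges/cells) so the R code keeps a single source of truth.

#include <Rcpp.h>
using namespace Rcpp;

// Pooled rod segments of all active (non-NULL) edges.
// Returns list(i, j, gamma, edge) with 1-based node and edge ids.
// [[Rcpp::export(name = ".pc_segments")]]
List pc_segments(List edges) {
  int ne = edges.size();
  int total = 0;
  for (int e = 0; e < ne; ++e) {
    if (Rf_isNull(edges[e])) continue;
    List ed = edges[e];
    IntegerVector ch = ed["chain"];
    total += ch.size() - 1;
  }
  IntegerVector si(total), sj(total), sedge(total);
  NumericVector sg(total);
  int k = 0;
  for (int e = 0; e < ne; ++e) {
    if (Rf_isNull(edges[e])) continue;
    List ed = edges[e];
    IntegerVector ch = ed["chain"];
    double g = as<double>(ed["tension"]);
    for (int s = 0; s + 1 < ch.size(); ++s) {
      si[k] = ch[s];
      sj[k] = ch[s + 1];
      sg[k] = g;
      sedge[k] = e + 1;
      ++k;
    }
  }
  return List::create(_["i"] = si, _["j"] = sj, _["gamma"] = sg,
                      _["edge"] = sedge);
}

// Boundary node chains of the given cells from their signed edge loops.
// loops: list of signed 1-based edge ids (+forward / -reversed).
// [[Rcpp::export(name = ".pc_loop_nodes")]]
List pc_loop_nodes(List edges, List loops) {
  int nc = loops.size();
  List out(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector loop = loops[c];
    int total = 0;
    for (int l = 0; l < loop.size(); ++l) {
      List ed = edges[std::abs(loop[l]) - 1];
      IntegerVector ch = ed["chain"];
      total += ch.size() - 1;
    }
    IntegerVector nodes(total);
    int k = 0;
    for (int l = 0; l < loop.size(); ++l) {
      List ed = edges[std::abs(loop[l]) - 1];
      IntegerVector ch = ed["chain"];
      int m = ch.size();
      if (loop[l] > 0) {
        for (int s = 0; s < m - 1; ++s) nodes[k++] = ch[s];
      } else {
        for (int s = m - 1; s > 0; --s) nodes[k++] = ch[s];
      }
    }
    out[c] = nodes;
  }
  return out;
}

// Shoelace areas of node loops (1-based ids into pos).
// [[Rcpp::export(name = ".pc_shoelace")]]
NumericVector pc_shoelace(NumericMatrix pos, List loops) {
  int nc = loops.size();
  NumericVector areas(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector v = loops[c];
    int m = v.size();
    double a = 0.0;
    for (int s = 0; s < m; ++s) {
      int i = v[s] - 1, j = v[(s + 1) % m] - 1;
      a += pos(i, 0) * pos(j, 1) - pos(j, 0) * pos(i, 1);
    }
    areas[c] = 0.5 * a;
  }
  return areas;
}

// Area gradients (shoelace derivatives) of node loops, concatenated:
// returns list(nodes, gx, gy, len) where len gives each loop's entry count.
// [[Rcpp::export(name = ".pc_area_grad")]]
List pc_area_grad(NumericMatrix pos, List loops) {
  int nc = loops.size();
  int total = 0;
  for (int c = 0; c < nc; ++c) total += as<IntegerVector>(loops[c]).size();
  IntegerVector nodes(total), len(nc);
  NumericVector gx(total), gy(total);
  int k = 0;
  for (int c = 0; c < nc; ++c) {
    IntegerVector v = loops[c];
    int m = v.size();
    len[c] = m;
    for (int s = 0; s < m; ++s) {
      int prv = v[(s + m - 1) % m] - 1, nxt = v[(s + 1) % m] - 1;
      nodes[k] = v[s];
      gx[k] = 0.5 * (pos(nxt, 1) - pos(prv, 1));
      gy[k] = 0.5 * (pos(prv, 0) - pos(nxt, 0));
      ++k;
    }
  }
  return List::create(_["nodes"] = nodes, _["gx"] = gx, _["gy"] = gy,
                      _["len"] = len);
}
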