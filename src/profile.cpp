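// Topological profile (231 components) and the truncation simulator.
//
// Profile layout (fixed order, all counts):
//   [1:3]     V, E, F        observed vertices; all visible edges; complete faces
//   [4:9]     F3..F8         complete faces by edge count (top bin clipped)
//   [10:15]   V3..V8         complete vertices (no incident incomplete edge) by degree
//   [16:23]   F3+..F10+      faces with at least k visible edges (censored)
//   [24:31]   V3+..V10+      vertices with at least k visible incident edges
//   [32:131]  EV 10x10       complete edges by observed endpoint degrees
//   [132:231] FV 10x10       complete edges by observed flanking-face sizes
// EV/FV are stored symmetrically (both (i,j) and (j,i) set; diagonal counted
// once per edge).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline int clipi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// core accumulator shared by the PG interface and the simulator
void profile_core(int nV, int nE_all, int nF_complete,
                  const std::vector<int> &deg_obs,       // per observed vertex
                  const std::vector<bool> &v_complete,   // no incident partial edge
                  const std::vector<int> &face_vis,      // visible edges per face (>=1)
                  const std::vector<bool> &face_complete,
                  const std::vector<int> &ce_a, const std::vector<int> &ce_b,
                  const std::vector<int> &ce_f1, const std::vector<int> &ce_f2,
                  int *out) {
  for (int i = 0; i < 231; ++i) out[i] = 0;
  out[0] = nV; out[1] = nE_all; out[2] = nF_complete;
  // face distributions
  for (size_t f = 0; f < face_vis.size(); ++f) {
    int s = face_vis[f];
    if (s < 1) continue;
    if (face_complete[f]) out[3 + clipi(s, 3, 8) - 3] += 1;
    int top = s > 10 ? 10 : s;
    for (int k = 3; k <= top; ++k) out[15 + k - 3] += 1;
  }
  // vertex distributions
  for (size_t v = 0; v < deg_obs.size(); ++v) {
    int dgr = deg_obs[v];
    if (dgr < 1) continue;
    if (v_complete[v]) out[9 + clipi(dgr, 3, 8) - 3] += 1;
    int top = dgr > 10 ? 10 : dgr;
    for (int k = 3; k <= top; ++k) out[23 + k - 3] += 1;
  }
  // EV / FV over complete edges
  for (size_t e = 0; e < ce_a.size(); ++e) {
    int i = clipi(deg_obs[ce_a[e]], 1, 10);
    int j = clipi(deg_obs[ce_b[e]], 1, 10);
    out[31 + (i - 1) * 10 + (j - 1)] += 1;
    if (i != j) out[31 + (j - 1) * 10 + (i - 1)] += 1;
    int s1 = ce_f1[e] >= 0 ? clipi(face_vis[ce_f1[e]], 1, 10) : 1;
    int s2 = ce_f2[e] >= 0 ? clipi(face_vis[ce_f2[e]], 1, 10) : 1;
    out[131 + (s1 - 1) * 10 + (s2 - 1)] += 1;
    if (s1 != s2) out[131 + (s2 - 1) * 10 + (s1 - 1)] += 1;
  }
}

} // namespace

// Profile of an explicit polyhedral graph.
// ce: complete edges (rows, 1-based vertex ids); ie: observed endpoint of each
// incomplete edge; face_vis/face_complete: per declared face; ceFaces: per
// complete edge the (1-based) indices of its flanking faces, 0 if unknown.
// [[Rcpp::export(name = ".cpp_profile_pg")]]
IntegerVector cpp_profile_pg(int nv, IntegerMatrix ce, IntegerVector ie,
                             IntegerVector face_vis, LogicalVector face_complete,
                             IntegerMatrix ceFaces) {
  int Ec = ce.nrow(), Ei = ie.size(), F = face_vis.size();
  std::vector<int> deg(nv, 0);
  std::vector<bool> vcomp(nv, true);
  for (int e = 0; e < Ec; ++e) {
    deg[ce(e,0)-1] += 1;
    deg[ce(e,1)-1] += 1;
  }
  for (int e = 0; e < Ei; ++e) {
    deg[ie[e]-1] += 1;
    vcomp[ie[e]-1] = false;
  }
  std::vector<int> fv(F), f1(Ec), f2(Ec);
  std::vector<bool> fc(F);
  int nFc = 0;
  for (int f = 0; f < F; ++f) {
    fv[f] = face_vis[f];
    fc[f] = face_complete[f];
    if (fc[f]) ++nFc;
  }
  for (int e = 0; e < Ec; ++e) {
    f1[e] = ceFaces(e,0) - 1;  // -1 when 0 (missing)
    f2[e] = ceFaces(e,1) - 1;
  }
  IntegerVector out(231);
  std::vector<int> buf(231);
  std::vector<int> ea(Ec), eb(Ec);
  for (int e = 0; e < Ec; ++e) { ea[e] = ce(e,0)-1; eb[e] = ce(e,1)-1; }
  profile_core(nv, Ec + Ei, nFc, deg, vcomp, fv, fc, ea, eb, f1, f2, buf.data());
  for (int i = 0; i < 231; ++i) out[i] = buf[i];
  return out;
}

// Batched truncation simulator: rotate, clip at planes z = +-d about the
// vertex centroid, build the incomplete PG implicitly and profile it.
// V: vertices (already centred); edges: 0-based Ex2; faceEdges: list of
// 0-based edge indices per face; edgeFaces: 0-based Ex2 face indices;
// phis: m x 2 rotation angles; del_u: uniforms for vertex deletion (or empty).
// [[Rcpp::export(name = ".cpp_simulate")]]
IntegerMatrix cpp_simulate(NumericMatrix V, IntegerMatrix edges, List faceEdges,
                           IntegerMatrix edgeFaces, NumericMatrix phis, double d,
                           NumericVector del_u, int del_mode = 2) {
  const int nv = V.nrow(), ne = edges.nrow(), nf = faceEdges.size();
  const int m = phis.nrow();
  const bool do_del = del_u.size() > 0;
  IntegerMatrix out(m, 231);

  // flatten face->edge lists
  std::vector<std::vector<int>> fe(nf);
  for (int f = 0; f < nf; ++f) {
    IntegerVector v = faceEdges[f];
    fe[f].assign(v.begin(), v.end());
  }

  std::vector<double> z(nv);
  std::vector<int> status(ne);        // 0 dropped, 1 complete, 2 partial
  std::vector<int> deg(nv), keep(nv);
  std::vector<bool> vcomp(nv);
  std::vector<int> face_vis(nf);
  std::vector<bool> face_complete(nf);
  std::vector<int> ea, eb, ef1, ef2;
  ea.reserve(ne); eb.reserve(ne); ef1.reserve(ne); ef2.reserve(ne);
  std::vector<int> vid(nv);
  int buf[231];

  for (int it = 0; it < m; ++it) {
    double cx = std::cos(phis(it,0)), sx = std::sin(phis(it,0));
    double cy = std::cos(phis(it,1)), sy = std::sin(phis(it,1));
    // z-row of R = Ry(phi_y) %*% Rx(phi_x):
    //   z' = -sy*x + cy*(sx*y + cx*z) ... derive:
    // Rx: (x, cx*y - sx*z, sx*y + cx*z); Ry: (cy*x + sy*z'', y', -sy*x + cy*z'')
    for (int v = 0; v < nv; ++v) {
      double zz = sx * V(v,1) + cx * V(v,2);
      z[v] = -sy * V(v,0) + cy * zz;
    }
    int nkeep = 0;
    for (int v = 0; v < nv; ++v) {
      keep[v] = (std::fabs(z[v]) <= d + 1e-12) ? 1 : 0;
      if (keep[v]) ++nkeep;
    }
    if (do_del && nkeep > 0) {
      int pick = (int)std::floor(del_u[it] * nkeep);
      if (pick >= nkeep) pick = nkeep - 1;
      int cnt = 0;
      for (int v = 0; v < nv; ++v) {
        if (!keep[v]) continue;
        if (cnt == pick) { keep[v] = del_mode; break; }  // 0 cut-like, 2 removed
        ++cnt;
      }
    }
    // vertex ids among retained (keep==1)
    int nV = 0;
    for (int v = 0; v < nv; ++v) {
      vid[v] = (keep[v] == 1) ? nV++ : -1;
      deg[v] = 0; vcomp[v] = true;
    }
    int nE_all = 0;
    for (int e = 0; e < ne; ++e) {
      int a = edges(e,0), b = edges(e,1);
      int ka = keep[a], kb = keep[b];
      if (ka == 1 && kb == 1) {
        status[e] = 1; ++nE_all;
        deg[a] += 1; deg[b] += 1;
      } else if (ka == 1 && kb == 0) {
        status[e] = 2; ++nE_all;
        deg[a] += 1; vcomp[a] = false;
      } else if (kb == 1 && ka == 0) {
        status[e] = 2; ++nE_all;
        deg[b] += 1; vcomp[b] = false;
      } else {
        status[e] = 0;  // dropped (both outside, or deleted endpoint)
      }
    }
    int nFc = 0;
    for (int f = 0; f < nf; ++f) {
      int vis = 0; bool comp = true;
      for (size_t k = 0; k < fe[f].size(); ++k) {
        int st = status[fe[f][k]];
        if (st > 0) ++vis;
        if (st != 1) comp = false;
      }
      face_vis[f] = vis;
      face_complete[f] = comp && vis > 0;
      if (face_complete[f]) ++nFc;
    }
    ea.clear(); eb.clear(); ef1.clear(); ef2.clear();
    for (int e = 0; e < ne; ++e) {
      if (status[e] != 1) continue;
      ea.push_back(edges(e,0)); eb.push_back(edges(e,1));
      ef1.push_back(edgeFaces(e,0));
      ef2.push_back(edgeFaces(e,1));
    }
    // compact degree/completeness arrays over retained vertices only
    std::vector<int> degc; degc.reserve(nkeep);
    std::vector<bool> vcompc; vcompc.reserve(nkeep);
    std::vector<int> remap(nv, -1);
    int idx = 0;
    for (int v = 0; v < nv; ++v) {
      if (keep[v] == 1) {
        remap[v] = idx++;
        degc.push_back(deg[v]);
        vcompc.push_back(vcomp[v]);
      }
    }
    for (size_t e = 0; e < ea.size(); ++e) { ea[e] = remap[ea[e]]; eb[e] = remap[eb[e]]; }
    profile_core((int)degc.size(), nE_all, nFc, degc, vcompc, face_vis,
                 face_complete, ea, eb, ef1, ef2, buf);
    for (int k = 0; k < 231; ++k) out(it, k) = buf[k];
  }
  return out;
}
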