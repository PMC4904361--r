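// Incremental 3-d convex hull with coplanar-facet merging.
//
// Inputs are vertex sets of convex polyhedra: every point is required to be an
// extreme point.  The triangulation is built on deterministically jittered
// copies of the points (so squares, hexagons etc. triangulate cleanly), then
// triangles are regrouped into polygonal faces by their supporting planes
// computed from the original coordinates.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tri {
  int a, b, c;
  double nx, ny, nz, off;   // outward plane (jittered coords)
  bool alive;
};

inline void plane(const std::vector<std::array<double,3>> &P, int a, int b,
                  int c, double &nx, double &ny, double &nz, double &off) {
  double ux = P[b][0]-P[a][0], uy = P[b][1]-P[a][1], uz = P[b][2]-P[a][2];
  double vx = P[c][0]-P[a][0], vy = P[c][1]-P[a][1], vz = P[c][2]-P[a][2];
  nx = uy*vz - uz*vy; ny = uz*vx - ux*vz; nz = ux*vy - uy*vx;
  double n = std::sqrt(nx*nx + ny*ny + nz*nz);
  nx /= n; ny /= n; nz /= n;
  off = nx*P[a][0] + ny*P[a][1] + nz*P[a][2];
}

} // namespace

// [[Rcpp::export(name = ".cpp_hull")]]
List cpp_hull(NumericMatrix V, double angtol = 1e-6, double offtol = 1e-8) {
  const int n = V.nrow();
  if (n < 4) stop("need at least 4 points");

  // scale for tolerances
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) scale = std::max(scale, std::fabs(V(i,k)));
  if (scale <= 0) stop("degenerate input");

  // deterministic jitter (LCG), relative magnitude 1e-9
  std::vector<std::array<double,3>> P(n), Q(n);
  unsigned long long s = 88172645463325252ULL;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      Q[i][k] = V(i,k);
      s ^= s << 13; s ^= s >> 7; s ^= s << 17;
      double u = (double)(s % 2000001) / 1000000.0 - 1.0; // [-1, 1]
      P[i][k] = V(i,k) + u * 1e-9 * scale;
    }
  }

  // initial tetrahedron: 0, farthest from 0, max area, max volume
  int i1 = -1; double best = -1;
  for (int i = 1; i < n; ++i) {
    double d = 0; for (int k = 0; k < 3; ++k) d += (P[i][k]-P[0][k])*(P[i][k]-P[0][k]);
    if (d > best) { best = d; i1 = i; }
  }
  int i2 = -1; best = -1;
  for (int i = 1; i < n; ++i) {
    if (i == i1) continue;
    double ux=P[i1][0]-P[0][0], uy=P[i1][1]-P[0][1], uz=P[i1][2]-P[0][2];
    double vx=P[i][0]-P[0][0], vy=P[i][1]-P[0][1], vz=P[i][2]-P[0][2];
    double cx=uy*vz-uz*vy, cy=uz*vx-ux*vz, cz=ux*vy-uy*vx;
    double a = cx*cx+cy*cy+cz*cz;
    if (a > best) { best = a; i2 = i; }
  }
  double nx, ny, nz, off;
  plane(P, 0, i1, i2, nx, ny, nz, off);
  int i3 = -1; best = -1;
  for (int i = 1; i < n; ++i) {
    if (i == i1 || i == i2) continue;
    double d = std::fabs(nx*P[i][0]+ny*P[i][1]+nz*P[i][2]-off);
    if (d > best) { best = d; i3 = i; }
  }
  if (best < 1e-12 * scale) stop("input points are coplanar");

  std::vector<Tri> tris;
  {
    int t0[4][3] = {{0,i1,i2},{0,i1,i3},{0,i2,i3},{i1,i2,i3}};
    double cx=(P[0][0]+P[i1][0]+P[i2][0]+P[i3][0])/4.0;
    double cy=(P[0][1]+P[i1][1]+P[i2][1]+P[i3][1])/4.0;
    double cz=(P[0][2]+P[i1][2]+P[i2][2]+P[i3][2])/4.0;
    for (int t = 0; t < 4; ++t) {
      Tri tr; tr.a=t0[t][0]; tr.b=t0[t][1]; tr.c=t0[t][2]; tr.alive=true;
      plane(P, tr.a, tr.b, tr.c, tr.nx, tr.ny, tr.nz, tr.off);
      if (tr.nx*cx + tr.ny*cy + tr.nz*cz > tr.off) { // flip outward
        std::swap(tr.b, tr.c);
        plane(P, tr.a, tr.b, tr.c, tr.nx, tr.ny, tr.nz, tr.off);
      }
      tris.push_back(tr);
    }
  }

  const double eps = 1e-11 * scale;
  std::vector<bool> used(n, false);
  used[0] = used[i1] = used[i2] = used[i3] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = true;
    // visible triangles
    std::vector<int> vis;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double d = tris[t].nx*P[p][0] + tris[t].ny*P[p][1] + tris[t].nz*P[p][2] - tris[t].off;
      if (d > eps) vis.push_back((int)t);
    }
    if (vis.empty())
      stop("interior point encountered (input not in convex position)");
    // horizon = edges of visible region counted once
    std::map<std::pair<int,int>, int> ecount;
    for (int t : vis) {
      int e[3][2] = {{tris[t].a,tris[t].b},{tris[t].b,tris[t].c},{tris[t].c,tris[t].a}};
      for (int k = 0; k < 3; ++k) {
        int a = e[k][0], b = e[k][1];
        std::pair<int,int> key(std::min(a,b), std::max(a,b));
        ecount[key]++;
      }
      tris[t].alive = false;
    }
    // directed horizon edges from dead tris occurring once
    for (int t : vis) {
      int e[3][2] = {{tris[t].a,tris[t].b},{tris[t].b,tris[t].c},{tris[t].c,tris[t].a}};
      for (int k = 0; k < 3; ++k) {
        int a = e[k][0], b = e[k][1];
        std::pair<int,int> key(std::min(a,b), std::max(a,b));
        if (ecount[key] == 1) {
          Tri tr; tr.a = a; tr.b = b; tr.c = p; tr.alive = true;
          plane(P, tr.a, tr.b, tr.c, tr.nx, tr.ny, tr.nz, tr.off);
          tris.push_back(tr);
        }
      }
    }
  }

  // collect live triangles, merge by true-coordinate supporting plane
  std::vector<int> live;
  for (size_t t = 0; t < tris.size(); ++t) if (tris[t].alive) live.push_back((int)t);
  int nt = (int)live.size();
  std::vector<double> tnx(nt), tny(nt), tnz(nt), toff(nt);
  for (int j = 0; j < nt; ++j) {
    const Tri &tr = tris[live[j]];
    plane(Q, tr.a, tr.b, tr.c, tnx[j], tny[j], tnz[j], toff[j]);
  }
  std::vector<int> grp(nt, -1);
  int ng = 0;
  for (int j = 0; j < nt; ++j) {
    if (grp[j] >= 0) continue;
    grp[j] = ng;
    for (int k = j + 1; k < nt; ++k) {
      if (grp[k] >= 0) continue;
      double dot = tnx[j]*tnx[k] + tny[j]*tny[k] + tnz[j]*tnz[k];
      if (dot > 1.0) dot = 1.0;
      if (std::acos(dot) < angtol && std::fabs(toff[j]-toff[k]) < offtol * std::max(1.0, scale))
        grp[k] = ng;
    }
    ++ng;
  }

  // face vertex sets, ordered CCW about outward normal
  List faces(ng);
  for (int g = 0; g < ng; ++g) {
    std::vector<int> vs;
    double nxg = 0, nyg = 0, nzg = 0;
    for (int j = 0; j < nt; ++j) {
      if (grp[j] != g) continue;
      const Tri &tr = tris[live[j]];
      nxg += tnx[j]; nyg += tny[j]; nzg += tnz[j];
      int ids[3] = {tr.a, tr.b, tr.c};
      for (int k = 0; k < 3; ++k)
        if (std::find(vs.begin(), vs.end(), ids[k]) == vs.end()) vs.push_back(ids[k]);
    }
    double nn = std::sqrt(nxg*nxg + nyg*nyg + nzg*nzg);
    nxg /= nn; nyg /= nn; nzg /= nn;
    double cx = 0, cy = 0, cz = 0;
    for (int v : vs) { cx += Q[v][0]; cy += Q[v][1]; cz += Q[v][2]; }
    cx /= vs.size(); cy /= vs.size(); cz /= vs.size();
    // in-plane basis
    double ax = Q[vs[0]][0]-cx, ay = Q[vs[0]][1]-cy, az = Q[vs[0]][2]-cz;
    double d = ax*nxg + ay*nyg + az*nzg;
    ax -= d*nxg; ay -= d*nyg; az -= d*nzg;
    double an = std::sqrt(ax*ax+ay*ay+az*az); ax/=an; ay/=an; az/=an;
    double bx = nyg*az - nzg*ay, by = nzg*ax - nxg*az, bz = nxg*ay - nyg*ax;
    std::vector<std::pair<double,int>> ang;
    for (int v : vs) {
      double dx = Q[v][0]-cx, dy = Q[v][1]-cy, dz = Q[v][2]-cz;
      ang.push_back(std::make_pair(std::atan2(dx*bx+dy*by+dz*bz, dx*ax+dy*ay+dz*az), v));
    }
    std::sort(ang.begin(), ang.end());
    IntegerVector f(ang.size());
    for (size_t k = 0; k < ang.size(); ++k) f[k] = ang[k].second + 1;
    faces[g] = f;
  }

  // edges + edge->face incidence from face cycles
  std::map<std::pair<int,int>, std::vector<int>> emap;
  for (int g = 0; g < ng; ++g) {
    IntegerVector f = faces[g];
    int m = f.size();
    for (int k = 0; k < m; ++k) {
      int a = f[k], b = f[(k+1)%m];
      emap[std::make_pair(std::min(a,b), std::max(a,b))].push_back(g + 1);
    }
  }
  int ne = (int)emap.size();
  IntegerMatrix edges(ne, 2), edgeFaces(ne, 2);
  int r = 0;
  for (std::map<std::pair<int,int>, std::vector<int>>::iterator it = emap.begin();
       it != emap.end(); ++it, ++r) {
    edges(r,0) = it->first.first; edges(r,1) = it->first.second;
    if (it->second.size() != 2) stop("edge not shared by exactly two faces");
    edgeFaces(r,0) = it->second[0]; edgeFaces(r,1) = it->second[1];
  }
  return List::create(_["faces"] = faces, _["edges"] = edges,
                      _["edge_faces"] = edgeFaces);
}
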