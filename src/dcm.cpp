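// Forward deformable cell model (DCM).
//
// Cells are closed triangle meshes whose nodes carry forces from: cortical
// surface tension (gradient of gamma * total area), a volumetric pressure
// P = K (V* - V)/V* acting along outward node normals, short-range
// repulsion + adhesion at cell-cell contacts, tangential contact friction,
// a rigid convex eggshell penalty, in-plane viscous damping on edge-length
// rate, and optional active models (cytokinetic ring, protrusion dipole).
// Motion is overdamped: dx/dt = F / (drag * A_i).
#include <Rcpp.h>
#include "vecmath.h"
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Cell {
  int n = 0, m = 0;
  std::vector<double> X, Xp;      // 3n current / previous positions
  std::vector<int> F;             // 3m vertex indices
  double gamma = 1, K = 50, Vstar = 1;
  // per-step geometry
  std::vector<double> nodeA, nodeN, triN, triA, Fo; // forces Fo 3n
  std::vector<double> dragMul;                      // per-node drag multiplier
  std::vector<int> edges;                           // 2e unique edges
  std::vector<int> degree;                          // per-node edge count
  double vol = 0, area = 0, P = 0;
};

void buildEdges(Cell& c) {
  std::vector<std::pair<int,int> > e;
  e.reserve(3 * c.m);
  for (int t = 0; t < c.m; ++t) {
    int v[3] = {c.F[3*t], c.F[3*t+1], c.F[3*t+2]};
    for (int k = 0; k < 3; ++k) {
      int a = v[k], b = v[(k+1)%3];
      e.push_back(std::make_pair(std::min(a,b), std::max(a,b)));
    }
  }
  std::sort(e.begin(), e.end());
  e.erase(std::unique(e.begin(), e.end()), e.end());
  c.edges.clear();
  c.degree.assign(c.n, 0);
  for (size_t i = 0; i < e.size(); ++i) {
    c.edges.push_back(e[i].first);
    c.edges.push_back(e[i].second);
    c.degree[e[i].first]++;
    c.degree[e[i].second]++;
  }
}

// volume, total area, mixed-Voronoi node areas, node normals, triangle data
void computeGeom(Cell& c) {
  c.nodeA.assign(c.n, 0.0);
  c.nodeN.assign(3 * c.n, 0.0);
  c.triN.assign(3 * c.m, 0.0);
  c.triA.assign(c.m, 0.0);
  c.vol = 0; c.area = 0;
  for (int t = 0; t < c.m; ++t) {
    int a = c.F[3*t], b = c.F[3*t+1], cc = c.F[3*t+2];
    const double *pa = &c.X[3*a], *pb = &c.X[3*b], *pc = &c.X[3*cc];
    double e1[3], e2[3], nr[3];
    vsub3(pb, pa, e1); vsub3(pc, pa, e2);
    vcross3(e1, e2, nr);
    double dbl = vnorm3(nr), A = 0.5 * dbl;
    c.triA[t] = A; c.area += A;
    double cr[3]; vcross3(pb, pc, cr);
    c.vol += vdot3(pa, cr) / 6.0;
    for (int k = 0; k < 3; ++k) {
      double nk = (dbl > 0) ? nr[k] / dbl : 0.0;
      c.triN[3*t+k] = nk;
      c.nodeN[3*a+k] += nr[k]; c.nodeN[3*b+k] += nr[k]; c.nodeN[3*cc+k] += nr[k];
    }
    const int idx[3] = {a, b, cc};
    const double* pp[3] = {pa, pb, pc};
    double cot[3]; bool obtuse = false; int obAt = -1;
    for (int k = 0; k < 3; ++k) {
      double u[3], w[3];
      vsub3(pp[(k+1)%3], pp[k], u);
      vsub3(pp[(k+2)%3], pp[k], w);
      double cu[3]; vcross3(u, w, cu);
      double s = vnorm3(cu), d = vdot3(u, w);
      cot[k] = (s > 1e-300) ? d / s : 0.0;
      if (d < 0) { obtuse = true; obAt = k; }
    }
    for (int k = 0; k < 3; ++k) {
      if (!obtuse) {
        double d1[3], d2[3];
        vsub3(pp[(k+1)%3], pp[k], d1);
        vsub3(pp[(k+2)%3], pp[k], d2);
        c.nodeA[idx[k]] += (vdot3(d1,d1)*cot[(k+2)%3] + vdot3(d2,d2)*cot[(k+1)%3]) / 8.0;
      } else {
        c.nodeA[idx[k]] += (k == obAt) ? A / 2.0 : A / 4.0;
      }
    }
  }
  for (int i = 0; i < c.n; ++i) {
    double l = vnorm3(&c.nodeN[3*i]);
    if (l > 0) for (int k = 0; k < 3; ++k) c.nodeN[3*i+k] /= l;
  }
}

// F_i -= gamma * dA_total/dx_i  (per-triangle area gradients)
void addTension(Cell& c) {
  for (int t = 0; t < c.m; ++t) {
    int v[3] = {c.F[3*t], c.F[3*t+1], c.F[3*t+2]};
    const double* nh = &c.triN[3*t];
    for (int k = 0; k < 3; ++k) {
      const double* pb = &c.X[3*v[(k+1)%3]];
      const double* pc = &c.X[3*v[(k+2)%3]];
      double e[3]; vsub3(pc, pb, e);
      double g[3]; vcross3(nh, e, g); // 2 * grad_vk A
      for (int kk = 0; kk < 3; ++kk)
        c.Fo[3*v[k]+kk] -= c.gamma * 0.5 * g[kk];
    }
  }
}

void addPressure(Cell& c) {
  c.P = c.K * (c.Vstar - c.vol) / c.Vstar;
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k)
      c.Fo[3*i+k] += c.P * c.nodeA[i] * c.nodeN[3*i+k];
}

void addEdgeViscosity(Cell& c, double eta, double dt) {
  if (eta <= 0 || c.Xp.empty()) return;
  const int ne = (int)c.edges.size() / 2;
  for (int e = 0; e < ne; ++e) {
    int i = c.edges[2*e], j = c.edges[2*e+1];
    double ev[3]; vsub3(&c.X[3*j], &c.X[3*i], ev);
    double l = vnorm3(ev);
    if (l < 1e-300) continue;
    for (int k = 0; k < 3; ++k) ev[k] /= l;
    double rate = 0; // relative velocity along the edge
    for (int k = 0; k < 3; ++k)
      rate += ((c.X[3*j+k] - c.Xp[3*j+k]) - (c.X[3*i+k] - c.Xp[3*i+k])) / dt * ev[k];
    // per-edge damping scaled by adjacent node areas so that the total
    // damping on a node stays below its drag (explicit-scheme stability)
    double w = 0.5 * (c.nodeA[i] / std::max(c.degree[i], 1) +
                      c.nodeA[j] / std::max(c.degree[j], 1));
    for (int k = 0; k < 3; ++k) {
      c.Fo[3*i+k] += eta * w * rate * ev[k];
      c.Fo[3*j+k] -= eta * w * rate * ev[k];
    }
  }
}

// Tangential mesh regularization: relax each node toward the average of
// its edge neighbors, projected into the local tangent plane so the shape
// is preserved to first order. Keeps the triangulation from developing
// slivers at contact rims and furrows.
void tangentialSmooth(Cell& c, double coef) {
  if (coef <= 0) return;
  std::vector<double> avg(3 * c.n, 0.0);
  std::vector<int> cnt(c.n, 0);
  const int ne = (int)c.edges.size() / 2;
  for (int e = 0; e < ne; ++e) {
    int i = c.edges[2*e], j = c.edges[2*e+1];
    for (int k = 0; k < 3; ++k) {
      avg[3*i+k] += c.X[3*j+k];
      avg[3*j+k] += c.X[3*i+k];
    }
    cnt[i]++; cnt[j]++;
  }
  for (int i = 0; i < c.n; ++i) {
    if (cnt[i] == 0) continue;
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = avg[3*i+k] / cnt[i] - c.X[3*i+k];
    double dn = vdot3(d, &c.nodeN[3*i]);
    for (int k = 0; k < 3; ++k)
      c.X[3*i+k] += coef * (d[k] - dn * c.nodeN[3*i+k]);
  }
}

struct Ring {
  int cell;
  std::vector<int> nodes;     // ordered closed loop
  std::vector<int> triSide;   // per-triangle side label (1 or 2)
  std::vector<int> nodeSide;  // per-node side label
  double k, KD, sigma, aref1, aref2;
  // cached Gaussian smear weights: per ring node, (mesh node, weight)
  std::vector<std::vector<std::pair<int,double> > > smearW;
};

// Ring constriction: zero-rest-length springs along consecutive ring nodes,
// each ring node's spring force smeared over nearby mesh nodes with Gaussian
// weights; plus side-area proportional controller. The combined active force
// is projected to zero net force over the cell.
void addRing(Cell& c, Ring& r, bool refreshWeights) {
  std::vector<double> Fa(3 * c.n, 0.0);
  const int nr = (int)r.nodes.size();
  if (r.k > 0 && nr >= 3) {
    std::vector<double> fr(3 * nr, 0.0);
    for (int j = 0; j < nr; ++j) {
      int i0 = r.nodes[j], ip = r.nodes[(j + nr - 1) % nr], in = r.nodes[(j + 1) % nr];
      for (int k = 0; k < 3; ++k)
        fr[3*j+k] = r.k * (c.X[3*ip+k] - c.X[3*i0+k]) + r.k * (c.X[3*in+k] - c.X[3*i0+k]);
    }
    const double s2 = 2.0 * r.sigma * r.sigma;
    if (refreshWeights || (int)r.smearW.size() != nr) {
      r.smearW.assign(nr, std::vector<std::pair<int,double> >());
      for (int j = 0; j < nr; ++j) {
        const double* xr = &c.X[3*r.nodes[j]];
        double wsum = 0;
        for (int i = 0; i < c.n; ++i) {
          double d[3]; vsub3(&c.X[3*i], xr, d);
          double q = vdot3(d, d);
          if (q < 9.0 * s2) {
            double w = std::exp(-q / s2);
            r.smearW[j].push_back(std::make_pair(i, w));
            wsum += w;
          }
        }
        for (size_t e = 0; e < r.smearW[j].size(); ++e)
          r.smearW[j][e].second /= std::max(wsum, 1e-300);
      }
    }
    for (int j = 0; j < nr; ++j)
      for (size_t e = 0; e < r.smearW[j].size(); ++e) {
        int i = r.smearW[j][e].first;
        double ww = r.smearW[j][e].second;
        for (int k = 0; k < 3; ++k) Fa[3*i+k] += ww * fr[3*j+k];
      }
  }
  if (r.KD > 0) {
    double A1 = 0, A2 = 0;
    for (int t = 0; t < c.m; ++t)
      (r.triSide[t] == 1 ? A1 : A2) += c.triA[t];
    double P1 = r.KD * (r.aref1 - A1) / r.aref1;
    double P2 = r.KD * (r.aref2 - A2) / r.aref2;
    for (int i = 0; i < c.n; ++i) {
      double Ps = (r.nodeSide[i] == 1) ? P1 : P2;
      for (int k = 0; k < 3; ++k)
        Fa[3*i+k] += Ps * c.nodeA[i] * c.nodeN[3*i+k];
    }
  }
  // enforce zero net force (area-weighted residual removal)
  double S[3] = {0,0,0};
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) S[k] += Fa[3*i+k];
  for (int i = 0; i < c.n; ++i) {
    double wi = c.nodeA[i] / c.area;
    for (int k = 0; k < 3; ++k)
      c.Fo[3*i+k] += Fa[3*i+k] - S[k] * wi;
  }
}

struct Prot {
  int cell; double axis[3], alpha, fp;
  std::vector<double> w; // cached DoG weight per node
};

// Protrusion: difference-of-Gaussians weight in the angle between node
// direction (from cell centroid) and the protrusion axis; outward force in
// the core, inward pull in the surrounding band; residual inverted and
// redistributed so the net force is exactly zero.
void addProtrusion(Cell& c, Prot& p, bool refreshWeights) {
  if (p.fp <= 0) return;
  if (refreshWeights || (int)p.w.size() != c.n) {
    double cen[3] = {0,0,0}, wa = 0;
    for (int i = 0; i < c.n; ++i) {
      wa += c.nodeA[i];
      for (int k = 0; k < 3; ++k) cen[k] += c.nodeA[i] * c.X[3*i+k];
    }
    for (int k = 0; k < 3; ++k) cen[k] /= wa;
    const double a = p.alpha, a2 = 2.0 * p.alpha;
    p.w.assign(c.n, 0.0);
    for (int i = 0; i < c.n; ++i) {
      double d[3]; vsub3(&c.X[3*i], cen, d);
      double l = vnorm3(d);
      if (l < 1e-300) continue;
      double cb = vdot3(d, p.axis) / l;
      cb = std::max(-1.0, std::min(1.0, cb));
      double beta = std::acos(cb);
      double g1 = std::exp(-beta*beta / (2*a*a)) / a;
      double g2 = std::exp(-beta*beta / (2*a2*a2)) / a2;
      p.w[i] = g1 - g2;
    }
  }
  const std::vector<double>& w = p.w;
  double sumPos = 0, sumAbs = 0;
  for (int i = 0; i < c.n; ++i) {
    if (w[i] > 0) sumPos += w[i] * c.nodeA[i];
    sumAbs += std::fabs(w[i]) * c.nodeA[i];
  }
  if (sumPos <= 0) return;
  const double s = p.fp / sumPos;
  double S[3] = {0,0,0};
  std::vector<double> Fa(3 * c.n, 0.0);
  for (int i = 0; i < c.n; ++i) {
    if (w[i] == 0) continue;
    for (int k = 0; k < 3; ++k) {
      Fa[3*i+k] = s * w[i] * c.nodeA[i] * c.nodeN[3*i+k];
      S[k] += Fa[3*i+k];
    }
  }
  for (int i = 0; i < c.n; ++i) {
    double wi = std::fabs(w[i]) * c.nodeA[i] / sumAbs;
    for (int k = 0; k < 3; ++k)
      c.Fo[3*i+k] += Fa[3*i+k] - S[k] * wi;
  }
}

// Rigid convex shell: penalty on nodes past the shell surface. The shell is
// given by outward face planes (n . x <= d inside). Penetration depth is
// capped so that badly violated initial states relax gently. The argmax
// face per node changes slowly, so it is cached and refreshed only
// periodically (full scan); between refreshes only the cached plane is
// evaluated.
void addShell(Cell& c, const std::vector<double>& N, const std::vector<double>& d,
              double stiff, double cap, std::vector<int>& faceCache, bool refresh) {
  const int q = (int)d.size();
  if ((int)faceCache.size() != c.n) { faceCache.assign(c.n, -1); refresh = true; }
  for (int i = 0; i < c.n; ++i) {
    int bf = faceCache[i];
    double best;
    if (refresh || bf < 0) {
      best = -std::numeric_limits<double>::infinity();
      for (int f = 0; f < q; ++f) {
        double s = vdot3(&N[3*f], &c.X[3*i]) - d[f];
        if (s > best) { best = s; bf = f; }
      }
      faceCache[i] = bf;
    } else {
      best = vdot3(&N[3*bf], &c.X[3*i]) - d[bf];
    }
    if (best > 0 && bf >= 0) {
      double mag = stiff * std::min(best, cap) * c.nodeA[i];
      for (int k = 0; k < 3; ++k) c.Fo[3*i+k] -= mag * N[3*bf+k];
    }
  }
}

struct Contact {
  int a, b;
  double omega, xi;
  // candidate target triangles per source node, rebuilt periodically
  std::vector<std::vector<int> > candA, candB;
};

struct TriBound { double cen[3]; double rad; };
typedef std::unordered_map<int64_t, std::vector<int> > TriGrid;

inline int64_t gridKey(int ix, int iy, int iz) {
  return ((int64_t)(ix + 1048576) << 42) | ((int64_t)(iy + 1048576) << 21) | (int64_t)(iz + 1048576);
}

void buildTriGrid(const Cell& c, double g, TriGrid& grid) {
  grid.clear();
  for (int t = 0; t < c.m; ++t) {
    double cx = 0, cy = 0, cz = 0;
    for (int k = 0; k < 3; ++k) {
      cx += c.X[3*c.F[3*t+k]] / 3.0;
      cy += c.X[3*c.F[3*t+k]+1] / 3.0;
      cz += c.X[3*c.F[3*t+k]+2] / 3.0;
    }
    grid[gridKey((int)std::floor(cx/g), (int)std::floor(cy/g), (int)std::floor(cz/g))].push_back(t);
  }
}

void rebuildCandidates(const Cell& src, const Cell& tgt, double rsearch,
                       std::vector<std::vector<int> >& cand) {
  cand.assign(src.n, std::vector<int>());
  // quick reject: bounding boxes of the two meshes
  double lo_s[3], hi_s[3], lo_t[3], hi_t[3];
  for (int k = 0; k < 3; ++k) {
    lo_s[k] = hi_s[k] = src.X[k]; lo_t[k] = hi_t[k] = tgt.X[k];
  }
  for (int i = 1; i < src.n; ++i) for (int k = 0; k < 3; ++k) {
    lo_s[k] = std::min(lo_s[k], src.X[3*i+k]);
    hi_s[k] = std::max(hi_s[k], src.X[3*i+k]);
  }
  for (int i = 1; i < tgt.n; ++i) for (int k = 0; k < 3; ++k) {
    lo_t[k] = std::min(lo_t[k], tgt.X[3*i+k]);
    hi_t[k] = std::max(hi_t[k], tgt.X[3*i+k]);
  }
  for (int k = 0; k < 3; ++k)
    if (lo_t[k] - hi_s[k] > rsearch || lo_s[k] - hi_t[k] > rsearch) return;
  // grid cell size: covers triangle extent + search radius
  double maxEdge = 0;
  for (int t = 0; t < tgt.m; ++t) {
    for (int k = 0; k < 3; ++k) {
      double e[3];
      vsub3(&tgt.X[3*tgt.F[3*t+(k+1)%3]], &tgt.X[3*tgt.F[3*t+k]], e);
      maxEdge = std::max(maxEdge, vnorm3(e));
    }
  }
  double g = std::max(maxEdge + rsearch, 1e-6);
  TriGrid grid;
  buildTriGrid(tgt, g, grid);
  // per-triangle bounding spheres for a cheap prefilter
  std::vector<TriBound> tb(tgt.m);
  for (int t = 0; t < tgt.m; ++t) {
    for (int k = 0; k < 3; ++k)
      tb[t].cen[k] = (tgt.X[3*tgt.F[3*t]+k] + tgt.X[3*tgt.F[3*t+1]+k] +
                      tgt.X[3*tgt.F[3*t+2]+k]) / 3.0;
    double r2 = 0;
    for (int k = 0; k < 3; ++k) {
      double d[3]; vsub3(&tgt.X[3*tgt.F[3*t+k]], tb[t].cen, d);
      r2 = std::max(r2, vdot3(d, d));
    }
    tb[t].rad = std::sqrt(r2);
  }
  double cp[3];
  std::vector<std::pair<double,int> > scratch;
  for (int i = 0; i < src.n; ++i) {
    const double* p = &src.X[3*i];
    int ix = (int)std::floor(p[0]/g), iy = (int)std::floor(p[1]/g), iz = (int)std::floor(p[2]/g);
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) for (int dz = -1; dz <= 1; ++dz) {
      TriGrid::const_iterator it = grid.find(gridKey(ix+dx, iy+dy, iz+dz));
      if (it == grid.end()) continue;
      for (size_t q = 0; q < it->second.size(); ++q) {
        int t = it->second[q];
        double d[3]; vsub3(p, tb[t].cen, d);
        double lim = rsearch + tb[t].rad;
        if (vdot3(d, d) > lim * lim) continue;
        double dd = closestPtTri3(p,
          &tgt.X[3*tgt.F[3*t]], &tgt.X[3*tgt.F[3*t+1]], &tgt.X[3*tgt.F[3*t+2]], cp);
        if (dd <= rsearch) scratch.push_back(std::make_pair(dd, t));
      }
    }
    // keep only the nearest few candidates: the closest triangle cannot
    // migrate far between neighbor-list rebuilds
    const size_t keep = 14;
    if (scratch.size() > keep)
      std::partial_sort(scratch.begin(), scratch.begin() + keep, scratch.end());
    for (size_t q = 0; q < std::min(scratch.size(), keep); ++q)
      cand[i].push_back(scratch[q].second);
    scratch.clear();
  }
}

// One direction of a contact pair: nodes of src against surface of tgt.
// half = 0.5 when the pair is processed symmetrically.
double applyContactDir(Cell& src, Cell& tgt,
                       const std::vector<std::vector<int> >& cand,
                       double omega, double xi, double rc, double krep,
                       double half, double dt, double extraDrag) {
  double carea = 0;
  double cp[3], bary[3], bcp[3], bbary[3];
  for (int i = 0; i < src.n; ++i) {
    if (cand[i].empty()) continue;
    const double* p = &src.X[3*i];
    double best = std::numeric_limits<double>::infinity();
    int bt = -1;
    for (size_t q = 0; q < cand[i].size(); ++q) {
      int t = cand[i][q];
      double dd = closestPtTri3(p,
        &tgt.X[3*tgt.F[3*t]], &tgt.X[3*tgt.F[3*t+1]], &tgt.X[3*tgt.F[3*t+2]], cp, bary);
      if (dd < best) {
        best = dd; bt = t;
        for (int k = 0; k < 3; ++k) { bcp[k] = cp[k]; bbary[k] = bary[k]; }
      }
    }
    if (bt < 0) continue;
    // smooth (barycentrically interpolated) surface normal: continuous
    // across triangle edges and vertices, unlike the face normal
    double nb[3];
    {
      int v0 = tgt.F[3*bt], v1 = tgt.F[3*bt+1], v2 = tgt.F[3*bt+2];
      for (int k = 0; k < 3; ++k)
        nb[k] = bbary[0]*tgt.nodeN[3*v0+k] + bbary[1]*tgt.nodeN[3*v1+k] +
                bbary[2]*tgt.nodeN[3*v2+k];
      double l = vnorm3(nb);
      if (l > 1e-300) for (int k = 0; k < 3; ++k) nb[k] /= l;
    }
    double dvec[3]; vsub3(p, bcp, dvec);
    // signed gap as the projection of (node - closest point) on a smooth
    // contact axis blending the two surface normals; for facing surfaces
    // the axis points from src toward tgt, so penetration gives a negative
    // gap. Both normals are mesh-smooth fields, so neither local rumple of
    // the target triangulation nor closest-triangle switches flip the sign.
    double axis[3];
    for (int k = 0; k < 3; ++k) axis[k] = src.nodeN[3*i+k] - nb[k];
    double axl = vnorm3(axis);
    if (axl < 1e-9) continue;
    for (int k = 0; k < 3; ++k) axis[k] /= axl;
    double g = -vdot3(dvec, axis);
    if (g > rc) continue;
    carea += src.nodeA[i];
    // interfaces carry wet friction: raise the local drag of nodes in
    // contact, which damps the stiff normal dynamics without changing the
    // static force balance
    if (!src.dragMul.empty()) {
      // additive per contact involvement: nodes on triple lines touch two
      // partners and need proportionally more damping
      src.dragMul[i] += extraDrag;
      for (int k = 0; k < 3; ++k) {
        int tv = tgt.F[3*bt+k];
        if (!tgt.dragMul.empty()) tgt.dragMul[tv] += extraDrag / 3.0;
      }
    }
    // normal traction: adhesion is a triangular well over (0, rc], peaking
    // at rc/2 and vanishing at zero gap, with total depth (work of
    // separation) exactly omega per unit area: k_adh = 4 omega / rc^2.
    // Repulsion is linear in the penetration. Traction is zero at g = 0,
    // so contacting surfaces equilibrate at near-zero gap with gentle
    // slopes on both sides (stable under explicit integration).
    double Fi[3] = {0, 0, 0};
    // Maugis-Dugdale-style adhesive contact from the closest-point gap:
    // linear repulsion on penetration plus a constant adhesive traction
    // sig0 persisting under compression, tapering to zero over the outer
    // 30% of the contact range; work of separation is omega per unit area.
    // Forces act along the closest-point direction (blended into the
    // smooth inter-normal axis at vanishing gap), so the peel collar at a
    // junction is pulled straight back onto the partner surface whatever
    // its tilt; a soft facing gate merely fades adhesion between strongly
    // non-facing surfaces.
    double facing = -vdot3(&src.nodeN[3*i], nb);
    if (facing > 0.05) {
      double aw = std::min(1.0, std::max(0.0, facing / 0.5));
      double sig0 = aw * omega / (0.85 * rc);
      double signet; // positive = repulsive (away from target)
      if (g < 0) signet = krep * (-g) - sig0;
      else if (g <= 0.7 * rc) signet = -sig0;
      else signet = -sig0 * (rc - g) / (0.3 * rc);
      double Fm = half * signet * src.nodeA[i];
      double wd = std::min(std::fabs(g) / (0.3 * rc), 1.0);
      double sgn = (g >= 0) ? 1.0 : -1.0;
      double dir[3];
      double invb = (best > 1e-12) ? 1.0 / best : 0.0;
      for (int k = 0; k < 3; ++k)
        dir[k] = wd * sgn * dvec[k] * invb - (1.0 - wd) * axis[k];
      double dl = vnorm3(dir);
      if (dl > 1e-9) {
        for (int k = 0; k < 3; ++k) Fi[k] = Fm * dir[k] / dl;
      }
    }
    // tangential friction against surface-relative sliding
    if (xi > 0 && !src.Xp.empty() && !tgt.Xp.empty()) {
      double vrel[3];
      int v0 = tgt.F[3*bt], v1 = tgt.F[3*bt+1], v2 = tgt.F[3*bt+2];
      for (int k = 0; k < 3; ++k) {
        double vs = (src.X[3*i+k] - src.Xp[3*i+k]) / dt;
        double vt = (bbary[0]*(tgt.X[3*v0+k]-tgt.Xp[3*v0+k]) +
                     bbary[1]*(tgt.X[3*v1+k]-tgt.Xp[3*v1+k]) +
                     bbary[2]*(tgt.X[3*v2+k]-tgt.Xp[3*v2+k])) / dt;
        vrel[k] = vs - vt;
      }
      double vn = vdot3(vrel, nb);
      for (int k = 0; k < 3; ++k) {
        double vt = vrel[k] - vn * nb[k];
        Fi[k] -= half * xi * src.nodeA[i] * vt;
      }
    }
    for (int k = 0; k < 3; ++k) {
      src.Fo[3*i+k] += Fi[k];
      // Newton's third law: reaction spread over the closest triangle
      tgt.Fo[3*tgt.F[3*bt]+k]   -= bbary[0] * Fi[k];
      tgt.Fo[3*tgt.F[3*bt+1]+k] -= bbary[1] * Fi[k];
      tgt.Fo[3*tgt.F[3*bt+2]+k] -= bbary[2] * Fi[k];
    }
  }
  return carea;
}

Cell cellFromR(List cl) {
  Cell c;
  NumericMatrix V = cl["V"];
  IntegerMatrix F = cl["F"];
  c.n = V.nrow(); c.m = F.nrow();
  c.X.resize(3 * c.n);
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) c.X[3*i+k] = V(i,k);
  c.F.resize(3 * c.m);
  for (int t = 0; t < c.m; ++t)
    for (int k = 0; k < 3; ++k) c.F[3*t+k] = F(t,k);
  if (cl.containsElementNamed("gamma")) c.gamma = as<double>(cl["gamma"]);
  if (cl.containsElementNamed("K")) c.K = as<double>(cl["K"]);
  if (cl.containsElementNamed("V_star")) c.Vstar = as<double>(cl["V_star"]);
  c.Fo.assign(3 * c.n, 0.0);
  return c;
}

NumericMatrix forcesOut(const Cell& c) {
  NumericMatrix M(c.n, 3);
  for (int i = 0; i < c.n; ++i)
    for (int k = 0; k < 3; ++k) M(i,k) = c.Fo[3*i+k];
  return M;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_tension_forces(NumericMatrix V, IntegerMatrix F, double gamma) {
  Cell c = cellFromR(List::create(_["V"] = V, _["F"] = F, _["gamma"] = gamma));
  computeGeom(c);
  addTension(c);
  return forcesOut(c);
}

// [[Rcpp::export]]
List cpp_pressure_forces(NumericMatrix V, IntegerMatrix F, double K, double V_star) {
  Cell c = cellFromR(List::create(_["V"] = V, _["F"] = F, _["K"] = K, _["V_star"] = V_star));
  computeGeom(c);
  addPressure(c);
  return List::create(_["P"] = c.P, _["forces"] = forcesOut(c), _["volume"] = c.vol);
}

// [[Rcpp::export]]
List cpp_contact_forces(NumericMatrix Va, IntegerMatrix Fa,
                        NumericMatrix Vb, IntegerMatrix Fb,
                        double omega, double xi, double contact_range, double k_rep) {
  Cell a = cellFromR(List::create(_["V"] = Va, _["F"] = Fa));
  Cell b = cellFromR(List::create(_["V"] = Vb, _["F"] = Fb));
  computeGeom(a); computeGeom(b);
  std::vector<std::vector<int> > ca, cb;
  rebuildCandidates(a, b, 2.5 * contact_range, ca);
  rebuildCandidates(b, a, 2.5 * contact_range, cb);
  double ar1 = applyContactDir(a, b, ca, omega, xi, contact_range, k_rep, 0.5, 1.0, 0.0);
  double ar2 = applyContactDir(b, a, cb, omega, xi, contact_range, k_rep, 0.5, 1.0, 0.0);
  return List::create(_["forces_a"] = forcesOut(a), _["forces_b"] = forcesOut(b),
                      _["contact_area"] = 0.5 * (ar1 + ar2));
}

// [[Rcpp::export]]
NumericMatrix cpp_shell_forces(NumericMatrix V, IntegerMatrix F,
                               NumericMatrix shellN, NumericVector shellD,
                               double stiffness, double cap) {
  Cell c = cellFromR(List::create(_["V"] = V, _["F"] = F));
  computeGeom(c);
  std::vector<double> N(3 * shellD.size()), d(shellD.size());
  for (int f = 0; f < shellD.size(); ++f) {
    for (int k = 0; k < 3; ++k) N[3*f+k] = shellN(f,k);
    d[f] = shellD[f];
  }
  std::vector<int> cacheTmp;
  addShell(c, N, d, stiffness, cap, cacheTmp, true);
  return forcesOut(c);
}

// [[Rcpp::export]]
NumericMatrix cpp_ring_forces(NumericMatrix V, IntegerMatrix F,
                              IntegerVector ring_nodes, double k, double sigma,
                              double KD, IntegerVector tri_side, IntegerVector node_side,
                              double aref1, double aref2) {
  Cell c = cellFromR(List::create(_["V"] = V, _["F"] = F));
  computeGeom(c);
  Ring r;
  r.cell = 0; r.k = k; r.KD = KD; r.sigma = sigma; r.aref1 = aref1; r.aref2 = aref2;
  r.nodes.assign(ring_nodes.begin(), ring_nodes.end());
  r.triSide.assign(tri_side.begin(), tri_side.end());
  r.nodeSide.assign(node_side.begin(), node_side.end());
  addRing(c, r, true);
  return forcesOut(c);
}

// [[Rcpp::export]]
NumericMatrix cpp_protrusion_forces(NumericMatrix V, IntegerMatrix F,
                                    NumericVector axis, double alpha, double F_P) {
  Cell c = cellFromR(List::create(_["V"] = V, _["F"] = F));
  computeGeom(c);
  Prot p;
  p.cell = 0; p.alpha = alpha; p.fp = F_P;
  double l = std::sqrt(axis[0]*axis[0] + axis[1]*axis[1] + axis[2]*axis[2]);
  for (int k = 0; k < 3; ++k) p.axis[k] = axis[k] / l;
  addProtrusion(c, p, true);
  return forcesOut(c);
}

// Run the overdamped DCM for n_steps (or until quasi-static).
// [[Rcpp::export]]
List cpp_relax(List cellsIn, List contactsIn, Nullable<List> shellIn,
               List ringsIn, List protsIn, List cfg) {
  const double dt = as<double>(cfg["dt"]);
  const int nSteps = as<int>(cfg["n_steps"]);
  const double drag = as<double>(cfg["drag"]);
  const double rc = as<double>(cfg["contact_range"]);
  const double krep = as<double>(cfg["k_rep"]);
  const double shellK = as<double>(cfg["shell_stiffness"]);
  const double etaEdge = as<double>(cfg["eta_edge"]);
  const double tol = as<double>(cfg["tol"]);
  const int checkEvery = as<int>(cfg["check_every"]);
  const int nlEvery = as<int>(cfg["nl_every"]);
  const double penCap = as<double>(cfg["pen_cap"]);
  const double extraDrag = as<double>(cfg["contact_extra_drag"]);
  const double smoothCoef = as<double>(cfg["mesh_smoothing"]);
  const double divCap = as<double>(cfg["div_cap"]); // per-step displacement abort

  const int nc = cellsIn.size();
  std::vector<Cell> cells(nc);
  for (int i = 0; i < nc; ++i) {
    cells[i] = cellFromR(cellsIn[i]);
    buildEdges(cells[i]);
  }
  std::vector<Contact> contacts(contactsIn.size());
  for (int c = 0; c < contactsIn.size(); ++c) {
    List cl = contactsIn[c];
    contacts[c].a = as<int>(cl["a"]);
    contacts[c].b = as<int>(cl["b"]);
    contacts[c].omega = as<double>(cl["omega"]);
    contacts[c].xi = as<double>(cl["xi"]);
  }
  std::vector<Ring> rings(ringsIn.size());
  for (int r = 0; r < ringsIn.size(); ++r) {
    List rl = ringsIn[r];
    rings[r].cell = as<int>(rl["cell"]);
    IntegerVector nd = rl["nodes"];
    rings[r].nodes.assign(nd.begin(), nd.end());
    rings[r].k = as<double>(rl["k"]);
    rings[r].KD = as<double>(rl["K_D"]);
    rings[r].sigma = as<double>(rl["sigma"]);
    IntegerVector ts = rl["tri_side"], ns = rl["node_side"];
    rings[r].triSide.assign(ts.begin(), ts.end());
    rings[r].nodeSide.assign(ns.begin(), ns.end());
    rings[r].aref1 = as<double>(rl["aref1"]);
    rings[r].aref2 = as<double>(rl["aref2"]);
  }
  std::vector<Prot> prots(protsIn.size());
  for (int p = 0; p < protsIn.size(); ++p) {
    List pl = protsIn[p];
    prots[p].cell = as<int>(pl["cell"]);
    NumericVector ax = pl["axis"];
    double l = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
    for (int k = 0; k < 3; ++k) prots[p].axis[k] = ax[k] / l;
    prots[p].alpha = as<double>(pl["alpha"]);
    prots[p].fp = as<double>(pl["F_P"]);
  }
  std::vector<double> shN; std::vector<double> shD;
  bool hasShell = shellIn.isNotNull();
  if (hasShell) {
    List sh(shellIn);
    NumericMatrix N = sh["N"];
    NumericVector d = sh["d"];
    shN.resize(3 * d.size()); shD.resize(d.size());
    for (int f = 0; f < d.size(); ++f) {
      for (int k = 0; k < 3; ++k) shN[3*f+k] = N(f,k);
      shD[f] = d[f];
    }
  }

  const double rsearch = 2.8 * rc;
  std::vector<std::vector<int> > shellFaceCache(nc);
  std::vector<double> contactArea(contacts.size(), 0.0);
  bool diverged = false;
  double lastMaxSpeed = NA_REAL;
  int step = 0;
  for (step = 0; step < nSteps; ++step) {
    for (int i = 0; i < nc; ++i) {
      computeGeom(cells[i]);
      std::fill(cells[i].Fo.begin(), cells[i].Fo.end(), 0.0);
      cells[i].dragMul.assign(cells[i].n, 1.0);
      addTension(cells[i]);
      addPressure(cells[i]);
      addEdgeViscosity(cells[i], etaEdge, dt);
    }
    bool refreshW = (step % nlEvery == 0);
    for (size_t r = 0; r < rings.size(); ++r)
      addRing(cells[rings[r].cell], rings[r], refreshW);
    for (size_t p = 0; p < prots.size(); ++p)
      addProtrusion(cells[prots[p].cell], prots[p], refreshW);
    for (size_t c = 0; c < contacts.size(); ++c) {
      Contact& co = contacts[c];
      if (step % nlEvery == 0) {
        rebuildCandidates(cells[co.a], cells[co.b], rsearch, co.candA);
        rebuildCandidates(cells[co.b], cells[co.a], rsearch, co.candB);
      }
      double a1 = applyContactDir(cells[co.a], cells[co.b], co.candA, co.omega, co.xi, rc, krep, 0.5, dt, extraDrag);
      double a2 = applyContactDir(cells[co.b], cells[co.a], co.candB, co.omega, co.xi, rc, krep, 0.5, dt, extraDrag);
      contactArea[c] = 0.5 * (a1 + a2);
    }
    if (hasShell)
      for (int i = 0; i < nc; ++i)
        addShell(cells[i], shN, shD, shellK, penCap, shellFaceCache[i],
                 step % 5 == 0);
    // overdamped update
    double maxDisp = 0;
    for (int i = 0; i < nc; ++i) {
      Cell& c = cells[i];
      if (c.Xp.empty()) c.Xp = c.X;
      // floor the drag area: a node whose Voronoi area collapses (crumpled
      // triangles) must not acquire unbounded mobility
      double areaFloor = 0.25 * c.area / c.n;
      for (int j = 0; j < c.n; ++j) {
        double ci = drag * std::max(c.nodeA[j], areaFloor) *
                    (c.dragMul.empty() ? 1.0 : c.dragMul[j]);
        double dsq = 0;
        double xn[3];
        for (int k = 0; k < 3; ++k) {
          double dx = dt * c.Fo[3*j+k] / ci;
          xn[k] = c.X[3*j+k] + dx;
          dsq += dx * dx;
        }
        maxDisp = std::max(maxDisp, dsq);
        c.Xp[3*j] = c.X[3*j]; c.Xp[3*j+1] = c.X[3*j+1]; c.Xp[3*j+2] = c.X[3*j+2];
        c.X[3*j] = xn[0]; c.X[3*j+1] = xn[1]; c.X[3*j+2] = xn[2];
      }
    }
    for (int i = 0; i < nc; ++i) tangentialSmooth(cells[i], smoothCoef);
    maxDisp = std::sqrt(maxDisp);
    lastMaxSpeed = maxDisp / dt;
    if (maxDisp > divCap) { diverged = true; break; }
    if ((step + 1) % checkEvery == 0 && lastMaxSpeed < tol) { ++step; break; }
  }

  List posOut(nc);
  NumericVector vols(nc), press(nc), areas(nc);
  for (int i = 0; i < nc; ++i) {
    computeGeom(cells[i]);
    NumericMatrix M(cells[i].n, 3);
    for (int j = 0; j < cells[i].n; ++j)
      for (int k = 0; k < 3; ++k) M(j,k) = cells[i].X[3*j+k];
    posOut[i] = M;
    vols[i] = cells[i].vol;
    areas[i] = cells[i].area;
    press[i] = cells[i].K * (cells[i].Vstar - cells[i].vol) / cells[i].Vstar;
  }
  return List::create(_["positions"] = posOut, _["volumes"] = vols,
                      _["areas"] = areas, _["pressures"] = press,
                      _["contact_areas"] = NumericVector(contactArea.begin(), contactArea.end()),
                      _["steps"] = step, _["max_speed"] = lastMaxSpeed,
                      _["diverged"] = diverged);
}
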