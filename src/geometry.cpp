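// Discrete differential-geometry kernels for closed triangle meshes:
// signed volume, mixed-Voronoi node areas, angle-consistent node normals,
// cotangent-Laplacian mean curvature, ray casting and closest-point queries,
// and an incremental 3D convex hull.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// Per-node geometry of a closed mesh. F is 0-based.
// [[Rcpp::export]]
List cpp_mesh_geometry(NumericMatrix V, IntegerMatrix F) {
  const int n = V.nrow(), m = F.nrow();
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3*i] = V(i,0); P[3*i+1] = V(i,1); P[3*i+2] = V(i,2);
  }
  NumericVector areaN(n), Hn(n), triArea(m);
  NumericMatrix normalN(n, 3);
  std::vector<double> nrm(3 * n, 0.0), lap(3 * n, 0.0), mixed(n, 0.0);
  double vol = 0.0, atot = 0.0;
  std::vector<double> fa(m), fn(3 * m);

  for (int t = 0; t < m; ++t) {
    int a = F(t,0), b = F(t,1), c = F(t,2);
    const double *pa = &P[3*a], *pb = &P[3*b], *pc = &P[3*c];
    double e1[3], e2[3], nrf[3];
    vsub(pb, pa, e1); vsub(pc, pa, e2);
    vcross(e1, e2, nrf);
    double dbl = vnorm(nrf);
    double A = 0.5 * dbl;
    fa[t] = A; triArea[t] = A; atot += A;
    // signed volume via divergence theorem (tet to origin)
    double cr[3]; vcross(pb, pc, cr);
    vol += vdot(pa, cr) / 6.0;
    for (int k = 0; k < 3; ++k) {
      fn[3*t+k] = (dbl > 0) ? nrf[k] / dbl : 0.0;
      // area-weighted normal accumulation
      nrm[3*a+k] += nrf[k]; nrm[3*b+k] += nrf[k]; nrm[3*c+k] += nrf[k];
    }
    // mixed Voronoi areas (Meyer et al.) and cotangent Laplacian terms
    const int idx[3] = {a, b, c};
    const double* pp[3] = {pa, pb, pc};
    double cot[3];
    bool obtuse = false; int obtuseAt = -1;
    for (int k = 0; k < 3; ++k) {
      // angle at vertex k between edges to k+1 and k+2
      double u[3], w[3];
      vsub(pp[(k+1)%3], pp[k], u);
      vsub(pp[(k+2)%3], pp[k], w);
      double cu[3]; vcross(u, w, cu);
      double s = vnorm(cu), d = vdot(u, w);
      cot[k] = (s > 1e-300) ? d / s : 0.0;
      if (d < 0) { obtuse = true; obtuseAt = k; }
    }
    for (int k = 0; k < 3; ++k) {
      int i0 = idx[k], i1 = idx[(k+1)%3], i2 = idx[(k+2)%3];
      // Laplacian: edge (i0,i1) is opposite vertex k+2, etc.
      const double* q0 = pp[k];
      double d1[3], d2[3];
      vsub(pp[(k+1)%3], q0, d1);
      vsub(pp[(k+2)%3], q0, d2);
      for (int kk = 0; kk < 3; ++kk) {
        lap[3*i0+kk] += cot[(k+2)%3] * d1[kk] + cot[(k+1)%3] * d2[kk];
      }
      (void)i1; (void)i2;
      if (!obtuse) {
        // Voronoi portion at vertex k: (|e1|^2 cot(opp1) + |e2|^2 cot(opp2))/8
        mixed[i0] += (vdot(d1,d1) * cot[(k+2)%3] + vdot(d2,d2) * cot[(k+1)%3]) / 8.0;
      } else {
        mixed[i0] += (k == obtuseAt) ? A / 2.0 : A / 4.0;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    double l = vnorm(&nrm[3*i]);
    for (int k = 0; k < 3; ++k) normalN(i,k) = (l > 0) ? nrm[3*i+k] / l : 0.0;
    areaN[i] = mixed[i];
    // mean curvature normal = Lap(x) / (2 A_i); points inward for convex
    double h[3] = { lap[3*i] / (4.0 * std::max(mixed[i], 1e-300)),
                    lap[3*i+1] / (4.0 * std::max(mixed[i], 1e-300)),
                    lap[3*i+2] / (4.0 * std::max(mixed[i], 1e-300)) };
    double mag = vnorm(h);
    double sgn = (vdot(h, &nrm[3*i]) <= 0) ? 1.0 : -1.0;
    Hn[i] = sgn * mag;
  }
  return List::create(_["volume"] = vol, _["area"] = atot,
                      _["normals"] = normalN, _["voronoi_area"] = areaN,
                      _["mean_curvature"] = Hn, _["tri_area"] = triArea);
}

// Moller-Trumbore ray/triangle intersection; returns t or NA.
static inline double rayTri(const double* o, const double* d,
                            const double* v0, const double* v1, const double* v2) {
  double e1[3], e2[3], pv[3];
  vsub(v1, v0, e1); vsub(v2, v0, e2);
  vcross(d, e2, pv);
  double det = vdot(e1, pv);
  if (std::fabs(det) < 1e-14) return std::numeric_limits<double>::quiet_NaN();
  double inv = 1.0 / det, tv[3];
  vsub(o, v0, tv);
  double u = vdot(tv, pv) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return std::numeric_limits<double>::quiet_NaN();
  double qv[3]; vcross(tv, e1, qv);
  double v = vdot(d, qv) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return std::numeric_limits<double>::quiet_NaN();
  return vdot(e2, qv) * inv;
}

// closest point on triangle (Ericson, Real-Time Collision Detection)
static inline double closestPtTri(const double* p, const double* a,
                                  const double* b, const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { for (int k=0;k<3;++k) out[k]=a[k]; }
  else {
    double bp[3]; vsub(p, b, bp);
    double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
    if (d3 >= 0 && d4 <= d3) { for (int k=0;k<3;++k) out[k]=b[k]; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        for (int k=0;k<3;++k) out[k] = a[k] + v*ab[k];
      } else {
        double cp[3]; vsub(p, c, cp);
        double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
        if (d6 >= 0 && d5 <= d6) { for (int k=0;k<3;++k) out[k]=c[k]; }
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            for (int k=0;k<3;++k) out[k] = a[k] + w*ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k=0;k<3;++k) out[k] = b[k] + w*(c[k]-b[k]);
            } else {
              double den = 1.0 / (va + vb + vc);
              double v = vb * den, w = vc * den;
              for (int k=0;k<3;++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
            }
          }
        }
      }
    }
  }
  double dd[3]; vsub(p, out, dd);
  return vnorm(dd);
}

// For each source node, cast a ray along +/- its normal onto the target mesh;
// keep the nearest intersection. Misses fall back to closest-point distance.
// [[Rcpp::export]]
List cpp_raycast(NumericMatrix Vsrc, NumericMatrix Nsrc,
                 NumericMatrix Vtgt, IntegerMatrix Ftgt) {
  const int n = Vsrc.nrow(), m = Ftgt.nrow();
  NumericVector dist(n);
  LogicalVector hit(n);
  for (int i = 0; i < n; ++i) {
    double o[3] = {Vsrc(i,0), Vsrc(i,1), Vsrc(i,2)};
    double d[3] = {Nsrc(i,0), Nsrc(i,1), Nsrc(i,2)};
    double best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < m; ++t) {
      double v0[3] = {Vtgt(Ftgt(t,0),0), Vtgt(Ftgt(t,0),1), Vtgt(Ftgt(t,0),2)};
      double v1[3] = {Vtgt(Ftgt(t,1),0), Vtgt(Ftgt(t,1),1), Vtgt(Ftgt(t,1),2)};
      double v2[3] = {Vtgt(Ftgt(t,2),0), Vtgt(Ftgt(t,2),1), Vtgt(Ftgt(t,2),2)};
      double tt = rayTri(o, d, v0, v1, v2);
      if (std::isfinite(tt) && std::fabs(tt) < best) best = std::fabs(tt);
    }
    if (std::isfinite(best)) { dist[i] = best; hit[i] = true; }
    else {
      // fallback: nearest point on target surface
      double bd = std::numeric_limits<double>::infinity(), cp[3];
      for (int t = 0; t < m; ++t) {
        double v0[3] = {Vtgt(Ftgt(t,0),0), Vtgt(Ftgt(t,0),1), Vtgt(Ftgt(t,0),2)};
        double v1[3] = {Vtgt(Ftgt(t,1),0), Vtgt(Ftgt(t,1),1), Vtgt(Ftgt(t,1),2)};
        double v2[3] = {Vtgt(Ftgt(t,2),0), Vtgt(Ftgt(t,2),1), Vtgt(Ftgt(t,2),2)};
        double dd = closestPtTri(o, v0, v1, v2, cp);
        if (dd < bd) bd = dd;
      }
      dist[i] = bd; hit[i] = false;
    }
  }
  return List::create(_["distance"] = dist, _["hit"] = hit);
}

// Closest surface point for a set of query points; signed by the outward
// normal of the nearest triangle (positive = outside). Per-triangle
// bounding spheres prune most of the brute-force scan.
// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int n = P.nrow(), m = F.nrow();
  NumericVector dist(n), sdist(n);
  IntegerVector tri(n);
  NumericMatrix CP(n, 3);
  std::vector<double> bc(3 * m), br(m);
  for (int t = 0; t < m; ++t) {
    for (int k = 0; k < 3; ++k)
      bc[3*t+k] = (V(F(t,0),k) + V(F(t,1),k) + V(F(t,2),k)) / 3.0;
    double r2 = 0;
    for (int j = 0; j < 3; ++j) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = V(F(t,j),k) - bc[3*t+k];
        d2 += d * d;
      }
      r2 = std::max(r2, d2);
    }
    br[t] = std::sqrt(r2);
  }
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i,0), P(i,1), P(i,2)};
    double best = std::numeric_limits<double>::infinity(), bcp[3] = {0,0,0};
    int bt = -1;
    for (int t = 0; t < m; ++t) {
      double dc[3] = {p[0]-bc[3*t], p[1]-bc[3*t+1], p[2]-bc[3*t+2]};
      double lb = std::sqrt(vdot(dc, dc)) - br[t];
      if (lb >= best) continue;
      double v0[3] = {V(F(t,0),0), V(F(t,0),1), V(F(t,0),2)};
      double v1[3] = {V(F(t,1),0), V(F(t,1),1), V(F(t,1),2)};
      double v2[3] = {V(F(t,2),0), V(F(t,2),1), V(F(t,2),2)};
      double cp[3];
      double dd = closestPtTri(p, v0, v1, v2, cp);
      if (dd < best) { best = dd; bt = t; for (int k=0;k<3;++k) bcp[k]=cp[k]; }
    }
    double v0[3] = {V(F(bt,0),0), V(F(bt,0),1), V(F(bt,0),2)};
    double v1[3] = {V(F(bt,1),0), V(F(bt,1),1), V(F(bt,1),2)};
    double v2[3] = {V(F(bt,2),0), V(F(bt,2),1), V(F(bt,2),2)};
    double e1[3], e2[3], nn[3];
    vsub(v1, v0, e1); vsub(v2, v0, e2); vcross(e1, e2, nn);
    double dvec[3] = {p[0]-bcp[0], p[1]-bcp[1], p[2]-bcp[2]};
    dist[i] = best; tri[i] = bt;
    sdist[i] = (vdot(dvec, nn) >= 0) ? best : -best;
    for (int k=0;k<3;++k) CP(i,k) = bcp[k];
  }
  return List::create(_["distance"] = dist, _["signed_distance"] = sdist,
                      _["triangle"] = tri, _["point"] = CP);
}

// ---------------------------------------------------------------------------
// Incremental convex hull (randomized quickhull-style with conflict lists
// kept simple: O(n^2) worst case, fine for embryo-scale point sets).
struct HullFace { int a, b, c; double n[3]; double off; bool alive; };

static void faceInit(HullFace& f, const std::vector<double>& P, int a, int b, int c,
                     const double* inner) {
  f.a = a; f.b = b; f.c = c; f.alive = true;
  double e1[3], e2[3];
  vsub(&P[3*b], &P[3*a], e1); vsub(&P[3*c], &P[3*a], e2);
  vcross(e1, e2, f.n);
  double l = vnorm(f.n);
  for (int k=0;k<3;++k) f.n[k] /= (l > 0 ? l : 1);
  f.off = vdot(f.n, &P[3*a]);
  // orient outward w.r.t. interior point
  if (vdot(f.n, inner) - f.off > 0) {
    std::swap(f.b, f.c);
    for (int k=0;k<3;++k) f.n[k] = -f.n[k];
    f.off = -f.off;
  }
}

// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix Pin) {
  const int n = Pin.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) { P[3*i]=Pin(i,0); P[3*i+1]=Pin(i,1); P[3*i+2]=Pin(i,2); }
  // initial tetrahedron: extreme points
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P[3*i] < P[3*i0]) i0 = i;
    if (P[3*i] > P[3*i1]) i1 = i;
  }
  if (i0 == i1) stop("degenerate point set");
  int i2 = -1; double bestA = 1e-18;
  for (int i = 0; i < n; ++i) {
    double e1[3], e2[3], cr[3];
    vsub(&P[3*i1], &P[3*i0], e1); vsub(&P[3*i], &P[3*i0], e2);
    vcross(e1, e2, cr);
    double a = vnorm(cr);
    if (a > bestA) { bestA = a; i2 = i; }
  }
  if (i2 < 0) stop("collinear point set");
  int i3 = -1; double bestV = 1e-16;
  double e1[3], e2[3], nn[3];
  vsub(&P[3*i1], &P[3*i0], e1); vsub(&P[3*i2], &P[3*i0], e2);
  vcross(e1, e2, nn);
  for (int i = 0; i < n; ++i) {
    double d[3]; vsub(&P[3*i], &P[3*i0], d);
    double v = std::fabs(vdot(nn, d));
    if (v > bestV) { bestV = v; i3 = i; }
  }
  if (i3 < 0) stop("coplanar point set");
  double inner[3];
  for (int k = 0; k < 3; ++k)
    inner[k] = (P[3*i0+k] + P[3*i1+k] + P[3*i2+k] + P[3*i3+k]) / 4.0;
  std::vector<HullFace> faces;
  int init[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  for (int f = 0; f < 4; ++f) {
    HullFace hf; faceInit(hf, P, init[f][0], init[f][1], init[f][2], inner);
    faces.push_back(hf);
  }
  // scale-aware tolerance
  double diag = 0;
  for (int k = 0; k < 3; ++k) {
    double lo = P[k], hi = P[k];
    for (int i = 1; i < n; ++i) { lo = std::min(lo, P[3*i+k]); hi = std::max(hi, P[3*i+k]); }
    diag += (hi - lo) * (hi - lo);
  }
  double tol = 1e-10 * std::sqrt(diag);
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // find visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (vdot(faces[f].n, &P[3*p]) - faces[f].off > tol) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon edges: edges of visible faces not shared with another visible face
    std::vector<std::pair<int,int> > edges;
    for (int fv : vis) {
      int vv[3] = {faces[fv].a, faces[fv].b, faces[fv].c};
      for (int k = 0; k < 3; ++k) edges.push_back(std::make_pair(vv[k], vv[(k+1)%3]));
      faces[fv].alive = false;
    }
    for (size_t e = 0; e < edges.size(); ++e) {
      bool shared = false;
      for (size_t g = 0; g < edges.size(); ++g) {
        if (g == e) continue;
        if (edges[g].first == edges[e].second && edges[g].second == edges[e].first) {
          shared = true; break;
        }
      }
      if (!shared) {
        HullFace hf; faceInit(hf, P, edges[e].first, edges[e].second, p, inner);
        faces.push_back(hf);
      }
    }
  }
  std::vector<int> fi;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) fi.push_back((int)f);
  IntegerMatrix Fout(fi.size(), 3);
  for (size_t f = 0; f < fi.size(); ++f) {
    Fout(f,0) = faces[fi[f]].a; Fout(f,1) = faces[fi[f]].b; Fout(f,2) = faces[fi[f]].c;
  }
  return List::create(_["faces"] = Fout);
}
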