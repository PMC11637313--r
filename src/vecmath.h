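#ifndef FIDES_VECMATH_H
#define FIDES_VECMATH_H
#include <cmath>
#include <limits>

static inline void vsub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross3(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}
static inline double vdot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline double vnorm3(const double* a) { return std::sqrt(vdot3(a, a)); }

// closest point on triangle abc to p; returns distance, writes point to out
// and barycentric coords (w.r.t. a,b,c) to bary if non-null.
static inline double closestPtTri3(const double* p, const double* a,
                                   const double* b, const double* c,
                                   double* out, double* bary = 0) {
  double ab[3], ac[3], ap[3];
  vsub3(b, a, ab); vsub3(c, a, ac); vsub3(p, a, ap);
  double d1 = vdot3(ab, ap), d2 = vdot3(ac, ap);
  double u = 1, v = 0, w = 0;
  bool done = false;
  if (d1 <= 0 && d2 <= 0) { u = 1; v = 0; w = 0; done = true; }
  if (!done) {
    double bp[3]; vsub3(p, b, bp);
    double d3 = vdot3(ab, bp), d4 = vdot3(ac, bp);
    if (d3 >= 0 && d4 <= d3) { u = 0; v = 1; w = 0; done = true; }
    if (!done) {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double t = d1 / (d1 - d3);
        u = 1 - t; v = t; w = 0; done = true;
      }
    }
    if (!done) {
      double cp[3]; vsub3(p, c, cp);
      double d5 = vdot3(ab, cp), d6 = vdot3(ac, cp);
      if (d6 >= 0 && d5 <= d6) { u = 0; v = 0; w = 1; done = true; }
      if (!done) {
        double vb = d5*d2 - d1*d6;
        if (vb <= 0 && d2 >= 0 && d6 <= 0) {
          double t = d2 / (d2 - d6);
          u = 1 - t; v = 0; w = t; done = true;
        }
      }
      if (!done) {
        double va = d3*d6 - d5*d4;
        if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
          double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
          u = 0; v = 1 - t; w = t; done = true;
        }
      }
      if (!done) {
        double va = d3*d6 - d5*d4;
        double vbb = d5*d2 - d1*d6, vcc = d1*d4 - d3*d2;
        double den = 1.0 / (va + vbb + vcc);
        v = vbb * den; w = vcc * den; u = 1 - v - w;
      }
    }
  }
  out[0] = u*a[0] + v*b[0] + w*c[0];
  out[1] = u*a[1] + v*b[1] + w*c[1];
  out[2] = u*a[2] + v*b[2] + w*c[2];
  if (bary) { bary[0] = u; bary[1] = v; bary[2] = w; }
  double dd[3]; vsub3(p, out, dd);
  return vnorm3(dd);
}


// Moller-Trumbore ray/triangle intersection; returns t (can be negative)
// or NaN on miss.
static inline double rayTri3(const double* o, const double* d,
                             const double* v0, const double* v1, const double* v2) {
  double e1[3], e2[3], pv[3];
  vsub3(v1, v0, e1); vsub3(v2, v0, e2);
  vcross3(d, e2, pv);
  double det = vdot3(e1, pv);
  if (std::fabs(det) < 1e-14) return std::numeric_limits<double>::quiet_NaN();
  double inv = 1.0 / det, tv[3];
  vsub3(o, v0, tv);
  double u = vdot3(tv, pv) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return std::numeric_limits<double>::quiet_NaN();
  double qv[3]; vcross3(tv, e1, qv);
  double v = vdot3(d, qv) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return std::numeric_limits<double>::quiet_NaN();
  return vdot3(e2, qv) * inv;
}

#endif
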