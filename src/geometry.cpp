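#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection. Returns t >= 0 on hit, else NaN.
static inline double ray_tri(const double *o, const double *d,
                             const double *a, const double *b, const double *c) {
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int i = 0; i < 3; ++i) { e1[i] = b[i] - a[i]; e2[i] = c[i] - a[i]; }
  pv[0] = d[1]*e2[2] - d[2]*e2[1];
  pv[1] = d[2]*e2[0] - d[0]*e2[2];
  pv[2] = d[0]*e2[1] - d[1]*e2[0];
  double det = e1[0]*pv[0] + e1[1]*pv[1] + e1[2]*pv[2];
  if (std::fabs(det) < 1e-14) return NA_REAL;
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) tv[i] = o[i] - a[i];
  double u = (tv[0]*pv[0] + tv[1]*pv[1] + tv[2]*pv[2]) * inv;
  if (u < -1e-10 || u > 1.0 + 1e-10) return NA_REAL;
  qv[0] = tv[1]*e1[2] - tv[2]*e1[1];
  qv[1] = tv[2]*e1[0] - tv[0]*e1[2];
  qv[2] = tv[0]*e1[1] - tv[1]*e1[0];
  double v = (d[0]*qv[0] + d[1]*qv[1] + d[2]*qv[2]) * inv;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return NA_REAL;
  double t = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
  if (t < -1e-10) return NA_REAL;
  return t;
}

// All intersections of one ray with a mesh, sorted by t.
// V: Vx3 vertices, F: Fx3 zero-based face indices.
// Returns matrix with columns t, x, y, z, face (zero-based).
// [[Rcpp::export]]
NumericMatrix cpp_ray_mesh_hits(NumericVector orig, NumericVector dir,
                                NumericMatrix V, IntegerMatrix F) {
  int nf = F.nrow();
  std::vector<std::pair<double,int> > hits;
  double o[3] = {orig[0], orig[1], orig[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  for (int f = 0; f < nf; ++f) {
    double a[3], b[3], c[3];
    int ia = F(f,0), ib = F(f,1), ic = F(f,2);
    for (int i = 0; i < 3; ++i) { a[i]=V(ia,i); b[i]=V(ib,i); c[i]=V(ic,i); }
    double t = ray_tri(o, d, a, b, c);
    if (!ISNAN(t)) hits.push_back(std::make_pair(t, f));
  }
  std::sort(hits.begin(), hits.end());
  // drop duplicate hits on shared edges/vertices (same t within tolerance)
  std::vector<std::pair<double,int> > uniq;
  for (size_t i = 0; i < hits.size(); ++i) {
    if (uniq.empty() || hits[i].first - uniq.back().first > 1e-9)
      uniq.push_back(hits[i]);
  }
  NumericMatrix out(uniq.size(), 5);
  for (size_t i = 0; i < uniq.size(); ++i) {
    double t = uniq[i].first;
    out(i,0) = t;
    for (int j = 0; j < 3; ++j) out(i,1+j) = o[j] + t*d[j];
    out(i,4) = uniq[i].second;
  }
  return out;
}

// First hit of many rays from a common origin. Returns Nx2 matrix (t, face),
// NA where the ray misses.
// [[Rcpp::export]]
NumericMatrix cpp_first_hits(NumericVector orig, NumericMatrix dirs,
                             NumericMatrix V, IntegerMatrix F) {
  int nr = dirs.nrow(), nf = F.nrow();
  double o[3] = {orig[0], orig[1], orig[2]};
  // precompute triangle vertices contiguously
  std::vector<double> tri(nf*9);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      int iv = F(f,k);
      for (int i = 0; i < 3; ++i) tri[f*9 + k*3 + i] = V(iv,i);
    }
  NumericMatrix out(nr, 2);
  for (int r = 0; r < nr; ++r) {
    double d[3] = {dirs(r,0), dirs(r,1), dirs(r,2)};
    double best = R_PosInf; int bf = -1;
    for (int f = 0; f < nf; ++f) {
      const double *a = &tri[f*9], *b = &tri[f*9+3], *c = &tri[f*9+6];
      double t = ray_tri(o, d, a, b, c);
      if (!ISNAN(t) && t > 1e-9 && t < best) { best = t; bf = f; }
    }
    if (bf >= 0) { out(r,0) = best; out(r,1) = bf; }
    else { out(r,0) = NA_REAL; out(r,1) = NA_REAL; }
  }
  return out;
}

// Closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision Detection).
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c, double *q) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) q[i]=a[i]; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) q[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) q[i]=a[i]+v*ab[i];
    return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) q[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) q[i]=a[i]+w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) q[i]=b[i]+w*(c[i]-b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) q[i]=a[i]+ab[i]*v+ac[i]*w;
}

// Unsigned distance from each point to the nearest mesh triangle.
// Returns Nx5: distance, qx, qy, qz, face (zero-based).
// Brute force over triangles with AABB lower-bound pruning.
// [[Rcpp::export]]
NumericMatrix cpp_closest_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  std::vector<double> tri(nf*9), lo(nf*3), hi(nf*3);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int iv = F(f,k);
      for (int i = 0; i < 3; ++i) tri[f*9 + k*3 + i] = V(iv,i);
    }
    for (int i = 0; i < 3; ++i) {
      double v0 = tri[f*9+i], v1 = tri[f*9+3+i], v2 = tri[f*9+6+i];
      lo[f*3+i] = std::min(v0, std::min(v1, v2));
      hi[f*3+i] = std::max(v0, std::max(v1, v2));
    }
  }
  NumericMatrix out(np, 5);
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {P(ip,0), P(ip,1), P(ip,2)};
    double best = R_PosInf, bq[3] = {0,0,0}; int bf = -1;
    for (int f = 0; f < nf; ++f) {
      // squared distance lower bound from the triangle's AABB
      double lb = 0;
      for (int i = 0; i < 3; ++i) {
        double d = 0;
        if (p[i] < lo[f*3+i]) d = lo[f*3+i] - p[i];
        else if (p[i] > hi[f*3+i]) d = p[i] - hi[f*3+i];
        lb += d*d;
      }
      if (lb >= best) continue;
      double q[3];
      closest_on_tri(p, &tri[f*9], &tri[f*9+3], &tri[f*9+6], q);
      double d2 = 0;
      for (int i = 0; i < 3; ++i) { double dd = p[i]-q[i]; d2 += dd*dd; }
      if (d2 < best) { best = d2; bf = f; for (int i=0;i<3;++i) bq[i]=q[i]; }
    }
    out(ip,0) = std::sqrt(best);
    for (int i = 0; i < 3; ++i) out(ip,1+i) = bq[i];
    out(ip,4) = bf;
  }
  return out;
}

// Mean distance from each point to its k nearest neighbours (excluding itself).
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix P, int k) {
  int n = P.nrow();
  NumericVector out(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < 3; ++c) { double d = P(i,c)-P(j,c); s += d*d; }
      d2[j] = s;
    }
    d2[i] = R_PosInf;                    // exclude self
    std::nth_element(d2.begin(), d2.begin()+k-1, d2.end());
    double acc = 0;
    for (int j = 0; j < k; ++j) acc += std::sqrt(d2[j]);
    out[i] = acc / k;
  }
  return out;
}

// Indices (zero-based) of the k nearest neighbours of each point.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_indices(NumericMatrix P, int k) {
  int n = P.nrow();
  IntegerMatrix out(n, k);
  std::vector<std::pair<double,int> > d2(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < 3; ++c) { double d = P(i,c)-P(j,c); s += d*d; }
      d2[j] = std::make_pair(j == i ? R_PosInf : s, j);
    }
    std::partial_sort(d2.begin(), d2.begin()+k, d2.end());
    for (int j = 0; j < k; ++j) out(i,j) = d2[j].second;
  }
  return out;
}

// Nearest neighbour in Q for every point of P. Returns Nx2 (distance, index0).
// [[Rcpp::export]]
NumericMatrix cpp_nn_cloud(NumericMatrix P, NumericMatrix Q) {
  int np = P.nrow(), nq = Q.nrow();
  NumericMatrix out(np, 2);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf; int bj = -1;
    double p0 = P(i,0), p1 = P(i,1), p2 = P(i,2);
    for (int j = 0; j < nq; ++j) {
      double d0 = p0-Q(j,0), d1 = p1-Q(j,1), d2 = p2-Q(j,2);
      double s = d0*d0 + d1*d1 + d2*d2;
      if (s < best) { best = s; bj = j; }
    }
    out(i,0) = std::sqrt(best);
    out(i,1) = bj;
  }
  return out;
}
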