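#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact convex-hull volume for point sets in 1..4 dimensions.
//
// Strategy: enumerate all d-point subsets, keep those whose affine hull is a
// supporting hyperplane of the point set, deduplicate hyperplanes, and sum
// pyramid volumes (facet (d-1)-volume x distance to an interior point / d).
// Facets with more than d coplanar vertices (squares, hexagon edges, ...) are
// handled by projecting the full facet vertex set into hyperplane coordinates
// and recursing in dimension d-1. Exact for points given exactly (tolerance
// only guards rank / coplanarity decisions).

typedef std::vector<double> Vec;
typedef std::vector<Vec> Mat;

static double dot(const Vec& a, const Vec& b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

static double norm2(const Vec& a) { return std::sqrt(dot(a, a)); }

// generalized cross product: normal to d-1 vectors in R^d (d = 2, 3, 4)
static Vec gen_cross(const Mat& v, int d) {
  Vec n(d, 0.0);
  if (d == 2) {
    n[0] = -v[0][1];
    n[1] = v[0][0];
  } else if (d == 3) {
    n[0] = v[0][1] * v[1][2] - v[0][2] * v[1][1];
    n[1] = v[0][2] * v[1][0] - v[0][0] * v[1][2];
    n[2] = v[0][0] * v[1][1] - v[0][1] * v[1][0];
  } else { // d == 4: cofactor expansion of det with unit-vector first row
    const Vec &a = v[0], &b = v[1], &c = v[2];
    auto det3 = [](double a11, double a12, double a13,
                   double a21, double a22, double a23,
                   double a31, double a32, double a33) {
      return a11 * (a22 * a33 - a23 * a32)
           - a12 * (a21 * a33 - a23 * a31)
           + a13 * (a21 * a32 - a22 * a31);
    };
    n[0] =  det3(a[1], a[2], a[3], b[1], b[2], b[3], c[1], c[2], c[3]);
    n[1] = -det3(a[0], a[2], a[3], b[0], b[2], b[3], c[0], c[2], c[3]);
    n[2] =  det3(a[0], a[1], a[3], b[0], b[1], b[3], c[0], c[1], c[3]);
    n[3] = -det3(a[0], a[1], a[2], b[0], b[1], b[2], c[0], c[1], c[2]);
  }
  return n;
}

// affine rank of the point set (Gram-Schmidt with tolerance)
static int affine_rank(const Mat& pts, double tol) {
  int n = pts.size();
  if (n < 2) return 0;
  int d = pts[0].size();
  Mat basis;
  for (int i = 1; i < n; ++i) {
    Vec v(d);
    for (int k = 0; k < d; ++k) v[k] = pts[i][k] - pts[0][k];
    for (size_t b = 0; b < basis.size(); ++b) {
      double pr = dot(v, basis[b]);
      for (int k = 0; k < d; ++k) v[k] -= pr * basis[b][k];
    }
    double nv = norm2(v);
    if (nv > tol) {
      for (int k = 0; k < d; ++k) v[k] /= nv;
      basis.push_back(v);
      if ((int)basis.size() == d) break;
    }
  }
  return basis.size();
}

static double hull_volume_rec(const Mat& pts_in, double tol);

// next combination of k indices out of n, lexicographic; returns false at end
static bool next_comb(std::vector<int>& idx, int n, int k) {
  int i = k - 1;
  while (i >= 0 && idx[i] == n - k + i) --i;
  if (i < 0) return false;
  ++idx[i];
  for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  return true;
}

static double hull_volume_rec(const Mat& pts_in, double tol) {
  // deduplicate points
  Mat pts;
  for (size_t i = 0; i < pts_in.size(); ++i) {
    bool dup = false;
    for (size_t j = 0; j < pts.size(); ++j) {
      double dmax = 0.0;
      for (size_t k = 0; k < pts_in[i].size(); ++k)
        dmax = std::max(dmax, std::fabs(pts_in[i][k] - pts[j][k]));
      if (dmax <= tol) { dup = true; break; }
    }
    if (!dup) pts.push_back(pts_in[i]);
  }
  int n = pts.size();
  if (n == 0) return 0.0;
  int d = pts[0].size();
  if (n <= d) return 0.0;

  if (d == 1) {
    double lo = pts[0][0], hi = pts[0][0];
    for (int i = 1; i < n; ++i) {
      lo = std::min(lo, pts[i][0]);
      hi = std::max(hi, pts[i][0]);
    }
    return hi - lo;
  }
  if (affine_rank(pts, tol) < d) return 0.0;

  Vec centroid(d, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) centroid[k] += pts[i][k] / n;

  // collect unique outward supporting hyperplanes (normal, offset, anchor)
  std::vector<Vec> normals;
  std::vector<double> offsets;
  std::vector<int> anchors;

  std::vector<int> idx(d);
  for (int i = 0; i < d; ++i) idx[i] = i;
  do {
    Mat edges(d - 1, Vec(d));
    for (int e = 1; e < d; ++e)
      for (int k = 0; k < d; ++k)
        edges[e - 1][k] = pts[idx[e]][k] - pts[idx[0]][k];
    Vec nrm = gen_cross(edges, d);
    double nn = norm2(nrm);
    double escale = 0.0;
    for (int e = 0; e < d - 1; ++e) escale = std::max(escale, norm2(edges[e]));
    if (nn <= tol * std::max(1.0, escale)) continue; // affinely dependent subset
    for (int k = 0; k < d; ++k) nrm[k] /= nn;
    double b = dot(nrm, pts[idx[0]]);
    // supporting?
    double mn = 0.0, mx = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = dot(nrm, pts[i]) - b;
      mn = std::min(mn, s);
      mx = std::max(mx, s);
    }
    bool sup_pos = (mn >= -tol), sup_neg = (mx <= tol);
    if (!sup_pos && !sup_neg) continue;
    if (sup_pos) { // points on positive side: flip so interior is negative
      for (int k = 0; k < d; ++k) nrm[k] = -nrm[k];
      b = -b;
    }
    // dedupe against accepted planes
    bool seen = false;
    for (size_t p = 0; p < normals.size(); ++p) {
      if (std::fabs(offsets[p] - b) > 10 * tol) continue;
      double dmax = 0.0;
      for (int k = 0; k < d; ++k)
        dmax = std::max(dmax, std::fabs(normals[p][k] - nrm[k]));
      if (dmax <= 1e-7) { seen = true; break; }
    }
    if (!seen) {
      normals.push_back(nrm);
      offsets.push_back(b);
      anchors.push_back(idx[0]);
    }
  } while (next_comb(idx, n, d));

  double vol = 0.0;
  for (size_t p = 0; p < normals.size(); ++p) {
    const Vec& nrm = normals[p];
    double b = offsets[p];
    // facet vertex set
    std::vector<int> fidx;
    for (int i = 0; i < n; ++i)
      if (std::fabs(dot(nrm, pts[i]) - b) <= tol) fidx.push_back(i);
    if ((int)fidx.size() < d) continue;
    // orthonormal basis of the hyperplane
    Mat basis;
    for (int k = 0; k < d && (int)basis.size() < d - 1; ++k) {
      Vec v(d, 0.0);
      v[k] = 1.0;
      double pr = dot(v, nrm);
      for (int j = 0; j < d; ++j) v[j] -= pr * nrm[j];
      for (size_t bb = 0; bb < basis.size(); ++bb) {
        double pr2 = dot(v, basis[bb]);
        for (int j = 0; j < d; ++j) v[j] -= pr2 * basis[bb][j];
      }
      double nv = norm2(v);
      if (nv > 1e-10) {
        for (int j = 0; j < d; ++j) v[j] /= nv;
        basis.push_back(v);
      }
    }
    if ((int)basis.size() != d - 1) continue;
    const Vec& p0 = pts[fidx[0]];
    Mat proj(fidx.size(), Vec(d - 1));
    for (size_t i = 0; i < fidx.size(); ++i)
      for (int e = 0; e < d - 1; ++e) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) s += (pts[fidx[i]][k] - p0[k]) * basis[e][k];
        proj[i][e] = s;
      }
    double fvol = hull_volume_rec(proj, tol);
    double height = std::fabs(b - dot(nrm, centroid));
    vol += height * fvol / d;
  }
  return vol;
}

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix x) {
  int n = x.nrow(), d = x.ncol();
  if (d < 1 || d > 4) stop("hull volume supported for 1 <= d <= 4");
  Mat pts(n, Vec(d));
  double scale = 1.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) {
      pts[i][k] = x(i, k);
      scale = std::max(scale, std::fabs(x(i, k)));
    }
  return hull_volume_rec(pts, 1e-9 * scale);
}
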