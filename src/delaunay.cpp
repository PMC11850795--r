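#include <Rcpp.h>
#include <set>
#include <utility>
using namespace Rcpp;

// Brute-force Delaunay edge extraction via the empty-circumcircle (2D) /
// empty-circumsphere (3D) property: a simplex belongs to the triangulation
// iff no other point lies strictly inside its circumscribed ball; the
// union of accepted simplices' edges is the Delaunay neighbour graph.
// Callers resolve exact degeneracies (co-circular / co-spherical points)
// beforehand with a deterministic jitter. O(n^3..n^4) with early exit —
// intended for the few-hundred-point tables this package works on.

static inline double orient2d(const NumericMatrix& p, int a, int b, int c) {
  return (p(b,0)-p(a,0))*(p(c,1)-p(a,1)) - (p(b,1)-p(a,1))*(p(c,0)-p(a,0));
}

// [[Rcpp::export]]
IntegerMatrix delaunay_edges_2d_cpp(NumericMatrix p) {
  const int n = p.nrow();
  if (n < 3) stop("need at least 3 points");
  std::set<std::pair<int,int>> edges;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      for (int k = j + 1; k < n; ++k) {
        double o = orient2d(p, i, j, k);
        if (o == 0.0) continue;  // collinear: no circumcircle
        // circumcentre
        double ax = p(i,0), ay = p(i,1), bx = p(j,0), by = p(j,1), cx = p(k,0), cy = p(k,1);
        double d = 2.0 * (ax*(by-cy) + bx*(cy-ay) + cx*(ay-by));
        double a2 = ax*ax + ay*ay, b2 = bx*bx + by*by, c2 = cx*cx + cy*cy;
        double ux = (a2*(by-cy) + b2*(cy-ay) + c2*(ay-by)) / d;
        double uy = (a2*(cx-bx) + b2*(ax-cx) + c2*(bx-ax)) / d;
        double r2 = (ax-ux)*(ax-ux) + (ay-uy)*(ay-uy);
        bool empty = true;
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j || m == k) continue;
          double dx = p(m,0)-ux, dy = p(m,1)-uy;
          if (dx*dx + dy*dy < r2) { empty = false; break; }
        }
        if (empty) {
          edges.insert({i, j}); edges.insert({i, k}); edges.insert({j, k});
        }
      }
    }
  }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (const auto& e : edges) { out(r,0) = e.first + 1; out(r,1) = e.second + 1; ++r; }
  return out;
}

// Solve the 3x3 system for the circumcentre of a tetrahedron; returns false
// when the four points are (near-)coplanar.
static bool circumsphere(const NumericMatrix& p, int a, int b, int c, int d,
                         double* centre, double* r2) {
  double M[3][3], rhs[3];
  int idx[3] = {b, c, d};
  for (int row = 0; row < 3; ++row) {
    double s = 0.0;
    for (int col = 0; col < 3; ++col) {
      M[row][col] = 2.0 * (p(idx[row],col) - p(a,col));
      s += p(idx[row],col)*p(idx[row],col) - p(a,col)*p(a,col);
    }
    rhs[row] = s;
  }
  // Cramer's rule
  double det =
      M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
    - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
    + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
  if (det == 0.0) return false;
  double Dx =
      rhs[0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
    - M[0][1]*(rhs[1]*M[2][2]-M[1][2]*rhs[2])
    + M[0][2]*(rhs[1]*M[2][1]-M[1][1]*rhs[2]);
  double Dy =
      M[0][0]*(rhs[1]*M[2][2]-M[1][2]*rhs[2])
    - rhs[0]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
    + M[0][2]*(M[1][0]*rhs[2]-rhs[1]*M[2][0]);
  double Dz =
      M[0][0]*(M[1][1]*rhs[2]-rhs[1]*M[2][1])
    - M[0][1]*(M[1][0]*rhs[2]-rhs[1]*M[2][0])
    + rhs[0]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
  centre[0] = Dx / det; centre[1] = Dy / det; centre[2] = Dz / det;
  double dx = p(a,0)-centre[0], dy = p(a,1)-centre[1], dz = p(a,2)-centre[2];
  *r2 = dx*dx + dy*dy + dz*dz;
  return true;
}

// [[Rcpp::export]]
IntegerMatrix delaunay_edges_3d_cpp(NumericMatrix p) {
  const int n = p.nrow();
  if (n < 4) stop("need at least 4 points");
  std::set<std::pair<int,int>> edges;
  double ctr[3], r2;
  for (int i = 0; i < n - 3; ++i)
    for (int j = i + 1; j < n - 2; ++j)
      for (int k = j + 1; k < n - 1; ++k)
        for (int l = k + 1; l < n; ++l) {
          if (!circumsphere(p, i, j, k, l, ctr, &r2)) continue;
          bool empty = true;
          for (int m = 0; m < n; ++m) {
            if (m == i || m == j || m == k || m == l) continue;
            double dx = p(m,0)-ctr[0], dy = p(m,1)-ctr[1], dz = p(m,2)-ctr[2];
            if (dx*dx + dy*dy + dz*dz < r2) { empty = false; break; }
          }
          if (empty) {
            int v[4] = {i, j, k, l};
            for (int a = 0; a < 3; ++a)
              for (int b = a + 1; b < 4; ++b)
                edges.insert({v[a], v[b]});
          }
        }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (const auto& e : edges) { out(r,0) = e.first + 1; out(r,1) = e.second + 1; ++r; }
  return out;
}
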