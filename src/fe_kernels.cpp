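// Compiled kernels for the hot loops: batched symmetric 3x3 eigen
// decomposition, constant-strain tetrahedron assembly and strain recovery,
// element-by-element matvec for the periodic voxel homogenization, and
// batched Voigt stiffness rotation.
//
// Voigt order throughout: (11, 22, 33, 23, 13, 12), engineering shear strains.
// Symmetric 6x6 matrices are packed column-major on the upper triangle as
// 21 values: (1,1),(1,2),(2,2),(1,3),(2,3),(3,3),...,(6,6).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void unpack21(const double* p, arma::mat& C) {
  int k = 0;
  for (int j = 0; j < 6; ++j)
    for (int i = 0; i <= j; ++i) {
      C(i, j) = p[k];
      C(j, i) = p[k];
      ++k;
    }
}

static inline void pack21(const arma::mat& C, double* p) {
  int k = 0;
  for (int j = 0; j < 6; ++j)
    for (int i = 0; i <= j; ++i) p[k++] = 0.5 * (C(i, j) + C(j, i));
}

// Batched eigen decomposition of symmetric 3x3 matrices.
// M: 6 x n, rows (11,22,33,23,13,12). Returns ascending eigenvalues (3 x n)
// and eigenvectors (9 x n; columns of the rotation stacked e1,e2,e3).
// [[Rcpp::export(name = ".eig_sym3_batch")]]
List eig_sym3_batch(const NumericMatrix& M) {
  const int n = M.ncol();
  NumericMatrix values(3, n), vectors(9, n);
  arma::mat33 A;
  arma::vec3 ev;
  arma::mat33 V;
  for (int c = 0; c < n; ++c) {
    A(0, 0) = M(0, c); A(1, 1) = M(1, c); A(2, 2) = M(2, c);
    A(1, 2) = A(2, 1) = M(3, c);
    A(0, 2) = A(2, 0) = M(4, c);
    A(0, 1) = A(1, 0) = M(5, c);
    arma::eig_sym(ev, V, A);
    for (int i = 0; i < 3; ++i) values(i, c) = ev(i);
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) vectors(3 * j + i, c) = V(i, j);
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}

// Gradient matrix (3 x 4) of linear shape functions on a tetrahedron and its
// signed volume. Returns false when degenerate.
static bool tet_grads(const double* x, const double* y, const double* z,
                      arma::mat& G, double& vol) {
  arma::mat44 J;
  for (int i = 0; i < 4; ++i) {
    J(0, i) = 1.0;
    J(1, i) = x[i];
    J(2, i) = y[i];
    J(3, i) = z[i];
  }
  double det = arma::det(J);
  vol = det / 6.0;
  if (std::abs(det) < 1e-300) return false;
  arma::mat44 Jin = arma::inv(J);
  // dN_i/dx = Jin(i, 1), etc.
  for (int i = 0; i < 4; ++i) {
    G(0, i) = Jin(i, 1);
    G(1, i) = Jin(i, 2);
    G(2, i) = Jin(i, 3);
  }
  return true;
}

static void tet_B(const arma::mat& G, arma::mat& B) {
  B.zeros();
  for (int i = 0; i < 4; ++i) {
    const double dx = G(0, i), dy = G(1, i), dz = G(2, i);
    B(0, 3 * i + 0) = dx;
    B(1, 3 * i + 1) = dy;
    B(2, 3 * i + 2) = dz;
    B(3, 3 * i + 1) = dz; B(3, 3 * i + 2) = dy;  // gamma_23
    B(4, 3 * i + 0) = dz; B(4, 3 * i + 2) = dx;  // gamma_13
    B(5, 3 * i + 0) = dy; B(5, 3 * i + 1) = dx;  // gamma_12
  }
}

// Assemble linear tetrahedra: returns COO triplets of the global stiffness
// (1-based DOF indices; DOFs are (node-1)*3 + comp) and element volumes.
// nodes: n x 3; elems: m x 4 (1-based); C21: 21 x m packed stiffnesses (MPa).
// [[Rcpp::export(name = ".tet_assemble")]]
List tet_assemble(const NumericMatrix& nodes, const IntegerMatrix& elems,
                  const NumericMatrix& C21) {
  const int m = elems.nrow();
  IntegerVector ti(144 * (R_xlen_t)m), tj(144 * (R_xlen_t)m);
  NumericVector tx(144 * (R_xlen_t)m), vols(m);
  arma::mat G(3, 4), B(6, 12), C(6, 6), Ke(12, 12);
  double x[4], y[4], z[4];
  int dof[12];
  R_xlen_t k = 0;
  for (int e = 0; e < m; ++e) {
    for (int i = 0; i < 4; ++i) {
      int nd = elems(e, i) - 1;
      x[i] = nodes(nd, 0); y[i] = nodes(nd, 1); z[i] = nodes(nd, 2);
      for (int c = 0; c < 3; ++c) dof[3 * i + c] = 3 * nd + c + 1;
    }
    double vol;
    if (!tet_grads(x, y, z, G, vol)) stop("degenerate tetrahedron %d", e + 1);
    vols[e] = vol;
    tet_B(G, B);
    unpack21(&C21(0, e), C);
    Ke = std::abs(vol) * (B.t() * C * B);
    for (int j = 0; j < 12; ++j)
      for (int i = 0; i < 12; ++i) {
        ti[k] = dof[i];
        tj[k] = dof[j];
        tx[k] = Ke(i, j);
        ++k;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx,
                      _["volume"] = vols);
}

// Element strains (6 x m, engineering shears) from a nodal displacement
// vector u (length 3n, DOFs as above).
// [[Rcpp::export(name = ".tet_strains")]]
NumericMatrix tet_strains(const NumericMatrix& nodes,
                          const IntegerMatrix& elems,
                          const NumericVector& u) {
  const int m = elems.nrow();
  NumericMatrix out(6, m);
  arma::mat G(3, 4), B(6, 12);
  arma::vec ue(12), eps(6);
  double x[4], y[4], z[4];
  for (int e = 0; e < m; ++e) {
    for (int i = 0; i < 4; ++i) {
      int nd = elems(e, i) - 1;
      x[i] = nodes(nd, 0); y[i] = nodes(nd, 1); z[i] = nodes(nd, 2);
      for (int c = 0; c < 3; ++c) ue(3 * i + c) = u[3 * nd + c];
    }
    double vol;
    tet_grads(x, y, z, G, vol);
    tet_B(G, B);
    eps = B * ue;
    for (int i = 0; i < 6; ++i) out(i, e) = eps(i);
  }
  return out;
}

// Element-by-element matvec  y = K x  for the periodic voxel grid, with a
// single shared element stiffness Ke (24 x 24) scaled per element by
// `dens` (partial-volume density). dofmap: 24 x nel matrix of 1-based
// global DOF indices. Used inside the homogenization CG loop.
// [[Rcpp::export(name = ".ebe_matvec")]]
NumericVector ebe_matvec(const NumericMatrix& Ke, const IntegerMatrix& dofmap,
                         const NumericVector& dens, const NumericVector& x,
                         int ndof) {
  NumericVector y(ndof);
  const int nel = dofmap.ncol();
  double xe[24], ye[24];
  for (int e = 0; e < nel; ++e) {
    const int* d = &dofmap(0, e);
    const double sc = dens[e];
    for (int i = 0; i < 24; ++i) xe[i] = x[d[i] - 1];
    for (int i = 0; i < 24; ++i) {
      double s = 0.0;
      const double* kcol = &Ke(0, i);  // Ke symmetric: column == row
      for (int j = 0; j < 24; ++j) s += kcol[j] * xe[j];
      ye[i] = sc * s;
    }
    for (int i = 0; i < 24; ++i) y[d[i] - 1] += ye[i];
  }
  return y;
}

// Diagonal of the element-by-element operator (Jacobi preconditioner).
// [[Rcpp::export(name = ".ebe_diag")]]
NumericVector ebe_diag(const NumericMatrix& Ke, const IntegerMatrix& dofmap,
                       const NumericVector& dens, int ndof) {
  NumericVector d(ndof);
  const int nel = dofmap.ncol();
  for (int e = 0; e < nel; ++e) {
    const int* dd = &dofmap(0, e);
    for (int i = 0; i < 24; ++i) d[dd[i] - 1] += dens[e] * Ke(i, i);
  }
  return d;
}

// Batched congruence rotation of packed Voigt stiffnesses into world axes.
// C21: 21 x n local stiffness; Q9: 9 x n rotation matrices (columns are the
// local basis vectors expressed in world coordinates, stacked e1,e2,e3).
// Uses the Bond transformation for engineering-strain Voigt matrices.
// [[Rcpp::export(name = ".rotate_stiffness_batch")]]
NumericMatrix rotate_stiffness_batch(const NumericMatrix& C21,
                                     const NumericMatrix& Q9) {
  const int n = C21.ncol();
  NumericMatrix out(21, n);
  arma::mat C(6, 6), M(6, 6), Cw(6, 6);
  arma::mat33 Q;
  // Voigt pair index ordering (11,22,33,23,13,12) -> (i,j) pairs
  const int pi_[6] = {0, 1, 2, 1, 0, 0};
  const int pj_[6] = {0, 1, 2, 2, 2, 1};
  for (int c = 0; c < n; ++c) {
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) Q(i, j) = Q9(3 * j + i, c);
    // Bond stress transformation matrix M: sigma_world = M sigma_local
    // (Q maps local components to world: a_world = Q a_local)
    for (int a = 0; a < 6; ++a) {
      int i = pi_[a], j = pj_[a];
      for (int b = 0; b < 6; ++b) {
        int k = pi_[b], l = pj_[b];
        double v = Q(i, k) * Q(j, l);
        if (k != l) v += Q(i, l) * Q(j, k);
        M(a, b) = v;
      }
    }
    unpack21(&C21(0, c), C);
    Cw = M * C * M.t();
    pack21(Cw, &out(0, c));
  }
  return out;
}

// Distance from grid points to a set of segments, reduced by min: used for
// voxelizing strut lattices. pts: 3 x np; segs: 6 x ns (a, b endpoints).
// [[Rcpp::export(name = ".min_dist_to_segments")]]
NumericVector min_dist_to_segments(const NumericMatrix& pts,
                                   const NumericMatrix& segs) {
  const int np = pts.ncol(), ns = segs.ncol();
  NumericVector out(np);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int s = 0; s < ns; ++s) {
    const double ax = segs(0, s), ay = segs(1, s), az = segs(2, s);
    const double dx = segs(3, s) - ax, dy = segs(4, s) - ay,
                 dz = segs(5, s) - az;
    const double L2 = dx * dx + dy * dy + dz * dz;
    for (int p = 0; p < np; ++p) {
      double px = pts(0, p) - ax, py = pts(1, p) - ay, pz = pts(2, p) - az;
      double t = L2 > 0 ? (px * dx + py * dy + pz * dz) / L2 : 0.0;
      t = t < 0 ? 0 : (t > 1 ? 1 : t);
      double qx = px - t * dx, qy = py - t * dy, qz = pz - t * dz;
      double d2 = qx * qx + qy * qy + qz * qz;
      if (d2 < out[p]) out[p] = d2;
    }
  }
  return sqrt(out);
}

// Distances to the 1st and 3rd nearest seed under periodic-free boundary:
// used for the implicit Voronoi strut lattice. pts: 3 x np; seeds: 3 x ns.
// [[Rcpp::export(name = ".voronoi_gap")]]
NumericMatrix voronoi_gap(const NumericMatrix& pts, const NumericMatrix& seeds) {
  const int np = pts.ncol(), ns = seeds.ncol();
  if (ns < 3) stop("need at least 3 seeds");
  NumericMatrix out(2, np);  // rows: d1, d3
  for (int p = 0; p < np; ++p) {
    double d1 = R_PosInf, d2 = R_PosInf, d3 = R_PosInf;
    const double px = pts(0, p), py = pts(1, p), pz = pts(2, p);
    for (int s = 0; s < ns; ++s) {
      double dx = px - seeds(0, s), dy = py - seeds(1, s), dz = pz - seeds(2, s);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < d1) { d3 = d2; d2 = d1; d1 = d; }
      else if (d < d2) { d3 = d2; d2 = d; }
      else if (d < d3) { d3 = d; }
    }
    out(0, p) = std::sqrt(d1);
    out(1, p) = std::sqrt(d3);
  }
  return out;
}
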