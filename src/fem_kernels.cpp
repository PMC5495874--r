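#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear hexahedral FEM kernels. Element corner ordering (VTK hexahedron):
// (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)
// Reference element [-1,1]^3; all node coordinates are expected in metres.

static const double SGN[8][3] = {
  {-1,-1,-1},{ 1,-1,-1},{ 1, 1,-1},{-1, 1,-1},
  {-1,-1, 1},{ 1,-1, 1},{ 1, 1, 1},{-1, 1, 1}};

// shape-function gradients on the reference element at point xi
static inline void dshape(const double *xi, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    const double *s = SGN[a];
    dN[a][0] = s[0] * (1.0 + s[1]*xi[1]) * (1.0 + s[2]*xi[2]) / 8.0;
    dN[a][1] = s[1] * (1.0 + s[0]*xi[0]) * (1.0 + s[2]*xi[2]) / 8.0;
    dN[a][2] = s[2] * (1.0 + s[0]*xi[0]) * (1.0 + s[1]*xi[1]) / 8.0;
  }
}

static inline double det3(const double J[3][3]) {
  return J[0][0]*(J[1][1]*J[2][2]-J[1][2]*J[2][1])
       - J[0][1]*(J[1][0]*J[2][2]-J[1][2]*J[2][0])
       + J[0][2]*(J[1][0]*J[2][1]-J[1][1]*J[2][0]);
}

static inline void inv3(const double J[3][3], double det, double Ji[3][3]) {
  Ji[0][0] =  (J[1][1]*J[2][2]-J[1][2]*J[2][1])/det;
  Ji[0][1] = -(J[0][1]*J[2][2]-J[0][2]*J[2][1])/det;
  Ji[0][2] =  (J[0][1]*J[1][2]-J[0][2]*J[1][1])/det;
  Ji[1][0] = -(J[1][0]*J[2][2]-J[1][2]*J[2][0])/det;
  Ji[1][1] =  (J[0][0]*J[2][2]-J[0][2]*J[2][0])/det;
  Ji[1][2] = -(J[0][0]*J[1][2]-J[0][2]*J[1][0])/det;
  Ji[2][0] =  (J[1][0]*J[2][1]-J[1][1]*J[2][0])/det;
  Ji[2][1] = -(J[0][0]*J[2][1]-J[0][1]*J[2][0])/det;
  Ji[2][2] =  (J[0][0]*J[1][1]-J[0][1]*J[1][0])/det;
}

// tensors: m x 6 lower-triangle packing (xx, xy, yy, xz, yz, zz), S/m
// (NumericMatrix is column-major: gather the row first)
static inline void unpack_sigma(const NumericMatrix &tens, int e, double S[3][3]) {
  double t[6];
  for (int j = 0; j < 6; ++j) t[j] = tens(e, j);
  S[0][0] = t[0]; S[0][1] = t[1]; S[1][1] = t[2];
  S[0][2] = t[3]; S[1][2] = t[4]; S[2][2] = t[5];
  S[1][0] = S[0][1]; S[2][0] = S[0][2]; S[2][1] = S[1][2];
}

// Assemble per-element 8x8 stiffness blocks with 8-point Gauss quadrature.
// Returns COO triplets plus element volumes; errors on non-positive Jacobians.
// [[Rcpp::export]]
List cpp_assemble_stiffness(NumericMatrix nodes, IntegerMatrix elements,
                            NumericMatrix tensors) {
  const int m = elements.nrow(), nn = nodes.nrow();
  const double g = 1.0 / std::sqrt(3.0);
  double gp[8][3];
  for (int q = 0; q < 8; ++q)
    for (int d = 0; d < 3; ++d) gp[q][d] = SGN[q][d] * g;

  double dNq[8][8][3];
  for (int q = 0; q < 8; ++q) dshape(gp[q], dNq[q]);

  IntegerVector ti((R_xlen_t)m * 64), tj((R_xlen_t)m * 64);
  NumericVector tx((R_xlen_t)m * 64);
  NumericVector vol(m);

  double crd[8][3], S[3][3];
  for (int e = 0; e < m; ++e) {
    int idx[8];
    for (int a = 0; a < 8; ++a) {
      idx[a] = elements(e, a) - 1;
      if (idx[a] < 0 || idx[a] >= nn) stop("element %d: node index out of range", e + 1);
      for (int d = 0; d < 3; ++d) crd[a][d] = nodes(idx[a], d);
    }
    unpack_sigma(tensors, e, S);
    double Ke[8][8] = {{0}};
    double v = 0.0;
    for (int q = 0; q < 8; ++q) {
      double J[3][3] = {{0}};
      for (int a = 0; a < 8; ++a)
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c) J[r][c] += dNq[q][a][r] * crd[a][c];
      double det = det3(J);
      if (det <= 0.0) stop("non-positive Jacobian in element %d", e + 1);
      double Ji[3][3];
      inv3(J, det, Ji);
      double G[8][3]; // physical gradients: G = dN * Ji (dN row vector times J^{-1})
      for (int a = 0; a < 8; ++a)
        for (int c = 0; c < 3; ++c)
          G[a][c] = dNq[q][a][0]*Ji[0][c] + dNq[q][a][1]*Ji[1][c] + dNq[q][a][2]*Ji[2][c];
      double SG[8][3];
      for (int a = 0; a < 8; ++a)
        for (int r = 0; r < 3; ++r)
          SG[a][r] = S[r][0]*G[a][0] + S[r][1]*G[a][1] + S[r][2]*G[a][2];
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b <= a; ++b) {
          double k = (G[a][0]*SG[b][0] + G[a][1]*SG[b][1] + G[a][2]*SG[b][2]) * det;
          Ke[a][b] += k;
          if (a != b) Ke[b][a] += k;
        }
      v += det;
    }
    vol[e] = v;
    R_xlen_t base = (R_xlen_t)e * 64;
    for (int a = 0; a < 8; ++a)
      for (int b = 0; b < 8; ++b) {
        ti[base + a*8 + b] = idx[a] + 1;
        tj[base + a*8 + b] = idx[b] + 1;
        tx[base + a*8 + b] = Ke[a][b];
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx, _["volumes"] = vol);
}

// Jacobian determinants at the 8 corners of every element (m x 8).
// [[Rcpp::export]]
NumericMatrix cpp_corner_jacobians(NumericMatrix nodes, IntegerMatrix elements) {
  const int m = elements.nrow();
  NumericMatrix out(m, 8);
  double crd[8][3];
  double corner_xi[8][3];
  for (int q = 0; q < 8; ++q)
    for (int d = 0; d < 3; ++d) corner_xi[q][d] = SGN[q][d];
  double dNq[8][8][3];
  for (int q = 0; q < 8; ++q) dshape(corner_xi[q], dNq[q]);
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < 8; ++a)
      for (int d = 0; d < 3; ++d) crd[a][d] = nodes(elements(e, a) - 1, d);
    for (int q = 0; q < 8; ++q) {
      double J[3][3] = {{0}};
      for (int a = 0; a < 8; ++a)
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c) J[r][c] += dNq[q][a][r] * crd[a][c];
      out(e, q) = det3(J);
    }
  }
  return out;
}

// Per-coil node weight vectors for the secondary magnetic flux:
// B_sec(p) . n = w^T u with one Gauss point (element centre) per element,
//   w_a -= mu0/(4 pi) * V_e / |R|^3 * G_a . (sigma (R x n)),  R = p - c_e.
// Returns a dense ncoil x nnodes matrix (SI: tesla per volt-node).
// [[Rcpp::export]]
NumericMatrix cpp_meg_weights(NumericMatrix nodes, IntegerMatrix elements,
                              NumericMatrix tensors, NumericVector volumes,
                              NumericMatrix coil_pos, NumericMatrix coil_ori) {
  const int m = elements.nrow(), nn = nodes.nrow(), nc = coil_pos.nrow();
  const double mu0_4pi = 1e-7;
  NumericMatrix W(nc, nn);
  double xi0[3] = {0.0, 0.0, 0.0};
  double dN0[8][3];
  dshape(xi0, dN0);

  std::vector<double> ctr(3 * m), grad(24 * m), sig(9 * m);
  std::vector<int> idx(8 * m);
  double crd[8][3], S[3][3];
  for (int e = 0; e < m; ++e) {
    for (int a = 0; a < 8; ++a) {
      idx[8*e + a] = elements(e, a) - 1;
      for (int d = 0; d < 3; ++d) crd[a][d] = nodes(idx[8*e + a], d);
    }
    double c0[3] = {0, 0, 0};
    for (int a = 0; a < 8; ++a)
      for (int d = 0; d < 3; ++d) c0[d] += crd[a][d] / 8.0;
    for (int d = 0; d < 3; ++d) ctr[3*e + d] = c0[d];
    double J[3][3] = {{0}};
    for (int a = 0; a < 8; ++a)
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) J[r][c] += dN0[a][r] * crd[a][c];
    double det = det3(J), Ji[3][3];
    inv3(J, det, Ji);
    for (int a = 0; a < 8; ++a)
      for (int c = 0; c < 3; ++c)
        grad[24*e + 3*a + c] = dN0[a][0]*Ji[0][c] + dN0[a][1]*Ji[1][c] + dN0[a][2]*Ji[2][c];
    unpack_sigma(tensors, e, S);
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) sig[9*e + 3*r + c] = S[r][c];
  }

  for (int k = 0; k < nc; ++k) {
    const double p0 = coil_pos(k,0), p1 = coil_pos(k,1), p2 = coil_pos(k,2);
    const double n0 = coil_ori(k,0), n1 = coil_ori(k,1), n2 = coil_ori(k,2);
    double *Wk = &W(k, 0);
    for (int e = 0; e < m; ++e) {
      const double R0 = p0 - ctr[3*e], R1 = p1 - ctr[3*e+1], R2 = p2 - ctr[3*e+2];
      const double r2 = R0*R0 + R1*R1 + R2*R2;
      const double r3 = r2 * std::sqrt(r2);
      // c = R x n
      const double c0 = R1*n2 - R2*n1, c1 = R2*n0 - R0*n2, c2 = R0*n1 - R1*n0;
      const double *Sg = &sig[9*e];
      const double t0 = Sg[0]*c0 + Sg[1]*c1 + Sg[2]*c2;
      const double t1 = Sg[3]*c0 + Sg[4]*c1 + Sg[5]*c2;
      const double t2 = Sg[6]*c0 + Sg[7]*c1 + Sg[8]*c2;
      const double fac = -mu0_4pi * volumes[e] / r3;
      const double *G = &grad[24*e];
      const int *id = &idx[8*e];
      for (int a = 0; a < 8; ++a) {
        Wk[(R_xlen_t)id[a] * nc] += fac * (G[3*a]*t0 + G[3*a+1]*t1 + G[3*a+2]*t2);
      }
    }
  }
  return W;
}
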