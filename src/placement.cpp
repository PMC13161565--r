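#include <Rcpp.h>
using namespace Rcpp;

// Shared half-open cube membership test.
//
// A point at offset d from the cube center lies inside the cube iff the
// cube-frame coordinate q = R^T d satisfies -side/2 <= q_i < side/2 on every
// axis.  Every code path that decides membership (per-placement scoring,
// rasterization, and the lattice kernels used by the fast optimizer) goes
// through this one compiled function so that floating-point decisions are
// bit-identical everywhere.
static bool in_cube(const double *R, double dx, double dy, double dz,
                    double half) {
  // R is column-major 3x3; (R^T d)_i = sum_j R[j + 3*i] * d_j
  double q0 = R[0] * dx + R[1] * dy + R[2] * dz;
  if (q0 < -half || q0 >= half) return false;
  double q1 = R[3] * dx + R[4] * dy + R[5] * dz;
  if (q1 < -half || q1 >= half) return false;
  double q2 = R[6] * dx + R[7] * dy + R[8] * dz;
  return (q2 >= -half && q2 < half);
}

// Count points (rows of pts, world mm) falling inside the cube.
// [[Rcpp::export]]
double cpp_count_in_cube(NumericMatrix pts, NumericMatrix R,
                         NumericVector center, double side) {
  const int n = pts.nrow();
  const double half = side / 2.0;
  const double cx = center[0], cy = center[1], cz = center[2];
  double Rl[9];
  for (int i = 0; i < 9; ++i) Rl[i] = R[i];
  const double *px = &pts(0, 0), *py = &pts(0, 1), *pz = &pts(0, 2);
  double count = 0.0;
  for (int i = 0; i < n; ++i) {
    if (in_cube(Rl, px[i] - cx, py[i] - cy, pz[i] - cz, half)) count += 1.0;
  }
  return count;
}

// Per-point membership flags (used for rasterization and kernel building).
// [[Rcpp::export]]
LogicalVector cpp_points_in_cube(NumericMatrix pts, NumericMatrix R,
                                 NumericVector center, double side) {
  const int n = pts.nrow();
  const double half = side / 2.0;
  const double cx = center[0], cy = center[1], cz = center[2];
  double Rl[9];
  for (int i = 0; i < 9; ++i) Rl[i] = R[i];
  const double *px = &pts(0, 0), *py = &pts(0, 1), *pz = &pts(0, 2);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = in_cube(Rl, px[i] - cx, py[i] - cy, pz[i] - cz, half);
  }
  return out;
}

// Enclosed-volume scores for every candidate center at one fixed rotation.
//
// cums:  mask array zero-padded on all sides, cumulatively summed along the
//        first (x) dimension; dims = its dimensions.
// runs:  K x 4 integer matrix (mx0, mx1, my, mz): for each (my, mz) lattice
//        line crossing the rotated cube, the inclusive integer x-offset run
//        [mx0, mx1] of lattice points inside the cube.
// bx, by, bz: 0-based indices into the padded array of each candidate
//        center's nearest grid voxel, per axis.
//
// Returns a numeric vector of length nx*ny*nz (x fastest) of enclosed
// voxel counts; exact integers stored as doubles.
// [[Rcpp::export]]
NumericVector cpp_conv_runs(NumericVector cums, IntegerVector dims,
                            IntegerMatrix runs, IntegerVector bx,
                            IntegerVector by, IntegerVector bz) {
  const int nx = bx.size(), ny = by.size(), nz = bz.size();
  const int d1 = dims[0], d2 = dims[1];
  const R_xlen_t planeStride = (R_xlen_t)d1 * d2;
  const int K = runs.nrow();
  const double *C = REAL(cums);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *O = REAL(out);

  std::vector<int> mx0(K), mx1(K), my(K), mz(K);
  for (int k = 0; k < K; ++k) {
    mx0[k] = runs(k, 0);
    mx1[k] = runs(k, 1);
    my[k] = runs(k, 2);
    mz[k] = runs(k, 3);
  }

  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      double *orow = O + ((R_xlen_t)iz * ny + iy) * nx;
      for (int k = 0; k < K; ++k) {
        const R_xlen_t base =
            (R_xlen_t)(by[iy] + my[k]) * d1 + (bz[iz] + mz[k]) * planeStride;
        const double *Chi = C + base + mx1[k];
        const double *Clo = C + base + mx0[k] - 1;
        for (int ix = 0; ix < nx; ++ix) {
          orow[ix] += Chi[bx[ix]] - Clo[bx[ix]];
        }
      }
    }
  }
  return out;
}

// Cumulative sum along the first dimension of a 3D array.
// [[Rcpp::export]]
NumericVector cpp_cumsum_x(NumericVector arr, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericVector out(clone(arr));
  double *A = REAL(out);
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      double *col = A + ((R_xlen_t)k * d2 + j) * d1;
      for (int i = 1; i < d1; ++i) col[i] += col[i - 1];
    }
  }
  return out;
}
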