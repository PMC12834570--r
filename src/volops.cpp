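#define ARMA_NO_DEBUG
// Low-level voxel operations: rigid translation resampling, grid resampling,
// and lattice normalized-cross-correlation search. All volumes are passed as
// flat numeric vectors in R column-major order with dims (nx, ny, nz); voxel
// (i, j, k) lives at index i + nx*(j + ny*k), 0-based. Out-of-grid samples
// are zero.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sample_trilinear(const double* v, int nx, int ny, int nz,
                                      double x, double y, double z) {
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)nx || y >= (double)ny || z >= (double)nz) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy < 2; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      double wzy = wz * wy;
      for (int dx = 0; dx < 2; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        acc += wzy * wx * v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
      }
    }
  }
  return acc;
}

static inline double sample_nearest(const double* v, int nx, int ny, int nz,
                                    double x, double y, double z) {
  int xi = (int)std::floor(x + 0.5);
  int yi = (int)std::floor(y + 0.5);
  int zi = (int)std::floor(z + 0.5);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) return 0.0;
  return v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
}

// Translate a volume by shift_vox (voxel units): out(p) = vol(p - shift).
// mode 0 = nearest neighbour, 1 = trilinear.
// [[Rcpp::export]]
NumericVector shift_volume_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector shift_vox, int mode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = shift_vox[0], sy = shift_vox[1], sz = shift_vox[2];
  NumericVector out((size_t)nx * ny * nz);
  const double* v = vol.begin();
  double* o = out.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i - sx, y = j - sy, z = k - sz;
        o[idx] = mode == 0 ? sample_nearest(v, nx, ny, nz, x, y, z)
                           : sample_trilinear(v, nx, ny, nz, x, y, z);
      }
  return out;
}

// Resample onto a new grid. Output voxel (i,j,k) sits at world position
// origin_mm + (i,j,k) * out_spacing; the source voxel (i,j,k) sits at
// (i,j,k) * spacing (world origin at the centre of source voxel 0).
// [[Rcpp::export]]
NumericVector resample_volume_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, IntegerVector out_dim,
                                  NumericVector out_spacing,
                                  NumericVector origin_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  double* o = out.begin();
  size_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    double z = (origin_mm[2] + k * out_spacing[2]) / spacing[2];
    for (int j = 0; j < oy; ++j) {
      double y = (origin_mm[1] + j * out_spacing[1]) / spacing[1];
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = (origin_mm[0] + i * out_spacing[0]) / spacing[0];
        o[idx] = sample_trilinear(v, nx, ny, nz, x, y, z);
      }
    }
  }
  return out;
}

// Normalized cross-correlation between ref and a translated moving volume,
// evaluated over mask voxels (0-based linear indices), for each candidate
// voxel shift (rows of cand). The moving volume is sampled trilinearly at
// (p - shift). Returns one NCC per candidate; NA when the sampled moving
// values are constant over the mask.
// [[Rcpp::export]]
NumericVector ncc_search_cpp(NumericVector mov, NumericVector ref,
                             IntegerVector dim, IntegerVector mask_idx,
                             NumericMatrix cand) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* mv = mov.begin();
  const double* rv = ref.begin();
  R_xlen_t nm = mask_idx.size();
  std::vector<int> mx(nm), my(nm), mz(nm);
  std::vector<double> rvals(nm);
  double rsum = 0.0, rsum2 = 0.0;
  for (R_xlen_t t = 0; t < nm; ++t) {
    size_t li = (size_t)mask_idx[t];
    int i = li % nx;
    int j = (li / nx) % ny;
    int k = li / ((size_t)nx * ny);
    mx[t] = i; my[t] = j; mz[t] = k;
    double r = rv[li];
    rvals[t] = r;
    rsum += r; rsum2 += r * r;
  }
  double rmean = rsum / nm;
  double rvar = rsum2 / nm - rmean * rmean;
  int ncand = cand.nrow();
  NumericVector scores(ncand);
  for (int c = 0; c < ncand; ++c) {
    double sx = cand(c, 0), sy = cand(c, 1), sz = cand(c, 2);
    bool integer_shift =
      std::fabs(sx - std::round(sx)) < 1e-9 &&
      std::fabs(sy - std::round(sy)) < 1e-9 &&
      std::fabs(sz - std::round(sz)) < 1e-9;
    double msum = 0.0, msum2 = 0.0, mr = 0.0;
    if (integer_shift) {
      int isx = (int)std::round(sx), isy = (int)std::round(sy),
          isz = (int)std::round(sz);
      for (R_xlen_t t = 0; t < nm; ++t) {
        int xi = mx[t] - isx, yi = my[t] - isy, zi = mz[t] - isz;
        double m = 0.0;
        if (xi >= 0 && yi >= 0 && zi >= 0 && xi < nx && yi < ny && zi < nz)
          m = mv[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        msum += m; msum2 += m * m; mr += m * rvals[t];
      }
    } else {
      for (R_xlen_t t = 0; t < nm; ++t) {
        double m = sample_trilinear(mv, nx, ny, nz, mx[t] - sx, my[t] - sy,
                                    mz[t] - sz);
        msum += m; msum2 += m * m; mr += m * rvals[t];
      }
    }
    double mmean = msum / nm;
    double mvar = msum2 / nm - mmean * mmean;
    if (mvar <= 0.0 || rvar <= 0.0) {
      scores[c] = NA_REAL;
    } else {
      scores[c] = (mr / nm - mmean * rmean) / std::sqrt(mvar * rvar);
    }
  }
  return scores;
}
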