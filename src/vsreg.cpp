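#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major 3D indexing, 0-based: (i, j, k) -> i + nx*(j + ny*k).
static inline double at3(const double* a, int nx, int ny, int i, int j, int k) {
  return a[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

// Trilinear sample of a at continuous 0-based voxel index (x, y, z).
// Returns `fill` (and sets ok=false) outside [0, n-1] on any axis.
static double trilinear(const double* a, int nx, int ny, int nz,
                        double x, double y, double z, double fill, bool& ok) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
    ok = false;
    return fill;
  }
  ok = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2;
  if (j0 > ny - 2) j0 = ny - 2;
  if (k0 > nz - 2) k0 = nz - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  // Degenerate axes (n == 1) fall back to the single plane.
  int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0, k1 = nz > 1 ? k0 + 1 : k0;
  double fx = nx > 1 ? x - i0 : 0.0, fy = ny > 1 ? y - j0 : 0.0, fz = nz > 1 ? z - k0 : 0.0;
  double c000 = at3(a, nx, ny, i0, j0, k0), c100 = at3(a, nx, ny, i1, j0, k0);
  double c010 = at3(a, nx, ny, i0, j1, k0), c110 = at3(a, nx, ny, i1, j1, k0);
  double c001 = at3(a, nx, ny, i0, j0, k1), c101 = at3(a, nx, ny, i1, j0, k1);
  double c011 = at3(a, nx, ny, i0, j1, k1), c111 = at3(a, nx, ny, i1, j1, k1);
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear_sample(NumericVector data, IntegerVector dims,
                                   NumericMatrix idx, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = idx.nrow();
  NumericVector out(n);
  bool ok;
  for (int r = 0; r < n; r++)
    out[r] = trilinear(REAL(data), nx, ny, nz, idx(r, 0), idx(r, 1), idx(r, 2), fill, ok);
  return out;
}

// Resample `moving` onto the target grid (trilinear, physical-space mapping).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector mdata, IntegerVector mdims,
                           NumericVector mspacing, NumericVector morigin,
                           IntegerVector tdims, NumericVector tspacing,
                           NumericVector torigin, double fill) {
  int nx = tdims[0], ny = tdims[1], nz = tdims[2];
  int mx = mdims[0], my = mdims[1], mz = mdims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* m = REAL(mdata);
  bool ok;
  R_xlen_t q = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double px = torigin[0] + i * tspacing[0];
        double py = torigin[1] + j * tspacing[1];
        double pz = torigin[2] + k * tspacing[2];
        out[q++] = trilinear(m, mx, my, mz,
                             (px - morigin[0]) / mspacing[0],
                             (py - morigin[1]) / mspacing[1],
                             (pz - morigin[2]) / mspacing[2], fill, ok);
      }
  return out;
}

// Separable 1D convolution along one axis (0=x, 1=y, 2=z) with edge replication.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector data, IntegerVector dims,
                            NumericVector kernel, int axis) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int kr = (kernel.size() - 1) / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* a = REAL(data);
  double* o = REAL(out);
  int n[3] = {nx, ny, nz};
  int na = n[axis];
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int idx[3] = {i, j, k};
        double s = 0.0;
        for (int t = -kr; t <= kr; t++) {
          int p = idx[axis] + t;
          if (p < 0) p = 0;
          if (p > na - 1) p = na - 1;
          int q[3] = {i, j, k};
          q[axis] = p;
          s += kernel[t + kr] * at3(a, nx, ny, q[0], q[1], q[2]);
        }
        o[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = s;
      }
  return out;
}

// Joint histogram + MI for a rigidly transformed region, all in one pass.
// Reference voxels in the half-open region [lo, hi) (0-based) are paired with
// trilinearly interpolated floating intensities at T(p) = c + R (p - c) + t.
// Intensities are assumed pre-windowed to [0, 255]; bin = floor(v*nbins/256),
// top-clamped. Returns (MI in bits, valid-sample fraction, n_valid).
// [[Rcpp::export]]
NumericVector cpp_mi_region(NumericVector ref, IntegerVector rdims,
                            NumericVector rspacing, NumericVector rorigin,
                            NumericVector flt, IntegerVector fdims,
                            NumericVector fspacing, NumericVector forigin,
                            IntegerVector lo, IntegerVector hi,
                            NumericMatrix rot, NumericVector trans,
                            NumericVector center, int nbins, int stride,
                            int detrend_z, int equalize, int jitter) {
  int rnx = rdims[0], rny = rdims[1], rnz = rdims[2];
  int fnx = fdims[0], fny = fdims[1], fnz = fdims[2];
  std::vector<double> H((size_t)nbins * nbins, 0.0);
  const double* rp = REAL(ref);
  const double* fp = REAL(flt);
  double R00 = rot(0, 0), R01 = rot(0, 1), R02 = rot(0, 2);
  double R10 = rot(1, 0), R11 = rot(1, 1), R12 = rot(1, 2);
  double R20 = rot(2, 0), R21 = rot(2, 1), R22 = rot(2, 2);
  long n_total = 0, n_valid = 0;
  bool ok, rok;
  std::vector<double> rs, fs, zs, ws;
  // Deterministic sub-voxel jitter of the sample positions. Exactly
  // grid-aligned floating samples skip interpolation, which sharpens the
  // floating marginal and inflates estimated MI at aligned transforms (the
  // classic MI interpolation artifact); jittering makes every candidate --
  // including the initialization -- sample off-grid, so the bias cancels
  // out of the comparison. The jitter is a fixed hash of the voxel index:
  // no RNG state, bit-reproducible everywhere.
  auto hash01 = [](unsigned int h) {
    h ^= h >> 16; h *= 0x7feb352dU; h ^= h >> 15; h *= 0x846ca68bU; h ^= h >> 16;
    return (double)h / 4294967296.0;
  };
  for (int k = lo[2]; k < hi[2]; k += stride)
    for (int j = lo[1]; j < hi[1]; j += stride)
      for (int i = lo[0]; i < hi[0]; i += stride) {
        n_total++;
        double xi = (double)i, yj = (double)j, zk = (double)k;
        if (jitter) {
          unsigned int h = (unsigned int)(i * 73856093) ^
                           (unsigned int)(j * 19349663) ^
                           (unsigned int)(k * 83492791);
          xi += hash01(h) - 0.5;
          yj += hash01(h * 2654435761U + 1U) - 0.5;
          zk += hash01(h * 40503U + 2U) - 0.5;
        }
        double rv;
        if (jitter) {
          rv = trilinear(rp, rnx, rny, rnz, xi, yj, zk, 0.0, rok);
          if (!rok) continue;
        } else {
          rv = at3(rp, rnx, rny, i, j, k);
        }
        double px = rorigin[0] + xi * rspacing[0] - center[0];
        double py = rorigin[1] + yj * rspacing[1] - center[1];
        double pz = rorigin[2] + zk * rspacing[2] - center[2];
        double qx = center[0] + R00 * px + R01 * py + R02 * pz + trans[0];
        double qy = center[1] + R10 * px + R11 * py + R12 * pz + trans[1];
        double qz = center[2] + R20 * px + R21 * py + R22 * pz + trans[2];
        double v = trilinear(fp, fnx, fny, fnz,
                             (qx - forigin[0]) / fspacing[0],
                             (qy - forigin[1]) / fspacing[1],
                             (qz - forigin[2]) / fspacing[2], 0.0, ok);
        if (!ok) continue;
        n_valid++;
        rs.push_back(rv);
        fs.push_back(v);
        zs.push_back(rorigin[2] + zk * rspacing[2]);
        ws.push_back(qz);
      }
  // Optional local stationarization: remove from each side the component
  // of its intensity linearly explained by its own axial coordinate inside
  // the region before binning. Cone-beam reconstruction degrades intensity
  // with axial distance from the central plane, which would otherwise
  // couple position to intensity inside every subvolume; a trend-free
  // image (planning CT) fits a near-zero slope and is left unchanged, so
  // the operation is symmetric in the two roles. The slope is capped at a
  // plausible shading gradient (20% of the 8-bit range over a 100 mm
  // axial run) so that genuine anatomical contrast, which produces much
  // steeper apparent trends, is left intact.
  const double slope_cap = 0.2 * 255.0 / 100.0;
  auto fit_slope = [&](const std::vector<double>& vals,
                       const std::vector<double>& zcoord, double& slope,
                       double& zmean) {
    slope = 0.0; zmean = 0.0;
    double sy = 0.0;
    for (long s = 0; s < n_valid; s++) { zmean += zcoord[s]; sy += vals[s]; }
    zmean /= n_valid; sy /= n_valid;
    double sxx = 0.0, sxy = 0.0;
    for (long s = 0; s < n_valid; s++) {
      double dz = zcoord[s] - zmean;
      sxx += dz * dz;
      sxy += dz * (vals[s] - sy);
    }
    if (sxx > 1e-9) slope = sxy / sxx;
    if (slope > slope_cap) slope = slope_cap;
    if (slope < -slope_cap) slope = -slope_cap;
  };
  double slope = 0.0, zmean = 0.0, fslope = 0.0, wmean = 0.0;
  if (detrend_z && n_valid > 2) {
    fit_slope(rs, zs, slope, zmean);
    fit_slope(fs, ws, fslope, wmean);
    for (long s = 0; s < n_valid; s++) {
      rs[s] -= slope * (zs[s] - zmean);
      fs[s] -= fslope * (ws[s] - wmean);
    }
  }
  if (equalize && n_valid > 1) {
    // Rank (equalized) binning: bins are the region's own intensity
    // quantiles. MI is invariant under monotone remaps, so this changes
    // only the estimator, spreading the locally informative band across
    // all bins instead of leaving it quantized into a few.
    std::vector<long> ord(n_valid);
    for (long s = 0; s < n_valid; s++) ord[s] = s;
    std::vector<int> br(n_valid), bf(n_valid);
    std::sort(ord.begin(), ord.end(), [&](long a, long b) {
      return rs[a] < rs[b];
    });
    // Ties (e.g. clamped air) must share a bin, or a constant class would
    // be smeared uniformly across the histogram.
    for (long p = 0; p < n_valid; p++)
      br[ord[p]] = (p > 0 && rs[ord[p]] == rs[ord[p - 1]])
                     ? br[ord[p - 1]] : (int)((double)p * nbins / n_valid);
    std::sort(ord.begin(), ord.end(), [&](long a, long b) {
      return fs[a] < fs[b];
    });
    for (long p = 0; p < n_valid; p++)
      bf[ord[p]] = (p > 0 && fs[ord[p]] == fs[ord[p - 1]])
                     ? bf[ord[p - 1]] : (int)((double)p * nbins / n_valid);
    for (long s = 0; s < n_valid; s++)
      H[br[s] + (size_t)nbins * bf[s]] += 1.0;
  } else {
    for (long s = 0; s < n_valid; s++) {
      int br = (int)std::floor(rs[s] * nbins / 256.0);
      int bf = (int)std::floor(fs[s] * nbins / 256.0);
      if (br < 0) br = 0;
      if (br > nbins - 1) br = nbins - 1;
      if (bf < 0) bf = 0;
      if (bf > nbins - 1) bf = nbins - 1;
      H[br + (size_t)nbins * bf] += 1.0;
    }
  }
  double mi = 0.0;
  if (n_valid > 0) {
    std::vector<double> pr(nbins, 0.0), pc(nbins, 0.0);
    double tot = (double)n_valid;
    for (int b = 0; b < nbins; b++)
      for (int c = 0; c < nbins; c++) {
        pr[b] += H[b + (size_t)nbins * c];
        pc[c] += H[b + (size_t)nbins * c];
      }
    for (int b = 0; b < nbins; b++)
      for (int c = 0; c < nbins; c++) {
        double h = H[b + (size_t)nbins * c];
        if (h > 0.0)
          mi += (h / tot) * std::log2(h * tot / (pr[b] * pc[c]));
      }
  }
  return NumericVector::create(mi,
                               n_total > 0 ? (double)n_valid / n_total : 0.0,
                               (double)n_valid);
}

static inline void quat_to_mat(const double* q, double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

static inline void catmull_rom(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2 * t2 - t);
  w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
  w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

// Dense displacement field from a regular control grid of rigid transforms.
// Controls are given in "displace x" form: y = R x + b, with R as a unit
// quaternion (w,x,y,z). Quaternions are sign-aligned to the containing cell's
// control, blended with separable Catmull-Rom weights (border replication),
// renormalized; b is blended with the same weights. u(x) = R_hat x + b_hat - x.
// [[Rcpp::export]]
NumericVector cpp_interpolate_field(NumericMatrix quats, NumericMatrix bvecs,
                                    IntegerVector gdims, NumericVector gorigin,
                                    NumericVector gstep, IntegerVector rdims,
                                    NumericVector rspacing, NumericVector rorigin) {
  int gx = gdims[0], gy = gdims[1], gz = gdims[2];
  int nx = rdims[0], ny = rdims[1], nz = rdims[2];
  NumericVector out((R_xlen_t)nx * ny * nz * 3);
  double* o = REAL(out);
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        double px = rorigin[0] + i * rspacing[0];
        double py = rorigin[1] + j * rspacing[1];
        double pz = rorigin[2] + k * rspacing[2];
        double gxc = (px - gorigin[0]) / gstep[0];
        double gyc = (py - gorigin[1]) / gstep[1];
        double gzc = (pz - gorigin[2]) / gstep[2];
        int i0 = (int)std::floor(gxc), j0 = (int)std::floor(gyc), k0 = (int)std::floor(gzc);
        double wx[4], wy[4], wz[4];
        catmull_rom(gxc - i0, wx);
        catmull_rom(gyc - j0, wy);
        catmull_rom(gzc - k0, wz);
        // Sign-reference: control of the containing (clamped) cell.
        int ci = std::min(std::max(i0, 0), gx - 1);
        int cj = std::min(std::max(j0, 0), gy - 1);
        int ck = std::min(std::max(k0, 0), gz - 1);
        int cref = ci + gx * (cj + gy * ck);
        double qr[4] = {quats(cref, 0), quats(cref, 1), quats(cref, 2), quats(cref, 3)};
        double qa[4] = {0, 0, 0, 0}, ba[3] = {0, 0, 0};
        for (int dk = -1; dk <= 2; dk++)
          for (int dj = -1; dj <= 2; dj++)
            for (int di = -1; di <= 2; di++) {
              int ii = std::min(std::max(i0 + di, 0), gx - 1);
              int jj = std::min(std::max(j0 + dj, 0), gy - 1);
              int kk = std::min(std::max(k0 + dk, 0), gz - 1);
              int c = ii + gx * (jj + gy * kk);
              double w = wx[di + 1] * wy[dj + 1] * wz[dk + 1];
              double dot = qr[0] * quats(c, 0) + qr[1] * quats(c, 1) +
                           qr[2] * quats(c, 2) + qr[3] * quats(c, 3);
              double s = dot < 0.0 ? -w : w;
              qa[0] += s * quats(c, 0);
              qa[1] += s * quats(c, 1);
              qa[2] += s * quats(c, 2);
              qa[3] += s * quats(c, 3);
              ba[0] += w * bvecs(c, 0);
              ba[1] += w * bvecs(c, 1);
              ba[2] += w * bvecs(c, 2);
            }
        double nrm = std::sqrt(qa[0] * qa[0] + qa[1] * qa[1] + qa[2] * qa[2] + qa[3] * qa[3]);
        if (nrm < 1e-12) {
          qa[0] = qr[0]; qa[1] = qr[1]; qa[2] = qr[2]; qa[3] = qr[3];
          nrm = 1.0;
        }
        for (int s = 0; s < 4; s++) qa[s] /= nrm;
        double R[9];
        quat_to_mat(qa, R);
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        o[v]            = R[0] * px + R[1] * py + R[2] * pz + ba[0] - px;
        o[v + nvox]     = R[3] * px + R[4] * py + R[5] * pz + ba[1] - py;
        o[v + 2 * nvox] = R[6] * px + R[7] * py + R[8] * pz + ba[2] - pz;
      }
  return out;
}

// Backward warp: out(x) = flt(x + u(x)), trilinear, fill outside.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector flt, IntegerVector fdims,
                       NumericVector fspacing, NumericVector forigin,
                       NumericVector u, IntegerVector rdims,
                       NumericVector rspacing, NumericVector rorigin,
                       double fill) {
  int nx = rdims[0], ny = rdims[1], nz = rdims[2];
  int fnx = fdims[0], fny = fdims[1], fnz = fdims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double* up = REAL(u);
  const double* fp = REAL(flt);
  bool ok;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double qx = rorigin[0] + i * rspacing[0] + up[v];
        double qy = rorigin[1] + j * rspacing[1] + up[v + nvox];
        double qz = rorigin[2] + k * rspacing[2] + up[v + 2 * nvox];
        out[v] = trilinear(fp, fnx, fny, fnz,
                           (qx - forigin[0]) / fspacing[0],
                           (qy - forigin[1]) / fspacing[1],
                           (qz - forigin[2]) / fspacing[2], fill, ok);
      }
  return out;
}

// Minimum over interior voxels of det(I + grad(u)), central differences in mm.
// [[Rcpp::export]]
double cpp_jacobian_min(NumericVector u, IntegerVector rdims, NumericVector rspacing) {
  int nx = rdims[0], ny = rdims[1], nz = rdims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* up = REAL(u);
  double jmin = R_PosInf;
  for (int k = 1; k < nz - 1; k++)
    for (int j = 1; j < ny - 1; j++)
      for (int i = 1; i < nx - 1; i++) {
        double J[9];
        for (int c = 0; c < 3; c++) {
          const double* uc = up + c * nvox;
          R_xlen_t vx1 = (i + 1) + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          R_xlen_t vx0 = (i - 1) + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          R_xlen_t vy1 = i + (R_xlen_t)nx * ((j + 1) + (R_xlen_t)ny * k);
          R_xlen_t vy0 = i + (R_xlen_t)nx * ((j - 1) + (R_xlen_t)ny * k);
          R_xlen_t vz1 = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * (k + 1));
          R_xlen_t vz0 = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * (k - 1));
          J[3 * c]     = (uc[vx1] - uc[vx0]) / (2.0 * rspacing[0]);
          J[3 * c + 1] = (uc[vy1] - uc[vy0]) / (2.0 * rspacing[1]);
          J[3 * c + 2] = (uc[vz1] - uc[vz0]) / (2.0 * rspacing[2]);
        }
        double det = (1 + J[0]) * ((1 + J[4]) * (1 + J[8]) - J[5] * J[7]) -
                     J[1] * (J[3] * (1 + J[8]) - J[5] * J[6]) +
                     J[2] * (J[3] * J[7] - (1 + J[4]) * J[6]);
        if (det < jmin) jmin = det;
      }
  return jmin == R_PosInf ? 1.0 : jmin;
}
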