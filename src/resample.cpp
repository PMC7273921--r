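#include <Rcpp.h>
using namespace Rcpp;

// Trilinear resampling of a 3-D volume.
//
// `src` is the source array (column-major, dims `srcDim`); `M` is a 4x4
// matrix mapping 0-based output voxel indices (homogeneous) to continuous
// 0-based source voxel indices; `outDim` gives the output grid.
//
// Voxels mapped outside the source support get value 0 and support 0;
// support marks voxels whose full trilinear neighbourhood lies inside.
// [[Rcpp::export]]
List resampleTrilinearC(NumericVector src, IntegerVector srcDim,
                        NumericMatrix M, IntegerVector outDim) {
  const int sx = srcDim[0], sy = srcDim[1], sz = srcDim[2];
  const int ox = outDim[0], oy = outDim[1], oz = outDim[2];
  const R_xlen_t n = (R_xlen_t)ox * oy * oz;
  NumericVector out(n);
  IntegerVector support(n);

  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);

  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      // accumulate the (i-independent) part once per row
      const double bx = m01 * j + m02 * k + m03;
      const double by = m11 * j + m12 * k + m13;
      const double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        const double x = m00 * i + bx;
        const double y = m10 * i + by;
        const double z = m20 * i + bz;
        if (x < 0 || y < 0 || z < 0 ||
            x > sx - 1 || y > sy - 1 || z > sz - 1) {
          out[idx] = 0.0;
          support[idx] = 0;
          continue;
        }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
        if (x0 == sx - 1) x0--;  // clamp so x1 stays inside when exactly on the far face
        if (y0 == sy - 1) y0--;
        if (z0 == sz - 1) z0--;
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        const R_xlen_t base = (R_xlen_t)x0 + (R_xlen_t)sx * (y0 + (R_xlen_t)sy * z0);
        const R_xlen_t dx = 1, dy = sx, dz = (R_xlen_t)sx * sy;
        const double c000 = src[base],           c100 = src[base + dx];
        const double c010 = src[base + dy],      c110 = src[base + dx + dy];
        const double c001 = src[base + dz],      c101 = src[base + dx + dz];
        const double c011 = src[base + dy + dz], c111 = src[base + dx + dy + dz];
        const double c00 = c000 + fx * (c100 - c000);
        const double c10 = c010 + fx * (c110 - c010);
        const double c01 = c001 + fx * (c101 - c001);
        const double c11 = c011 + fx * (c111 - c011);
        const double c0 = c00 + fy * (c10 - c00);
        const double c1 = c01 + fy * (c11 - c01);
        out[idx] = c0 + fz * (c1 - c0);
        support[idx] = 1;
      }
    }
  }
  return List::create(_["values"] = out, _["support"] = support);
}

// Nearest-neighbour variant for label volumes (atlases, masks).
// [[Rcpp::export]]
List resampleNearestC(NumericVector src, IntegerVector srcDim,
                      NumericMatrix M, IntegerVector outDim) {
  const int sx = srcDim[0], sy = srcDim[1], sz = srcDim[2];
  const int ox = outDim[0], oy = outDim[1], oz = outDim[2];
  const R_xlen_t n = (R_xlen_t)ox * oy * oz;
  NumericVector out(n);
  IntegerVector support(n);

  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      const double bx = M(0,1) * j + M(0,2) * k + M(0,3);
      const double by = M(1,1) * j + M(1,2) * k + M(1,3);
      const double bz = M(2,1) * j + M(2,2) * k + M(2,3);
      for (int i = 0; i < ox; ++i, ++idx) {
        const long xi = (long)std::lround(M(0,0) * i + bx);
        const long yi = (long)std::lround(M(1,0) * i + by);
        const long zi = (long)std::lround(M(2,0) * i + bz);
        if (xi < 0 || yi < 0 || zi < 0 || xi >= sx || yi >= sy || zi >= sz) {
          out[idx] = 0.0;
          support[idx] = 0;
        } else {
          out[idx] = src[xi + (R_xlen_t)sx * (yi + (R_xlen_t)sy * zi)];
          support[idx] = 1;
        }
      }
    }
  }
  return List::create(_["values"] = out, _["support"] = support);
}

// Fused rigid-MI evaluation used inside registration: for each within-mask
// fixed voxel (0-based indices in `ijk`, one row per voxel, paired with
// `fixedVals`), map through M into the moving volume, sample trilinearly,
// and accumulate the joint histogram of the supported pairs. Bins span the
// [min, max] range of each sample. Returns MI in nats and the support count.
// [[Rcpp::export]]
List miRigidC(NumericVector fixedVals, NumericMatrix ijk, NumericMatrix M,
              NumericVector mov, IntegerVector movDim, int nBins) {
  const int sx = movDim[0], sy = movDim[1], sz = movDim[2];
  const R_xlen_t n = ijk.nrow();
  std::vector<double> fv; fv.reserve(n);
  std::vector<double> mv; mv.reserve(n);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);

  for (R_xlen_t r = 0; r < n; ++r) {
    const double i = ijk(r, 0), j = ijk(r, 1), k = ijk(r, 2);
    const double x = m00 * i + m01 * j + m02 * k + m03;
    const double y = m10 * i + m11 * j + m12 * k + m13;
    const double z = m20 * i + m21 * j + m22 * k + m23;
    if (x < 0 || y < 0 || z < 0 || x > sx - 1 || y > sy - 1 || z > sz - 1)
      continue;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == sx - 1) x0--;
    if (y0 == sy - 1) y0--;
    if (z0 == sz - 1) z0--;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const R_xlen_t base = (R_xlen_t)x0 + (R_xlen_t)sx * (y0 + (R_xlen_t)sy * z0);
    const R_xlen_t dx = 1, dy = sx, dz = (R_xlen_t)sx * sy;
    const double c00 = mov[base] + fx * (mov[base + dx] - mov[base]);
    const double c10 = mov[base + dy] + fx * (mov[base + dx + dy] - mov[base + dy]);
    const double c01 = mov[base + dz] + fx * (mov[base + dx + dz] - mov[base + dz]);
    const double c11 = mov[base + dy + dz] + fx * (mov[base + dx + dy + dz] - mov[base + dy + dz]);
    const double c0 = c00 + fy * (c10 - c00);
    const double c1 = c01 + fy * (c11 - c01);
    fv.push_back(fixedVals[r]);
    mv.push_back(c0 + fz * (c1 - c0));
  }

  const R_xlen_t ns = (R_xlen_t)fv.size();
  if (ns == 0)
    return List::create(_["mi"] = 0.0, _["n"] = 0, _["constant"] = false);
  double fmin = fv[0], fmax = fv[0], mmin = mv[0], mmax = mv[0];
  for (R_xlen_t r = 1; r < ns; ++r) {
    fmin = std::min(fmin, fv[r]); fmax = std::max(fmax, fv[r]);
    mmin = std::min(mmin, mv[r]); mmax = std::max(mmax, mv[r]);
  }
  if (fmin == fmax || mmin == mmax)
    return List::create(_["mi"] = 0.0, _["n"] = (double)ns, _["constant"] = true);

  std::vector<int> joint(nBins * nBins, 0);
  const double fw = nBins / (fmax - fmin), mw = nBins / (mmax - mmin);
  for (R_xlen_t r = 0; r < ns; ++r) {
    int bi = (int)((fv[r] - fmin) * fw);
    int bj = (int)((mv[r] - mmin) * mw);
    if (bi >= nBins) bi = nBins - 1;
    if (bj >= nBins) bj = nBins - 1;
    joint[bj * nBins + bi]++;
  }
  std::vector<double> pa(nBins, 0.0), pb(nBins, 0.0);
  for (int bj = 0; bj < nBins; ++bj)
    for (int bi = 0; bi < nBins; ++bi) {
      const double p = (double)joint[bj * nBins + bi] / ns;
      pa[bi] += p; pb[bj] += p;
    }
  double mi = 0.0;
  for (int bj = 0; bj < nBins; ++bj)
    for (int bi = 0; bi < nBins; ++bi) {
      const int c = joint[bj * nBins + bi];
      if (c > 0) {
        const double p = (double)c / ns;
        mi += p * std::log(p / (pa[bi] * pb[bj]));
      }
    }
  return List::create(_["mi"] = mi, _["n"] = (double)ns, _["constant"] = false);
}
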