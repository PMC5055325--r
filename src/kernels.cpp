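#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Convolve every column of `mat` with `kernel` (odd length, centre tap at
// (len-1)/2), reflecting at the borders.  Columns are the axial (z) direction,
// so the inner loop walks contiguous memory.
// [[Rcpp::export(name = ".conv_cols_cpp")]]
NumericMatrix conv_cols_cpp(const NumericMatrix& mat, const NumericVector& kernel) {
  const int nz = mat.nrow(), nx = mat.ncol(), nk = kernel.size();
  const int h = (nk - 1) / 2;
  NumericMatrix out(nz, nx);
  const int lo = std::min(h, nz), hi = std::max(nz - h, lo);
  for (int x = 0; x < nx; ++x) {
    const double* col = &mat(0, x);
    double* o = &out(0, x);
    for (int z = lo; z < hi; ++z) {          // interior: branch-free
      double acc = 0.0;
      const double* c = col + z - h;
      for (int j = 0; j < nk; ++j) acc += kernel[j] * c[j];
      o[z] = acc;
    }
    auto border = [&](int z) {               // borders: reflect
      double acc = 0.0;
      for (int j = 0; j < nk; ++j) {
        int zz = z + j - h;
        if (zz < 0) zz = -zz - 1;            // reflect (half-sample symmetry)
        else if (zz >= nz) zz = 2 * nz - zz - 1;
        acc += kernel[j] * col[zz];
      }
      o[z] = acc;
    };
    for (int z = 0; z < lo; ++z) border(z);
    for (int z = hi; z < nz; ++z) border(z);
  }
  return out;
}

// Render one B-scan: piecewise-constant compartments delimited by the nine
// boundary depths (px, half-open), box-averaged over each pixel [z, z+1).
// intensities has 10 entries: above boundary 1, the eight interior bands,
// below boundary 9.
// [[Rcpp::export(name = ".render_bscan_cpp")]]
NumericMatrix render_bscan_cpp(const NumericMatrix& boundaries_px,  // 9 x nx
                               const NumericVector& intensities,    // 10
                               int nz) {
  const int nb = boundaries_px.nrow(), nx = boundaries_px.ncol();
  NumericMatrix out(nz, nx);
  for (int x = 0; x < nx; ++x) {
    double* o = &out(0, x);
    for (int z = 0; z < nz; ++z) o[z] = intensities[0];
    for (int k = 0; k < nb; ++k) {
      const double p = boundaries_px(k, x);
      const double dI = intensities[k + 1] - intensities[k];
      if (dI == 0.0) continue;
      // pixel z gains dI * coverage of [z, z+1) below p
      int z0 = (int)std::floor(p);
      if (z0 >= nz) continue;
      for (int z = (z0 < 0 ? 0 : z0); z < nz; ++z) {
        double cov = (double)z + 1.0 - p;
        if (cov > 1.0) cov = 1.0;
        if (cov > 0.0) o[z] += dI * cov;
      }
    }
  }
  return out;
}

// Exact maximisation of sum_x E(z_x, x) - lambda * sum |z_x - z_{x+1}| over
// per-column bands [zmin[x], zmax[x]] (0-based, inclusive) by dynamic
// programming; the L1 transition is applied with a two-pass (forward/backward)
// max-transform so each column costs O(nz).  Ties break toward the shallower
// (smaller z) node.  Returns 0-based node indices, one per column.
// [[Rcpp::export(name = ".dp_trace_cpp")]]
IntegerVector dp_trace_cpp(const NumericMatrix& E,
                           const IntegerVector& zmin,
                           const IntegerVector& zmax,
                           double lambda) {
  const int nzfull = E.nrow(), nx = E.ncol();
  // the DP only ever visits rows inside some column's band
  int rlo = nzfull, rhi = -1;
  for (int x = 0; x < nx; ++x) {
    rlo = std::min(rlo, (int)zmin[x]);
    rhi = std::max(rhi, (int)zmax[x]);
  }
  rlo = std::max(rlo, 0); rhi = std::min(rhi, nzfull - 1);
  const int nz = rhi - rlo + 1;
  const double NEG = -1e300;
  std::vector<double> D(nz), M(nz);
  std::vector<int> srcv(nz);
  std::vector<int> parent((size_t)nz * nx);
  for (int z = 0; z < nz; ++z)
    D[z] = (z + rlo >= zmin[0] && z + rlo <= zmax[0]) ? E(z + rlo, 0) : NEG;
  for (int x = 1; x < nx; ++x) {
    // forward pass: best over z' <= z; strict '>' keeps the smaller source on ties
    M[0] = D[0]; srcv[0] = 0;
    for (int z = 1; z < nz; ++z) {
      const double prop = M[z - 1] - lambda;
      if (D[z] > prop) { M[z] = D[z]; srcv[z] = z; }
      else             { M[z] = prop; srcv[z] = srcv[z - 1]; }
    }
    // backward pass: best over z' >= z, merged on strict improvement only so
    // that equal-valued sources resolve to the smaller z'
    double mb = D[nz - 1]; int sb = nz - 1;
    for (int z = nz - 1; z >= 0; --z) {
      if (z < nz - 1) {
        mb -= lambda;
        if (D[z] >= mb) { mb = D[z]; sb = z; }
      }
      if (mb > M[z]) { M[z] = mb; srcv[z] = sb; }
    }
    int* par = &parent[(size_t)nz * x];
    for (int z = 0; z < nz; ++z) {
      par[z] = srcv[z];
      D[z] = (z + rlo >= zmin[x] && z + rlo <= zmax[x]) ? E(z + rlo, x) + M[z] : NEG;
    }
  }
  int zbest = 0; double vbest = -HUGE_VAL;
  for (int z = 0; z < nz; ++z)
    if (D[z] > vbest) { vbest = D[z]; zbest = z; }
  IntegerVector path(nx);
  path[nx - 1] = zbest;
  for (int x = nx - 1; x >= 1; --x)
    path[x - 1] = parent[(size_t)nz * x + path[x]];
  for (int x = 0; x < nx; ++x) path[x] += rlo;
  return path;
}
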