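#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Patch features for scribble-seeded segmentation.
//
// Each pixel is described by its 9x9 in-plane region of interest (ROI):
//   2 intensity statistics (mean, sample sd),
//   4 GLCM Haralick statistics (contrast, correlation, energy, homogeneity)
//     averaged over the four symmetric distance-1 offsets, after quantizing
//     the ROI to 8 gray levels between its min and max,
//   7 Haar statistics: mean absolute detail coefficient of the LH/HL/HH
//     subbands of a 2-level orthonormal 2D Haar transform of the leading
//     8x8 block of the ROI, plus the mean level-2 approximation coefficient.
// Out-of-image ROI pixels are filled by whole-sample reflection.

static const int ROI = 9;     // ROI side
static const int NLEV = 8;    // GLCM gray levels

static inline int reflect_index(int i, int n) {
  // whole-sample reflection: -1 -> 1, n -> n-2 (no border duplication)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static void gather_roi(const NumericMatrix &img, int r0, int c0, double *roi) {
  int nr = img.nrow(), nc = img.ncol();
  int h = ROI / 2;
  for (int dc = -h; dc <= h; ++dc) {
    int c = reflect_index(c0 + dc, nc);
    for (int dr = -h; dr <= h; ++dr) {
      int r = reflect_index(r0 + dr, nr);
      roi[(dc + h) * ROI + (dr + h)] = img(r, c);
    }
  }
}

static void intensity_stats(const double *roi, int n, double *out) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += roi[i];
  double mean = s / n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) { double d = roi[i] - mean; ss += d * d; }
  out[0] = mean;
  out[1] = (n > 1) ? std::sqrt(ss / (n - 1)) : 0.0;
}

// GLCM over a square patch of side m (column-major), 4 symmetric offsets.
static void glcm_stats_impl(const double *roi, int m, double *out) {
  double lo = roi[0], hi = roi[0];
  int n = m * m;
  for (int i = 1; i < n; ++i) {
    if (roi[i] < lo) lo = roi[i];
    if (roi[i] > hi) hi = roi[i];
  }
  std::vector<int> q(n);
  if (hi > lo) {
    double w = (hi - lo);
    for (int i = 0; i < n; ++i) {
      int l = (int)std::floor((roi[i] - lo) / w * NLEV);
      if (l > NLEV - 1) l = NLEV - 1;
      if (l < 0) l = 0;
      q[i] = l;
    }
  } // constant patch: all level 0

  // offsets (dr, dc): 0, 45, 90, 135 degrees in image coordinates
  const int drs[4] = {0, -1, -1, -1};
  const int dcs[4] = {1,  1,  0, -1};
  double contrast = 0, corr = 0, energy = 0, homog = 0;

  for (int o = 0; o < 4; ++o) {
    double P[NLEV][NLEV] = {{0}};
    double tot = 0;
    for (int c = 0; c < m; ++c) {
      for (int r = 0; r < m; ++r) {
        int r2 = r + drs[o], c2 = c + dcs[o];
        if (r2 < 0 || r2 >= m || c2 < 0 || c2 >= m) continue;
        int a = q[c * m + r], b = q[c2 * m + r2];
        P[a][b] += 1.0;  // symmetric GLCM: count both directions
        P[b][a] += 1.0;
        tot += 2.0;
      }
    }
    if (tot <= 0) continue;
    double con = 0, en = 0, hom = 0;
    double mu_r = 0, mu_c = 0;
    for (int a = 0; a < NLEV; ++a)
      for (int b = 0; b < NLEV; ++b) {
        double p = P[a][b] / tot;
        P[a][b] = p;
        con += p * (a - b) * (a - b);
        en  += p * p;
        hom += p / (1.0 + (a - b) * (a - b));
        mu_r += a * p;
        mu_c += b * p;
      }
    double var_r = 0, var_c = 0, cov = 0;
    for (int a = 0; a < NLEV; ++a)
      for (int b = 0; b < NLEV; ++b) {
        double p = P[a][b];
        var_r += (a - mu_r) * (a - mu_r) * p;
        var_c += (b - mu_c) * (b - mu_c) * p;
        cov   += (a - mu_r) * (b - mu_c) * p;
      }
    double cr = (var_r > 1e-14 && var_c > 1e-14)
      ? cov / std::sqrt(var_r * var_c) : 1.0;  // constant patch: perfectly correlated
    contrast += con; corr += cr; energy += en; homog += hom;
  }
  out[0] = contrast / 4.0;
  out[1] = corr / 4.0;
  out[2] = energy / 4.0;
  out[3] = homog / 4.0;
}

// one orthonormal 2D Haar analysis level in place:
// in: side x side (column-major, stride = side), out subbands each half x half
static void haar_level(const double *in, int side, int stride,
                       double *ll, double *lh, double *hl, double *hh) {
  int h = side / 2;
  for (int c = 0; c < h; ++c) {
    for (int r = 0; r < h; ++r) {
      double a = in[(2 * c) * stride + 2 * r];       // top-left
      double b = in[(2 * c + 1) * stride + 2 * r];   // top-right
      double cc = in[(2 * c) * stride + 2 * r + 1];  // bottom-left
      double d = in[(2 * c + 1) * stride + 2 * r + 1];
      ll[c * h + r] = (a + b + cc + d) / 2.0;
      hl[c * h + r] = (a - b + cc - d) / 2.0;  // difference across columns
      lh[c * h + r] = (a + b - cc - d) / 2.0;  // difference across rows
      hh[c * h + r] = (a - b - cc + d) / 2.0;
    }
  }
}

static double mean_abs(const double *x, int n) {
  double s = 0;
  for (int i = 0; i < n; ++i) s += std::fabs(x[i]);
  return s / n;
}

// 2-level Haar on the leading 8x8 block of a patch with side m >= 8
static void haar_stats_impl(const double *roi, int m, double *out) {
  double blk[64];
  for (int c = 0; c < 8; ++c)
    for (int r = 0; r < 8; ++r)
      blk[c * 8 + r] = roi[c * m + r];
  double ll1[16], lh1[16], hl1[16], hh1[16];
  haar_level(blk, 8, 8, ll1, lh1, hl1, hh1);
  double ll2[4], lh2[4], hl2[4], hh2[4];
  haar_level(ll1, 4, 4, ll2, lh2, hl2, hh2);
  out[0] = mean_abs(lh1, 16);
  out[1] = mean_abs(hl1, 16);
  out[2] = mean_abs(hh1, 16);
  out[3] = mean_abs(lh2, 4);
  out[4] = mean_abs(hl2, 4);
  out[5] = mean_abs(hh2, 4);
  double s = 0;
  for (int i = 0; i < 4; ++i) s += ll2[i];
  out[6] = s / 4.0;  // = 4 * patch mean for a constant patch
}

// [[Rcpp::export]]
NumericMatrix extract_features_cpp(NumericMatrix img, IntegerMatrix pixels,
                                   bool low_level) {
  int n = pixels.nrow();
  int nf = low_level ? 2 : 13;
  NumericMatrix out(n, nf);
  int nr = img.nrow(), nc = img.ncol();
  double roi[ROI * ROI];
  double buf[7];
  for (int i = 0; i < n; ++i) {
    int r = pixels(i, 0) - 1, c = pixels(i, 1) - 1;  // 1-based in, 0-based here
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("pixel (%d, %d) outside the slice", pixels(i, 0), pixels(i, 1));
    gather_roi(img, r, c, roi);
    intensity_stats(roi, ROI * ROI, buf);
    out(i, 0) = buf[0];
    out(i, 1) = buf[1];
    if (!low_level) {
      glcm_stats_impl(roi, ROI, buf);
      for (int k = 0; k < 4; ++k) out(i, 2 + k) = buf[k];
      haar_stats_impl(roi, ROI, buf);
      for (int k = 0; k < 7; ++k) out(i, 6 + k) = buf[k];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector glcm_stats_cpp(NumericMatrix roi) {
  if (roi.nrow() != roi.ncol()) stop("ROI must be square");
  double out[4];
  glcm_stats_impl(&roi(0, 0), roi.nrow(), out);
  return NumericVector::create(out[0], out[1], out[2], out[3]);
}

// [[Rcpp::export]]
NumericVector haar_stats_cpp(NumericMatrix roi) {
  if (roi.nrow() < 8 || roi.ncol() < 8) stop("ROI must be at least 8x8");
  double out[7];
  // copy column-major with the matrix's own stride
  std::vector<double> tmp(roi.nrow() * roi.ncol());
  for (int c = 0; c < roi.ncol(); ++c)
    for (int r = 0; r < roi.nrow(); ++r)
      tmp[c * roi.nrow() + r] = roi(r, c);
  haar_stats_impl(tmp.data(), roi.nrow(), out);
  return NumericVector::create(out[0], out[1], out[2], out[3], out[4],
                               out[5], out[6]);
}
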