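// Fused per-pixel kernels for the whole-slide pipeline. Each replaces a
// chain of vectorised R operations that would otherwise allocate several
// full-frame temporaries per call.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bright-field Lambert-Beer render: per channel I = 255 * 10^-(a_h*h + a_d*d
// + noise), noise drawn from R's RNG so renders stay seed-reproducible.
// [[Rcpp::export]]
NumericVector render_channels_cpp(NumericVector a_h, NumericVector a_d,
                                  NumericVector hvec, NumericVector dvec,
                                  double noise_sd) {
  const R_xlen_t n = a_h.size();
  NumericVector out(n * 3);
  const double ln10 = std::log(10.0);
  for (int ch = 0; ch < 3; ++ch) {
    const double h = hvec[ch], d = dvec[ch];
    double* o = out.begin() + ch * n;
    if (noise_sd > 0) {
      for (R_xlen_t i = 0; i < n; ++i) {
        double od = a_h[i] * h + a_d[i] * d + R::rnorm(0.0, noise_sd);
        if (od < 0) od = 0;
        o[i] = 255.0 * std::exp(-ln10 * od);
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i)
        o[i] = 255.0 * std::exp(-ln10 * (a_h[i] * h + a_d[i] * d));
    }
  }
  return out;
}

// Edge-aware mean filter with a (2r+1)^2 window via an integral image.
// [[Rcpp::export]]
NumericMatrix box_blur_cpp(NumericMatrix m, int r) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<double> ii((nr + 1) * (size_t)(nc + 1), 0.0);
  const int w = nr + 1;
  for (int c = 0; c < nc; ++c)
    for (int rr = 0; rr < nr; ++rr)
      ii[(c + 1) * (size_t)w + rr + 1] =
        ii[(c + 1) * (size_t)w + rr] + m(rr, c);
  for (int c = 1; c <= nc; ++c)
    for (int rr = 0; rr <= nr; ++rr)
      ii[c * (size_t)w + rr] += ii[(c - 1) * (size_t)w + rr];
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int x0 = std::max(0, c - r), x1 = std::min(nc - 1, c + r);
    for (int rr = 0; rr < nr; ++rr) {
      int y0 = std::max(0, rr - r), y1 = std::min(nr - 1, rr + r);
      double s = ii[(x1 + 1) * (size_t)w + y1 + 1] -
                 ii[x0 * (size_t)w + y1 + 1] -
                 ii[(x1 + 1) * (size_t)w + y0] + ii[x0 * (size_t)w + y0];
      out(rr, c) = s / ((y1 - y0 + 1) * (double)(x1 - x0 + 1));
    }
  }
  return out;
}

// Rec. 601 luma of an nr x nc x 3 array (stored as a vector).
// [[Rcpp::export]]
NumericMatrix luma_cpp(NumericVector img, int nr, int nc) {
  NumericMatrix out(nr, nc);
  const R_xlen_t n = (R_xlen_t)nr * nc;
  const double* r = img.begin();
  const double* g = r + n;
  const double* b = g + n;
  double* o = out.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    o[i] = 0.299 * r[i] + 0.587 * g[i] + 0.114 * b[i];
  return out;
}

// Integer translation of a matrix with constant fill.
// [[Rcpp::export]]
NumericMatrix translate_matrix_cpp(NumericMatrix m, int dy, int dx,
                                   double fill) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), fill);
  for (int c = 0; c < nc; ++c) {
    int sc = c - dx;
    if (sc < 0 || sc >= nc) continue;
    for (int rr = 0; rr < nr; ++rr) {
      int sr = rr - dy;
      if (sr < 0 || sr >= nr) continue;
      out(rr, c) = m(sr, sc);
    }
  }
  return out;
}

// Per-patch sums of `val` and counts of `mask` over a patch tessellation.
// [[Rcpp::export]]
List patch_sums_cpp(NumericMatrix val, LogicalMatrix mask, int ps) {
  const int nr = val.nrow(), nc = val.ncol();
  const int pr = (nr + ps - 1) / ps, pc = (nc + ps - 1) / ps;
  NumericMatrix sum(pr, pc);
  IntegerMatrix cnt(pr, pc);
  for (int c = 0; c < nc; ++c) {
    const int pcI = c / ps;
    for (int rr = 0; rr < nr; ++rr) {
      if (mask(rr, c)) {
        sum(rr / ps, pcI) += val(rr, c);
        cnt(rr / ps, pcI) += 1;
      }
    }
  }
  return List::create(_["sum"] = sum, _["count"] = cnt);
}

// DAB optical density in one pass: channel OD = -log10(max(I,1)/255)
// projected onto the least-squares DAB row of the stain inverse, clipped to
// [0, ceiling].
// [[Rcpp::export]]
NumericMatrix dab_od_cpp(NumericVector img, int nr, int nc,
                         NumericVector proj, double ceiling) {
  NumericMatrix out(nr, nc);
  const R_xlen_t n = (R_xlen_t)nr * nc;
  const double* r = img.begin();
  const double* g = r + n;
  const double* b = g + n;
  const double inv255 = 1.0 / 255.0, ln10 = std::log(10.0);
  double* o = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double odr = -std::log(std::max(r[i], 1.0) * inv255) / ln10;
    double odg = -std::log(std::max(g[i], 1.0) * inv255) / ln10;
    double odb = -std::log(std::max(b[i], 1.0) * inv255) / ln10;
    double v = proj[0] * odr + proj[1] * odg + proj[2] * odb;
    if (v < 0) v = 0;
    if (v > ceiling) v = ceiling;
    o[i] = v;
  }
  return out;
}

// Zero-mean correlation of two masks at the given candidate shifts,
// evaluated over the overlap region only; returns one value per candidate.
// [[Rcpp::export]]
NumericVector shift_corr_cpp(LogicalMatrix a, LogicalMatrix b,
                             IntegerVector dys, IntegerVector dxs,
                             double mean_a, double mean_b) {
  const int nr = a.nrow(), nc = a.ncol();
  const int k = dys.size();
  NumericVector out(k);
  // C(s) = sum_x (a(x) - ma) (b(x + s) - mb), matching the FFT convention
  for (int s = 0; s < k; ++s) {
    const int dy = dys[s], dx = dxs[s];
    const int r0 = std::max(0, -dy), r1 = std::min(nr, nr - dy);
    const int c0 = std::max(0, -dx), c1 = std::min(nc, nc - dx);
    double acc = 0.0;
    for (int c = c0; c < c1; ++c)
      for (int rr = r0; rr < r1; ++rr)
        acc += ((double)a(rr, c) - mean_a) *
               ((double)b(rr + dy, c + dx) - mean_b);
    out[s] = acc;
  }
  return out;
}

// Multiplicative per-tile shading applied at canvas level (valid when tiles
// do not overlap): gain at canvas (r, c) is g(r mod th, c mod tw); the
// result is clamped to 0..255 and rounded to 8-bit in the same pass.
// [[Rcpp::export]]
NumericVector vignette_round_cpp(NumericVector img, int nr, int nc,
                                 NumericMatrix gain) {
  const int th = gain.nrow(), tw = gain.ncol();
  NumericVector out(img.size());
  const R_xlen_t n = (R_xlen_t)nr * nc;
  for (int ch = 0; ch < 3; ++ch) {
    const double* p = img.begin() + ch * n;
    double* o = out.begin() + ch * n;
    for (int c = 0; c < nc; ++c) {
      const int gc = c % tw;
      for (int rr = 0; rr < nr; ++rr) {
        double v = p[(R_xlen_t)c * nr + rr] * gain(rr % th, gc);
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        o[(R_xlen_t)c * nr + rr] = std::round(v);
      }
    }
  }
  return out;
}

// 2x block-mean downsample of a logical mask into a numeric matrix.
// [[Rcpp::export]]
NumericMatrix downsample2_cpp(LogicalMatrix m) {
  const int nr = m.nrow() / 2, nc = m.ncol() / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int rr = 0; rr < nr; ++rr)
      out(rr, c) = 0.25 * ((double)m(2 * rr, 2 * c) + m(2 * rr + 1, 2 * c) +
                           m(2 * rr, 2 * c + 1) + m(2 * rr + 1, 2 * c + 1));
  return out;
}
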