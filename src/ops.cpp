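// Low-level raster kernels: binary morphology, connected-component labelling,
// bilinear resampling/warping, and the convolution/pooling primitives used by
// the lane classifier. All images are column-major R arrays; binary masks are
// integer matrices in {0,1}.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Binary morphology with a k x k square structuring element.
// Erosion uses the fit-inside rule: pixels outside the image count as
// background, so a full-foreground image erodes to a frame of background.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_binary_erode")]]
IntegerMatrix cpp_binary_erode(const IntegerMatrix& mask, int k) {
  const int h = mask.nrow(), w = mask.ncol(), r = k / 2;
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int keep = 1;
      for (int dj = -r; dj <= r && keep; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= w) { keep = 0; break; }
        for (int di = -r; di <= r; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= h || mask(ii, jj) == 0) { keep = 0; break; }
        }
      }
      out(i, j) = keep;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_binary_dilate")]]
IntegerMatrix cpp_binary_dilate(const IntegerMatrix& mask, int k) {
  const int h = mask.nrow(), w = mask.ncol(), r = k / 2;
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int hit = 0;
      for (int dj = -r; dj <= r && !hit; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= w) continue;
        for (int di = -r; di <= r; ++di) {
          const int ii = i + di;
          if (ii >= 0 && ii < h && mask(ii, jj) == 1) { hit = 1; break; }
        }
      }
      out(i, j) = hit;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected components, 8-connectivity, union-find with final relabelling in
// raster order of each component's first pixel (column-major raster to match
// R's array order would be unusual for images; we use row-major raster over
// (row, col) scanning rows first within each... actually: raster order means
// scanning row by row, left to right).
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> parent(1, 0);
  int next = 1;
  // first pass, row-major raster scan; neighbours already visited:
  // (i-1, j-1), (i-1, j), (i-1, j+1), (i, j-1)
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (mask(i, j) == 0) continue;
      int nb[4]; int nn = 0;
      if (i > 0) {
        if (j > 0     && lab(i - 1, j - 1) > 0) nb[nn++] = lab(i - 1, j - 1);
        if (             lab(i - 1, j    ) > 0) nb[nn++] = lab(i - 1, j);
        if (j + 1 < w && lab(i - 1, j + 1) > 0) nb[nn++] = lab(i - 1, j + 1);
      }
      if (j > 0 && lab(i, j - 1) > 0) nb[nn++] = lab(i, j - 1);
      if (nn == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        int m = uf_find(parent, nb[0]);
        for (int t = 1; t < nn; ++t) {
          int r2 = uf_find(parent, nb[t]);
          if (r2 < m) { parent[m] = r2; m = r2; }
          else if (r2 > m) parent[r2] = m;
        }
        lab(i, j) = m;
      }
    }
  }
  // second pass: resolve and relabel in raster order of first occurrence
  std::vector<int> remap(next, 0);
  int n_comp = 0;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (lab(i, j) == 0) continue;
      int r = uf_find(parent, lab(i, j));
      if (remap[r] == 0) remap[r] = ++n_comp;
      lab(i, j) = remap[r];
    }
  }
  lab.attr("n_components") = n_comp;
  return lab;
}

// ---------------------------------------------------------------------------
// Bilinear resampling. Half-pixel-centre convention: output pixel centre
// (i + 0.5, j + 0.5) maps to source (i + 0.5) * h/out_h - 0.5 etc., so a
// same-size resize is the identity. Coordinates clamped (border replication).
// img is an H x W x C numeric array.
// ---------------------------------------------------------------------------

static inline double sample_bilinear(const double* ch, int h, int w,
                                     double sr, double sc) {
  if (sr < 0) sr = 0; if (sr > h - 1) sr = h - 1;
  if (sc < 0) sc = 0; if (sc > w - 1) sc = w - 1;
  const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
  const int r1 = std::min(r0 + 1, h - 1), c1 = std::min(c0 + 1, w - 1);
  const double fr = sr - r0, fc = sc - c0;
  const double v00 = ch[r0 + h * c0], v01 = ch[r0 + h * c1];
  const double v10 = ch[r1 + h * c0], v11 = ch[r1 + h * c1];
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) +
         fr       * ((1 - fc) * v10 + fc * v11);
}

// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericVector cpp_resize_bilinear(const NumericVector& img, int out_h, int out_w) {
  IntegerVector dm = img.attr("dim");
  const int h = dm[0], w = dm[1], nc = (dm.size() == 3) ? dm[2] : 1;
  NumericVector out(out_h * out_w * nc);
  const double sr_scale = (double)h / out_h, sc_scale = (double)w / out_w;
  for (int c = 0; c < nc; ++c) {
    const double* ch = img.begin() + (R_xlen_t)h * w * c;
    double* oc = out.begin() + (R_xlen_t)out_h * out_w * c;
    for (int j = 0; j < out_w; ++j) {
      const double sc = (j + 0.5) * sc_scale - 0.5;
      for (int i = 0; i < out_h; ++i) {
        const double sr = (i + 0.5) * sr_scale - 0.5;
        oc[i + out_h * j] = sample_bilinear(ch, h, w, sr, sc);
      }
    }
  }
  if (nc == 1 && dm.size() == 2) out.attr("dim") = Dimension(out_h, out_w);
  else out.attr("dim") = Dimension(out_h, out_w, nc);
  return out;
}

// Affine warp: output pixel (i, j), 0-based, maps to source coordinates
// (m11*i + m12*j + m13, m21*i + m22*j + m23); bilinear, border replication.
// [[Rcpp::export(name = ".cpp_warp_affine")]]
NumericVector cpp_warp_affine(const NumericVector& img, const NumericMatrix& m) {
  IntegerVector dm = img.attr("dim");
  const int h = dm[0], w = dm[1], nc = (dm.size() == 3) ? dm[2] : 1;
  NumericVector out(img.size());
  for (int c = 0; c < nc; ++c) {
    const double* ch = img.begin() + (R_xlen_t)h * w * c;
    double* oc = out.begin() + (R_xlen_t)h * w * c;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const double sr = m(0, 0) * i + m(0, 1) * j + m(0, 2);
        const double sc = m(1, 0) * i + m(1, 1) * j + m(1, 2);
        oc[i + h * j] = sample_bilinear(ch, h, w, sr, sc);
      }
    }
  }
  out.attr("dim") = img.attr("dim");
  return out;
}

// ---------------------------------------------------------------------------
// CNN primitives. Activations are H x W x C x N arrays (column-major),
// weights K x K x Cin x Cout, odd K, zero padding K/2 (shape-preserving),
// stride 1.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_conv2d_forward")]]
NumericVector cpp_conv2d_forward(const NumericVector& x, const NumericVector& wgt,
                                 const NumericVector& bias) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim");
  const int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  const int k = wd[0], cout = wd[3], r = k / 2;
  NumericVector out((R_xlen_t)h * w * cout * n);
  const double* xp = x.begin(); const double* wp = wgt.begin();
  for (int im = 0; im < n; ++im) {
    const double* xim = xp + (R_xlen_t)h * w * cin * im;
    double* oim = out.begin() + (R_xlen_t)h * w * cout * im;
    for (int co = 0; co < cout; ++co) {
      double* och = oim + (R_xlen_t)h * w * co;
      const double b = bias[co];
      for (R_xlen_t t = 0; t < (R_xlen_t)h * w; ++t) och[t] = b;
      for (int ci = 0; ci < cin; ++ci) {
        const double* xch = xim + (R_xlen_t)h * w * ci;
        const double* wch = wp + (R_xlen_t)k * k * (ci + cin * co);
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const double wv = wch[ki + k * kj];
            if (wv == 0.0) continue;
            const int di = ki - r, dj = kj - r;
            const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
            const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
            for (int j = j0; j < j1; ++j) {
              const double* xcol = xch + (R_xlen_t)h * (j + dj) + di;
              double* ocol = och + (R_xlen_t)h * j;
              for (int i = i0; i < i1; ++i) ocol[i] += wv * xcol[i];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, cout, n);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_backward")]]
List cpp_conv2d_backward(const NumericVector& x, const NumericVector& wgt,
                         const NumericVector& gout) {
  IntegerVector xd = x.attr("dim"), wd = wgt.attr("dim");
  const int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  const int k = wd[0], cout = wd[3], r = k / 2;
  NumericVector gx(x.size()), gw(wgt.size()), gb(cout);
  for (int im = 0; im < n; ++im) {
    const double* xim = x.begin() + (R_xlen_t)h * w * cin * im;
    const double* gim = gout.begin() + (R_xlen_t)h * w * cout * im;
    double* gxim = gx.begin() + (R_xlen_t)h * w * cin * im;
    for (int co = 0; co < cout; ++co) {
      const double* gch = gim + (R_xlen_t)h * w * co;
      double bsum = 0.0;
      for (R_xlen_t t = 0; t < (R_xlen_t)h * w; ++t) bsum += gch[t];
      gb[co] += bsum;
      for (int ci = 0; ci < cin; ++ci) {
        const double* xch = xim + (R_xlen_t)h * w * ci;
        double* gxch = gxim + (R_xlen_t)h * w * ci;
        const double* wch = wgt.begin() + (R_xlen_t)k * k * (ci + cin * co);
        double* gwch = gw.begin() + (R_xlen_t)k * k * (ci + cin * co);
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const int di = ki - r, dj = kj - r;
            const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
            const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
            const double wv = wch[ki + k * kj];
            double acc = 0.0;
            for (int j = j0; j < j1; ++j) {
              const double* xcol = xch + (R_xlen_t)h * (j + dj) + di;
              double* gxcol = gxch + (R_xlen_t)h * (j + dj) + di;
              const double* gcol = gch + (R_xlen_t)h * j;
              for (int i = i0; i < i1; ++i) {
                acc += xcol[i] * gcol[i];
                gxcol[i] += wv * gcol[i];
              }
            }
            gwch[ki + k * kj] += acc;
          }
        }
      }
    }
  }
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = wgt.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling p x p, stride p, floor output size; argmax recorded as 1-based
// linear index into the input array for the backward pass.
// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cpp_maxpool_forward(const NumericVector& x, int p) {
  IntegerVector xd = x.attr("dim");
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  const int oh = h / p, ow = w / p;
  NumericVector out((R_xlen_t)oh * ow * c * n);
  IntegerVector arg(out.size());
  for (int im = 0; im < n; ++im) {
    for (int ch = 0; ch < c; ++ch) {
      const R_xlen_t xoff = (R_xlen_t)h * w * (ch + c * im);
      const R_xlen_t ooff = (R_xlen_t)oh * ow * (ch + c * im);
      const double* xc = x.begin() + xoff;
      for (int oj = 0; oj < ow; ++oj) {
        for (int oi = 0; oi < oh; ++oi) {
          double best = -1e300; R_xlen_t bidx = 0;
          for (int dj = 0; dj < p; ++dj) {
            for (int di = 0; di < p; ++di) {
              const R_xlen_t idx = (R_xlen_t)(oi * p + di) + (R_xlen_t)h * (oj * p + dj);
              if (xc[idx] > best) { best = xc[idx]; bidx = idx; }
            }
          }
          out[ooff + oi + (R_xlen_t)oh * oj] = best;
          arg[ooff + oi + (R_xlen_t)oh * oj] = (int)(xoff + bidx) + 1;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, c, n);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericVector cpp_maxpool_backward(const NumericVector& gout, const IntegerVector& arg,
                                   const IntegerVector& in_dim) {
  R_xlen_t sz = 1;
  for (int t = 0; t < in_dim.size(); ++t) sz *= in_dim[t];
  NumericVector gx(sz);
  for (R_xlen_t t = 0; t < gout.size(); ++t) gx[arg[t] - 1] += gout[t];
  gx.attr("dim") = in_dim;
  return gx;
}
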