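#include <Rcpp.h>
using namespace Rcpp;

// Separable 1D correlation along one axis of a 3D array with replicate
// (clamp-to-edge) boundary handling. kernel index t runs -r..r and
// out[i] = sum_t kernel[t+r] * in[clamp(i+t)].
// [[Rcpp::export(name = ".conv1d_axis")]]
NumericVector conv1d_axis(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  if (klen % 2 == 0) stop("kernel length must be odd");
  NumericVector out(vol.size());
  out.attr("dim") = dims;

  const double *in = vol.begin();
  double *o = out.begin();
  const double *k = kernel.begin();

  if (axis == 1) {
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2) {
        const R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
        for (int i1 = 0; i1 < n1; ++i1) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int j = i1 + t;
            if (j < 0) j = 0; else if (j >= n1) j = n1 - 1;
            acc += k[t + r] * in[base + j];
          }
          o[base + i1] = acc;
        }
      }
  } else if (axis == 2) {
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i1 = 0; i1 < n1; ++i1) {
        const R_xlen_t base = i1 + (R_xlen_t)n1 * n2 * (R_xlen_t)i3;
        for (int i2 = 0; i2 < n2; ++i2) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int j = i2 + t;
            if (j < 0) j = 0; else if (j >= n2) j = n2 - 1;
            acc += k[t + r] * in[base + (R_xlen_t)n1 * j];
          }
          o[base + (R_xlen_t)n1 * i2] = acc;
        }
      }
  } else if (axis == 3) {
    const R_xlen_t stride = (R_xlen_t)n1 * n2;
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        const R_xlen_t base = i1 + (R_xlen_t)n1 * i2;
        for (int i3 = 0; i3 < n3; ++i3) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int j = i3 + t;
            if (j < 0) j = 0; else if (j >= n3) j = n3 - 1;
            acc += k[t + r] * in[base + stride * j];
          }
          o[base + stride * i3] = acc;
        }
      }
  } else {
    stop("axis must be 1, 2 or 3");
  }
  return out;
}

// Grey-scale erosion (min) or dilation (max) over an arbitrary structuring
// element given as voxel offsets (m x 3, zero-centred). Out-of-bounds
// neighbours are ignored, so flats (constant volumes) are preserved exactly.
// [[Rcpp::export(name = ".morph_minmax")]]
NumericVector morph_minmax(NumericVector vol, IntegerMatrix offsets, bool dilate) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int m = offsets.nrow();
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  const double *in = vol.begin();
  double *o = out.begin();

  std::vector<int> o1(m), o2(m), o3(m);
  for (int q = 0; q < m; ++q) { o1[q] = offsets(q,0); o2[q] = offsets(q,1); o3[q] = offsets(q,2); }

  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        double best = dilate ? R_NegInf : R_PosInf;
        for (int q = 0; q < m; ++q) {
          const int j1 = i1 + o1[q], j2 = i2 + o2[q], j3 = i3 + o3[q];
          if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
          const double v = in[j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3)];
          if (dilate) { if (v > best) best = v; } else { if (v < best) best = v; }
        }
        o[i1 + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3)] = best;
      }
  return out;
}

// Trilinear resampling of a 3D array at fractional source indices given per
// output axis (0-based), clamp-to-edge outside the source grid.
// [[Rcpp::export(name = ".trilinear_gather")]]
NumericVector trilinear_gather(NumericVector vol, NumericVector s1,
                               NumericVector s2, NumericVector s3) {
  IntegerVector dims = vol.attr("dim");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int m1 = s1.size(), m2 = s2.size(), m3 = s3.size();
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  out.attr("dim") = IntegerVector::create(m1, m2, m3);
  const double *in = vol.begin();
  double *o = out.begin();

  std::vector<int> f1(m1), f2(m2), f3(m3), c1(m1), c2(m2), c3(m3);
  std::vector<double> w1(m1), w2(m2), w3(m3);
  auto prep = [](const NumericVector &s, int n, std::vector<int> &f,
                 std::vector<int> &c, std::vector<double> &w) {
    for (int i = 0; i < s.size(); ++i) {
      double x = s[i];
      if (x < 0) x = 0;
      if (x > n - 1) x = n - 1;
      int lo = (int)std::floor(x);
      if (lo > n - 2) lo = n - 2;
      if (lo < 0) lo = 0;
      int hi = (n == 1) ? 0 : lo + 1;
      f[i] = lo; c[i] = hi; w[i] = (n == 1) ? 0.0 : x - lo;
    }
  };
  prep(s1, n1, f1, c1, w1);
  prep(s2, n2, f2, c2, w2);
  prep(s3, n3, f3, c3, w3);

  for (int k = 0; k < m3; ++k)
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i) {
        const double a = w1[i], b = w2[j], c = w3[k];
        const R_xlen_t i00 = f1[i] + (R_xlen_t)n1 * (f2[j] + (R_xlen_t)n2 * f3[k]);
        const R_xlen_t i10 = c1[i] + (R_xlen_t)n1 * (f2[j] + (R_xlen_t)n2 * f3[k]);
        const R_xlen_t i01 = f1[i] + (R_xlen_t)n1 * (c2[j] + (R_xlen_t)n2 * f3[k]);
        const R_xlen_t i11 = c1[i] + (R_xlen_t)n1 * (c2[j] + (R_xlen_t)n2 * f3[k]);
        const R_xlen_t j00 = f1[i] + (R_xlen_t)n1 * (f2[j] + (R_xlen_t)n2 * c3[k]);
        const R_xlen_t j10 = c1[i] + (R_xlen_t)n1 * (f2[j] + (R_xlen_t)n2 * c3[k]);
        const R_xlen_t j01 = f1[i] + (R_xlen_t)n1 * (c2[j] + (R_xlen_t)n2 * c3[k]);
        const R_xlen_t j11 = c1[i] + (R_xlen_t)n1 * (c2[j] + (R_xlen_t)n2 * c3[k]);
        const double v0 = (1-a)*(1-b)*in[i00] + a*(1-b)*in[i10] +
                          (1-a)*b*in[i01] + a*b*in[i11];
        const double v1 = (1-a)*(1-b)*in[j00] + a*(1-b)*in[j10] +
                          (1-a)*b*in[j01] + a*b*in[j11];
        o[i + (R_xlen_t)m1 * (j + (R_xlen_t)m2 * k)] = (1-c)*v0 + c*v1;
      }
  return out;
}
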