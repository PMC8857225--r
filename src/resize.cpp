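// Separable image resampling: coverage-weighted area averaging when a
// dimension shrinks (the antialiased choice for large reduction factors such
// as 1024 -> 256) and half-pixel-centre bilinear interpolation when it grows.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

namespace {

struct Tap { int src; double w; };

// Weights mapping src -> dst along one axis.
std::vector<std::vector<Tap>> axis_weights(int src, int dst) {
  std::vector<std::vector<Tap>> taps(dst);
  const double scale = (double)src / dst;
  if (dst <= src) {
    // box filter over the exact source span [i*scale, (i+1)*scale)
    for (int i = 0; i < dst; ++i) {
      const double lo = i * scale, hi = (i + 1) * scale;
      const int a = (int)std::floor(lo), b = (int)std::ceil(hi);
      for (int s = a; s < b && s < src; ++s) {
        const double cover = std::min<double>(hi, s + 1) - std::max<double>(lo, s);
        if (cover > 0) taps[i].push_back({s, cover / scale});
      }
    }
  } else {
    // bilinear, half-pixel centres: srcpos = (i + .5) * scale - .5
    for (int i = 0; i < dst; ++i) {
      double pos = (i + 0.5) * scale - 0.5;
      pos = std::min(std::max(pos, 0.0), (double)src - 1.0);
      const int s0 = (int)std::floor(pos);
      const int s1 = std::min(s0 + 1, src - 1);
      const double f = pos - s0;
      if (s1 == s0) taps[i].push_back({s0, 1.0});
      else { taps[i].push_back({s0, 1.0 - f}); taps[i].push_back({s1, f}); }
    }
  }
  return taps;
}

}  // namespace

// [[Rcpp::export(name = ".resize_rgb_cpp")]]
Rcpp::NumericVector resize_rgb_cpp(Rcpp::NumericVector img, int oh, int ow) {
  Rcpp::IntegerVector dm = img.attr("dim");
  if (dm.size() != 3) Rcpp::stop("img must be an (H, W, C) array");
  const int H = dm[0], W = dm[1], C = dm[2];
  if (oh < 1 || ow < 1) Rcpp::stop("output size must be positive");

  const auto rw = axis_weights(H, oh);
  const auto cw = axis_weights(W, ow);

  // pass 1: rows (H -> oh), per channel
  std::vector<double> tmp((size_t)oh * W * C, 0.0);
  const double* src = img.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      const double* col = src + (size_t)H * (j + (size_t)W * c);
      double* out = tmp.data() + (size_t)oh * (j + (size_t)W * c);
      for (int i = 0; i < oh; ++i) {
        double acc = 0.0;
        for (const Tap& t : rw[i]) acc += t.w * col[t.src];
        out[i] = acc;
      }
    }
  }
  // pass 2: cols (W -> ow)
  Rcpp::NumericVector res((R_xlen_t)oh * ow * C);
  res.attr("dim") = Rcpp::IntegerVector::create(oh, ow, C);
  double* dst = res.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < ow; ++j) {
      double* out = dst + (size_t)oh * (j + (size_t)ow * c);
      std::fill(out, out + oh, 0.0);
      for (const Tap& t : cw[j]) {
        const double* col = tmp.data() + (size_t)oh * (t.src + (size_t)W * c);
        for (int i = 0; i < oh; ++i) out[i] += t.w * col[i];
      }
    }
  }
  return res;
}
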