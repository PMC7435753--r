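// Convolution, pooling and resampling kernels.
//
// Tensor layout throughout: column-major R arrays of dim (H, W, C, N),
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)), 0-based.
// Weights are (kh, kw, Cin, Cout). All convolutions support per-axis
// stride, zero padding and dilation. The transposed convolution is
// realised in R by calling the backward-data pass as a forward pass,
// so only three primitives are needed here.

#include <RcppArmadillo.h>
#include <functional>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int eff_kernel(int k, int d) { return k + (k - 1) * (d - 1); }

static inline int out_size(int i, int k, int d, int s, int p) {
  int n = eff_kernel(k, d);
  return (i + 2 * p - n) / s + 1;
}

// Gather one sample's receptive-field columns: col is (kh*kw*C) x (Ho*Wo),
// row index r = dh + kh*(dw + kw*c), column index j = ho + Ho*wo.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int sh, int sw,
                   int ph, int pw, int dh, int dw,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int r = khi + kh * (kwi + kw * c);
        double* dst = col.colptr(0) + r; // stride between cols = col.n_rows
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * sw - pw + kwi * dw;
          bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * sh - ph + khi * dh;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wi];
            dst[(size_t)col.n_rows * (ho + (size_t)Ho * wo)] = v;
          }
        }
      }
    }
  }
}

// Scatter-accumulate the column representation back onto the input grid.
static void col2im(const arma::mat& col, double* dx, int H, int W, int C,
                   int kh, int kw, int sh, int sw,
                   int ph, int pw, int dh, int dw,
                   int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int r = khi + kh * (kwi + kw * c);
        const double* src = col.colptr(0) + r;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * sw - pw + kwi * dw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * sh - ph + khi * dh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] +=
              src[(size_t)col.n_rows * (ho + (size_t)Ho * wo)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int sh, int sw, int ph, int pw, int dh, int dw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cin);
  int Ho = out_size(H, kh, dh, sh, ph), Wo = out_size(W, kw, dw, sw, pw);
  if (Ho < 1 || Wo < 1) stop("effective kernel exceeds padded input");

  NumericVector y(Ho * Wo * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false);
  arma::mat col((size_t)kh * kw * C, (size_t)Ho * Wo);

  bool has_b = b.size() == Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, col);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n, (size_t)Ho * Wo, Cout, false, true);
    Y = col.t() * Wmat;
    if (has_b)
      for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector dy, NumericVector w,
                                int H, int W,
                                int sh, int sw, int ph, int pw, int dh, int dw) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  int kh = wd[0], kw = wd[1], C = wd[2];
  if (yd[2] != wd[3]) stop("channel mismatch in backward-data");

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false);

  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false);
    arma::mat dcol = Wmat * dY.t(); // (kh*kw*C) x (Ho*Wo)
    col2im(dcol, dx.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo);
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_weight(NumericVector x, NumericVector dy,
                                  int kh, int kw,
                                  int sh, int sw, int ph, int pw, int dh, int dw) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];

  NumericVector dwv((size_t)kh * kw * C * Cout);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  arma::mat dW(dwv.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::mat col((size_t)kh * kw * C, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, col);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false);
    dW += col * dY;
  }
  return dwv;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_bias(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  NumericVector db(Cout);
  const double* p = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      double s = 0.0;
      const double* q = p + (size_t)Ho * Wo * (c + (size_t)Cout * n);
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j) s += q[j];
      db[c] += s;
    }
  return db;
}

// Block-average pooling by integer factors (fh, fw); input dims must divide.
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, int fh, int fw) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / fh, Wo = W / fw;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double inv = 1.0 / (fh * fw);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = x.begin() + (size_t)H * W * cn;
    double* ys = y.begin() + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double s = 0.0;
        for (int dw2 = 0; dw2 < fw; ++dw2)
          for (int dh2 = 0; dh2 < fh; ++dh2)
            s += xs[(ho * fh + dh2) + (size_t)H * (wo * fw + dw2)];
        ys[ho + (size_t)Ho * wo] = s * inv;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dy, int fh, int fw) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho * fh, W = Wo * fw;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double inv = 1.0 / (fh * fw);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* ys = dy.begin() + (size_t)Ho * Wo * cn;
    double* xs = dx.begin() + (size_t)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double g = ys[ho + (size_t)Ho * wo] * inv;
        for (int dw2 = 0; dw2 < fw; ++dw2)
          for (int dh2 = 0; dh2 < fh; ++dh2)
            xs[(ho * fh + dh2) + (size_t)H * (wo * fw + dw2)] = g;
      }
  }
  return dx;
}

// Nearest-neighbour upsampling by integer factors.
// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, int fh, int fw) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H * fh, Wo = W * fw;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = x.begin() + (size_t)H * W * cn;
    double* ys = y.begin() + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        ys[ho + (size_t)Ho * wo] = xs[(ho / fh) + (size_t)H * (wo / fw)];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dy, int fh, int fw) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho / fh, W = Wo / fw;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* ys = dy.begin() + (size_t)Ho * Wo * cn;
    double* xs = dx.begin() + (size_t)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        xs[(ho / fh) + (size_t)H * (wo / fw)] += ys[ho + (size_t)Ho * wo];
  }
  return dx;
}

// 2x2 stride-2 max pooling with argmax indices for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xs = x.begin() + (size_t)H * W * cn;
    double* ys = y.begin() + (size_t)Ho * Wo * cn;
    int* is = idx.begin() + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int best = -1; double bv = -1e300;
        for (int dw2 = 0; dw2 < 2; ++dw2)
          for (int dh2 = 0; dh2 < 2; ++dh2) {
            int off = (ho * 2 + dh2) + H * (wo * 2 + dw2);
            if (xs[off] > bv) { bv = xs[off]; best = off; }
          }
        ys[ho + (size_t)Ho * wo] = bv;
        is[ho + (size_t)Ho * wo] = best;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* ys = dy.begin() + (size_t)Ho * Wo * cn;
    const int* is = idx.begin() + (size_t)Ho * Wo * cn;
    double* xs = dx.begin() + (size_t)H * W * cn;
    for (size_t j = 0; j < (size_t)Ho * Wo; ++j) xs[is[j]] += ys[j];
  }
  return dx;
}

// 8-connected component labelling of a binary matrix (two-pass union-find).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w)) continue;
      int best = 0;
      // previously-scanned 8-neighbours (column-major scan order)
      const int dh[4] = {-1, -1, 0, 1}, dw[4] = {0, -1, -1, -1};
      for (int t = 0; t < 4; ++t) {
        int hh = h + dh[t], ww = w + dw[t];
        if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
        int l = lab(hh, ww);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) { best = next++; parent.push_back(best); }
      lab(h, w) = best;
    }
  // second pass: flatten and renumber densely
  std::map<int, int> renum;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!lab(h, w)) continue;
      int r = find(lab(h, w));
      auto it = renum.find(r);
      if (it == renum.end()) { int id = renum.size() + 1; renum[r] = id; lab(h, w) = id; }
      else lab(h, w) = it->second;
    }
  return lab;
}

// CRC-32 (ISO 3309) over a raw vector; used by the 16-bit PNG writer.
// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
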