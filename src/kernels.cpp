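#include <Rcpp.h>
using namespace Rcpp;

// Volumetric tensors are column-major R arrays laid out (D, H, W, C);
// weights are (K, K, K, Cin_per_group, Cout). Grouped convolution assigns
// output channel co to group co / (Cout/groups), which sees input channels
// [g*Cig, (g+1)*Cig).

static inline size_t idx4(int d, int h, int w, int c,
                          int D, int H, int W) {
  return (size_t)d + (size_t)D * ((size_t)h + (size_t)H *
         ((size_t)w + (size_t)W * (size_t)c));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 5)
    stop("conv3d_fwd expects a 4-d input and 5-d weights");
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int K = wd[0], Cig = wd[3], Co = wd[4];
  if (wd[1] != K || wd[2] != K) stop("kernel must be cubic");
  if (Ci != Cig * groups) stop("input channels inconsistent with groups");
  if (Co % groups != 0) stop("output channels not divisible by groups");
  if (D + 2 * pad < K) stop("kernel larger than padded input");
  const int Do = (D + 2 * pad - K) / stride + 1;
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const int cog = Co / groups;

  NumericVector y((size_t)Do * Ho * Wo * Co);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co);

  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();

  for (int co = 0; co < Co; ++co) {
    const int g = co / cog;
    const int ci0 = g * Cig;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od) {
          double acc = b[co];
          for (int cig = 0; cig < Cig; ++cig) {
            const int ci = ci0 + cig;
            for (int kw = 0; kw < K; ++kw) {
              const int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              for (int kh = 0; kh < K; ++kh) {
                const int ih = oh * stride - pad + kh;
                if (ih < 0 || ih >= H) continue;
                for (int kd = 0; kd < K; ++kd) {
                  const int id = od * stride - pad + kd;
                  if (id < 0 || id >= D) continue;
                  acc += px[idx4(id, ih, iw, ci, D, H, W)] *
                         pw[(size_t)kd + (size_t)K * ((size_t)kh +
                            (size_t)K * ((size_t)kw + (size_t)K *
                            ((size_t)cig + (size_t)Cig * (size_t)co)))];
                }
              }
            }
          }
          py[idx4(od, oh, ow, co, Do, Ho, Wo)] = acc;
        }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int K = wd[0], Cig = wd[3], Co = wd[4];
  const int Do = yd[0], Ho = yd[1], Wo = yd[2];
  const int cog = Co / groups;

  NumericVector gx((size_t)D * H * W * Ci);
  gx.attr("dim") = IntegerVector::create(D, H, W, Ci);
  NumericVector gw((size_t)K * K * K * Cig * Co);
  gw.attr("dim") = IntegerVector::create(K, K, K, Cig, Co);
  NumericVector gb(Co);

  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();

  for (int co = 0; co < Co; ++co) {
    const int g = co / cog;
    const int ci0 = g * Cig;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od) {
          const double go = pg[idx4(od, oh, ow, co, Do, Ho, Wo)];
          if (go == 0.0) continue;
          gb[co] += go;
          for (int cig = 0; cig < Cig; ++cig) {
            const int ci = ci0 + cig;
            for (int kw = 0; kw < K; ++kw) {
              const int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              for (int kh = 0; kh < K; ++kh) {
                const int ih = oh * stride - pad + kh;
                if (ih < 0 || ih >= H) continue;
                for (int kd = 0; kd < K; ++kd) {
                  const int id = od * stride - pad + kd;
                  if (id < 0 || id >= D) continue;
                  const size_t xi = idx4(id, ih, iw, ci, D, H, W);
                  const size_t wi = (size_t)kd + (size_t)K * ((size_t)kh +
                      (size_t)K * ((size_t)kw + (size_t)K *
                      ((size_t)cig + (size_t)Cig * (size_t)co)));
                  pgw[wi] += px[xi] * go;
                  pgx[xi] += pw[wi] * go;
                }
              }
            }
          }
        }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling over cubic windows; ties broken toward the earliest linear
// index. Returns the pooled tensor and 1-based argmax indices into x.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, int K, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Do = (D + 2 * pad - K) / stride + 1;
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;

  NumericVector y((size_t)Do * Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  IntegerVector am((size_t)Do * Ho * Wo * C);

  const double *px = x.begin();
  double *py = y.begin();

  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kw = 0; kw < K; ++kw) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              for (int kd = 0; kd < K; ++kd) {
                const int id = od * stride - pad + kd;
                if (id < 0 || id >= D) continue;
                const size_t xi = idx4(id, ih, iw, c, D, H, W);
                if (px[xi] > best) { best = px[xi]; besti = xi; }
              }
            }
          }
          const size_t oi = idx4(od, oh, ow, c, Do, Ho, Wo);
          py[oi] = best;
          am[oi] = (int)(besti + 1);
        }
  List out = List::create(_["y"] = y, _["argmax"] = am);
  return out;
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gy, IntegerVector argmax,
                            IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double *pgx = gx.begin();
  const double *pg = gy.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) pgx[argmax[i] - 1] += pg[i];
  return gx;
}
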