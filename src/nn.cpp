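// Dense deformation-field U-Net with spatial-transformer warping, trained by
// Adam on a masked MSE + displacement-smoothness loss. Written directly against
// Armadillo (float32, OpenBLAS GEMM via im2col) because no autodiff framework
// is available to R here and the network is the package's core method.
//
// Tensor layout: feature maps are fmat (C x H*W*B); spatial index p = i + j*H
// (column-major rows), batch-major blocks of size H*W. Conv kernels are 3x3,
// pad 1; weights are fmat (Cout x 9*Cin) with column index kk*Cin + c where
// kk = kj*3 + ki, (ki,kj) the kernel offset in {0,1,2}^2 (di = ki-1, dj = kj-1).
// Parameter vector order: for each layer in plan order, W (column-major) then b.
//
// All large buffers (im2col matrices, activations, gradients) live in a
// Workspace that persists across training steps: repeated 100+ MB
// allocate/free cycles cost more than the GEMMs themselves.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::IntegerMatrix;
using Rcpp::stop;

static const float LSLOPE = 0.2f;
static const int NLAYER = 12;

struct Conv { fmat Wm; fvec b; int s; };
struct LayerPlan { int cin, cout, stride; };

// 4 stride-2 encoder convs, 7 decoder convs, 1 flow conv (VoxelMorph-2 2D).
static std::vector<LayerPlan> net_plan(const std::vector<int>& enc,
                                       const std::vector<int>& dec) {
  std::vector<LayerPlan> P;
  int c = 2;
  for (int k = 0; k < 4; k++) { P.push_back({c, enc[k], 2}); c = enc[k]; }
  P.push_back({enc[3],          dec[0], 1});  // d1 @ 1/16
  P.push_back({dec[0] + enc[2], dec[1], 1});  // d2 @ 1/8   (skip e3)
  P.push_back({dec[1] + enc[1], dec[2], 1});  // d3 @ 1/4   (skip e2)
  P.push_back({dec[2] + enc[0], dec[3], 1});  // d4 @ 1/2   (skip e1)
  P.push_back({dec[3],          dec[4], 1});  // d5 @ 1/2
  P.push_back({dec[4] + 2,      dec[5], 1});  // d6 @ full  (skip input)
  P.push_back({dec[5],          dec[6], 1});  // d7 @ full
  P.push_back({dec[6],          2,      1});  // flow
  return P;
}

static std::vector<int> as_ivec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

static size_t plan_n_params(const std::vector<LayerPlan>& P) {
  size_t n = 0;
  for (auto& L : P) n += (size_t)L.cout * 9 * L.cin + L.cout;
  return n;
}

// [[Rcpp::export]]
double cpp_unet_n_params(IntegerVector enc, IntegerVector dec) {
  return (double)plan_n_params(net_plan(as_ivec(enc), as_ivec(dec)));
}

static std::vector<Conv> unflatten(const NumericVector& par,
                                   const std::vector<LayerPlan>& P) {
  if ((size_t)par.size() != plan_n_params(P))
    stop("parameter vector has wrong length");
  std::vector<Conv> Ls;
  size_t off = 0;
  for (auto& L : P) {
    Conv C;
    C.Wm.set_size(L.cout, 9 * L.cin);
    for (uword k = 0; k < C.Wm.n_elem; k++) C.Wm(k) = (float)par[off + k];
    off += C.Wm.n_elem;
    C.b.set_size(L.cout);
    for (uword k = 0; k < C.b.n_elem; k++) C.b(k) = (float)par[off + k];
    off += C.b.n_elem;
    C.s = L.stride;
    Ls.push_back(std::move(C));
  }
  return Ls;
}

static int out_dim(int n, int s) { return (n - 1) / s + 1; }

static void im2col3(const fmat& A, int H, int W, int B, int s, fmat& K,
                    int& Ho, int& Wo) {
  const int C = A.n_rows;
  Ho = out_dim(H, s); Wo = out_dim(W, s);
  K.set_size((size_t)9 * C, (size_t)Ho * Wo * B);
  for (int b = 0; b < B; b++) {
    const size_t in_off = (size_t)H * W * b;
    const size_t out_off = (size_t)Ho * Wo * b;
    for (int jo = 0; jo < Wo; jo++) {
      for (int io = 0; io < Ho; io++) {
        const size_t q = out_off + (size_t)io + (size_t)jo * Ho;
        float* dst0 = K.colptr(q);
        for (int kj = 0; kj < 3; kj++) {
          const int jj = jo * s + kj - 1;
          for (int ki = 0; ki < 3; ki++) {
            const int ii = io * s + ki - 1;
            float* dst = dst0 + (size_t)(kj * 3 + ki) * C;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W)
              std::memset(dst, 0, sizeof(float) * C);
            else
              std::memcpy(dst, A.colptr(in_off + (size_t)ii + (size_t)jj * H),
                          sizeof(float) * C);
          }
        }
      }
    }
  }
}

static void col2im3(const fmat& G, int H, int W, int B, int s, fmat& dA) {
  const int C = dA.n_rows;
  const int Ho = out_dim(H, s), Wo = out_dim(W, s);
  for (int b = 0; b < B; b++) {
    const size_t in_off = (size_t)H * W * b;
    const size_t out_off = (size_t)Ho * Wo * b;
    for (int jo = 0; jo < Wo; jo++) {
      for (int io = 0; io < Ho; io++) {
        const size_t q = out_off + (size_t)io + (size_t)jo * Ho;
        const float* src0 = G.colptr(q);
        for (int kj = 0; kj < 3; kj++) {
          const int jj = jo * s + kj - 1;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < 3; ki++) {
            const int ii = io * s + ki - 1;
            if (ii < 0 || ii >= H) continue;
            float* dst = dA.colptr(in_off + (size_t)ii + (size_t)jj * H);
            const float* src = src0 + (size_t)(kj * 3 + ki) * C;
            for (int c = 0; c < C; c++) dst[c] += src[c];
          }
        }
      }
    }
  }
}

static void lrelu_(fmat& X) {
  float* p = X.memptr();
  for (uword k = 0; k < X.n_elem; k++)
    if (p[k] < 0.0f) p[k] *= LSLOPE;
}
// uses post-activation sign (valid because the slope is positive)
static void lrelu_bwd_(fmat& dY, const fmat& Y) {
  float* d = dY.memptr();
  const float* y = Y.memptr();
  for (uword k = 0; k < Y.n_elem; k++)
    if (y[k] <= 0.0f) d[k] *= LSLOPE;
}

static void up2(const fmat& A, int H, int W, int B, fmat& O) {
  const int H2 = 2 * H, W2 = 2 * W;
  const int C = A.n_rows;
  O.set_size(C, (size_t)H2 * W2 * B);
  for (int b = 0; b < B; b++)
    for (int j = 0; j < W2; j++)
      for (int i = 0; i < H2; i++) {
        const size_t q = (size_t)i + (size_t)j * H2 + (size_t)H2 * W2 * b;
        const size_t p = (size_t)(i / 2) + (size_t)(j / 2) * H + (size_t)H * W * b;
        std::memcpy(O.colptr(q), A.colptr(p), sizeof(float) * C);
      }
}

static void up2_bwd(const fmat& dO, int H, int W, int B, fmat& dA) {
  const int H2 = 2 * H, W2 = 2 * W;
  const int C = dO.n_rows;
  dA.zeros(C, (size_t)H * W * B);
  for (int b = 0; b < B; b++)
    for (int j = 0; j < W2; j++)
      for (int i = 0; i < H2; i++) {
        const size_t q = (size_t)i + (size_t)j * H2 + (size_t)H2 * W2 * b;
        float* dst = dA.colptr((size_t)(i / 2) + (size_t)(j / 2) * H +
                               (size_t)H * W * b);
        const float* src = dO.colptr(q);
        for (int c = 0; c < C; c++) dst[c] += src[c];
      }
}

// rows [0, ctop) of dst <- up2 of A; rows [ctop, ctop+skip rows) <- S
static void concat_up(const fmat& A, int H, int W, int B, const fmat& S,
                      fmat& O) {
  const int H2 = 2 * H, W2 = 2 * W;
  const int Cu = A.n_rows, Cs = S.n_rows;
  O.set_size(Cu + Cs, (size_t)H2 * W2 * B);
  for (int b = 0; b < B; b++)
    for (int j = 0; j < W2; j++)
      for (int i = 0; i < H2; i++) {
        const size_t q = (size_t)i + (size_t)j * H2 + (size_t)H2 * W2 * b;
        const size_t p = (size_t)(i / 2) + (size_t)(j / 2) * H + (size_t)H * W * b;
        float* dst = O.colptr(q);
        std::memcpy(dst, A.colptr(p), sizeof(float) * Cu);
        std::memcpy(dst + Cu, S.colptr(q), sizeof(float) * Cs);
      }
}

// Bilinear warp: out(i,j) = moving(i + u_row, j + u_col), border clamped.
static void warp_fwd(const fmat& Mv, const fmat& Flow, int H, int W, int B,
                     fmat& Wp) {
  Wp.set_size((size_t)H * W, B);
  for (int b = 0; b < B; b++) {
    const float* m = Mv.colptr(b);
    float* o = Wp.colptr(b);
    const float* fl = Flow.colptr((size_t)H * W * b);
    for (int j = 0; j < W; j++)
      for (int i = 0; i < H; i++) {
        const size_t p = (size_t)i + (size_t)j * H;
        float sr = i + fl[2 * p];
        float sc = j + fl[2 * p + 1];
        if (sr < 0) sr = 0; if (sr > H - 1) sr = (float)(H - 1);
        if (sc < 0) sc = 0; if (sc > W - 1) sc = (float)(W - 1);
        int i0 = (int)sr; if (i0 > H - 2) i0 = H - 2;
        int j0 = (int)sc; if (j0 > W - 2) j0 = W - 2;
        const float fr = sr - i0, fc = sc - j0;
        const float m00 = m[i0 + j0 * H],       m10 = m[i0 + 1 + j0 * H];
        const float m01 = m[i0 + (j0 + 1) * H], m11 = m[i0 + 1 + (j0 + 1) * H];
        o[p] = (1 - fr) * (1 - fc) * m00 + fr * (1 - fc) * m10 +
               (1 - fr) * fc * m01 + fr * fc * m11;
      }
  }
}

static void warp_bwd_flow(const fmat& Mv, const fmat& Flow, int H, int W,
                          int B, const fmat& dWp, fmat& dFlow) {
  dFlow.set_size(2, (size_t)H * W * B);
  for (int b = 0; b < B; b++) {
    const float* m = Mv.colptr(b);
    const float* g = dWp.colptr(b);
    const float* fl = Flow.colptr((size_t)H * W * b);
    float* df = dFlow.colptr((size_t)H * W * b);
    for (int j = 0; j < W; j++)
      for (int i = 0; i < H; i++) {
        const size_t p = (size_t)i + (size_t)j * H;
        float sr = i + fl[2 * p];
        float sc = j + fl[2 * p + 1];
        const bool cr = (sr <= 0 || sr >= H - 1);
        const bool cc = (sc <= 0 || sc >= W - 1);
        if (sr < 0) sr = 0; if (sr > H - 1) sr = (float)(H - 1);
        if (sc < 0) sc = 0; if (sc > W - 1) sc = (float)(W - 1);
        int i0 = (int)sr; if (i0 > H - 2) i0 = H - 2;
        int j0 = (int)sc; if (j0 > W - 2) j0 = W - 2;
        const float fr = sr - i0, fc = sc - j0;
        const float m00 = m[i0 + j0 * H],       m10 = m[i0 + 1 + j0 * H];
        const float m01 = m[i0 + (j0 + 1) * H], m11 = m[i0 + 1 + (j0 + 1) * H];
        df[2 * p] = cr ? 0.0f
                       : g[p] * ((1 - fc) * (m10 - m00) + fc * (m11 - m01));
        df[2 * p + 1] = cc ? 0.0f
                           : g[p] * ((1 - fr) * (m01 - m00) + fr * (m11 - m10));
      }
  }
}

struct Workspace {
  int H, W, B;
  int H1, W1, H2, W2, H3, W3, H4, W4;
  // forward activations (post-LeakyReLU) and conv inputs
  fmat x0, e1, e2, e3, e4, d1, c1, d2, c2, d3, c3, d4, d5, c4, d6, d7, flow;
  fmat warped;
  fmat K[NLAYER];   // cached im2col matrices
  fmat G[NLAYER];   // Wm' * dY scratch
  fmat dA[NLAYER];  // input-gradient scratch
  fmat gu, dWp, dFlow;
};

static void conv_fwd_ws(const Conv& L, const fmat& A, int H, int W, int B,
                        fmat& K, fmat& Y, int& Ho, int& Wo) {
  im2col3(A, H, W, B, L.s, K, Ho, Wo);
  Y = L.Wm * K;
  Y.each_col() += L.b;
}

static void conv_bwd_ws(const Conv& L, const fmat& K, int H, int W, int B,
                        const fmat& dY, fmat& dWm, fvec& db, fmat& G, fmat& dA,
                        int Cin, bool want_dA) {
  dWm = dY * K.t();
  db = sum(dY, 1);
  if (!want_dA) return;
  if (L.s == 1) {
    // Input gradient as a stride-1 convolution of dY with the spatially
    // flipped kernels: far better GEMM shape than col2im(Wm' * dY).
    const int Cout = L.Wm.n_rows;
    fmat Wr(Cin, 9 * Cout);
    for (int kk = 0; kk < 9; kk++) {
      const int kf = 8 - kk;  // 180-degree kernel flip
      for (int co = 0; co < Cout; co++)
        for (int ci = 0; ci < Cin; ci++)
          Wr(ci, (size_t)kk * Cout + co) = L.Wm(co, (size_t)kf * Cin + ci);
    }
    int ho, wo;
    im2col3(dY, H, W, B, 1, G, ho, wo);
    dA = Wr * G;
  } else {
    G = L.Wm.t() * dY;
    dA.zeros(Cin, (size_t)H * W * B);
    col2im3(G, H, W, B, L.s, dA);
  }
}

static void net_forward_full(const std::vector<Conv>& L, const fmat& FxF,
                             const fmat& MvF, int H, int W, int B,
                             Workspace& C) {
  // FxF/MvF are float (HW x B)
  if (H % 16 || W % 16) stop("image size must be a multiple of 16");
  C.H = H; C.W = W; C.B = B;
  const size_t HW = (size_t)H * W;
  C.x0.set_size(2, HW * B);
  for (int b = 0; b < B; b++) {
    const float* f = FxF.colptr(b);
    const float* m = MvF.colptr(b);
    float* x = C.x0.colptr(HW * b);
    for (size_t p = 0; p < HW; p++) { x[2 * p] = f[p]; x[2 * p + 1] = m[p]; }
  }
  int ho, wo;
  conv_fwd_ws(L[0], C.x0, H, W, B, C.K[0], C.e1, C.H1, C.W1); lrelu_(C.e1);
  conv_fwd_ws(L[1], C.e1, C.H1, C.W1, B, C.K[1], C.e2, C.H2, C.W2); lrelu_(C.e2);
  conv_fwd_ws(L[2], C.e2, C.H2, C.W2, B, C.K[2], C.e3, C.H3, C.W3); lrelu_(C.e3);
  conv_fwd_ws(L[3], C.e3, C.H3, C.W3, B, C.K[3], C.e4, C.H4, C.W4); lrelu_(C.e4);
  conv_fwd_ws(L[4], C.e4, C.H4, C.W4, B, C.K[4], C.d1, ho, wo); lrelu_(C.d1);
  concat_up(C.d1, C.H4, C.W4, B, C.e3, C.c1);
  conv_fwd_ws(L[5], C.c1, C.H3, C.W3, B, C.K[5], C.d2, ho, wo); lrelu_(C.d2);
  concat_up(C.d2, C.H3, C.W3, B, C.e2, C.c2);
  conv_fwd_ws(L[6], C.c2, C.H2, C.W2, B, C.K[6], C.d3, ho, wo); lrelu_(C.d3);
  concat_up(C.d3, C.H2, C.W2, B, C.e1, C.c3);
  conv_fwd_ws(L[7], C.c3, C.H1, C.W1, B, C.K[7], C.d4, ho, wo); lrelu_(C.d4);
  conv_fwd_ws(L[8], C.d4, C.H1, C.W1, B, C.K[8], C.d5, ho, wo); lrelu_(C.d5);
  concat_up(C.d5, C.H1, C.W1, B, C.x0, C.c4);
  conv_fwd_ws(L[9], C.c4, H, W, B, C.K[9], C.d6, ho, wo); lrelu_(C.d6);
  conv_fwd_ws(L[10], C.d6, H, W, B, C.K[10], C.d7, ho, wo); lrelu_(C.d7);
  conv_fwd_ws(L[11], C.d7, H, W, B, C.K[11], C.flow, ho, wo);
  warp_fwd(MvF, C.flow, H, W, B, C.warped);
}

// Masked per-image MSE (mean over mask pixels), batch-averaged; writes
// d(loss)/d(warped).
static double loss_mse_batch(const fmat& Fx, const fmat& Wp, const fmat& Msk,
                             int B, fmat& dWp) {
  dWp.set_size(Wp.n_rows, Wp.n_cols);
  double total = 0.0;
  for (int b = 0; b < B; b++) {
    const float* f = Fx.colptr(b);
    const float* w = Wp.colptr(b);
    const float* m = Msk.colptr(b);
    double nb = 0.0, s = 0.0;
    for (uword p = 0; p < Wp.n_rows; p++) nb += m[p];
    if (nb <= 0) stop("empty mask in batch");
    float* d = dWp.colptr(b);
    const float scale = (float)(2.0 / (nb * B));
    for (uword p = 0; p < Wp.n_rows; p++) {
      const float e = (w[p] - f[p]) * m[p];
      s += (double)e * e;
      d[p] = scale * e;
    }
    total += s / nb;
  }
  return total / B;
}

// Smoothness: forward differences of each displacement component in each
// direction; each direction's sum of squares is divided by (2 * its valid
// positions), the two directions are summed; batch-averaged. Adds
// lambda-scaled gradients into dFlow.
static double loss_smooth_batch(const fmat& Flow, int H, int W, int B,
                                double lambda, fmat& dFlow_add) {
  double total = 0.0;
  const size_t HW = (size_t)H * W;
  const double nr = 2.0 * (double)(H - 1) * W;
  const double nc = 2.0 * (double)H * (W - 1);
  const float gr = (float)(lambda * 2.0 / (nr * B));
  const float gc = (float)(lambda * 2.0 / (nc * B));
  for (int b = 0; b < B; b++) {
    const float* fl = Flow.colptr(HW * b);
    float* df = dFlow_add.colptr(HW * b);
    double sr = 0.0, sc = 0.0;
    for (int comp = 0; comp < 2; comp++) {
      for (int j = 0; j < W; j++)
        for (int i = 0; i < H - 1; i++) {
          const size_t p = 2 * ((size_t)i + (size_t)j * H) + comp;
          const float d = fl[p + 2] - fl[p];
          sr += (double)d * d;
          df[p + 2] += gr * d;
          df[p] -= gr * d;
        }
      for (int j = 0; j < W - 1; j++)
        for (int i = 0; i < H; i++) {
          const size_t p = 2 * ((size_t)i + (size_t)j * H) + comp;
          const float d = fl[p + 2 * H] - fl[p];
          sc += (double)d * d;
          df[p + 2 * H] += gc * d;
          df[p] -= gc * d;
        }
    }
    total += sr / nr + sc / nc;
  }
  return total / B;
}

static void net_backward(const std::vector<Conv>& L,
                         const std::vector<LayerPlan>& P, Workspace& C,
                         const fmat& dFlow, std::vector<fmat>& dW,
                         std::vector<fvec>& db) {
  const int B = C.B;
  conv_bwd_ws(L[11], C.K[11], C.H, C.W, B, dFlow, dW[11], db[11], C.G[11],
              C.dA[11], P[11].cin, true);
  lrelu_bwd_(C.dA[11], C.d7);
  conv_bwd_ws(L[10], C.K[10], C.H, C.W, B, C.dA[11], dW[10], db[10], C.G[10],
              C.dA[10], P[10].cin, true);
  lrelu_bwd_(C.dA[10], C.d6);
  conv_bwd_ws(L[9], C.K[9], C.H, C.W, B, C.dA[10], dW[9], db[9], C.G[9],
              C.dA[9], P[9].cin, true);
  C.gu = C.dA[9].rows(0, C.d5.n_rows - 1);  // skip-input grad dropped
  up2_bwd(C.gu, C.H1, C.W1, B, C.dA[8]);    // reuse slot as d5 grad
  lrelu_bwd_(C.dA[8], C.d5);
  conv_bwd_ws(L[8], C.K[8], C.H1, C.W1, B, C.dA[8], dW[8], db[8], C.G[8],
              C.dA[7], P[8].cin, true);
  lrelu_bwd_(C.dA[7], C.d4);
  conv_bwd_ws(L[7], C.K[7], C.H1, C.W1, B, C.dA[7], dW[7], db[7], C.G[7],
              C.dA[6], P[7].cin, true);
  fmat ge1 = C.dA[6].rows(C.d3.n_rows, C.dA[6].n_rows - 1);
  C.gu = C.dA[6].rows(0, C.d3.n_rows - 1);
  up2_bwd(C.gu, C.H2, C.W2, B, C.dA[5]);
  lrelu_bwd_(C.dA[5], C.d3);
  conv_bwd_ws(L[6], C.K[6], C.H2, C.W2, B, C.dA[5], dW[6], db[6], C.G[6],
              C.dA[4], P[6].cin, true);
  fmat ge2 = C.dA[4].rows(C.d2.n_rows, C.dA[4].n_rows - 1);
  C.gu = C.dA[4].rows(0, C.d2.n_rows - 1);
  up2_bwd(C.gu, C.H3, C.W3, B, C.dA[3]);
  lrelu_bwd_(C.dA[3], C.d2);
  conv_bwd_ws(L[5], C.K[5], C.H3, C.W3, B, C.dA[3], dW[5], db[5], C.G[5],
              C.dA[2], P[5].cin, true);
  fmat ge3 = C.dA[2].rows(C.d1.n_rows, C.dA[2].n_rows - 1);
  C.gu = C.dA[2].rows(0, C.d1.n_rows - 1);
  up2_bwd(C.gu, C.H4, C.W4, B, C.dA[1]);
  lrelu_bwd_(C.dA[1], C.d1);
  conv_bwd_ws(L[4], C.K[4], C.H4, C.W4, B, C.dA[1], dW[4], db[4], C.G[4],
              C.dA[0], P[4].cin, true);
  lrelu_bwd_(C.dA[0], C.e4);
  fmat g;
  conv_bwd_ws(L[3], C.K[3], C.H3, C.W3, B, C.dA[0], dW[3], db[3], C.G[3], g,
              P[3].cin, true);
  g += ge3;
  lrelu_bwd_(g, C.e3);
  fmat g2;
  conv_bwd_ws(L[2], C.K[2], C.H2, C.W2, B, g, dW[2], db[2], C.G[2], g2,
              P[2].cin, true);
  g2 += ge2;
  lrelu_bwd_(g2, C.e2);
  fmat g3;
  conv_bwd_ws(L[1], C.K[1], C.H1, C.W1, B, g2, dW[1], db[1], C.G[1], g3,
              P[1].cin, true);
  g3 += ge1;
  lrelu_bwd_(g3, C.e1);
  fmat gunused;
  conv_bwd_ws(L[0], C.K[0], C.H, C.W, B, g3, dW[0], db[0], C.G[0], gunused,
              P[0].cin, false);
}

static void cols_to_f(const NumericMatrix& X, const int* idx, int B, fmat& M) {
  M.set_size(X.nrow(), B);
  for (int k = 0; k < B; k++) {
    const double* src = &X(0, idx[k] - 1);
    float* dst = M.colptr(k);
    for (int r = 0; r < X.nrow(); r++) dst[r] = (float)src[r];
  }
}

static double eval_loss_set(const std::vector<Conv>& L, const NumericMatrix& Fx,
                            const NumericMatrix& Mv, const NumericMatrix& Msk,
                            int H, int W, int batch, double lambda,
                            Workspace& C) {
  const int N = Fx.ncol();
  double tot = 0.0;
  int done = 0;
  fmat fx, mv, mk;
  while (done < N) {
    const int B = std::min(batch, N - done);
    std::vector<int> idx(B);
    for (int k = 0; k < B; k++) idx[k] = done + k + 1;
    cols_to_f(Fx, idx.data(), B, fx);
    cols_to_f(Mv, idx.data(), B, mv);
    cols_to_f(Msk, idx.data(), B, mk);
    net_forward_full(L, fx, mv, H, W, B, C);
    fmat dWp;
    const double lm = loss_mse_batch(fx, C.warped, mk, B, dWp);
    fmat dFlow(2, C.flow.n_cols, fill::zeros);
    const double ls = loss_smooth_batch(C.flow, H, W, B, lambda, dFlow);
    tot += (lm + lambda * ls) * B;
    done += B;
  }
  return tot / N;
}

// [[Rcpp::export]]
List cpp_unet_train(NumericVector params, IntegerVector enc, IntegerVector dec,
                    NumericMatrix fixed_tr, NumericMatrix mov_tr,
                    NumericMatrix mask_tr, NumericMatrix fixed_va,
                    NumericMatrix mov_va, NumericMatrix mask_va, int H, int W,
                    IntegerMatrix perm, int epochs, int batch, double base_lr,
                    double lambda) {
  std::vector<LayerPlan> P = net_plan(as_ivec(enc), as_ivec(dec));
  std::vector<Conv> L = unflatten(params, P);
  const size_t np = plan_n_params(P);
  std::vector<double> adam_m(np, 0.0), adam_v(np, 0.0), theta(np);
  for (size_t k = 0; k < np; k++) theta[k] = params[k];
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  const int Ntr = fixed_tr.ncol();
  NumericVector train_curve(epochs), val_curve(epochs), lr_curve(epochs);
  Workspace C, Cval;
  std::vector<fmat> dW(NLAYER);
  std::vector<fvec> db(NLAYER);
  fmat fx, mv, mk;

  for (int ep = 0; ep < epochs; ep++) {
    const double lr =
        base_lr * (1.0 + std::cos(M_PI * (double)ep / epochs)) / 2.0;
    lr_curve[ep] = lr;
    double ep_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < Ntr; start += batch) {
      const int B = std::min(batch, Ntr - start);
      std::vector<int> idx(B);
      for (int k = 0; k < B; k++) idx[k] = perm(ep, start + k);
      cols_to_f(fixed_tr, idx.data(), B, fx);
      cols_to_f(mov_tr, idx.data(), B, mv);
      cols_to_f(mask_tr, idx.data(), B, mk);
      net_forward_full(L, fx, mv, H, W, B, C);
      const double lm = loss_mse_batch(fx, C.warped, mk, B, C.dWp);
      warp_bwd_flow(mv, C.flow, H, W, B, C.dWp, C.dFlow);
      const double ls = loss_smooth_batch(C.flow, H, W, B, lambda, C.dFlow);
      const double lossb = lm + lambda * ls;
      if (!std::isfinite(lossb))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
      ep_loss += lossb; nb++;
      net_backward(L, P, C, C.dFlow, dW, db);
      // Adam on the flattened double-precision shadow parameters
      step++;
      const double bc1 = 1.0 - std::pow(b1, (double)step);
      const double bc2 = 1.0 - std::pow(b2, (double)step);
      size_t off = 0;
      for (int li = 0; li < NLAYER; li++) {
        const float* gW = dW[li].memptr();
        for (uword k = 0; k < dW[li].n_elem; k++) {
          const double gk = gW[k];
          adam_m[off] = b1 * adam_m[off] + (1 - b1) * gk;
          adam_v[off] = b2 * adam_v[off] + (1 - b2) * gk * gk;
          theta[off] -= lr * (adam_m[off] / bc1) /
                        (std::sqrt(adam_v[off] / bc2) + eps);
          L[li].Wm(k) = (float)theta[off];
          off++;
        }
        const float* gb = db[li].memptr();
        for (uword k = 0; k < db[li].n_elem; k++) {
          const double gk = gb[k];
          adam_m[off] = b1 * adam_m[off] + (1 - b1) * gk;
          adam_v[off] = b2 * adam_v[off] + (1 - b2) * gk * gk;
          theta[off] -= lr * (adam_m[off] / bc1) /
                        (std::sqrt(adam_v[off] / bc2) + eps);
          L[li].b(k) = (float)theta[off];
          off++;
        }
      }
      Rcpp::checkUserInterrupt();
    }
    train_curve[ep] = ep_loss / nb;
    val_curve[ep] = (fixed_va.ncol() > 0)
                        ? eval_loss_set(L, fixed_va, mov_va, mask_va, H, W,
                                        batch, lambda, Cval)
                        : NA_REAL;
  }
  NumericVector out_par(np);
  for (size_t k = 0; k < np; k++) out_par[k] = theta[k];
  return List::create(Rcpp::Named("params") = out_par,
                      Rcpp::Named("train_loss") = train_curve,
                      Rcpp::Named("val_loss") = val_curve,
                      Rcpp::Named("lr") = lr_curve);
}

// [[Rcpp::export]]
NumericMatrix cpp_unet_flow(NumericVector params, IntegerVector enc,
                            IntegerVector dec, NumericMatrix fixed,
                            NumericMatrix moving, int H, int W) {
  std::vector<LayerPlan> P = net_plan(as_ivec(enc), as_ivec(dec));
  std::vector<Conv> L = unflatten(params, P);
  const int B = fixed.ncol();
  std::vector<int> idx(B);
  for (int k = 0; k < B; k++) idx[k] = k + 1;
  fmat fx, mv;
  cols_to_f(fixed, idx.data(), B, fx);
  cols_to_f(moving, idx.data(), B, mv);
  Workspace C;
  net_forward_full(L, fx, mv, H, W, B, C);
  NumericMatrix out(2, C.flow.n_cols);
  for (uword j = 0; j < C.flow.n_cols; j++) {
    out(0, j) = C.flow(0, j);
    out(1, j) = C.flow(1, j);
  }
  return out;
}
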