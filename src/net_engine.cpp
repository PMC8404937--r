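// Single-precision convolutional network engine.
//
// A network is a flat "tape" of ops executed in order on an activation tensor
// stored as an (H*W*B) x C matrix (spatial index p = y + H*x, column-major
// like an R matrix; images of a batch stacked along rows; one channel per
// column).  Supported ops:
//
//   type 1 CONV  k, s, cin, cout, bn, act   "same" zero padding, odd k;
//                                           batch-norm + activation fused
//   type 2 POOL  2x2 max pool, stride 2
//   type 3 UP    2x nearest-neighbour upsampling
//   type 4 SAVE  stash the current activation in a slot
//   type 5 ADD   add a stashed slot to the current activation (additive skip)
//
// Convolutions run as im2col (transposed layout: HW x C*k*k) + one sgemm per
// image, reading and writing batch row-blocks in place (leading-dimension
// tricks, no temporaries); the im2col buffers built forward are reused by the
// backward pass.  Very narrow outputs (cout <= 2, e.g. a final channels->1
// projection) use a direct shifted-axpy path that stays in cache and needs no
// im2col buffer.  All large buffers live in a persistent pool reused across
// steps, so a training loop does no repeated large allocations.
//
// Parameters live in one flat double vector on the R side (converted to
// float once per call): for each CONV in tape order
//   W (k*k*cin x cout, column-major), b (cout), then if bn: gamma, beta.
// Batch-norm running statistics live in a separate flat "state" vector:
// running mean then running variance per bn layer.  Training mode uses batch
// statistics (biased variance) and updates the running ones with momentum 0.1.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::IntegerMatrix;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::stop;

extern "C" void sgemm_(const char* transa, const char* transb,
                       const int* m, const int* n, const int* k,
                       const float* alpha, const float* a, const int* lda,
                       const float* b, const int* ldb, const float* beta,
                       float* c, const int* ldc);

static void xgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

enum { OP_CONV = 1, OP_POOL = 2, OP_UP = 3, OP_SAVE = 4, OP_ADD = 5 };

struct NetOp {
  int type, k, s, cin, cout, bn, act, slot;
  int Hin, Win, Hout, Wout;
  size_t wOff, bOff, gOff, beOff, sOff;
};

static std::vector<NetOp> parse_tape(const IntegerMatrix& tape, int H, int W,
                                     size_t* nPar, size_t* nState) {
  std::vector<NetOp> ops;
  size_t po = 0, so = 0;
  int h = H, w = W, chan = 1;
  for (int i = 0; i < tape.nrow(); ++i) {
    NetOp op;
    op.type = tape(i, 0); op.k = tape(i, 1); op.s = tape(i, 2);
    op.cin = tape(i, 3); op.cout = tape(i, 4); op.bn = tape(i, 5);
    op.act = tape(i, 6); op.slot = tape(i, 7);
    op.Hin = h; op.Win = w;
    op.wOff = op.bOff = op.gOff = op.beOff = op.sOff = 0;
    switch (op.type) {
    case OP_CONV: {
      if (op.k < 1 || op.k % 2 == 0) stop("conv kernel must be odd and >= 1");
      if (op.cin != chan) stop("conv cin mismatch in tape");
      int pad = (op.k - 1) / 2;
      op.Hout = (h + 2 * pad - op.k) / op.s + 1;
      op.Wout = (w + 2 * pad - op.k) / op.s + 1;
      op.wOff = po; po += (size_t)op.k * op.k * op.cin * op.cout;
      op.bOff = po; po += op.cout;
      if (op.bn) {
        op.gOff = po; po += op.cout;
        op.beOff = po; po += op.cout;
        op.sOff = so; so += 2 * (size_t)op.cout;
      }
      chan = op.cout; h = op.Hout; w = op.Wout;
      break;
    }
    case OP_POOL:
      if (h % 2 || w % 2) stop("pool input dims must be even");
      op.Hout = h / 2; op.Wout = w / 2; op.cin = op.cout = chan;
      h = op.Hout; w = op.Wout;
      break;
    case OP_UP:
      op.Hout = h * 2; op.Wout = w * 2; op.cin = op.cout = chan;
      h = op.Hout; w = op.Wout;
      break;
    case OP_SAVE:
    case OP_ADD:
      op.Hout = h; op.Wout = w; op.cin = op.cout = chan;
      break;
    default: stop("unknown op type in tape");
    }
    ops.push_back(op);
  }
  *nPar = po; *nState = so;
  return ops;
}

// [[Rcpp::export]]
List cpp_param_layout(const IntegerMatrix& tape, int H, int W) {
  size_t np, ns;
  std::vector<NetOp> ops = parse_tape(tape, H, W, &np, &ns);
  std::vector<double> wOff, wLen, bOff, gOff, beOff, cin, cout, kk;
  for (const NetOp& o : ops) {
    if (o.type != OP_CONV) continue;
    wOff.push_back((double)o.wOff + 1); // 1-based for R
    wLen.push_back((double)o.k * o.k * o.cin * o.cout);
    bOff.push_back((double)o.bOff + 1);
    gOff.push_back(o.bn ? (double)o.gOff + 1 : NA_REAL);
    beOff.push_back(o.bn ? (double)o.beOff + 1 : NA_REAL);
    cin.push_back(o.cin); cout.push_back(o.cout); kk.push_back(o.k);
  }
  return List::create(
    Rcpp::Named("nParams") = (double)np,
    Rcpp::Named("nState") = (double)ns,
    Rcpp::Named("wOff") = wOff, Rcpp::Named("wLen") = wLen,
    Rcpp::Named("bOff") = bOff, Rcpp::Named("gOff") = gOff,
    Rcpp::Named("beOff") = beOff,
    Rcpp::Named("k") = kk, Rcpp::Named("cin") = cin,
    Rcpp::Named("cout") = cout);
}

// transposed im2col; stride-1 path zeroes only the stale (padding) segments
static void im2col_t(const fmat& A, int H, int W, int b, int cin, int k,
                     int s, int Ho, int Wo, fmat& col) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  col.set_size((size_t)Ho * Wo, (size_t)cin * k * k);
  if (s != 1) col.zeros();
  for (int c = 0; c < cin; ++c) {
    const float* src = A.colptr(c) + (size_t)b * HW;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        float* dst = col.colptr((size_t)c * k * k + (size_t)dx * k + dy);
        for (int ox = 0; ox < Wo; ++ox) {
          int xi = ox * s - pad + dx;
          if (xi < 0 || xi >= W) {
            if (s == 1)
              memset(dst + (size_t)ox * Ho, 0, sizeof(float) * Ho);
            continue;
          }
          if (s == 1) {
            int y0 = dy - pad;                  // yi = oy + y0
            int a = std::max(0, -y0);
            int e = std::min(Ho, H - y0);
            if (a > 0) memset(dst + (size_t)ox * Ho, 0, sizeof(float) * a);
            if (e < Ho)
              memset(dst + (size_t)ox * Ho + e, 0, sizeof(float) * (Ho - e));
            if (e > a)
              memcpy(dst + (size_t)ox * Ho + a,
                     src + (size_t)xi * H + a + y0, sizeof(float) * (e - a));
          } else {
            for (int oy = 0; oy < Ho; ++oy) {
              int yi = oy * s - pad + dy;
              if (yi < 0 || yi >= H) continue;
              dst[(size_t)ox * Ho + oy] = src[(size_t)xi * H + yi];
            }
          }
        }
      }
    }
  }
}

// adjoint of im2col_t (stride 1 only): scatter-add columns back into dA
static void col2im_t(const fmat& col, int H, int W, int b, int cin, int k,
                     int Ho, int Wo, fmat& dA) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < cin; ++c) {
    float* dst = dA.colptr(c) + (size_t)b * HW;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const float* src = col.colptr((size_t)c * k * k + (size_t)dx * k + dy);
        for (int ox = 0; ox < Wo; ++ox) {
          int xi = ox - pad + dx;
          if (xi < 0 || xi >= W) continue;
          int y0 = dy - pad;
          int a = std::max(0, -y0);
          int e = std::min(Ho, H - y0);
          float* d = dst + (size_t)xi * H + y0;
          const float* ss = src + (size_t)ox * Ho;
          for (int oy = a; oy < e; ++oy) d[oy] += ss[oy];
        }
      }
    }
  }
}

// direct shifted-segment convolution for narrow outputs (cout <= 2)
static void conv_direct_fwd(const fmat& A, int H, int W, int B, int cin,
                            int k, const fmat& Wm, fmat& out) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const int cout = Wm.n_cols;
  out.zeros();
  for (int o = 0; o < cout; ++o) {
    for (int c = 0; c < cin; ++c) {
      for (int dx = 0; dx < k; ++dx) {
        for (int dy = 0; dy < k; ++dy) {
          float wv = Wm((size_t)c * k * k + (size_t)dx * k + dy, o);
          int y0 = dy - pad;
          int a = std::max(0, -y0);
          int e = std::min(H, H - y0);
          for (int b = 0; b < B; ++b) {
            const float* src = A.colptr(c) + (size_t)b * HW;
            float* dst = out.colptr(o) + (size_t)b * HW;
            for (int ox = 0; ox < W; ++ox) {
              int xi = ox - pad + dx;
              if (xi < 0 || xi >= W) continue;
              const float* s = src + (size_t)xi * H + y0;
              float* d = dst + (size_t)ox * H;
              for (int oy = a; oy < e; ++oy) d[oy] += wv * s[oy];
            }
          }
        }
      }
    }
  }
}

static void conv_direct_bwd(const fmat& A, const fmat& dZ, int H, int W,
                            int B, int cin, int k, const fmat& Wm,
                            fmat* dX, fvec& grad, size_t wOff) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const int cout = Wm.n_cols;
  for (int o = 0; o < cout; ++o) {
    for (int c = 0; c < cin; ++c) {
      for (int dx = 0; dx < k; ++dx) {
        for (int dy = 0; dy < k; ++dy) {
          int y0 = dy - pad;
          int a = std::max(0, -y0);
          int e = std::min(H, H - y0);
          float wv = Wm((size_t)c * k * k + (size_t)dx * k + dy, o);
          double acc = 0.0;
          for (int b = 0; b < B; ++b) {
            const float* src = A.colptr(c) + (size_t)b * HW;
            const float* dz = dZ.colptr(o) + (size_t)b * HW;
            float* dxp = dX ? dX->colptr(c) + (size_t)b * HW : NULL;
            for (int ox = 0; ox < W; ++ox) {
              int xi = ox - pad + dx;
              if (xi < 0 || xi >= W) continue;
              const float* s = src + (size_t)xi * H + y0;
              const float* g = dz + (size_t)ox * H;
              for (int oy = a; oy < e; ++oy) acc += (double)s[oy] * g[oy];
              if (dxp) {
                float* d = dxp + (size_t)xi * H + y0;
                for (int oy = a; oy < e; ++oy) d[oy] += wv * g[oy];
              }
            }
          }
          grad[wOff + (size_t)o * cin * k * k +
               (size_t)c * k * k + (size_t)dx * k + dy] += (float)acc;
        }
      }
    }
  }
}

// persistent buffer pool: reused across engine calls so a training loop does
// no repeated large allocations
struct Pool {
  std::vector<fmat> act;                  // activation after op i-1 (act[0]=x)
  std::vector<fmat> dact;                 // gradient buffers per op
  std::vector<std::vector<fmat> > cols;   // im2col buffers per op, per image
  std::vector<Mat<int> > poolIdx;
  std::vector<fmat> z;                    // pre-batch-norm conv outputs
  std::vector<fvec> mu, invstd;
  fmat dcol, gW;
};
static Pool g_pool;

static bool useDirect(const NetOp& o) {
  return o.cout <= 2 && o.cin > 2 && o.s == 1;
}

// Forward through the tape into pool.act[0..n]; training = batch statistics.
static void run_forward_pool(const std::vector<NetOp>& ops, const fvec& par,
                             fvec& state, int B, bool training, bool cache) {
  const size_t n = ops.size();
  Pool& P = g_pool;
  P.act.resize(n + 1);
  if (cache) {
    P.cols.resize(n); P.poolIdx.resize(n);
    P.z.resize(n); P.mu.resize(n); P.invstd.resize(n);
  }
  std::map<int, size_t> slotIdx;
  for (size_t i = 0; i < n; ++i) {
    const NetOp& o = ops[i];
    const fmat& Ain = P.act[i];
    fmat& out = P.act[i + 1];
    if (o.type == OP_CONV) {
      const size_t HoWo = (size_t)o.Hout * o.Wout;
      const int ldo = (int)(HoWo * B);
      fmat Wm(const_cast<float*>(par.memptr() + o.wOff),
              (size_t)o.k * o.k * o.cin, o.cout, false, true);
      out.set_size(HoWo * B, o.cout);
      if (useDirect(o)) {
        conv_direct_fwd(Ain, o.Hin, o.Win, B, o.cin, o.k, Wm, out);
      } else {
        const int K = o.k * o.k * o.cin;
        if (cache) P.cols[i].resize(B);
        fmat colScratch;
        for (int b = 0; b < B; ++b) {
          fmat& col = cache ? P.cols[i][b] : colScratch;
          im2col_t(Ain, o.Hin, o.Win, b, o.cin, o.k, o.s, o.Hout, o.Wout,
                   col);
          xgemm('N', 'N', (int)HoWo, o.cout, K, 1.0f,
                col.memptr(), (int)HoWo, Wm.memptr(), K,
                0.0f, out.memptr() + (size_t)b * HoWo, ldo);
        }
      }
      // fused epilogue: bias, batch-norm, activation in two passes
      const size_t M = out.n_rows;
      if (o.bn) {
        fvec mu(o.cout), invstd(o.cout);
        fmat* zc = NULL;
        if (cache) { P.z[i].set_size(M, o.cout); zc = &P.z[i]; }
        for (int c = 0; c < o.cout; ++c) {
          const float bias = par[o.bOff + c];
          float* p = out.colptr(c);
          float m, v;
          if (training) {
            double s1 = 0.0, s2 = 0.0;
            for (size_t j = 0; j < M; ++j) {
              s1 += p[j];
              s2 += (double)p[j] * p[j];
            }
            m = (float)(s1 / M) + bias;
            v = (float)(s2 / M - (s1 / M) * (s1 / M));
            state[o.sOff + c] =
              (1 - BN_MOMENTUM) * state[o.sOff + c] + BN_MOMENTUM * m;
            state[o.sOff + o.cout + c] =
              (1 - BN_MOMENTUM) * state[o.sOff + o.cout + c] + BN_MOMENTUM * v;
          } else {
            m = state[o.sOff + c];
            v = state[o.sOff + o.cout + c];
          }
          mu[c] = m;
          invstd[c] = 1.0f / std::sqrt(v + BN_EPS);
          const float sc = invstd[c] * par[o.gOff + c];
          const float be = par[o.beOff + c];
          float* zp = zc ? zc->colptr(c) : NULL;
          if (o.act == 1) {
            for (size_t j = 0; j < M; ++j) {
              float z = p[j] + bias;
              if (zp) zp[j] = z;
              float y = (z - m) * sc + be;
              p[j] = y > 0 ? y : 0.0f;
            }
          } else if (o.act == 2) {
            for (size_t j = 0; j < M; ++j) {
              float z = p[j] + bias;
              if (zp) zp[j] = z;
              p[j] = std::tanh((z - m) * sc + be);
            }
          } else {
            for (size_t j = 0; j < M; ++j) {
              float z = p[j] + bias;
              if (zp) zp[j] = z;
              p[j] = (z - m) * sc + be;
            }
          }
        }
        if (cache) { P.mu[i] = std::move(mu); P.invstd[i] = std::move(invstd); }
      } else {
        for (int c = 0; c < o.cout; ++c) {
          const float bias = par[o.bOff + c];
          float* p = out.colptr(c);
          if (o.act == 1) {
            for (size_t j = 0; j < M; ++j) {
              float y = p[j] + bias;
              p[j] = y > 0 ? y : 0.0f;
            }
          } else if (o.act == 2) {
            for (size_t j = 0; j < M; ++j) p[j] = std::tanh(p[j] + bias);
          } else {
            for (size_t j = 0; j < M; ++j) p[j] += bias;
          }
        }
      }
    } else if (o.type == OP_POOL) {
      const int H = o.Hin, Ho = o.Hout, Wo = o.Wout;
      const size_t HW = (size_t)o.Hin * o.Win, HoWo = (size_t)Ho * Wo;
      out.set_size(HoWo * B, Ain.n_cols);
      Mat<int>* idx = NULL;
      if (cache) {
        P.poolIdx[i].set_size(HoWo * B, Ain.n_cols);
        idx = &P.poolIdx[i];
      }
      for (uword c = 0; c < Ain.n_cols; ++c) {
        const float* src = Ain.colptr(c);
        float* dst = out.colptr(c);
        for (int b = 0; b < B; ++b) {
          const float* s0 = src + (size_t)b * HW;
          float* d0 = dst + (size_t)b * HoWo;
          for (int ox = 0; ox < Wo; ++ox) {
            for (int oy = 0; oy < Ho; ++oy) {
              size_t p00 = (size_t)(2 * ox) * H + 2 * oy;
              size_t cand[4] = { p00, p00 + 1, p00 + H, p00 + H + 1 };
              int best = 0;
              float bv = s0[cand[0]];
              for (int j = 1; j < 4; ++j)
                if (s0[cand[j]] > bv) { bv = s0[cand[j]]; best = j; }
              d0[(size_t)ox * Ho + oy] = bv;
              if (idx)
                (*idx)((size_t)b * HoWo + (size_t)ox * Ho + oy, c) =
                  (int)((size_t)b * HW + cand[best]);
            }
          }
        }
      }
    } else if (o.type == OP_UP) {
      const int H = o.Hin, Ho = o.Hout, Wo = o.Wout;
      const size_t HW = (size_t)o.Hin * o.Win, HoWo = (size_t)Ho * Wo;
      out.set_size(HoWo * B, Ain.n_cols);
      for (uword c = 0; c < Ain.n_cols; ++c) {
        const float* src = Ain.colptr(c);
        float* dst = out.colptr(c);
        for (int b = 0; b < B; ++b)
          for (int ox = 0; ox < Wo; ++ox)
            for (int oy = 0; oy < Ho; ++oy)
              dst[(size_t)b * HoWo + (size_t)ox * Ho + oy] =
                src[(size_t)b * HW + (size_t)(ox / 2) * H + oy / 2];
      }
    } else if (o.type == OP_SAVE) {
      slotIdx[o.slot] = i;
      out = Ain;
    } else if (o.type == OP_ADD) {
      std::map<int, size_t>::iterator it = slotIdx.find(o.slot);
      if (it == slotIdx.end()) stop("ADD references an unsaved slot");
      const fmat& sv = P.act[it->second];
      if (sv.n_rows != Ain.n_rows || sv.n_cols != Ain.n_cols)
        stop("skip connection shape mismatch");
      out = Ain + sv;
    }
  }
}

static void load_input(const NumericMatrix& X, size_t HW, int B) {
  if (g_pool.act.empty()) g_pool.act.resize(1);
  g_pool.act[0].set_size(HW * B, 1);
  for (int b = 0; b < B; ++b)
    for (size_t p = 0; p < HW; ++p)
      g_pool.act[0](b * HW + p, 0) = (float)X(p, b);
}

// [[Rcpp::export]]
NumericMatrix cpp_net_forward(const IntegerMatrix& tape, int H, int W,
                              const NumericVector& params,
                              const NumericVector& state,
                              const NumericMatrix& X, bool training) {
  size_t np, ns;
  std::vector<NetOp> ops = parse_tape(tape, H, W, &np, &ns);
  if ((size_t)params.size() != np) stop("params length mismatch");
  if ((size_t)state.size() != ns) stop("state length mismatch");
  const int B = X.ncol();
  if ((size_t)X.nrow() != (size_t)H * W) stop("input rows != H*W");
  fvec par = conv_to<fvec>::from(Rcpp::as<std::vector<double> >(params));
  fvec st = conv_to<fvec>::from(Rcpp::as<std::vector<double> >(state));
  if (g_pool.act.size() < ops.size() + 1) g_pool.act.resize(ops.size() + 1);
  load_input(X, (size_t)H * W, B);
  run_forward_pool(ops, par, st, B, training, false);
  const fmat& out = g_pool.act[ops.size()];
  if (out.n_cols != 1) stop("network output must have one channel");
  const size_t HWo = out.n_rows / B;
  NumericMatrix Y((int)HWo, B);
  for (int b = 0; b < B; ++b)
    for (size_t p = 0; p < HWo; ++p)
      Y(p, b) = out((size_t)b * HWo + p, 0);
  return Y;
}

// Forward pass in training mode, returning only the updated batch-norm
// running statistics: used to recalibrate them after the last weight update.
// [[Rcpp::export]]
NumericVector cpp_net_calibrate(const IntegerMatrix& tape, int H, int W,
                                const NumericVector& params,
                                const NumericVector& state,
                                const NumericMatrix& X) {
  size_t np, ns;
  std::vector<NetOp> ops = parse_tape(tape, H, W, &np, &ns);
  if ((size_t)params.size() != np) stop("params length mismatch");
  if ((size_t)state.size() != ns) stop("state length mismatch");
  const int B = X.ncol();
  if ((size_t)X.nrow() != (size_t)H * W) stop("input rows != H*W");
  fvec par = conv_to<fvec>::from(Rcpp::as<std::vector<double> >(params));
  fvec st = conv_to<fvec>::from(Rcpp::as<std::vector<double> >(state));
  if (g_pool.act.size() < ops.size() + 1) g_pool.act.resize(ops.size() + 1);
  load_input(X, (size_t)H * W, B);
  run_forward_pool(ops, par, st, B, true, false);
  NumericVector out(ns);
  for (size_t j = 0; j < ns; ++j) out[j] = st[j];
  return out;
}

// Forward + backward; returns mean-over-batch of per-image summed squared
// error, the parameter gradient, and updated batch-norm running statistics.
// [[Rcpp::export]]
List cpp_net_train_step(const IntegerMatrix& tape, int H, int W,
                        const NumericVector& params,
                        const NumericVector& state,
                        const NumericMatrix& X, const NumericMatrix& GT) {
  size_t np, ns;
  std::vector<NetOp> ops = parse_tape(tape, H, W, &np, &ns);
  if ((size_t)params.size() != np) stop("params length mismatch");
  if ((size_t)state.size() != ns) stop("state length mismatch");
  const int B = X.ncol();
  const size_t HW = (size_t)H * W;
  const size_t n = ops.size();
  if ((size_t)X.nrow() != HW || GT.ncol() != B || (size_t)GT.nrow() != HW)
    stop("input/target shape mismatch");
  fvec par = conv_to<fvec>::from(Rcpp::as<std::vector<double> >(params));
  fvec st = conv_to<fvec>::from(Rcpp::as<std::vector<double> >(state));
  Pool& P = g_pool;
  if (P.act.size() < n + 1) P.act.resize(n + 1);
  load_input(X, HW, B);
  run_forward_pool(ops, par, st, B, true, true);
  const fmat& out = P.act[n];
  if (out.n_cols != 1 || out.n_rows != HW * B)
    stop("network output must be one channel of the input size");

  double loss = 0.0;
  P.dact.resize(n + 1);
  fmat* dA = &P.dact[n];
  dA->set_size(HW * B, 1);
  for (int b = 0; b < B; ++b)
    for (size_t p = 0; p < HW; ++p) {
      double d = (double)out(b * HW + p, 0) - GT(p, b);
      loss += d * d;
      (*dA)(b * HW + p, 0) = (float)(2.0 * d / B);
    }
  loss /= B;

  fvec grad(np, fill::zeros);
  std::map<int, int> slotAddOp;   // slot -> op index of the consuming ADD
  for (int i = (int)n - 1; i >= 0; --i) {
    const NetOp& o = ops[i];
    fmat& dOut = *dA;            // gradient w.r.t. this op's output
    if (o.type == OP_CONV) {
      if (o.s != 1) stop("backward requires stride-1 convolutions");
      const size_t HoWo = (size_t)o.Hout * o.Wout;
      const int ldo = (int)(HoWo * B);
      const fmat& aout = P.act[i + 1];
      if (o.act == 1) {
        for (uword j = 0; j < dOut.n_elem; ++j)
          if (aout(j) <= 0) dOut(j) = 0.0f;
      } else if (o.act == 2) {
        dOut %= (1.0f - square(aout));
      }
      if (o.bn) {
        const size_t M = dOut.n_rows;
        const fmat& z = P.z[i];
        for (int c = 0; c < o.cout; ++c) {
          const float m = P.mu[i][c], is = P.invstd[i][c];
          const float* zp = z.colptr(c);
          float* dp = dOut.colptr(c);
          double dg = 0.0, db = 0.0;
          for (size_t j = 0; j < M; ++j) {
            dg += (double)dp[j] * (zp[j] - m) * is;
            db += dp[j];
          }
          grad[o.gOff + c] += (float)dg;
          grad[o.beOff + c] += (float)db;
          const float g = par[o.gOff + c];
          const float a1 = g * is;
          const float a2 = (float)(db / M);
          const float a3 = (float)(dg / M) * is;
          double dbias = 0.0;
          for (size_t j = 0; j < M; ++j) {
            float v = a1 * (dp[j] - a2 - (zp[j] - m) * a3);
            dp[j] = v;
            dbias += v;
          }
          grad[o.bOff + c] += (float)dbias;
        }
      } else {
        for (int c = 0; c < o.cout; ++c)
          grad[o.bOff + c] += accu(dOut.col(c));
      }
      fmat Wm(const_cast<float*>(par.memptr() + o.wOff),
              (size_t)o.k * o.k * o.cin, o.cout, false, true);
      const int K = o.k * o.k * o.cin;
      bool needDx = (i > 0);
      fmat* dX = NULL;
      if (needDx) {
        dX = &P.dact[i];
        dX->set_size((size_t)o.Hin * o.Win * B, o.cin);
        dX->zeros();
      }
      if (useDirect(o)) {
        conv_direct_bwd(P.act[i], dOut, o.Hin, o.Win, B, o.cin, o.k, Wm,
                        dX, grad, o.wOff);
      } else {
        P.gW.set_size(K, o.cout);
        P.gW.zeros();
        for (int b = 0; b < B; ++b) {
          const fmat& col = P.cols[i][b];
          // gW += col^T (K x HoWo) * dZ_b
          xgemm('T', 'N', K, o.cout, (int)HoWo, 1.0f,
                col.memptr(), (int)HoWo,
                dOut.memptr() + (size_t)b * HoWo, ldo,
                1.0f, P.gW.memptr(), K);
          if (needDx) {
            P.dcol.set_size(HoWo, K);
            xgemm('N', 'T', (int)HoWo, K, o.cout, 1.0f,
                  dOut.memptr() + (size_t)b * HoWo, ldo,
                  Wm.memptr(), K, 0.0f, P.dcol.memptr(), (int)HoWo);
            col2im_t(P.dcol, o.Hin, o.Win, b, o.cin, o.k, o.Hout, o.Wout,
                     *dX);
          }
        }
        for (size_t j = 0; j < P.gW.n_elem; ++j)
          grad[o.wOff + j] += P.gW(j);
      }
      if (needDx) dA = dX;
    } else if (o.type == OP_POOL) {
      const Mat<int>& idx = P.poolIdx[i];
      fmat& dX = P.dact[i];
      dX.set_size((size_t)o.Hin * o.Win * B, dOut.n_cols);
      dX.zeros();
      for (uword c = 0; c < dOut.n_cols; ++c) {
        float* d = dX.colptr(c);
        const float* s = dOut.colptr(c);
        const int* ix = idx.colptr(c);
        for (uword j = 0; j < dOut.n_rows; ++j) d[(size_t)ix[j]] += s[j];
      }
      dA = &dX;
    } else if (o.type == OP_UP) {
      const int Hi = o.Hin, Ho = o.Hout;
      const size_t HWo = (size_t)o.Hout * o.Wout, HWi = (size_t)o.Hin * o.Win;
      fmat& dX = P.dact[i];
      dX.set_size(HWi * B, dOut.n_cols);
      dX.zeros();
      for (uword c = 0; c < dOut.n_cols; ++c) {
        float* d = dX.colptr(c);
        const float* s = dOut.colptr(c);
        for (int b = 0; b < B; ++b)
          for (int ox = 0; ox < o.Wout; ++ox)
            for (int oy = 0; oy < Ho; ++oy)
              d[(size_t)b * HWi + (size_t)(ox / 2) * Hi + oy / 2] +=
                s[(size_t)b * HWo + (size_t)ox * Ho + oy];
      }
      dA = &dX;
    } else if (o.type == OP_SAVE) {
      // add the gradient accumulated at the consuming ADD op(s)
      std::map<int, int>::iterator it = slotAddOp.find(o.slot);
      if (it != slotAddOp.end()) {
        fmat& extra = P.dact[it->second];
        if (dA->n_elem == 0) dA = &extra;
        else *dA += extra;
        slotAddOp.erase(it);
      }
    } else if (o.type == OP_ADD) {
      // gradient flows unchanged to the main path and to the saved slot;
      // stash a copy for the SAVE op under this op's own buffer index
      std::map<int, int>::iterator it = slotAddOp.find(o.slot);
      if (it == slotAddOp.end()) {
        P.dact[i] = dOut;
        slotAddOp[o.slot] = i;
      } else {
        P.dact[it->second] += dOut;
      }
    }
  }

  NumericVector gradOut(np), stateOut(ns);
  for (size_t j = 0; j < np; ++j) gradOut[j] = grad[j];
  for (size_t j = 0; j < ns; ++j) stateOut[j] = st[j];
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("grad") = gradOut,
                      Rcpp::Named("state") = stateOut);
}
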