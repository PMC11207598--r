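// Compact convolutional pose-delta regressor.
//
// Fixed architecture (input 4 x 120 x 180, channels = image stack):
//   block1: conv3x3(4->4)   relu, conv3x3(4->4)   relu, dropout, maxpool2
//   block2: conv3x3(4->16)  relu, conv3x3(16->16) relu, dropout, maxpool2
//   block3: conv3x3(16->64) relu, conv3x3(64->64) relu, dropout, maxpool2
//   fc: flatten(64*15*22=21120) -> 128 relu -> 6 linear
// Trained with Adam + L2 weight decay on mean-squared error, Kaiming
// normal initialisation, seeded mt19937 for reproducibility.
//
// Implementation: activations live in a zero-padded layout (one-pixel
// ring per image), so a 3x3 pad-1 convolution is nine accumulating
// GEMMs on shifted contiguous column ranges -- no im2col gather. All
// compute is single precision through BLAS sgemm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

extern "C" void mp_sgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float* A, int lda, const float* B, int ldb,
                         float beta, float* C, int ldc);

using namespace arma;

namespace {

inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  mp_sgemm(ta, tb, m, n, k, alpha, A, lda, B, ldb, beta, C, ldc);
}

// fixed architecture
const int IN_H = 120, IN_W = 180, IN_C = 4, N_OUT = 6, FC_HID = 128;
struct BlockDims {
  int H, W, Cin, Cout;          // conv resolution and channels
  int Hp() const { return H + 2; }
  int Wp() const { return W + 2; }
  int S() const { return Hp() * Wp(); }
};
const BlockDims BD[3] = { {120, 180, 4, 4}, {60, 90, 4, 16}, {30, 45, 16, 64} };
const int H3 = 15, W3 = 22, FLAT = 64 * H3 * W3;

struct Net {
  std::vector<fmat> W;   // 6 conv (Cout x Cin*9, column block per offset) + 2 fc
  std::vector<fvec> b;
  std::mt19937 rng;

  fmat kaiming(int rows, int fan_in, int cols) {
    std::normal_distribution<float> g(0.0f, std::sqrt(2.0f / fan_in));
    fmat m(rows, cols);
    for (uword i = 0; i < m.n_elem; ++i) m(i) = g(rng);
    return m;
  }
  void init(unsigned seed) {
    rng.seed(seed);
    W.resize(8); b.resize(8);
    for (int blk = 0; blk < 3; ++blk) {
      const BlockDims& d = BD[blk];
      W[2 * blk] = kaiming(d.Cout, d.Cin * 9, d.Cin * 9);
      b[2 * blk] = fvec(d.Cout, fill::zeros);
      W[2 * blk + 1] = kaiming(d.Cout, d.Cout * 9, d.Cout * 9);
      b[2 * blk + 1] = fvec(d.Cout, fill::zeros);
    }
    W[6] = kaiming(FC_HID, FLAT, FLAT); b[6] = fvec(FC_HID, fill::zeros);
    W[7] = kaiming(N_OUT, FC_HID, FC_HID); b[7] = fvec(N_OUT, fill::zeros);
  }
};

// zero the pad-ring columns of a padded activation (C x S*B)
void zero_pads(fmat& A, const BlockDims& d, int B) {
  const int Hp = d.Hp(), Wp = d.Wp(), S = d.S();
  const int C = A.n_rows;
  for (int b = 0; b < B; ++b) {
    const uword off = (uword)b * S;
    for (int j = 0; j < Wp; ++j) {
      std::memset(A.colptr(off + (uword)j * Hp), 0, sizeof(float) * C);
      std::memset(A.colptr(off + (uword)j * Hp + Hp - 1), 0,
                  sizeof(float) * C);
    }
    for (int i = 1; i < Hp - 1; ++i) {
      std::memset(A.colptr(off + i), 0, sizeof(float) * C);
      std::memset(A.colptr(off + (uword)(Wp - 1) * Hp + i), 0,
                  sizeof(float) * C);
    }
  }
}

// forward conv: Y = W (*) A (+ bias, relu), pads of Y re-zeroed.
// W columns grouped per offset k = (kh+1) + 3*(kw+1), shift d = kh+Hp*kw.
void conv_forward(const fmat& A, const fmat& W, const fvec& bias,
                  const BlockDims& d, int Cin, int Cout, int B, fmat& Y) {
  const int Hp = d.Hp();
  const uword Np = (uword)d.S() * B;
  Y.zeros(Cout, Np);
  for (int kw = -1; kw <= 1; ++kw)
    for (int kh = -1; kh <= 1; ++kh) {
      const int k = (kh + 1) + 3 * (kw + 1);
      const int sh = kh + Hp * kw;
      const int n = (int)Np - std::abs(sh);
      const float* Aptr = A.colptr(sh > 0 ? sh : 0);
      float* Yptr = Y.colptr(sh > 0 ? 0 : -sh);
      sgemm('N', 'N', Cout, n, Cin, 1.0f, W.colptr((uword)k * Cin), Cout,
            Aptr, Cin, 1.0f, Yptr, Cout);
    }
  // bias + relu over the whole buffer, then re-zero the pad ring
  float* y = Y.memptr();
  const float* bb = bias.memptr();
  for (uword j = 0; j < Np; ++j) {
    float* col = y + (size_t)j * Cout;
    for (int c = 0; c < Cout; ++c) {
      float v = col[c] + bb[c];
      col[c] = v > 0 ? v : 0.0f;
    }
  }
}

// backward: given dY (pads zeroed via relu mask), accumulate dW, db and
// compute dA (gradient wrt the padded input A)
void conv_backward(const fmat& A, const fmat& W, const fmat& dY,
                   const BlockDims& d, int Cin, int Cout, int B,
                   fmat& dW, fvec& db, fmat& dA, bool need_dA) {
  const int Hp = d.Hp();
  const uword Np = (uword)d.S() * B;
  dW.zeros(Cout, (uword)Cin * 9);
  if (need_dA) dA.zeros(Cin, Np);
  for (int kw = -1; kw <= 1; ++kw)
    for (int kh = -1; kh <= 1; ++kh) {
      const int k = (kh + 1) + 3 * (kw + 1);
      const int sh = kh + Hp * kw;
      const int n = (int)Np - std::abs(sh);
      const float* Aptr = A.colptr(sh > 0 ? sh : 0);
      const float* dYptr = dY.colptr(sh > 0 ? 0 : -sh);
      // dWk = dY_range * A_range^T
      sgemm('N', 'T', Cout, Cin, n, 1.0f, dYptr, Cout, Aptr, Cin, 1.0f,
            dW.colptr((uword)k * Cin), Cout);
      if (need_dA) {
        // dA_range += Wk^T * dY_range
        sgemm('T', 'N', Cin, n, Cout, 1.0f, W.colptr((uword)k * Cin), Cout,
              dYptr, Cout, 1.0f, dA.colptr(sh > 0 ? sh : 0), Cin);
      }
    }
  db = sum(dY, 1);
}

// max-pool 2x2 from a padded activation to the next block's padded
// layout (or to a compact C x H2*W2*B buffer for the last block)
void maxpool2(const fmat& A, const BlockDims& d, int B, bool pad_out,
              const BlockDims* dnext, fmat& P, std::vector<uword>& amax) {
  const int Hp = d.Hp(), H2 = d.H / 2, W2 = d.W / 2;
  const int C = A.n_rows;
  const int Sout = pad_out ? dnext->S() : H2 * W2;
  P.zeros(C, (uword)Sout * B);
  amax.assign((size_t)C * H2 * W2 * B, 0);
  for (int b = 0; b < B; ++b) {
    const uword offi = (uword)b * d.S();
    const uword offo = (uword)b * Sout;
    for (int j2 = 0; j2 < W2; ++j2)
      for (int i2 = 0; i2 < H2; ++i2) {
        const uword c00 = offi + (uword)(2 * j2 + 1) * Hp + (2 * i2 + 1);
        const uword cand[4] = {c00, c00 + 1, c00 + Hp, c00 + Hp + 1};
        const uword dst = pad_out
          ? offo + (uword)(j2 + 1) * dnext->Hp() + (i2 + 1)
          : offo + (uword)j2 * H2 + i2;
        const size_t ax = (size_t)C * ((size_t)b * H2 * W2 + (size_t)j2 * H2 + i2);
        float* pd = P.colptr(dst);
        for (int c = 0; c < C; ++c) {
          float best = A(c, cand[0]); uword bi = cand[0];
          for (int q = 1; q < 4; ++q) {
            float v = A(c, cand[q]);
            if (v > best) { best = v; bi = cand[q]; }
          }
          pd[c] = best;
          amax[ax + c] = bi;
        }
      }
  }
}

// scatter pooled gradients (compact or padded source) back to the
// padded conv activation gradient
void maxpool2_back(const fmat& dP, const std::vector<uword>& amax,
                   const BlockDims& d, int B, bool pad_in,
                   const BlockDims* dnext, fmat& dA) {
  const int H2 = d.H / 2, W2 = d.W / 2;
  const int C = dP.n_rows;
  dA.zeros(C, (uword)d.S() * B);
  for (int b = 0; b < B; ++b) {
    const uword offo = pad_in ? (uword)b * dnext->S() : (uword)b * H2 * W2;
    for (int j2 = 0; j2 < W2; ++j2)
      for (int i2 = 0; i2 < H2; ++i2) {
        const uword src = pad_in
          ? offo + (uword)(j2 + 1) * dnext->Hp() + (i2 + 1)
          : offo + (uword)j2 * H2 + i2;
        const size_t ax = (size_t)C * ((size_t)b * H2 * W2 + (size_t)j2 * H2 + i2);
        const float* ps = dP.colptr(src);
        for (int c = 0; c < C; ++c) dA(c, amax[ax + c]) += ps[c];
      }
  }
}

void relu_mask(const fmat& act, fmat& grad) {
  const float* a = act.memptr();
  float* g = grad.memptr();
  const uword n = act.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a[i] <= 0) g[i] = 0.0f;
}

struct Cache {
  fmat block_in[3];              // padded input of each block
  fmat conv_out[6];              // padded post-relu activations
  fmat pooled3;                  // compact output of the last pool
  std::vector<uword> amax[3];
  fmat drop_mask[3];
  fmat flat, hid;
};

struct Engine {
  // x: (H*W*C) x B sample layout from the R array -> padded block-1 input
  static void to_padded(const fmat& x, int B, fmat& A) {
    const BlockDims& d = BD[0];
    const int HW = IN_H * IN_W, Hp = d.Hp();
    A.zeros(IN_C, (uword)d.S() * B);
    for (int bq = 0; bq < B; ++bq) {
      const float* src = x.colptr(bq);
      const uword off = (uword)bq * d.S();
      for (int j = 0; j < IN_W; ++j)
        for (int i = 0; i < IN_H; ++i) {
          float* col = A.colptr(off + (uword)(j + 1) * Hp + (i + 1));
          const size_t sp = (size_t)j * IN_H + i;
          for (int c = 0; c < IN_C; ++c) col[c] = src[(size_t)c * HW + sp];
        }
    }
  }

  fmat forward(Net& net, const fmat& xb, int B, bool train, float p_drop,
               Cache& cc) {
    to_padded(xb, B, cc.block_in[0]);
    std::uniform_real_distribution<float> un(0.0f, 1.0f);
    for (int blk = 0; blk < 3; ++blk) {
      const BlockDims& d = BD[blk];
      conv_forward(cc.block_in[blk], net.W[2 * blk], net.b[2 * blk], d,
                   d.Cin, d.Cout, B, cc.conv_out[2 * blk]);
      zero_pads(cc.conv_out[2 * blk], d, B);
      conv_forward(cc.conv_out[2 * blk], net.W[2 * blk + 1],
                   net.b[2 * blk + 1], d, d.Cout, d.Cout, B,
                   cc.conv_out[2 * blk + 1]);
      zero_pads(cc.conv_out[2 * blk + 1], d, B);
      // the block's 20% dropout layer, implemented channel-wise (the
      // convolutional convention): zeroing whole feature maps commutes
      // exactly with max-pooling, so applying the channel mask to the
      // pooled output is identical to applying it before the pool, and
      // training-time and inference-time activation scales agree.
      // Unit-wise variants mis-behave for a *regression* head: before
      // the pool, the max of 1/(1-p)-scaled dropped units is biased
      // upward (train/eval mis-calibration); after the pool, the last
      // block's mask lands directly on the fully-connected input and
      // destabilises the fit.
      fmat& pooled_out = (blk < 2) ? cc.block_in[blk + 1] : cc.pooled3;
      if (blk < 2)
        maxpool2(cc.conv_out[2 * blk + 1], d, B, true, &BD[blk + 1],
                 pooled_out, cc.amax[blk]);
      else
        maxpool2(cc.conv_out[5], d, B, false, nullptr, pooled_out,
                 cc.amax[2]);
      if (train && p_drop > 0) {
        fmat& M = cc.drop_mask[blk];
        const int C = pooled_out.n_rows;
        const uword Sout = pooled_out.n_cols / B;
        M.set_size(C, pooled_out.n_cols);
        const float scale = 1.0f / (1.0f - p_drop);
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < C; ++c) {
            const float v = (un(net.rng) < p_drop) ? 0.0f : scale;
            float* row = M.memptr() + c;
            for (uword j = 0; j < Sout; ++j)
              row[(size_t)((uword)b * Sout + j) * C] = v;
          }
        pooled_out %= M;
      }
    }
    // flatten (row = c + C*spatial) and the fully-connected head
    const int C = 64, HW3 = H3 * W3;
    cc.flat.set_size(FLAT, B);
    for (int bq = 0; bq < B; ++bq)
      for (int j = 0; j < HW3; ++j) {
        const float* ps = cc.pooled3.colptr((uword)bq * HW3 + j);
        float* pf = cc.flat.colptr(bq) + (size_t)C * j;
        std::memcpy(pf, ps, sizeof(float) * C);
      }
    cc.hid = net.W[6] * cc.flat;
    cc.hid.each_col() += net.b[6];
    cc.hid.transform([](float v) { return v > 0 ? v : 0.0f; });
    fmat out = net.W[7] * cc.hid;
    out.each_col() += net.b[7];
    return out;  // N_OUT x B
  }

  void backward(Net& net, const Cache& cc, const fmat& dout, int B,
                float p_drop, std::vector<fmat>& dW, std::vector<fvec>& db) {
    dW.assign(8, fmat()); db.assign(8, fvec());
    dW[7] = dout * cc.hid.t();
    db[7] = sum(dout, 1);
    fmat dhid = net.W[7].t() * dout;
    relu_mask(cc.hid, dhid);
    dW[6] = dhid * cc.flat.t();
    db[6] = sum(dhid, 1);
    fmat dflat = net.W[6].t() * dhid;
    // unflatten to the compact pooled-3 layout
    const int C = 64, HW3 = H3 * W3;
    fmat dpool(C, (uword)HW3 * B);
    for (int bq = 0; bq < B; ++bq)
      for (int j = 0; j < HW3; ++j)
        std::memcpy(dpool.colptr((uword)bq * HW3 + j),
                    dflat.colptr(bq) + (size_t)C * j, sizeof(float) * C);
    fmat dcur = dpool;     // gradient wrt the pool output of block blk
    fmat dact, dprev;
    for (int blk = 2; blk >= 0; --blk) {
      const BlockDims& d = BD[blk];
      if (p_drop > 0) dcur %= cc.drop_mask[blk];
      maxpool2_back(dcur, cc.amax[blk], d, B, blk < 2,
                    blk < 2 ? &BD[blk + 1] : nullptr, dact);
      relu_mask(cc.conv_out[2 * blk + 1], dact);
      conv_backward(cc.conv_out[2 * blk], net.W[2 * blk + 1], dact, d,
                    d.Cout, d.Cout, B, dW[2 * blk + 1], db[2 * blk + 1],
                    dprev, true);
      relu_mask(cc.conv_out[2 * blk], dprev);
      conv_backward(cc.block_in[blk], net.W[2 * blk], dprev, d,
                    d.Cin, d.Cout, B, dW[2 * blk], db[2 * blk],
                    dact, blk > 0);
      if (blk > 0) {
        // dact holds the gradient wrt this block's padded input, which
        // is the previous block's (padded) pool output
        dcur = dact;
      }
    }
  }
};

Engine& engine() {
  static Engine e;
  return e;
}

void net_from_list(const Rcpp::List& wl, Net& net) {
  net.W.resize(8); net.b.resize(8);
  Rcpp::List Ws = wl["W"], bs = wl["b"];
  for (int i = 0; i < 8; ++i) {
    net.W[i] = conv_to<fmat>::from(Rcpp::as<mat>(Ws[i]));
    net.b[i] = conv_to<fvec>::from(Rcpp::as<vec>(bs[i]));
  }
}

Rcpp::List net_to_list(const Net& net) {
  Rcpp::List Ws(8), bs(8);
  for (int i = 0; i < 8; ++i) {
    Ws[i] = Rcpp::wrap(conv_to<mat>::from(net.W[i]));
    bs[i] = Rcpp::wrap(conv_to<vec>::from(net.b[i]));
  }
  return Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs);
}

fmat eval_in_batches(Engine& eng, Net& net, const fmat& X,
                     const std::vector<int>& idx, int batch) {
  const int n = idx.size();
  fmat pred(N_OUT, n);
  Cache cc;
  for (int s = 0; s < n; s += batch) {
    const int B = std::min(batch, n - s);
    fmat xb(X.n_rows, B);
    for (int q = 0; q < B; ++q) xb.col(q) = X.col(idx[s + q]);
    pred.cols(s, s + B - 1) = eng.forward(net, xb, B, false, 0.0f, cc);
  }
  return pred;
}

fmat input_to_fmat(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 4 || dims[0] != IN_H || dims[1] != IN_W ||
      dims[2] != IN_C)
    Rcpp::stop("input stack must be 120 x 180 x 4 per sample");
  const int N = dims[3], D = IN_H * IN_W * IN_C;
  fmat X(D, N);
  const double* src = x.begin();
  for (int nq = 0; nq < N; ++nq) {
    float* dst = X.colptr(nq);
    const double* s = src + (size_t)nq * D;
    for (int d = 0; d < D; ++d) dst[d] = (float)s[d];
  }
  return X;
}

Rcpp::List train_core(const fmat& X, const Rcpp::NumericMatrix& y,
                      const Rcpp::IntegerVector& train_idx,
                      const Rcpp::IntegerVector& val_idx,
                      int epochs, int batch, double lr, double weight_decay,
                      double dropout, int seed);

} // namespace

// A dataset store holds the input stacks as single-precision columns in
// C++ memory (roughly a quarter of the equivalent R array), so the full
// 2000-pair training set fits comfortably; samples are appended one at
// a time while rendering.

// [[Rcpp::export(name = ".hp_store_create")]]
SEXP hp_store_create(int n) {
  fmat* X = new fmat(IN_H * IN_W * IN_C, n, fill::zeros);
  return Rcpp::XPtr<fmat>(X, true);
}

// [[Rcpp::export(name = ".hp_store_set")]]
void hp_store_set(SEXP ptr, int i, const Rcpp::NumericVector& stack) {
  Rcpp::XPtr<fmat> X(ptr);
  if (stack.size() != (R_xlen_t)X->n_rows)
    Rcpp::stop("stack has the wrong length");
  if (i < 1 || i > (int)X->n_cols) Rcpp::stop("index out of range");
  float* dst = X->colptr(i - 1);
  const double* src = stack.begin();
  for (uword d = 0; d < X->n_rows; ++d) dst[d] = (float)src[d];
}

// [[Rcpp::export(name = ".hp_store_n")]]
int hp_store_n(SEXP ptr) {
  Rcpp::XPtr<fmat> X(ptr);
  return X->n_cols;
}

// [[Rcpp::export(name = ".hp_cnn_train_ptr")]]
Rcpp::List hp_cnn_train_ptr(SEXP ptr, const Rcpp::NumericMatrix& y,
                            const Rcpp::IntegerVector& train_idx,
                            const Rcpp::IntegerVector& val_idx,
                            int epochs, int batch, double lr,
                            double weight_decay, double dropout, int seed) {
  Rcpp::XPtr<fmat> X(ptr);
  return train_core(*X, y, train_idx, val_idx, epochs, batch, lr,
                    weight_decay, dropout, seed);
}

// [[Rcpp::export(name = ".hp_cnn_predict_ptr")]]
Rcpp::NumericMatrix hp_cnn_predict_ptr(const Rcpp::List& weights, SEXP ptr,
                                       const Rcpp::IntegerVector& idx,
                                       int batch) {
  Rcpp::XPtr<fmat> X(ptr);
  Engine& eng = engine();
  Net net;
  net_from_list(weights, net);
  std::vector<int> ix(idx.begin(), idx.end());
  for (auto& i : ix) --i;
  fmat pred = eval_in_batches(eng, net, *X, ix, batch);
  const int n = ix.size();
  Rcpp::NumericMatrix out(n, N_OUT);
  for (int q = 0; q < n; ++q)
    for (int k = 0; k < N_OUT; ++k) out(q, k) = pred(k, q);
  return out;
}

// [[Rcpp::export(name = ".hp_cnn_train")]]
Rcpp::List hp_cnn_train(const Rcpp::NumericVector& x,
                        const Rcpp::NumericMatrix& y,
                        const Rcpp::IntegerVector& train_idx,
                        const Rcpp::IntegerVector& val_idx,
                        int epochs, int batch, double lr, double weight_decay,
                        double dropout, int seed) {
  fmat X = input_to_fmat(x);
  return train_core(X, y, train_idx, val_idx, epochs, batch, lr,
                    weight_decay, dropout, seed);
}

namespace {

Rcpp::List train_core(const fmat& X, const Rcpp::NumericMatrix& y,
                      const Rcpp::IntegerVector& train_idx,
                      const Rcpp::IntegerVector& val_idx,
                      int epochs, int batch, double lr, double weight_decay,
                      double dropout, int seed) {
  const int N = X.n_cols;
  fmat Y(N_OUT, N);
  for (int nq = 0; nq < N; ++nq)
    for (int k = 0; k < N_OUT; ++k) Y(k, nq) = (float)y(nq, k);

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  for (auto& i : tr) --i;
  for (auto& i : va) --i;

  Engine& eng = engine();
  Net net;
  net.init((unsigned)seed);

  std::vector<fmat> mW(8), vW(8);
  std::vector<fvec> mb(8), vb(8);
  for (int i = 0; i < 8; ++i) {
    mW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    vW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    mb[i].zeros(net.b[i].n_elem);
    vb[i].zeros(net.b[i].n_elem);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;

  Rcpp::NumericVector train_loss(epochs), val_loss(epochs);
  Cache cc;
  std::vector<fmat> dW; std::vector<fvec> db;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), net.rng);
    double ep_loss = 0; long n_seen = 0;
    for (size_t s = 0; s < tr.size(); s += batch) {
      const int B = std::min<size_t>(batch, tr.size() - s);
      fmat xb(X.n_rows, B), yb(N_OUT, B);
      for (int q = 0; q < B; ++q) {
        xb.col(q) = X.col(tr[s + q]);
        yb.col(q) = Y.col(tr[s + q]);
      }
      fmat out = eng.forward(net, xb, B, true, (float)dropout, cc);
      fmat diff = out - yb;
      ep_loss += accu(square(diff));
      n_seen += (long)B * N_OUT;
      fmat dout = diff * (2.0f / (B * N_OUT));
      eng.backward(net, cc, dout, B, (float)dropout, dW, db);
      ++step;
      const float bc1 = 1.0f - std::pow(b1, (float)step);
      const float bc2 = 1.0f - std::pow(b2, (float)step);
      for (int i = 0; i < 8; ++i) {
        dW[i] += (float)weight_decay * net.W[i];
        mW[i] = b1 * mW[i] + (1 - b1) * dW[i];
        vW[i] = b2 * vW[i] + (1 - b2) * square(dW[i]);
        net.W[i] -= (float)lr * (mW[i] / bc1) / (sqrt(vW[i] / bc2) + eps);
        db[i] += (float)weight_decay * net.b[i];
        mb[i] = b1 * mb[i] + (1 - b1) * db[i];
        vb[i] = b2 * vb[i] + (1 - b2) * square(db[i]);
        net.b[i] -= (float)lr * (mb[i] / bc1) / (sqrt(vb[i] / bc2) + eps);
      }
    }
    train_loss[ep] = ep_loss / n_seen;
    if (!va.empty()) {
      fmat pv = eval_in_batches(eng, net, X, va, batch);
      fmat yv(N_OUT, va.size());
      for (size_t q = 0; q < va.size(); ++q) yv.col(q) = Y.col(va[q]);
      val_loss[ep] = accu(square(pv - yv)) / (double)(va.size() * N_OUT);
    } else val_loss[ep] = NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(net),
    Rcpp::Named("train_loss") = train_loss,
    Rcpp::Named("val_loss") = val_loss);
}

} // namespace

// loss and analytic gradients for one batch (no dropout): used by the
// finite-difference gradient check in the test suite
// [[Rcpp::export(name = ".hp_cnn_grad")]]
Rcpp::List hp_cnn_grad(const Rcpp::List& weights,
                       const Rcpp::NumericVector& x,
                       const Rcpp::NumericMatrix& y) {
  fmat X = input_to_fmat(x);
  const int B = X.n_cols;
  fmat Y(N_OUT, B);
  for (int q = 0; q < B; ++q)
    for (int k = 0; k < N_OUT; ++k) Y(k, q) = (float)y(q, k);
  Engine& eng = engine();
  Net net;
  net_from_list(weights, net);
  Cache cc;
  fmat out = eng.forward(net, X, B, true, 0.0f, cc);
  fmat diff = out - Y;
  double loss = accu(square(diff)) / (double)(B * N_OUT);
  fmat dout = diff * (2.0f / (B * N_OUT));
  std::vector<fmat> dW; std::vector<fvec> db;
  eng.backward(net, cc, dout, B, 0.0f, dW, db);
  Rcpp::List dWs(8), dbs(8);
  for (int i = 0; i < 8; ++i) {
    dWs[i] = Rcpp::wrap(conv_to<mat>::from(dW[i]));
    dbs[i] = Rcpp::wrap(conv_to<vec>::from(db[i]));
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("dW") = dWs,
                            Rcpp::Named("db") = dbs);
}

// [[Rcpp::export(name = ".hp_cnn_predict")]]
Rcpp::NumericMatrix hp_cnn_predict(const Rcpp::List& weights,
                                   const Rcpp::NumericVector& x, int batch) {
  fmat X = input_to_fmat(x);
  const int N = X.n_cols;
  Engine& eng = engine();
  Net net;
  net_from_list(weights, net);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fmat pred = eval_in_batches(eng, net, X, idx, batch);
  Rcpp::NumericMatrix out(N, N_OUT);
  for (int nq = 0; nq < N; ++nq)
    for (int k = 0; k < N_OUT; ++k) out(nq, k) = pred(k, nq);
  return out;
}
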