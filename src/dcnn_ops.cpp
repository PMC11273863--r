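// Forward/backward/SGD engine for the fixed three-block convolutional
// network: conv(5x5, same) -> ReLU -> maxpool(2x2, floor), three times,
// then dropout -> dense(1000, ReLU) -> dense(2, softmax), trained with
// momentum SGD under an exponential learning-rate decay.
//
// Arithmetic is single precision (the standard for CNN training).
// Activations are channels-last: (H*W*batch x C) matrices with
// column-major spatial indexing s = i + j*H and sample-major row
// blocks. With this layout the im2col fill is contiguous memcpy runs
// and every convolution / dense step is one sgemm over the whole batch.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Single-precision gemm with accumulation (C = alpha*op(A)*op(B) +
// beta*C), used to fold the momentum decay and gradient accumulation of
// the weight-velocity update into one BLAS call without materializing
// the gradient. Resolved from the same BLAS Armadillo's fmat ops use.
extern "C" void sgemm_(const char* transa, const char* transb,
                       const int* m, const int* n, const int* k,
                       const float* alpha, const float* a, const int* lda,
                       const float* b, const int* ldb, const float* beta,
                       float* c, const int* ldc);

static void gemmAcc(char transa, char transb, int m, int n, int k,
                    float alpha, const float* A, int lda, const float* B,
                    int ldb, float beta, float* C, int ldc) {
  sgemm_(&transa, &transb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
         C, &ldc);
}

static const int K = 5;      // kernel edge
static const int P = 2;      // same padding for 5x5

// colT(n*HW + s, c*25 + (dj+2)*5 + (di+2)) = A(n*HW + (i+di) + (j+dj)*H, c),
// zero outside the image. Every (c,dj,di,n,j) cell is one contiguous
// run over i, filled by memcpy with zeroed borders.
static void im2colT(const fmat& A, int H, int W, int bs, fmat& colT) {
  const int C = A.n_cols, HW = H * W;
  colT.set_size((uword)HW * bs, (uword)C * K * K);
  for (int c = 0; c < C; ++c) {
    const float* src0 = A.colptr(c);
    for (int dj = -P; dj <= P; ++dj) {
      for (int di = -P; di <= P; ++di) {
        float* out = colT.colptr(c * K * K + (dj + P) * K + (di + P));
        for (int n = 0; n < bs; ++n) {
          const uword off = (uword)n * HW;
          for (int j = 0; j < W; ++j) {
            float* dst = out + off + (uword)j * H;
            const int jj = j + dj;
            if (jj < 0 || jj >= W) { std::memset(dst, 0, H * sizeof(float)); continue; }
            const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
            if (i0 > 0) std::memset(dst, 0, i0 * sizeof(float));
            std::memcpy(dst + i0, src0 + off + (i0 + di) + (uword)jj * H,
                        (i1 - i0) * sizeof(float));
            if (i1 < H) std::memset(dst + i1, 0, (H - i1) * sizeof(float));
          }
        }
      }
    }
  }
}

// Transpose of the above: accumulate column gradients back onto the
// activation gradient; contiguous vectorizable runs over i.
static void col2imT(const fmat& dcolT, int H, int W, int C, int bs,
                    fmat& dA) {
  const int HW = H * W;
  dA.zeros((uword)HW * bs, C);
  for (int c = 0; c < C; ++c) {
    float* dst0 = dA.colptr(c);
    for (int dj = -P; dj <= P; ++dj) {
      for (int di = -P; di <= P; ++di) {
        const float* in = dcolT.colptr(c * K * K + (dj + P) * K + (di + P));
        for (int n = 0; n < bs; ++n) {
          const uword off = (uword)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj;
            if (jj < 0 || jj >= W) continue;
            const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
            const float* src = in + off + (uword)j * H + i0;
            float* dst = dst0 + off + (i0 + di) + (uword)jj * H;
            for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
}

// 2x2 max-pool with floor rounding (partial windows dropped); idx keeps
// the winning source row for the backward scatter.
static void maxpool(const fmat& A, int H, int W, int bs, fmat& Pm,
                    umat& idx) {
  const int C = A.n_cols, Hp = H / 2, Wp = W / 2;
  Pm.set_size((uword)Hp * Wp * bs, C);
  idx.set_size((uword)Hp * Wp * bs, C);
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    float* pm = Pm.colptr(c);
    uword* ix = idx.colptr(c);
    for (int n = 0; n < bs; ++n) {
      const uword offIn = (uword)n * H * W, offOut = (uword)n * Hp * Wp;
      for (int jp = 0; jp < Wp; ++jp) {
        for (int ip = 0; ip < Hp; ++ip) {
          const uword s0 = offIn + 2 * ip + (uword)2 * jp * H;
          const uword cand[4] = { s0, s0 + 1, s0 + H, s0 + H + 1 };
          float best = a[cand[0]]; uword bi = cand[0];
          for (int q = 1; q < 4; ++q)
            if (a[cand[q]] > best) { best = a[cand[q]]; bi = cand[q]; }
          pm[offOut + ip + (uword)jp * Hp] = best;
          ix[offOut + ip + (uword)jp * Hp] = bi;
        }
      }
    }
  }
}

static void unpool(const fmat& dP, const umat& idx, uword nRows, fmat& dA) {
  dA.zeros(nRows, dP.n_cols);
  for (uword c = 0; c < dP.n_cols; ++c) {
    const float* dp = dP.colptr(c);
    const uword* ix = idx.colptr(c);
    float* da = dA.colptr(c);
    for (uword s = 0; s < dP.n_rows; ++s) da[ix[s]] += dp[s];
  }
}

// dZ *= (A > 0) elementwise, where A = relu(Z) was kept.
static void reluMask(fmat& dZ, const fmat& A) {
  const float* a = A.memptr();
  float* d = dZ.memptr();
  for (uword i = 0; i < dZ.n_elem; ++i)
    if (a[i] <= 0.0f) d[i] = 0.0f;
}

struct Net {
  fmat W1, W2, W3, W4, W5;
  fvec b1, b2, b3, b4, b5;
  int H0, W0d, H1, W1d, H2, W2d, H3, W3d, flat;

  void load(const Rcpp::List& w, int H, int Wd) {
    W1 = conv_to<fmat>::from(Rcpp::as<mat>(w["W1"]));
    W2 = conv_to<fmat>::from(Rcpp::as<mat>(w["W2"]));
    W3 = conv_to<fmat>::from(Rcpp::as<mat>(w["W3"]));
    W4 = conv_to<fmat>::from(Rcpp::as<mat>(w["W4"]));
    W5 = conv_to<fmat>::from(Rcpp::as<mat>(w["W5"]));
    b1 = conv_to<fvec>::from(Rcpp::as<vec>(w["b1"]));
    b2 = conv_to<fvec>::from(Rcpp::as<vec>(w["b2"]));
    b3 = conv_to<fvec>::from(Rcpp::as<vec>(w["b3"]));
    b4 = conv_to<fvec>::from(Rcpp::as<vec>(w["b4"]));
    b5 = conv_to<fvec>::from(Rcpp::as<vec>(w["b5"]));
    H0 = H; W0d = Wd;
    H1 = H0 / 2; W1d = W0d / 2;
    H2 = H1 / 2; W2d = W1d / 2;
    H3 = H2 / 2; W3d = W2d / 2;
    flat = 128 * H3 * W3d;
    if (H3 < 1 || W3d < 1)
      Rcpp::stop("input too small for three 2x2 poolings");
    if ((int)W4.n_cols != flat)
      Rcpp::stop("dense layer does not match flattened size");
  }

  Rcpp::List dump() const {
    return Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(W1),
      Rcpp::Named("b1") = conv_to<vec>::from(b1),
      Rcpp::Named("W2") = conv_to<mat>::from(W2),
      Rcpp::Named("b2") = conv_to<vec>::from(b2),
      Rcpp::Named("W3") = conv_to<mat>::from(W3),
      Rcpp::Named("b3") = conv_to<vec>::from(b3),
      Rcpp::Named("W4") = conv_to<mat>::from(W4),
      Rcpp::Named("b4") = conv_to<vec>::from(b4),
      Rcpp::Named("W5") = conv_to<mat>::from(W5),
      Rcpp::Named("b5") = conv_to<vec>::from(b5));
  }

  struct Cache {
    fmat A0, col1T, col2T, col3T;
    fmat A1, A2, A3, P1, P2, P3;   // post-ReLU conv maps, pooled maps
    umat i1, i2, i3;
    fmat F, mask, a4, p;
  };

  // Forward a batch; X slices (H x W doubles) indexed by ids.
  void forward(const cube& X, const uvec& ids, Cache& c, bool useMask) {
    const int bs = ids.n_elem;
    const uword HW = (uword)H0 * W0d;
    c.A0.set_size(HW * bs, 1);
    for (int n = 0; n < bs; ++n) {
      const double* src = X.slice_memptr(ids(n));
      float* dst = c.A0.memptr() + n * HW;
      for (uword i = 0; i < HW; ++i) dst[i] = (float)src[i];
    }

    im2colT(c.A0, H0, W0d, bs, c.col1T);
    c.A1 = c.col1T * W1.t();
    c.A1.each_row() += b1.t();
    c.A1.clamp(0.0f, datum::inf);
    maxpool(c.A1, H0, W0d, bs, c.P1, c.i1);

    im2colT(c.P1, H1, W1d, bs, c.col2T);
    c.A2 = c.col2T * W2.t();
    c.A2.each_row() += b2.t();
    c.A2.clamp(0.0f, datum::inf);
    maxpool(c.A2, H1, W1d, bs, c.P2, c.i2);

    im2colT(c.P2, H2, W2d, bs, c.col3T);
    c.A3 = c.col3T * W3.t();
    c.A3.each_row() += b3.t();
    c.A3.clamp(0.0f, datum::inf);
    maxpool(c.A3, H2, W2d, bs, c.P3, c.i3);

    // flatten sample blocks: F(s + c*s3, n) = P3(n*s3 + s, c)
    const uword s3 = (uword)H3 * W3d;
    c.F.set_size(flat, bs);
    for (int n = 0; n < bs; ++n)
      for (int ch = 0; ch < 128; ++ch)
        std::memcpy(c.F.colptr(n) + (uword)ch * s3,
                    c.P3.colptr(ch) + (uword)n * s3, s3 * sizeof(float));
    if (useMask) c.F %= c.mask;

    fmat z4 = W4 * c.F;
    z4.each_col() += b4;
    c.a4 = clamp(z4, 0.0f, datum::inf);
    fmat z5 = W5 * c.a4;
    z5.each_col() += b5;
    z5.each_row() -= max(z5, 0);
    c.p = exp(z5);
    c.p.each_row() /= sum(c.p, 0);
  }

  struct Vel {
    fmat W1, W2, W3, W4, W5;
    fvec b1, b2, b3, b4, b5;
    void zero(const Net& n) {
      W1.zeros(size(n.W1)); W2.zeros(size(n.W2)); W3.zeros(size(n.W3));
      W4.zeros(size(n.W4)); W5.zeros(size(n.W5));
      b1.zeros(size(n.b1)); b2.zeros(size(n.b2)); b3.zeros(size(n.b3));
      b4.zeros(size(n.b4)); b5.zeros(size(n.b5));
    }
  };

  struct BackWork {
    fmat d5, d4, dF, dP3, dA3, dcol3T, dP2, dA2, dcol2T, dP1, dA1;
  };

  // Backward pass fused with the momentum update: every weight velocity
  // is refreshed in place as vel = mom*vel - (lr/bs) * grad via one
  // accumulating gemm, then weights advance by the velocity.
  void backwardUpdate(const uvec& ids, const ivec& y, Cache& c,
                      bool useMask, Vel& v, BackWork& w, float lr,
                      float mom) {
    const int bs = ids.n_elem;
    const float a = -lr / bs;
    w.d5 = c.p;                            // 2 x bs
    for (int n = 0; n < bs; ++n) w.d5(y(ids(n)), n) -= 1.0f;
    gemmAcc('N', 'T', 2, W5.n_cols, bs, a, w.d5.memptr(), 2,
            c.a4.memptr(), c.a4.n_rows, mom, v.W5.memptr(), 2);
    v.b5 = mom * v.b5 + a * sum(w.d5, 1);

    w.d4 = W5.t() * w.d5;
    reluMask(w.d4, c.a4);
    gemmAcc('N', 'T', W4.n_rows, flat, bs, a, w.d4.memptr(), W4.n_rows,
            c.F.memptr(), flat, mom, v.W4.memptr(), W4.n_rows);
    v.b4 = mom * v.b4 + a * sum(w.d4, 1);

    w.dF = W4.t() * w.d4;                  // flat x bs
    if (useMask) w.dF %= c.mask;
    const uword s3 = (uword)H3 * W3d;
    w.dP3.set_size(s3 * bs, 128);
    for (int n = 0; n < bs; ++n)
      for (int ch = 0; ch < 128; ++ch)
        std::memcpy(w.dP3.colptr(ch) + (uword)n * s3,
                    w.dF.colptr(n) + (uword)ch * s3, s3 * sizeof(float));

    unpool(w.dP3, c.i3, c.A3.n_rows, w.dA3);
    reluMask(w.dA3, c.A3);
    gemmAcc('T', 'N', 128, W3.n_cols, w.dA3.n_rows, a, w.dA3.memptr(),
            w.dA3.n_rows, c.col3T.memptr(), c.col3T.n_rows, mom,
            v.W3.memptr(), 128);
    v.b3 = mom * v.b3 + a * conv_to<fvec>::from(sum(w.dA3, 0));
    w.dcol3T = w.dA3 * W3;

    col2imT(w.dcol3T, H2, W2d, 64, bs, w.dP2);
    unpool(w.dP2, c.i2, c.A2.n_rows, w.dA2);
    reluMask(w.dA2, c.A2);
    gemmAcc('T', 'N', 64, W2.n_cols, w.dA2.n_rows, a, w.dA2.memptr(),
            w.dA2.n_rows, c.col2T.memptr(), c.col2T.n_rows, mom,
            v.W2.memptr(), 64);
    v.b2 = mom * v.b2 + a * conv_to<fvec>::from(sum(w.dA2, 0));
    w.dcol2T = w.dA2 * W2;

    col2imT(w.dcol2T, H1, W1d, 32, bs, w.dP1);
    unpool(w.dP1, c.i1, c.A1.n_rows, w.dA1);
    reluMask(w.dA1, c.A1);
    gemmAcc('T', 'N', 32, W1.n_cols, w.dA1.n_rows, a, w.dA1.memptr(),
            w.dA1.n_rows, c.col1T.memptr(), c.col1T.n_rows, mom,
            v.W1.memptr(), 32);
    v.b1 = mom * v.b1 + a * conv_to<fvec>::from(sum(w.dA1, 0));

    W1 += v.W1; b1 += v.b1;
    W2 += v.W2; b2 += v.b2;
    W3 += v.W3; b3 += v.b3;
    W4 += v.W4; b4 += v.b4;
    W5 += v.W5; b5 += v.b5;
  }
};

// [[Rcpp::export]]
arma::mat cpp_dcnn_predict(const arma::cube& X, const Rcpp::List& weights) {
  Net net;
  net.load(weights, X.n_rows, X.n_cols);
  const int N = X.n_slices, chunk = 32;
  mat probs(N, 2);
  Net::Cache c;
  for (int at = 0; at < N; at += chunk) {
    const int bs = std::min(chunk, N - at);
    uvec ids = regspace<uvec>(at, at + bs - 1);
    net.forward(X, ids, c, false);
    for (int n = 0; n < bs; ++n) {
      probs(at + n, 0) = c.p(0, n);
      probs(at + n, 1) = c.p(1, n);
    }
  }
  return probs;
}

// [[Rcpp::export]]
Rcpp::List cpp_dcnn_train(const arma::cube& X, const arma::ivec& y,
                          const Rcpp::List& weights,
                          double lr0, double decayRate, double decaySteps,
                          bool staircase, double momentum, int batchSize,
                          int epochs, double dropoutRate,
                          const arma::imat& order, int dropoutSeed) {
  Net net;
  net.load(weights, X.n_rows, X.n_cols);
  const int N = X.n_slices;
  Net::Vel v;
  v.zero(net);
  Net::BackWork w;

  std::mt19937 rng(dropoutSeed);
  std::bernoulli_distribution keepDraw(1.0 - dropoutRate);
  const float scale = dropoutRate > 0 ? 1.0f / (1.0f - dropoutRate) : 1.0f;
  const bool useMask = dropoutRate > 0;

  vec lossHist(epochs, fill::zeros);
  long step = 0;
  Net::Cache c;

  for (int ep = 0; ep < epochs; ++ep) {
    double epLoss = 0.0;
    int done = 0;
    while (done < N) {
      const int bs = std::min(batchSize, N - done);
      uvec ids(bs);
      for (int b = 0; b < bs; ++b) ids(b) = order(ep, done + b);
      if (useMask) {
        c.mask.set_size(net.flat, bs);
        for (uword i = 0; i < c.mask.n_elem; ++i)
          c.mask(i) = keepDraw(rng) ? scale : 0.0f;
      }
      net.forward(X, ids, c, useMask);
      for (int b = 0; b < bs; ++b)
        epLoss += -std::log(std::max((double)c.p(y(ids(b)), b), 1e-12));
      const double expo = staircase ? std::floor(step / decaySteps)
                                    : step / decaySteps;
      const float lr = (float)(lr0 * std::pow(decayRate, expo));
      net.backwardUpdate(ids, y, c, useMask, v, w, lr, (float)momentum);
      ++step;
      done += bs;
    }
    lossHist(ep) = epLoss / N;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = net.dump(),
    Rcpp::Named("loss") = lossHist,
    Rcpp::Named("steps") = (double)step);
}
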