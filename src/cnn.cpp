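// Small CNN engine for sEMG image classification.
//
// Implements the two-block architecture used by both classifiers:
//   conv(32, 3x3, stride 1, pad 1) -> batch norm -> ReLU -> max pool
//   conv(64, 3x3, stride 1, no pad) -> batch norm -> ReLU -> max pool
//   flatten -> fully connected (hidden) -> ReLU -> fully connected -> softmax
// Pool window sizes are configurable (rows x cols), which is the only
// difference between the time-domain and spectral variants. Convolutions
// are evaluated as im2col + GEMM in single precision (the conventional
// inference/training precision for small CNNs; it halves memory traffic
// on feature maps that dominate the cost here), with batch-norm and ReLU
// fused into single passes. Training is mini-batch Adam on the
// cross-entropy loss. All randomness (init, shuffling) flows from explicit
// integer seeds through a private mt19937, so repeated runs are
// bit-identical.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int H, W;            // input image
  int C1, C2;          // conv filter counts
  int p1h, p1w, p2h, p2w;
  int fc, ncls;
  int P1;              // conv1 output positions (pad 1: H*W)
  int Hp1, Wp1;        // after pool1
  int H2, W2, P2;      // conv2 output (valid)
  int Hp2, Wp2, P3;    // after pool2
  int flat;
};

Dims make_dims(const Rcpp::List& cfg) {
  Dims d;
  d.H = cfg["H"]; d.W = cfg["W"];
  d.C1 = cfg["C1"]; d.C2 = cfg["C2"];
  d.p1h = cfg["p1h"]; d.p1w = cfg["p1w"];
  d.p2h = cfg["p2h"]; d.p2w = cfg["p2w"];
  d.fc = cfg["fc"]; d.ncls = cfg["n_classes"];
  d.P1 = d.H * d.W;
  d.Hp1 = d.H / d.p1h; d.Wp1 = d.W / d.p1w;
  d.H2 = d.Hp1 - 2; d.W2 = d.Wp1 - 2;
  if (d.H2 < 1 || d.W2 < 1)
    Rcpp::stop("input collapses before the second convolution (rows=%d, cols=%d after pool 1)",
               d.Hp1, d.Wp1);
  d.P2 = d.H2 * d.W2;
  d.Hp2 = d.H2 / d.p2h; d.Wp2 = d.W2 / d.p2w;
  if (d.Hp2 < 1 || d.Wp2 < 1)
    Rcpp::stop("input collapses at the second pooling layer");
  d.P3 = d.Hp2 * d.Wp2;
  d.flat = d.C2 * d.P3;
  return d;
}

// patches of a single-channel image with 1-pixel zero padding -> 9 x H*W,
// written into columns [off, off + H*W) of X
void im2col_pad1(const fmat& img, int H, int W, fmat& X, int off) {
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      float* col = X.colptr(off + j * H + i);
      for (int kj = 0; kj < 3; ++kj) {
        const int jj = j + kj - 1;
        for (int ki = 0; ki < 3; ++ki) {
          const int ii = i + ki - 1;
          col[kj * 3 + ki] =
            (ii < 0 || ii >= H || jj < 0 || jj >= W) ? 0.0f : img.at(ii, jj);
        }
      }
    }
  }
}

// patches of a C-channel feature map (stored C x Hp*Wp, cols [in_off..)),
// valid 3x3 conv -> C*9 columns written at [out_off, out_off + H2*W2)
void im2col_valid(const fmat& A, int in_off, int Hp, int C, int H2, int W2,
                  fmat& X, int out_off) {
  for (int j = 0; j < W2; ++j) {
    for (int i = 0; i < H2; ++i) {
      float* col = X.colptr(out_off + j * H2 + i);
      for (int kj = 0; kj < 3; ++kj) {
        for (int ki = 0; ki < 3; ++ki) {
          const float* src = A.colptr(in_off + (j + kj) * Hp + (i + ki));
          float* dst = col + kj * 3 + ki;
          for (int c = 0; c < C; ++c) dst[c * 9] = src[c];
        }
      }
    }
  }
}

// scatter-add transpose of im2col_valid
void col2im_valid(const fmat& dX, int src_off, int Hp, int C, int H2, int W2,
                  fmat& dA, int dst_off) {
  for (int j = 0; j < W2; ++j) {
    for (int i = 0; i < H2; ++i) {
      const float* col = dX.colptr(src_off + j * H2 + i);
      for (int kj = 0; kj < 3; ++kj) {
        for (int ki = 0; ki < 3; ++ki) {
          float* dst = dA.colptr(dst_off + (j + kj) * Hp + (i + ki));
          const float* src = col + kj * 3 + ki;
          for (int c = 0; c < C; ++c) dst[c] += src[c * 9];
        }
      }
    }
  }
}

// non-overlapping max pool on one image slab (C x Hin*Win cols)
void maxpool(const fmat& A, int Hin, int ph, int pw, int C, int Hp, int Wp,
             fmat& out, Mat<unsigned>& argmax, int out_off, int in_off) {
  for (int oj = 0; oj < Wp; ++oj) {
    for (int oi = 0; oi < Hp; ++oi) {
      const int q = out_off + oj * Hp + oi;
      float* po = out.colptr(q);
      unsigned* pa = argmax.colptr(q);
      for (int c = 0; c < C; ++c) { po[c] = -datum::inf; pa[c] = 0; }
      for (int kj = 0; kj < pw; ++kj) {
        for (int ki = 0; ki < ph; ++ki) {
          const int p = (oj * pw + kj) * Hin + (oi * ph + ki);
          const float* pc = A.colptr(in_off + p);
          for (int c = 0; c < C; ++c) {
            if (pc[c] > po[c]) { po[c] = pc[c]; pa[c] = (unsigned)p; }
          }
        }
      }
    }
  }
}

// Batch norm + ReLU, training mode, fused: Z is overwritten with xhat,
// A receives relu(gamma * xhat + beta); running stats updated.
void bn_relu_train(fmat& Z, const fvec& g, const fvec& be, fmat& A,
                   fvec& mu, fvec& invstd, fvec& rm, fvec& rv,
                   float momentum, float eps) {
  const int C = Z.n_rows;
  const uword N = Z.n_cols;
  fvec s1(C, fill::zeros), s2(C, fill::zeros);
  for (uword j = 0; j < N; ++j) {
    const float* z = Z.colptr(j);
    for (int i = 0; i < C; ++i) { s1[i] += z[i]; s2[i] += z[i] * z[i]; }
  }
  mu = s1 / (float)N;
  fvec va = s2 / (float)N - square(mu);
  va.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  invstd = 1.0f / sqrt(va + eps);
  A.set_size(C, N);
  for (uword j = 0; j < N; ++j) {
    float* z = Z.colptr(j);
    float* a = A.colptr(j);
    for (int i = 0; i < C; ++i) {
      const float xh = (z[i] - mu[i]) * invstd[i];
      z[i] = xh;
      const float v = g[i] * xh + be[i];
      a[i] = v > 0.0f ? v : 0.0f;
    }
  }
  rm = (1.0f - momentum) * rm + momentum * mu;
  rv = (1.0f - momentum) * rv + momentum * va;
}

// Backward through ReLU + batch norm, fused. dA is the gradient w.r.t. the
// ReLU output and is overwritten with the gradient w.r.t. Z; A is the ReLU
// output (mask), xhat the stored normalized input.
void bn_relu_backward(fmat& dA, const fmat& A, const fmat& xhat,
                      const fvec& g, const fvec& invstd,
                      fvec& dg, fvec& dbe) {
  const int C = dA.n_rows;
  const uword N = dA.n_cols;
  dg.zeros(C); dbe.zeros(C);
  for (uword j = 0; j < N; ++j) {
    float* d = dA.colptr(j);
    const float* a = A.colptr(j);
    const float* xh = xhat.colptr(j);
    for (int i = 0; i < C; ++i) {
      if (a[i] <= 0.0f) d[i] = 0.0f;
      dbe[i] += d[i];
      dg[i] += d[i] * xh[i];
    }
  }
  const fvec m1 = dbe / (float)N;
  const fvec m2 = dg / (float)N;
  for (uword j = 0; j < N; ++j) {
    float* d = dA.colptr(j);
    const float* xh = xhat.colptr(j);
    for (int i = 0; i < C; ++i) {
      d[i] = g[i] * invstd[i] * (d[i] - m1[i] - xh[i] * m2[i]);
    }
  }
}

struct Params {
  fmat W1, W2, W3, W4;
  fvec b1, b2, b3, b4, g1, be1, rm1, rv1, g2, be2, rm2, rv2;
};

fmat as_f(const Rcpp::List& w, const char* nm) {
  return conv_to<fmat>::from(Rcpp::as<mat>(w[nm]));
}
fvec as_fv(const Rcpp::List& w, const char* nm) {
  return conv_to<fvec>::from(Rcpp::as<vec>(w[nm]));
}

Params params_from_list(const Rcpp::List& w) {
  Params p;
  p.W1 = as_f(w, "W1"); p.b1 = as_fv(w, "b1");
  p.g1 = as_fv(w, "g1"); p.be1 = as_fv(w, "be1");
  p.rm1 = as_fv(w, "rm1"); p.rv1 = as_fv(w, "rv1");
  p.W2 = as_f(w, "W2"); p.b2 = as_fv(w, "b2");
  p.g2 = as_fv(w, "g2"); p.be2 = as_fv(w, "be2");
  p.rm2 = as_fv(w, "rm2"); p.rv2 = as_fv(w, "rv2");
  p.W3 = as_f(w, "W3"); p.b3 = as_fv(w, "b3");
  p.W4 = as_f(w, "W4"); p.b4 = as_fv(w, "b4");
  return p;
}

Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = conv_to<mat>::from(p.W1),
    Rcpp::Named("b1") = conv_to<vec>::from(p.b1),
    Rcpp::Named("g1") = conv_to<vec>::from(p.g1),
    Rcpp::Named("be1") = conv_to<vec>::from(p.be1),
    Rcpp::Named("rm1") = conv_to<vec>::from(p.rm1),
    Rcpp::Named("rv1") = conv_to<vec>::from(p.rv1),
    Rcpp::Named("W2") = conv_to<mat>::from(p.W2),
    Rcpp::Named("b2") = conv_to<vec>::from(p.b2),
    Rcpp::Named("g2") = conv_to<vec>::from(p.g2),
    Rcpp::Named("be2") = conv_to<vec>::from(p.be2),
    Rcpp::Named("rm2") = conv_to<vec>::from(p.rm2),
    Rcpp::Named("rv2") = conv_to<vec>::from(p.rv2),
    Rcpp::Named("W3") = conv_to<mat>::from(p.W3),
    Rcpp::Named("b3") = conv_to<vec>::from(p.b3),
    Rcpp::Named("W4") = conv_to<mat>::from(p.W4),
    Rcpp::Named("b4") = conv_to<vec>::from(p.b4));
}

void softmax_cols(fmat& L) {
  for (uword j = 0; j < L.n_cols; ++j) {
    fvec c = L.col(j);
    c -= c.max();
    c = exp(c);
    L.col(j) = c / accu(c);
  }
}

struct Adam {
  fmat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4;
  fvec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4;
  fvec mg1, vg1, mbe1, vbe1, mg2, vg2, mbe2, vbe2;
  long t = 0;
  void init(const Params& p) {
    mW1.zeros(size(p.W1)); vW1.zeros(size(p.W1));
    mW2.zeros(size(p.W2)); vW2.zeros(size(p.W2));
    mW3.zeros(size(p.W3)); vW3.zeros(size(p.W3));
    mW4.zeros(size(p.W4)); vW4.zeros(size(p.W4));
    mb1.zeros(size(p.b1)); vb1.zeros(size(p.b1));
    mb2.zeros(size(p.b2)); vb2.zeros(size(p.b2));
    mb3.zeros(size(p.b3)); vb3.zeros(size(p.b3));
    mb4.zeros(size(p.b4)); vb4.zeros(size(p.b4));
    mg1.zeros(size(p.g1)); vg1.zeros(size(p.g1));
    mbe1.zeros(size(p.be1)); vbe1.zeros(size(p.be1));
    mg2.zeros(size(p.g2)); vg2.zeros(size(p.g2));
    mbe2.zeros(size(p.be2)); vbe2.zeros(size(p.be2));
  }
};

template <typename T>
void adam_step(T& w, const T& g, T& m, T& v, float lr, float b1, float b2,
               float eps, long t) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

// Inference-mode batch norm + ReLU, fused single pass (Z overwritten).
void bn_relu_infer(fmat& Z, const fvec& g, const fvec& be, const fvec& rm,
                   const fvec& rv, float eps) {
  const int C = Z.n_rows;
  fvec sc(C), sh(C);
  for (int i = 0; i < C; ++i) {
    sc[i] = g[i] / std::sqrt(rv[i] + eps);
    sh[i] = be[i] - rm[i] * sc[i];
  }
  for (uword j = 0; j < Z.n_cols; ++j) {
    float* z = Z.colptr(j);
    for (int i = 0; i < C; ++i) {
      const float v = sc[i] * z[i] + sh[i];
      z[i] = v > 0.0f ? v : 0.0f;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_init(Rcpp::List cfg, int seed) {
  Dims d = make_dims(cfg);
  std::mt19937 gen(static_cast<unsigned>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);
  auto fill = [&](fmat& M, double sd) {
    for (uword j = 0; j < M.n_cols; ++j)
      for (uword i = 0; i < M.n_rows; ++i)
        M(i, j) = (float)(nd(gen) * sd);
  };
  Params p;
  p.W1.set_size(d.C1, 9); fill(p.W1, std::sqrt(2.0 / 9.0));
  p.W2.set_size(d.C2, d.C1 * 9); fill(p.W2, std::sqrt(2.0 / (d.C1 * 9.0)));
  p.W3.set_size(d.fc, d.flat); fill(p.W3, std::sqrt(2.0 / d.flat));
  p.W4.set_size(d.ncls, d.fc); fill(p.W4, std::sqrt(2.0 / d.fc));
  p.b1.zeros(d.C1); p.b2.zeros(d.C2); p.b3.zeros(d.fc); p.b4.zeros(d.ncls);
  p.g1.ones(d.C1); p.be1.zeros(d.C1); p.rm1.zeros(d.C1); p.rv1.ones(d.C1);
  p.g2.ones(d.C2); p.be2.zeros(d.C2); p.rm2.zeros(d.C2); p.rv2.ones(d.C2);
  return params_to_list(p);
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_cnn_check_shapes(Rcpp::List cfg) {
  Dims d = make_dims(cfg);
  return Rcpp::IntegerVector::create(
    Rcpp::Named("pool1_rows") = d.Hp1, Rcpp::Named("pool1_cols") = d.Wp1,
    Rcpp::Named("conv2_rows") = d.H2, Rcpp::Named("conv2_cols") = d.W2,
    Rcpp::Named("pool2_rows") = d.Hp2, Rcpp::Named("pool2_cols") = d.Wp2,
    Rcpp::Named("flatten") = d.flat);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List weights, Rcpp::List cfg, arma::cube X,
                         Rcpp::IntegerVector y, int epochs, int batch,
                         double lr, int seed) {
  Dims d = make_dims(cfg);
  const int N = X.n_slices;
  if ((int)X.n_rows != d.H || (int)X.n_cols != d.W)
    Rcpp::stop("image dimensions do not match the model");
  fcube Xf = conv_to<fcube>::from(X);
  Params p = params_from_list(weights);
  Adam ad; ad.init(p);
  const float beta1 = 0.9f, beta2 = 0.999f, adam_eps = 1e-8f, bn_eps = 1e-5f,
              bn_mom = 0.1f;
  const float flr = (float)lr;
  std::mt19937 gen(static_cast<unsigned>(seed));
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  vec ep_loss(epochs, fill::zeros), ep_acc(epochs, fill::zeros);
  const int B0 = std::min(batch, N);
  const int Q1 = d.Hp1 * d.Wp1;

  fmat X1all, X2all, Z1, A1, A1p, Z2, A2, A2p, F, H1, logits;
  Mat<unsigned> idx1, idx2;
  fvec mu1, is1, mu2, is2;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), gen);
    double tot_loss = 0; int tot_correct = 0;
    for (int start = 0; start < N; start += B0) {
      const int B = std::min(B0, N - start);
      // ---- forward ----
      X1all.set_size(9, d.P1 * B);
      for (int b = 0; b < B; ++b)
        im2col_pad1(Xf.slice(order[start + b]), d.H, d.W, X1all, b * d.P1);
      Z1 = p.W1 * X1all;
      Z1.each_col() += p.b1;
      bn_relu_train(Z1, p.g1, p.be1, A1, mu1, is1, p.rm1, p.rv1, bn_mom,
                    bn_eps);                      // Z1 now holds xhat1
      A1p.set_size(d.C1, Q1 * B);
      idx1.set_size(d.C1, Q1 * B);
      for (int b = 0; b < B; ++b)
        maxpool(A1, d.H, d.p1h, d.p1w, d.C1, d.Hp1, d.Wp1, A1p, idx1,
                b * Q1, b * d.P1);
      X2all.set_size(d.C1 * 9, d.P2 * B);
      for (int b = 0; b < B; ++b)
        im2col_valid(A1p, b * Q1, d.Hp1, d.C1, d.H2, d.W2, X2all, b * d.P2);
      Z2 = p.W2 * X2all;
      Z2.each_col() += p.b2;
      bn_relu_train(Z2, p.g2, p.be2, A2, mu2, is2, p.rm2, p.rv2, bn_mom,
                    bn_eps);                      // Z2 now holds xhat2
      A2p.set_size(d.C2, d.P3 * B);
      idx2.set_size(d.C2, d.P3 * B);
      for (int b = 0; b < B; ++b)
        maxpool(A2, d.H2, d.p2h, d.p2w, d.C2, d.Hp2, d.Wp2, A2p, idx2,
                b * d.P3, b * d.P2);
      F = fmat(A2p.memptr(), d.flat, B);          // flatten view (copy)
      H1 = p.W3 * F;
      H1.each_col() += p.b3;
      H1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      logits = p.W4 * H1;
      logits.each_col() += p.b4;
      fmat prob = logits;
      softmax_cols(prob);

      for (int b = 0; b < B; ++b) {
        const int yb = y[order[start + b]];
        tot_loss += -std::log(std::max((double)prob(yb, b), 1e-12));
        if ((int)prob.col(b).index_max() == yb) ++tot_correct;
      }

      // ---- backward ----
      fmat dlog = prob;
      for (int b = 0; b < B; ++b) dlog(y[order[start + b]], b) -= 1.0f;
      dlog /= (float)B;
      fmat dW4 = dlog * H1.t();
      fvec db4 = sum(dlog, 1);
      fmat dH1 = p.W4.t() * dlog;
      dH1.elem(find(H1 <= 0.0f)).zeros();
      fmat dW3 = dH1 * F.t();
      fvec db3 = sum(dH1, 1);
      fmat dF = p.W3.t() * dH1;
      fmat dA2(d.C2, d.P2 * B, fill::zeros);      // pool2 backward (scatter)
      {
        const fmat dA2p(dF.memptr(), d.C2, d.P3 * B, false, true);
        for (int b = 0; b < B; ++b) {
          for (int q = 0; q < d.P3; ++q) {
            const float* src = dA2p.colptr(b * d.P3 + q);
            const unsigned* am = idx2.colptr(b * d.P3 + q);
            for (int c = 0; c < d.C2; ++c)
              dA2.at(c, b * d.P2 + am[c]) += src[c];
          }
        }
      }
      fvec dg2, dbe2;
      bn_relu_backward(dA2, A2, Z2, p.g2, is2, dg2, dbe2);  // dA2 -> dZ2
      fmat dW2 = dA2 * X2all.t();
      fvec db2 = sum(dA2, 1);
      fmat dX2 = p.W2.t() * dA2;
      fmat dA1p(d.C1, Q1 * B, fill::zeros);
      for (int b = 0; b < B; ++b)
        col2im_valid(dX2, b * d.P2, d.Hp1, d.C1, d.H2, d.W2, dA1p, b * Q1);
      fmat dA1(d.C1, d.P1 * B, fill::zeros);      // pool1 backward
      for (int b = 0; b < B; ++b) {
        for (int q = 0; q < Q1; ++q) {
          const float* src = dA1p.colptr(b * Q1 + q);
          const unsigned* am = idx1.colptr(b * Q1 + q);
          for (int c = 0; c < d.C1; ++c)
            dA1.at(c, b * d.P1 + am[c]) += src[c];
        }
      }
      fvec dg1, dbe1;
      bn_relu_backward(dA1, A1, Z1, p.g1, is1, dg1, dbe1);  // dA1 -> dZ1
      fmat dW1 = dA1 * X1all.t();
      fvec db1 = sum(dA1, 1);

      ++ad.t;
      adam_step(p.W1, dW1, ad.mW1, ad.vW1, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.b1, db1, ad.mb1, ad.vb1, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.g1, dg1, ad.mg1, ad.vg1, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.be1, dbe1, ad.mbe1, ad.vbe1, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.W2, dW2, ad.mW2, ad.vW2, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.b2, db2, ad.mb2, ad.vb2, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.g2, dg2, ad.mg2, ad.vg2, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.be2, dbe2, ad.mbe2, ad.vbe2, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.W3, dW3, ad.mW3, ad.vW3, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.b3, db3, ad.mb3, ad.vb3, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.W4, dW4, ad.mW4, ad.vW4, flr, beta1, beta2, adam_eps, ad.t);
      adam_step(p.b4, db4, ad.mb4, ad.vb4, flr, beta1, beta2, adam_eps, ad.t);
    }
    ep_loss(ep) = tot_loss / N;
    ep_acc(ep) = (double)tot_correct / N;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = params_to_list(p),
    Rcpp::Named("loss") = ep_loss, Rcpp::Named("accuracy") = ep_acc);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(Rcpp::List weights, Rcpp::List cfg, arma::cube X) {
  Dims d = make_dims(cfg);
  const int N = X.n_slices;
  if ((int)X.n_rows != d.H || (int)X.n_cols != d.W)
    Rcpp::stop("image dimensions do not match the model");
  Params p = params_from_list(weights);
  const float bn_eps = 1e-5f;
  mat out(N, d.ncls);
  const int CH = 64;  // evaluate in chunks to bound memory
  const int Q1 = d.Hp1 * d.Wp1;
  Mat<unsigned> idx1, idx2;
  for (int start = 0; start < N; start += CH) {
    const int B = std::min(CH, N - start);
    fmat X1all(9, d.P1 * B);
    for (int b = 0; b < B; ++b) {
      fmat img = conv_to<fmat>::from(X.slice(start + b));
      im2col_pad1(img, d.H, d.W, X1all, b * d.P1);
    }
    fmat Z1 = p.W1 * X1all;
    Z1.each_col() += p.b1;
    bn_relu_infer(Z1, p.g1, p.be1, p.rm1, p.rv1, bn_eps);
    fmat A1p(d.C1, Q1 * B);
    idx1.set_size(d.C1, Q1 * B);
    for (int b = 0; b < B; ++b)
      maxpool(Z1, d.H, d.p1h, d.p1w, d.C1, d.Hp1, d.Wp1, A1p, idx1,
              b * Q1, b * d.P1);
    fmat X2all(d.C1 * 9, d.P2 * B);
    for (int b = 0; b < B; ++b)
      im2col_valid(A1p, b * Q1, d.Hp1, d.C1, d.H2, d.W2, X2all, b * d.P2);
    fmat Z2 = p.W2 * X2all;
    Z2.each_col() += p.b2;
    bn_relu_infer(Z2, p.g2, p.be2, p.rm2, p.rv2, bn_eps);
    fmat A2p(d.C2, d.P3 * B);
    idx2.set_size(d.C2, d.P3 * B);
    for (int b = 0; b < B; ++b)
      maxpool(Z2, d.H2, d.p2h, d.p2w, d.C2, d.Hp2, d.Wp2, A2p, idx2,
              b * d.P3, b * d.P2);
    fmat F(A2p.memptr(), d.flat, B);
    fmat H1 = p.W3 * F;
    H1.each_col() += p.b3;
    H1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    fmat logits = p.W4 * H1;
    logits.each_col() += p.b4;
    softmax_cols(logits);
    out.rows(start, start + B - 1) = conv_to<mat>::from(logits.t());
  }
  return out;
}
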