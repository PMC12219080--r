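// Compiled training/inference engine for the hybrid BiLSTM-CNN classifier.
// Single-precision throughout; all randomness (init, shuffling, dropout)
// comes from one explicit Mersenne-Twister stream so runs are bit-for-bit
// reproducible for a given seed.
//
// Feature maps are stored as (Ho*Wo) x channels matrices (column = one map,
// column-major), which is byte-identical to the (Ho, Wo, C) cube layout but
// lets every layer run as plain GEMM on preallocated buffers.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cmath>

using namespace arma;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(unsigned int seed) : gen(seed) {}
  double unif() {  // (0, 1)
    return (static_cast<double>(gen()) + 0.5) / 4294967296.0;
  }
  double gauss() {  // Box-Muller, implementation-independent
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  std::vector<int> permutation(int n) {
    std::vector<int> p(n);
    for (int i = 0; i < n; ++i) p[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif() * (i + 1));
      if (j > i) j = i;
      std::swap(p[i], p[j]);
    }
    return p;
  }
};

struct Spec {
  int input_size;
  std::vector<int> kernels, channels;
  std::vector<bool> pools;
  std::vector<double> conv_dropout;
  int resample_after1, pool_k, pool_s;
  int lstm_hidden, dense_units, n_classes, fusion_dim;
  double dropout_lstm;
};

Spec parse_spec(const Rcpp::List& s) {
  Spec sp;
  sp.input_size = Rcpp::as<int>(s["input_size"]);
  sp.kernels = Rcpp::as<std::vector<int>>(s["conv_kernels"]);
  sp.channels = Rcpp::as<std::vector<int>>(s["conv_channels"]);
  Rcpp::LogicalVector pl = s["conv_pools"];
  for (int i = 0; i < pl.size(); ++i) sp.pools.push_back(pl[i] == TRUE);
  sp.conv_dropout = Rcpp::as<std::vector<double>>(s["conv_dropout"]);
  sp.resample_after1 = Rcpp::as<int>(s["resample_after1"]);
  sp.pool_k = Rcpp::as<int>(s["pool_kernel"]);
  sp.pool_s = Rcpp::as<int>(s["pool_stride"]);
  sp.lstm_hidden = Rcpp::as<int>(s["lstm_hidden"]);
  sp.dropout_lstm = Rcpp::as<double>(s["dropout_lstm"]);
  sp.dense_units = Rcpp::as<int>(s["dense_units"]);
  sp.n_classes = Rcpp::as<int>(s["n_classes"]);
  sp.fusion_dim = Rcpp::as<int>(s["fusion_dim"]);
  return sp;
}

// bilinear pixel-centre resampling weights, matching the R-side convention
fmat bilinear_w(int n_in, int n_out) {
  fmat W(n_out, n_in, fill::zeros);
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) * static_cast<double>(n_in) / n_out - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int lo = static_cast<int>(std::floor(src));
    int hi = std::min(lo + 1, n_in - 1);
    double f = src - lo;
    W(i, lo) += static_cast<float>(1.0 - f);
    W(i, hi) += static_cast<float>(f);
  }
  return W;
}

// one conv block's persistent buffers (all reused across samples)
struct BlockBuf {
  fmat A;          // im2col, (Ho*Wo) x (k*k*Cin)
  fmat Z;          // conv output post-relu (pre-resample for block 1)
  fmat R;          // post-resample maps (block 1 only)
  fmat out;        // block output after pool/dropout
  fmat drop;       // dropout mask on `out`
  umat argmax;     // pool argmax (linear index into pre-pool map)
  fmat dZ, dpre, dA, dout;  // backward scratch
  int Hc = 0, Wc = 0;   // conv output spatial dims
  int Hq = 0, Wq = 0;   // post-(resample+pool) spatial dims
};

struct Net {
  Spec sp;
  std::vector<fmat> P;
  std::vector<BlockBuf> bb;
  fmat Wr;                 // block-1 resampling weights
  fmat x0;                 // input (H*W) x 3
  fvec seq, dseq;
  struct LstmCache {
    fmat i, f, g, o, c, tc, h;
  } lf, lb;
  fvec hcat, hdrop, dropmask_lstm, fused, a1, a1pre, z2, prob;

  int n_conv() const { return static_cast<int>(sp.kernels.size()); }

  void init_params(Rng& rng) {
    P.clear();
    int cin = 3;
    for (int b = 0; b < n_conv(); ++b) {
      int k = sp.kernels[b], cout = sp.channels[b];
      fmat W(k * k * cin, cout);
      double sd = std::sqrt(2.0 / (k * k * cin));
      for (uword t = 0; t < W.n_elem; ++t)
        W(t) = static_cast<float>(sd * rng.gauss());
      P.push_back(W);
      P.push_back(fmat(1, cout, fill::zeros));
      cin = cout;
    }
    int h = sp.lstm_hidden;
    double a = 1.0 / std::sqrt(static_cast<double>(h));
    for (int d = 0; d < 2; ++d) {
      fmat Wx(4 * h, 1), Wh(4 * h, h), bv(4 * h, 1, fill::zeros);
      for (uword t = 0; t < Wx.n_elem; ++t)
        Wx(t) = static_cast<float>(a * (2 * rng.unif() - 1));
      for (uword t = 0; t < Wh.n_elem; ++t)
        Wh(t) = static_cast<float>(a * (2 * rng.unif() - 1));
      for (int t = h; t < 2 * h; ++t) bv(t) = 1.0f;  // forget-gate bias
      P.push_back(Wx); P.push_back(Wh); P.push_back(bv);
    }
    int din = 2 * h + sp.fusion_dim;
    fmat W1(din, sp.dense_units);
    double sd1 = std::sqrt(2.0 / din);
    for (uword t = 0; t < W1.n_elem; ++t)
      W1(t) = static_cast<float>(sd1 * rng.gauss());
    P.push_back(W1);
    P.push_back(fmat(1, sp.dense_units, fill::zeros));
    fmat W2(sp.dense_units, sp.n_classes);
    double sd2 = std::sqrt(1.0 / sp.dense_units);
    for (uword t = 0; t < W2.n_elem; ++t)
      W2(t) = static_cast<float>(sd2 * rng.gauss());
    P.push_back(W2);
    P.push_back(fmat(1, sp.n_classes, fill::zeros));
  }

  // im2col from an (Hin*Win) x Cin matrix of maps into A ((Ho*Wo) x k*k*Cin)
  static void im2col(const fmat& X, int Hin, int Win, int k, fmat& A,
                     int& Ho, int& Wo) {
    Ho = Hin - k + 1; Wo = Win - k + 1;
    int Cin = X.n_cols;
    A.set_size(Ho * Wo, k * k * Cin);
    for (int c = 0; c < Cin; ++c) {
      const float* src = X.colptr(c);
      for (int kr = 0; kr < k; ++kr)
        for (int kc = 0; kc < k; ++kc) {
          float* dst = A.colptr((c * k + kr) * k + kc);
          for (int j = 0; j < Wo; ++j) {
            const float* s = src + (kc + j) * Hin + kr;
            std::memcpy(dst + j * Ho, s, sizeof(float) * Ho);
          }
        }
    }
  }

  static void col2im(const fmat& dA, int Hin, int Win, int Cin, int k,
                     fmat& dX) {
    int Ho = Hin - k + 1, Wo = Win - k + 1;
    dX.set_size(Hin * Win, Cin);
    dX.zeros();
    for (int c = 0; c < Cin; ++c) {
      float* dst = dX.colptr(c);
      for (int kr = 0; kr < k; ++kr)
        for (int kc = 0; kc < k; ++kc) {
          const float* src = dA.colptr((c * k + kr) * k + kc);
          for (int j = 0; j < Wo; ++j) {
            float* d = dst + (kc + j) * Hin + kr;
            const float* s = src + j * Ho;
            for (int i = 0; i < Ho; ++i) d[i] += s[i];
          }
        }
    }
  }

  void maxpool(const fmat& X, int Hin, int Win, int k, int s, fmat& out,
               umat& arg, int& Ho, int& Wo) {
    Ho = (Hin - k) / s + 1;
    Wo = (Win - k) / s + 1;
    int C = X.n_cols;
    out.set_size(Ho * Wo, C);
    arg.set_size(Ho * Wo, C);
    for (int c = 0; c < C; ++c) {
      const float* m = X.colptr(c);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int r0 = i * s, c0 = j * s;
          float best = m[c0 * Hin + r0];
          int bi = c0 * Hin + r0;
          for (int dc = 0; dc < k; ++dc)
            for (int dr = 0; dr < k; ++dr) {
              float v = m[(c0 + dc) * Hin + (r0 + dr)];
              if (v > best) { best = v; bi = (c0 + dc) * Hin + (r0 + dr); }
            }
          out(j * Ho + i, c) = best;
          arg(j * Ho + i, c) = bi;
        }
    }
  }

  void lstm_forward(const fvec& s, const fmat& Wx, const fmat& Wh,
                    const fmat& bv, LstmCache& L, bool reverse) {
    int T = s.n_elem, h = sp.lstm_hidden;
    L.i.set_size(h, T); L.f.set_size(h, T); L.g.set_size(h, T);
    L.o.set_size(h, T); L.c.set_size(h, T); L.tc.set_size(h, T);
    L.h.set_size(h, T + 1);
    L.h.col(0).zeros();
    fvec cprev(h, fill::zeros);
    for (int t = 0; t < T; ++t) {
      float xt = reverse ? s(T - 1 - t) : s(t);
      fvec pre = Wx * xt + Wh * L.h.col(t) + bv;
      fvec ig = 1.0f / (1.0f + exp(-pre.subvec(0, h - 1)));
      fvec fg = 1.0f / (1.0f + exp(-pre.subvec(h, 2 * h - 1)));
      fvec gg = tanh(pre.subvec(2 * h, 3 * h - 1));
      fvec og = 1.0f / (1.0f + exp(-pre.subvec(3 * h, 4 * h - 1)));
      fvec cc = fg % cprev + ig % gg;
      fvec tc = tanh(cc);
      L.i.col(t) = ig; L.f.col(t) = fg; L.g.col(t) = gg; L.o.col(t) = og;
      L.c.col(t) = cc; L.tc.col(t) = tc;
      L.h.col(t + 1) = og % tc;
      cprev = cc;
    }
  }

  void lstm_backward(const fvec& s, const fmat& Wx, const fmat& Wh,
                     const LstmCache& L, const fvec& dh_final, bool reverse,
                     fmat& dWx, fmat& dWh, fmat& db, fvec& ds) {
    int T = s.n_elem, h = sp.lstm_hidden;
    fvec dh = dh_final, dc(h, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      fvec og = L.o.col(t), tc = L.tc.col(t);
      fvec do_ = dh % tc;
      dc += dh % og % (1.0f - tc % tc);
      fvec ig = L.i.col(t), fg = L.f.col(t), gg = L.g.col(t);
      fvec cprev = (t == 0) ? fvec(h, fill::zeros) : fvec(L.c.col(t - 1));
      fvec dpre(4 * h);
      dpre.subvec(0, h - 1) = (dc % gg) % ig % (1.0f - ig);
      dpre.subvec(h, 2 * h - 1) = (dc % cprev) % fg % (1.0f - fg);
      dpre.subvec(2 * h, 3 * h - 1) = (dc % ig) % (1.0f - gg % gg);
      dpre.subvec(3 * h, 4 * h - 1) = do_ % og % (1.0f - og);
      float xt = reverse ? s(T - 1 - t) : s(t);
      dWx += dpre * xt;
      dWh += dpre * L.h.col(t).t();
      db += dpre;
      int si = reverse ? (T - 1 - t) : t;
      ds(si) += dot(Wx.col(0), dpre);
      dh = Wh.t() * dpre;
      dc = dc % fg;
    }
  }

  // spatial dims entering block b (after previous block's pool/resample)
  void block_dims(int b, int& Hin, int& Win) const {
    if (b == 0) { Hin = Win = sp.input_size; return; }
    Hin = bb[b - 1].Hq; Win = bb[b - 1].Wq;
  }

  fvec forward(const fmat& img, const fvec& feat, bool train, Rng* rng) {
    int nb = n_conv();
    bb.resize(nb);
    int H = img.n_rows, W = img.n_cols;
    x0.set_size(H * W, 3);
    for (int c = 0; c < 3; ++c)
      std::memcpy(x0.colptr(c), img.memptr(), sizeof(float) * H * W);

    const fmat* cur = &x0;
    int Hin = H, Win = W;
    for (int b = 0; b < nb; ++b) {
      BlockBuf& B = bb[b];
      im2col(*cur, Hin, Win, sp.kernels[b], B.A, B.Hc, B.Wc);
      B.Z = B.A * P[2 * b];
      B.Z.each_row() += P[2 * b + 1];
      B.Z.transform([](float v) { return v > 0 ? v : 0.0f; });
      int Hc = B.Hc, Wc = B.Wc;
      const fmat* stage = &B.Z;
      if (b == 0 && sp.resample_after1 > 0) {
        int n = sp.resample_after1;
        if (static_cast<int>(Wr.n_rows) != n ||
            static_cast<int>(Wr.n_cols) != Hc) {
          Wr = bilinear_w(Hc, n);
        }
        B.R.set_size(n * n, B.Z.n_cols);
        for (uword c = 0; c < B.Z.n_cols; ++c) {
          fmat m(const_cast<float*>(B.Z.colptr(c)), Hc, Wc, false, true);
          fmat r(B.R.colptr(c), n, n, false, true);
          r = Wr * m * Wr.t();
        }
        stage = &B.R;
        Hc = Wc = n;
      }
      if (sp.pools[b]) {
        maxpool(*stage, Hc, Wc, sp.pool_k, sp.pool_s, B.out, B.argmax,
                B.Hq, B.Wq);
      } else {
        B.out = *stage;
        B.Hq = Hc; B.Wq = Wc;
      }
      if (train && sp.conv_dropout[b] > 0) {
        double keep = 1.0 - sp.conv_dropout[b];
        B.drop.set_size(size(B.out));
        for (uword t = 0; t < B.drop.n_elem; ++t)
          B.drop(t) = rng->unif() < keep ? static_cast<float>(1.0 / keep)
                                         : 0.0f;
        B.out %= B.drop;
      } else {
        B.drop.reset();
      }
      cur = &B.out;
      Hin = B.Hq; Win = B.Wq;
    }
    const fmat& last = bb[nb - 1].out;
    seq = fvec(const_cast<float*>(last.memptr()), last.n_elem, false, true);
    // (seq aliases the last block's buffer; LSTM caches copy what they need)
    int h = sp.lstm_hidden;
    lstm_forward(seq, P[2 * nb], P[2 * nb + 1], P[2 * nb + 2], lf, false);
    lstm_forward(seq, P[2 * nb + 3], P[2 * nb + 4], P[2 * nb + 5], lb, true);
    hcat.set_size(2 * h);
    hcat.subvec(0, h - 1) = lf.h.col(seq.n_elem);
    hcat.subvec(h, 2 * h - 1) = lb.h.col(seq.n_elem);
    hdrop = hcat;
    if (train && sp.dropout_lstm > 0) {
      double keep = 1.0 - sp.dropout_lstm;
      dropmask_lstm.set_size(2 * h);
      for (int t = 0; t < 2 * h; ++t)
        dropmask_lstm(t) = rng->unif() < keep ? static_cast<float>(1.0 / keep)
                                              : 0.0f;
      hdrop %= dropmask_lstm;
    } else {
      dropmask_lstm.reset();
    }
    fused.set_size(2 * h + sp.fusion_dim);
    fused.subvec(0, 2 * h - 1) = hdrop;
    if (sp.fusion_dim > 0)
      fused.subvec(2 * h, 2 * h + sp.fusion_dim - 1) = feat;
    int base = 2 * nb + 6;
    a1pre = P[base].t() * fused + P[base + 1].t();
    a1 = a1pre;
    a1.transform([](float v) { return v > 0 ? v : 0.0f; });
    z2 = P[base + 2].t() * a1 + P[base + 3].t();
    fvec zs = z2 - z2.max();
    fvec e = exp(zs);
    prob = e / accu(e);
    return prob;
  }

  void backward(int y, std::vector<fmat>& G) {
    int nb = n_conv(), h = sp.lstm_hidden;
    int base = 2 * nb + 6;
    fvec dz2 = prob;
    dz2(y) -= 1.0f;
    G[base + 2] += a1 * dz2.t();
    G[base + 3] += dz2.t();
    fvec da1 = P[base + 2] * dz2;
    for (uword t = 0; t < da1.n_elem; ++t) if (a1pre(t) <= 0) da1(t) = 0;
    G[base] += fused * da1.t();
    G[base + 1] += da1.t();
    fvec dfused = P[base] * da1;
    fvec dhdrop = dfused.subvec(0, 2 * h - 1);
    if (dropmask_lstm.n_elem) dhdrop %= dropmask_lstm;
    dseq.zeros(seq.n_elem);
    lstm_backward(seq, P[2 * nb], P[2 * nb + 1], lf, dhdrop.subvec(0, h - 1),
                  false, G[2 * nb], G[2 * nb + 1], G[2 * nb + 2], dseq);
    lstm_backward(seq, P[2 * nb + 3], P[2 * nb + 4], lb,
                  dhdrop.subvec(h, 2 * h - 1), true,
                  G[2 * nb + 3], G[2 * nb + 4], G[2 * nb + 5], dseq);

    // dout for the last block aliases dseq's memory
    bb[nb - 1].dout = fmat(dseq.memptr(), bb[nb - 1].out.n_rows,
                           bb[nb - 1].out.n_cols, false, true);
    for (int b = nb - 1; b >= 0; --b) {
      BlockBuf& B = bb[b];
      fmat& dout = B.dout;
      if (B.drop.n_elem) dout %= B.drop;
      int Hc = (b == 0 && sp.resample_after1 > 0) ? sp.resample_after1 : B.Hc;
      int Wc = Hc == B.Hc ? B.Wc : sp.resample_after1;
      // un-pool into the pre-pool map
      fmat* dstage;
      if (sp.pools[b]) {
        B.dpre.set_size(Hc * Wc, B.out.n_cols);
        B.dpre.zeros();
        for (uword c = 0; c < dout.n_cols; ++c) {
          float* dst = B.dpre.colptr(c);
          const float* src = dout.colptr(c);
          const uword* am = B.argmax.colptr(c);
          for (uword t = 0; t < dout.n_rows; ++t) dst[am[t]] += src[t];
        }
        dstage = &B.dpre;
      } else {
        dstage = &dout;
      }
      if (b == 0 && sp.resample_after1 > 0) {
        // back through the bilinear resample onto the conv-output grid
        B.dZ.set_size(B.Hc * B.Wc, B.Z.n_cols);
        int n = sp.resample_after1;
        for (uword c = 0; c < B.Z.n_cols; ++c) {
          fmat dm(dstage->colptr(c), n, n, false, true);
          fmat dz(B.dZ.colptr(c), B.Hc, B.Wc, false, true);
          dz = Wr.t() * dm * Wr;
        }
      } else {
        B.dZ = *dstage;
      }
      // relu mask lives on the conv output Z
      {
        const float* z = B.Z.memptr();
        float* d = B.dZ.memptr();
        for (uword t = 0; t < B.dZ.n_elem; ++t)
          if (z[t] <= 0) d[t] = 0;
      }
      G[2 * b] += B.A.t() * B.dZ;
      G[2 * b + 1] += sum(B.dZ, 0);
      if (b > 0) {
        B.dA = B.dZ * P[2 * b].t();
        int Hin, Win;
        block_dims(b, Hin, Win);
        col2im(B.dA, Hin, Win, sp.channels[b - 1], sp.kernels[b],
               bb[b - 1].dout);
      }
    }
  }
};

std::vector<fmat> params_from_r(const Rcpp::List& pl) {
  std::vector<fmat> P;
  for (int i = 0; i < pl.size(); ++i) {
    P.push_back(conv_to<fmat>::from(Rcpp::as<mat>(pl[i])));
  }
  return P;
}

Rcpp::List params_to_r(const std::vector<fmat>& P) {
  Rcpp::List out(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    out[i] = Rcpp::wrap(conv_to<mat>::from(P[i]));
  }
  return out;
}

fmat image_slice(const Rcpp::NumericVector& images, int H, int W, int idx) {
  fmat m(H, W);
  const double* src = images.begin() + static_cast<size_t>(idx) * H * W;
  for (int t = 0; t < H * W; ++t) m(t) = static_cast<float>(src[t]);
  return m;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List spec, Rcpp::NumericVector images,
                     Rcpp::NumericMatrix feats, Rcpp::IntegerVector y,
                     double lr, int batch_size, int epochs, int seed) {
  Net net;
  net.sp = parse_spec(spec);
  Rcpp::IntegerVector dims = images.attr("dim");
  int H = dims[0], W = dims[1], N = dims[2];
  Rng rng(static_cast<unsigned int>(seed) * 2654435769u + 12345u);
  net.init_params(rng);

  fmat F(feats.nrow(), feats.ncol());
  for (int i = 0; i < feats.nrow(); ++i)
    for (int j = 0; j < feats.ncol(); ++j)
      F(i, j) = static_cast<float>(feats(i, j));

  std::vector<fmat> G, M, V;
  for (auto& p : net.P) {
    G.emplace_back(size(p), fill::zeros);
    M.emplace_back(size(p), fill::zeros);
    V.emplace_back(size(p), fill::zeros);
  }
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  Rcpp::NumericVector loss_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::vector<int> perm = rng.permutation(N);
    double ep_loss = 0;
    for (int start = 0; start < N; start += batch_size) {
      int end = std::min(start + batch_size, N);
      int bs = end - start;
      for (auto& g : G) g.zeros();
      for (int s = start; s < end; ++s) {
        int i = perm[s];
        fmat img = image_slice(images, H, W, i);
        fvec ft = (F.n_cols > 0) ? fvec(F.row(i).t()) : fvec();
        fvec p = net.forward(img, ft, true, &rng);
        double pl = std::max(static_cast<double>(p(y[i])), 1e-12);
        ep_loss += -std::log(pl);
        net.backward(y[i], G);
      }
      ++step;
      double corr = std::sqrt(1.0 - std::pow(b2, step)) /
                    (1.0 - std::pow(b1, step));
      for (size_t k = 0; k < net.P.size(); ++k) {
        fmat g = G[k] / static_cast<float>(bs);
        M[k] = static_cast<float>(b1) * M[k] + static_cast<float>(1 - b1) * g;
        V[k] = static_cast<float>(b2) * V[k] +
               static_cast<float>(1 - b2) * (g % g);
        net.P[k] -= static_cast<float>(lr * corr) *
                    (M[k] / (sqrt(V[k]) + static_cast<float>(eps)));
      }
      Rcpp::checkUserInterrupt();
    }
    loss_hist[ep] = ep_loss / N;
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_r(net.P),
                            Rcpp::Named("loss") = loss_hist);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_predict(Rcpp::List spec, Rcpp::List params,
                                Rcpp::NumericVector images,
                                Rcpp::NumericMatrix feats) {
  Net net;
  net.sp = parse_spec(spec);
  net.P = params_from_r(params);
  Rcpp::IntegerVector dims = images.attr("dim");
  int H = dims[0], W = dims[1], N = dims[2];
  Rcpp::NumericMatrix out(N, net.sp.n_classes);
  for (int i = 0; i < N; ++i) {
    fmat img = image_slice(images, H, W, i);
    fvec ft(net.sp.fusion_dim);
    for (int j = 0; j < net.sp.fusion_dim; ++j)
      ft(j) = static_cast<float>(feats(i, j));
    fvec p = net.forward(img, ft, false, nullptr);
    for (int c = 0; c < net.sp.n_classes; ++c) out(i, c) = p(c);
  }
  return out;
}

// Loss and full parameter gradient for one sample with dropout disabled;
// used by the finite-difference gradient checks.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List spec, Rcpp::List params,
                         Rcpp::NumericMatrix image, Rcpp::NumericVector feat,
                         int y) {
  Net net;
  net.sp = parse_spec(spec);
  net.P = params_from_r(params);
  fmat img(image.nrow(), image.ncol());
  for (int t = 0; t < image.nrow() * image.ncol(); ++t)
    img(t) = static_cast<float>(image[t]);
  fvec ft(net.sp.fusion_dim);
  for (int j = 0; j < net.sp.fusion_dim; ++j)
    ft(j) = static_cast<float>(feat[j]);
  fvec p = net.forward(img, ft, false, nullptr);
  double loss = -std::log(std::max(static_cast<double>(p(y)), 1e-12));
  std::vector<fmat> G;
  for (auto& pp : net.P) G.emplace_back(size(pp), fill::zeros);
  net.backward(y, G);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_r(G),
                            Rcpp::Named("probs") = Rcpp::wrap(
                                conv_to<vec>::from(p)));
}

// Deterministic initial parameters for a spec/seed (gradient-check support).
// [[Rcpp::export]]
Rcpp::List cpp_init_params(Rcpp::List spec, int seed) {
  Net net;
  net.sp = parse_spec(spec);
  Rng rng(static_cast<unsigned int>(seed) * 2654435769u + 12345u);
  net.init_params(rng);
  return params_to_r(net.P);
}

// Dry forward pass on a zero image recording each stage's output shape.
// [[Rcpp::export]]
Rcpp::List cpp_forward_trace(Rcpp::List spec, int seed) {
  Net net;
  net.sp = parse_spec(spec);
  Rng rng(static_cast<unsigned int>(seed));
  net.init_params(rng);
  fmat img(net.sp.input_size, net.sp.input_size, fill::zeros);
  fvec ft(net.sp.fusion_dim, fill::zeros);
  net.forward(img, ft, false, nullptr);
  Rcpp::List out;
  for (int b = 0; b < net.n_conv(); ++b) {
    int Hc = (b == 0 && net.sp.resample_after1 > 0) ? net.sp.resample_after1
                                                    : net.bb[b].Hc;
    int Wc = Hc;
    out.push_back(Rcpp::IntegerVector::create(Hc, Wc,
                                              net.sp.channels[b]),
                  std::string("conv") + std::to_string(b + 1));
    if (net.sp.pools[b]) {
      out.push_back(Rcpp::IntegerVector::create(net.bb[b].Hq, net.bb[b].Wq,
                                                net.sp.channels[b]),
                    std::string("pool") + std::to_string(b + 1));
    }
  }
  out.push_back(Rcpp::IntegerVector::create(net.seq.n_elem, 1), "reshape");
  out.push_back(Rcpp::IntegerVector::create(net.hcat.n_elem), "bilstm");
  out.push_back(Rcpp::IntegerVector::create(net.fused.n_elem), "concat");
  out.push_back(Rcpp::IntegerVector::create(net.a1.n_elem), "dense1");
  out.push_back(Rcpp::IntegerVector::create(net.prob.n_elem), "softmax");
  return out;
}
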