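// Residual convolutional network regressing surface-marker values from
// 32x32 single-channel brightfield images.
//
// Fixed topology (convolution widths w = (w1, w2, w3)):
//   stem: 3x3 conv 1->w1 (zero pad), BN, ReLU, 2x2 max pool  (32 -> 16)
//   stage 1: 2 residual blocks @ w1                           (16 x 16)
//   2x2 avg pool (16 -> 8), stage 2: 3 residual blocks @ w2   (8 x 8)
//   2x2 avg pool (8 -> 4),  stage 3: 3 residual blocks @ w3   (4 x 4)
//   global average pool, dense -> n_markers, sigmoid
// A residual block is conv-BN-ReLU-conv-BN + identity skip, then ReLU;
// when the width grows across a block the skip is zero-padded in channels
// (parameter-free), so the network has exactly 17 convolutional layers
// (1 + 2*2 + 3*2 + 3*2) and every activation except the final sigmoid is
// preceded by batch normalization. Spatial size changes only at pooling;
// every convolution zero-pads. Training is mini-batch Adam on the mean
// squared error, with optional flip augmentation, a held-out validation
// fraction, best-weight checkpointing and early stopping.
//
// Activations are stored channels x (H*H*B); convolutions run as im2col
// followed by one BLAS GEMM per layer per batch.

#include <RcppArmadillo.h>
#include <random>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int N_CONV = 17;
static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.9;

namespace {

struct ConvSpec {
  int cin, cout, H;  // spatial size is preserved by the conv (zero pad)
};

std::vector<ConvSpec> conv_specs(int w1, int w2, int w3) {
  std::vector<ConvSpec> s;
  s.push_back({1, w1, 32});                            // stem
  for (int b = 0; b < 2; ++b) {                        // stage 1 @ 16
    s.push_back({w1, w1, 16});
    s.push_back({w1, w1, 16});
  }
  s.push_back({w1, w2, 8});                            // stage 2 @ 8
  s.push_back({w2, w2, 8});
  for (int b = 1; b < 3; ++b) {
    s.push_back({w2, w2, 8});
    s.push_back({w2, w2, 8});
  }
  s.push_back({w2, w3, 4});                            // stage 3 @ 4
  s.push_back({w3, w3, 4});
  for (int b = 1; b < 3; ++b) {
    s.push_back({w3, w3, 4});
    s.push_back({w3, w3, 4});
  }
  return s;
}

// gather 3x3 neighbourhoods: A (C x H*H*B) -> (9C x H*H*B), zero padding
arma::mat im2col(const arma::mat& A, int C, int H, int B) {
  int HH = H * H;
  arma::mat X(9 * C, (arma::uword)HH * B, arma::fill::zeros);
  int o = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++o) {
      int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);  // valid out rows
      if (r1 <= r0) continue;
      for (int b = 0; b < B; ++b) {
        for (int c = 0; c < H; ++c) {
          int sc = c + dc;
          if (sc < 0 || sc >= H) continue;
          arma::uword dst = (arma::uword)b * HH + (arma::uword)c * H + r0;
          arma::uword src = (arma::uword)b * HH + (arma::uword)sc * H + r0 + dr;
          X.submat(o * C, dst, (o + 1) * C - 1, dst + (r1 - r0) - 1) =
              A.cols(src, src + (r1 - r0) - 1);
        }
      }
    }
  }
  return X;
}

// scatter-add transpose of im2col
void col2im_add(arma::mat& dA, const arma::mat& dX, int C, int H, int B) {
  int HH = H * H;
  int o = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++o) {
      int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      if (r1 <= r0) continue;
      for (int b = 0; b < B; ++b) {
        for (int c = 0; c < H; ++c) {
          int sc = c + dc;
          if (sc < 0 || sc >= H) continue;
          arma::uword dst = (arma::uword)b * HH + (arma::uword)c * H + r0;
          arma::uword src = (arma::uword)b * HH + (arma::uword)sc * H + r0 + dr;
          dA.cols(src, src + (r1 - r0) - 1) +=
              dX.submat(o * C, dst, (o + 1) * C - 1, dst + (r1 - r0) - 1);
        }
      }
    }
  }
}

arma::mat maxpool(const arma::mat& A, int C, int H, int B,
                  arma::umat& argmax) {
  int h = H / 2, HH = H * H, hh = h * h;
  arma::mat out(C, (arma::uword)hh * B);
  argmax.set_size(C, (arma::uword)hh * B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < h; ++c) {
      for (int r = 0; r < h; ++r) {
        arma::uword j = (arma::uword)b * hh + (arma::uword)c * h + r;
        arma::uword s[4] = {
            (arma::uword)b * HH + (arma::uword)(2 * c) * H + 2 * r,
            (arma::uword)b * HH + (arma::uword)(2 * c) * H + 2 * r + 1,
            (arma::uword)b * HH + (arma::uword)(2 * c + 1) * H + 2 * r,
            (arma::uword)b * HH + (arma::uword)(2 * c + 1) * H + 2 * r + 1};
        for (int ch = 0; ch < C; ++ch) {
          double best = A(ch, s[0]);
          arma::uword bi = s[0];
          for (int k = 1; k < 4; ++k)
            if (A(ch, s[k]) > best) { best = A(ch, s[k]); bi = s[k]; }
          out(ch, j) = best;
          argmax(ch, j) = bi;
        }
      }
    }
  }
  return out;
}

void maxpool_back(arma::mat& dA, const arma::mat& dOut,
                  const arma::umat& argmax) {
  for (arma::uword j = 0; j < dOut.n_cols; ++j)
    for (arma::uword ch = 0; ch < dOut.n_rows; ++ch)
      dA(ch, argmax(ch, j)) += dOut(ch, j);
}

arma::mat avgpool(const arma::mat& A, int C, int H, int B) {
  int h = H / 2, HH = H * H, hh = h * h;
  arma::mat out(C, (arma::uword)hh * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < h; ++c)
      for (int r = 0; r < h; ++r) {
        arma::uword j = (arma::uword)b * hh + (arma::uword)c * h + r;
        out.col(j) =
            0.25 * (A.col((arma::uword)b * HH + (2 * c) * H + 2 * r) +
                    A.col((arma::uword)b * HH + (2 * c) * H + 2 * r + 1) +
                    A.col((arma::uword)b * HH + (2 * c + 1) * H + 2 * r) +
                    A.col((arma::uword)b * HH + (2 * c + 1) * H + 2 * r + 1));
      }
  return out;
}

void avgpool_back(arma::mat& dA, const arma::mat& dOut, int C, int H,
                  int B) {
  int h = H / 2, HH = H * H, hh = h * h;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < h; ++c)
      for (int r = 0; r < h; ++r) {
        arma::uword j = (arma::uword)b * hh + (arma::uword)c * h + r;
        arma::vec g = 0.25 * dOut.col(j);
        dA.col((arma::uword)b * HH + (2 * c) * H + 2 * r) += g;
        dA.col((arma::uword)b * HH + (2 * c) * H + 2 * r + 1) += g;
        dA.col((arma::uword)b * HH + (2 * c + 1) * H + 2 * r) += g;
        dA.col((arma::uword)b * HH + (2 * c + 1) * H + 2 * r + 1) += g;
      }
}

struct ConvCache {
  arma::mat Ain;   // conv input
  arma::mat Xhat;  // BN-normalized pre-activation
  arma::vec istd;  // 1 / sqrt(var + eps)
  arma::mat Out;   // post-(BN, optional ReLU) output (ReLU mask source)
};

struct Net {
  int M, w1, w2, w3;
  std::vector<ConvSpec> spec;
  std::vector<arma::mat> W, dW;
  std::vector<arma::vec> ga, be, dga, dbe, rm, rv;
  arma::mat Wd, dWd;
  arma::vec bd, dbd;

  void from_list(const List& params) {
    IntegerVector widths = params["widths"];
    w1 = widths[0]; w2 = widths[1]; w3 = widths[2];
    M = as<int>(params["n_markers"]);
    spec = conv_specs(w1, w2, w3);
    List Wl = params["conv"], gl = params["gamma"], bl = params["beta"];
    List rml = params["run_mean"], rvl = params["run_var"];
    W.clear(); ga.clear(); be.clear(); rm.clear(); rv.clear();
    for (int l = 0; l < N_CONV; ++l) {
      W.push_back(as<arma::mat>(Wl[l]));
      ga.push_back(as<arma::vec>(gl[l]));
      be.push_back(as<arma::vec>(bl[l]));
      rm.push_back(as<arma::vec>(rml[l]));
      rv.push_back(as<arma::vec>(rvl[l]));
      if ((int)W[l].n_rows != spec[l].cout ||
          (int)W[l].n_cols != 9 * spec[l].cin)
        stop("conv weight %d has wrong shape", l);
    }
    Wd = as<arma::mat>(params["dense_W"]);
    bd = as<arma::vec>(params["dense_b"]);
  }

  List to_list() const {
    List Wl(N_CONV), gl(N_CONV), bl(N_CONV), rml(N_CONV), rvl(N_CONV);
    for (int l = 0; l < N_CONV; ++l) {
      Wl[l] = W[l]; gl[l] = ga[l]; bl[l] = be[l];
      rml[l] = rm[l]; rvl[l] = rv[l];
    }
    return List::create(
        Named("conv") = Wl, Named("gamma") = gl, Named("beta") = bl,
        Named("run_mean") = rml, Named("run_var") = rvl,
        Named("dense_W") = Wd, Named("dense_b") = bd,
        Named("widths") = IntegerVector::create(w1, w2, w3),
        Named("n_markers") = M);
  }

  // sizes on first call, zeroes in place afterwards so that pointers
  // collected by the optimizer stay valid
  void zero_grads() {
    if (dW.empty()) {
      dW.resize(N_CONV);
      dga.resize(N_CONV);
      dbe.resize(N_CONV);
    }
    for (int l = 0; l < N_CONV; ++l) {
      dW[l].zeros(W[l].n_rows, W[l].n_cols);
      dga[l].zeros(ga[l].n_elem);
      dbe[l].zeros(be[l].n_elem);
    }
    dWd.zeros(Wd.n_rows, Wd.n_cols);
    dbd.zeros(bd.n_elem);
  }

  // ---- forward/backward pieces -------------------------------------------

  arma::mat convbn_f(int l, const arma::mat& A, int B, bool relu,
                     bool training, ConvCache* c) {
    const ConvSpec& sp = spec[l];
    arma::mat Xcol = im2col(A, sp.cin, sp.H, B);
    arma::mat Z = W[l] * Xcol;
    arma::mat out;
    if (training) {
      arma::vec mu = arma::mean(Z, 1);
      Z.each_col() -= mu;
      arma::vec va = arma::mean(arma::square(Z), 1);
      arma::vec istd = 1.0 / arma::sqrt(va + BN_EPS);
      Z.each_col() %= istd;  // Z is now xhat
      rm[l] = BN_MOM * rm[l] + (1 - BN_MOM) * mu;
      rv[l] = BN_MOM * rv[l] + (1 - BN_MOM) * va;
      out = Z;
      out.each_col() %= ga[l];
      out.each_col() += be[l];
      if (relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
      if (c) {
        c->Ain = A;
        c->Xhat = std::move(Z);
        c->istd = std::move(istd);
        c->Out = out;
      }
    } else {
      arma::vec istd = 1.0 / arma::sqrt(rv[l] + BN_EPS);
      Z.each_col() -= rm[l];
      Z.each_col() %= istd % ga[l];
      Z.each_col() += be[l];
      if (relu) Z.transform([](double v) { return v > 0 ? v : 0.0; });
      out = std::move(Z);
    }
    return out;
  }

  // dOut is consumed; returns gradient wrt the conv input
  arma::mat convbn_b(int l, arma::mat dOut, int B, bool relu,
                     const ConvCache& c) {
    const ConvSpec& sp = spec[l];
    if (relu) dOut %= arma::conv_to<arma::mat>::from(c.Out > 0);
    dga[l] += arma::sum(dOut % c.Xhat, 1);
    dbe[l] += arma::sum(dOut, 1);
    arma::mat dxhat = dOut;
    dxhat.each_col() %= ga[l];
    double N = (double)dxhat.n_cols;
    arma::vec s1 = arma::sum(dxhat, 1) / N;
    arma::vec s2 = arma::sum(dxhat % c.Xhat, 1) / N;
    arma::mat dZ = c.Xhat;
    dZ.each_col() %= s2;
    dZ = dxhat - dZ;
    dZ.each_col() -= s1;
    dZ.each_col() %= c.istd;
    arma::mat Xcol = im2col(c.Ain, sp.cin, sp.H, B);
    dW[l] += dZ * Xcol.t();
    arma::mat dXcol = W[l].t() * dZ;
    arma::mat dA(sp.cin, c.Ain.n_cols, arma::fill::zeros);
    col2im_add(dA, dXcol, sp.cin, sp.H, B);
    return dA;
  }

  // training-mode forward + backward on one batch; returns the MSE loss.
  // A0: 1 x (1024*B) input; T: M x B targets.
  double forward_backward(const arma::mat& A0, const arma::mat& T, int B) {
    std::vector<ConvCache> cc(N_CONV);
    std::vector<arma::mat> blockOut(8);  // post-ReLU block outputs
    arma::umat mp_arg;

    int l = 0;
    arma::mat stem = convbn_f(l, A0, B, true, true, &cc[l]); ++l;
    arma::mat cur = maxpool(stem, w1, 32, B, mp_arg);

    int blk = 0;
    std::vector<arma::mat> blockIn(8);
    // stages: {nblocks, H, cin_first}
    int stages[3][2] = {{2, 16}, {3, 8}, {3, 4}};
    for (int s = 0; s < 3; ++s) {
      if (s > 0) cur = avgpool(cur, spec[l].cin, stages[s - 1][1], B);
      for (int b = 0; b < stages[s][0]; ++b, ++blk) {
        blockIn[blk] = cur;
        int cin = spec[l].cin, cout = spec[l].cout;
        arma::mat h1 = convbn_f(l, cur, B, true, true, &cc[l]); ++l;
        arma::mat h2 = convbn_f(l, h1, B, false, true, &cc[l]); ++l;
        if (cin == cout) h2 += blockIn[blk];
        else h2.rows(0, cin - 1) += blockIn[blk];
        h2.transform([](double v) { return v > 0 ? v : 0.0; });
        blockOut[blk] = std::move(h2);
        cur = blockOut[blk];
      }
    }

    // head: global average pool + dense + sigmoid
    int HH = 16;  // 4x4
    arma::mat G(w3, B);
    for (int b = 0; b < B; ++b)
      G.col(b) = arma::mean(cur.cols((arma::uword)b * HH,
                                     (arma::uword)b * HH + HH - 1), 1);
    arma::mat pre = Wd * G;
    pre.each_col() += bd;
    arma::mat Y = 1.0 / (1.0 + arma::exp(-pre));
    arma::mat diff = Y - T;
    double loss = arma::accu(arma::square(diff)) / (double)(M * B);

    // ---- backward ----
    arma::mat dpre = (2.0 / (double)(M * B)) * diff % Y % (1.0 - Y);
    dWd += dpre * G.t();
    dbd += arma::sum(dpre, 1);
    arma::mat dG = Wd.t() * dpre;
    arma::mat dcur(w3, cur.n_cols, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      dcur.cols((arma::uword)b * HH, (arma::uword)b * HH + HH - 1)
          .each_col() += dG.col(b) / (double)HH;

    l = N_CONV;  // walk conv indices backwards
    blk = 7;
    for (int s = 2; s >= 0; --s) {
      for (int b = stages[s][0] - 1; b >= 0; --b, --blk) {
        arma::mat dsum =
            dcur % arma::conv_to<arma::mat>::from(blockOut[blk] > 0);
        --l;
        arma::mat dh1 = convbn_b(l, dsum, B, false, cc[l]);
        --l;
        arma::mat dIn = convbn_b(l, std::move(dh1), B, true, cc[l]);
        int cin = spec[l].cin, cout = spec[l].cout;
        if (cin == cout) dIn += dsum;
        else dIn += dsum.rows(0, cin - 1);
        dcur = std::move(dIn);
      }
      if (s > 0) {
        int Hprev = stages[s - 1][1];
        arma::mat dA(spec[l].cin, (arma::uword)Hprev * Hprev * B,
                     arma::fill::zeros);
        avgpool_back(dA, dcur, spec[l].cin, Hprev, B);
        dcur = std::move(dA);
      }
    }
    // stem: maxpool then conv 0
    arma::mat dStem(w1, (arma::uword)32 * 32 * B, arma::fill::zeros);
    maxpool_back(dStem, dcur, mp_arg);
    --l;
    convbn_b(l, std::move(dStem), B, true, cc[l]);
    return loss;
  }

  // inference forward; A0: 1 x (1024*B)
  arma::mat infer(const arma::mat& A0, int B) {
    int l = 0;
    arma::mat cur = convbn_f(l, A0, B, true, false, nullptr); ++l;
    arma::umat dummy;
    cur = maxpool(cur, w1, 32, B, dummy);
    int stages[3][2] = {{2, 16}, {3, 8}, {3, 4}};
    for (int s = 0; s < 3; ++s) {
      if (s > 0) cur = avgpool(cur, spec[l].cin, stages[s - 1][1], B);
      for (int b = 0; b < stages[s][0]; ++b) {
        int cin = spec[l].cin, cout = spec[l].cout;
        arma::mat skip = cur;
        cur = convbn_f(l, cur, B, true, false, nullptr); ++l;
        cur = convbn_f(l, cur, B, false, false, nullptr); ++l;
        if (cin == cout) cur += skip;
        else cur.rows(0, cin - 1) += skip;
        cur.transform([](double v) { return v > 0 ? v : 0.0; });
      }
    }
    int HH = 16;
    arma::mat G(w3, B);
    for (int b = 0; b < B; ++b)
      G.col(b) = arma::mean(cur.cols((arma::uword)b * HH,
                                     (arma::uword)b * HH + HH - 1), 1);
    arma::mat pre = Wd * G;
    pre.each_col() += bd;
    return 1.0 / (1.0 + arma::exp(-pre));
  }
};

// assemble batch input (1 x 1024*B) from image cube slices, with optional
// per-image flips (0 none, 1 vertical, 2 horizontal, 3 both)
arma::mat make_input(const arma::cube& imgs, const std::vector<int>& idx,
                     const std::vector<int>& flips) {
  int B = (int)idx.size();
  arma::mat A0(1, (arma::uword)1024 * B);
  for (int b = 0; b < B; ++b) {
    arma::mat s = imgs.slice(idx[b]);
    int f = flips.empty() ? 0 : flips[b];
    if (f == 1 || f == 3) s = arma::flipud(s);
    if (f == 2 || f == 3) s = arma::fliplr(s);
    std::memcpy(A0.memptr() + (arma::uword)1024 * b, s.memptr(),
                1024 * sizeof(double));
  }
  return A0;
}

struct Adam {
  std::vector<arma::mat> mM, vM;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void init(const std::vector<arma::mat*>& params) {
    mM.clear(); vM.clear();
    for (auto* p : params) {
      mM.emplace_back(arma::size(*p), arma::fill::zeros);
      vM.emplace_back(arma::size(*p), arma::fill::zeros);
    }
  }
  void step(const std::vector<arma::mat*>& params,
            const std::vector<arma::mat*>& grads, double lr) {
    ++t;
    double c1 = 1 - std::pow(b1, (double)t);
    double c2 = 1 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      mM[i] = b1 * mM[i] + (1 - b1) * (*grads[i]);
      vM[i] = b2 * vM[i] + (1 - b2) * arma::square(*grads[i]);
      *params[i] -= lr * (mM[i] / c1) / (arma::sqrt(vM[i] / c2) + eps);
    }
  }
};

void collect_params(Net& net, std::vector<arma::mat*>& p,
                    std::vector<arma::mat*>& g) {
  p.clear(); g.clear();
  for (int l = 0; l < N_CONV; ++l) {
    p.push_back(&net.W[l]); g.push_back(&net.dW[l]);
    p.push_back((arma::mat*)&net.ga[l]); g.push_back((arma::mat*)&net.dga[l]);
    p.push_back((arma::mat*)&net.be[l]); g.push_back((arma::mat*)&net.dbe[l]);
  }
  p.push_back(&net.Wd); g.push_back(&net.dWd);
  p.push_back((arma::mat*)&net.bd); g.push_back((arma::mat*)&net.dbd);
}

}  // namespace

// [[Rcpp::export]]
List cnn_init_cpp(int n_markers, IntegerVector widths, int seed) {
  if (widths.size() != 3) stop("widths must have length 3");
  Net net;
  net.M = n_markers;
  net.w1 = widths[0]; net.w2 = widths[1]; net.w3 = widths[2];
  net.spec = conv_specs(net.w1, net.w2, net.w3);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  for (int l = 0; l < N_CONV; ++l) {
    const ConvSpec& sp = net.spec[l];
    double sd = std::sqrt(2.0 / (9.0 * sp.cin));  // He initialization
    arma::mat Wl(sp.cout, 9 * sp.cin);
    for (auto& v : Wl) v = sd * nd(rng);
    net.W.push_back(Wl);
    net.ga.push_back(arma::vec(sp.cout, arma::fill::ones));
    net.be.push_back(arma::vec(sp.cout, arma::fill::zeros));
    net.rm.push_back(arma::vec(sp.cout, arma::fill::zeros));
    net.rv.push_back(arma::vec(sp.cout, arma::fill::ones));
  }
  double sdd = std::sqrt(1.0 / net.w3);
  net.Wd.set_size(n_markers, net.w3);
  for (auto& v : net.Wd) v = sdd * nd(rng);
  net.bd = arma::vec(n_markers, arma::fill::zeros);
  return net.to_list();
}

// [[Rcpp::export]]
List cnn_train_cpp(List params, const arma::cube& images,
                   const arma::mat& targets, int epochs, int batch,
                   double lr, double val_frac, int patience, bool augment,
                   int seed) {
  Net net;
  net.from_list(params);
  int n = (int)images.n_slices;
  if ((int)targets.n_cols != n)
    stop("cnn_train: %d images but %d target rows", n, (int)targets.n_cols);
  if (images.n_rows != 32 || images.n_cols != 32)
    stop("cnn_train: images must be 32x32");

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  int n_val = std::max(1, (int)std::floor(val_frac * n));
  if (n_val >= n) stop("cnn_train: validation fraction leaves no training data");
  std::vector<int> val_idx(order.begin(), order.begin() + n_val);
  std::vector<int> tr_idx(order.begin() + n_val, order.end());
  int n_tr = (int)tr_idx.size();
  if (batch > n_tr) batch = n_tr;

  net.zero_grads();  // size gradient buffers before taking pointers
  std::vector<arma::mat*> p, g;
  collect_params(net, p, g);
  Adam opt;
  opt.init(p);

  auto eval_loss = [&](const std::vector<int>& idx) {
    double tot = 0;
    int done = 0;
    while (done < (int)idx.size()) {
      int B = std::min(batch, (int)idx.size() - done);
      std::vector<int> bi(idx.begin() + done, idx.begin() + done + B);
      arma::mat A0 = make_input(images, bi, {});
      arma::mat Y = net.infer(A0, B);
      arma::mat T(net.M, B);
      for (int b = 0; b < B; ++b) T.col(b) = targets.col(bi[b]);
      tot += arma::accu(arma::square(Y - T)) / (double)net.M;
      done += B;
    }
    return tot / (double)idx.size();
  };

  std::vector<double> tr_loss_log, val_loss_log;
  double best_val = std::numeric_limits<double>::infinity();
  List best_params = net.to_list();
  int bad_epochs = 0, stopped_epoch = 0;
  std::uniform_int_distribution<int> flip_draw(0, 3);

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(tr_idx.begin(), tr_idx.end(), rng);
    double ep_loss = 0;
    int done = 0, n_batches = 0;
    while (done < n_tr) {
      int B = std::min(batch, n_tr - done);
      std::vector<int> bi(tr_idx.begin() + done, tr_idx.begin() + done + B);
      std::vector<int> flips;
      if (augment) {
        flips.resize(B);
        for (int b = 0; b < B; ++b) flips[b] = flip_draw(rng);
      }
      arma::mat A0 = make_input(images, bi, flips);
      arma::mat T(net.M, B);
      for (int b = 0; b < B; ++b) T.col(b) = targets.col(bi[b]);
      net.zero_grads();
      ep_loss += net.forward_backward(A0, T, B);
      opt.step(p, g, lr);
      done += B;
      ++n_batches;
      Rcpp::checkUserInterrupt();
    }
    double vl = eval_loss(val_idx);
    tr_loss_log.push_back(ep_loss / n_batches);
    val_loss_log.push_back(vl);
    stopped_epoch = e + 1;
    if (vl < best_val) {
      best_val = vl;
      best_params = net.to_list();
      bad_epochs = 0;
    } else if (++bad_epochs >= patience) {
      break;
    }
  }

  return List::create(
      Named("params") = best_params,
      Named("train_loss") = NumericVector(tr_loss_log.begin(),
                                          tr_loss_log.end()),
      Named("val_loss") = NumericVector(val_loss_log.begin(),
                                        val_loss_log.end()),
      Named("best_val_loss") = best_val,
      Named("stopped_epoch") = stopped_epoch,
      Named("n_train") = n_tr, Named("n_val") = n_val,
      Named("batch_size") = batch);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List params, const arma::cube& images,
                          int batch = 256) {
  Net net;
  net.from_list(params);
  if (images.n_rows != 32 || images.n_cols != 32)
    stop("cnn_predict: images must be 32x32");
  int n = (int)images.n_slices;
  arma::mat out(n, net.M);
  int done = 0;
  while (done < n) {
    int B = std::min(batch, n - done);
    std::vector<int> bi(B);
    for (int b = 0; b < B; ++b) bi[b] = done + b;
    arma::mat A0 = make_input(images, bi, {});
    out.rows(done, done + B - 1) = net.infer(A0, B).t();
    done += B;
  }
  return out;
}

// training-mode loss and gradients on a full (small) batch; used by the
// finite-difference gradient checks
// [[Rcpp::export]]
List cnn_loss_grad_cpp(List params, const arma::cube& images,
                       const arma::mat& targets) {
  Net net;
  net.from_list(params);
  int B = (int)images.n_slices;
  std::vector<int> bi(B);
  for (int b = 0; b < B; ++b) bi[b] = b;
  arma::mat A0 = make_input(images, bi, {});
  net.zero_grads();
  double loss = net.forward_backward(A0, targets.t(), B);
  List dWl(N_CONV), dgl(N_CONV), dbl(N_CONV);
  for (int l = 0; l < N_CONV; ++l) {
    dWl[l] = net.dW[l]; dgl[l] = net.dga[l]; dbl[l] = net.dbe[l];
  }
  return List::create(Named("loss") = loss, Named("d_conv") = dWl,
                      Named("d_gamma") = dgl, Named("d_beta") = dbl,
                      Named("d_dense_W") = net.dWd,
                      Named("d_dense_b") = net.dbd);
}

// [[Rcpp::export]]
double cnn_loss_cpp(List params, const arma::cube& images,
                    const arma::mat& targets) {
  Net net;
  net.from_list(params);
  int B = (int)images.n_slices;
  std::vector<int> bi(B);
  for (int b = 0; b < B; ++b) bi[b] = b;
  arma::mat A0 = make_input(images, bi, {});
  net.zero_grads();
  return net.forward_backward(A0, targets.t(), B);
}
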