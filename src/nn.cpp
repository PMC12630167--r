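// Compact two-branch convolutional network engine.
//
// Branch 1: VGG-style 3x3 convolution blocks (two convolutions + ReLU each,
// then 2x2 max-pooling) over the two stacked holograms. Branch 2: a small
// dense layer over the 13 fluorescence channels plus a presence flag.
// Fusion: concatenation into a linear softmax head. Training is plain
// minibatch Adam on the cross-entropy, single-threaded and fully
// deterministic given the seed. Feature maps are stored as (channels x
// pixels) matrices with pixel index p = x*S + y (column-major images, as R
// vectorises matrices).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

struct Net {
  int B = 0, side = 0, n_classes = 0, h = 0;
  std::vector<int> ch;
  std::vector<mat> W1, W2;
  std::vector<vec> b1, b2;
  mat Wf, Wo;
  vec bf, bo;
};

static std::string key(const char* stem, int b) {
  return "b" + std::to_string(b + 1) + "_" + stem;
}

static Net unpack(const List& params, const IntegerVector& channels, int side) {
  Net net;
  net.B = channels.size();
  net.side = side;
  net.ch.assign(channels.begin(), channels.end());
  for (int b = 0; b < net.B; ++b) {
    net.W1.push_back(as<mat>(params[key("W1", b)]));
    net.b1.push_back(as<vec>(params[key("b1", b)]));
    net.W2.push_back(as<mat>(params[key("W2", b)]));
    net.b2.push_back(as<vec>(params[key("b2", b)]));
  }
  net.Wf = as<mat>(params["Wf"]);
  net.bf = as<vec>(params["bf"]);
  net.Wo = as<mat>(params["Wo"]);
  net.bo = as<vec>(params["bo"]);
  net.n_classes = net.Wo.n_rows;
  net.h = net.Wf.n_rows;
  return net;
}

static List pack(const Net& net) {
  List out;
  for (int b = 0; b < net.B; ++b) {
    out[key("W1", b)] = net.W1[b];
    out[key("b1", b)] = net.b1[b];
    out[key("W2", b)] = net.W2[b];
    out[key("b2", b)] = net.b2[b];
  }
  out["Wf"] = net.Wf;
  out["bf"] = net.bf;
  out["Wo"] = net.Wo;
  out["bo"] = net.bo;
  return out;
}

// 3x3, pad 1 im2col: A is (C x S*S), col is (C*9 x S*S), row c*9 + ky*3 + kx.
static void im2col3(const mat& A, int C, int S, mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int r = c * 9 + ky * 3 + kx;
        for (int x = 0; x < S; ++x) {
          const int xs = x + kx - 1;
          if (xs < 0 || xs >= S) continue;
          const int ylo = std::max(0, 1 - ky), yhi = std::min(S, S + 1 - ky);
          for (int y = ylo; y < yhi; ++y)
            col(r, x * S + y) = A(c, xs * S + y + ky - 1);
        }
      }
}

// adjoint of im2col3: accumulate dcol back onto a (C x S*S) map.
static void col2im3(const mat& dcol, int C, int S, mat& dA) {
  dA.zeros(C, S * S);
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int r = c * 9 + ky * 3 + kx;
        for (int x = 0; x < S; ++x) {
          const int xs = x + kx - 1;
          if (xs < 0 || xs >= S) continue;
          const int ylo = std::max(0, 1 - ky), yhi = std::min(S, S + 1 - ky);
          for (int y = ylo; y < yhi; ++y)
            dA(c, xs * S + y + ky - 1) += dcol(r, x * S + y);
        }
      }
}

static inline void relu_(mat& z) {
  z.for_each([](double& v) { if (v < 0) v = 0; });
}

struct BlockCache {
  mat col1, col2, A1, A2, P;
  arma::umat amax;
  int s = 0;  // input spatial side of the block
};

struct Grads {
  std::vector<mat> W1, W2;
  std::vector<vec> b1, b2;
  mat Wf, Wo;
  vec bf, bo;
  void init(const Net& net) {
    W1.clear(); W2.clear(); b1.clear(); b2.clear();
    for (int b = 0; b < net.B; ++b) {
      W1.push_back(arma::zeros<mat>(arma::size(net.W1[b])));
      b1.push_back(arma::zeros<vec>(net.b1[b].n_elem));
      W2.push_back(arma::zeros<mat>(arma::size(net.W2[b])));
      b2.push_back(arma::zeros<vec>(net.b2[b].n_elem));
    }
    Wf = arma::zeros<mat>(arma::size(net.Wf));
    bf = arma::zeros<vec>(net.bf.n_elem);
    Wo = arma::zeros<mat>(arma::size(net.Wo));
    bo = arma::zeros<vec>(net.bo.n_elem);
  }
};

// Forward pass for one sample; fills caches when `caches` is non-null.
static vec forward_sample(const Net& net, const vec& ximg, const vec& xfl,
                          std::vector<BlockCache>* caches, vec& cat,
                          vec& ffl_pre) {
  const int S = net.side;
  mat A(2, S * S);
  A.row(0) = ximg.subvec(0, S * S - 1).t();
  A.row(1) = ximg.subvec(S * S, 2 * S * S - 1).t();

  int s = S;
  for (int b = 0; b < net.B; ++b) {
    const int Cin = A.n_rows, Cout = net.ch[b];
    mat col1(Cin * 9, s * s);
    im2col3(A, Cin, s, col1);
    mat A1 = net.W1[b] * col1;
    A1.each_col() += net.b1[b];
    relu_(A1);
    mat col2(Cout * 9, s * s);
    im2col3(A1, Cout, s, col2);
    mat A2 = net.W2[b] * col2;
    A2.each_col() += net.b2[b];
    relu_(A2);

    const int sp = s / 2;
    mat P(Cout, sp * sp);
    arma::umat am(Cout, sp * sp);
    for (int c = 0; c < Cout; ++c)
      for (int px = 0; px < sp; ++px)
        for (int py = 0; py < sp; ++py) {
          const int base = (2 * px) * s + 2 * py;
          const uword cand[4] = {(uword)base, (uword)(base + 1),
                                 (uword)(base + s), (uword)(base + s + 1)};
          double best = A2(c, cand[0]);
          uword bi = cand[0];
          for (int t = 1; t < 4; ++t)
            if (A2(c, cand[t]) > best) { best = A2(c, cand[t]); bi = cand[t]; }
          P(c, px * sp + py) = best;
          am(c, px * sp + py) = bi;
        }
    if (caches) {
      BlockCache bc;
      bc.col1 = std::move(col1);
      bc.col2 = std::move(col2);
      bc.A1 = A1;
      bc.A2 = A2;
      bc.P = P;
      bc.amax = am;
      bc.s = s;
      (*caches)[b] = std::move(bc);
    }
    A = std::move(P);
    s = sp;
  }

  const int nflat = A.n_rows * A.n_cols;
  vec flat = arma::vectorise(A, 1).t();  // channel-major

  ffl_pre = net.Wf * xfl + net.bf;
  vec ffl = ffl_pre;
  ffl.for_each([](double& v) { if (v < 0) v = 0; });

  cat.set_size(nflat + net.h);
  cat.head(nflat) = flat;
  cat.tail(net.h) = ffl;
  return net.Wo * cat + net.bo;
}

static vec softmax(const vec& z) {
  vec p = arma::exp(z - z.max());
  return p / arma::accu(p);
}

// Forward + backward for one sample; accumulates into g; returns the loss.
static double backward_sample(const Net& net, const vec& ximg, const vec& xfl,
                              int label, Grads& g) {
  std::vector<BlockCache> caches(net.B);
  vec cat, ffl_pre;
  vec logits = forward_sample(net, ximg, xfl, &caches, cat, ffl_pre);
  vec probs = softmax(logits);
  double loss = -std::log(std::max(probs(label), 1e-300));

  vec dz = probs;
  dz(label) -= 1.0;
  g.Wo += dz * cat.t();
  g.bo += dz;
  vec dcat = net.Wo.t() * dz;
  const int nflat = cat.n_elem - net.h;

  vec dffl = dcat.tail(net.h);
  for (int i = 0; i < net.h; ++i) if (ffl_pre(i) <= 0) dffl(i) = 0;
  g.Wf += dffl * xfl.t();
  g.bf += dffl;

  // gradient w.r.t. the flattened pooled map of the last block
  const BlockCache& last = caches[net.B - 1];
  const int Clast = last.P.n_rows, nplast = last.P.n_cols;
  mat dP = arma::reshape(dcat.head(nflat), nplast, Clast).t();

  for (int b = net.B - 1; b >= 0; --b) {
    const BlockCache& bc = caches[b];
    const int s = bc.s, Cout = bc.A2.n_rows;
    mat dA2(Cout, s * s, arma::fill::zeros);
    for (int c = 0; c < Cout; ++c)
      for (uword j = 0; j < bc.amax.n_cols; ++j)
        dA2(c, bc.amax(c, j)) += dP(c, j);
    dA2.elem(arma::find(bc.A2 <= 0)).zeros();

    g.W2[b] += dA2 * bc.col2.t();
    g.b2[b] += arma::sum(dA2, 1);
    mat dcol2 = net.W2[b].t() * dA2;
    mat dA1;
    col2im3(dcol2, Cout, s, dA1);
    dA1.elem(arma::find(bc.A1 <= 0)).zeros();

    g.W1[b] += dA1 * bc.col1.t();
    g.b1[b] += arma::sum(dA1, 1);
    if (b > 0) {
      mat dcol1 = net.W1[b].t() * dA1;
      mat dA0;
      col2im3(dcol1, caches[b - 1].P.n_rows, s, dA0);
      dP = std::move(dA0);
    }
  }
  return loss;
}

// [[Rcpp::export]]
arma::mat nn_forward_cpp(List params, const arma::mat& Ximg,
                         const arma::mat& Xfl, IntegerVector channels,
                         int side) {
  Net net = unpack(params, channels, side);
  const int N = Ximg.n_cols;
  mat logits(net.n_classes, N);
  vec cat, ffl_pre;
  for (int i = 0; i < N; ++i)
    logits.col(i) = forward_sample(net, Ximg.col(i), Xfl.col(i), nullptr,
                                   cat, ffl_pre);
  return logits;
}

// [[Rcpp::export]]
List nn_loss_grad_cpp(List params, const arma::mat& Ximg, const arma::mat& Xfl,
                      IntegerVector y, IntegerVector channels, int side) {
  Net net = unpack(params, channels, side);
  const int N = Ximg.n_cols;
  Grads g;
  g.init(net);
  double loss = 0;
  for (int i = 0; i < N; ++i)
    loss += backward_sample(net, Ximg.col(i), Xfl.col(i), y[i] - 1, g);
  loss /= N;
  Net gn = net;
  gn.W1 = g.W1; gn.b1 = g.b1; gn.W2 = g.W2; gn.b2 = g.b2;
  gn.Wf = g.Wf / N; gn.bf = g.bf / N; gn.Wo = g.Wo / N; gn.bo = g.bo / N;
  for (int b = 0; b < net.B; ++b) {
    gn.W1[b] /= N; gn.b1[b] /= N; gn.W2[b] /= N; gn.b2[b] /= N;
  }
  return List::create(_["loss"] = loss, _["grads"] = pack(gn));
}

struct Adam {
  std::vector<mat> mW1, vW1, mW2, vW2;
  std::vector<vec> mb1, vb1, mb2, vb2;
  mat mWf, vWf, mWo, vWo;
  vec mbf, vbf, mbo, vbo;
  long t = 0;
  void init(const Net& net) {
    for (int b = 0; b < net.B; ++b) {
      mW1.push_back(arma::zeros<mat>(arma::size(net.W1[b])));
      vW1.push_back(arma::zeros<mat>(arma::size(net.W1[b])));
      mb1.push_back(arma::zeros<vec>(net.b1[b].n_elem));
      vb1.push_back(arma::zeros<vec>(net.b1[b].n_elem));
      mW2.push_back(arma::zeros<mat>(arma::size(net.W2[b])));
      vW2.push_back(arma::zeros<mat>(arma::size(net.W2[b])));
      mb2.push_back(arma::zeros<vec>(net.b2[b].n_elem));
      vb2.push_back(arma::zeros<vec>(net.b2[b].n_elem));
    }
    mWf = arma::zeros<mat>(arma::size(net.Wf)); vWf = mWf;
    mbf = arma::zeros<vec>(net.bf.n_elem); vbf = mbf;
    mWo = arma::zeros<mat>(arma::size(net.Wo)); vWo = mWo;
    mbo = arma::zeros<vec>(net.bo.n_elem); vbo = mbo;
  }
  template <class T>
  void step1(T& w, const T& gr, T& m, T& v, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * (gr % gr);
    const double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
  void step(Net& net, const Grads& g, double lr) {
    ++t;
    for (int b = 0; b < net.B; ++b) {
      step1(net.W1[b], g.W1[b], mW1[b], vW1[b], lr);
      step1(net.b1[b], g.b1[b], mb1[b], vb1[b], lr);
      step1(net.W2[b], g.W2[b], mW2[b], vW2[b], lr);
      step1(net.b2[b], g.b2[b], mb2[b], vb2[b], lr);
    }
    step1(net.Wf, g.Wf, mWf, vWf, lr);
    step1(net.bf, g.bf, mbf, vbf, lr);
    step1(net.Wo, g.Wo, mWo, vWo, lr);
    step1(net.bo, g.bo, mbo, vbo, lr);
  }
};

// Deterministic portable RNG (xorshift-derived uniforms; avoids the
// implementation-defined std distributions).
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed * 6364136223846793005ULL + 1442695040888963407ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (double)(next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// [[Rcpp::export]]
List nn_train_cpp(List params, const arma::mat& Ximg, const arma::mat& Xfl,
                  IntegerVector y, const arma::mat& Vimg,
                  const arma::mat& Vfl, IntegerVector yv,
                  IntegerVector channels, int side, int epochs, double lr,
                  int batch_size, double mask_p, double seed) {
  Net net = unpack(params, channels, side);
  const int N = Ximg.n_cols;
  Adam adam;
  adam.init(net);
  Rng rng((uint64_t)seed + 1ULL);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  NumericVector epoch_loss(epochs), val_acc(epochs);

  for (int e = 0; e < epochs; ++e) {
    // fluorescence dropout, re-drawn each epoch: an event keeps its signal
    // with probability 1 - mask_p, otherwise it is presented as absent
    // (zeros + presence flag 0)
    mat Xfl_e = Xfl;
    for (int i = 0; i < N; ++i)
      if (rng.unif() < mask_p) Xfl_e.col(i).zeros();
    for (int i = N - 1; i > 0; --i)
      std::swap(idx[i], idx[rng.below(i + 1)]);

    double tot = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int stop = std::min(N, start + batch_size), nb = stop - start;
      Grads g;
      g.init(net);
      for (int i = start; i < stop; ++i)
        tot += backward_sample(net, Ximg.col(idx[i]), Xfl_e.col(idx[i]),
                               y[idx[i]] - 1, g);
      const double inv = 1.0 / nb;
      for (int b = 0; b < net.B; ++b) {
        g.W1[b] *= inv; g.b1[b] *= inv; g.W2[b] *= inv; g.b2[b] *= inv;
      }
      g.Wf *= inv; g.bf *= inv; g.Wo *= inv; g.bo *= inv;
      adam.step(net, g, lr);
    }
    epoch_loss[e] = tot / N;

    if (Vimg.n_cols > 0) {
      int ok = 0;
      vec cat, ffl_pre;
      for (uword i = 0; i < Vimg.n_cols; ++i) {
        vec logits = forward_sample(net, Vimg.col(i), Vfl.col(i), nullptr,
                                    cat, ffl_pre);
        if ((int)logits.index_max() == yv[i] - 1) ++ok;
      }
      val_acc[e] = (double)ok / Vimg.n_cols;
    } else {
      val_acc[e] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack(net), _["epoch_loss"] = epoch_loss,
                      _["val_acc"] = val_acc);
}
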