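// Small CNN engine for the per-feature-map weak classifiers.
//
// Layer stack: [conv(k x k, same padding) -> ReLU -> maxpool(2x2, stride 2)]*L
//              -> flatten -> dense(hidden) -> ReLU -> dropout -> dense -> softmax
// Training: mini-batch SGD with momentum on categorical cross-entropy.
//
// Whole mini-batches are pushed through each layer jointly (im2col rows of
// all samples stacked), so every convolution is one large GEMM: on the
// single-CPU budgets this package targets, BLAS utilization dominates the
// run time of the whole pipeline.
//
// All randomness (init, shuffling, dropout) comes from a private mt19937
// stream; normal deviates use Box-Muller, never std::normal_distribution,
// so identical seeds give identical parameters on any platform.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

constexpr int kChunk = 16;  // max samples pushed through a joint GEMM

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  double unif() {
    return (static_cast<double>(gen()) + 0.5) / 4294967296.0;
  }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int below(int n) {
    return static_cast<int>(gen() % static_cast<uint32_t>(n));
  }
};

struct Net {
  std::vector<mat> conv_w;   // (k*k*Cin) x F
  std::vector<vec> conv_b;
  std::vector<int> ksize;
  mat fc1_w; vec fc1_b;      // flat x hidden
  mat fc2_w; vec fc2_b;      // hidden x classes
  int in_h, in_w;

  static Net from_list(const List& params) {
    Net n;
    List cw = params["conv_w"], cb = params["conv_b"];
    IntegerVector ks = params["ksize"];
    for (int l = 0; l < cw.size(); ++l) {
      n.conv_w.push_back(as<mat>(cw[l]));
      n.conv_b.push_back(as<vec>(cb[l]));
      n.ksize.push_back(ks[l]);
    }
    n.fc1_w = as<mat>(params["fc1_w"]); n.fc1_b = as<vec>(params["fc1_b"]);
    n.fc2_w = as<mat>(params["fc2_w"]); n.fc2_b = as<vec>(params["fc2_b"]);
    n.in_h = params["in_h"]; n.in_w = params["in_w"];
    return n;
  }
};

// Activations of one layer for a chunk of B samples: rows are the H*W
// spatial positions of sample 0, then sample 1, ... ; columns are channels.
struct Act {
  int H, W, C, B;
  mat data;  // (H*W*B) x C
};

// im2col with 'same' padding (top/left (k-1)/2, remainder bottom/right).
mat im2col_same(const Act& a, int k) {
  const int H = a.H, W = a.W, C = a.C, B = a.B, HW = H * W;
  const int p = (k - 1) / 2;
  mat out(static_cast<uword>(HW) * B, static_cast<uword>(k) * k * C);
  mat padded(H + k - 1, W + k - 1);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      padded.zeros();
      padded.submat(p, p, p + H - 1, p + W - 1) =
          arma::reshape(a.data.col(c).rows(s * HW, (s + 1) * HW - 1), H, W);
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          uword col = static_cast<uword>(c) * k * k + dj * k + di;
          out.col(col).rows(s * HW, (s + 1) * HW - 1) = arma::vectorise(
              padded.submat(di, dj, di + H - 1, dj + W - 1));
        }
    }
  return out;
}

// scatter-add of column gradients back onto the inputs
void col2im_same(const mat& dcols, Act& din, int k) {
  const int H = din.H, W = din.W, C = din.C, B = din.B, HW = H * W;
  const int p = (k - 1) / 2;
  din.data.zeros();
  mat padded(H + k - 1, W + k - 1);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      padded.zeros();
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          uword col = static_cast<uword>(c) * k * k + dj * k + di;
          padded.submat(di, dj, di + H - 1, dj + W - 1) += arma::reshape(
              dcols.col(col).rows(s * HW, (s + 1) * HW - 1), H, W);
        }
      din.data.col(c).rows(s * HW, (s + 1) * HW - 1) = arma::vectorise(
          padded.submat(p, p, p + H - 1, p + W - 1));
    }
}

void maxpool(const Act& in, Act& out, arma::umat& argmax) {
  const int H2 = in.H / 2, W2 = in.W / 2, HW = in.H * in.W, HW2 = H2 * W2;
  out.H = H2; out.W = W2; out.C = in.C; out.B = in.B;
  out.data.set_size(static_cast<uword>(HW2) * in.B, in.C);
  argmax.set_size(static_cast<uword>(HW2) * in.B, in.C);
  for (int c = 0; c < in.C; ++c) {
    const double* src = in.data.colptr(c);
    double* dst = out.data.colptr(c);
    uword* am = argmax.colptr(c);
    for (int s = 0; s < in.B; ++s)
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          uword base = static_cast<uword>(s) * HW + 2 * j * in.H + 2 * i;
          uword best = base;
          double bv = src[base];
          const uword cand[3] = {base + 1, base + static_cast<uword>(in.H),
                                 base + static_cast<uword>(in.H) + 1};
          for (uword t : cand)
            if (src[t] > bv) { bv = src[t]; best = t; }
          uword o = static_cast<uword>(s) * HW2 + j * H2 + i;
          dst[o] = bv;
          am[o] = best;
        }
  }
}

void maxpool_back(const mat& dout, const arma::umat& argmax, Act& din) {
  din.data.zeros();
  for (uword c = 0; c < dout.n_cols; ++c) {
    const double* d = dout.colptr(c);
    const uword* am = argmax.colptr(c);
    double* dst = din.data.colptr(c);
    for (uword r = 0; r < dout.n_rows; ++r) dst[am[r]] += d[r];
  }
}

struct ChunkCache {
  std::vector<mat> cols;         // im2col per conv layer
  std::vector<mat> convZ;        // pre-ReLU conv outputs
  std::vector<arma::umat> arg;   // maxpool argmax
  std::vector<Act> pre;          // activation entering each conv
  mat flat;                      // flat x B
  mat h1pre, h1;                 // hidden x B
  mat probs;                     // classes x B
};

// flatten pooled activations to (H*W*C) x B column vectors, matching the
// (row, col, channel) order of cube vectorisation
mat flatten(const Act& a) {
  const int HW = a.H * a.W;
  mat out(static_cast<uword>(HW) * a.C, a.B);
  for (int s = 0; s < a.B; ++s)
    for (int c = 0; c < a.C; ++c)
      out.col(s).rows(static_cast<uword>(c) * HW,
                      static_cast<uword>(c + 1) * HW - 1) =
          a.data.col(c).rows(s * HW, (s + 1) * HW - 1);
  return out;
}

void unflatten(const mat& dflat, Act& a) {
  const int HW = a.H * a.W;
  a.data.set_size(static_cast<uword>(HW) * a.B, a.C);
  for (int s = 0; s < a.B; ++s)
    for (int c = 0; c < a.C; ++c)
      a.data.col(c).rows(s * HW, (s + 1) * HW - 1) =
          dflat.col(s).rows(static_cast<uword>(c) * HW,
                            static_cast<uword>(c + 1) * HW - 1);
}

// forward a chunk; dropmask (hidden x B) empty => inference (no dropout)
void forward_chunk(const Net& net, const cube& X,
                   const std::vector<int>& idx, ChunkCache& c,
                   const mat& dropmask, bool keep) {
  const int B = idx.size(), HW = net.in_h * net.in_w;
  Act a;
  a.H = net.in_h; a.W = net.in_w; a.C = 1; a.B = B;
  a.data.set_size(static_cast<uword>(HW) * B, 1);
  for (int s = 0; s < B; ++s)
    a.data.col(0).rows(s * HW, (s + 1) * HW - 1) =
        arma::vectorise(X.slice(idx[s]));
  c.cols.clear(); c.convZ.clear(); c.arg.clear(); c.pre.clear();
  for (size_t l = 0; l < net.conv_w.size(); ++l) {
    if (keep) c.pre.push_back(a);
    mat cols = im2col_same(a, net.ksize[l]);
    mat Z = cols * net.conv_w[l];
    Z.each_row() += net.conv_b[l].t();
    if (keep) { c.cols.push_back(std::move(cols)); c.convZ.push_back(Z); }
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    Act act{a.H, a.W, static_cast<int>(Z.n_cols), B, std::move(Z)};
    arma::umat am;
    maxpool(act, a, am);
    if (keep) c.arg.push_back(std::move(am));
  }
  c.flat = flatten(a);
  c.h1pre = net.fc1_w.t() * c.flat;
  c.h1pre.each_col() += net.fc1_b;
  c.h1 = arma::clamp(c.h1pre, 0.0, arma::datum::inf);
  if (dropmask.n_elem) c.h1 %= dropmask;
  mat z2 = net.fc2_w.t() * c.h1;
  z2.each_col() += net.fc2_b;
  z2.each_row() -= arma::max(z2, 0);
  c.probs = arma::exp(z2);
  c.probs.each_row() /= arma::sum(c.probs, 0);
}

struct Grads {
  std::vector<mat> conv_w; std::vector<vec> conv_b;
  mat fc1_w; vec fc1_b; mat fc2_w; vec fc2_b;
  void zeros_like(const Net& n) {
    conv_w.clear(); conv_b.clear();
    for (size_t l = 0; l < n.conv_w.size(); ++l) {
      conv_w.push_back(mat(arma::size(n.conv_w[l]), arma::fill::zeros));
      conv_b.push_back(vec(n.conv_b[l].n_elem, arma::fill::zeros));
    }
    fc1_w.zeros(arma::size(n.fc1_w)); fc1_b.zeros(n.fc1_b.n_elem);
    fc2_w.zeros(arma::size(n.fc2_w)); fc2_b.zeros(n.fc2_b.n_elem);
  }
};

// backward a chunk; grads are summed over the chunk's samples
void backward_chunk(const Net& net, const ChunkCache& c,
                    const IntegerVector& y, const std::vector<int>& idx,
                    const mat& dropmask, Grads& g) {
  const int B = idx.size();
  mat dz2 = c.probs;
  for (int s = 0; s < B; ++s) dz2(y[idx[s]], s) -= 1.0;
  g.fc2_w += c.h1 * dz2.t();
  g.fc2_b += arma::sum(dz2, 1);
  mat dh1 = net.fc2_w * dz2;
  if (dropmask.n_elem) dh1 %= dropmask;
  mat dpre1 = dh1 % arma::conv_to<mat>::from(c.h1pre > 0.0);
  g.fc1_w += c.flat * dpre1.t();
  g.fc1_b += arma::sum(dpre1, 1);
  mat dflat = net.fc1_w * dpre1;

  const int L = net.conv_w.size();
  Act da;  // gradient leaving the last pool
  da.H = c.pre[L - 1].H / 2; da.W = c.pre[L - 1].W / 2;
  da.C = net.conv_w[L - 1].n_cols; da.B = B;
  unflatten(dflat, da);
  for (int l = L - 1; l >= 0; --l) {
    Act dact{c.pre[l].H, c.pre[l].W, static_cast<int>(c.convZ[l].n_cols), B,
             mat(c.convZ[l].n_rows, c.convZ[l].n_cols)};
    maxpool_back(da.data, c.arg[l], dact);
    dact.data %= arma::conv_to<mat>::from(c.convZ[l] > 0.0);  // ReLU gate
    g.conv_w[l] += c.cols[l].t() * dact.data;
    g.conv_b[l] += arma::sum(dact.data, 0).t();
    if (l > 0) {
      mat dcols = dact.data * net.conv_w[l].t();
      da.H = c.pre[l].H; da.W = c.pre[l].W; da.C = c.pre[l].C; da.B = B;
      da.data.set_size(c.pre[l].data.n_rows, c.pre[l].data.n_cols);
      col2im_same(dcols, da, net.ksize[l]);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_cnn_init(IntegerVector filters, IntegerVector ksize,
                  int in_h, int in_w, int hidden, int n_classes, int seed) {
  Rng rng(static_cast<uint32_t>(seed));
  List cw(filters.size()), cb(filters.size());
  int h = in_h, w = in_w, cin = 1;
  for (int l = 0; l < filters.size(); ++l) {
    int k = ksize[l], f = filters[l];
    int fan_in = k * k * cin;
    double sd = std::sqrt(2.0 / fan_in);
    mat W(fan_in, f);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = sd * rng.norm();
    cw[l] = W;
    cb[l] = vec(f, arma::fill::zeros);
    h /= 2; w /= 2; cin = f;
  }
  int flat = h * w * cin;
  double sd1 = std::sqrt(2.0 / flat);
  mat fc1(flat, hidden);
  for (uword i = 0; i < fc1.n_elem; ++i) fc1(i) = sd1 * rng.norm();
  double sd2 = std::sqrt(2.0 / hidden);
  mat fc2(hidden, n_classes);
  for (uword i = 0; i < fc2.n_elem; ++i) fc2(i) = sd2 * rng.norm();
  return List::create(
      _["conv_w"] = cw, _["conv_b"] = cb, _["ksize"] = ksize,
      _["fc1_w"] = fc1, _["fc1_b"] = vec(hidden, arma::fill::zeros),
      _["fc2_w"] = fc2, _["fc2_b"] = vec(n_classes, arma::fill::zeros),
      _["in_h"] = in_h, _["in_w"] = in_w);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(List params, const arma::cube& X) {
  Net net = Net::from_list(params);
  const int N = X.n_slices;
  mat out(N, net.fc2_w.n_cols);
  ChunkCache c;
  mat nodrop;
  for (int start = 0; start < N; start += kChunk) {
    int bn = std::min(kChunk, N - start);
    std::vector<int> idx(bn);
    for (int i = 0; i < bn; ++i) idx[i] = start + i;
    forward_chunk(net, X, idx, c, nodrop, false);
    for (int i = 0; i < bn; ++i) out.row(start + i) = c.probs.col(i).t();
  }
  return out;
}

// [[Rcpp::export]]
double cpp_cnn_loss(List params, const arma::cube& X, IntegerVector y) {
  mat p = cpp_cnn_predict(params, X);
  double loss = 0.0;
  for (uword s = 0; s < X.n_slices; ++s)
    loss += -std::log(std::max(p(s, y[s]), 1e-12));
  return loss / X.n_slices;
}

// [[Rcpp::export]]
List cpp_cnn_train(List params, const arma::cube& X, IntegerVector y,
                   int epochs, double lr, double momentum, int batch,
                   double dropout, int seed, Nullable<List> velocity_) {
  Net net = Net::from_list(params);
  const int N = X.n_slices;
  Rng rng(static_cast<uint32_t>(seed));

  Grads vel;
  vel.zeros_like(net);
  if (velocity_.isNotNull()) {
    List v(velocity_);
    List vcw = v["conv_w"], vcb = v["conv_b"];
    for (size_t l = 0; l < net.conv_w.size(); ++l) {
      vel.conv_w[l] = as<mat>(vcw[l]); vel.conv_b[l] = as<vec>(vcb[l]);
    }
    vel.fc1_w = as<mat>(v["fc1_w"]); vel.fc1_b = as<vec>(v["fc1_b"]);
    vel.fc2_w = as<mat>(v["fc2_w"]); vel.fc2_b = as<vec>(v["fc2_b"]);
  }

  const uword hidden = net.fc1_w.n_cols;
  NumericVector epoch_loss(epochs);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  Grads g;
  ChunkCache c;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = N - 1; i > 0; --i)
      std::swap(order[i], order[rng.below(i + 1)]);
    double lsum = 0.0;
    for (int start = 0; start < N; start += batch) {
      int bn = std::min(batch, N - start);
      g.zeros_like(net);
      for (int cs = 0; cs < bn; cs += kChunk) {
        int cn = std::min(kChunk, bn - cs);
        std::vector<int> idx(order.begin() + start + cs,
                             order.begin() + start + cs + cn);
        mat mask(hidden, cn);
        if (dropout > 0.0) {
          for (int s = 0; s < cn; ++s)
            for (uword i = 0; i < hidden; ++i)
              mask(i, s) =
                  rng.unif() < dropout ? 0.0 : 1.0 / (1.0 - dropout);
        } else mask.fill(1.0);
        forward_chunk(net, X, idx, c, mask, true);
        for (int s = 0; s < cn; ++s)
          lsum += -std::log(std::max(c.probs(y[idx[s]], s), 1e-12));
        backward_chunk(net, c, y, idx, mask, g);
      }
      double inv = 1.0 / bn;
      for (size_t l = 0; l < net.conv_w.size(); ++l) {
        vel.conv_w[l] = momentum * vel.conv_w[l] - lr * inv * g.conv_w[l];
        vel.conv_b[l] = momentum * vel.conv_b[l] - lr * inv * g.conv_b[l];
        net.conv_w[l] += vel.conv_w[l];
        net.conv_b[l] += vel.conv_b[l];
      }
      vel.fc1_w = momentum * vel.fc1_w - lr * inv * g.fc1_w;
      vel.fc1_b = momentum * vel.fc1_b - lr * inv * g.fc1_b;
      vel.fc2_w = momentum * vel.fc2_w - lr * inv * g.fc2_w;
      vel.fc2_b = momentum * vel.fc2_b - lr * inv * g.fc2_b;
      net.fc1_w += vel.fc1_w; net.fc1_b += vel.fc1_b;
      net.fc2_w += vel.fc2_w; net.fc2_b += vel.fc2_b;
    }
    epoch_loss[ep] = lsum / N;
  }

  List cw(net.conv_w.size()), cb(net.conv_b.size());
  List vcw(net.conv_w.size()), vcb(net.conv_b.size());
  for (size_t l = 0; l < net.conv_w.size(); ++l) {
    cw[l] = net.conv_w[l]; cb[l] = net.conv_b[l];
    vcw[l] = vel.conv_w[l]; vcb[l] = vel.conv_b[l];
  }
  List out_params = List::create(
      _["conv_w"] = cw, _["conv_b"] = cb,
      _["ksize"] = params["ksize"],
      _["fc1_w"] = net.fc1_w, _["fc1_b"] = net.fc1_b,
      _["fc2_w"] = net.fc2_w, _["fc2_b"] = net.fc2_b,
      _["in_h"] = net.in_h, _["in_w"] = net.in_w);
  List out_vel = List::create(
      _["conv_w"] = vcw, _["conv_b"] = vcb,
      _["fc1_w"] = vel.fc1_w, _["fc1_b"] = vel.fc1_b,
      _["fc2_w"] = vel.fc2_w, _["fc2_b"] = vel.fc2_b);

  // deterministic post-step training loss (no dropout, fixed order)
  double final_loss = cpp_cnn_loss(out_params, X, y);

  return List::create(_["params"] = out_params, _["velocity"] = out_vel,
                      _["epoch_loss"] = epoch_loss,
                      _["final_loss"] = final_loss);
}
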