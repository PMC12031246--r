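// Compact CNN engine for small grayscale-image classifiers.
//
// Architecture: repeated [same-padded conv (kh x kw) -> ReLU -> 2x2 max
// pool] blocks, flatten, dense+ReLU, dense+softmax. Forward/backward use
// float32 im2col buffers multiplied with BLAS sgemm via Armadillo; the
// optimizer is Adam with minibatches, optional validation-based early
// stopping with best-weight restore. All randomness (shuffling) comes from
// a caller-supplied integer seed.
//
// Memory layout: the im2col buffer is (H*W) x (kh*kw*Cin) so that, for a
// fixed patch feature, writes and reads are contiguous memcpy spans; conv
// weights are kept transposed as Wt (kh*kw*Cin) x Cout so the convolution
// is a single gemm Y = cols * Wt with Y's columns being the channel
// planes (no reshuffling).

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::fcube;

namespace {

struct LayerDims {
  int H, W, C;      // input dims
  int Ho, Wo;       // after pooling
};

struct Net {
  int kh, kw, pool, dense_units, n_classes, H, W;
  std::vector<int> filters;
  std::vector<fmat> Wt;       // (kh*kw*cin) x cout
  std::vector<fvec> bc;
  fmat W1; fvec b1;           // dense_units x flat
  fmat W2; fvec b2;           // n_classes x dense_units
  std::vector<LayerDims> dims;
  int flat = 0;
};

void compute_dims(Net& net) {
  net.dims.clear();
  int H = net.H, W = net.W, C = 1;
  for (size_t l = 0; l < net.filters.size(); ++l) {
    LayerDims d;
    d.H = H; d.W = W; d.C = C;
    d.Ho = H / net.pool; d.Wo = W / net.pool;
    if (d.Ho < 1 || d.Wo < 1)
      Rcpp::stop("input too small for the pooling stack at conv layer %d", (int)l + 1);
    net.dims.push_back(d);
    H = d.Ho; W = d.Wo; C = net.filters[l];
  }
  net.flat = H * W * C;
}

Net net_from_r(const Rcpp::List& weights, const Rcpp::List& conf) {
  Net net;
  net.kh = Rcpp::as<int>(conf["kh"]);
  net.kw = Rcpp::as<int>(conf["kw"]);
  net.pool = Rcpp::as<int>(conf["pool"]);
  net.dense_units = Rcpp::as<int>(conf["dense_units"]);
  net.n_classes = Rcpp::as<int>(conf["n_classes"]);
  net.H = Rcpp::as<int>(conf["input_h"]);
  net.W = Rcpp::as<int>(conf["input_w"]);
  net.filters = Rcpp::as<std::vector<int>>(conf["conv_filters"]);

  Rcpp::List conv = weights["conv"];
  int cin = 1;
  for (size_t l = 0; l < net.filters.size(); ++l) {
    Rcpp::List layer = conv[l];
    Rcpp::NumericVector Wr = layer["W"];   // dim kh, kw, cin, cout
    Rcpp::NumericVector br = layer["b"];
    const int cout = net.filters[l];
    fmat Wt(net.kh * net.kw * cin, cout);
    // R array index: u + kh*(v + kw*(c + cin*o)); patch feature f = u + kh*(v + kw*c)
    for (int o = 0; o < cout; ++o)
      for (int c = 0; c < cin; ++c)
        for (int v = 0; v < net.kw; ++v)
          for (int u = 0; u < net.kh; ++u)
            Wt(u + net.kh * (v + net.kw * c), o) =
              (float)Wr[u + net.kh * (v + net.kw * (c + cin * (R_xlen_t)o))];
    net.Wt.push_back(std::move(Wt));
    net.bc.push_back(arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(br)));
    cin = cout;
  }
  Rcpp::List d1 = weights["dense1"], d2 = weights["dense2"];
  net.W1 = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(d1["W"]));
  net.b1 = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(d1["b"]));
  net.W2 = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(d2["W"]));
  net.b2 = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(d2["b"]));
  compute_dims(net);
  if ((int)net.W1.n_cols != net.flat)
    Rcpp::stop("dense layer expects %d inputs but the conv stack produces %d",
               (int)net.W1.n_cols, net.flat);
  return net;
}

Rcpp::List net_to_r(const Net& net) {
  Rcpp::List conv(net.filters.size());
  int cin = 1;
  for (size_t l = 0; l < net.filters.size(); ++l) {
    const int cout = net.filters[l];
    Rcpp::NumericVector Wr((R_xlen_t)net.kh * net.kw * cin * cout);
    Wr.attr("dim") = Rcpp::IntegerVector::create(net.kh, net.kw, cin, cout);
    for (int o = 0; o < cout; ++o)
      for (int c = 0; c < cin; ++c)
        for (int v = 0; v < net.kw; ++v)
          for (int u = 0; u < net.kh; ++u)
            Wr[u + net.kh * (v + net.kw * (c + cin * (R_xlen_t)o))] =
              net.Wt[l](u + net.kh * (v + net.kw * c), o);
    Rcpp::NumericVector br(cout);
    for (int o = 0; o < cout; ++o) br[o] = net.bc[l](o);
    conv[l] = Rcpp::List::create(Rcpp::Named("W") = Wr, Rcpp::Named("b") = br);
    cin = cout;
  }
  return Rcpp::List::create(
    Rcpp::Named("conv") = conv,
    Rcpp::Named("dense1") = Rcpp::List::create(
      Rcpp::Named("W") = arma::conv_to<arma::mat>::from(net.W1),
      Rcpp::Named("b") = arma::conv_to<arma::vec>::from(net.b1)),
    Rcpp::Named("dense2") = Rcpp::List::create(
      Rcpp::Named("W") = arma::conv_to<arma::mat>::from(net.W2),
      Rcpp::Named("b") = arma::conv_to<arma::vec>::from(net.b2)));
}

// im2col with zero ("same") padding, transposed layout: out(p, f) with
// p = i + H*j, f = u + kh*(v + kw*c); offsets top = (kh-1)/2, left = (kw-1)/2.
// For fixed (f, j) the i-span is contiguous in both source and destination.
void im2col_t(const fcube& X, int kh, int kw, fmat& out) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int top = (kh - 1) / 2, left = (kw - 1) / 2;
  out.zeros((R_xlen_t)H * W, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const float* slice = X.slice_memptr(c);
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const int f = u + kh * (v + kw * c);
        float* dst_col = out.colptr(f);
        const int i_lo = std::max(0, top - u);
        const int i_hi = std::min(H, H + top - u);
        if (i_hi <= i_lo) continue;
        for (int j = 0; j < W; ++j) {
          const int jj = j - left + v;
          if (jj < 0 || jj >= W) continue;
          std::memcpy(dst_col + i_lo + (R_xlen_t)H * j,
                      slice + (i_lo - top + u) + (R_xlen_t)H * jj,
                      sizeof(float) * (i_hi - i_lo));
        }
      }
    }
  }
}

// Scatter-add transpose of im2col_t.
void col2im_t(const fmat& cols, int kh, int kw, fcube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int top = (kh - 1) / 2, left = (kw - 1) / 2;
  X.zeros();
  for (int c = 0; c < C; ++c) {
    float* slice = X.slice_memptr(c);
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const int f = u + kh * (v + kw * c);
        const float* src_col = cols.colptr(f);
        const int i_lo = std::max(0, top - u);
        const int i_hi = std::min(H, H + top - u);
        if (i_hi <= i_lo) continue;
        for (int j = 0; j < W; ++j) {
          const int jj = j - left + v;
          if (jj < 0 || jj >= W) continue;
          float* dst = slice + (i_lo - top + u) + (R_xlen_t)H * jj;
          const float* src = src_col + i_lo + (R_xlen_t)H * j;
          for (int i = 0; i < i_hi - i_lo; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

struct ForwardCache {
  std::vector<fmat> activ;        // post-ReLU conv output, (H*W) x cout
  std::vector<arma::umat> argmax; // pooled argmax linear index per channel
  fvec flat, hidden, probs;
};

// One conv block: conv -> ReLU -> max pool. Yt columns are channel planes.
void conv_block_forward(const Net& net, int l, const fcube& X, fcube& pooled,
                        ForwardCache* cache, fmat& cols_buf) {
  const LayerDims& d = net.dims[l];
  const int cout = net.filters[l];
  im2col_t(X, net.kh, net.kw, cols_buf);
  fmat Yt = cols_buf * net.Wt[l];           // (H*W) x cout
  for (int o = 0; o < cout; ++o) {
    float* col = Yt.colptr(o);
    const float b = net.bc[l](o);
    const R_xlen_t n = (R_xlen_t)d.H * d.W;
    for (R_xlen_t k = 0; k < n; ++k) {
      const float y = col[k] + b;
      col[k] = y > 0.0f ? y : 0.0f;
    }
  }

  const int p = net.pool;
  pooled.set_size(d.Ho, d.Wo, cout);
  arma::umat amax(d.Ho * d.Wo, cout);
  for (int o = 0; o < cout; ++o) {
    const float* s = Yt.colptr(o);          // H x W plane
    for (int j = 0; j < d.Wo; ++j) {
      for (int i = 0; i < d.Ho; ++i) {
        float best = -std::numeric_limits<float>::infinity();
        R_xlen_t bpos = 0;
        for (int v = 0; v < p; ++v)
          for (int u = 0; u < p; ++u) {
            const R_xlen_t pos = (i * p + u) + (R_xlen_t)d.H * (j * p + v);
            if (s[pos] > best) { best = s[pos]; bpos = pos; }
          }
        pooled(i, j, o) = best;
        amax(i + d.Ho * (R_xlen_t)j, o) = bpos;
      }
    }
  }
  if (cache) {
    cache->activ.push_back(std::move(Yt));
    cache->argmax.push_back(std::move(amax));
  }
}

fvec softmax(fvec z) {
  z -= z.max();
  fvec e = arma::exp(z);
  return e / arma::accu(e);
}

fvec forward_one(const Net& net, const fcube& img, ForwardCache* cache,
                 std::vector<fmat>& cols_bufs) {
  fcube X = img;
  for (size_t l = 0; l < net.filters.size(); ++l) {
    fcube pooled;
    conv_block_forward(net, l, X, pooled, cache, cols_bufs[l]);
    X = std::move(pooled);
  }
  fvec flat(X.memptr(), X.n_elem);   // cube memory: column-major, slices consecutive
  fvec hidden = net.W1 * flat + net.b1;
  hidden.transform([](float y) { return y > 0.0f ? y : 0.0f; });
  fvec probs = softmax(net.W2 * hidden + net.b2);
  if (cache) { cache->flat = std::move(flat); cache->hidden = std::move(hidden); cache->probs = probs; }
  return probs;
}

struct Grads {
  std::vector<fmat> Wt; std::vector<fvec> bc;
  fmat W1; fvec b1; fmat W2; fvec b2;
  void zeros_like(const Net& net) {
    Wt.clear(); bc.clear();
    for (size_t l = 0; l < net.Wt.size(); ++l) {
      Wt.push_back(arma::zeros<fmat>(net.Wt[l].n_rows, net.Wt[l].n_cols));
      bc.push_back(arma::zeros<fvec>(net.bc[l].n_elem));
    }
    W1.zeros(net.W1.n_rows, net.W1.n_cols); b1.zeros(net.b1.n_elem);
    W2.zeros(net.W2.n_rows, net.W2.n_cols); b2.zeros(net.b2.n_elem);
  }
};

// Backward from a filled forward cache; accumulates into g. cols_bufs must
// still hold this image's im2col buffers from the forward pass (they are
// per-layer and nothing runs between forward and backward of one image).
void backward_from_cache(const Net& net, const ForwardCache& cache, int label,
                         Grads& g, std::vector<fmat>& cols_bufs) {
  fvec dlogits = cache.probs;
  dlogits(label) -= 1.0f;
  g.W2 += dlogits * cache.hidden.t();
  g.b2 += dlogits;
  fvec dhidden = net.W2.t() * dlogits;
  for (arma::uword i = 0; i < dhidden.n_elem; ++i)
    if (cache.hidden(i) <= 0.0f) dhidden(i) = 0.0f;
  g.W1 += dhidden * cache.flat.t();
  g.b1 += dhidden;
  fvec dflat = net.W1.t() * dhidden;

  const int L = (int)net.filters.size();
  const LayerDims& dl = net.dims[L - 1];
  fcube dpooled(dl.Ho, dl.Wo, net.filters[L - 1]);
  std::memcpy(dpooled.memptr(), dflat.memptr(), sizeof(float) * dflat.n_elem);

  for (int l = L - 1; l >= 0; --l) {
    const LayerDims& d = net.dims[l];
    const int cout = net.filters[l];
    // un-pool: route gradient to argmax positions (ReLU mask: activation > 0)
    fmat dYt((R_xlen_t)d.H * d.W, cout, arma::fill::zeros);
    const arma::umat& amax = cache.argmax[l];
    const fmat& A = cache.activ[l];
    for (int o = 0; o < cout; ++o) {
      const float* s = A.colptr(o);
      float* dy = dYt.colptr(o);
      for (int j = 0; j < d.Wo; ++j)
        for (int i = 0; i < d.Ho; ++i) {
          const arma::uword pos = amax(i + d.Ho * (R_xlen_t)j, o);
          if (s[pos] > 0.0f) dy[pos] += dpooled(i, j, o);
        }
    }
    g.Wt[l] += cols_bufs[l].t() * dYt;      // gemm with transpose flag
    g.bc[l] += arma::sum(dYt, 0).t();
    if (l > 0) {
      fmat dcols = dYt * net.Wt[l].t();
      fcube dX(d.H, d.W, d.C);
      col2im_t(dcols, net.kh, net.kw, dX);
      const LayerDims& dp = net.dims[l - 1];
      dpooled.set_size(dp.Ho, dp.Wo, net.filters[l - 1]);
      std::memcpy(dpooled.memptr(), dX.memptr(), sizeof(float) * dX.n_elem);
    }
  }
}

float backward_one(const Net& net, const fcube& img, int label, Grads& g,
                   std::vector<fmat>& cols_bufs) {
  ForwardCache cache;
  forward_one(net, img, &cache, cols_bufs);
  const float loss = -std::log(std::max(cache.probs(label), 1e-12f));
  backward_from_cache(net, cache, label, g, cols_bufs);
  return loss;
}

struct Adam {
  std::vector<fmat> mWt, vWt; std::vector<fvec> mbc, vbc;
  fmat mW1, vW1, mW2, vW2; fvec mb1, vb1, mb2, vb2;
  float lr, beta1 = 0.9f, beta2 = 0.999f, eps = 1e-7f;
  long t = 0;

  void init(const Net& net, float lr_) {
    lr = lr_;
    for (size_t l = 0; l < net.Wt.size(); ++l) {
      mWt.push_back(arma::zeros<fmat>(arma::size(net.Wt[l])));
      vWt.push_back(arma::zeros<fmat>(arma::size(net.Wt[l])));
      mbc.push_back(arma::zeros<fvec>(net.bc[l].n_elem));
      vbc.push_back(arma::zeros<fvec>(net.bc[l].n_elem));
    }
    mW1.zeros(arma::size(net.W1)); vW1.zeros(arma::size(net.W1));
    mW2.zeros(arma::size(net.W2)); vW2.zeros(arma::size(net.W2));
    mb1.zeros(net.b1.n_elem); vb1.zeros(net.b1.n_elem);
    mb2.zeros(net.b2.n_elem); vb2.zeros(net.b2.n_elem);
  }

  template <typename T>
  void step_one(T& w, const T& grad, T& m, T& v, float corr1, float corr2) {
    m = beta1 * m + (1.0f - beta1) * grad;
    v = beta2 * v + (1.0f - beta2) * (grad % grad);
    w -= lr * (m / corr1) / (arma::sqrt(v / corr2) + eps);
  }

  void step(Net& net, const Grads& g) {
    ++t;
    const float corr1 = 1.0f - std::pow(beta1, (float)t);
    const float corr2 = 1.0f - std::pow(beta2, (float)t);
    for (size_t l = 0; l < net.Wt.size(); ++l) {
      step_one(net.Wt[l], g.Wt[l], mWt[l], vWt[l], corr1, corr2);
      step_one(net.bc[l], g.bc[l], mbc[l], vbc[l], corr1, corr2);
    }
    step_one(net.W1, g.W1, mW1, vW1, corr1, corr2);
    step_one(net.b1, g.b1, mb1, vb1, corr1, corr2);
    step_one(net.W2, g.W2, mW2, vW2, corr1, corr2);
    step_one(net.b2, g.b2, mb2, vb2, corr1, corr2);
  }
};

// Inputs arrive in [0, 1]; the engine centers them to [-1, 1], which
// conditions the first conv layer's gradients much better than a 0.5-mean
// input. Purely internal: probabilities and gradients are unaffected
// beyond the reparameterization.
fcube image_from_r(const Rcpp::NumericVector& X, int H, int W, R_xlen_t n_idx) {
  fcube img(H, W, 1);
  const double* src = X.begin() + n_idx * (R_xlen_t)H * W;
  float* dst = img.memptr();
  for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k)
    dst[k] = (float)(2.0 * src[k] - 1.0);
  return img;
}

double eval_set(const Net& net, const Rcpp::NumericVector& X,
                const Rcpp::IntegerVector& y, std::vector<fmat>& bufs,
                double* acc_out) {
  const int n = y.size();
  double loss = 0.0; int correct = 0;
  for (int i = 0; i < n; ++i) {
    fcube img = image_from_r(X, net.H, net.W, i);
    fvec p = forward_one(net, img, nullptr, bufs);
    loss += -std::log(std::max((double)p(y[i]), 1e-12));
    if ((int)p.index_max() == y[i]) ++correct;   // index_max: lowest index wins ties
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  if (acc_out) *acc_out = (double)correct / n;
  return loss / n;
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_forward_probs(Rcpp::List weights, Rcpp::List conf,
                                      Rcpp::NumericVector X, int n) {
  Net net = net_from_r(weights, conf);
  std::vector<fmat> bufs(net.filters.size());
  Rcpp::NumericMatrix probs(n, net.n_classes);
  for (int i = 0; i < n; ++i) {
    fcube img = image_from_r(X, net.H, net.W, i);
    fvec p = forward_one(net, img, nullptr, bufs);
    for (int k = 0; k < net.n_classes; ++k) probs(i, k) = p(k);
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return probs;
}

// [[Rcpp::export]]
double cnn_mean_loss(Rcpp::List weights, Rcpp::List conf,
                     Rcpp::NumericVector X, Rcpp::IntegerVector y) {
  Net net = net_from_r(weights, conf);
  std::vector<fmat> bufs(net.filters.size());
  return eval_set(net, X, y, bufs, nullptr);
}

// [[Rcpp::export]]
Rcpp::List cnn_gradients(Rcpp::List weights, Rcpp::List conf,
                         Rcpp::NumericVector X, Rcpp::IntegerVector y) {
  Net net = net_from_r(weights, conf);
  std::vector<fmat> bufs(net.filters.size());
  Grads g; g.zeros_like(net);
  double loss = 0.0;
  const int n = y.size();
  for (int i = 0; i < n; ++i) {
    fcube img = image_from_r(X, net.H, net.W, i);
    loss += backward_one(net, img, y[i], g, bufs);
  }
  Net gn = net;   // reuse the converter for the gradient container
  for (size_t l = 0; l < g.Wt.size(); ++l) { gn.Wt[l] = g.Wt[l] / n; gn.bc[l] = g.bc[l] / n; }
  gn.W1 = g.W1 / n; gn.b1 = g.b1 / n; gn.W2 = g.W2 / n; gn.b2 = g.b2 / n;
  Rcpp::List out = net_to_r(gn);
  out["loss"] = loss / n;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_train(Rcpp::List weights, Rcpp::List conf,
                     Rcpp::NumericVector X, Rcpp::IntegerVector y,
                     Rcpp::Nullable<Rcpp::NumericVector> Xval,
                     Rcpp::Nullable<Rcpp::IntegerVector> yval,
                     double lr, int batch_size, int max_epochs,
                     int patience, int seed, bool verbose) {
  Net net = net_from_r(weights, conf);
  std::vector<fmat> bufs(net.filters.size());
  Adam adam; adam.init(net, (float)lr);
  const int n = y.size();
  if (n == 0) Rcpp::stop("empty training set");

  const bool has_val = Xval.isNotNull() && yval.isNotNull();
  Rcpp::NumericVector Xv; Rcpp::IntegerVector yv;
  if (has_val) { Xv = Xval.get(); yv = yval.get(); }

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> h_loss, h_acc, h_vloss, h_vacc;
  double best_vloss = std::numeric_limits<double>::infinity();
  int bad_epochs = 0;
  Rcpp::List best_weights;
  bool have_best = false;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0; int ep_correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      Grads g; g.zeros_like(net);
      for (int b = start; b < stop; ++b) {
        const int i = order[b];
        fcube img = image_from_r(X, net.H, net.W, i);
        ForwardCache cache;
        fvec p = forward_one(net, img, &cache, bufs);
        if ((int)p.index_max() == y[i]) ++ep_correct;
        ep_loss += -std::log(std::max(p(y[i]), 1e-12f));
        backward_from_cache(net, cache, y[i], g, bufs);
      }
      const float scale = 1.0f / (stop - start);
      for (size_t l = 0; l < g.Wt.size(); ++l) { g.Wt[l] *= scale; g.bc[l] *= scale; }
      g.W1 *= scale; g.b1 *= scale; g.W2 *= scale; g.b2 *= scale;
      adam.step(net, g);
      Rcpp::checkUserInterrupt();
    }
    h_loss.push_back(ep_loss / n);
    h_acc.push_back((double)ep_correct / n);

    if (has_val) {
      double vacc = 0.0;
      const double vloss = eval_set(net, Xv, yv, bufs, &vacc);
      h_vloss.push_back(vloss); h_vacc.push_back(vacc);
      if (verbose)
        Rcpp::Rcout << "epoch " << epoch + 1 << ": loss " << h_loss.back()
                    << " acc " << h_acc.back() << " val_loss " << vloss
                    << " val_acc " << vacc << "\n";
      if (vloss < best_vloss - 1e-6) {
        best_vloss = vloss; bad_epochs = 0;
        best_weights = net_to_r(net);
        have_best = true;
      } else if (++bad_epochs >= patience) {
        break;
      }
    } else {
      h_vloss.push_back(NA_REAL); h_vacc.push_back(NA_REAL);
      if (verbose)
        Rcpp::Rcout << "epoch " << epoch + 1 << ": loss " << h_loss.back()
                    << " acc " << h_acc.back() << "\n";
    }
  }

  Rcpp::List final_weights = have_best ? best_weights : net_to_r(net);
  const int n_ep = (int)h_loss.size();
  Rcpp::NumericVector ep(n_ep), lo(n_ep), ac(n_ep), vl(n_ep), va(n_ep);
  for (int i = 0; i < n_ep; ++i) {
    ep[i] = i + 1; lo[i] = h_loss[i]; ac[i] = h_acc[i];
    vl[i] = h_vloss[i]; va[i] = h_vacc[i];
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = final_weights,
    Rcpp::Named("epoch") = ep, Rcpp::Named("loss") = lo,
    Rcpp::Named("accuracy") = ac, Rcpp::Named("val_loss") = vl,
    Rcpp::Named("val_accuracy") = va);
}
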