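// Residual convolutional network for scalogram-to-blood-pressure
// regression: single-precision batched im2col + GEMM convolutions, batch
// normalisation, ReLU, strided residual blocks with 1x1 projection
// shortcuts, global average pooling and a small fully connected head.
// Includes the Adam training loop with an explicit L2 weight penalty on
// convolution / dense weights (biases and normalisation parameters
// excluded), matching the mean-over-batch half-squared-error loss.
//
// Activations for a whole mini-batch live in one C x (H*W*N) matrix so
// each convolution is a single GEMM; everything is deterministic given
// the initial parameters and the permutation schedule supplied by the
// caller.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

// batch of feature maps: column ix*H + iy of block i holds pixel (iy, ix)
// of image i; rows are channels
struct Act {
  fmat A;            // C x (H*W*N)
  int H = 0, W = 0, C = 0, N = 0;
};

struct ConvLayer {
  fmat W;            // Cout x (Cin*k*k)
  int k, stride, pad, Cin, Cout;
};
struct BN { fvec g, b, rm, rv; };
struct Dense { fmat W; fvec b; };

struct Block {
  ConvLayer c1, c2, sc;
  BN bn1, bn2, bnsc;
};

struct Net {
  ConvLayer stem;
  BN bn0;
  std::vector<Block> blocks;
  Dense fc1, fc2;
};

static int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// ---------------------------------------------------------------------------
// batched im2col / col2im

// rows of the patch matrix are ordered channel-fastest, (kx*k + ky)*C + c,
// so that every (kx, ky) tap of one output pixel is a contiguous C-float
// copy from one pixel column of A; weight matrices use the same ordering
static fmat im2col_batch(const Act& x, int k, int stride, int pad,
                         int& Ho, int& Wo) {
  Ho = out_dim(x.H, k, stride, pad);
  Wo = out_dim(x.W, k, stride, pad);
  const int P = Ho * Wo, HW = x.H * x.W, C = x.C;
  fmat cols(C * k * k, (size_t)x.N * P, fill::zeros);
  const float* Aptr = x.A.memptr();
  for (int i = 0; i < x.N; ++i) {
    const size_t xoff = (size_t)i * HW, coff = (size_t)i * P;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        float* dst = cols.colptr(coff + (size_t)ox * Ho + oy);
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= x.W) continue;
          const int ky0 = std::max(0, pad - oy * stride);
          const int ky1 = std::min(k, x.H + pad - oy * stride);
          const float* src = Aptr + (xoff + (size_t)ix * x.H +
                                     oy * stride - pad + ky0) * C;
          std::memcpy(dst + (kx * k + ky0) * C, src,
                      sizeof(float) * C * (ky1 - ky0));
        }
      }
    }
  }
  return cols;
}

static void col2im_batch(const fmat& cols, Act& dx, int k, int stride,
                         int pad) {
  const int Ho = out_dim(dx.H, k, stride, pad);
  const int Wo = out_dim(dx.W, k, stride, pad);
  const int P = Ho * Wo, HW = dx.H * dx.W, C = dx.C;
  dx.A.zeros(C, (size_t)dx.N * HW);
  float* Aptr = dx.A.memptr();
  for (int i = 0; i < dx.N; ++i) {
    const size_t xoff = (size_t)i * HW, coff = (size_t)i * P;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const float* src = cols.colptr(coff + (size_t)ox * Ho + oy);
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= dx.W) continue;
          const int ky0 = std::max(0, pad - oy * stride);
          const int ky1 = std::min(k, dx.H + pad - oy * stride);
          float* dst = Aptr + (xoff + (size_t)ix * dx.H +
                               oy * stride - pad + ky0) * C;
          const float* s = src + (kx * k + ky0) * C;
          const int nn = C * (ky1 - ky0);
          for (int t = 0; t < nn; ++t) dst[t] += s[t];
        }
      }
    }
  }
}

static Act conv_forward(const Act& x, const ConvLayer& L, fmat& cols) {
  Act out;
  int Ho, Wo;
  cols = im2col_batch(x, L.k, L.stride, L.pad, Ho, Wo);
  out.A = L.W * cols;
  out.H = Ho; out.W = Wo; out.C = L.Cout; out.N = x.N;
  return out;
}

static Act conv_backward(const Act& dy, const fmat& cols, const ConvLayer& L,
                         int Hin, int Win, fmat& dW) {
  dW += dy.A * cols.t();
  fmat dcols = L.W.t() * dy.A;
  Act dx;
  dx.H = Hin; dx.W = Win; dx.C = L.Cin; dx.N = dy.N;
  col2im_batch(dcols, dx, L.k, L.stride, L.pad);
  return dx;
}

// ---------------------------------------------------------------------------
// batch normalisation: per-channel = per-row statistics

struct BNCache { fvec mu, var; };

static void bn_forward(Act& z, BN& bn, bool train, BNCache& cache) {
  const float m = (float)z.A.n_cols;
  fvec mu, var;
  if (train) {
    mu = mean(z.A, 1);
    var = mean(square(z.A.each_col() - mu), 1);
    bn.rm = (1.0f - BN_MOMENTUM) * bn.rm + BN_MOMENTUM * mu;
    bn.rv = (1.0f - BN_MOMENTUM) * bn.rv + BN_MOMENTUM * var;
  } else {
    mu = bn.rm; var = bn.rv;
  }
  cache.mu = mu; cache.var = var;
  const fvec s = bn.g / sqrt(var + BN_EPS);
  const fvec o = bn.b - s % mu;
  z.A.each_col() %= s;
  z.A.each_col() += o;
  (void)m;
}

// dy.A in place becomes dx; z_in is the ORIGINAL BN input
static void bn_backward(Act& dy, const Act& z_in, const BN& bn,
                        const BNCache& cache, fvec& dg, fvec& db) {
  const float m = (float)dy.A.n_cols;
  const fvec inv_sd = 1.0f / sqrt(cache.var + BN_EPS);
  const fvec sum_dy = sum(dy.A, 1);
  // sum of dy * xhat per channel
  fvec sum_dy_xhat = sum(dy.A % (z_in.A.each_col() - cache.mu), 1) % inv_sd;
  dg += sum_dy_xhat;
  db += sum_dy;
  const fvec a = bn.g % inv_sd;
  const fvec b1 = sum_dy / m;
  const fvec b2 = sum_dy_xhat / m % inv_sd;
  // dx = a * (dy - b1 - (x - mu) * inv_sd^2 * sum_dy_xhat / m)
  dy.A.each_col() -= b1;
  dy.A -= (z_in.A.each_col() - cache.mu).eval().each_col() % b2;
  dy.A.each_col() %= a;
}

static void relu_inplace(Act& a) {
  a.A.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// ---------------------------------------------------------------------------
// parameter plumbing

static ConvLayer conv_from(const List& p, const std::string& nm, int Cin,
                           int Cout, int k, int stride) {
  ConvLayer L;
  L.W = conv_to<fmat>::from(Rcpp::as<mat>(p[nm]));
  L.k = k; L.stride = stride; L.pad = (k - 1) / 2;
  L.Cin = Cin; L.Cout = Cout;
  if ((int)L.W.n_rows != Cout || (int)L.W.n_cols != Cin * k * k)
    Rcpp::stop("construction error: %s has shape %dx%d, expected %dx%d",
               nm.c_str(), (int)L.W.n_rows, (int)L.W.n_cols, Cout,
               Cin * k * k);
  return L;
}

static BN bn_from(const List& p, const std::string& base, int C) {
  BN bn;
  bn.g = conv_to<fvec>::from(Rcpp::as<vec>(p[base + "_g"]));
  bn.b = conv_to<fvec>::from(Rcpp::as<vec>(p[base + "_b"]));
  bn.rm = conv_to<fvec>::from(Rcpp::as<vec>(p[base + "_rm"]));
  bn.rv = conv_to<fvec>::from(Rcpp::as<vec>(p[base + "_rv"]));
  if ((int)bn.g.n_elem != C)
    Rcpp::stop("construction error: %s has %d channels, expected %d",
               base.c_str(), (int)bn.g.n_elem, C);
  return bn;
}

static Net net_from(const List& params, const List& spec) {
  Net net;
  const int stem_k = spec["stem_kernel"], stem_s = spec["stem_stride"];
  const int C0 = spec["stem_channels"];
  ivec bc = Rcpp::as<ivec>(spec["block_channels"]);
  const int hidden = spec["head_hidden"];
  net.stem = conv_from(params, "stem_W", 1, C0, stem_k, stem_s);
  net.bn0 = bn_from(params, "stem_bn", C0);
  int cin = C0;
  for (size_t b = 0; b < bc.n_elem; ++b) {
    const std::string pre = "b" + std::to_string(b + 1);
    Block blk;
    blk.c1 = conv_from(params, pre + "_conv1_W", cin, bc(b), 3, 2);
    blk.bn1 = bn_from(params, pre + "_bn1", bc(b));
    blk.c2 = conv_from(params, pre + "_conv2_W", bc(b), bc(b), 3, 1);
    blk.bn2 = bn_from(params, pre + "_bn2", bc(b));
    blk.sc = conv_from(params, pre + "_sc_W", cin, bc(b), 1, 2);
    blk.bnsc = bn_from(params, pre + "_bnsc", bc(b));
    net.blocks.push_back(blk);
    cin = bc(b);
  }
  net.fc1.W = conv_to<fmat>::from(Rcpp::as<mat>(params["fc1_W"]));
  net.fc1.b = conv_to<fvec>::from(Rcpp::as<vec>(params["fc1_b"]));
  net.fc2.W = conv_to<fmat>::from(Rcpp::as<mat>(params["fc2_W"]));
  net.fc2.b = conv_to<fvec>::from(Rcpp::as<vec>(params["fc2_b"]));
  if ((int)net.fc1.W.n_rows != hidden || (int)net.fc1.W.n_cols != cin)
    Rcpp::stop("construction error: fc1_W expected %dx%d", hidden, cin);
  if ((int)net.fc2.W.n_rows != 2 || (int)net.fc2.W.n_cols != hidden)
    Rcpp::stop("construction error: fc2_W expected 2x%d", hidden);
  return net;
}

static List net_to_list(const Net& net, const List& proto) {
  List out = Rcpp::clone(proto);
  out["stem_W"] = conv_to<mat>::from(net.stem.W);
  auto put_bn = [&out](const std::string& base, const BN& bn) {
    out[base + "_g"] = conv_to<vec>::from(bn.g);
    out[base + "_b"] = conv_to<vec>::from(bn.b);
    out[base + "_rm"] = conv_to<vec>::from(bn.rm);
    out[base + "_rv"] = conv_to<vec>::from(bn.rv);
  };
  put_bn("stem_bn", net.bn0);
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    const std::string pre = "b" + std::to_string(b + 1);
    out[pre + "_conv1_W"] = conv_to<mat>::from(net.blocks[b].c1.W);
    out[pre + "_conv2_W"] = conv_to<mat>::from(net.blocks[b].c2.W);
    out[pre + "_sc_W"] = conv_to<mat>::from(net.blocks[b].sc.W);
    put_bn(pre + "_bn1", net.blocks[b].bn1);
    put_bn(pre + "_bn2", net.blocks[b].bn2);
    put_bn(pre + "_bnsc", net.blocks[b].bnsc);
  }
  out["fc1_W"] = conv_to<mat>::from(net.fc1.W);
  out["fc1_b"] = conv_to<vec>::from(net.fc1.b);
  out["fc2_W"] = conv_to<mat>::from(net.fc2.W);
  out["fc2_b"] = conv_to<vec>::from(net.fc2.b);
  return out;
}

// ---------------------------------------------------------------------------
// forward / backward over one batch

struct BatchCache {
  fmat stem_cols;
  Act stem_z, stem_a;
  BNCache stem_bnc;
  struct BlockCache {
    fmat cols1, cols2, colsc;
    Act z1, a1, z2, zs, out;
    BNCache bnc1, bnc2, bncsc;
    int Hin, Win;
  };
  std::vector<BlockCache> blocks;
  fmat feat;                       // C x N after GAP
  fmat h1;                         // hidden post-ReLU
};

static fmat forward_batch(Net& net, const Act& X, bool train,
                          BatchCache& cache) {
  const int N = X.N;
  cache.stem_z = conv_forward(X, net.stem, cache.stem_cols);
  cache.stem_a = cache.stem_z;
  bn_forward(cache.stem_a, net.bn0, train, cache.stem_bnc);
  relu_inplace(cache.stem_a);

  const Act* in = &cache.stem_a;
  cache.blocks.resize(net.blocks.size());
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    Block& blk = net.blocks[b];
    auto& bc = cache.blocks[b];
    bc.Hin = in->H; bc.Win = in->W;
    bc.z1 = conv_forward(*in, blk.c1, bc.cols1);
    bc.a1 = bc.z1;
    bn_forward(bc.a1, blk.bn1, train, bc.bnc1);
    relu_inplace(bc.a1);
    bc.z2 = conv_forward(bc.a1, blk.c2, bc.cols2);
    Act y2 = bc.z2;
    bn_forward(y2, blk.bn2, train, bc.bnc2);
    bc.zs = conv_forward(*in, blk.sc, bc.colsc);
    Act ys = bc.zs;
    bn_forward(ys, blk.bnsc, train, bc.bncsc);
    bc.out = y2;
    bc.out.A += ys.A;
    relu_inplace(bc.out);
    in = &bc.out;
  }

  // global average pooling -> features C x N
  const int C = in->C, P = in->H * in->W;
  cache.feat.set_size(C, N);
  for (int i = 0; i < N; ++i)
    cache.feat.col(i) = mean(in->A.cols((size_t)i * P, (size_t)(i + 1) * P - 1), 1);

  fmat h = net.fc1.W * cache.feat;
  h.each_col() += net.fc1.b;
  h.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  cache.h1 = h;
  fmat out = net.fc2.W * h;        // 2 x N
  out.each_col() += net.fc2.b;
  return out;
}

struct Grads {
  fmat stem_W;
  fvec stem_g, stem_b;
  struct BlockG {
    fmat W1, W2, Wsc;
    fvec g1, b1, g2, b2, gsc, bsc;
  };
  std::vector<BlockG> blocks;
  fmat fc1_W, fc2_W;
  fvec fc1_b, fc2_b;
  void init(const Net& net) {
    stem_W.zeros(size(net.stem.W));
    stem_g.zeros(net.bn0.g.n_elem); stem_b.zeros(net.bn0.g.n_elem);
    blocks.resize(net.blocks.size());
    for (size_t b = 0; b < net.blocks.size(); ++b) {
      blocks[b].W1.zeros(size(net.blocks[b].c1.W));
      blocks[b].W2.zeros(size(net.blocks[b].c2.W));
      blocks[b].Wsc.zeros(size(net.blocks[b].sc.W));
      const int C = net.blocks[b].bn1.g.n_elem;
      blocks[b].g1.zeros(C); blocks[b].b1.zeros(C);
      blocks[b].g2.zeros(C); blocks[b].b2.zeros(C);
      blocks[b].gsc.zeros(C); blocks[b].bsc.zeros(C);
    }
    fc1_W.zeros(size(net.fc1.W)); fc1_b.zeros(net.fc1.b.n_elem);
    fc2_W.zeros(size(net.fc2.W)); fc2_b.zeros(net.fc2.b.n_elem);
  }
};

static void backward_batch(Net& net, const Act& X, const fmat& dout,
                           BatchCache& cache, Grads& g) {
  // head
  g.fc2_W += dout * cache.h1.t();
  g.fc2_b += sum(dout, 1);
  fmat dh = net.fc2.W.t() * dout;
  dh.elem(find(cache.h1 <= 0.0f)).zeros();
  g.fc1_W += dh * cache.feat.t();
  g.fc1_b += sum(dh, 1);
  fmat dfeat = net.fc1.W.t() * dh;   // C x N

  // un-pool into the last block's output shape
  auto& lastc = cache.blocks.back();
  Act dx;
  dx.H = lastc.out.H; dx.W = lastc.out.W; dx.C = lastc.out.C;
  dx.N = lastc.out.N;
  const int P = dx.H * dx.W;
  const float inv_hw = 1.0f / (float)P;
  dx.A.set_size(dx.C, lastc.out.A.n_cols);
  for (int i = 0; i < dx.N; ++i)
    dx.A.cols((size_t)i * P, (size_t)(i + 1) * P - 1) =
      repmat(dfeat.col(i) * inv_hw, 1, P);

  // blocks, reversed
  for (int b = (int)net.blocks.size() - 1; b >= 0; --b) {
    Block& blk = net.blocks[b];
    auto& bc = cache.blocks[b];
    auto& bg = g.blocks[b];
    dx.A.elem(find(bc.out.A <= 0.0f)).zeros();
    // shortcut branch
    Act dys = dx;
    bn_backward(dys, bc.zs, blk.bnsc, bc.bncsc, bg.gsc, bg.bsc);
    Act dx_sc = conv_backward(dys, bc.colsc, blk.sc, bc.Hin, bc.Win, bg.Wsc);
    // main branch
    bn_backward(dx, bc.z2, blk.bn2, bc.bnc2, bg.g2, bg.b2);
    Act da1 = conv_backward(dx, bc.cols2, blk.c2, bc.a1.H, bc.a1.W, bg.W2);
    da1.A.elem(find(bc.a1.A <= 0.0f)).zeros();
    bn_backward(da1, bc.z1, blk.bn1, bc.bnc1, bg.g1, bg.b1);
    dx = conv_backward(da1, bc.cols1, blk.c1, bc.Hin, bc.Win, bg.W1);
    dx.A += dx_sc.A;
  }

  // stem
  dx.A.elem(find(cache.stem_a.A <= 0.0f)).zeros();
  bn_backward(dx, cache.stem_z, net.bn0, cache.stem_bnc, g.stem_g, g.stem_b);
  conv_backward(dx, cache.stem_cols, net.stem, X.H, X.W, g.stem_W);
}

// ---------------------------------------------------------------------------
// Adam

struct AdamState {
  std::vector<fmat> m_mat, v_mat;
  std::vector<fvec> m_vec, v_vec;
};

struct ParamRefs {
  std::vector<fmat*> mats;   // penalised weights
  std::vector<fvec*> vecs;   // unpenalised (BN params, biases)
  std::vector<fmat*> grad_mats;
  std::vector<fvec*> grad_vecs;
};

static ParamRefs collect_refs(Net& net, Grads& g) {
  ParamRefs r;
  r.mats = { &net.stem.W };
  r.grad_mats = { &g.stem_W };
  r.vecs = { &net.bn0.g, &net.bn0.b };
  r.grad_vecs = { &g.stem_g, &g.stem_b };
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    Block& blk = net.blocks[b];
    auto& bg = g.blocks[b];
    r.mats.push_back(&blk.c1.W); r.grad_mats.push_back(&bg.W1);
    r.mats.push_back(&blk.c2.W); r.grad_mats.push_back(&bg.W2);
    r.mats.push_back(&blk.sc.W); r.grad_mats.push_back(&bg.Wsc);
    r.vecs.insert(r.vecs.end(), { &blk.bn1.g, &blk.bn1.b, &blk.bn2.g,
                                  &blk.bn2.b, &blk.bnsc.g, &blk.bnsc.b });
    r.grad_vecs.insert(r.grad_vecs.end(), { &bg.g1, &bg.b1, &bg.g2, &bg.b2,
                                            &bg.gsc, &bg.bsc });
  }
  r.mats.push_back(&net.fc1.W); r.grad_mats.push_back(&g.fc1_W);
  r.mats.push_back(&net.fc2.W); r.grad_mats.push_back(&g.fc2_W);
  r.vecs.push_back(&net.fc1.b); r.grad_vecs.push_back(&g.fc1_b);
  r.vecs.push_back(&net.fc2.b); r.grad_vecs.push_back(&g.fc2_b);
  return r;
}

static double weight_penalty(const ParamRefs& r) {
  double s = 0;
  for (const fmat* w : r.mats) s += accu(conv_to<mat>::from(*w % *w));
  return s;
}

// ---------------------------------------------------------------------------
// exported functions

// R array (H, W, N) -> Act with C = 1; the memory layouts coincide
static Act images_from_array(const Rcpp::NumericVector& X) {
  Rcpp::IntegerVector dim = X.attr("dim");
  if (dim.size() != 3) Rcpp::stop("images must be an H x W x N array");
  Act out;
  out.H = dim[0]; out.W = dim[1]; out.N = dim[2]; out.C = 1;
  out.A.set_size(1, (size_t)out.H * out.W * out.N);
  std::copy(X.begin(), X.end(), out.A.memptr());
  return out;
}

static Act subset_images(const Act& X, const uvec& idx0) {
  Act out;
  const size_t HW = (size_t)X.H * X.W;
  out.H = X.H; out.W = X.W; out.C = 1; out.N = idx0.n_elem;
  out.A.set_size(1, HW * out.N);
  for (size_t i = 0; i < idx0.n_elem; ++i)
    out.A.cols(i * HW, (i + 1) * HW - 1) =
      X.A.cols(idx0(i) * HW, (idx0(i) + 1) * HW - 1);
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_resnet_predict(List params, List spec,
                                       Rcpp::NumericVector images) {
  Net net = net_from(params, spec);
  Act X = images_from_array(images);
  BatchCache cache;
  fmat out = forward_batch(net, X, false, cache);
  mat outd = conv_to<mat>::from(out.t());     // N x 2
  return Rcpp::wrap(outd);
}

// [[Rcpp::export]]
List cpp_resnet_train(List params, List spec, Rcpp::NumericVector images,
                      arma::mat Y, arma::uvec train_idx, arma::uvec val_idx,
                      arma::umat perms, List cfg) {
  Net net = net_from(params, spec);
  Act X = images_from_array(images);
  const double lr = cfg["lr"], beta1 = cfg["beta1"], beta2 = cfg["beta2"];
  const double lambda = cfg["weight_decay"];
  const int batch_size = cfg["batch_size"], max_epochs = cfg["max_epochs"];
  const int patience = cfg["patience"];
  const bool early_stop = cfg["early_stop"];
  const double eps = 1e-8;

  Grads g; g.init(net);
  ParamRefs refs = collect_refs(net, g);
  AdamState ad;
  ad.m_mat.resize(refs.mats.size()); ad.v_mat.resize(refs.mats.size());
  for (size_t i = 0; i < refs.mats.size(); ++i) {
    ad.m_mat[i].zeros(size(*refs.mats[i]));
    ad.v_mat[i].zeros(size(*refs.mats[i]));
  }
  ad.m_vec.resize(refs.vecs.size()); ad.v_vec.resize(refs.vecs.size());
  for (size_t i = 0; i < refs.vecs.size(); ++i) {
    ad.m_vec[i].zeros(refs.vecs[i]->n_elem);
    ad.v_vec[i].zeros(refs.vecs[i]->n_elem);
  }

  const size_t n_train = train_idx.n_elem;
  std::vector<double> hist_train, hist_val;
  double best_val = datum::inf;
  int best_epoch = -1, since_best = 0;
  List best_params = net_to_list(net, params);
  long t_step = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double epoch_loss = 0;
    int n_batches = 0;
    for (size_t start = 0; start < n_train; start += batch_size) {
      const size_t stop = std::min(n_train, start + batch_size);
      const size_t N = stop - start;
      uvec ix(N);
      fmat yb(2, N);
      for (size_t i = 0; i < N; ++i) {
        ix(i) = train_idx(perms(start + i, epoch) - 1) - 1;
        yb(0, i) = (float)Y(ix(i), 0);
        yb(1, i) = (float)Y(ix(i), 1);
      }
      Act xb = subset_images(X, ix);
      BatchCache cache;
      fmat pred = forward_batch(net, xb, true, cache);
      fmat err = pred - yb;
      const double data_loss = 0.5 * accu(conv_to<mat>::from(err % err)) / N;
      epoch_loss += data_loss + 0.5 * lambda * weight_penalty(refs);
      ++n_batches;
      for (fmat* gm : refs.grad_mats) gm->zeros();
      for (fvec* gv : refs.grad_vecs) gv->zeros();
      fmat dout = err / (float)N;
      backward_batch(net, xb, dout, cache, g);
      // L2 penalty on weights only
      for (size_t i = 0; i < refs.mats.size(); ++i)
        *refs.grad_mats[i] += (float)lambda * (*refs.mats[i]);
      // Adam step
      ++t_step;
      const double bc1 = 1.0 - std::pow(beta1, (double)t_step);
      const double bc2 = 1.0 - std::pow(beta2, (double)t_step);
      for (size_t i = 0; i < refs.mats.size(); ++i) {
        ad.m_mat[i] = (float)beta1 * ad.m_mat[i] +
                      (float)(1 - beta1) * (*refs.grad_mats[i]);
        ad.v_mat[i] = (float)beta2 * ad.v_mat[i] +
                      (float)(1 - beta2) * square(*refs.grad_mats[i]);
        *refs.mats[i] -= (float)(lr / bc1) * ad.m_mat[i] /
                         (sqrt(ad.v_mat[i] / (float)bc2) + (float)eps);
      }
      for (size_t i = 0; i < refs.vecs.size(); ++i) {
        ad.m_vec[i] = (float)beta1 * ad.m_vec[i] +
                      (float)(1 - beta1) * (*refs.grad_vecs[i]);
        ad.v_vec[i] = (float)beta2 * ad.v_vec[i] +
                      (float)(1 - beta2) * square(*refs.grad_vecs[i]);
        *refs.vecs[i] -= (float)(lr / bc1) * ad.m_vec[i] /
                         (sqrt(ad.v_vec[i] / (float)bc2) + (float)eps);
      }
    }
    hist_train.push_back(epoch_loss / n_batches);

    // validation in eval mode
    double val_loss = NA_REAL;
    if (val_idx.n_elem > 0) {
      double acc = 0;
      for (size_t start = 0; start < val_idx.n_elem; start += batch_size) {
        const size_t stop = std::min((size_t)val_idx.n_elem,
                                     start + batch_size);
        uvec ix = val_idx.subvec(start, stop - 1) - 1;
        Act xb = subset_images(X, ix);
        fmat yb(2, stop - start);
        for (size_t i = 0; i < stop - start; ++i) {
          yb(0, i) = (float)Y(ix(i), 0);
          yb(1, i) = (float)Y(ix(i), 1);
        }
        BatchCache cache;
        fmat pred = forward_batch(net, xb, false, cache);
        fmat err = pred - yb;
        acc += 0.5 * accu(conv_to<mat>::from(err % err));
      }
      val_loss = acc / val_idx.n_elem + 0.5 * lambda * weight_penalty(refs);
      if (val_loss < best_val - 1e-12) {
        best_val = val_loss;
        best_epoch = epoch;
        since_best = 0;
        best_params = net_to_list(net, params);
      } else {
        ++since_best;
      }
    }
    hist_val.push_back(val_loss);
    Rcpp::checkUserInterrupt();
    if (early_stop && val_idx.n_elem > 0 && since_best >= patience) break;
  }

  List final_params = (val_idx.n_elem > 0 && best_epoch >= 0)
    ? best_params : net_to_list(net, params);
  return List::create(
    Named("params") = final_params,
    Named("train_loss") = hist_train,
    Named("val_loss") = hist_val,
    Named("best_epoch") = best_epoch + 1);
}

// Forward pass through a single residual block in evaluation mode; used to
// verify the residual contract (zero main path == normalised shortcut).
// [[Rcpp::export]]
Rcpp::NumericVector cpp_resblock_forward(List bparams, Rcpp::NumericVector x,
                                         int in_channels, int out_channels) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[2] != in_channels)
    Rcpp::stop("input must be H x W x in_channels");
  Act xa;
  xa.H = dim[0]; xa.W = dim[1]; xa.C = in_channels; xa.N = 1;
  xa.A.set_size(xa.C, (size_t)xa.H * xa.W);
  for (int c = 0; c < xa.C; ++c)
    for (int j = 0; j < xa.H * xa.W; ++j)
      xa.A(c, j) = (float)x[j + c * xa.H * xa.W];
  Block blk;
  blk.c1 = conv_from(bparams, "conv1_W", in_channels, out_channels, 3, 2);
  blk.bn1 = bn_from(bparams, "bn1", out_channels);
  blk.c2 = conv_from(bparams, "conv2_W", out_channels, out_channels, 3, 1);
  blk.bn2 = bn_from(bparams, "bn2", out_channels);
  blk.sc = conv_from(bparams, "sc_W", in_channels, out_channels, 1, 2);
  blk.bnsc = bn_from(bparams, "bnsc", out_channels);
  fmat cols;
  BNCache c1, c2, c3;
  Act z1 = conv_forward(xa, blk.c1, cols);
  bn_forward(z1, blk.bn1, false, c1);
  relu_inplace(z1);
  Act z2 = conv_forward(z1, blk.c2, cols);
  bn_forward(z2, blk.bn2, false, c2);
  Act zs = conv_forward(xa, blk.sc, cols);
  bn_forward(zs, blk.bnsc, false, c3);
  z2.A += zs.A;
  z2.A.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  Rcpp::NumericVector res((size_t)z2.H * z2.W * z2.C);
  for (int c = 0; c < z2.C; ++c)
    for (int j = 0; j < z2.H * z2.W; ++j)
      res[j + (size_t)c * z2.H * z2.W] = z2.A(c, j);
  res.attr("dim") = Rcpp::IntegerVector::create(z2.H, z2.W, z2.C);
  return res;
}

// Plain strided convolution on one feature map; exposed for layer-shape
// verification in the test suite.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d(Rcpp::NumericVector x, arma::mat W, int k,
                               int stride, int pad, int in_channels,
                               int out_channels) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[2] != in_channels)
    Rcpp::stop("input must be H x W x in_channels");
  Act xa;
  xa.H = dim[0]; xa.W = dim[1]; xa.C = in_channels; xa.N = 1;
  xa.A.set_size(xa.C, (size_t)xa.H * xa.W);
  for (int c = 0; c < xa.C; ++c)
    for (int j = 0; j < xa.H * xa.W; ++j)
      xa.A(c, j) = (float)x[j + (size_t)c * xa.H * xa.W];
  ConvLayer L;
  L.W = conv_to<fmat>::from(W);
  L.k = k; L.stride = stride; L.pad = pad;
  L.Cin = in_channels; L.Cout = out_channels;
  fmat cols;
  Act out = conv_forward(xa, L, cols);
  Rcpp::NumericVector res((size_t)out.H * out.W * out.C);
  for (int c = 0; c < out.C; ++c)
    for (int j = 0; j < out.H * out.W; ++j)
      res[j + (size_t)c * out.H * out.W] = out.A(c, j);
  res.attr("dim") = Rcpp::IntegerVector::create(out.H, out.W, out.C);
  return res;
}

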