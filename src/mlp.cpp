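// Multi-layer perceptron core used by the gene screening and transfer
// prediction stages.  All stochastic draws (weight init, dropout masks,
// minibatch shuffles) use R's RNG so every fit is reproducible from
// set.seed() on any platform.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

struct Net {
  std::vector<mat> W;  // W[l]: in_l x out_l
  std::vector<vec> b;  // b[l]: out_l
};

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  double t = 0.0;
  void init(const Net& net) {
    size_t L = net.W.size();
    mW.resize(L); vW.resize(L); mb.resize(L); vb.resize(L);
    for (size_t l = 0; l < L; ++l) {
      mW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
      vW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
      mb[l].zeros(net.b[l].n_elem);
      vb[l].zeros(net.b[l].n_elem);
    }
  }
};

const double B1 = 0.9, B2 = 0.999, EPS = 1e-8;

inline void adam_update(mat& p, mat& g, mat& m, mat& v, double lr, double t) {
  m = B1 * m + (1.0 - B1) * g;
  v = B2 * v + (1.0 - B2) * (g % g);
  p -= lr * (m / (1.0 - std::pow(B1, t))) /
       (arma::sqrt(v / (1.0 - std::pow(B2, t))) + EPS);
}
inline void adam_update(vec& p, vec& g, vec& m, vec& v, double lr, double t) {
  m = B1 * m + (1.0 - B1) * g;
  v = B2 * v + (1.0 - B2) * (g % g);
  p -= lr * (m / (1.0 - std::pow(B1, t))) /
       (arma::sqrt(v / (1.0 - std::pow(B2, t))) + EPS);
}

// He-normal initialisation via R's RNG.
Net init_net(int in_dim, const std::vector<int>& hidden, int out_dim) {
  Net net;
  std::vector<int> dims;
  dims.push_back(in_dim);
  for (int h : hidden) dims.push_back(h);
  dims.push_back(out_dim);
  for (size_t l = 0; l + 1 < dims.size(); ++l) {
    mat W(dims[l], dims[l + 1]);
    double sd = std::sqrt(2.0 / std::max(1, dims[l]));
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i)
        W(i, j) = R::norm_rand() * sd;
    net.W.push_back(W);
    vec b(dims[l + 1], arma::fill::zeros);
    if (l + 2 < dims.size()) {
      // hidden-layer biases start spread out so ReLU breakpoints cover the
      // data range instead of all sitting at the origin
      for (arma::uword i = 0; i < b.n_elem; ++i)
        b(i) = R::norm_rand() * 0.5;
    }
    net.b.push_back(b);
  }
  return net;
}

Net net_from_list(const List& Wl, const List& bl) {
  Net net;
  for (int l = 0; l < Wl.size(); ++l) {
    net.W.push_back(as<mat>(Wl[l]));
    net.b.push_back(as<vec>(bl[l]));
  }
  return net;
}

List net_to_list(const Net& net) {
  List Wl(net.W.size()), bl(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    Wl[l] = net.W[l];
    bl[l] = net.b[l];
  }
  return List::create(_["W"] = Wl, _["b"] = bl);
}

// Forward pass caching activations.  Hidden layers use ReLU; the final layer
// is linear (a sigmoid is applied inside the loss for binary outcomes).
// When train && dropout > 0 an inverted-dropout mask is applied after the
// first hidden layer and returned for the backward pass.
struct Cache {
  std::vector<mat> A;  // A[0] = X, A[l] = activation after layer l
  mat mask;            // dropout mask (possibly empty)
  mat Z;               // final linear output (n x out)
};

Cache forward(const Net& net, const mat& X, double dropout, bool train) {
  Cache c;
  c.A.push_back(X);
  size_t L = net.W.size();
  mat cur = X;
  for (size_t l = 0; l + 1 < L; ++l) {
    mat z = cur * net.W[l];
    z.each_row() += net.b[l].t();
    mat a = arma::clamp(z, 0.0, arma::datum::inf);  // ReLU
    if (l == 0 && dropout > 0.0 && train) {
      mat mask(a.n_rows, a.n_cols);
      double keep = 1.0 - dropout;
      for (arma::uword j = 0; j < mask.n_cols; ++j)
        for (arma::uword i = 0; i < mask.n_rows; ++i)
          mask(i, j) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
      a %= mask;
      c.mask = mask;
    }
    c.A.push_back(a);
    cur = a;
  }
  c.Z = cur * net.W[L - 1];
  c.Z.each_row() += net.b[L - 1].t();
  return c;
}

// Backward pass given dZ = dL/dZ (n x out).  Returns gradient net; also
// fills dX (dL/dX) when requested (needed to backprop into gene subnets).
Net backward(const Net& net, const Cache& c, const mat& dZ, double dropout,
             mat* dX) {
  size_t L = net.W.size();
  Net g;
  g.W.resize(L);
  g.b.resize(L);
  mat delta = dZ;
  for (int l = (int)L - 1; l >= 0; --l) {
    g.W[l] = c.A[l].t() * delta;
    g.b[l] = arma::sum(delta, 0).t();
    if (l > 0) {
      mat da = delta * net.W[l].t();
      // derivative through dropout + ReLU at layer l (activation index l)
      const mat& a = c.A[l];
      if (l == 1 && dropout > 0.0 && c.mask.n_elem > 0) da %= c.mask;
      da %= arma::conv_to<mat>::from(a > 0.0);
      delta = da;
    } else if (dX != nullptr) {
      *dX = delta * net.W[0].t();
    }
  }
  return g;
}

// dL/dZ and mean loss for a batch.  Continuous: mean squared error.
// Binary: cross-entropy with logits.
double loss_grad(const vec& y, const mat& Z, bool binary, mat& dZ) {
  vec z = Z.col(0);
  int n = z.n_elem;
  double loss;
  vec d(n);
  if (binary) {
    vec p = 1.0 / (1.0 + arma::exp(-z));
    loss = 0.0;
    for (int i = 0; i < n; ++i) {
      double zi = z(i);
      // log(1+exp(z)) - y*z, numerically stable
      double sp = zi > 0 ? zi + std::log1p(std::exp(-zi))
                         : std::log1p(std::exp(zi));
      loss += sp - y(i) * zi;
    }
    loss /= n;
    d = (p - y) / n;
  } else {
    vec r = z - y;
    loss = arma::dot(r, r) / n;
    d = 2.0 * r / n;
  }
  dZ = mat(d);
  dZ.reshape(n, 1);
  return loss;
}

// Shuffled row order via R's RNG (Fisher-Yates).
uvec shuffle_idx(int n) {
  uvec idx(n);
  for (int i = 0; i < n; ++i) idx(i) = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx(i), idx(j));
  }
  return idx;
}

int resolve_batch(int n, int batch) {
  if (batch > 0) return std::min(batch, n);
  return n;  // batch <= 0 means full batch
}

}  // namespace

// Fit an MLP (ReLU hidden layers, dropout after the first hidden layer,
// Adam) on dosage block X and outcome y.
// [[Rcpp::export]]
List cpp_mlp_fit(const arma::mat& X, const arma::vec& y,
                 const IntegerVector& hidden, double dropout, int epochs,
                 double lr, int batch, bool binary) {
  std::vector<int> h(hidden.begin(), hidden.end());
  Net net = init_net(X.n_cols, h, 1);
  Adam opt;
  opt.init(net);
  int n = X.n_rows;
  int bs = resolve_batch(n, batch);
  NumericVector loss_hist(epochs);
  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    int nb = 0;
    if (bs >= n) {
      Cache c = forward(net, X, dropout, true);
      mat dZ;
      epoch_loss = loss_grad(y, c.Z, binary, dZ);
      Net g = backward(net, c, dZ, dropout, nullptr);
      opt.t += 1.0;
      for (size_t l = 0; l < net.W.size(); ++l) {
        adam_update(net.W[l], g.W[l], opt.mW[l], opt.vW[l], lr, opt.t);
        adam_update(net.b[l], g.b[l], opt.mb[l], opt.vb[l], lr, opt.t);
      }
      nb = 1;
    } else {
      uvec idx = shuffle_idx(n);
      for (int s = 0; s < n; s += bs) {
        int e2 = std::min(s + bs, n);
        uvec sel = idx.subvec(s, e2 - 1);
        mat Xb = X.rows(sel);
        vec yb = y.elem(sel);
        Cache c = forward(net, Xb, dropout, true);
        mat dZ;
        epoch_loss += loss_grad(yb, c.Z, binary, dZ);
        Net g = backward(net, c, dZ, dropout, nullptr);
        opt.t += 1.0;
        for (size_t l = 0; l < net.W.size(); ++l) {
          adam_update(net.W[l], g.W[l], opt.mW[l], opt.vW[l], lr, opt.t);
          adam_update(net.b[l], g.b[l], opt.mb[l], opt.vb[l], lr, opt.t);
        }
        ++nb;
      }
    }
    loss_hist[e] = epoch_loss / nb;
  }
  List out = net_to_list(net);
  out["loss"] = loss_hist;
  return out;
}

// Deterministic inference: predictions and last-hidden-layer activations.
// [[Rcpp::export]]
List cpp_mlp_forward(const List& W, const List& b, const arma::mat& X,
                     bool binary) {
  Net net = net_from_list(W, b);
  Cache c = forward(net, X, 0.0, false);
  vec z = c.Z.col(0);
  vec pred = binary ? 1.0 / (1.0 + arma::exp(-z)) : z;
  return List::create(_["pred"] = pred, _["linear"] = z,
                      _["hidden"] = c.A.back());
}

// Composite transfer network: p gene subnets feeding a stacked MLP, plus a
// scalar background weight gamma0 entering additively on the linear scale.
// freeze = true trains only (gamma0, stack); freeze = false retrains gene
// subnet parameters too (with dropout active after their first hidden layer).
// [[Rcpp::export]]
List cpp_composite_fit(const List& geneNets, const List& Xlist,
                       const arma::vec& bg, const arma::vec& y,
                       const IntegerVector& stackHidden, double geneDropout,
                       double stackDropout, bool freeze, bool binary,
                       int epochs, double lr, int batch,
                       Nullable<List> stackMask = R_NilValue) {
  int p = geneNets.size();
  std::vector<Net> genes(p);
  std::vector<mat> Xg(p);
  std::vector<Adam> gopt(p);
  int hidden_total = 0;
  for (int k = 0; k < p; ++k) {
    List gk = geneNets[k];
    genes[k] = net_from_list(gk["W"], gk["b"]);
    Xg[k] = as<mat>(Xlist[k]);
    // width of last hidden layer = rows of the output weight matrix
    hidden_total += genes[k].W.back().n_rows;
    if (!freeze) gopt[k].init(genes[k]);
  }
  int n = y.n_elem;
  std::vector<int> sh(stackHidden.begin(), stackHidden.end());
  Net stack = init_net(std::max(hidden_total, 1), sh, 1);
  // optional sparsity masks (block-diagonal wiring for the
  // no-between-gene-interaction variant); entries outside the mask stay 0
  std::vector<mat> masks(stack.W.size());
  bool use_mask = stackMask.isNotNull();
  if (use_mask) {
    List ml(stackMask);
    for (size_t l = 0; l < stack.W.size(); ++l) {
      if (l < (size_t)ml.size() && !Rf_isNull(ml[l])) {
        masks[l] = as<mat>(ml[l]);
        stack.W[l] %= masks[l];
      }
    }
  }
  Adam sopt;
  sopt.init(stack);
  double gamma0 = 1.0, m0 = 0.0, v0 = 0.0;
  bool has_bg = bg.n_elem == (arma::uword)n && arma::any(bg != 0.0);

  // Frozen gene activations can be computed once only when the gene nets
  // carry no dropout: freezing parameters does not switch the architecture
  // to inference mode, so train-time dropout in the gene subnets stays
  // active (gradients simply never reach the frozen weights).
  bool precompute = freeze && geneDropout <= 0.0;
  mat Hfull;
  if (precompute && p > 0) {
    Hfull.set_size(n, hidden_total);
    int off = 0;
    for (int k = 0; k < p; ++k) {
      Cache c = forward(genes[k], Xg[k], 0.0, false);
      int w = c.A.back().n_cols;
      Hfull.cols(off, off + w - 1) = c.A.back();
      off += w;
    }
  }

  int bs = resolve_batch(n, batch);
  NumericVector loss_hist(epochs);
  for (int e = 0; e < epochs; ++e) {
    uvec order;
    if (bs < n) order = shuffle_idx(n);
    double epoch_loss = 0.0;
    int nb = 0;
    for (int s = 0; s < n; s += bs) {
      int e2 = std::min(s + bs, n);
      uvec sel;
      if (bs < n) sel = order.subvec(s, e2 - 1);
      else { sel.set_size(n); for (int i = 0; i < n; ++i) sel(i) = i; }
      int nbatch = sel.n_elem;
      vec yb = y.elem(sel);
      vec bgb = has_bg ? vec(bg.elem(sel)) : vec(nbatch, arma::fill::zeros);

      // gene forward
      mat H;
      std::vector<Cache> gc(p);
      if (p > 0) {
        if (precompute) {
          H = Hfull.rows(sel);
        } else {
          H.set_size(nbatch, hidden_total);
          int off = 0;
          for (int k = 0; k < p; ++k) {
            mat Xb = Xg[k].rows(sel);
            // drop the output head: forward through hidden layers only
            gc[k] = forward(genes[k], Xb, geneDropout, true);
            // last hidden activation is A[L-1] (A.back() excludes Z)
            const mat& a = gc[k].A.back();
            H.cols(off, off + a.n_cols - 1) = a;
            off += a.n_cols;
          }
        }
      } else {
        H.zeros(nbatch, 1);
      }

      Cache sc = forward(stack, H, stackDropout, true);
      mat Zt = sc.Z;
      if (has_bg) Zt.col(0) += gamma0 * bgb;
      mat dZ;
      epoch_loss += loss_grad(yb, Zt, binary, dZ);
      ++nb;

      // gradients
      double g0 = has_bg ? arma::dot(dZ.col(0), bgb) : 0.0;
      mat dH;
      Net gs = backward(stack, sc, dZ, stackDropout,
                        (p > 0 && !freeze) ? &dH : nullptr);
      sopt.t += 1.0;
      double t = sopt.t;
      for (size_t l = 0; l < stack.W.size(); ++l) {
        adam_update(stack.W[l], gs.W[l], sopt.mW[l], sopt.vW[l], lr, t);
        adam_update(stack.b[l], gs.b[l], sopt.mb[l], sopt.vb[l], lr, t);
        if (use_mask && masks[l].n_elem > 0) stack.W[l] %= masks[l];
      }
      if (has_bg) {
        m0 = B1 * m0 + (1 - B1) * g0;
        v0 = B2 * v0 + (1 - B2) * g0 * g0;
        gamma0 -= lr * (m0 / (1 - std::pow(B1, t))) /
                  (std::sqrt(v0 / (1 - std::pow(B2, t))) + EPS);
      }
      if (p > 0 && !freeze) {
        int off = 0;
        for (int k = 0; k < p; ++k) {
          // backprop dH slice through gene hidden layers (output head of the
          // gene net is unused in the composite architecture)
          size_t Lk = genes[k].W.size();
          int w = genes[k].W[Lk - 1].n_rows;
          mat delta = dH.cols(off, off + w - 1);
          off += w;
          // derivative through activation of last hidden layer
          const Cache& c = gc[k];
          // activations: A[0]=X, A[1..Lk-1]=hidden outputs
          {
            const mat& a = c.A[Lk - 1];
            if ((int)Lk - 1 == 1 && geneDropout > 0.0 && c.mask.n_elem > 0)
              delta %= c.mask;
            delta %= arma::conv_to<mat>::from(a > 0.0);
          }
          gopt[k].t += 1.0;
          double tk = gopt[k].t;
          for (int l = (int)Lk - 2; l >= 0; --l) {
            mat gW = c.A[l].t() * delta;
            vec gb = arma::sum(delta, 0).t();
            if (l > 0) {
              mat da = delta * genes[k].W[l].t();
              const mat& a = c.A[l];
              if (l == 1 && geneDropout > 0.0 && c.mask.n_elem > 0)
                da %= c.mask;
              da %= arma::conv_to<mat>::from(a > 0.0);
              delta = da;
            }
            adam_update(genes[k].W[l], gW, gopt[k].mW[l], gopt[k].vW[l], lr, tk);
            adam_update(genes[k].b[l], gb, gopt[k].mb[l], gopt[k].vb[l], lr, tk);
          }
        }
      }
    }
    loss_hist[e] = epoch_loss / nb;
  }

  List geneOut(p);
  for (int k = 0; k < p; ++k) geneOut[k] = net_to_list(genes[k]);
  List st = net_to_list(stack);
  return List::create(_["genes"] = geneOut, _["stack"] = st,
                      _["gamma0"] = gamma0, _["loss"] = loss_hist);
}

// Composite prediction, returning the gene-stack part and the background
// part separately so the additive decomposition is observable.
// [[Rcpp::export]]
List cpp_composite_predict(const List& geneNets, const List& stack,
                           double gamma0, const List& Xlist,
                           const arma::vec& bg, bool binary) {
  int p = geneNets.size();
  int n = 0;
  std::vector<Net> genes(p);
  int hidden_total = 0;
  for (int k = 0; k < p; ++k) {
    List gk = geneNets[k];
    genes[k] = net_from_list(gk["W"], gk["b"]);
    hidden_total += genes[k].W.back().n_rows;
  }
  if (p > 0) n = as<mat>(Xlist[0]).n_rows; else n = bg.n_elem;
  mat H;
  if (p > 0) {
    H.set_size(n, hidden_total);
    int off = 0;
    for (int k = 0; k < p; ++k) {
      Cache c = forward(genes[k], as<mat>(Xlist[k]), 0.0, false);
      const mat& a = c.A.back();
      H.cols(off, off + a.n_cols - 1) = a;
      off += a.n_cols;
    }
  } else {
    H.zeros(n, 1);
  }
  Net snet = net_from_list(stack["W"], stack["b"]);
  Cache sc = forward(snet, H, 0.0, false);
  vec gene_part = sc.Z.col(0);
  vec bg_part(n, arma::fill::zeros);
  if (bg.n_elem == (arma::uword)n) bg_part = gamma0 * bg;
  vec z = gene_part + bg_part;
  vec pred = binary ? 1.0 / (1.0 + arma::exp(-z)) : z;
  return List::create(_["pred"] = pred, _["linear"] = z,
                      _["gene_part"] = gene_part, _["bg_part"] = bg_part);
}
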