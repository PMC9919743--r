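// LSTM fall classifier: batched forward pass, full BPTT, Adam.
//
// Architectures (U units, 3 input channels):
//   baseline: LSTM(U) -> Dense(U, relu) -> BatchNorm -> Dense(1, sigmoid)
//   improved: LSTM(U) -> Dense(U, relu) -> BatchNorm
//                     -> Dense(U, relu) -> BatchNorm -> Dense(1, sigmoid)
//
// Weights travel as a named R list of numeric matrices/vectors; shapes are
// validated on the R side. Gate order in the stacked LSTM matrices is
// [input; forget; cell; output]. All math is double precision; training is
// bit-deterministic given (weights, data, seed).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-3;

// Plain clamped loops vectorize (libmvec) far better than arma's functors;
// the clamp keeps exp() finite so -ffast-math stays safe.
static inline void sigmoid_inplace(double* p, uword n) {
  for (uword i = 0; i < n; ++i) {
    double x = std::min(19.0, std::max(-19.0, p[i]));
    p[i] = 1.0 / (1.0 + std::exp(-x));
  }
}

static inline void tanh_inplace(double* p, uword n) {
  for (uword i = 0; i < n; ++i) {
    double e = std::exp(2.0 * std::min(19.0, std::max(-19.0, p[i])));
    p[i] = (e - 1.0) / (e + 1.0);
  }
}

// Gather time step t across the blocks in `idx` -> (nb x 3) matrix.
// X has dims (T, 3, n_blocks): one slice per block.
static mat gather_t(const cube& X, const uvec& idx, unsigned int t) {
  mat out(idx.n_elem, X.n_cols);
  for (uword j = 0; j < idx.n_elem; ++j)
    out.row(j) = X.slice(idx(j)).row(t);
  return out;
}

struct BnLayer {
  rowvec gamma, beta, rmean, rvar;
};

struct Net {
  mat Wx, Wh;      // (4U x 3), (4U x U)
  rowvec b;        // 4U
  mat W1; rowvec b1; BnLayer bn1;
  bool improved;
  mat W2; rowvec b2; BnLayer bn2; // improved only
  mat Wout; double bout;          // (1 x U)
  unsigned int U;
};

static Net net_from_list(const Rcpp::List& w, bool improved) {
  Net n;
  n.Wx = Rcpp::as<mat>(w["lstm_Wx"]);
  n.Wh = Rcpp::as<mat>(w["lstm_Wh"]);
  n.b  = Rcpp::as<rowvec>(w["lstm_b"]);
  n.W1 = Rcpp::as<mat>(w["d1_W"]);
  n.b1 = Rcpp::as<rowvec>(w["d1_b"]);
  n.bn1.gamma = Rcpp::as<rowvec>(w["bn1_gamma"]);
  n.bn1.beta  = Rcpp::as<rowvec>(w["bn1_beta"]);
  n.bn1.rmean = Rcpp::as<rowvec>(w["bn1_mean"]);
  n.bn1.rvar  = Rcpp::as<rowvec>(w["bn1_var"]);
  n.improved = improved;
  if (improved) {
    n.W2 = Rcpp::as<mat>(w["d2_W"]);
    n.b2 = Rcpp::as<rowvec>(w["d2_b"]);
    n.bn2.gamma = Rcpp::as<rowvec>(w["bn2_gamma"]);
    n.bn2.beta  = Rcpp::as<rowvec>(w["bn2_beta"]);
    n.bn2.rmean = Rcpp::as<rowvec>(w["bn2_mean"]);
    n.bn2.rvar  = Rcpp::as<rowvec>(w["bn2_var"]);
  }
  n.Wout = Rcpp::as<mat>(w["out_W"]);
  n.bout = Rcpp::as<rowvec>(w["out_b"])(0);
  n.U = n.Wh.n_cols;
  return n;
}

static Rcpp::NumericVector rvec(const rowvec& v) {
  return Rcpp::NumericVector(v.begin(), v.end());
}

static Rcpp::List net_to_list(const Net& n) {
  Rcpp::List w = Rcpp::List::create(
    Rcpp::Named("lstm_Wx") = n.Wx,
    Rcpp::Named("lstm_Wh") = n.Wh,
    Rcpp::Named("lstm_b")  = rvec(n.b),
    Rcpp::Named("d1_W") = n.W1,
    Rcpp::Named("d1_b") = rvec(n.b1),
    Rcpp::Named("bn1_gamma") = rvec(n.bn1.gamma),
    Rcpp::Named("bn1_beta")  = rvec(n.bn1.beta),
    Rcpp::Named("bn1_mean")  = rvec(n.bn1.rmean),
    Rcpp::Named("bn1_var")   = rvec(n.bn1.rvar));
  if (n.improved) {
    w["d2_W"] = n.W2;
    w["d2_b"] = rvec(n.b2);
    w["bn2_gamma"] = rvec(n.bn2.gamma);
    w["bn2_beta"]  = rvec(n.bn2.beta);
    w["bn2_mean"]  = rvec(n.bn2.rmean);
    w["bn2_var"]   = rvec(n.bn2.rvar);
  }
  w["out_W"] = n.Wout;
  w["out_b"] = Rcpp::NumericVector::create(n.bout);
  return w;
}

// Batched LSTM over all T steps; returns final hidden state (nb x U).
// When `cache` is non-null, per-step activations are stored for BPTT.
struct LstmCache {
  std::vector<mat> xt, i, f, g, o, tc, hprev, cprev;
};

static mat lstm_forward(const Net& net, const cube& X, const uvec& idx,
                        LstmCache* cache) {
  const uword nb = idx.n_elem, T = X.n_rows, U = net.U;
  mat h(nb, U, fill::zeros), c(nb, U, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat xt = gather_t(X, idx, t);
    mat G = xt * net.Wx.t() + h * net.Wh.t();
    G.each_row() += net.b;
    // gate layout [i f g o]: sigmoid on i,f; tanh on g; sigmoid on o
    sigmoid_inplace(G.memptr(), nb * 2 * U);
    tanh_inplace(G.memptr() + (size_t)nb * 2 * U, nb * U);
    sigmoid_inplace(G.memptr() + (size_t)nb * 3 * U, nb * U);
    mat gi = G.cols(0, U - 1);
    mat gf = G.cols(U, 2 * U - 1);
    mat gg = G.cols(2 * U, 3 * U - 1);
    mat go = G.cols(3 * U, 4 * U - 1);
    if (cache) {
      cache->xt.push_back(xt);
      cache->hprev.push_back(h);
      cache->cprev.push_back(c);
    }
    c = gf % c + gi % gg;
    mat tc = c;
    tanh_inplace(tc.memptr(), tc.n_elem);
    h = go % tc;
    if (cache) {
      cache->i.push_back(gi); cache->f.push_back(gf);
      cache->g.push_back(gg); cache->o.push_back(go);
      cache->tc.push_back(tc);
    }
  }
  return h;
}

static mat bn_eval(const BnLayer& bn, const mat& x) {
  mat xhat = x.each_row() - bn.rmean;
  xhat.each_row() /= sqrt(bn.rvar + BN_EPS);
  xhat.each_row() %= bn.gamma;
  xhat.each_row() += bn.beta;
  return xhat;
}

// [[Rcpp::export]]
arma::vec nn_predict_cpp(Rcpp::List weights, const arma::cube& X, bool improved) {
  Net net = net_from_list(weights, improved);
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  mat h = lstm_forward(net, X, idx, nullptr);
  mat a1 = clamp(h * net.W1.t() + repmat(net.b1, h.n_rows, 1), 0.0, datum::inf);
  mat a = bn_eval(net.bn1, a1);
  if (improved) {
    mat a2 = clamp(a * net.W2.t() + repmat(net.b2, a.n_rows, 1), 0.0, datum::inf);
    a = bn_eval(net.bn2, a2);
  }
  vec z = a * net.Wout.t() + net.bout;
  sigmoid_inplace(z.memptr(), z.n_elem);
  return z;
}

// Batch-norm training-mode forward; returns output, fills xhat/invstd.
static mat bn_train(BnLayer& bn, const mat& x, mat& xhat, rowvec& invstd,
                    bool update_stats, double momentum) {
  rowvec mu = mean(x, 0);
  rowvec va = mean(square(x.each_row() - mu), 0); // biased, population
  invstd = 1.0 / sqrt(va + BN_EPS);
  xhat = (x.each_row() - mu).each_row() % invstd;
  if (update_stats) {
    bn.rmean = momentum * bn.rmean + (1 - momentum) * mu;
    bn.rvar  = momentum * bn.rvar  + (1 - momentum) * va;
  }
  mat y = xhat.each_row() % bn.gamma;
  y.each_row() += bn.beta;
  return y;
}

// Backward through training-mode batch norm. dy -> dx; fills dgamma/dbeta.
static mat bn_backward(const mat& dy, const mat& xhat, const rowvec& invstd,
                       const rowvec& gamma, rowvec& dgamma, rowvec& dbeta) {
  const double nb = (double)dy.n_rows;
  dgamma = sum(dy % xhat, 0);
  dbeta = sum(dy, 0);
  mat dxhat = dy.each_row() % gamma;
  rowvec s1 = sum(dxhat, 0);
  rowvec s2 = sum(dxhat % xhat, 0);
  mat dx = nb * dxhat;
  dx.each_row() -= s1;
  dx -= xhat.each_row() % s2;
  dx.each_row() %= invstd / nb;
  return dx;
}

struct Grads {
  mat Wx, Wh; rowvec b;
  mat W1; rowvec b1, g1, beta1;
  mat W2; rowvec b2, g2, beta2;
  mat Wout; double bout;
  double loss;
};

// One minibatch: training-mode forward, weighted BCE loss, full backward.
// Running statistics in `net` are updated in place when update_bn is set.
static Grads batch_grads(Net& net, const cube& X, const uvec& idx,
                         const vec& y, const vec& sw, bool train_lstm,
                         bool update_bn, double bn_momentum) {
  const uword nb = idx.n_elem, U = net.U, T = X.n_rows;
  vec yb(nb), swb(nb);
  for (uword j = 0; j < nb; ++j) { yb(j) = y(idx(j)); swb(j) = sw(idx(j)); }
  double wsum = accu(swb);

  LstmCache cache;
  mat h = lstm_forward(net, X, idx, train_lstm ? &cache : nullptr);
  mat z1 = h * net.W1.t() + repmat(net.b1, nb, 1);
  mat a1 = clamp(z1, 0.0, datum::inf);
  mat xhat1; rowvec invstd1;
  mat o1 = bn_train(net.bn1, a1, xhat1, invstd1, update_bn, bn_momentum);
  mat z2, a2, xhat2, o2; rowvec invstd2;
  mat alast;
  if (net.improved) {
    z2 = o1 * net.W2.t() + repmat(net.b2, nb, 1);
    a2 = clamp(z2, 0.0, datum::inf);
    o2 = bn_train(net.bn2, a2, xhat2, invstd2, update_bn, bn_momentum);
    alast = o2;
  } else {
    alast = o1;
  }
  vec z = alast * net.Wout.t() + net.bout;
  vec p = z;
  sigmoid_inplace(p.memptr(), p.n_elem);

  Grads gr;
  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  gr.loss = -accu(swb % (yb % log(pc) + (1.0 - yb) % log(1.0 - pc))) / wsum;

  vec dz = swb % (p - yb) / wsum;
  gr.Wout = dz.t() * alast;
  gr.bout = accu(dz);
  mat dalast = dz * net.Wout;

  gr.g1.zeros(U); gr.beta1.zeros(U); gr.g2.zeros(U); gr.beta2.zeros(U);
  mat dh;
  if (net.improved) {
    mat da2 = bn_backward(dalast, xhat2, invstd2, net.bn2.gamma, gr.g2,
                          gr.beta2);
    mat dz2 = da2 % conv_to<mat>::from(z2 > 0.0);
    gr.W2 = dz2.t() * o1;
    gr.b2 = sum(dz2, 0);
    dalast = dz2 * net.W2;
  }
  mat da1 = bn_backward(dalast, xhat1, invstd1, net.bn1.gamma, gr.g1,
                        gr.beta1);
  mat dz1 = da1 % conv_to<mat>::from(z1 > 0.0);
  gr.W1 = dz1.t() * h;
  gr.b1 = sum(dz1, 0);
  dh = dz1 * net.W1;

  if (train_lstm) {
    gr.Wx = zeros<mat>(4 * U, X.n_cols);
    gr.Wh = zeros<mat>(4 * U, U);
    gr.b = zeros<rowvec>(4 * U);
    mat dc(nb, U, fill::zeros);
    for (sword t = (sword)T - 1; t >= 0; --t) {
      const mat& gi = cache.i[t]; const mat& gf = cache.f[t];
      const mat& gg = cache.g[t]; const mat& go = cache.o[t];
      const mat& tc = cache.tc[t];
      mat dgo = dh % tc;
      dc += dh % go % (1.0 - square(tc));
      mat dgi = dc % gg;
      mat dgf = dc % cache.cprev[t];
      mat dgg = dc % gi;
      mat dA(nb, 4 * U);
      dA.cols(0, U - 1)         = dgi % gi % (1.0 - gi);
      dA.cols(U, 2 * U - 1)     = dgf % gf % (1.0 - gf);
      dA.cols(2 * U, 3 * U - 1) = dgg % (1.0 - square(gg));
      dA.cols(3 * U, 4 * U - 1) = dgo % go % (1.0 - go);
      gr.Wx += dA.t() * cache.xt[t];
      gr.Wh += dA.t() * cache.hprev[t];
      gr.b += sum(dA, 0);
      dh = dA * net.Wh;
      dc = dc % gf;
    }
  }
  return gr;
}

// Training-mode loss and gradients over one full batch, for verification
// against finite differences. Running statistics are left untouched.
// [[Rcpp::export]]
Rcpp::List nn_grad_cpp(Rcpp::List weights, const arma::cube& X,
                       const arma::vec& y, const arma::vec& sample_weights,
                       bool improved) {
  Net net = net_from_list(weights, improved);
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  Grads gr = batch_grads(net, X, idx, y, sample_weights, true, false, 0.9);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = gr.loss,
    Rcpp::Named("lstm_Wx") = gr.Wx, Rcpp::Named("lstm_Wh") = gr.Wh,
    Rcpp::Named("lstm_b") = rvec(gr.b),
    Rcpp::Named("d1_W") = gr.W1, Rcpp::Named("d1_b") = rvec(gr.b1),
    Rcpp::Named("bn1_gamma") = rvec(gr.g1),
    Rcpp::Named("bn1_beta") = rvec(gr.beta1));
  if (improved) {
    out["d2_W"] = gr.W2; out["d2_b"] = rvec(gr.b2);
    out["bn2_gamma"] = rvec(gr.g2); out["bn2_beta"] = rvec(gr.beta2);
  }
  out["out_W"] = gr.Wout;
  out["out_b"] = Rcpp::NumericVector::create(gr.bout);
  return out;
}

// [[Rcpp::export]]
double nn_loss_cpp(Rcpp::List weights, const arma::cube& X,
                   const arma::vec& y, const arma::vec& sample_weights,
                   bool improved) {
  Net net = net_from_list(weights, improved);
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  Grads gr = batch_grads(net, X, idx, y, sample_weights, false, false, 0.9);
  return gr.loss;
}

struct Adam {
  mat m, v;
  void init(uword r, uword c) { m.zeros(r, c); v.zeros(r, c); }
};

static void adam_step(mat& W, Adam& st, const mat& grad, double lr,
                      long tstep) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  st.m = b1 * st.m + (1 - b1) * grad;
  st.v = b2 * st.v + (1 - b2) * square(grad);
  mat mhat = st.m / (1 - std::pow(b1, (double)tstep));
  mat vhat = st.v / (1 - std::pow(b2, (double)tstep));
  W -= lr * mhat / (sqrt(vhat) + eps);
}

static void adam_row(rowvec& w, Adam& st, const rowvec& grad, double lr,
                     long tstep) {
  mat W(w);
  adam_step(W, st, mat(grad), lr, tstep);
  w = W.row(0);
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List weights, const arma::cube& X,
                        const arma::vec& y, const arma::vec& sample_weights,
                        int epochs, int batch_size, double lr, int seed,
                        bool improved, bool train_lstm, bool train_dense1,
                        bool update_bn_stats, double bn_momentum) {
  Net net = net_from_list(weights, improved);
  const uword n = X.n_slices, U = net.U;

  Adam aWx, aWh, ab, aW1, ab1, ag1, abeta1, aW2, ab2, ag2, abeta2, aWout,
       about;
  aWx.init(4 * U, X.n_cols); aWh.init(4 * U, U); ab.init(1, 4 * U);
  aW1.init(U, U); ab1.init(1, U); ag1.init(1, U); abeta1.init(1, U);
  if (improved) {
    aW2.init(U, U); ab2.init(1, U); ag2.init(1, U); abeta2.init(1, U);
  }
  aWout.init(1, U); about.init(1, 1);

  std::mt19937 rng((unsigned int)seed);
  std::vector<uword> perm(n);
  for (uword i = 0; i < n; ++i) perm[i] = i;

  vec loss_hist(epochs > 0 ? epochs : 0, fill::zeros);
  long tstep = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0;
    uword n_batch = 0;
    for (uword start = 0; start < n; start += (uword)batch_size) {
      uword stop = std::min(n, start + (uword)batch_size);
      uvec idx(stop - start);
      for (uword j = start; j < stop; ++j) idx(j - start) = perm[j];

      Grads gr = batch_grads(net, X, idx, y, sample_weights, train_lstm,
                             update_bn_stats, bn_momentum);
      ep_loss += gr.loss;
      ++n_batch;

      ++tstep;
      adam_step(net.Wout, aWout, gr.Wout, lr, tstep);
      { rowvec bo(1); bo(0) = net.bout; rowvec g(1); g(0) = gr.bout;
        adam_row(bo, about, g, lr, tstep); net.bout = bo(0); }
      if (improved) {
        adam_step(net.W2, aW2, gr.W2, lr, tstep);
        adam_row(net.b2, ab2, gr.b2, lr, tstep);
        adam_row(net.bn2.gamma, ag2, gr.g2, lr, tstep);
        adam_row(net.bn2.beta, abeta2, gr.beta2, lr, tstep);
      }
      if (train_dense1) {
        adam_step(net.W1, aW1, gr.W1, lr, tstep);
        adam_row(net.b1, ab1, gr.b1, lr, tstep);
        adam_row(net.bn1.gamma, ag1, gr.g1, lr, tstep);
        adam_row(net.bn1.beta, abeta1, gr.beta1, lr, tstep);
      }
      if (train_lstm) {
        adam_step(net.Wx, aWx, gr.Wx, lr, tstep);
        adam_step(net.Wh, aWh, gr.Wh, lr, tstep);
        adam_row(net.b, ab, gr.b, lr, tstep);
      }
    }
    loss_hist(ep) = ep_loss / n_batch;
  }

  return Rcpp::List::create(Rcpp::Named("weights") = net_to_list(net),
                            Rcpp::Named("loss") = loss_hist);
}
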