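// LSTM sequence classifier: forward, BPTT gradients, Adam training loop.
// Single-precision arithmetic; all randomness from an internal mt19937 so a
// given seed reproduces training exactly.  Gate layout in the 4H-wide weight
// matrices: [input | forget | output | cell] blocks.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

struct Params {
  fmat Wx, Wh, Wy;
  frowvec b, by;
};

struct Cache {
  std::vector<fmat> i, f, o, g, c, tc, h;  // per timestep, each B x H
  fmat Xcat;                               // (T*B) x D, timesteps stacked
};

static fmat sigm(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }

// stack timesteps vertically so the input projection is one large GEMM
static fmat stack_timesteps(const std::vector<fmat>& X) {
  int T = X.size(), B = X[0].n_rows;
  fmat Xcat(T * B, X[0].n_cols);
  for (int t = 0; t < T; t++) Xcat.rows(t * B, (t + 1) * B - 1) = X[t];
  return Xcat;
}

static fmat lstm_forward(const Params& P, const std::vector<fmat>& X,
                         Cache* cache) {
  int T = X.size(), B = X[0].n_rows, H = P.Wh.n_rows;
  fmat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  fmat Xcat = stack_timesteps(X);
  fmat Zx = Xcat * P.Wx;  // (T*B) x 4H
  if (cache) cache->Xcat = std::move(Xcat);
  for (int t = 0; t < T; t++) {
    fmat z = Zx.rows(t * B, (t + 1) * B - 1) + h * P.Wh;
    z.each_row() += P.b;
    fmat i = sigm(z.cols(0, H - 1));
    fmat f = sigm(z.cols(H, 2 * H - 1));
    fmat o = sigm(z.cols(2 * H, 3 * H - 1));
    fmat g = arma::tanh(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    fmat tc = arma::tanh(c);
    h = o % tc;
    if (cache) {
      cache->i.push_back(i); cache->f.push_back(f); cache->o.push_back(o);
      cache->g.push_back(g); cache->c.push_back(c); cache->tc.push_back(tc);
      cache->h.push_back(h);
    }
  }
  fmat logits = h * P.Wy;
  logits.each_row() += P.by;
  return logits;
}

static fmat softmax_rows(fmat logits) {
  logits.each_col() -= arma::max(logits, 1);
  fmat e = arma::exp(logits);
  e.each_col() /= arma::sum(e, 1);
  return e;
}

// y: 0-based class index per sample; cw: per-class loss weights
static double ce_loss(const fmat& prob, const arma::ivec& y,
                      const arma::fvec& cw) {
  double L = 0, W = 0;
  for (arma::uword b = 0; b < prob.n_rows; b++) {
    L -= cw[y[b]] * std::log(std::max(prob(b, y[b]), 1e-12f));
    W += cw[y[b]];
  }
  return L / W;
}

static double backward(const Params& P, const std::vector<fmat>& X,
                       const arma::ivec& y, const arma::fvec& cw, Params& G) {
  Cache cc;
  fmat logits = lstm_forward(P, X, &cc);
  fmat prob = softmax_rows(logits);
  double loss = ce_loss(prob, y, cw);
  int T = X.size(), B = X[0].n_rows, H = P.Wh.n_rows;
  float W = 0;
  for (int b = 0; b < B; b++) W += cw[y[b]];
  fmat dlogits = prob;
  for (int b = 0; b < B; b++) {
    dlogits(b, y[b]) -= 1.0f;
    dlogits.row(b) *= cw[y[b]];
  }
  dlogits /= W;
  G.Wy = cc.h[T - 1].t() * dlogits;
  G.by = arma::sum(dlogits, 0);
  G.Wh.zeros(P.Wh.n_rows, P.Wh.n_cols);
  G.b.zeros(P.b.n_elem);
  fmat dh = dlogits * P.Wy.t();
  fmat dc(B, H, arma::fill::zeros);
  fmat dZcat(T * B, 4 * H);
  for (int t = T - 1; t >= 0; t--) {
    fmat do_ = dh % cc.tc[t];
    dc += dh % cc.o[t] % (1.0f - cc.tc[t] % cc.tc[t]);
    fmat cprev = (t > 0) ? cc.c[t - 1] : fmat(B, H, arma::fill::zeros);
    fmat di = dc % cc.g[t];
    fmat df = dc % cprev;
    fmat dg = dc % cc.i[t];
    dc = dc % cc.f[t];
    fmat dZ(B, 4 * H);
    dZ.cols(0, H - 1) = di % cc.i[t] % (1.0f - cc.i[t]);
    dZ.cols(H, 2 * H - 1) = df % cc.f[t] % (1.0f - cc.f[t]);
    dZ.cols(2 * H, 3 * H - 1) = do_ % cc.o[t] % (1.0f - cc.o[t]);
    dZ.cols(3 * H, 4 * H - 1) = dg % (1.0f - cc.g[t] % cc.g[t]);
    G.b += arma::sum(dZ, 0);
    if (t > 0) G.Wh += cc.h[t - 1].t() * dZ;
    dh = dZ * P.Wh.t();
    dZcat.rows(t * B, (t + 1) * B - 1) = std::move(dZ);
  }
  G.Wx = cc.Xcat.t() * dZcat;  // one large GEMM over all timesteps
  return loss;
}

static std::vector<fmat> to_timesteps(const NumericVector& Xarr) {
  IntegerVector d = Xarr.attr("dim");  // (B, T, D)
  int B = d[0], T = d[1], D = d[2];
  std::vector<fmat> X(T, fmat(B, D));
  const double* p = REAL(Xarr);
  for (int t = 0; t < T; t++)
    for (int dd = 0; dd < D; dd++)
      for (int b = 0; b < B; b++)
        X[t](b, dd) = (float)p[b + (R_xlen_t)t * B + (R_xlen_t)dd * B * T];
  return X;
}

static Params from_list(List w) {
  Params P;
  P.Wx = arma::conv_to<fmat>::from(as<arma::mat>(w["Wx"]));
  P.Wh = arma::conv_to<fmat>::from(as<arma::mat>(w["Wh"]));
  P.Wy = arma::conv_to<fmat>::from(as<arma::mat>(w["Wy"]));
  P.b = arma::conv_to<frowvec>::from(as<arma::rowvec>(w["b"]));
  P.by = arma::conv_to<frowvec>::from(as<arma::rowvec>(w["by"]));
  return P;
}

static List to_list(const Params& P) {
  return List::create(
      _["Wx"] = arma::conv_to<arma::mat>::from(P.Wx),
      _["Wh"] = arma::conv_to<arma::mat>::from(P.Wh),
      _["Wy"] = arma::conv_to<arma::mat>::from(P.Wy),
      _["b"] = arma::conv_to<arma::rowvec>::from(P.b),
      _["by"] = arma::conv_to<arma::rowvec>::from(P.by));
}

// [[Rcpp::export]]
List cpp_lstm_loss_grad(List w, NumericVector Xarr, IntegerVector y0,
                        bool want_grad,
                        Rcpp::Nullable<NumericVector> class_wt = R_NilValue) {
  Params P = from_list(w);
  std::vector<fmat> X = to_timesteps(Xarr);
  arma::ivec y(y0.size());
  for (int i = 0; i < y0.size(); i++) y[i] = y0[i];
  arma::fvec cw(P.by.n_elem, arma::fill::ones);
  if (class_wt.isNotNull()) {
    NumericVector w0(class_wt);
    for (arma::uword c = 0; c < cw.n_elem; c++) cw[c] = (float)w0[c];
  }
  if (!want_grad) {
    fmat prob = softmax_rows(lstm_forward(P, X, nullptr));
    return List::create(_["loss"] = ce_loss(prob, y, cw));
  }
  Params G;
  double loss = backward(P, X, y, cw, G);
  return List::create(_["loss"] = loss, _["grad"] = to_list(G));
}

// [[Rcpp::export]]
NumericMatrix cpp_lstm_predict(List w, NumericVector Xarr) {
  Params P = from_list(w);
  std::vector<fmat> X = to_timesteps(Xarr);
  fmat prob = softmax_rows(lstm_forward(P, X, nullptr));
  arma::mat pd = arma::conv_to<arma::mat>::from(prob);
  return wrap(pd);
}

struct Adam {
  fmat mWx, vWx, mWh, vWh, mWy, vWy;
  frowvec mb, vb, mby, vby;
  int t = 0;
  void init(const Params& P) {
    mWx.zeros(arma::size(P.Wx)); vWx.zeros(arma::size(P.Wx));
    mWh.zeros(arma::size(P.Wh)); vWh.zeros(arma::size(P.Wh));
    mWy.zeros(arma::size(P.Wy)); vWy.zeros(arma::size(P.Wy));
    mb.zeros(P.b.n_elem); vb.zeros(P.b.n_elem);
    mby.zeros(P.by.n_elem); vby.zeros(P.by.n_elem);
  }
  template <class M>
  void upd(M& w, const M& g, M& m, M& v, float lr) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    float c1 = 1 - std::pow(b1, (float)t), c2 = 1 - std::pow(b2, (float)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
  void step(Params& P, const Params& G, float lr) {
    t++;
    upd(P.Wx, G.Wx, mWx, vWx, lr);
    upd(P.Wh, G.Wh, mWh, vWh, lr);
    upd(P.Wy, G.Wy, mWy, vWy, lr);
    upd(P.b, G.b, mb, vb, lr);
    upd(P.by, G.by, mby, vby, lr);
  }
};

// [[Rcpp::export]]
List cpp_lstm_train(NumericVector Xtr, IntegerVector ytr, NumericVector Xva,
                    IntegerVector yva, int H, int nclass, double lr, int batch,
                    int max_epochs, int patience, int seed, bool verbose,
                    NumericVector class_wt) {
  std::vector<fmat> X = to_timesteps(Xtr), Xv;
  bool has_val = yva.size() > 0;
  if (has_val) Xv = to_timesteps(Xva);
  int B = X[0].n_rows, D = X[0].n_cols, T = X.size();
  arma::ivec y(ytr.size()), yv(yva.size());
  for (int i = 0; i < ytr.size(); i++) y[i] = ytr[i];
  for (int i = 0; i < yva.size(); i++) yv[i] = yva[i];
  arma::fvec cw(nclass, arma::fill::ones);
  for (int c = 0; c < std::min((int)class_wt.size(), nclass); c++)
    cw[c] = (float)class_wt[c];

  std::mt19937 rng(seed);
  auto runif = [&](float a, float b_) {
    return a + (b_ - a) * (float)(rng() / 4294967296.0);
  };
  Params P;
  float rx = std::sqrt(6.0f / (D + H)), rh = std::sqrt(6.0f / (2 * H)),
        ry = std::sqrt(6.0f / (H + nclass));
  P.Wx.set_size(D, 4 * H);
  P.Wh.set_size(H, 4 * H);
  P.Wy.set_size(H, nclass);
  for (auto& e : P.Wx) e = runif(-rx, rx);
  for (auto& e : P.Wh) e = runif(-rh, rh);
  for (auto& e : P.Wy) e = runif(-ry, ry);
  P.b.zeros(4 * H);
  P.b.cols(H, 2 * H - 1).fill(1.0f);  // forget-gate bias
  P.by.zeros(nclass);

  Adam opt;
  opt.init(P);
  std::vector<int> order(B);
  for (int i = 0; i < B; i++) order[i] = i;
  Params best = P;
  double best_val = INFINITY;
  int best_epoch = 0, bad = 0;
  NumericVector tr_hist, va_hist;
  for (int ep = 1; ep <= max_epochs; ep++) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0;
    int nb = 0;
    for (int s = 0; s < B; s += batch) {
      int e = std::min(B, s + batch);
      arma::uvec idx(e - s);
      for (int k = s; k < e; k++) idx[k - s] = order[k];
      std::vector<fmat> Xb(T);
      for (int t = 0; t < T; t++) Xb[t] = X[t].rows(idx);
      arma::ivec yb(e - s);
      for (int k = s; k < e; k++) yb[k - s] = y[order[k]];
      Params G;
      tr_loss += backward(P, Xb, yb, cw, G);
      nb++;
      opt.step(P, G, (float)lr);
    }
    tr_loss /= nb;
    tr_hist.push_back(tr_loss);
    double va_loss = tr_loss;
    if (has_val) {
      fmat prob = softmax_rows(lstm_forward(P, Xv, nullptr));
      va_loss = ce_loss(prob, yv, cw);
    }
    va_hist.push_back(va_loss);
    if (verbose)
      Rprintf("epoch %d train %.4f val %.4f\n", ep, tr_loss, va_loss);
    if (va_loss < best_val - 1e-5) {
      best_val = va_loss;
      best = P;
      best_epoch = ep;
      bad = 0;
    } else if (++bad >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = to_list(best),
                      _["best_epoch"] = best_epoch,
                      _["best_val_loss"] = best_val,
                      _["train_loss"] = tr_hist, _["val_loss"] = va_hist);
}
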