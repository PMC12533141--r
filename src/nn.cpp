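// Compiled core for the dynamic-static fusion regressors.
//
// Mirrors the reference implementation in R/nn.R (which the test suite
// keeps as an oracle, together with finite-difference checks): valid 1-D
// convolution blocks over the time axis with ReLU and max-pool(2, stride
// 1), an LSTM whose final hidden state feeds the fusion head, a dense
// static branch, Adam on MSE. All randomness (batch shuffling, dropout
// masks) is drawn from R's RNG so runs are reproducible from R seeds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Config {
  int H, K;
  bool has_conv;
  double dropout, lr;
  int batch, epochs;
};

struct Params {
  mat c1W, c2W, Wx, Wh, sW, fW, oW;
  vec c1b, c2b, b, sb, fb;
  double ob;
  bool has_conv;
};

Params unpack(const Rcpp::List& p, bool has_conv) {
  Params P;
  P.has_conv = has_conv;
  if (has_conv) {
    P.c1W = Rcpp::as<mat>(p["conv1_W"]); P.c1b = Rcpp::as<vec>(p["conv1_b"]);
    P.c2W = Rcpp::as<mat>(p["conv2_W"]); P.c2b = Rcpp::as<vec>(p["conv2_b"]);
  }
  P.Wx = Rcpp::as<mat>(p["lstm_Wx"]); P.Wh = Rcpp::as<mat>(p["lstm_Wh"]);
  P.b = Rcpp::as<vec>(p["lstm_b"]);
  P.sW = Rcpp::as<mat>(p["static_W"]); P.sb = Rcpp::as<vec>(p["static_b"]);
  P.fW = Rcpp::as<mat>(p["fuse_W"]); P.fb = Rcpp::as<vec>(p["fuse_b"]);
  P.oW = Rcpp::as<mat>(p["out_W"]);
  P.ob = Rcpp::as<double>(p["out_b"]);
  return P;
}

Rcpp::List pack(const Params& P) {
  Rcpp::List out;
  if (P.has_conv) {
    out["conv1_W"] = P.c1W; out["conv1_b"] = P.c1b;
    out["conv2_W"] = P.c2W; out["conv2_b"] = P.c2b;
  }
  out["lstm_Wx"] = P.Wx; out["lstm_Wh"] = P.Wh; out["lstm_b"] = P.b;
  out["static_W"] = P.sW; out["static_b"] = P.sb;
  out["fuse_W"] = P.fW; out["fuse_b"] = P.fb;
  out["out_W"] = P.oW; out["out_b"] = P.ob;
  return out;
}

// time-step matrices (n x d) from an n x T x d cube
std::vector<mat> time_steps(const cube& X) {
  const uword n = X.n_rows, T = X.n_cols, d = X.n_slices;
  std::vector<mat> out(T, mat(n, d));
  for (uword t = 0; t < T; ++t)
    for (uword f = 0; f < d; ++f)
      out[t].col(f) = X.slice(f).col(t);
  return out;
}

struct Cache {
  std::vector<mat> A0, Z1, R1, P1, M1, Z2, R2, P2, M2, Xl;
  std::vector<mat> li, lf, lg, lo, lc, ltc, lcprev, lhprev;
  mat h, hd, hs, u, f1, S;
  vec yhat;
};

void conv_fwd(const std::vector<mat>& A, const mat& W, const vec& b, int K,
              std::vector<mat>& Z) {
  const int Lout = (int)A.size() - K + 1;
  const uword C = A[0].n_cols;
  Z.assign(Lout, mat());
  for (int j = 0; j < Lout; ++j) {
    mat z = A[j] * W.rows(0, C - 1);
    for (int k = 1; k < K; ++k)
      z += A[j + k] * W.rows(k * C, (k + 1) * C - 1);
    z.each_row() += b.t();
    Z[j] = z;
  }
}

void pool_fwd(const std::vector<mat>& A, std::vector<mat>& P,
              std::vector<mat>& M) {
  const int Lout = (int)A.size() - 1;
  P.assign(Lout, mat());
  M.assign(Lout, mat());
  for (int j = 0; j < Lout; ++j) {
    M[j] = conv_to<mat>::from(A[j] >= A[j + 1]);
    P[j] = max(A[j], A[j + 1]);
  }
}

void forward(const Params& P, const Config& cfg, const cube& X, const mat& S,
             const mat* dropmask, Cache& C) {
  C.A0 = time_steps(X);
  C.S = S;
  const std::vector<mat>* A = &C.A0;
  if (P.has_conv) {
    conv_fwd(*A, P.c1W, P.c1b, cfg.K, C.Z1);
    C.R1.resize(C.Z1.size());
    for (size_t j = 0; j < C.Z1.size(); ++j)
      C.R1[j] = clamp(C.Z1[j], 0.0, datum::inf);
    pool_fwd(C.R1, C.P1, C.M1);
    conv_fwd(C.P1, P.c2W, P.c2b, cfg.K, C.Z2);
    C.R2.resize(C.Z2.size());
    for (size_t j = 0; j < C.Z2.size(); ++j)
      C.R2[j] = clamp(C.Z2[j], 0.0, datum::inf);
    pool_fwd(C.R2, C.P2, C.M2);
    A = &C.P2;
  }
  C.Xl = *A;
  const uword n = X.n_rows, H = cfg.H, L = C.Xl.size();
  mat h = zeros<mat>(n, H), cc = zeros<mat>(n, H);
  C.li.assign(L, mat()); C.lf.assign(L, mat()); C.lg.assign(L, mat());
  C.lo.assign(L, mat()); C.lc.assign(L, mat()); C.ltc.assign(L, mat());
  C.lcprev.assign(L, mat()); C.lhprev.assign(L, mat());
  // project every time step through Wx in one BLAS call
  mat Xbig(n * L, P.Wx.n_rows);
  for (uword t = 0; t < L; ++t) Xbig.rows(t * n, (t + 1) * n - 1) = C.Xl[t];
  mat XWx = Xbig * P.Wx;
  const rowvec brow = P.b.t();
  for (uword t = 0; t < L; ++t) {
    mat z = XWx.rows(t * n, (t + 1) * n - 1) + h * P.Wh;
    z.each_row() += brow;
    mat i = 1.0 / (1.0 + exp(-z.cols(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-z.cols(H, 2 * H - 1)));
    mat g = tanh(z.cols(2 * H, 3 * H - 1));
    mat o = 1.0 / (1.0 + exp(-z.cols(3 * H, 4 * H - 1)));
    C.lhprev[t] = h; C.lcprev[t] = cc;
    cc = f % cc + i % g;
    mat tc = tanh(cc);
    h = o % tc;
    C.li[t] = i; C.lf[t] = f; C.lg[t] = g; C.lo[t] = o;
    C.lc[t] = cc; C.ltc[t] = tc;
  }
  C.h = h;
  C.hd = dropmask ? mat(h % (*dropmask)) : h;
  mat hsz = S * P.sW;
  hsz.each_row() += P.sb.t();
  C.hs = max(hsz, zeros<mat>(hsz.n_rows, hsz.n_cols));
  C.u = join_rows(C.hd, C.hs);
  mat f1z = C.u * P.fW;
  f1z.each_row() += P.fb.t();
  C.f1 = max(f1z, zeros<mat>(f1z.n_rows, f1z.n_cols));
  C.yhat = C.f1 * P.oW + P.ob;
}

// backward from d(loss)/d(yhat); fills parameter gradients (same shapes,
// flattened into G in pack order) and optionally input gradients
void backward(const Params& P, const Config& cfg, const Cache& C,
              const vec& dy, const mat* dropmask, Params& G,
              cube* dX, mat* dS) {
  const uword n = dy.n_elem, H = cfg.H;
  G.has_conv = P.has_conv;
  G.oW = C.f1.t() * dy;
  G.ob = accu(dy);
  mat df1 = (dy * P.oW.t()) % conv_to<mat>::from(C.f1 > 0);
  G.fW = C.u.t() * df1;
  G.fb = sum(df1, 0).t();
  mat du = df1 * P.fW.t();
  mat dhd = du.cols(0, H - 1);
  mat dhs = du.cols(H, du.n_cols - 1) % conv_to<mat>::from(C.hs > 0);
  G.sW = C.S.t() * dhs;
  G.sb = sum(dhs, 0).t();
  if (dS) *dS = dhs * P.sW.t();
  mat dh = dropmask ? mat(dhd % (*dropmask)) : dhd;

  const uword L = C.Xl.size();
  G.Wh = zeros<mat>(P.Wh.n_rows, P.Wh.n_cols);
  mat dzbig(n * L, 4 * H);
  mat dc = zeros<mat>(n, H);
  for (int t = L - 1; t >= 0; --t) {
    mat dov = dh % C.ltc[t];
    dc += dh % C.lo[t] % (1.0 - square(C.ltc[t]));
    mat di = dc % C.lg[t];
    mat dg = dc % C.li[t];
    mat df = dc % C.lcprev[t];
    mat dc_prev = dc % C.lf[t];
    mat dz = join_rows(join_rows(di % C.li[t] % (1.0 - C.li[t]),
                                 df % C.lf[t] % (1.0 - C.lf[t])),
                       join_rows(dg % (1.0 - square(C.lg[t])),
                                 dov % C.lo[t] % (1.0 - C.lo[t])));
    dzbig.rows(t * n, (t + 1) * n - 1) = dz;
    G.Wh += C.lhprev[t].t() * dz;
    dh = dz * P.Wh.t();
    dc = dc_prev;
  }
  // batch the input-side products over all time steps
  mat Xbig(n * L, P.Wx.n_rows);
  for (uword t = 0; t < L; ++t) Xbig.rows(t * n, (t + 1) * n - 1) = C.Xl[t];
  G.Wx = Xbig.t() * dzbig;
  G.b = sum(dzbig, 0).t();
  mat dXbig = dzbig * P.Wx.t();
  std::vector<mat> dXl(L);
  for (uword t = 0; t < L; ++t) dXl[t] = dXbig.rows(t * n, (t + 1) * n - 1);

  if (P.has_conv) {
    const int K = cfg.K;
    // pool2 backward
    std::vector<mat> dR2(C.R2.size());
    for (size_t j = 0; j < C.R2.size(); ++j)
      dR2[j] = zeros<mat>(n, C.R2[j].n_cols);
    for (size_t j = 0; j < dXl.size(); ++j) {
      dR2[j] += dXl[j] % C.M2[j];
      dR2[j + 1] += dXl[j] % (1.0 - C.M2[j]);
    }
    // conv2 backward (through ReLU)
    const uword C1 = C.P1[0].n_cols;
    G.c2W = zeros<mat>(P.c2W.n_rows, P.c2W.n_cols);
    G.c2b = zeros<vec>(P.c2b.n_elem);
    std::vector<mat> dP1(C.P1.size());
    for (size_t j = 0; j < C.P1.size(); ++j)
      dP1[j] = zeros<mat>(n, C1);
    for (size_t j = 0; j < C.Z2.size(); ++j) {
      mat dZ = dR2[j] % conv_to<mat>::from(C.Z2[j] > 0);
      G.c2b += sum(dZ, 0).t();
      for (int k = 0; k < K; ++k) {
        G.c2W.rows(k * C1, (k + 1) * C1 - 1) += C.P1[j + k].t() * dZ;
        dP1[j + k] += dZ * P.c2W.rows(k * C1, (k + 1) * C1 - 1).t();
      }
    }
    // pool1 backward
    std::vector<mat> dR1(C.R1.size());
    for (size_t j = 0; j < C.R1.size(); ++j)
      dR1[j] = zeros<mat>(n, C.R1[j].n_cols);
    for (size_t j = 0; j < dP1.size(); ++j) {
      dR1[j] += dP1[j] % C.M1[j];
      dR1[j + 1] += dP1[j] % (1.0 - C.M1[j]);
    }
    // conv1 backward
    const uword C0 = C.A0[0].n_cols;
    G.c1W = zeros<mat>(P.c1W.n_rows, P.c1W.n_cols);
    G.c1b = zeros<vec>(P.c1b.n_elem);
    std::vector<mat> dA0;
    if (dX) {
      dA0.assign(C.A0.size(), mat());
      for (size_t j = 0; j < C.A0.size(); ++j)
        dA0[j] = zeros<mat>(n, C0);
    }
    for (size_t j = 0; j < C.Z1.size(); ++j) {
      mat dZ = dR1[j] % conv_to<mat>::from(C.Z1[j] > 0);
      G.c1b += sum(dZ, 0).t();
      for (int k = 0; k < K; ++k) {
        G.c1W.rows(k * C0, (k + 1) * C0 - 1) += C.A0[j + k].t() * dZ;
        if (dX) dA0[j + k] += dZ * P.c1W.rows(k * C0, (k + 1) * C0 - 1).t();
      }
    }
    if (dX) {
      dX->set_size(n, C.A0.size(), C0);
      for (size_t t = 0; t < dA0.size(); ++t)
        for (uword f = 0; f < C0; ++f)
          dX->slice(f).col(t) = dA0[t].col(f);
    }
  } else if (dX) {
    const uword d = C.A0[0].n_cols;
    dX->set_size(n, L, d);
    for (uword t = 0; t < L; ++t)
      for (uword f = 0; f < d; ++f)
        dX->slice(f).col(t) = dXl[t].col(f);
  }
}

Config read_config(const Rcpp::List& cfg) {
  Config c;
  c.H = Rcpp::as<int>(cfg["hidden_units"]);
  c.K = Rcpp::as<int>(cfg["conv_kernel"]);
  c.has_conv = Rcpp::as<std::string>(cfg["arch"]) == "cnn_lstm";
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.lr = Rcpp::as<double>(cfg["learning_rate"]);
  c.batch = Rcpp::as<int>(cfg["batch_size"]);
  c.epochs = Rcpp::as<int>(cfg["epochs"]);
  return c;
}

// flat views over parameters for Adam
std::vector<mat*> mats_of(Params& P) {
  std::vector<mat*> v;
  if (P.has_conv) { v.push_back(&P.c1W); v.push_back(&P.c2W); }
  v.push_back(&P.Wx); v.push_back(&P.Wh);
  v.push_back(&P.sW); v.push_back(&P.fW); v.push_back(&P.oW);
  return v;
}
std::vector<vec*> vecs_of(Params& P) {
  std::vector<vec*> v;
  if (P.has_conv) { v.push_back(&P.c1b); v.push_back(&P.c2b); }
  v.push_back(&P.b); v.push_back(&P.sb); v.push_back(&P.fb);
  return v;
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericVector nn_forward_cpp(Rcpp::List params, Rcpp::NumericVector Xr,
                                   arma::mat S, Rcpp::List cfg) {
  Config c = read_config(cfg);
  Rcpp::IntegerVector dim = Xr.attr("dim");
  cube X(Xr.begin(), dim[0], dim[1], dim[2]);
  Params P = unpack(params, c.has_conv);
  Cache C;
  forward(P, c, X, S, nullptr, C);
  return Rcpp::wrap(C.yhat);
}

// gradient of the scalar output summed over the batch w.r.t. the inputs
// [[Rcpp::export]]
Rcpp::List nn_input_grad_cpp(Rcpp::List params, Rcpp::NumericVector Xr,
                             arma::mat S, Rcpp::List cfg) {
  Config c = read_config(cfg);
  Rcpp::IntegerVector dim = Xr.attr("dim");
  cube X(Xr.begin(), dim[0], dim[1], dim[2]);
  Params P = unpack(params, c.has_conv);
  Cache C;
  forward(P, c, X, S, nullptr, C);
  Params G;
  cube dX;
  mat dS;
  backward(P, c, C, ones<vec>(X.n_rows), nullptr, G, &dX, &dS);
  return Rcpp::List::create(Rcpp::Named("yhat") = C.yhat,
                            Rcpp::Named("dX") = dX,
                            Rcpp::Named("dS") = dS);
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List params, Rcpp::NumericVector Xr,
                        arma::mat S, arma::vec y, Rcpp::List cfg,
                        Rcpp::Nullable<Rcpp::NumericVector> Xvr,
                        Rcpp::Nullable<Rcpp::NumericMatrix> Svr,
                        Rcpp::Nullable<Rcpp::NumericVector> yvr) {
  Config c = read_config(cfg);
  Rcpp::IntegerVector dim = Xr.attr("dim");
  const int n = dim[0];
  cube X(Xr.begin(), n, dim[1], dim[2]);
  Params P = unpack(params, c.has_conv);

  bool has_val = Xvr.isNotNull();
  cube Xv; mat Sv; vec yv;
  if (has_val) {
    Rcpp::NumericVector Xvv(Xvr);
    Rcpp::IntegerVector dv = Xvv.attr("dim");
    Xv = cube(Xvv.begin(), dv[0], dv[1], dv[2]);
    Sv = Rcpp::as<mat>(Rcpp::NumericMatrix(Svr));
    yv = Rcpp::as<vec>(Rcpp::NumericVector(yvr));
  }

  // Adam state, one entry per parameter tensor
  Params M = P, V = P;
  for (mat* m : mats_of(M)) m->zeros();
  for (vec* v : vecs_of(M)) v->zeros();
  M.ob = 0;
  for (mat* m : mats_of(V)) m->zeros();
  for (vec* v : vecs_of(V)) v->zeros();
  V.ob = 0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  vec hist_train(c.epochs), hist_val(has_val ? c.epochs : 0);
  Rcpp::RNGScope rng;  // batch shuffles and dropout masks use R's RNG

  for (int ep = 0; ep < c.epochs; ++ep) {
    // shuffle sample indices with R's RNG (Fisher-Yates)
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double loss_sum = 0;
    int n_batches = 0;
    for (int start = 0; start < n; start += c.batch) {
      const int nb = std::min(c.batch, n - start);
      uvec bi(nb);
      for (int i = 0; i < nb; ++i) bi[i] = idx[start + i];
      cube Xb(nb, dim[1], dim[2]);
      for (int f = 0; f < dim[2]; ++f)
        Xb.slice(f) = X.slice(f).rows(bi);
      mat Sb = S.rows(bi);
      vec yb = y.elem(bi);
      mat mask;
      const mat* maskp = nullptr;
      if (c.dropout > 0) {
        mask.set_size(nb, c.H);
        for (uword i = 0; i < mask.n_elem; ++i)
          mask[i] = (unif_rand() >= c.dropout) ? 1.0 / (1.0 - c.dropout) : 0.0;
        maskp = &mask;
      }
      Cache C;
      forward(P, c, Xb, Sb, maskp, C);
      vec err = C.yhat - yb;
      double loss = dot(err, err) / nb;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
      loss_sum += loss;
      ++n_batches;
      Params G;
      backward(P, c, C, err * (2.0 / nb), maskp, G, nullptr, nullptr);
      // Adam update
      ++step;
      const double bc1 = 1.0 - std::pow(b1, (double)step);
      const double bc2 = 1.0 - std::pow(b2, (double)step);
      std::vector<mat*> pm = mats_of(P), gm = mats_of(G), mm = mats_of(M),
                        vm = mats_of(V);
      for (size_t k = 0; k < pm.size(); ++k) {
        *mm[k] = b1 * (*mm[k]) + (1 - b1) * (*gm[k]);
        *vm[k] = b2 * (*vm[k]) + (1 - b2) * square(*gm[k]);
        *pm[k] -= c.lr * ((*mm[k]) / bc1) / (sqrt((*vm[k]) / bc2) + eps);
      }
      std::vector<vec*> pv = vecs_of(P), gv = vecs_of(G), mv = vecs_of(M),
                        vv = vecs_of(V);
      for (size_t k = 0; k < pv.size(); ++k) {
        *mv[k] = b1 * (*mv[k]) + (1 - b1) * (*gv[k]);
        *vv[k] = b2 * (*vv[k]) + (1 - b2) * square(*gv[k]);
        *pv[k] -= c.lr * ((*mv[k]) / bc1) / (sqrt((*vv[k]) / bc2) + eps);
      }
      M.ob = b1 * M.ob + (1 - b1) * G.ob;
      V.ob = b2 * V.ob + (1 - b2) * G.ob * G.ob;
      P.ob -= c.lr * (M.ob / bc1) / (std::sqrt(V.ob / bc2) + eps);
    }
    hist_train[ep] = loss_sum / n_batches;
    if (has_val) {
      Cache Cv;
      forward(P, c, Xv, Sv, nullptr, Cv);
      vec ev = Cv.yhat - yv;
      hist_val[ep] = dot(ev, ev) / yv.n_elem;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = pack(P),
      Rcpp::Named("train") = hist_train,
      Rcpp::Named("val") = has_val ? Rcpp::wrap(hist_val) : R_NilValue);
}
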