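// Hand-rolled sequence models: a stacked bidirectional LSTM per-timestep
// classifier and a two-block 1-D CNN regressor, with exact analytic
// gradients for Adam training driven from R. Batches are processed as
// (features x time x batch) cubes so the per-timestep recurrences become
// (4H x H) * (H x B) GEMMs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------- BLSTM ----------------

struct LstmDims {
  int L, H, F, C;
  int layer_dir_size(int l) const {
    int din = (l == 0) ? F : 2 * H;
    return 4 * H * din + 4 * H * H + 4 * H;
  }
  int total() const {
    int n = 0;
    for (int l = 0; l < L; ++l) n += 2 * layer_dir_size(l);
    n += C * 2 * H + C;
    return n;
  }
};

struct DirCache {
  cube i, f, g, o, c, h; // each H x B x T
};

// run one direction of one layer; rev=true processes time reversed but
// stores outputs aligned to original time
static void lstm_dir_forward(const cube& X, const mat& W, const mat& U,
                             const vec& b, bool rev, DirCache& cc, int H) {
  int T = X.n_cols, B = X.n_slices;
  cc.i.set_size(H, B, T); cc.f.set_size(H, B, T); cc.g.set_size(H, B, T);
  cc.o.set_size(H, B, T); cc.c.set_size(H, B, T); cc.h.set_size(H, B, T);
  mat hprev(H, B, fill::zeros), cprev(H, B, fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = rev ? (T - 1 - s) : s;
    mat xt(X.n_rows, B);
    for (int bb = 0; bb < B; ++bb) xt.col(bb) = X.slice(bb).col(t);
    mat Z = W * xt + U * hprev;
    Z.each_col() += b;
    mat zi = sigm(Z.rows(0, H - 1));
    mat zf = sigm(Z.rows(H, 2 * H - 1));
    mat zg = tanh(Z.rows(2 * H, 3 * H - 1));
    mat zo = sigm(Z.rows(3 * H, 4 * H - 1));
    mat ct = zf % cprev + zi % zg;
    mat ht = zo % tanh(ct);
    cc.i.slice(t) = zi; cc.f.slice(t) = zf; cc.g.slice(t) = zg;
    cc.o.slice(t) = zo; cc.c.slice(t) = ct; cc.h.slice(t) = ht;
    hprev = ht; cprev = ct;
  }
}

// backward through one direction; accumulates dW/dU/db and returns dX
static void lstm_dir_backward(const cube& X, const cube& dH, const mat& W,
                              const mat& U, const DirCache& cc, bool rev,
                              mat& dW, mat& dU, vec& db, cube& dX, int H) {
  int T = X.n_cols, B = X.n_slices;
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = rev ? (T - 1 - s) : s;
    int tprev = rev ? (t + 1) : (t - 1);
    bool has_prev = rev ? (t + 1 < T) : (t - 1 >= 0);
    mat dh = dH.slice(t) + dh_next;
    mat tc = tanh(cc.c.slice(t));
    mat dzo = dh % tc;
    mat dct = dh % cc.o.slice(t) % (1.0 - tc % tc) + dc_next;
    mat cprev = has_prev ? cc.c.slice(tprev) : mat(H, B, fill::zeros);
    mat dzi = dct % cc.g.slice(t);
    mat dzf = dct % cprev;
    mat dzg = dct % cc.i.slice(t);
    dc_next = dct % cc.f.slice(t);
    mat Z(4 * H, B);
    Z.rows(0, H - 1) = dzi % cc.i.slice(t) % (1.0 - cc.i.slice(t));
    Z.rows(H, 2 * H - 1) = dzf % cc.f.slice(t) % (1.0 - cc.f.slice(t));
    Z.rows(2 * H, 3 * H - 1) = dzg % (1.0 - cc.g.slice(t) % cc.g.slice(t));
    Z.rows(3 * H, 4 * H - 1) = dzo % cc.o.slice(t) % (1.0 - cc.o.slice(t));
    mat xt(X.n_rows, B), hprev(H, B, fill::zeros);
    for (int bb = 0; bb < B; ++bb) xt.col(bb) = X.slice(bb).col(t);
    if (has_prev) hprev = cc.h.slice(tprev);
    dW += Z * xt.t();
    dU += Z * hprev.t();
    db += sum(Z, 1);
    mat dx = W.t() * Z;
    for (int bb = 0; bb < B; ++bb) dX.slice(bb).col(t) += dx.col(bb);
    dh_next = U.t() * Z;
  }
}

struct LstmViews {
  std::vector<mat> W, U; std::vector<vec> b;
  mat Wf; vec bf;
};

static LstmViews unpack_lstm(const vec& p, const LstmDims& d) {
  LstmViews v;
  int off = 0;
  for (int l = 0; l < d.L; ++l) {
    int din = (l == 0) ? d.F : 2 * d.H;
    for (int dir = 0; dir < 2; ++dir) {
      v.W.push_back(mat(&p[off], 4 * d.H, din)); off += 4 * d.H * din;
      v.U.push_back(mat(&p[off], 4 * d.H, d.H)); off += 4 * d.H * d.H;
      v.b.push_back(vec(&p[off], 4 * d.H)); off += 4 * d.H;
    }
  }
  v.Wf = mat(&p[off], d.C, 2 * d.H); off += d.C * 2 * d.H;
  v.bf = vec(&p[off], d.C); off += d.C;
  return v;
}

// forward through the whole stack; per-layer outputs kept for backprop
static void blstm_forward_stack(const vec& p, const cube& X,
                                const LstmDims& d, std::vector<cube>& layer_in,
                                std::vector<DirCache>& caches, cube& scores) {
  LstmViews v = unpack_lstm(p, d);
  int T = X.n_cols, B = X.n_slices;
  layer_in.clear(); caches.assign(2 * d.L, DirCache());
  layer_in.push_back(X);
  for (int l = 0; l < d.L; ++l) {
    const cube& in = layer_in[l];
    lstm_dir_forward(in, v.W[2 * l], v.U[2 * l], v.b[2 * l], false,
                     caches[2 * l], d.H);
    lstm_dir_forward(in, v.W[2 * l + 1], v.U[2 * l + 1], v.b[2 * l + 1], true,
                     caches[2 * l + 1], d.H);
    cube out(2 * d.H, T, B);
    for (int bb = 0; bb < B; ++bb) {
      for (int t = 0; t < T; ++t) {
        out.slice(bb).col(t).rows(0, d.H - 1) = caches[2 * l].h.slice(t).col(bb);
        out.slice(bb).col(t).rows(d.H, 2 * d.H - 1) =
          caches[2 * l + 1].h.slice(t).col(bb);
      }
    }
    layer_in.push_back(out);
  }
  scores.set_size(d.C, T, B);
  for (int bb = 0; bb < B; ++bb) {
    scores.slice(bb) = v.Wf * layer_in[d.L].slice(bb);
    scores.slice(bb).each_col() += v.bf;
  }
}

// [[Rcpp::export]]
Rcpp::List blstm_batch_grad(const arma::vec& params, const arma::cube& X,
                            const arma::imat& Y, int L, int H, int C) {
  LstmDims d{L, H, (int)X.n_rows, C};
  int T = X.n_cols, B = X.n_slices;
  std::vector<cube> layer_in;
  std::vector<DirCache> caches;
  cube scores;
  blstm_forward_stack(params, X, d, layer_in, caches, scores);

  LstmViews v = unpack_lstm(params, d);
  vec grad(params.n_elem, fill::zeros);

  double loss = 0.0;
  cube dTop(2 * H, T, B, fill::zeros);
  mat dWf(C, 2 * H, fill::zeros);
  vec dbf(C, fill::zeros);
  double denom = (double)T * B;
  for (int bb = 0; bb < B; ++bb) {
    mat sc = scores.slice(bb);
    sc.each_row() -= max(sc, 0);
    mat ex = exp(sc);
    rowvec se = sum(ex, 0);
    mat pr = ex.each_row() / se;
    for (int t = 0; t < T; ++t) {
      int y = Y(t, bb) - 1;
      loss -= std::log(std::max(pr(y, t), 1e-300)) / denom;
    }
    mat dsc = pr;
    for (int t = 0; t < T; ++t) dsc(Y(t, bb) - 1, t) -= 1.0;
    dsc /= denom;
    dWf += dsc * layer_in[d.L].slice(bb).t();
    dbf += sum(dsc, 1);
    dTop.slice(bb) = v.Wf.t() * dsc;
  }

  // backprop through layers, top down
  std::vector<mat> dW(2 * L), dU(2 * L);
  std::vector<vec> db(2 * L);
  cube dOut = dTop;
  for (int l = L - 1; l >= 0; --l) {
    const cube& in = layer_in[l];
    cube dIn(in.n_rows, T, B, fill::zeros);
    for (int dir = 0; dir < 2; ++dir) {
      int k = 2 * l + dir;
      cube dH_dir(H, B, T);
      for (int bb = 0; bb < B; ++bb)
        for (int t = 0; t < T; ++t)
          dH_dir.slice(t).col(bb) =
            dOut.slice(bb).col(t).rows(dir * H, (dir + 1) * H - 1);
      dW[k].zeros(4 * H, in.n_rows);
      dU[k].zeros(4 * H, H);
      db[k].zeros(4 * H);
      lstm_dir_backward(in, dH_dir, v.W[k], v.U[k], caches[k], dir == 1,
                        dW[k], dU[k], db[k], dIn, H);
    }
    dOut = dIn;
  }

  // pack gradient
  int off = 0;
  for (int l = 0; l < L; ++l) {
    int din = (l == 0) ? d.F : 2 * H;
    for (int dir = 0; dir < 2; ++dir) {
      int k = 2 * l + dir;
      std::memcpy(grad.memptr() + off, dW[k].memptr(),
                  sizeof(double) * 4 * H * din);
      off += 4 * H * din;
      std::memcpy(grad.memptr() + off, dU[k].memptr(),
                  sizeof(double) * 4 * H * H);
      off += 4 * H * H;
      std::memcpy(grad.memptr() + off, db[k].memptr(), sizeof(double) * 4 * H);
      off += 4 * H;
    }
  }
  std::memcpy(grad.memptr() + off, dWf.memptr(), sizeof(double) * C * 2 * H);
  off += C * 2 * H;
  std::memcpy(grad.memptr() + off, dbf.memptr(), sizeof(double) * C);

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
double blstm_batch_loss(const arma::vec& params, const arma::cube& X,
                        const arma::imat& Y, int L, int H, int C) {
  LstmDims d{L, H, (int)X.n_rows, C};
  int T = X.n_cols, B = X.n_slices;
  std::vector<cube> layer_in;
  std::vector<DirCache> caches;
  cube scores;
  blstm_forward_stack(params, X, d, layer_in, caches, scores);
  double loss = 0.0, denom = (double)T * B;
  for (int bb = 0; bb < B; ++bb) {
    mat sc = scores.slice(bb);
    sc.each_row() -= max(sc, 0);
    mat ex = exp(sc);
    mat pr = ex.each_row() / sum(ex, 0);
    for (int t = 0; t < T; ++t)
      loss -= std::log(std::max(pr(Y(t, bb) - 1, t), 1e-300)) / denom;
  }
  return loss;
}

// [[Rcpp::export]]
arma::mat blstm_probs(const arma::vec& params, const arma::mat& X, int L,
                      int H, int C) {
  cube Xc(X.n_rows, X.n_cols, 1);
  Xc.slice(0) = X;
  LstmDims d{L, H, (int)X.n_rows, C};
  std::vector<cube> layer_in;
  std::vector<DirCache> caches;
  cube scores;
  blstm_forward_stack(params, Xc, d, layer_in, caches, scores);
  mat sc = scores.slice(0);
  sc.each_row() -= max(sc, 0);
  mat ex = exp(sc);
  return ex.each_row() / sum(ex, 0);
}

// ---------------- 1-D CNN ----------------

struct CnnSpecC {
  int F, T, K1, F1, P1, K2, F2, P2, HFC, OUT;
  int T1() const { return T - K1 + 1; }
  int Tp1() const { return T1() / P1; }
  int T2() const { return Tp1() - K2 + 1; }
  int Tp2() const { return T2() / P2; }
  int flat() const { return F2 * Tp2(); }
  int total() const {
    return F1 * F * K1 + F1 + F2 * F1 * K2 + F2 + HFC * flat() + HFC +
      OUT * HFC + OUT;
  }
};

struct CnnViews {
  mat W1, W2, Wfc, Wo; vec b1, b2, bfc, bo;
};

static CnnViews unpack_cnn(const vec& p, const CnnSpecC& s) {
  CnnViews v; int off = 0;
  v.W1 = mat(&p[off], s.F1, s.F * s.K1); off += s.F1 * s.F * s.K1;
  v.b1 = vec(&p[off], s.F1); off += s.F1;
  v.W2 = mat(&p[off], s.F2, s.F1 * s.K2); off += s.F2 * s.F1 * s.K2;
  v.b2 = vec(&p[off], s.F2); off += s.F2;
  v.Wfc = mat(&p[off], s.HFC, s.flat()); off += s.HFC * s.flat();
  v.bfc = vec(&p[off], s.HFC); off += s.HFC;
  v.Wo = mat(&p[off], s.OUT, s.HFC); off += s.OUT * s.HFC;
  v.bo = vec(&p[off], s.OUT);
  return v;
}

// valid-mode conv along time via im2col: in (Fin x T), W (Fout x Fin*K)
static mat im2col(const mat& in, int K) {
  int Tout = in.n_cols - K + 1, Fin = in.n_rows;
  mat col(Fin * K, Tout);
  for (int c = 0; c < Fin; ++c)
    for (int k = 0; k < K; ++k)
      col.row(c * K + k) = in.row(c).cols(k, k + Tout - 1);
  return col;
}

static mat conv1d(const mat& in, const mat& W, const vec& b, int K) {
  mat out = W * im2col(in, K);
  out.each_col() += b;
  return out;
}

static void conv1d_backward(const mat& in, const mat& W, const mat& dout,
                            int K, mat& dW, vec& db, mat& din) {
  int Tout = dout.n_cols, Fin = in.n_rows;
  db += sum(dout, 1);
  mat col = im2col(in, K);
  dW += dout * col.t();
  mat dcol = W.t() * dout;
  for (int c = 0; c < Fin; ++c)
    for (int k = 0; k < K; ++k)
      din.row(c).cols(k, k + Tout - 1) += dcol.row(c * K + k);
}

static mat maxpool(const mat& in, int P, umat& amax) {
  int Tout = in.n_cols / P, Fc = in.n_rows;
  mat out(Fc, Tout);
  amax.set_size(Fc, Tout);
  for (int t = 0; t < Tout; ++t)
    for (int c = 0; c < Fc; ++c) {
      uword rel;
      out(c, t) = in.row(c).cols(t * P, t * P + P - 1).max(rel);
      amax(c, t) = t * P + rel;
    }
  return out;
}

struct CnnCache {
  mat x, z1, a1, p1, q1, z2, a2, p2, q2; umat am1, am2; vec flat_v, zf, af, yhat;
};

static void cnn_forward_one(const CnnViews& v, const CnnSpecC& s, const mat& X,
                            CnnCache& c) {
  c.x = X;
  c.z1 = conv1d(X, v.W1, v.b1, s.K1);
  c.a1 = tanh(c.z1);
  c.p1 = maxpool(c.a1, s.P1, c.am1);
  c.q1 = tanh(c.p1);
  c.z2 = conv1d(c.q1, v.W2, v.b2, s.K2);
  c.a2 = tanh(c.z2);
  c.p2 = maxpool(c.a2, s.P2, c.am2);
  c.q2 = tanh(c.p2);
  c.flat_v = vectorise(c.q2);
  c.zf = v.Wfc * c.flat_v + v.bfc;
  c.af = tanh(c.zf);
  c.yhat = v.Wo * c.af + v.bo;
}

// batched forward pass: one GEMM per layer across the minibatch
struct CnnBatch {
  mat col1, z1, a1;      // col1: F*K1 x T1*B
  cube q1;               // F1 x Tp1 x B (tanh of pooled)
  std::vector<umat> am1, am2;
  mat col2, z2, a2;
  cube q2;
  mat flat, zf, af, yhat;
};

static void cnn_forward_batch(const CnnViews& v, const CnnSpecC& s,
                              const cube& X, CnnBatch& cb) {
  int B = X.n_slices, T1 = s.T1(), Tp1 = s.Tp1(), T2 = s.T2(), Tp2 = s.Tp2();
  cb.col1.set_size(s.F * s.K1, T1 * B);
  for (int b = 0; b < B; ++b)
    cb.col1.cols(b * T1, (b + 1) * T1 - 1) = im2col(X.slice(b), s.K1);
  cb.z1 = v.W1 * cb.col1;
  cb.z1.each_col() += v.b1;
  cb.a1 = tanh(cb.z1);
  cb.q1.set_size(s.F1, Tp1, B);
  cb.am1.assign(B, umat());
  for (int b = 0; b < B; ++b)
    cb.q1.slice(b) = tanh(maxpool(cb.a1.cols(b * T1, (b + 1) * T1 - 1), s.P1,
                                  cb.am1[b]));
  cb.col2.set_size(s.F1 * s.K2, T2 * B);
  for (int b = 0; b < B; ++b)
    cb.col2.cols(b * T2, (b + 1) * T2 - 1) = im2col(cb.q1.slice(b), s.K2);
  cb.z2 = v.W2 * cb.col2;
  cb.z2.each_col() += v.b2;
  cb.a2 = tanh(cb.z2);
  cb.q2.set_size(s.F2, Tp2, B);
  cb.am2.assign(B, umat());
  for (int b = 0; b < B; ++b)
    cb.q2.slice(b) = tanh(maxpool(cb.a2.cols(b * T2, (b + 1) * T2 - 1), s.P2,
                                  cb.am2[b]));
  cb.flat.set_size(s.flat(), B);
  for (int b = 0; b < B; ++b) cb.flat.col(b) = vectorise(cb.q2.slice(b));
  cb.zf = v.Wfc * cb.flat;
  cb.zf.each_col() += v.bfc;
  cb.af = tanh(cb.zf);
  cb.yhat = v.Wo * cb.af;
  cb.yhat.each_col() += v.bo;
}

// [[Rcpp::export]]
Rcpp::List cnn_batch_grad(const arma::vec& params, const arma::cube& X,
                          const arma::mat& Y, int K1, int F1, int P1, int K2,
                          int F2, int P2, int HFC) {
  CnnSpecC s{(int)X.n_rows, (int)X.n_cols, K1, F1, P1, K2, F2, P2, HFC,
             (int)Y.n_rows};
  CnnViews v = unpack_cnn(params, s);
  int B = X.n_slices, T1 = s.T1(), T2 = s.T2();
  CnnBatch cb;
  cnn_forward_batch(v, s, X, cb);
  double denom = (double)B * s.OUT;
  mat err = cb.yhat - Y;
  double loss = accu(err % err) / denom;

  mat dy = 2.0 * err / denom;
  mat dWo = dy * cb.af.t();
  vec dbo = sum(dy, 1);
  mat dzf = (v.Wo.t() * dy) % (1.0 - cb.af % cb.af);
  mat dWfc = dzf * cb.flat.t();
  vec dbfc = sum(dzf, 1);
  mat dflat = v.Wfc.t() * dzf;

  mat da2(s.F2, T2 * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat dq2(dflat.colptr(b), s.F2, s.Tp2(), false);
    mat dp2 = dq2 % (1.0 - cb.q2.slice(b) % cb.q2.slice(b));
    for (int t = 0; t < s.Tp2(); ++t)
      for (int ch = 0; ch < s.F2; ++ch)
        da2(ch, b * T2 + cb.am2[b](ch, t)) += dp2(ch, t);
  }
  mat dz2 = da2 % (1.0 - cb.a2 % cb.a2);
  mat dW2 = dz2 * cb.col2.t();
  vec db2 = sum(dz2, 1);
  mat dcol2 = v.W2.t() * dz2;

  mat da1(s.F1, T1 * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    // fold the col2 gradient back onto q1, then through tanh and pool
    mat dq1(s.F1, s.Tp1(), fill::zeros);
    for (int c = 0; c < s.F1; ++c)
      for (int k = 0; k < s.K2; ++k)
        dq1.row(c).cols(k, k + T2 - 1) +=
          dcol2.row(c * s.K2 + k).cols(b * T2, (b + 1) * T2 - 1);
    mat dp1 = dq1 % (1.0 - cb.q1.slice(b) % cb.q1.slice(b));
    for (int t = 0; t < s.Tp1(); ++t)
      for (int ch = 0; ch < s.F1; ++ch)
        da1(ch, b * T1 + cb.am1[b](ch, t)) += dp1(ch, t);
  }
  mat dz1 = da1 % (1.0 - cb.a1 % cb.a1);
  mat dW1 = dz1 * cb.col1.t();
  vec db1 = sum(dz1, 1);
  // no input gradient needed below the first layer

  vec grad(params.n_elem, fill::zeros);
  int off = 0;
  auto put = [&](const mat& m) {
    std::memcpy(grad.memptr() + off, m.memptr(), sizeof(double) * m.n_elem);
    off += m.n_elem;
  };
  auto putv = [&](const vec& m) {
    std::memcpy(grad.memptr() + off, m.memptr(), sizeof(double) * m.n_elem);
    off += m.n_elem;
  };
  put(dW1); putv(db1); put(dW2); putv(db2); put(dWfc); putv(dbfc);
  put(dWo); putv(dbo);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
double cnn_batch_loss(const arma::vec& params, const arma::cube& X,
                      const arma::mat& Y, int K1, int F1, int P1, int K2,
                      int F2, int P2, int HFC) {
  CnnSpecC s{(int)X.n_rows, (int)X.n_cols, K1, F1, P1, K2, F2, P2, HFC,
             (int)Y.n_rows};
  CnnViews v = unpack_cnn(params, s);
  CnnBatch cb;
  cnn_forward_batch(v, s, X, cb);
  mat err = cb.yhat - Y;
  return accu(err % err) / ((double)X.n_slices * s.OUT);
}

// [[Rcpp::export]]
arma::vec cnn_predict_one(const arma::vec& params, const arma::mat& X, int K1,
                          int F1, int P1, int K2, int F2, int P2, int HFC,
                          int n_out) {
  CnnSpecC s{(int)X.n_rows, (int)X.n_cols, K1, F1, P1, K2, F2, P2, HFC, n_out};
  CnnViews v = unpack_cnn(params, s);
  CnnCache c;
  cnn_forward_one(v, s, X, c);
  return c.yhat;
}

// ---------------- direct-form II transposed IIR with initial state ----------

// [[Rcpp::export]]
arma::vec iir_filter(const arma::vec& b, const arma::vec& a,
                     const arma::vec& x, const arma::vec& zi) {
  int n = x.n_elem, m = b.n_elem - 1;
  vec z = zi, y(n);
  for (int i = 0; i < n; ++i) {
    double yi = b[0] * x[i] + z[0];
    for (int k = 0; k < m - 1; ++k)
      z[k] = b[k + 1] * x[i] + z[k + 1] - a[k + 1] * yi;
    z[m - 1] = b[m] * x[i] - a[m] * yi;
    y[i] = yi;
  }
  return y;
}
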