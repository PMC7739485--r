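// Enhanced sequential inference model (ESIM) for sequence-pair
// classification, implemented directly on Armadillo matrices.
//
// Architecture: shared character embedding; two BiLSTM input encoders (one
// per side); dot-product soft attention; enhancement [x; x~; x-x~; x*x~];
// two composition BiLSTMs; average + max pooling; one-hidden-layer MLP with
// two-way softmax. Trained with minibatch SGD on cross-entropy.
//
// Parameters live in one flat vector. Layout (column-major, in order):
//   embedding (d x V)
//   8 LSTMs (enc_a fwd/bwd, enc_b fwd/bwd, comp_a fwd/bwd, comp_b fwd/bwd):
//     W (4h x in), U (4h x h), b (4h); in = d for encoders, 8h for composers
//   W1 (m x 8h), b1 (m), W2 (2 x m), b2 (2)
// Gate row order within 4h blocks: input, forget, output, cell.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Dims {
  int V, d, h, m;
  bool tied;  // share the encoder (and composer) weights across sides
  bool proj;  // ReLU projection 8h -> h before composition
  size_t offEmb, offLstm[8], offProjW[2], offProjB[2];
  size_t offW1, offB1, offW2, offB2, total;
  int lstmIn(int l) const {
    if (l < 4) return d;
    return proj ? h : 8 * h;
  }
  Dims(int V_, int d_, int h_, int m_, bool tied_ = false,
       bool proj_ = true)
      : V(V_), d(d_), h(h_), m(m_), tied(tied_), proj(proj_) {
    size_t off = 0;
    offEmb = off; off += (size_t)d * V;
    for (int l = 0; l < 8; ++l) {
      if (tied && (l == 2 || l == 3 || l == 6 || l == 7)) {
        offLstm[l] = offLstm[l - 2];  // alias the a-side weights
        continue;
      }
      offLstm[l] = off;
      off += (size_t)4 * h * lstmIn(l) + (size_t)4 * h * h + 4 * h;
    }
    for (int sdx = 0; sdx < 2; ++sdx) {
      if (!proj) { offProjW[sdx] = offProjB[sdx] = 0; continue; }
      if (tied && sdx == 1) {
        offProjW[1] = offProjW[0]; offProjB[1] = offProjB[0];
        continue;
      }
      offProjW[sdx] = off; off += (size_t)h * 8 * h;
      offProjB[sdx] = off; off += h;
    }
    offW1 = off; off += (size_t)m * 8 * h;
    offB1 = off; off += m;
    offW2 = off; off += (size_t)2 * m;
    offB2 = off; off += 2;
    total = off;
  }
};

// Non-owning views into a flat parameter (or gradient) buffer.
struct Views {
  mat emb;
  std::vector<mat> W, U;
  std::vector<vec> b;
  std::vector<mat> Wf;  // projection weights (per side), when enabled
  std::vector<vec> bf;
  mat W1; vec b1; mat W2; vec b2;
  Views(double* p, const Dims& dm)
      : emb(p + dm.offEmb, dm.d, dm.V, false, true),
        W1(p + dm.offW1, dm.m, 8 * dm.h, false, true),
        b1(p + dm.offB1, dm.m, false, true),
        W2(p + dm.offW2, 2, dm.m, false, true),
        b2(p + dm.offB2, 2, false, true) {
    W.reserve(8); U.reserve(8); b.reserve(8);
    for (int l = 0; l < 8; ++l) {
      size_t off = dm.offLstm[l];
      int in = dm.lstmIn(l);
      W.emplace_back(p + off, 4 * dm.h, in, false, true);
      off += (size_t)4 * dm.h * in;
      U.emplace_back(p + off, 4 * dm.h, dm.h, false, true);
      off += (size_t)4 * dm.h * dm.h;
      b.emplace_back(p + off, 4 * dm.h, false, true);
    }
    if (dm.proj) {
      Wf.reserve(2); bf.reserve(2);
      for (int sdx = 0; sdx < 2; ++sdx) {
        Wf.emplace_back(p + dm.offProjW[sdx], dm.h, 8 * dm.h, false, true);
        bf.emplace_back(p + dm.offProjB[sdx], dm.h, false, true);
      }
    }
  }
};

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  mat X, G, C, Tc, H;  // input, activated gates, cell, tanh(cell), hidden
};

static void lstm_forward(const mat& W, const mat& U, const vec& b,
                         const mat& X, LstmCache& cc) {
  const int T = X.n_cols, h = U.n_cols;
  cc.X = X;
  cc.G.set_size(4 * h, T); cc.C.set_size(h, T);
  cc.Tc.set_size(h, T); cc.H.set_size(h, T);
  mat pre = W * X;            // input contributions for all steps at once
  pre.each_col() += b;
  for (int t = 0; t < T; ++t) {
    double* a = cc.G.colptr(t);
    std::memcpy(a, pre.colptr(t), sizeof(double) * 4 * h);
    if (t > 0) {
      // recurrent term as explicit axpy loops: the per-step matvec is too
      // small for a BLAS call to pay for its dispatch overhead
      const double* hp = cc.H.colptr(t - 1);
      for (int j = 0; j < h; ++j) {
        const double hj = hp[j];
        const double* Uj = U.colptr(j);
        for (int k = 0; k < 4 * h; ++k) a[k] += Uj[k] * hj;
      }
    }
    for (int k = 0; k < 3 * h; ++k) a[k] = 1.0 / (1.0 + std::exp(-a[k]));
    for (int k = 3 * h; k < 4 * h; ++k) a[k] = std::tanh(a[k]);
    for (int k = 0; k < h; ++k) {
      double cprev = t > 0 ? cc.C(k, t - 1) : 0.0;
      double c = a[h + k] * cprev + a[k] * a[3 * h + k];
      double tc = std::tanh(c);
      cc.C(k, t) = c; cc.Tc(k, t) = tc; cc.H(k, t) = a[2 * h + k] * tc;
    }
  }
}

// Accumulates dW/dU/db; returns gradient wrt the input sequence.
static mat lstm_backward(const mat& W, const mat& U, const LstmCache& cc,
                         const mat& dHext, mat& dW, mat& dU, vec& db) {
  const int T = cc.H.n_cols, h = cc.H.n_rows;
  mat dA(4 * h, T);            // pre-activation gate gradients, all steps
  vec dh_next(h, fill::zeros), dc_next(h, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    double* da = dA.colptr(t);
    for (int k = 0; k < h; ++k) {
      double gi = cc.G(k, t), gf = cc.G(h + k, t);
      double go = cc.G(2 * h + k, t), gg = cc.G(3 * h + k, t);
      double tc = cc.Tc(k, t);
      double dh = dHext(k, t) + dh_next[k];
      double dc = dh * go * (1.0 - tc * tc) + dc_next[k];
      double cprev = t > 0 ? cc.C(k, t - 1) : 0.0;
      da[k] = dc * gg * gi * (1.0 - gi);
      da[h + k] = dc * cprev * gf * (1.0 - gf);
      da[2 * h + k] = dh * tc * go * (1.0 - go);
      da[3 * h + k] = dc * gi * (1.0 - gg * gg);
      dc_next[k] = dc * gf;
    }
    if (t > 0) {  // dh_next = U' * da, as per-column dot products
      for (int j = 0; j < h; ++j) {
        const double* Uj = U.colptr(j);
        double acc = 0.0;
        for (int k = 0; k < 4 * h; ++k) acc += Uj[k] * da[k];
        dh_next[j] = acc;
      }
    }
  }
  dW += dA * cc.X.t();
  if (T > 1) dU += dA.cols(1, T - 1) * cc.H.cols(0, T - 2).t();
  db += sum(dA, 1);
  return W.t() * dA;           // gradient wrt the input sequence
}

struct BiCache { LstmCache f, r; };

// Output: 2h x T, forward states on rows [0,h), backward on [h,2h).
static mat bilstm_forward(const Views& P, int l, const mat& X, BiCache& cc) {
  lstm_forward(P.W[l], P.U[l], P.b[l], X, cc.f);
  lstm_forward(P.W[l + 1], P.U[l + 1], P.b[l + 1], fliplr(X), cc.r);
  return join_cols(cc.f.H, fliplr(cc.r.H));
}

static mat bilstm_backward(const Views& P, Views& G, int l, const BiCache& cc,
                           const mat& dOut) {
  const int h = cc.f.H.n_rows;
  mat dXf = lstm_backward(P.W[l], P.U[l], cc.f, dOut.rows(0, h - 1),
                          G.W[l], G.U[l], G.b[l]);
  mat dXr = lstm_backward(P.W[l + 1], P.U[l + 1], cc.r,
                          fliplr(dOut.rows(h, 2 * h - 1)),
                          G.W[l + 1], G.U[l + 1], G.b[l + 1]);
  return dXf + fliplr(dXr);
}

static mat row_softmax(const mat& E) {
  mat A = E.each_col() - max(E, 1);
  A = exp(A);
  A.each_col() /= sum(A, 1);
  return A;
}

static mat col_softmax(const mat& E) {
  mat B = E.each_row() - max(E, 0);
  B = exp(B);
  B.each_row() /= sum(B, 0);
  return B;
}

// Strips padding (id <= 0) and converts to 0-based indices.
static uvec clean_ids(const Rcpp::IntegerVector& x, int V) {
  std::vector<uword> out;
  out.reserve(x.size());
  for (int i = 0; i < x.size(); ++i) {
    if (x[i] <= 0) continue;  // 0 = padding
    if (x[i] > V) Rcpp::stop("token id %d out of vocabulary range", x[i]);
    out.push_back((uword)(x[i] - 1));
  }
  if (out.empty()) Rcpp::stop("sequence is empty after padding removal");
  return uvec(out);
}

struct PairCache {
  uvec a, b;
  BiCache encA, encB, compA, compB;
  mat Ahat, Bhat, E, Alpha, Beta, Atilde, Btilde, Ma, Mb, Va, Vb;
  mat FaPre, FbPre, Fa, Fb;  // projection pre-activations and outputs
  uvec idxA, idxB;       // argmax positions for max pooling
  vec v, vdrop, hpre, hmlp, hdrop, logits, p;
  vec maskV, maskH;      // dropout masks (inverted scaling)
};

static void esim_forward(const Views& P, const Dims& dm, const uvec& aIds,
                         const uvec& bIds, double dropout, std::mt19937* rng,
                         PairCache& pc) {
  const int h = dm.h;
  pc.a = aIds; pc.b = bIds;
  const int La = aIds.n_elem, Lb = bIds.n_elem;
  mat Xa = P.emb.cols(aIds), Xb = P.emb.cols(bIds);
  pc.Ahat = bilstm_forward(P, 0, Xa, pc.encA);   // 2h x La
  pc.Bhat = bilstm_forward(P, 2, Xb, pc.encB);   // 2h x Lb
  pc.E = pc.Ahat.t() * pc.Bhat;                  // La x Lb
  pc.Alpha = row_softmax(pc.E);
  pc.Beta = col_softmax(pc.E);
  pc.Atilde = pc.Bhat * pc.Alpha.t();            // 2h x La
  pc.Btilde = pc.Ahat * pc.Beta;                 // 2h x Lb
  pc.Ma = join_cols(join_cols(pc.Ahat, pc.Atilde),
                    join_cols(pc.Ahat - pc.Atilde, pc.Ahat % pc.Atilde));
  pc.Mb = join_cols(join_cols(pc.Bhat, pc.Btilde),
                    join_cols(pc.Bhat - pc.Btilde, pc.Bhat % pc.Btilde));
  if (dm.proj) {  // ReLU projection 8h -> h before composition
    pc.FaPre = P.Wf[0] * pc.Ma; pc.FaPre.each_col() += P.bf[0];
    pc.FbPre = P.Wf[1] * pc.Mb; pc.FbPre.each_col() += P.bf[1];
    pc.Fa = clamp(pc.FaPre, 0.0, datum::inf);
    pc.Fb = clamp(pc.FbPre, 0.0, datum::inf);
    pc.Va = bilstm_forward(P, 4, pc.Fa, pc.compA); // 2h x La
    pc.Vb = bilstm_forward(P, 6, pc.Fb, pc.compB);
  } else {
    pc.Va = bilstm_forward(P, 4, pc.Ma, pc.compA); // 2h x La
    pc.Vb = bilstm_forward(P, 6, pc.Mb, pc.compB);
  }
  pc.idxA = index_max(pc.Va, 1);
  pc.idxB = index_max(pc.Vb, 1);
  vec vaAvg = mean(pc.Va, 1), vbAvg = mean(pc.Vb, 1);
  vec vaMax = max(pc.Va, 1), vbMax = max(pc.Vb, 1);
  pc.v = join_cols(join_cols(vaAvg, vaMax), join_cols(vbAvg, vbMax));
  auto makeMask = [&](int n) {
    vec msk(n, fill::ones);
    if (dropout > 0 && rng) {
      std::uniform_real_distribution<double> U01(0.0, 1.0);
      for (int i = 0; i < n; ++i)
        msk[i] = U01(*rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
    }
    return msk;
  };
  pc.maskV = makeMask(8 * h);
  pc.vdrop = pc.v % pc.maskV;
  pc.hpre = P.W1 * pc.vdrop + P.b1;
  pc.hmlp = tanh(pc.hpre);
  pc.maskH = makeMask(dm.m);
  pc.hdrop = pc.hmlp % pc.maskH;
  pc.logits = P.W2 * pc.hdrop + P.b2;
  vec z = pc.logits - pc.logits.max();
  vec ez = exp(z);
  pc.p = ez / accu(ez);
}

// Cross-entropy gradient for one pair; accumulates into G. Returns loss.
static double esim_backward(const Views& P, Views& G, const Dims& dm,
                            const PairCache& pc, int y) {
  const int h = dm.h;
  const int La = pc.a.n_elem, Lb = pc.b.n_elem;
  double loss = -std::log(std::max(pc.p[y], 1e-12));
  vec dlogits = pc.p;
  dlogits[y] -= 1.0;
  G.W2 += dlogits * pc.hdrop.t();
  G.b2 += dlogits;
  vec dhdrop = P.W2.t() * dlogits;
  vec dhmlp = dhdrop % pc.maskH;
  vec dhpre = dhmlp % (1.0 - pc.hmlp % pc.hmlp);
  G.W1 += dhpre * pc.vdrop.t();
  G.b1 += dhpre;
  vec dvdrop = P.W1.t() * dhpre;
  vec dv = dvdrop % pc.maskV;
  vec dvaAvg = dv.subvec(0, 2 * h - 1);
  vec dvaMax = dv.subvec(2 * h, 4 * h - 1);
  vec dvbAvg = dv.subvec(4 * h, 6 * h - 1);
  vec dvbMax = dv.subvec(6 * h, 8 * h - 1);
  mat dVa = repmat(dvaAvg / La, 1, La);
  mat dVb = repmat(dvbAvg / Lb, 1, Lb);
  for (int r = 0; r < 2 * h; ++r) {
    dVa(r, pc.idxA[r]) += dvaMax[r];
    dVb(r, pc.idxB[r]) += dvbMax[r];
  }
  mat dMa, dMb;
  if (dm.proj) {
    mat dFa = bilstm_backward(P, G, 4, pc.compA, dVa);
    mat dFb = bilstm_backward(P, G, 6, pc.compB, dVb);
    dFa %= conv_to<mat>::from(pc.FaPre > 0);
    dFb %= conv_to<mat>::from(pc.FbPre > 0);
    G.Wf[0] += dFa * pc.Ma.t();
    G.bf[0] += sum(dFa, 1);
    G.Wf[1] += dFb * pc.Mb.t();
    G.bf[1] += sum(dFb, 1);
    dMa = P.Wf[0].t() * dFa;
    dMb = P.Wf[1].t() * dFb;
  } else {
    dMa = bilstm_backward(P, G, 4, pc.compA, dVa);
    dMb = bilstm_backward(P, G, 6, pc.compB, dVb);
  }
  mat dAhat = dMa.rows(0, 2 * h - 1) + dMa.rows(4 * h, 6 * h - 1) +
              dMa.rows(6 * h, 8 * h - 1) % pc.Atilde;
  mat dAtilde = dMa.rows(2 * h, 4 * h - 1) - dMa.rows(4 * h, 6 * h - 1) +
                dMa.rows(6 * h, 8 * h - 1) % pc.Ahat;
  mat dBhat = dMb.rows(0, 2 * h - 1) + dMb.rows(4 * h, 6 * h - 1) +
              dMb.rows(6 * h, 8 * h - 1) % pc.Btilde;
  mat dBtilde = dMb.rows(2 * h, 4 * h - 1) - dMb.rows(4 * h, 6 * h - 1) +
                dMb.rows(6 * h, 8 * h - 1) % pc.Bhat;
  // attention: Atilde = Bhat Alpha', Btilde = Ahat Beta, E = Ahat' Bhat
  mat dAlpha = dAtilde.t() * pc.Bhat;       // La x Lb
  dBhat += dAtilde * pc.Alpha;
  mat dBeta = pc.Ahat.t() * dBtilde;        // La x Lb
  dAhat += dBtilde * pc.Beta.t();
  mat dE(La, Lb, fill::zeros);
  for (int i = 0; i < La; ++i) {
    rowvec al = pc.Alpha.row(i), dal = dAlpha.row(i);
    dE.row(i) += al % (dal - accu(dal % al));
  }
  for (int j = 0; j < Lb; ++j) {
    vec be = pc.Beta.col(j), dbe = dBeta.col(j);
    dE.col(j) += be % (dbe - accu(dbe % be));
  }
  dAhat += pc.Bhat * dE.t();
  dBhat += pc.Ahat * dE;
  mat dXa = bilstm_backward(P, G, 0, pc.encA, dAhat);
  mat dXb = bilstm_backward(P, G, 2, pc.encB, dBhat);
  for (int t = 0; t < La; ++t) G.emb.col(pc.a[t]) += dXa.col(t);
  for (int t = 0; t < Lb; ++t) G.emb.col(pc.b[t]) += dXb.col(t);
  return loss;
}

// [[Rcpp::export]]
double esim_param_count(int V, int d, int h, int m, bool tied = false,
                        bool proj = true) {
  return (double)Dims(V, d, h, m, tied, proj).total;
}

// Glorot-uniform init per weight matrix, uniform(-0.5, 0.5) embeddings,
// forget-gate biases 1; softmax head zeroed so an untrained model outputs
// p = 0.5 for every pair.
// [[Rcpp::export]]
Rcpp::NumericVector esim_init_params(int V, int d, int h, int m, int seed,
                                     bool tied = false, bool proj = true) {
  Dims dm(V, d, h, m, tied, proj);
  Rcpp::NumericVector out((R_xlen_t)dm.total);
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  Views P(out.begin(), dm);
  auto glorot = [&](mat& M) {
    double lim = std::sqrt(6.0 / (M.n_rows + M.n_cols));
    for (uword j = 0; j < M.n_cols; ++j)
      for (uword i = 0; i < M.n_rows; ++i)
        M(i, j) = (2.0 * U01(rng) - 1.0) * lim;
  };
  for (uword j = 0; j < P.emb.n_cols; ++j)
    for (uword i = 0; i < P.emb.n_rows; ++i)
      P.emb(i, j) = U01(rng) - 0.5;
  for (int l = 0; l < 8; ++l) {
    if (dm.tied && (l == 2 || l == 3 || l == 6 || l == 7)) continue;
    glorot(P.W[l]);
    glorot(P.U[l]);
    P.b[l].zeros();
    P.b[l].subvec(h, 2 * h - 1).ones();  // forget gate bias
  }
  if (dm.proj) {
    for (int sdx = 0; sdx < 2; ++sdx) {
      if (dm.tied && sdx == 1) continue;
      glorot(P.Wf[sdx]);
      P.bf[sdx].zeros();
    }
  }
  glorot(P.W1);
  P.b1.zeros();
  P.W2.zeros();
  P.b2.zeros();
  return out;
}

static std::vector<uvec> clean_list(const Rcpp::List& xs, int V) {
  std::vector<uvec> out;
  out.reserve(xs.size());
  for (int i = 0; i < xs.size(); ++i)
    out.push_back(clean_ids(xs[i], V));
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector esim_predict(Rcpp::NumericVector params, int V, int d,
                                 int h, int m, Rcpp::List aList,
                                 Rcpp::List bList, bool tied = false,
                                 bool proj = true) {
  Dims dm(V, d, h, m, tied, proj);
  if ((size_t)params.size() != dm.total) Rcpp::stop("bad parameter length");
  Views P(params.begin(), dm);
  std::vector<uvec> as = clean_list(aList, V), bs = clean_list(bList, V);
  if (as.size() != bs.size()) Rcpp::stop("pair lists differ in length");
  Rcpp::NumericVector out(as.size());
  PairCache pc;
  for (size_t i = 0; i < as.size(); ++i) {
    esim_forward(P, dm, as[i], bs[i], 0.0, nullptr, pc);
    out[i] = pc.p[1];
  }
  return out;
}

// Mean loss and gradient over a batch, no dropout (used by the
// finite-difference gradient check and available for inspection).
// [[Rcpp::export]]
Rcpp::List esim_loss_grad(Rcpp::NumericVector params, int V, int d, int h,
                          int m, Rcpp::List aList, Rcpp::List bList,
                          Rcpp::IntegerVector labels, bool tied = false,
                          bool proj = true) {
  Dims dm(V, d, h, m, tied, proj);
  if ((size_t)params.size() != dm.total) Rcpp::stop("bad parameter length");
  Views P(params.begin(), dm);
  std::vector<uvec> as = clean_list(aList, V), bs = clean_list(bList, V);
  Rcpp::NumericVector grad((R_xlen_t)dm.total);
  Views G(grad.begin(), dm);
  double loss = 0.0;
  PairCache pc;
  for (size_t i = 0; i < as.size(); ++i) {
    esim_forward(P, dm, as[i], bs[i], 0.0, nullptr, pc);
    loss += esim_backward(P, G, dm, pc, labels[i]);
  }
  double n = (double)as.size();
  for (R_xlen_t i = 0; i < grad.size(); ++i) grad[i] /= n;
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("grad") = grad);
}

static double f1_at_half(const std::vector<double>& p,
                         const Rcpp::IntegerVector& y) {
  double tp = 0, fp = 0, fn = 0;
  for (size_t i = 0; i < p.size(); ++i) {
    bool pred = p[i] > 0.5, gold = y[i] == 1;
    if (pred && gold) tp++;
    else if (pred) fp++;
    else if (gold) fn++;
  }
  if (tp == 0) return 0.0;
  double prec = tp / (tp + fp), rec = tp / (tp + fn);
  return 2 * prec * rec / (prec + rec);
}

// Minibatch SGD with optional gradient-norm clipping. When validation pairs
// are supplied the parameters from the best-validation-F1 epoch are
// returned; otherwise the final parameters.
// [[Rcpp::export]]
Rcpp::List esim_train(Rcpp::NumericVector params, int V, int d, int h, int m,
                      Rcpp::List aList, Rcpp::List bList,
                      Rcpp::IntegerVector labels, int epochs, int batchSize,
                      double lr, double momentum, double dropout, int seed,
                      double gradClip,
                      Rcpp::List valA, Rcpp::List valB,
                      Rcpp::IntegerVector valLabels, bool tied = false,
                      int decayEvery = 0, double decayFactor = 0.5,
                      bool proj = true) {
  Dims dm(V, d, h, m, tied, proj);
  if ((size_t)params.size() != dm.total) Rcpp::stop("bad parameter length");
  Rcpp::NumericVector theta = Rcpp::clone(params);
  Views P(theta.begin(), dm);
  std::vector<uvec> as = clean_list(aList, V), bs = clean_list(bList, V);
  const int n = as.size();
  if (n == 0) Rcpp::stop("no training pairs");
  bool hasVal = valA.size() > 0;
  std::vector<uvec> vas, vbs;
  if (hasVal) { vas = clean_list(valA, V); vbs = clean_list(valB, V); }
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  Rcpp::NumericVector lossHist(epochs), valHist(epochs);
  vec gradBuf(dm.total, fill::zeros);
  vec veloc(dm.total, fill::zeros);
  Views G(gradBuf.memptr(), dm);
  vec thetaVec(theta.begin(), dm.total, false, true);
  vec best;
  double bestF1 = -1.0;
  int bestEpoch = 0;
  PairCache pc;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epLoss = 0.0;
    for (int start = 0; start < n; start += batchSize) {
      int stop = std::min(start + batchSize, n);
      gradBuf.zeros();
      for (int k = start; k < stop; ++k) {
        int i = order[k];
        esim_forward(P, dm, as[i], bs[i], dropout, &rng, pc);
        epLoss += esim_backward(P, G, dm, pc, labels[i]);
      }
      gradBuf /= (double)(stop - start);
      if (gradClip > 0) {
        double nrm = norm(gradBuf, 2);
        if (nrm > gradClip) gradBuf *= gradClip / nrm;
      }
      if (momentum > 0) {
        veloc = momentum * veloc + gradBuf;
        thetaVec -= lr * veloc;
      } else {
        thetaVec -= lr * gradBuf;
      }
    }
    lossHist[ep] = epLoss / n;
    if (decayEvery > 0 && (ep + 1) % decayEvery == 0) lr *= decayFactor;
    if (hasVal) {
      std::vector<double> vp(vas.size());
      for (size_t i = 0; i < vas.size(); ++i) {
        esim_forward(P, dm, vas[i], vbs[i], 0.0, nullptr, pc);
        vp[i] = pc.p[1];
      }
      valHist[ep] = f1_at_half(vp, valLabels);
      if (valHist[ep] > bestF1) {
        bestF1 = valHist[ep];
        best = thetaVec;
        bestEpoch = ep + 1;
      }
    } else {
      valHist[ep] = NA_REAL;
    }
  }
  if (hasVal && best.n_elem == dm.total) thetaVec = best;
  return Rcpp::List::create(
      Rcpp::Named("params") = theta, Rcpp::Named("loss") = lossHist,
      Rcpp::Named("val_f1") = valHist,
      Rcpp::Named("best_epoch") = hasVal ? bestEpoch : epochs);
}

// Full forward pass for one pair with every intermediate exposed, for
// block-level verification against independent implementations.
// [[Rcpp::export]]
Rcpp::List esim_forward_debug(Rcpp::NumericVector params, int V, int d, int h,
                              int m, Rcpp::IntegerVector a,
                              Rcpp::IntegerVector b, bool tied = false,
                              bool proj = true) {
  Dims dm(V, d, h, m, tied, proj);
  if ((size_t)params.size() != dm.total) Rcpp::stop("bad parameter length");
  Views P(params.begin(), dm);
  PairCache pc;
  esim_forward(P, dm, clean_ids(a, V), clean_ids(b, V), 0.0, nullptr, pc);
  return Rcpp::List::create(
      Rcpp::Named("ahat") = pc.Ahat, Rcpp::Named("bhat") = pc.Bhat,
      Rcpp::Named("e") = pc.E, Rcpp::Named("alpha") = pc.Alpha,
      Rcpp::Named("beta") = pc.Beta, Rcpp::Named("atilde") = pc.Atilde,
      Rcpp::Named("btilde") = pc.Btilde, Rcpp::Named("ma") = pc.Ma,
      Rcpp::Named("mb") = pc.Mb, Rcpp::Named("va") = pc.Va,
      Rcpp::Named("vb") = pc.Vb, Rcpp::Named("v") = pc.v,
      Rcpp::Named("hidden") = pc.hmlp, Rcpp::Named("logits") = pc.logits,
      Rcpp::Named("p") = pc.p);
}
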