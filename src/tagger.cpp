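// Bi-LSTM-CRF sequence tagger and Bi-LSTM pair classifier.
//
// Batch-1 stochastic gradient descent with full backpropagation through
// time, written against Armadillo. All label/word/char/role indices
// crossing the R boundary are 0-based. The CRF transition matrix is
// (L+2)x(L+2) with the start state at row L and the stop state at column
// L+1; transitions into start and out of stop are masked with a large
// negative constant and never receive gradient.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double NEG_INF = -1e4;

// ---------------------------------------------------------------- LSTM cell

struct LSTMCache {
  mat I, F, O, G, C, H;  // T x h each, gate activations and states
};

static void lstm_forward(const mat& X, const mat& W, const mat& U,
                         const vec& b, LSTMCache& cc) {
  const int T = X.n_rows, h = U.n_cols;
  cc.I.set_size(T, h); cc.F.set_size(T, h); cc.O.set_size(T, h);
  cc.G.set_size(T, h); cc.C.set_size(T, h); cc.H.set_size(T, h);
  vec hprev(h, arma::fill::zeros), cprev(h, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec a = W * X.row(t).t() + U * hprev + b;
    vec i_ = 1.0 / (1.0 + arma::exp(-a.subvec(0, h - 1)));
    vec f_ = 1.0 / (1.0 + arma::exp(-a.subvec(h, 2 * h - 1)));
    vec o_ = 1.0 / (1.0 + arma::exp(-a.subvec(2 * h, 3 * h - 1)));
    vec g_ = arma::tanh(a.subvec(3 * h, 4 * h - 1));
    vec c_ = f_ % cprev + i_ % g_;
    vec h_ = o_ % arma::tanh(c_);
    cc.I.row(t) = i_.t(); cc.F.row(t) = f_.t(); cc.O.row(t) = o_.t();
    cc.G.row(t) = g_.t(); cc.C.row(t) = c_.t(); cc.H.row(t) = h_.t();
    hprev = h_; cprev = c_;
  }
}

// dH: T x h gradient arriving at the hidden states; accumulates into
// dW/dU/db, writes dX.
static void lstm_backward(const mat& X, const mat& W, const mat& U,
                          const LSTMCache& cc, const mat& dH,
                          mat& dX, mat& dW, mat& dU, vec& db) {
  const int T = X.n_rows, h = U.n_cols;
  dX.zeros(X.n_rows, X.n_cols);
  vec dh_next(h, arma::fill::zeros), dc_next(h, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dH.row(t).t() + dh_next;
    vec i_ = cc.I.row(t).t(), f_ = cc.F.row(t).t(), o_ = cc.O.row(t).t();
    vec g_ = cc.G.row(t).t(), c_ = cc.C.row(t).t();
    vec tc = arma::tanh(c_);
    vec dc = dc_next + dh % o_ % (1.0 - tc % tc);
    vec cprev = (t > 0) ? vec(cc.C.row(t - 1).t()) : vec(h, arma::fill::zeros);
    vec hprev = (t > 0) ? vec(cc.H.row(t - 1).t()) : vec(h, arma::fill::zeros);
    vec da(4 * h);
    da.subvec(0, h - 1)         = (dc % g_) % i_ % (1.0 - i_);
    da.subvec(h, 2 * h - 1)     = (dc % cprev) % f_ % (1.0 - f_);
    da.subvec(2 * h, 3 * h - 1) = (dh % tc) % o_ % (1.0 - o_);
    da.subvec(3 * h, 4 * h - 1) = (dc % i_) % (1.0 - g_ % g_);
    dW += da * X.row(t);
    dU += da * hprev.t();
    db += da;
    dX.row(t) = (W.t() * da).t();
    dh_next = U.t() * da;
    dc_next = dc % f_;
  }
}

// ---------------------------------------------------------------- CRF

static double logsumexp(const vec& v) {
  double m = v.max();
  return m + std::log(arma::sum(arma::exp(v - m)));
}

// alpha: T x L forward log-scores (filled if non-null)
static double crf_alpha(const mat& em, const mat& trans, mat* alpha_out) {
  const int T = em.n_rows, L = em.n_cols, S = L, E = L + 1;
  mat alpha(T, L);
  for (int l = 0; l < L; ++l) alpha(0, l) = trans(S, l) + em(0, l);
  for (int t = 1; t < T; ++t)
    for (int l = 0; l < L; ++l)
      alpha(t, l) = em(t, l) +
        logsumexp(alpha.row(t - 1).t() + trans.submat(0, l, L - 1, l));
  vec fin = alpha.row(T - 1).t() + trans.submat(0, E, L - 1, E);
  if (alpha_out) *alpha_out = alpha;
  return logsumexp(fin);
}

// [[Rcpp::export]]
double cpp_crf_logZ(const arma::mat& em, const arma::mat& trans) {
  if (em.n_rows == 0) return 0.0;
  return crf_alpha(em, trans, nullptr);
}

static double crf_gold_score(const mat& em, const mat& trans,
                             const arma::ivec& y) {
  const int T = em.n_rows, L = em.n_cols, S = L, E = L + 1;
  double s = trans(S, y(0)) + em(0, y(0));
  for (int t = 1; t < T; ++t) s += trans(y(t - 1), y(t)) + em(t, y(t));
  s += trans(y(T - 1), E);
  return s;
}

// loss = logZ - gold score; fills gradients of the loss.
static double crf_loss_grad(const mat& em, const mat& trans,
                            const arma::ivec& y, mat& dEm, mat& dTrans) {
  const int T = em.n_rows, L = em.n_cols, S = L, E = L + 1;
  mat alpha;
  double logZ = crf_alpha(em, trans, &alpha);
  mat beta(T, L);
  for (int l = 0; l < L; ++l) beta(T - 1, l) = trans(l, E);
  for (int t = T - 2; t >= 0; --t)
    for (int l = 0; l < L; ++l)
      beta(t, l) = logsumexp(trans.submat(l, 0, l, L - 1).t() +
                             em.row(t + 1).t() + beta.row(t + 1).t());
  dEm = arma::exp(alpha + beta - logZ);          // unary marginals
  dTrans.zeros(L + 2, L + 2);
  for (int l = 0; l < L; ++l) {
    dTrans(S, l) += std::exp(trans(S, l) + em(0, l) + beta(0, l) - logZ);
    dTrans(l, E) += std::exp(alpha(T - 1, l) + trans(l, E) - logZ);
  }
  for (int t = 0; t + 1 < T; ++t)
    for (int k = 0; k < L; ++k)
      for (int l = 0; l < L; ++l)
        dTrans(k, l) += std::exp(alpha(t, k) + trans(k, l) + em(t + 1, l) +
                                 beta(t + 1, l) - logZ);
  // subtract gold path counts
  dEm(0, y(0)) -= 1.0;
  dTrans(S, y(0)) -= 1.0;
  for (int t = 1; t < T; ++t) {
    dEm(t, y(t)) -= 1.0;
    dTrans(y(t - 1), y(t)) -= 1.0;
  }
  dTrans(y(T - 1), E) -= 1.0;
  return logZ - crf_gold_score(em, trans, y);
}

// [[Rcpp::export]]
double cpp_crf_nll(const arma::mat& em, const arma::mat& trans,
                   const arma::ivec& gold) {
  mat dEm, dTrans;
  return crf_loss_grad(em, trans, gold, dEm, dTrans);
}

// [[Rcpp::export]]
List cpp_viterbi(const arma::mat& em, const arma::mat& trans) {
  const int T = em.n_rows, L = em.n_cols, S = L, E = L + 1;
  if (T == 0)
    return List::create(_["path"] = IntegerVector(0), _["score"] = 0.0);
  mat delta(T, L);
  arma::imat bp(T, L, arma::fill::zeros);
  for (int l = 0; l < L; ++l) delta(0, l) = trans(S, l) + em(0, l);
  for (int t = 1; t < T; ++t)
    for (int l = 0; l < L; ++l) {
      double best = delta(t - 1, 0) + trans(0, l);
      int arg = 0;
      for (int k = 1; k < L; ++k) {
        double s = delta(t - 1, k) + trans(k, l);
        if (s > best) { best = s; arg = k; }   // ties keep lower label index
      }
      delta(t, l) = best + em(t, l);
      bp(t, l) = arg;
    }
  double best = delta(T - 1, 0) + trans(0, E);
  int arg = 0;
  for (int l = 1; l < L; ++l) {
    double s = delta(T - 1, l) + trans(l, E);
    if (s > best) { best = s; arg = l; }
  }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = bp(t, path[t]);
  return List::create(_["path"] = path, _["score"] = best);
}

// ---------------------------------------------------------------- tagger

struct Seq {
  arma::ivec words, roles, labels;
  std::vector<arma::ivec> chars;
};

static std::vector<Seq> unpack_seqs(List seqs) {
  std::vector<Seq> out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    List s = seqs[i];
    out[i].words = as<arma::ivec>(s["words"]);
    out[i].roles = as<arma::ivec>(s["roles"]);
    out[i].labels = as<arma::ivec>(s["labels"]);
    List ch = s["chars"];
    out[i].chars.resize(ch.size());
    for (int j = 0; j < ch.size(); ++j)
      out[i].chars[j] = as<arma::ivec>(ch[j]);
  }
  return out;
}

struct TaggerParams {
  mat Ew, Ec, Er;
  mat CfW, CfU, CbW, CbU;
  vec Cfb, Cbb;
  mat WfW, WfU, WbW, WbU;
  vec Wfb, Wbb;
  mat P; vec pb;
  mat trans;
};

static TaggerParams unpack_tagger(List p) {
  TaggerParams q;
  q.Ew = as<mat>(p["Ew"]); q.Ec = as<mat>(p["Ec"]); q.Er = as<mat>(p["Er"]);
  q.CfW = as<mat>(p["Cf_W"]); q.CfU = as<mat>(p["Cf_U"]); q.Cfb = as<vec>(p["Cf_b"]);
  q.CbW = as<mat>(p["Cb_W"]); q.CbU = as<mat>(p["Cb_U"]); q.Cbb = as<vec>(p["Cb_b"]);
  q.WfW = as<mat>(p["Wf_W"]); q.WfU = as<mat>(p["Wf_U"]); q.Wfb = as<vec>(p["Wf_b"]);
  q.WbW = as<mat>(p["Wb_W"]); q.WbU = as<mat>(p["Wb_U"]); q.Wbb = as<vec>(p["Wb_b"]);
  q.P = as<mat>(p["P"]); q.pb = as<vec>(p["pb"]);
  q.trans = as<mat>(p["trans"]);
  return q;
}

static List pack_tagger(const TaggerParams& q) {
  return List::create(
    _["Ew"] = q.Ew, _["Ec"] = q.Ec, _["Er"] = q.Er,
    _["Cf_W"] = q.CfW, _["Cf_U"] = q.CfU, _["Cf_b"] = q.Cfb,
    _["Cb_W"] = q.CbW, _["Cb_U"] = q.CbU, _["Cb_b"] = q.Cbb,
    _["Wf_W"] = q.WfW, _["Wf_U"] = q.WfU, _["Wf_b"] = q.Wfb,
    _["Wb_W"] = q.WbW, _["Wb_U"] = q.WbU, _["Wb_b"] = q.Wbb,
    _["P"] = q.P, _["pb"] = q.pb, _["trans"] = q.trans);
}

struct TaggerGrads {
  TaggerParams g;
  void zero_like(const TaggerParams& q) {
    g.Ew.zeros(q.Ew.n_rows, q.Ew.n_cols);
    g.Ec.zeros(q.Ec.n_rows, q.Ec.n_cols);
    g.Er.zeros(q.Er.n_rows, q.Er.n_cols);
    g.CfW.zeros(q.CfW.n_rows, q.CfW.n_cols); g.CfU.zeros(q.CfU.n_rows, q.CfU.n_cols);
    g.Cfb.zeros(q.Cfb.n_elem);
    g.CbW.zeros(q.CbW.n_rows, q.CbW.n_cols); g.CbU.zeros(q.CbU.n_rows, q.CbU.n_cols);
    g.Cbb.zeros(q.Cbb.n_elem);
    g.WfW.zeros(q.WfW.n_rows, q.WfW.n_cols); g.WfU.zeros(q.WfU.n_rows, q.WfU.n_cols);
    g.Wfb.zeros(q.Wfb.n_elem);
    g.WbW.zeros(q.WbW.n_rows, q.WbW.n_cols); g.WbU.zeros(q.WbU.n_rows, q.WbU.n_cols);
    g.Wbb.zeros(q.Wbb.n_elem);
    g.P.zeros(q.P.n_rows, q.P.n_cols); g.pb.zeros(q.pb.n_elem);
    g.trans.zeros(q.trans.n_rows, q.trans.n_cols);
  }
  double sqnorm() const {
    double s = 0;
    auto acc = [&s](const mat& m) { s += arma::accu(m % m); };
    acc(g.Ew); acc(g.Ec); acc(g.Er);
    acc(g.CfW); acc(g.CfU); acc(g.CbW); acc(g.CbU);
    acc(g.WfW); acc(g.WfU); acc(g.WbW); acc(g.WbU); acc(g.P); acc(g.trans);
    s += arma::dot(g.Cfb, g.Cfb) + arma::dot(g.Cbb, g.Cbb) +
         arma::dot(g.Wfb, g.Wfb) + arma::dot(g.Wbb, g.Wbb) +
         arma::dot(g.pb, g.pb);
    return s;
  }
  void apply(TaggerParams& q, double step) {
    q.Ew -= step * g.Ew; q.Ec -= step * g.Ec; q.Er -= step * g.Er;
    q.CfW -= step * g.CfW; q.CfU -= step * g.CfU; q.Cfb -= step * g.Cfb;
    q.CbW -= step * g.CbW; q.CbU -= step * g.CbU; q.Cbb -= step * g.Cbb;
    q.WfW -= step * g.WfW; q.WfU -= step * g.WfU; q.Wfb -= step * g.Wfb;
    q.WbW -= step * g.WbW; q.WbU -= step * g.WbU; q.Wbb -= step * g.Wbb;
    q.P -= step * g.P; q.pb -= step * g.pb; q.trans -= step * g.trans;
  }
};

struct EmbedCache {
  mat X0;                       // T x D, pre-dropout input
  std::vector<mat> Xc;          // per token, n_chars x dc
  std::vector<LSTMCache> cf, cb;
};

// Per-token input: word embedding (+ role embedding when use_role) plus the
// final hidden states of forward/backward character LSTMs.
static void embed_forward(const Seq& s, const TaggerParams& q, bool use_role,
                          EmbedCache& ec) {
  const int T = s.words.n_elem;
  const int dw = q.Ew.n_cols, hc = q.CfU.n_cols, dr = q.Er.n_cols;
  const int D = dw + 2 * hc + (use_role ? dr : 0);
  ec.X0.set_size(T, D);
  ec.Xc.resize(T); ec.cf.resize(T); ec.cb.resize(T);
  for (int t = 0; t < T; ++t) {
    const arma::ivec& ch = s.chars[t];
    mat Xc(ch.n_elem, q.Ec.n_cols);
    for (arma::uword j = 0; j < ch.n_elem; ++j) Xc.row(j) = q.Ec.row(ch(j));
    ec.Xc[t] = Xc;
    lstm_forward(Xc, q.CfW, q.CfU, q.Cfb, ec.cf[t]);
    mat Xcr = arma::flipud(Xc);
    lstm_forward(Xcr, q.CbW, q.CbU, q.Cbb, ec.cb[t]);
    ec.X0.submat(t, 0, t, dw - 1) = q.Ew.row(s.words(t));
    ec.X0.submat(t, dw, t, dw + hc - 1) = ec.cf[t].H.tail_rows(1);
    ec.X0.submat(t, dw + hc, t, dw + 2 * hc - 1) = ec.cb[t].H.tail_rows(1);
    if (use_role)
      ec.X0.submat(t, dw + 2 * hc, t, D - 1) = q.Er.row(s.roles(t));
  }
}

static void embed_backward(const Seq& s, const TaggerParams& q, bool use_role,
                           const EmbedCache& ec, const mat& dX0,
                           TaggerGrads& gr) {
  const int T = s.words.n_elem;
  const int dw = q.Ew.n_cols, hc = q.CfU.n_cols;
  for (int t = 0; t < T; ++t) {
    gr.g.Ew.row(s.words(t)) += dX0.submat(t, 0, t, dw - 1);
    if (use_role)
      gr.g.Er.row(s.roles(t)) +=
        dX0.submat(t, dw + 2 * hc, t, dX0.n_cols - 1);
    const mat& Xc = ec.Xc[t];
    const int n = Xc.n_rows;
    mat dHf(n, hc, arma::fill::zeros), dHb(n, hc, arma::fill::zeros);
    dHf.row(n - 1) = dX0.submat(t, dw, t, dw + hc - 1);
    dHb.row(n - 1) = dX0.submat(t, dw + hc, t, dw + 2 * hc - 1);
    mat dXc_f, dXc_b;
    lstm_backward(Xc, q.CfW, q.CfU, ec.cf[t], dHf, dXc_f,
                  gr.g.CfW, gr.g.CfU, gr.g.Cfb);
    mat Xcr = arma::flipud(Xc);
    lstm_backward(Xcr, q.CbW, q.CbU, ec.cb[t], dHb, dXc_b,
                  gr.g.CbW, gr.g.CbU, gr.g.Cbb);
    mat dXc = dXc_f + arma::flipud(dXc_b);
    for (int j = 0; j < n; ++j) gr.g.Ec.row(s.chars[t](j)) += dXc.row(j);
  }
}

// Full forward pass to emissions; caches everything needed for backward.
struct NetCache {
  EmbedCache ec;
  mat M1, M2;                  // dropout masks (empty when not training)
  mat X;                       // input after dropout
  LSTMCache wf, wb;
  mat H;                       // T x 2H after dropout
  mat Em;
};

static void net_forward(const Seq& s, const TaggerParams& q, bool use_role,
                        bool train, double keep_scale_p, std::mt19937_64* rng,
                        NetCache& nc) {
  embed_forward(s, q, use_role, nc.ec);
  const int T = nc.ec.X0.n_rows;
  const int Hh = q.WfU.n_cols;
  nc.X = nc.ec.X0;
  if (train && keep_scale_p > 0) {
    std::bernoulli_distribution keep(1.0 - keep_scale_p);
    nc.M1.set_size(T, nc.X.n_cols);
    for (arma::uword i = 0; i < nc.M1.n_elem; ++i)
      nc.M1(i) = keep(*rng) ? 1.0 / (1.0 - keep_scale_p) : 0.0;
    nc.X %= nc.M1;
  }
  lstm_forward(nc.X, q.WfW, q.WfU, q.Wfb, nc.wf);
  mat Xr = arma::flipud(nc.X);
  lstm_forward(Xr, q.WbW, q.WbU, q.Wbb, nc.wb);
  nc.H.set_size(T, 2 * Hh);
  nc.H.cols(0, Hh - 1) = nc.wf.H;
  nc.H.cols(Hh, 2 * Hh - 1) = arma::flipud(nc.wb.H);
  if (train && keep_scale_p > 0) {
    std::bernoulli_distribution keep(1.0 - keep_scale_p);
    nc.M2.set_size(T, 2 * Hh);
    for (arma::uword i = 0; i < nc.M2.n_elem; ++i)
      nc.M2(i) = keep(*rng) ? 1.0 / (1.0 - keep_scale_p) : 0.0;
    nc.H %= nc.M2;
  }
  nc.Em = nc.H * q.P.t();
  nc.Em.each_row() += q.pb.t();
}

static double net_train_step(const Seq& s, TaggerParams& q, bool use_role,
                             double dropout, double lr, double clip,
                             std::mt19937_64& rng, TaggerGrads& gr) {
  NetCache nc;
  net_forward(s, q, use_role, true, dropout, &rng, nc);
  const int Hh = q.WfU.n_cols;
  mat dEm, dTrans;
  double loss = crf_loss_grad(nc.Em, q.trans, s.labels, dEm, dTrans);
  gr.zero_like(q);
  gr.g.trans = dTrans;
  gr.g.P = dEm.t() * nc.H;
  gr.g.pb = arma::sum(dEm, 0).t();
  mat dH = dEm * q.P;
  if (nc.M2.n_elem) dH %= nc.M2;
  mat dX_f, dX_b;
  lstm_backward(nc.X, q.WfW, q.WfU, nc.wf, dH.cols(0, Hh - 1),
                dX_f, gr.g.WfW, gr.g.WfU, gr.g.Wfb);
  mat Xr = arma::flipud(nc.X);
  lstm_backward(Xr, q.WbW, q.WbU, nc.wb,
                arma::flipud(dH.cols(Hh, 2 * Hh - 1)),
                dX_b, gr.g.WbW, gr.g.WbU, gr.g.Wbb);
  mat dX = dX_f + arma::flipud(dX_b);
  if (nc.M1.n_elem) dX %= nc.M1;
  embed_backward(s, q, use_role, nc.ec, dX, gr);
  double nrm = std::sqrt(gr.sqnorm());
  double step = lr;
  if (clip > 0 && nrm > clip) step = lr * clip / nrm;
  gr.apply(q, step);
  return loss;
}

// [[Rcpp::export]]
List cpp_tagger_train(List seqs, List params, List cfg) {
  std::vector<Seq> ss = unpack_seqs(seqs);
  TaggerParams q = unpack_tagger(params);
  const double lr = as<double>(cfg["learning_rate"]);
  const double dropout = as<double>(cfg["dropout"]);
  const double clip = as<double>(cfg["clip"]);
  const int epochs = as<int>(cfg["epochs"]);
  const bool use_role = as<bool>(cfg["use_role"]);
  const double unk_prob = as<double>(cfg["unk_prob"]);
  const int unk_index = as<int>(cfg["unk_index"]);
  LogicalVector singleton = cfg["singleton"];
  std::mt19937_64 rng(static_cast<uint64_t>(as<double>(cfg["seed"])));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> order(ss.size());
  for (size_t i = 0; i < ss.size(); ++i) order[i] = i;
  NumericVector trace(epochs);
  TaggerGrads gr;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tot = 0;
    for (int idx : order) {
      Seq s = ss[idx];
      if (unk_prob > 0) {      // train the UNK vector on rare words
        for (arma::uword t = 0; t < s.words.n_elem; ++t)
          if (singleton[s.words(t)] && unif(rng) < unk_prob)
            s.words(t) = unk_index;
      }
      tot += net_train_step(s, q, use_role, dropout, lr, clip, rng, gr);
    }
    trace[ep] = tot / std::max<size_t>(1, ss.size());
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack_tagger(q), _["loss"] = trace);
}

// Loss and full analytic gradient for one sequence, dropout disabled.
// Used by finite-difference gradient checks.
// [[Rcpp::export]]
List cpp_tagger_grad(List seq, List params, bool use_role) {
  List one = List::create(seq);
  std::vector<Seq> ss = unpack_seqs(one);
  TaggerParams q = unpack_tagger(params);
  NetCache nc;
  net_forward(ss[0], q, use_role, false, 0.0, nullptr, nc);
  const int Hh = q.WfU.n_cols;
  mat dEm, dTrans;
  double loss = crf_loss_grad(nc.Em, q.trans, ss[0].labels, dEm, dTrans);
  TaggerGrads gr;
  gr.zero_like(q);
  gr.g.trans = dTrans;
  gr.g.P = dEm.t() * nc.H;
  gr.g.pb = arma::sum(dEm, 0).t();
  mat dH = dEm * q.P;
  mat dX_f, dX_b;
  lstm_backward(nc.X, q.WfW, q.WfU, nc.wf, dH.cols(0, Hh - 1),
                dX_f, gr.g.WfW, gr.g.WfU, gr.g.Wfb);
  mat Xr = arma::flipud(nc.X);
  lstm_backward(Xr, q.WbW, q.WbU, nc.wb,
                arma::flipud(dH.cols(Hh, 2 * Hh - 1)),
                dX_b, gr.g.WbW, gr.g.WbU, gr.g.Wbb);
  mat dX = dX_f + arma::flipud(dX_b);
  embed_backward(ss[0], q, use_role, nc.ec, dX, gr);
  return List::create(_["loss"] = loss, _["grads"] = pack_tagger(gr.g));
}

// [[Rcpp::export]]
List cpp_tagger_predict(List seqs, List params, bool use_role) {
  std::vector<Seq> ss = unpack_seqs(seqs);
  TaggerParams q = unpack_tagger(params);
  List out(ss.size());
  for (size_t i = 0; i < ss.size(); ++i) {
    NetCache nc;
    net_forward(ss[i], q, use_role, false, 0.0, nullptr, nc);
    List v = cpp_viterbi(nc.Em, q.trans);
    out[i] = v["path"];
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_embed_sequence(List seq, List params, bool use_role) {
  List one = List::create(seq);
  std::vector<Seq> ss = unpack_seqs(one);
  TaggerParams q = unpack_tagger(params);
  EmbedCache ec;
  embed_forward(ss[0], q, use_role, ec);
  return ec.X0;
}

// [[Rcpp::export]]
double cpp_tagger_seq_nll(List seq, List params, bool use_role,
                          arma::ivec gold) {
  List one = List::create(seq);
  std::vector<Seq> ss = unpack_seqs(one);
  TaggerParams q = unpack_tagger(params);
  NetCache nc;
  net_forward(ss[0], q, use_role, false, 0.0, nullptr, nc);
  mat dEm, dTrans;
  return crf_loss_grad(nc.Em, q.trans, gold, dEm, dTrans);
}

// ------------------------------------------------------- pair classifier

struct PairParams {
  mat Ew, Epc, Epa;
  mat WfW, WfU, WbW, WbU;
  vec Wfb, Wbb;
  mat SoW; vec Sob;
};

static PairParams unpack_pair(List p) {
  PairParams q;
  q.Ew = as<mat>(p["Ew"]); q.Epc = as<mat>(p["Epc"]); q.Epa = as<mat>(p["Epa"]);
  q.WfW = as<mat>(p["Wf_W"]); q.WfU = as<mat>(p["Wf_U"]); q.Wfb = as<vec>(p["Wf_b"]);
  q.WbW = as<mat>(p["Wb_W"]); q.WbU = as<mat>(p["Wb_U"]); q.Wbb = as<vec>(p["Wb_b"]);
  q.SoW = as<mat>(p["So_W"]); q.Sob = as<vec>(p["So_b"]);
  return q;
}

static List pack_pair(const PairParams& q) {
  return List::create(
    _["Ew"] = q.Ew, _["Epc"] = q.Epc, _["Epa"] = q.Epa,
    _["Wf_W"] = q.WfW, _["Wf_U"] = q.WfU, _["Wf_b"] = q.Wfb,
    _["Wb_W"] = q.WbW, _["Wb_U"] = q.WbU, _["Wb_b"] = q.Wbb,
    _["So_W"] = q.SoW, _["So_b"] = q.Sob);
}

struct PairInst {
  arma::ivec words, posc, posa;
  int label;
};

static std::vector<PairInst> unpack_insts(List insts) {
  std::vector<PairInst> out(insts.size());
  for (int i = 0; i < insts.size(); ++i) {
    List s = insts[i];
    out[i].words = as<arma::ivec>(s["words"]);
    out[i].posc = as<arma::ivec>(s["posc"]);
    out[i].posa = as<arma::ivec>(s["posa"]);
    out[i].label = as<int>(s["label"]);
  }
  return out;
}

static mat pair_input(const PairInst& s, const PairParams& q) {
  const int T = s.words.n_elem;
  const int dw = q.Ew.n_cols, dp = q.Epc.n_cols;
  mat X(T, dw + 2 * dp);
  for (int t = 0; t < T; ++t) {
    X.submat(t, 0, t, dw - 1) = q.Ew.row(s.words(t));
    X.submat(t, dw, t, dw + dp - 1) = q.Epc.row(s.posc(t));
    X.submat(t, dw + dp, t, dw + 2 * dp - 1) = q.Epa.row(s.posa(t));
  }
  return X;
}

// softmax over final Bi-LSTM states; returns P(related)
static double pair_forward(const PairInst& s, const PairParams& q,
                           mat* X_out, LSTMCache* cf, LSTMCache* cb,
                           vec* probs_out) {
  mat X = pair_input(s, q);
  LSTMCache f, b;
  lstm_forward(X, q.WfW, q.WfU, q.Wfb, f);
  mat Xr = arma::flipud(X);
  lstm_forward(Xr, q.WbW, q.WbU, q.Wbb, b);
  const int Hh = q.WfU.n_cols;
  vec u(2 * Hh);
  u.subvec(0, Hh - 1) = f.H.tail_rows(1).t();
  u.subvec(Hh, 2 * Hh - 1) = b.H.tail_rows(1).t();
  vec logits = q.SoW * u + q.Sob;
  vec p = arma::exp(logits - logsumexp(logits));
  if (X_out) { *X_out = X; *cf = f; *cb = b; }
  if (probs_out) *probs_out = p;
  return p(1);
}

// [[Rcpp::export]]
List cpp_pair_train(List insts, List params, List cfg) {
  std::vector<PairInst> ss = unpack_insts(insts);
  PairParams q = unpack_pair(params);
  const double lr = as<double>(cfg["learning_rate"]);
  const double clip = as<double>(cfg["clip"]);
  const int epochs = as<int>(cfg["epochs"]);
  std::mt19937_64 rng(static_cast<uint64_t>(as<double>(cfg["seed"])));
  std::vector<int> order(ss.size());
  for (size_t i = 0; i < ss.size(); ++i) order[i] = i;
  NumericVector trace(epochs);
  const int Hh = q.WfU.n_cols;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tot = 0;
    for (int idx : order) {
      const PairInst& s = ss[idx];
      mat X; LSTMCache f, b; vec p;
      pair_forward(s, q, &X, &f, &b, &p);
      tot += -std::log(std::max(p(s.label), 1e-12));
      vec dlog = p;
      dlog(s.label) -= 1.0;
      const int T = X.n_rows;
      vec u(2 * Hh);
      u.subvec(0, Hh - 1) = f.H.tail_rows(1).t();
      u.subvec(Hh, 2 * Hh - 1) = b.H.tail_rows(1).t();
      mat dSoW = dlog * u.t();
      vec dSob = dlog;
      vec du = q.SoW.t() * dlog;
      mat dHf(T, Hh, arma::fill::zeros), dHb(T, Hh, arma::fill::zeros);
      dHf.row(T - 1) = du.subvec(0, Hh - 1).t();
      dHb.row(T - 1) = du.subvec(Hh, 2 * Hh - 1).t();
      mat dX_f, dX_b;
      mat gWfW(arma::size(q.WfW), arma::fill::zeros),
          gWfU(arma::size(q.WfU), arma::fill::zeros),
          gWbW(arma::size(q.WbW), arma::fill::zeros),
          gWbU(arma::size(q.WbU), arma::fill::zeros);
      vec gWfb(q.Wfb.n_elem, arma::fill::zeros),
          gWbb(q.Wbb.n_elem, arma::fill::zeros);
      lstm_backward(X, q.WfW, q.WfU, f, dHf, dX_f, gWfW, gWfU, gWfb);
      mat Xr = arma::flipud(X);
      lstm_backward(Xr, q.WbW, q.WbU, b, dHb, dX_b, gWbW, gWbU, gWbb);
      mat dX = dX_f + arma::flipud(dX_b);
      const int dw = q.Ew.n_cols, dp = q.Epc.n_cols;
      mat gEw(arma::size(q.Ew), arma::fill::zeros),
          gEpc(arma::size(q.Epc), arma::fill::zeros),
          gEpa(arma::size(q.Epa), arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        gEw.row(s.words(t)) += dX.submat(t, 0, t, dw - 1);
        gEpc.row(s.posc(t)) += dX.submat(t, dw, t, dw + dp - 1);
        gEpa.row(s.posa(t)) += dX.submat(t, dw + dp, t, dw + 2 * dp - 1);
      }
      double sq = arma::accu(arma::square(dSoW)) + arma::dot(dSob, dSob) +
        arma::accu(arma::square(gWfW)) + arma::accu(arma::square(gWfU)) +
        arma::accu(arma::square(gWbW)) + arma::accu(arma::square(gWbU)) +
        arma::dot(gWfb, gWfb) + arma::dot(gWbb, gWbb) +
        arma::accu(arma::square(gEw)) + arma::accu(arma::square(gEpc)) +
        arma::accu(arma::square(gEpa));
      double nrm = std::sqrt(sq), step = lr;
      if (clip > 0 && nrm > clip) step = lr * clip / nrm;
      q.SoW -= step * dSoW; q.Sob -= step * dSob;
      q.WfW -= step * gWfW; q.WfU -= step * gWfU; q.Wfb -= step * gWfb;
      q.WbW -= step * gWbW; q.WbU -= step * gWbU; q.Wbb -= step * gWbb;
      q.Ew -= step * gEw; q.Epc -= step * gEpc; q.Epa -= step * gEpa;
    }
    trace[ep] = tot / std::max<size_t>(1, ss.size());
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack_pair(q), _["loss"] = trace);
}

// [[Rcpp::export]]
NumericVector cpp_pair_predict(List insts, List params) {
  std::vector<PairInst> ss = unpack_insts(insts);
  PairParams q = unpack_pair(params);
  NumericVector out(ss.size());
  for (size_t i = 0; i < ss.size(); ++i)
    out[i] = pair_forward(ss[i], q, nullptr, nullptr, nullptr, nullptr);
  return out;
}
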