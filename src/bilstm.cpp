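// Compiled kernels for the bi-LSTM artifact classifier: full forward pass
// and backpropagation through the stacked sequence-to-sequence bi-LSTM
// layers, the sequence-to-one bi-LSTM layer, the fully connected head and
// the softmax. The pure-R implementation of the same computation is kept
// in the package as the reference; equivalence is asserted in the tests.
//
// All per-timestep quantities are cached in (B*T) x H slabs (rows of
// timestep t at [t*B, (t+1)*B)), so one training step performs a handful
// of large GEMMs plus a light recurrent loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct LstmParams {
  arma::mat W;   // in x 4H
  arma::mat U;   // H x 4H
  arma::rowvec b;
};

LstmParams get_lstm(const List &l) {
  LstmParams p;
  p.W = as<arma::mat>(l["W"]);
  p.U = as<arma::mat>(l["U"]);
  p.b = arma::rowvec(as<arma::vec>(l["b"]).t());
  return p;
}

struct LstmCache {
  arma::mat i, f, g, o, tc, c_prev, h_prev, h;  // (B*T) x H slabs
  bool reverse;
  arma::mat last;                               // final hidden state, B x H
};

inline arma::mat sigm(const arma::mat &x) { return 1.0 / (1.0 + arma::exp(-x)); }

// forward pass of one direction over stacked inputs Xs ((B*T) x in)
void lstm_forward(const arma::mat &Xs, int B, int T, const LstmParams &prm,
                  bool reverse, LstmCache &cc) {
  const int H = prm.U.n_rows;
  cc.reverse = reverse;
  cc.i.set_size(B * T, H); cc.f.set_size(B * T, H);
  cc.g.set_size(B * T, H); cc.o.set_size(B * T, H);
  cc.tc.set_size(B * T, H); cc.c_prev.set_size(B * T, H);
  cc.h_prev.set_size(B * T, H); cc.h.set_size(B * T, H);
  arma::mat P = Xs * prm.W;
  P.each_row() += prm.b;
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  for (int k = 0; k < T; ++k) {
    const int t = reverse ? T - 1 - k : k;
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    arma::mat a = P.rows(r0, r1);
    a += h * prm.U;
    arma::mat ig = sigm(a.cols(0, H - 1));
    arma::mat fg = sigm(a.cols(H, 2 * H - 1));
    arma::mat gg = arma::tanh(a.cols(2 * H, 3 * H - 1));
    arma::mat og = sigm(a.cols(3 * H, 4 * H - 1));
    cc.c_prev.rows(r0, r1) = c;
    cc.h_prev.rows(r0, r1) = h;
    c = fg % c + ig % gg;
    arma::mat tc = arma::tanh(c);
    h = og % tc;
    cc.i.rows(r0, r1) = ig; cc.f.rows(r0, r1) = fg;
    cc.g.rows(r0, r1) = gg; cc.o.rows(r0, r1) = og;
    cc.tc.rows(r0, r1) = tc; cc.h.rows(r0, r1) = h;
  }
  cc.last = h;
}

// backward pass of one direction; dh_ext is (B*T) x H stacked external
// gradients; Xs is the stacked input of the forward pass
arma::mat lstm_backward(const arma::mat &Xs, const LstmParams &prm,
                        const LstmCache &cc, int B, int T,
                        const arma::mat &dh_ext,
                        arma::mat &dW, arma::mat &dU, arma::rowvec &db) {
  const int H = prm.U.n_rows;
  arma::mat da_all(B * T, 4 * H);
  arma::mat Ut = prm.U.t();
  arma::mat dh_rec(B, H, arma::fill::zeros), dc_rec(B, H, arma::fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    const int t = cc.reverse ? T - 1 - k : k;
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    arma::mat dh = dh_rec + dh_ext.rows(r0, r1);
    arma::mat tc = cc.tc.rows(r0, r1), o = cc.o.rows(r0, r1);
    arma::mat i = cc.i.rows(r0, r1), f = cc.f.rows(r0, r1);
    arma::mat g = cc.g.rows(r0, r1);
    arma::mat do_ = dh % tc;
    arma::mat dtc = dh % o % (1.0 - arma::square(tc)) + dc_rec;
    dc_rec = dtc % f;
    arma::mat da(B, 4 * H);
    da.cols(0, H - 1)         = (dtc % g) % i % (1.0 - i);
    da.cols(H, 2 * H - 1)     = (dtc % cc.c_prev.rows(r0, r1)) % f % (1.0 - f);
    da.cols(2 * H, 3 * H - 1) = (dtc % i) % (1.0 - arma::square(g));
    da.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    da_all.rows(r0, r1) = da;
    dh_rec = da * Ut;
  }
  dW = Xs.t() * da_all;
  dU = cc.h_prev.t() * da_all;
  db = arma::sum(da_all, 0);
  return da_all * prm.W.t();
}

List lstm_grad_list(const arma::mat &dW, const arma::mat &dU, const arma::rowvec &db) {
  return List::create(_["W"] = dW, _["U"] = dU, _["b"] = arma::vec(db.t()));
}

struct ModelState {
  arma::mat emb;
  std::vector<LstmParams> fwd, bwd;   // seq2seq layers
  LstmParams s2o_f, s2o_b;
  arma::mat fc1W; arma::rowvec fc1b;
  arma::mat fc2W; arma::rowvec fc2b;
};

ModelState load_model(const List &prm) {
  ModelState m;
  m.emb = as<arma::mat>(prm["emb"]);
  List layers = prm["layers"];
  for (int li = 0; li < layers.size(); ++li) {
    List l = layers[li];
    m.fwd.push_back(get_lstm(l["fwd"]));
    m.bwd.push_back(get_lstm(l["bwd"]));
  }
  List s2o = prm["seq2one"];
  m.s2o_f = get_lstm(s2o["fwd"]);
  m.s2o_b = get_lstm(s2o["bwd"]);
  List fc1 = prm["fc1"], fc2 = prm["fc2"];
  m.fc1W = as<arma::mat>(fc1["W"]);
  m.fc1b = arma::rowvec(as<arma::vec>(fc1["b"]).t());
  m.fc2W = as<arma::mat>(fc2["W"]);
  m.fc2b = arma::rowvec(as<arma::vec>(fc2["b"]).t());
  return m;
}

struct FwdResult {
  arma::mat probs, feat, a1;
  std::vector<LstmCache> cf, cb;        // per seq2seq layer
  LstmCache s2o_f, s2o_b;
  std::vector<arma::mat> stage_in;      // stacked input of each stage
};

void model_forward(const ModelState &m, const arma::imat &ids, FwdResult &r) {
  const int B = ids.n_rows, T = ids.n_cols;
  const int L = m.fwd.size();
  r.cf.resize(L); r.cb.resize(L);
  r.stage_in.clear();
  r.stage_in.reserve(L + 1);
  {
    arma::mat X0(B * T, m.emb.n_cols);
    for (int t = 0; t < T; ++t)
      for (int bi = 0; bi < B; ++bi)
        X0.row(t * B + bi) = m.emb.row(ids(bi, t) - 1);
    r.stage_in.push_back(std::move(X0));
  }
  for (int li = 0; li < L; ++li) {
    const arma::mat &Xin = r.stage_in[li];
    lstm_forward(Xin, B, T, m.fwd[li], false, r.cf[li]);
    lstm_forward(Xin, B, T, m.bwd[li], true, r.cb[li]);
    r.stage_in.push_back(arma::join_rows(r.cf[li].h, r.cb[li].h));
  }
  const arma::mat &Xlast = r.stage_in[L];
  lstm_forward(Xlast, B, T, m.s2o_f, false, r.s2o_f);
  lstm_forward(Xlast, B, T, m.s2o_b, true, r.s2o_b);
  r.feat = arma::join_rows(r.s2o_f.last, r.s2o_b.last);
  arma::mat z1 = r.feat * m.fc1W;
  z1.each_row() += m.fc1b;
  r.a1 = arma::clamp(z1, 0.0, arma::datum::inf);
  arma::mat z2 = r.a1 * m.fc2W;
  z2.each_row() += m.fc2b;
  z2.each_col() -= arma::max(z2, 1);
  arma::mat e = arma::exp(z2);
  r.probs = e.each_col() / arma::sum(e, 1);
}

} // namespace

// [[Rcpp::export(name = ".cpp_bilstm_fwd")]]
NumericMatrix cpp_bilstm_fwd(List prm, IntegerMatrix ids_) {
  ModelState m = load_model(prm);
  arma::imat ids = as<arma::imat>(ids_);
  FwdResult r;
  model_forward(m, ids, r);
  return wrap(r.probs);
}

// [[Rcpp::export(name = ".cpp_bilstm_fwdbwd")]]
List cpp_bilstm_fwdbwd(List prm, IntegerMatrix ids_, IntegerVector labels_) {
  ModelState m = load_model(prm);
  arma::imat ids = as<arma::imat>(ids_);
  const int B = ids.n_rows, T = ids.n_cols;
  FwdResult r;
  model_forward(m, ids, r);

  // cross-entropy loss and softmax gradient (label 1 = artifact, column 2)
  arma::vec loss(B);
  arma::mat dz2 = r.probs;
  for (int bi = 0; bi < B; ++bi) {
    const int cls = labels_[bi];
    double p = std::max(r.probs(bi, cls), 1e-12);
    loss[bi] = -std::log(p);
    dz2(bi, cls) -= 1.0;
  }
  dz2 /= (double)B;

  arma::mat dfc2W = r.a1.t() * dz2;
  arma::rowvec dfc2b = arma::sum(dz2, 0);
  arma::mat da1 = dz2 * m.fc2W.t();
  arma::mat dz1 = da1 % arma::conv_to<arma::mat>::from(r.a1 > 0);
  arma::mat dfc1W = r.feat.t() * dz1;
  arma::rowvec dfc1b = arma::sum(dz1, 0);
  arma::mat dfeat = dz1 * m.fc1W.t();

  const int L = m.fwd.size();
  const int Hs = m.s2o_f.U.n_rows;
  // gradient enters the seq2one directions only at their final steps
  arma::mat dh_ext_f(B * T, Hs, arma::fill::zeros);
  arma::mat dh_ext_b(B * T, Hs, arma::fill::zeros);
  dh_ext_f.rows((T - 1) * B, T * B - 1) = dfeat.cols(0, Hs - 1);
  dh_ext_b.rows(0, B - 1) = dfeat.cols(Hs, 2 * Hs - 1);
  arma::mat dWf, dUf, dWb, dUb; arma::rowvec dbf, dbb;
  arma::mat dinp =
    lstm_backward(r.stage_in[L], m.s2o_f, r.s2o_f, B, T, dh_ext_f, dWf, dUf, dbf) +
    lstm_backward(r.stage_in[L], m.s2o_b, r.s2o_b, B, T, dh_ext_b, dWb, dUb, dbb);
  List g_s2o = List::create(_["fwd"] = lstm_grad_list(dWf, dUf, dbf),
                            _["bwd"] = lstm_grad_list(dWb, dUb, dbb));

  List g_layers(L);
  for (int li = L - 1; li >= 0; --li) {
    const int H = m.fwd[li].U.n_rows;
    arma::mat dWlf, dUlf, dWlb, dUlb; arma::rowvec dblf, dblb;
    arma::mat dnew =
      lstm_backward(r.stage_in[li], m.fwd[li], r.cf[li], B, T,
                    dinp.cols(0, H - 1), dWlf, dUlf, dblf) +
      lstm_backward(r.stage_in[li], m.bwd[li], r.cb[li], B, T,
                    dinp.cols(H, 2 * H - 1), dWlb, dUlb, dblb);
    dinp = std::move(dnew);
    g_layers[li] = List::create(_["fwd"] = lstm_grad_list(dWlf, dUlf, dblf),
                                _["bwd"] = lstm_grad_list(dWlb, dUlb, dblb));
  }

  arma::mat demb(m.emb.n_rows, m.emb.n_cols, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int bi = 0; bi < B; ++bi)
      demb.row(ids(bi, t) - 1) += dinp.row(t * B + bi);

  List g = List::create(
    _["emb"] = demb,
    _["layers"] = g_layers,
    _["seq2one"] = g_s2o,
    _["fc1"] = List::create(_["W"] = dfc1W, _["b"] = arma::vec(dfc1b.t())),
    _["fc2"] = List::create(_["W"] = dfc2W, _["b"] = arma::vec(dfc2b.t())));
  return List::create(_["loss"] = arma::mean(loss),
                      _["probs"] = r.probs,
                      _["grads"] = g);
}
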