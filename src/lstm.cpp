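// Compiled core of the LSTM encoder-decoder: full forward pass,
// categorical cross-entropy and backpropagation through time for one
// padded index batch.  Mirrors the reference R implementation in
// R/lstm.R exactly (gate layout [input | forget | candidate | output],
// teacher forcing, loss averaged over batch x (T-1) positions); the
// two are cross-checked in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct StepCache {
  mat i, f, g, o, tc, h_prev, c_prev;
  uvec x_idx;
};

static void lstm_step(const mat& Wx, const mat& Wh, const rowvec& b,
                      const uvec& x_idx, mat& h, mat& c, StepCache& cache) {
  const uword H = h.n_cols;
  mat z = Wx.rows(x_idx) + h * Wh;
  z.each_row() += b;
  cache.i = sigmoid(z.cols(0, H - 1));
  cache.f = sigmoid(z.cols(H, 2 * H - 1));
  cache.g = tanh(z.cols(2 * H, 3 * H - 1));
  cache.o = sigmoid(z.cols(3 * H, 4 * H - 1));
  cache.h_prev = h;
  cache.c_prev = c;
  cache.x_idx = x_idx;
  c = cache.f % c + cache.i % cache.g;
  cache.tc = tanh(c);
  h = cache.o % cache.tc;
}

// Backward through one step; accumulates parameter gradients in place
// and rewrites dh/dc with the gradients for the previous step's state.
static void lstm_step_back(const mat& Wx, const mat& Wh, const StepCache& cc,
                           mat& dh, mat& dc,
                           mat& dWx, mat& dWh, rowvec& db) {
  mat dz(dh.n_rows, 4 * dh.n_cols);
  const uword H = dh.n_cols;
  mat do_g = dh % cc.tc % cc.o % (1.0 - cc.o);
  mat dcf = dc + dh % cc.o % (1.0 - square(cc.tc));
  dz.cols(0, H - 1) = dcf % cc.g % cc.i % (1.0 - cc.i);
  dz.cols(H, 2 * H - 1) = dcf % cc.c_prev % cc.f % (1.0 - cc.f);
  dz.cols(2 * H, 3 * H - 1) = dcf % cc.i % (1.0 - square(cc.g));
  dz.cols(3 * H, 4 * H - 1) = do_g;
  for (uword r = 0; r < cc.x_idx.n_elem; ++r) {
    dWx.row(cc.x_idx(r)) += dz.row(r);
  }
  dWh += cc.h_prev.t() * dz;
  db += sum(dz, 0);
  dh = dz * Wh.t();
  dc = dcf % cc.f;
}

// [[Rcpp::export(name = ".cpp_seq2seq_loss")]]
Rcpp::List cpp_seq2seq_loss(const Rcpp::List& params,
                            const arma::umat& idx0,  // B x T, 1-based
                            const int H_, bool want_grads,
                            bool reverse_encoder) {
  const uword H = (uword)H_;
  const mat Wx_e = params["Wx_e"], Wh_e = params["Wh_e"];
  const mat Wx_d = params["Wx_d"], Wh_d = params["Wh_d"];
  const rowvec b_e = params["b_e"], b_d = params["b_d"];
  const mat Wy = params["Wy"];
  const rowvec by = params["by"];
  const uword B = idx0.n_rows, T = idx0.n_cols, V = Wx_e.n_rows;
  umat idx = idx0 - 1;  // 0-based

  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  std::vector<StepCache> enc(T), dec(T - 1);
  for (uword t = 0; t < T; ++t) {
    uword col = reverse_encoder ? (T - 1 - t) : t;
    lstm_step(Wx_e, Wh_e, b_e, idx.col(col), h, c, enc[t]);
  }

  const uword Td = T - 1;
  const double denom = (double)(B * Td);
  std::vector<mat> probs(Td), dec_h(Td);
  double loss = 0.0;
  for (uword t = 0; t < Td; ++t) {
    lstm_step(Wx_d, Wh_d, b_d, idx.col(t), h, c, dec[t]);
    dec_h[t] = h;
    mat logits = h * Wy;
    logits.each_row() += by;
    logits.each_col() -= max(logits, 1);
    mat p = exp(logits);
    p.each_col() /= sum(p, 1);
    probs[t] = p;
    for (uword r = 0; r < B; ++r) {
      loss -= std::log(std::max(p(r, idx(r, t + 1)), 1e-12)) / denom;
    }
  }
  if (!want_grads) return Rcpp::List::create(Rcpp::Named("loss") = loss);

  mat dWx_e(V, 4 * H, fill::zeros), dWh_e(H, 4 * H, fill::zeros);
  mat dWx_d(V, 4 * H, fill::zeros), dWh_d(H, 4 * H, fill::zeros);
  rowvec db_e(4 * H, fill::zeros), db_d(4 * H, fill::zeros);
  mat dWy(H, V, fill::zeros);
  rowvec dby(V, fill::zeros);

  mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
  for (uword t = Td; t-- > 0;) {
    mat dy = probs[t];
    for (uword r = 0; r < B; ++r) dy(r, idx(r, t + 1)) -= 1.0;
    dy /= denom;
    dWy += dec_h[t].t() * dy;
    dby += sum(dy, 0);
    dh += dy * Wy.t();
    lstm_step_back(Wx_d, Wh_d, dec[t], dh, dc, dWx_d, dWh_d, db_d);
  }
  for (uword t = T; t-- > 0;) {
    lstm_step_back(Wx_e, Wh_e, enc[t], dh, dc, dWx_e, dWh_e, db_e);
  }

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("Wx_e") = dWx_e, Rcpp::Named("Wh_e") = dWh_e,
          Rcpp::Named("b_e") = db_e, Rcpp::Named("Wx_d") = dWx_d,
          Rcpp::Named("Wh_d") = dWh_d, Rcpp::Named("b_d") = db_d,
          Rcpp::Named("Wy") = dWy, Rcpp::Named("by") = dby));
}
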