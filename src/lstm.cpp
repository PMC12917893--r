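// Batched forward/backward pass for the context-aware sequence model:
// three stacked LSTM layers, additive attention conditioned on a static
// clinical context vector, and a two-layer regression head. Sequences
// are passed as their valid (unmasked) windows only and tail-padded to
// the batch maximum; padded steps freeze the recurrent state and are
// excluded from attention, which makes predictions exactly invariant to
// padding.
//
// Parameter list layout (R side constructs it):
//   W1,U1,b1, W2,U2,b2, W3,U3,b3   LSTM layers (gate order i,f,g,o)
//   Wh (A x n3), Wc (A x C), ba (A), va (A)   additive attention
//   W1h (Hh x (n3+C)), b1h (Hh), w2h (1 x Hh), b2h (1)   head

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LayerCache {
  cube ga;   // activated gates, 4n x B x T
  cube c;    // cell states
  cube tc;   // tanh(cell)
  cube h;    // hidden states
};

struct ForwardCache {
  cube x0;          // F x B x T input
  std::vector<LayerCache> layers;
  mat active;       // B x T, 1 = real step
  mat q_all;        // not stored per design; see attn cubes below
  cube q;           // A x B x T attention tanh pre-score
  mat scores;       // T x B
  mat alpha;        // T x B
  mat pooled;       // n3 x B
  mat pooled_drop;  // after dropout
  mat u1;           // (n3+C) x B head input
  mat a1;           // Hh x B
  mat a1_drop;
  rowvec y;         // 1 x B
};

static void lstm_layer_forward(const mat& W, const mat& U, const vec& b,
                               const cube& xin, const mat& active,
                               LayerCache& lc) {
  const uword n = U.n_cols, B = xin.n_cols, T = xin.n_slices;
  lc.ga.set_size(4 * n, B, T);
  lc.c.set_size(n, B, T);
  lc.tc.set_size(n, B, T);
  lc.h.set_size(n, B, T);
  // input projection for all steps in one GEMM
  const mat xall(const_cast<double*>(xin.memptr()), xin.n_rows, B * T,
                 false, true);
  mat ain = W * xall;
  ain.each_col() += b;
  mat h_prev(n, B, fill::zeros), c_prev(n, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat a = ain.cols(t * B, t * B + B - 1) + U * h_prev;
    mat gi = sigmoid(a.rows(0, n - 1));
    mat gf = sigmoid(a.rows(n, 2 * n - 1));
    mat gg = tanh(a.rows(2 * n, 3 * n - 1));
    mat go = sigmoid(a.rows(3 * n, 4 * n - 1));
    mat ct = gf % c_prev + gi % gg;
    mat tct = tanh(ct);
    mat ht = go % tct;
    rowvec m = active.row(t); // broadcast over rows
    ct = ct.each_row() % m + c_prev.each_row() % (1.0 - m);
    ht = ht.each_row() % m + h_prev.each_row() % (1.0 - m);
    tct = tanh(ct);
    lc.ga.slice(t) = join_cols(join_cols(gi, gf), join_cols(gg, go));
    lc.c.slice(t) = ct;
    lc.tc.slice(t) = tct;
    lc.h.slice(t) = ht;
    h_prev = ht;
    c_prev = ct;
  }
}

static ForwardCache forward_pass(const List& params, const List& xs,
                                 const mat& ctx, const mat& drop_p,
                                 const mat& drop_h, bool use_dropout) {
  const uword B = xs.size();
  uword T = 0, F = 0;
  std::vector<mat> xmats(B);
  std::vector<uword> tlen(B);
  for (uword j = 0; j < B; ++j) {
    xmats[j] = Rcpp::as<mat>(xs[j]); // F x T_j
    tlen[j] = xmats[j].n_cols;
    if (tlen[j] > T) T = tlen[j];
    F = xmats[j].n_rows;
  }
  if (T == 0) Rcpp::stop("all sequences are empty");

  ForwardCache fc;
  fc.x0.set_size(F, B, T);
  fc.x0.zeros();
  fc.active.set_size(T, B);
  fc.active.zeros();
  for (uword j = 0; j < B; ++j) {
    for (uword t = 0; t < tlen[j]; ++t) {
      fc.x0.slice(t).col(j) = xmats[j].col(t);
      fc.active(t, j) = 1.0;
    }
  }
  const mat W1 = params["W1"], U1 = params["U1"];
  const mat W2 = params["W2"], U2 = params["U2"];
  const mat W3 = params["W3"], U3 = params["U3"];
  const vec b1 = params["b1"], b2 = params["b2"], b3 = params["b3"];
  fc.layers.resize(3);
  // active mask indexed by row t inside layer forward: pass T x B
  lstm_layer_forward(W1, U1, b1, fc.x0, fc.active, fc.layers[0]);
  lstm_layer_forward(W2, U2, b2, fc.layers[0].h, fc.active, fc.layers[1]);
  lstm_layer_forward(W3, U3, b3, fc.layers[1].h, fc.active, fc.layers[2]);

  const mat Wh = params["Wh"], Wc = params["Wc"];
  const vec ba = params["ba"], va = params["va"];
  const uword A = Wh.n_rows, n3 = Wh.n_cols;
  const mat h3all(fc.layers[2].h.memptr(), n3, B * T, false, true);
  const mat wc_ctx = Wc * ctx; // A x B
  mat r_all = Wh * h3all;
  for (uword t = 0; t < T; ++t) r_all.cols(t * B, t * B + B - 1) += wc_ctx;
  r_all.each_col() += ba;
  mat q_mat = tanh(r_all);
  fc.q = cube(q_mat.memptr(), A, B, T);
  rowvec sv = va.t() * q_mat;
  fc.scores = reshape(mat(sv), B, T).t();
  // masked softmax over time, per column
  fc.alpha.set_size(T, B);
  for (uword j = 0; j < B; ++j) {
    vec s = fc.scores.col(j);
    double mx = -datum::inf;
    for (uword t = 0; t < tlen[j]; ++t) mx = std::max(mx, s(t));
    vec e(T, fill::zeros);
    double z = 0.0;
    for (uword t = 0; t < tlen[j]; ++t) { e(t) = std::exp(s(t) - mx); z += e(t); }
    fc.alpha.col(j) = e / z;
  }
  fc.pooled.set_size(n3, B);
  fc.pooled.zeros();
  for (uword t = 0; t < T; ++t) {
    fc.pooled += fc.layers[2].h.slice(t).each_row() % fc.alpha.row(t);
  }
  fc.pooled_drop = use_dropout ? mat(fc.pooled % drop_p) : fc.pooled;
  fc.u1 = join_cols(fc.pooled_drop, ctx);
  const mat W1h = params["W1h"], w2h = params["w2h"];
  const vec b1h = params["b1h"];
  const double b2h = Rcpp::as<double>(params["b2h"]);
  mat z1 = W1h * fc.u1;
  z1.each_col() += b1h;
  fc.a1 = tanh(z1);
  fc.a1_drop = use_dropout ? mat(fc.a1 % drop_h) : fc.a1;
  fc.y = w2h * fc.a1_drop + b2h;
  return fc;
}

// [[Rcpp::export]]
List cpp_model_forward(List params, List xs, arma::mat ctx,
                       bool return_attention = false) {
  mat empty;
  ForwardCache fc = forward_pass(params, xs, ctx, empty, empty, false);
  List out;
  out["y"] = Rcpp::NumericVector(fc.y.begin(), fc.y.end());
  if (return_attention) {
    List aw(xs.size());
    for (uword j = 0; j < (uword)xs.size(); ++j) {
      uword tj = Rcpp::as<mat>(xs[j]).n_cols;
      vec a = fc.alpha.col(j);
      aw[j] = Rcpp::NumericVector(a.begin(), a.begin() + tj);
    }
    out["attention"] = aw;
  }
  return out;
}

static void lstm_layer_backward(const mat& W, const mat& U,
                                const cube& xin, const mat& active,
                                const LayerCache& lc, const cube& dh_ext,
                                mat& gW, mat& gU, vec& gb, cube& dxin) {
  const uword n = U.n_cols, B = xin.n_cols, T = xin.n_slices;
  cube da_all(4 * n, B, T);
  mat dh_next(n, B, fill::zeros), dc_next(n, B, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    rowvec m = active.row(tt);
    mat dh = dh_ext.slice(tt) + dh_next;
    const mat& ga = lc.ga.slice(tt);
    mat gi = ga.rows(0, n - 1), gf = ga.rows(n, 2 * n - 1);
    mat gg = ga.rows(2 * n, 3 * n - 1), go = ga.rows(3 * n, 4 * n - 1);
    const mat& tct = lc.tc.slice(tt);
    mat c_prev = (tt == 0) ? mat(n, B, fill::zeros) : mat(lc.c.slice(tt - 1));
    mat do_ = dh % tct;
    mat dc = dc_next + dh % go % (1.0 - tct % tct);
    mat di = dc % gg, dg = dc % gi, df = dc % c_prev;
    mat da = join_cols(join_cols(di % gi % (1.0 - gi), df % gf % (1.0 - gf)),
                       join_cols(dg % (1.0 - gg % gg), do_ % go % (1.0 - go)));
    da = da.each_row() % m; // no gate gradients on frozen (padded) steps
    da_all.slice(tt) = da;
    dh_next = U.t() * da + dh.each_row() % (1.0 - m);
    mat dc_prev = dc % gf;
    dc_next = dc_prev.each_row() % m + dc_next.each_row() % (1.0 - m);
  }
  // weight-gradient contractions batched over all steps
  const mat xall(const_cast<double*>(xin.memptr()), xin.n_rows, B * T,
                 false, true);
  const mat da_mat(da_all.memptr(), 4 * n, B * T, false, true);
  gW = da_mat * xall.t();
  gb = sum(da_mat, 1);
  mat h_prev_all(n, B * T, fill::zeros);
  if (T > 1) {
    const mat hall(const_cast<double*>(lc.h.memptr()), n, B * T, false, true);
    h_prev_all.cols(B, B * T - 1) = hall.cols(0, B * (T - 1) - 1);
  }
  gU = da_mat * h_prev_all.t();
  mat dx_mat = W.t() * da_mat;
  dxin = cube(dx_mat.memptr(), xin.n_rows, B, T);
}

// [[Rcpp::export]]
List cpp_model_grad(List params, List xs, arma::mat ctx,
                    arma::vec targets, arma::mat drop_p, arma::mat drop_h,
                    bool use_dropout) {
  ForwardCache fc = forward_pass(params, xs, ctx, drop_p, drop_h, use_dropout);
  const uword B = xs.size(), T = fc.active.n_rows;
  const mat Wh = params["Wh"];
  const vec va = params["va"];
  const mat W1h = params["W1h"], w2h = params["w2h"];
  const uword n3 = Wh.n_cols, A = Wh.n_rows;

  rowvec err = fc.y - targets.t();
  double loss = accu(err % err) / B;
  rowvec dy = 2.0 * err / B;

  // head
  mat gw2h = dy * fc.a1_drop.t();      // 1 x Hh
  double gb2h = accu(dy);
  mat da1d = w2h.t() * dy;             // Hh x B
  mat da1 = use_dropout ? mat(da1d % drop_h) : da1d;
  mat dz1 = da1 % (1.0 - fc.a1 % fc.a1);
  mat gW1h = dz1 * fc.u1.t();
  vec gb1h = sum(dz1, 1);
  mat du1 = W1h.t() * dz1;
  mat dpd = du1.rows(0, n3 - 1);
  mat dpool = use_dropout ? mat(dpd % drop_p) : dpd;

  // attention
  mat dalpha(T, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    dalpha.row(t) = sum(dpool % fc.layers[2].h.slice(t), 0);
  }
  rowvec colsum = sum(fc.alpha % dalpha, 0);
  mat ds = fc.alpha % (dalpha.each_row() - colsum);
  rowvec dsv = vectorise(ds.t()).t();              // B*T, t-major blocks
  const mat q_mat(fc.q.memptr(), A, B * T, false, true);
  const mat h3all(fc.layers[2].h.memptr(), n3, B * T, false, true);
  mat dq_all = va * dsv;                           // A x B*T
  mat dr_all = dq_all % (1.0 - q_mat % q_mat);
  mat gWh = dr_all * h3all.t();
  mat gWc(A, ctx.n_rows, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    gWc += dr_all.cols(t * B, t * B + B - 1) * ctx.t();
  }
  vec gba = sum(dr_all, 1);
  vec gva = q_mat * dsv.t();
  mat dh3_mat = Wh.t() * dr_all;
  cube dh3(dh3_mat.memptr(), n3, B, T);
  for (uword t = 0; t < T; ++t) {
    dh3.slice(t) += dpool.each_row() % fc.alpha.row(t);
  }

  const mat W1 = params["W1"], U1 = params["U1"];
  const mat W2 = params["W2"], U2 = params["U2"];
  const mat W3 = params["W3"], U3 = params["U3"];
  mat gW3, gU3, gW2, gU2, gW1, gU1;
  vec gb3, gb2, gb1;
  cube dx3, dx2, dx1;
  lstm_layer_backward(W3, U3, fc.layers[1].h, fc.active, fc.layers[2], dh3,
                      gW3, gU3, gb3, dx3);
  lstm_layer_backward(W2, U2, fc.layers[0].h, fc.active, fc.layers[1], dx3,
                      gW2, gU2, gb2, dx2);
  lstm_layer_backward(W1, U1, fc.x0, fc.active, fc.layers[0], dx2,
                      gW1, gU1, gb1, dx1);

  List grads = List::create(
    Rcpp::Named("W1") = gW1, Rcpp::Named("U1") = gU1, Rcpp::Named("b1") = gb1,
    Rcpp::Named("W2") = gW2, Rcpp::Named("U2") = gU2, Rcpp::Named("b2") = gb2,
    Rcpp::Named("W3") = gW3, Rcpp::Named("U3") = gU3, Rcpp::Named("b3") = gb3,
    Rcpp::Named("Wh") = gWh, Rcpp::Named("Wc") = gWc,
    Rcpp::Named("ba") = gba, Rcpp::Named("va") = gva,
    Rcpp::Named("W1h") = gW1h, Rcpp::Named("b1h") = gb1h,
    Rcpp::Named("w2h") = gw2h, Rcpp::Named("b2h") = gb2h);
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("y") = Rcpp::NumericVector(fc.y.begin(), fc.y.end()),
                      Rcpp::Named("grads") = grads);
}
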