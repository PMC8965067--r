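// Core network: per-window bidirectional LSTM, global bidirectional LSTM over
// window summaries, self-attention annotation, penalties, squared-error loss,
// and the full analytic backward pass. All randomness (parameter init, window
// segmentation) lives on the R side; this file is deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static inline vec sigmoid_vec(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cell {
  mat W, U;  // W: 4u x in, U: 4u x u, gate order [i; f; g; o]
  vec b;     // 4u
  uword u() const { return U.n_cols; }
};

struct Params {
  Cell lf, lb, gf, gb;
  mat Ws1, Ws2;
  vec wout;
  double bout;
};

static Cell get_cell(const List& p, const char* w, const char* uu,
                     const char* b) {
  Cell c;
  c.W = Rcpp::as<mat>(p[w]);
  c.U = Rcpp::as<mat>(p[uu]);
  c.b = Rcpp::as<vec>(p[b]);
  return c;
}

static Params get_params(const List& p) {
  Params pp;
  pp.lf = get_cell(p, "Wlf", "Ulf", "blf");
  pp.lb = get_cell(p, "Wlb", "Ulb", "blb");
  pp.gf = get_cell(p, "Wgf", "Ugf", "bgf");
  pp.gb = get_cell(p, "Wgb", "Ugb", "bgb");
  pp.Ws1 = Rcpp::as<mat>(p["Ws1"]);
  pp.Ws2 = Rcpp::as<mat>(p["Ws2"]);
  pp.wout = Rcpp::as<vec>(p["wout"]);
  pp.bout = Rcpp::as<double>(p["bout"]);
  return pp;
}

struct SeqCache {
  mat X;                   // T x in, already in sweep order
  mat I, F, G, O, C, TC;   // gate activations / cell states, T x u
  mat Hs;                  // hidden states, T x u
};

static void lstm_forward(const mat& X, const Cell& cl, SeqCache& ca) {
  const uword T = X.n_rows, u = cl.u();
  ca.X = X;
  ca.I.set_size(T, u); ca.F.set_size(T, u); ca.G.set_size(T, u);
  ca.O.set_size(T, u); ca.C.set_size(T, u); ca.TC.set_size(T, u);
  ca.Hs.set_size(T, u);
  mat WX = cl.W * X.t();  // 4u x T, one GEMM for all input projections
  vec h(u, fill::zeros), c(u, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec z = WX.col(t) + cl.U * h + cl.b;
    vec i = sigmoid_vec(z.subvec(0, u - 1));
    vec f = sigmoid_vec(z.subvec(u, 2 * u - 1));
    vec g = tanh(z.subvec(2 * u, 3 * u - 1));
    vec o = sigmoid_vec(z.subvec(3 * u, 4 * u - 1));
    c = f % c + i % g;
    vec tc = tanh(c);
    h = o % tc;
    ca.I.row(t) = i.t(); ca.F.row(t) = f.t(); ca.G.row(t) = g.t();
    ca.O.row(t) = o.t(); ca.C.row(t) = c.t(); ca.TC.row(t) = tc.t();
    ca.Hs.row(t) = h.t();
  }
}

struct CellGrad {
  mat dW, dU;
  vec db;
  void init(const Cell& c) {
    dW.zeros(size(c.W));
    dU.zeros(size(c.U));
    db.zeros(c.b.n_elem);
  }
};

// Backward through one direction; dHout holds upstream gradients on every
// hidden state (rows aligned with the forward sweep). Returns dX.
static mat lstm_backward(const SeqCache& ca, const Cell& cl, const mat& dHout,
                         CellGrad& gr) {
  const uword T = ca.X.n_rows, u = cl.u();
  mat DZ(4 * u, T);
  vec dh_carry(u, fill::zeros), dc_carry(u, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    vec dh = dHout.row(tt).t() + dh_carry;
    vec i = ca.I.row(tt).t(), f = ca.F.row(tt).t(), g = ca.G.row(tt).t();
    vec o = ca.O.row(tt).t(), tc = ca.TC.row(tt).t();
    vec c_prev = (tt == 0) ? vec(u, fill::zeros) : vec(ca.C.row(tt - 1).t());
    vec do_ = dh % tc;
    vec dc = dc_carry + dh % o % (1.0 - tc % tc);
    vec di = dc % g, df = dc % c_prev, dg = dc % i;
    dc_carry = dc % f;
    vec dz(4 * u);
    dz.subvec(0, u - 1)         = di % i % (1.0 - i);
    dz.subvec(u, 2 * u - 1)     = df % f % (1.0 - f);
    dz.subvec(2 * u, 3 * u - 1) = dg % (1.0 - g % g);
    dz.subvec(3 * u, 4 * u - 1) = do_ % o % (1.0 - o);
    DZ.col(tt) = dz;
    dh_carry = cl.U.t() * dz;
  }
  mat Hprev(T, u, fill::zeros);
  if (T > 1) Hprev.rows(1, T - 1) = ca.Hs.rows(0, T - 2);
  gr.dW += DZ * ca.X;
  gr.dU += DZ * Hprev;
  gr.db += sum(DZ, 1);
  return (cl.W.t() * DZ).t();
}

// Sweep order over the k+2 rows of one encoded window. With state_first the
// overlap-state rows are consumed before the residue rows in each direction
// (prev-overlap state row k first on the forward sweep, next-overlap state
// row k+1 first on the backward sweep).
static uvec sweep_order(int k, bool state_first) {
  uvec ord(k + 2);
  if (state_first) {
    ord(0) = (uword)k;
    for (int j = 0; j < k; ++j) ord(j + 1) = (uword)j;
    ord(k + 1) = (uword)(k + 1);
  } else {
    for (int j = 0; j < k + 2; ++j) ord(j) = (uword)j;
  }
  return ord;
}

struct ForwardCache {
  std::vector<SeqCache> locF, locB;
  SeqCache gF, gB;
  mat M, H, Pre, Tnh;
  rowvec A, m;
  double logit = 0.0, prob = 0.0;
};

static void full_forward(const mat& X, int k, int n, const Params& pp,
                         bool state_first, ForwardCache& fc) {
  const int rows_per = k + 2;
  if ((int)X.n_rows != rows_per * n || X.n_cols != 22)
    Rcpp::stop("encoded input must be (k+2)*n rows by 22 channels");
  const uword u = pp.lf.u();
  uvec ordF = sweep_order(k, state_first);
  uvec ordB = reverse(ordF);
  fc.locF.resize(n); fc.locB.resize(n);
  fc.M.set_size(n, 2 * u);
  for (int w = 0; w < n; ++w) {
    mat blk = X.rows((uword)w * rows_per, (uword)(w + 1) * rows_per - 1);
    lstm_forward(blk.rows(ordF), pp.lf, fc.locF[w]);
    lstm_forward(blk.rows(ordB), pp.lb, fc.locB[w]);
    fc.M(w, span(0, u - 1))     = fc.locF[w].Hs.row(rows_per - 1);
    fc.M(w, span(u, 2 * u - 1)) = fc.locB[w].Hs.row(rows_per - 1);
  }
  lstm_forward(fc.M, pp.gf, fc.gF);
  lstm_forward(reverse(fc.M, 0), pp.gb, fc.gB);
  fc.H.set_size(n, 2 * u);
  for (int i = 0; i < n; ++i) {
    fc.H(i, span(0, u - 1))     = fc.gF.Hs.row(i);
    fc.H(i, span(u, 2 * u - 1)) = fc.gB.Hs.row((uword)(n - 1 - i));
  }
  fc.Pre = pp.Ws1 * fc.H.t();       // d_a x n
  fc.Tnh = tanh(fc.Pre);
  rowvec e = pp.Ws2 * fc.Tnh;       // 1 x n
  rowvec ex = exp(e - e.max());
  fc.A = ex / accu(ex);
  fc.m = fc.A * fc.H;               // 1 x 2u
  fc.logit = dot(fc.m.t(), pp.wout) + pp.bout;
  fc.prob = 1.0 / (1.0 + std::exp(-fc.logit));
}

static double penalty_value(const rowvec& A, const vec* S) {
  if (S == nullptr) {
    double s2 = accu(A % A);
    return (s2 - 1.0) * (s2 - 1.0);
  }
  rowvec d = S->t() - A;
  return accu(d % d);
}

// [[Rcpp::export]]
List cpp_forward(const arma::mat& X, int k, int n, List params,
                 bool state_first) {
  Params pp = get_params(params);
  ForwardCache fc;
  full_forward(X, k, n, pp, state_first, fc);
  return List::create(
      Rcpp::Named("prob") = fc.prob, Rcpp::Named("logit") = fc.logit,
      Rcpp::Named("A") = Rcpp::NumericVector(fc.A.begin(), fc.A.end()),
      Rcpp::Named("H") = fc.H, Rcpp::Named("M") = fc.M);
}

// [[Rcpp::export]]
arma::mat cpp_local_forward(const arma::mat& X, int k, int n, List params,
                            bool state_first) {
  const int rows_per = k + 2;
  if ((int)X.n_rows != rows_per * n || X.n_cols != 22)
    Rcpp::stop("encoded input must be (k+2)*n rows by 22 channels");
  Params pp = get_params(params);
  const uword u = pp.lf.u();
  uvec ordF = sweep_order(k, state_first);
  uvec ordB = reverse(ordF);
  mat M(n, 2 * u);
  SeqCache ca;
  for (int w = 0; w < n; ++w) {
    mat blk = X.rows((uword)w * rows_per, (uword)(w + 1) * rows_per - 1);
    lstm_forward(blk.rows(ordF), pp.lf, ca);
    M(w, span(0, u - 1)) = ca.Hs.row(rows_per - 1);
    lstm_forward(blk.rows(ordB), pp.lb, ca);
    M(w, span(u, 2 * u - 1)) = ca.Hs.row(rows_per - 1);
  }
  return M;
}

// [[Rcpp::export]]
arma::mat cpp_global_forward(const arma::mat& M, List params) {
  Params pp = get_params(params);
  const uword u = pp.gf.u(), n = M.n_rows;
  SeqCache cf, cb;
  lstm_forward(M, pp.gf, cf);
  lstm_forward(reverse(M, 0), pp.gb, cb);
  mat H(n, 2 * u);
  for (uword i = 0; i < n; ++i) {
    H(i, span(0, u - 1))     = cf.Hs.row(i);
    H(i, span(u, 2 * u - 1)) = cb.Hs.row(n - 1 - i);
  }
  return H;
}

struct GradSet {
  CellGrad lf, lb, gf, gb;
  mat dWs1, dWs2;
  vec dwout;
  double dbout = 0.0;
  void init(const Params& pp) {
    lf.init(pp.lf); lb.init(pp.lb); gf.init(pp.gf); gb.init(pp.gb);
    dWs1.zeros(size(pp.Ws1)); dWs2.zeros(size(pp.Ws2));
    dwout.zeros(pp.wout.n_elem); dbout = 0.0;
  }
};

// Accumulates one view's gradients into gr (which must be init()ed).
static void full_backward(const ForwardCache& fc, int k, int n,
                          const Params& pp, bool state_first, const vec* S,
                          double y, double alpha, GradSet& gr) {
  const uword u = pp.lf.u();

  // classification head
  double dlogit = -2.0 * (y - fc.prob) * fc.prob * (1.0 - fc.prob);
  gr.dwout += dlogit * fc.m.t();
  gr.dbout += dlogit;
  rowvec dm = dlogit * pp.wout.t();
  rowvec dA = dm * fc.H.t();
  mat dH = fc.A.t() * dm;

  // penalty
  if (S == nullptr) {
    double s2 = accu(fc.A % fc.A);
    dA += alpha * 4.0 * (s2 - 1.0) * fc.A;
  } else {
    dA += alpha * (-2.0) * (S->t() - fc.A);
  }

  // softmax + attention projections
  rowvec de = fc.A % (dA - accu(dA % fc.A));
  gr.dWs2 += de * fc.Tnh.t();
  mat dPre = (pp.Ws2.t() * de) % (1.0 - fc.Tnh % fc.Tnh);
  gr.dWs1 += dPre * fc.H;
  dH += dPre.t() * pp.Ws1;

  // global layer
  mat dHf = dH.cols(0, u - 1);
  mat dHb(n, u);
  for (int i = 0; i < n; ++i) dHb.row(i) = dH(n - 1 - i, span(u, 2 * u - 1));
  mat dM = lstm_backward(fc.gF, pp.gf, dHf, gr.gf);
  dM += reverse(lstm_backward(fc.gB, pp.gb, dHb, gr.gb), 0);

  // local layer (summary = final hidden state of each direction's sweep)
  const int T = k + 2;
  mat dOutF(T, u), dOutB(T, u);
  for (int w = 0; w < n; ++w) {
    dOutF.zeros(); dOutB.zeros();
    dOutF.row(T - 1) = dM(w, span(0, u - 1));
    dOutB.row(T - 1) = dM(w, span(u, 2 * u - 1));
    lstm_backward(fc.locF[w], pp.lf, dOutF, gr.lf);
    lstm_backward(fc.locB[w], pp.lb, dOutB, gr.lb);
  }
}

static List grads_to_list(const GradSet& gr) {
  return List::create(
      Rcpp::Named("Wlf") = gr.lf.dW, Rcpp::Named("Ulf") = gr.lf.dU,
      Rcpp::Named("blf") = gr.lf.db, Rcpp::Named("Wlb") = gr.lb.dW,
      Rcpp::Named("Ulb") = gr.lb.dU, Rcpp::Named("blb") = gr.lb.db,
      Rcpp::Named("Wgf") = gr.gf.dW, Rcpp::Named("Ugf") = gr.gf.dU,
      Rcpp::Named("bgf") = gr.gf.db, Rcpp::Named("Wgb") = gr.gb.dW,
      Rcpp::Named("Ugb") = gr.gb.dU, Rcpp::Named("bgb") = gr.gb.db,
      Rcpp::Named("Ws1") = gr.dWs1, Rcpp::Named("Ws2") = gr.dWs2,
      Rcpp::Named("wout") = gr.dwout, Rcpp::Named("bout") = gr.dbout);
}

// [[Rcpp::export]]
List cpp_loss_grad(const arma::mat& X, int k, int n, List params,
                   bool state_first, Rcpp::Nullable<Rcpp::NumericVector> S,
                   double y, double alpha, bool want_grad) {
  Params pp = get_params(params);
  ForwardCache fc;
  full_forward(X, k, n, pp, state_first, fc);
  vec Sv;
  const vec* Sp = nullptr;
  if (S.isNotNull()) {
    Sv = Rcpp::as<vec>(S.get());
    if ((int)Sv.n_elem != n)
      Rcpp::stop("position-score length must equal window count");
    Sp = &Sv;
  }
  double err = y - fc.prob;
  double loss = err * err + alpha * penalty_value(fc.A, Sp);
  List out = List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("prob") = fc.prob,
      Rcpp::Named("A") = Rcpp::NumericVector(fc.A.begin(), fc.A.end()));
  if (want_grad) {
    GradSet gr;
    gr.init(pp);
    full_backward(fc, k, n, pp, state_first, Sp, y, alpha, gr);
    out["grads"] = grads_to_list(gr);
  }
  return out;
}

// One call per minibatch: sums loss and gradients over the views. Each view
// is a list(X = stacked encoded windows, S = position scores or NULL, y = 0/1).
// [[Rcpp::export]]
List cpp_batch_loss_grad(List views, int k, int n, List params,
                         bool state_first, double alpha) {
  const int B = views.size();
  Params pp = get_params(params);
  GradSet tot;
  tot.init(pp);
  double loss = 0.0;
  Rcpp::NumericVector probs(B);
  for (int b = 0; b < B; ++b) {
    List v = views[b];
    mat X = Rcpp::as<mat>(v["X"]);
    double y = Rcpp::as<double>(v["y"]);
    vec Sv;
    const vec* Sp = nullptr;
    if (v.containsElementNamed("S")) {
      SEXP Ssexp = v["S"];
      if (!Rf_isNull(Ssexp)) {
        Sv = Rcpp::as<vec>(Ssexp);
        Sp = &Sv;
      }
    }
    ForwardCache fc;
    full_forward(X, k, n, pp, state_first, fc);
    double err = y - fc.prob;
    loss += err * err + alpha * penalty_value(fc.A, Sp);
    probs[b] = fc.prob;
    full_backward(fc, k, n, pp, state_first, Sp, y, alpha, tot);
  }
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("probs") = probs,
                      Rcpp::Named("grads") = grads_to_list(tot));
}

// Batched forward-only pass: returns per-view prob and argmax-attention
// window index (1-based, ties to the lowest index).
// [[Rcpp::export]]
List cpp_batch_forward(List views, int k, int n, List params,
                       bool state_first) {
  const int B = views.size();
  Params pp = get_params(params);
  Rcpp::NumericVector probs(B);
  Rcpp::IntegerVector best(B);
  for (int b = 0; b < B; ++b) {
    List v = views[b];
    mat X = Rcpp::as<mat>(v["X"]);
    ForwardCache fc;
    full_forward(X, k, n, pp, state_first, fc);
    probs[b] = fc.prob;
    best[b] = (int)fc.A.index_max() + 1;
  }
  return List::create(Rcpp::Named("probs") = probs,
                      Rcpp::Named("best") = best);
}
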