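// Single-layer LSTM for binary window classification.
//
// Architecture: LSTM over T timesteps, hidden states mean-pooled over
// time, linear + sigmoid head. Loss is class-weighted binary
// cross-entropy. Training is full-batch Adam; all randomness (parameter
// initialisation) comes from R, so results are reproducible under a
// fixed R seed.
//
// Shapes: X is an n x d x T cube (windows x features x timesteps).
// Gate order in the packed 4h dimension: input, forget, output, cell.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct LstmParams {
  mat Wx;   // d x 4h
  mat Wh;   // h x 4h
  rowvec b; // 4h
  vec v;    // h (output head)
  double c; // output bias
};

static LstmParams unpack(const Rcpp::List& par) {
  LstmParams p;
  p.Wx = Rcpp::as<mat>(par["Wx"]);
  p.Wh = Rcpp::as<mat>(par["Wh"]);
  p.b  = Rcpp::as<rowvec>(par["b"]);
  p.v  = Rcpp::as<vec>(par["v"]);
  p.c  = Rcpp::as<double>(par["c"]);
  return p;
}

struct ForwardCache {
  cube I, F, O, G, C, H, TanhC; // each n x h x T
  mat Hbar;                     // n x h
  vec p;                        // n
};

static void forward(const cube& X, const LstmParams& par, ForwardCache& fc) {
  const uword n = X.n_rows, T = X.n_slices;
  const uword h = par.Wh.n_rows;
  fc.I.set_size(n, h, T); fc.F.set_size(n, h, T); fc.O.set_size(n, h, T);
  fc.G.set_size(n, h, T); fc.C.set_size(n, h, T); fc.H.set_size(n, h, T);
  fc.TanhC.set_size(n, h, T);
  mat Hprev(n, h, fill::zeros), Cprev(n, h, fill::zeros);
  mat Hbar(n, h, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = X.slice(t) * par.Wx + Hprev * par.Wh;
    A.each_row() += par.b;
    mat i = sigmoid(A.cols(0, h - 1));
    mat f = sigmoid(A.cols(h, 2 * h - 1));
    mat o = sigmoid(A.cols(2 * h, 3 * h - 1));
    mat g = tanh(A.cols(3 * h, 4 * h - 1));
    mat C = f % Cprev + i % g;
    mat tc = tanh(C);
    mat H = o % tc;
    fc.I.slice(t) = i; fc.F.slice(t) = f; fc.O.slice(t) = o;
    fc.G.slice(t) = g; fc.C.slice(t) = C; fc.H.slice(t) = H;
    fc.TanhC.slice(t) = tc;
    Hbar += H;
    Hprev = H; Cprev = C;
  }
  fc.Hbar = Hbar / (double)T;
  vec z = fc.Hbar * par.v + par.c;
  fc.p = 1.0 / (1.0 + exp(-z));
}

static double wbce(const vec& p, const vec& y, const vec& w) {
  const double eps = 1e-12;
  vec l = -(y % log(p + eps) + (1 - y) % log(1 - p + eps));
  return dot(w, l) / accu(w);
}

// [[Rcpp::export]]
Rcpp::NumericVector lstm_predict_cpp(const arma::cube& X,
                                     const Rcpp::List& params) {
  LstmParams par = unpack(params);
  ForwardCache fc;
  forward(X, par, fc);
  return Rcpp::wrap(fc.p);
}

// [[Rcpp::export]]
double lstm_loss_cpp(const arma::cube& X, const arma::vec& y,
                     const arma::vec& w, const Rcpp::List& params) {
  LstmParams par = unpack(params);
  ForwardCache fc;
  forward(X, par, fc);
  return wbce(fc.p, y, w);
}

// [[Rcpp::export]]
Rcpp::List lstm_grad_cpp(const arma::cube& X, const arma::vec& y,
                         const arma::vec& w, const Rcpp::List& params) {
  LstmParams par = unpack(params);
  const uword n = X.n_rows, T = X.n_slices, h = par.Wh.n_rows;
  ForwardCache fc;
  forward(X, par, fc);
  double loss = wbce(fc.p, y, w);

  // head gradients
  vec dz = (w % (fc.p - y)) / accu(w);        // n
  vec dv = fc.Hbar.t() * dz;                  // h
  double dc = accu(dz);
  mat dHpool = (dz * par.v.t()) / (double)T;  // n x h, added at every t

  mat dWx(size(par.Wx), fill::zeros);
  mat dWh(size(par.Wh), fill::zeros);
  rowvec db(4 * h, fill::zeros);

  mat dHnext(n, h, fill::zeros), dCnext(n, h, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat dH = dHpool + dHnext;
    const mat& o = fc.O.slice(t); const mat& i = fc.I.slice(t);
    const mat& f = fc.F.slice(t); const mat& g = fc.G.slice(t);
    const mat& tc = fc.TanhC.slice(t);
    mat dO = dH % tc;
    mat dC = dCnext + dH % o % (1 - tc % tc);
    mat Cprev = (t == 0) ? mat(n, h, fill::zeros) : fc.C.slice(t - 1);
    mat Hprev = (t == 0) ? mat(n, h, fill::zeros) : fc.H.slice(t - 1);
    mat dI = dC % g;
    mat dF = dC % Cprev;
    mat dG = dC % i;
    dCnext = dC % f;
    mat dA(n, 4 * h);
    dA.cols(0, h - 1)         = dI % i % (1 - i);
    dA.cols(h, 2 * h - 1)     = dF % f % (1 - f);
    dA.cols(2 * h, 3 * h - 1) = dO % o % (1 - o);
    dA.cols(3 * h, 4 * h - 1) = dG % (1 - g % g);
    dWx += X.slice(t).t() * dA;
    dWh += Hprev.t() * dA;
    db  += sum(dA, 0);
    dHnext = dA * par.Wh.t();
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("Wx") = dWx, Rcpp::Named("Wh") = dWh,
    Rcpp::Named("b") = db, Rcpp::Named("v") = dv,
    Rcpp::Named("c") = dc);
}

// Full-batch Adam on the packed parameter set.
// [[Rcpp::export]]
Rcpp::List lstm_fit_cpp(const arma::cube& X, const arma::vec& y,
                        const arma::vec& w, const Rcpp::List& init,
                        const int epochs, const double lr) {
  LstmParams par = unpack(init);
  const uword h = par.Wh.n_rows;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  // flatten helpers
  auto nparam = par.Wx.n_elem + par.Wh.n_elem + par.b.n_elem +
                par.v.n_elem + 1;
  vec m(nparam, fill::zeros), v2(nparam, fill::zeros);
  std::vector<double> loss_hist;
  loss_hist.reserve(epochs);

  for (int e = 1; e <= epochs; ++e) {
    Rcpp::List par_list = Rcpp::List::create(
      Rcpp::Named("Wx") = par.Wx, Rcpp::Named("Wh") = par.Wh,
      Rcpp::Named("b") = par.b, Rcpp::Named("v") = par.v,
      Rcpp::Named("c") = par.c);
    Rcpp::List gr = lstm_grad_cpp(X, y, w, par_list);
    loss_hist.push_back(Rcpp::as<double>(gr["loss"]));

    vec g = join_cols(join_cols(vectorise(Rcpp::as<mat>(gr["Wx"])),
                                vectorise(Rcpp::as<mat>(gr["Wh"]))),
                      join_cols(vectorise(Rcpp::as<rowvec>(gr["b"]).t()),
                                join_cols(Rcpp::as<vec>(gr["v"]),
                                          vec{Rcpp::as<double>(gr["c"])})));
    m = b1 * m + (1 - b1) * g;
    v2 = b2 * v2 + (1 - b2) * (g % g);
    vec mhat = m / (1 - std::pow(b1, e));
    vec vhat = v2 / (1 - std::pow(b2, e));
    vec step = lr * mhat / (sqrt(vhat) + eps);

    uword off = 0;
    par.Wx -= reshape(step.subvec(off, off + par.Wx.n_elem - 1),
                      par.Wx.n_rows, par.Wx.n_cols);
    off += par.Wx.n_elem;
    par.Wh -= reshape(step.subvec(off, off + par.Wh.n_elem - 1),
                      par.Wh.n_rows, par.Wh.n_cols);
    off += par.Wh.n_elem;
    par.b -= step.subvec(off, off + par.b.n_elem - 1).t();
    off += par.b.n_elem;
    par.v -= step.subvec(off, off + par.v.n_elem - 1);
    off += par.v.n_elem;
    par.c -= step(off);
  }

  return Rcpp::List::create(
    Rcpp::Named("Wx") = par.Wx, Rcpp::Named("Wh") = par.Wh,
    Rcpp::Named("b") = par.b, Rcpp::Named("v") = par.v,
    Rcpp::Named("c") = par.c,
    Rcpp::Named("loss_history") = loss_hist);
}
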