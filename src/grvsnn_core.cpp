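// Compiled core of the gated residual variable selection network.
//
// Layout conventions (P features, H hidden units, T traits, N samples):
//   W1, b1, b2, b3, skip, gain, bias, red : P x H matrices (row j = feature j)
//   W2, W3   : P x (H*H) matrices, column (k-1)*H + l holds W[k, l] of feature j
//   red_b    : length-P vector (scalar score bias per feature)
//   Wout     : T x P output head, bout length-T
//
// Per sample, every feature runs through its own gated residual block
// (nonlinear ELU layer -> dropout -> linear unit and gate -> residual mix ->
// layer normalization -> scalar score); the variable selection block applies
// a softmax over the P scores and re-weights them before the linear
// multi-task head.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double LN_EPS = 1e-5;

struct Params {
  mat W1, b1, W2, b2, W3, b3, skip, gain, bias, red;
  vec red_b;
  mat Wout;
  vec bout;
  int P, H, T;
};

static Params unpack(const List& p) {
  Params q;
  q.W1 = Rcpp::as<mat>(p["W1"]);   q.b1 = Rcpp::as<mat>(p["b1"]);
  q.W2 = Rcpp::as<mat>(p["W2"]);   q.b2 = Rcpp::as<mat>(p["b2"]);
  q.W3 = Rcpp::as<mat>(p["W3"]);   q.b3 = Rcpp::as<mat>(p["b3"]);
  q.skip = Rcpp::as<mat>(p["skip"]); q.gain = Rcpp::as<mat>(p["gain"]);
  q.bias = Rcpp::as<mat>(p["bias"]); q.red = Rcpp::as<mat>(p["red"]);
  q.red_b = Rcpp::as<vec>(p["red_b"]);
  q.Wout = Rcpp::as<mat>(p["Wout"]); q.bout = Rcpp::as<vec>(p["bout"]);
  q.P = q.W1.n_rows; q.H = q.W1.n_cols; q.T = q.Wout.n_rows;
  return q;
}

// workspace of P x H matrices reused across samples
struct Work {
  mat A1, F1, F2, Hh, A3, G, GP, XS, Z, ZN, ZH;
  vec mu, sd, score;
  Work(int P, int H)
    : A1(P, H), F1(P, H), F2(P, H), Hh(P, H), A3(P, H), G(P, H), GP(P, H),
      XS(P, H), Z(P, H), ZN(P, H), ZH(P, H), mu(P), sd(P), score(P) {}
};

// forward pass for one sample; x is the length-P input row.
// mask: P x H dropout keep mask (already divided semantics handled by keep).
static void forward_sample(const Params& q, const rowvec& x, Work& w,
                           int gate_kind, double elu_gamma,
                           bool training, const mat* mask, double keep) {
  const int H = q.H;
  vec xc = x.t();
  // nonlinear layer: a1 = W1 * x + b1 (per feature, H units)
  w.A1 = q.W1.each_col() % xc;
  w.A1 += q.b1;
  // ELU
  w.F1 = w.A1;
  uvec neg = find(w.A1 <= 0);
  w.F1.elem(neg) = elu_gamma * (exp(w.A1.elem(neg)) - 1.0);
  // dropout (inverted scaling)
  if (training && mask != nullptr) {
    w.F2 = (w.F1 % (*mask)) / keep;
  } else {
    w.F2 = w.F1;
  }
  // linear unit h = W2 f2 + b2 and gate preactivation a3 = W3 f2 + b3
  w.Hh = q.b2;
  w.A3 = q.b3;
  for (int k = 0; k < H; ++k) {
    for (int l = 0; l < H; ++l) {
      const int kl = k * H + l;
      w.Hh.col(k) += q.W2.col(kl) % w.F2.col(l);
      w.A3.col(k) += q.W3.col(kl) % w.F2.col(l);
    }
  }
  // gate
  if (gate_kind == 0) {           // sigmoid
    w.G = 1.0 / (1.0 + exp(-w.A3));
    w.GP = w.G % (1.0 - w.G);
  } else {                        // hard sigmoid: clamp(0.2 a + 0.5, 0, 1)
    w.G = clamp(0.2 * w.A3 + 0.5, 0.0, 1.0);
    w.GP.zeros();
    w.GP.elem(find((w.A3 > -2.5) % (w.A3 < 2.5))).fill(0.2);
  }
  // skip projection of the scalar input to width H, residual mix
  w.XS = q.skip.each_col() % xc;
  w.Z = w.G % w.Hh + (1.0 - w.G) % w.XS;
  // layer normalization across the H hidden units of each feature
  w.mu = mean(w.Z, 1);
  w.sd = sqrt(mean(square(w.Z.each_col() - w.mu), 1) + LN_EPS);
  w.ZN = w.Z.each_col() - w.mu;
  w.ZN.each_col() /= w.sd;
  w.ZH = q.gain % w.ZN + q.bias;
  // scalar score per feature
  w.score = sum(q.red % w.ZH, 1) + q.red_b;
}

static vec softmax_vec(const vec& s) {
  vec e = exp(s - s.max());
  return e / accu(e);
}

// [[Rcpp::export(name = ".cpp_grvsnn_forward")]]
List cpp_grvsnn_forward(List params, const arma::mat& X, int gate_kind,
                        double elu_gamma, bool intermediates) {
  Params q = unpack(params);
  const int N = X.n_rows;
  if ((int)X.n_cols != q.P) Rcpp::stop("input has %d columns but model expects %d", (int)X.n_cols, q.P);
  Work w(q.P, q.H);
  mat Yhat(N, q.T), Wm(N, q.P), Sc(N, q.P), Zp(N, q.P);
  cube ZHc;
  if (intermediates) ZHc.set_size(q.P, q.H, N);
  for (int n = 0; n < N; ++n) {
    forward_sample(q, X.row(n), w, gate_kind, elu_gamma, false, nullptr, 1.0);
    vec sw = softmax_vec(w.score);
    vec zp = sw % w.score;
    // the head consumes P-scaled re-weighted features (so a feature at
    // uniform softmax weight contributes at unit order)
    Yhat.row(n) = (q.Wout * (q.P * zp) + q.bout).t();
    Wm.row(n) = sw.t();
    Sc.row(n) = w.score.t();
    Zp.row(n) = zp.t();
    if (intermediates) ZHc.slice(n) = w.ZH;
  }
  List out = List::create(Named("yhat") = Yhat, Named("weights") = Wm,
                          Named("scores") = Sc, Named("reweighted") = Zp);
  if (intermediates) out["zhat"] = ZHc;
  return out;
}

// [[Rcpp::export(name = ".cpp_grvsnn_loss_grad")]]
List cpp_grvsnn_loss_grad(List params, const arma::mat& X, const arma::mat& Y,
                          const arma::mat& Ymask, const arma::cube& dropmask,
                          double keep, int gate_kind, double elu_gamma,
                          bool training, double l2_gate) {
  Params q = unpack(params);
  const int N = X.n_rows, H = q.H, P = q.P;
  Work w(P, H);
  // gradient accumulators
  mat gW1(P, H, fill::zeros), gb1(P, H, fill::zeros),
      gW2(P, H * H, fill::zeros), gb2(P, H, fill::zeros),
      gW3(P, H * H, fill::zeros), gb3(P, H, fill::zeros),
      gskip(P, H, fill::zeros), ggain(P, H, fill::zeros),
      gbias(P, H, fill::zeros), gred(P, H, fill::zeros);
  vec gred_b(P, fill::zeros);
  mat gWout(q.T, P, fill::zeros);
  vec gbout(q.T, fill::zeros);

  const double nobs = accu(Ymask);
  if (nobs <= 0) Rcpp::stop("no observed phenotype entries");
  const double fac = 2.0 / nobs;
  double loss = 0.0;

  mat dZH(P, H), dZN(P, H), dZ(P, H), dG(P, H), dH(P, H), dXS(P, H),
      dA3(P, H), dF2(P, H), dF1(P, H), dA1(P, H), EP(P, H);

  for (int n = 0; n < N; ++n) {
    const mat* mask = training ? &dropmask.slice(n) : nullptr;
    forward_sample(q, X.row(n), w, gate_kind, elu_gamma, training, mask, keep);
    vec sw = softmax_vec(w.score);
    vec zp = sw % w.score;
    vec u = q.P * zp;   // P-scaled re-weighted features into the head
    vec yh = q.Wout * u + q.bout;
    vec e = (yh - Y.row(n).t()) % Ymask.row(n).t();
    loss += dot(e, e);
    vec dy = fac * e;
    gWout += dy * u.t();
    gbout += dy;
    vec dzp = q.P * (q.Wout.t() * dy);
    // softmax re-weighting backward: z' = w .* s, w = softmax(s)
    vec t = dzp % w.score % sw;
    vec ds = sw % dzp + t - sw * accu(t);
    // score -> layer-normalized block output
    dZH = q.red.each_col() % ds;
    gred += w.ZH.each_col() % ds;
    gred_b += ds;
    ggain += dZH % w.ZN;
    gbias += dZH;
    dZN = dZH % q.gain;
    // layer norm backward (per feature row, H units)
    vec m1 = mean(dZN, 1);
    vec m2 = mean(dZN % w.ZN, 1);
    dZ = dZN;
    dZ.each_col() -= m1;
    dZ -= w.ZN.each_col() % m2;
    dZ.each_col() /= w.sd;
    // residual mix backward
    dG = dZ % (w.Hh - w.XS);
    dH = dZ % w.G;
    dXS = dZ % (1.0 - w.G);
    vec xc = X.row(n).t();
    gskip += dXS.each_col() % xc;
    dA3 = dG % w.GP;
    dF2.zeros();
    for (int k = 0; k < H; ++k) {
      for (int l = 0; l < H; ++l) {
        const int kl = k * H + l;
        gW2.col(kl) += dH.col(k) % w.F2.col(l);
        gW3.col(kl) += dA3.col(k) % w.F2.col(l);
        dF2.col(l) += q.W2.col(kl) % dH.col(k) + q.W3.col(kl) % dA3.col(k);
      }
    }
    gb2 += dH;
    gb3 += dA3;
    if (training) {
      dF1 = (dF2 % (*mask)) / keep;
    } else {
      dF1 = dF2;
    }
    // ELU derivative: 1 where a1 > 0, else f1 + gamma
    EP.ones();
    uvec neg = find(w.A1 <= 0);
    EP.elem(neg) = w.F1.elem(neg) + elu_gamma;
    dA1 = dF1 % EP;
    gW1 += dA1.each_col() % xc;
    gb1 += dA1;
  }
  loss /= nobs;
  if (l2_gate > 0) {
    loss += l2_gate * (accu(square(q.W1)) + accu(square(q.W3)));
    gW1 += 2.0 * l2_gate * q.W1;
    gW3 += 2.0 * l2_gate * q.W3;
  }
  List grads = List::create(
      Named("W1") = gW1, Named("b1") = gb1, Named("W2") = gW2, Named("b2") = gb2,
      Named("W3") = gW3, Named("b3") = gb3, Named("skip") = gskip,
      Named("gain") = ggain, Named("bias") = gbias, Named("red") = gred,
      Named("red_b") = gred_b, Named("Wout") = gWout, Named("bout") = gbout);
  return List::create(Named("loss") = loss, Named("grads") = grads);
}
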