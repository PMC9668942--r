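// LSTM encoder-decoder core: forward pass, backpropagation through time,
// and one Adam training epoch over precomputed mini-batch indices.
//
// Layout conventions:
//   - a batch is an arma::cube with dimensions (cases, items, timesteps),
//     so X.slice(t) is the (B x d) matrix of item values at step t;
//   - gate blocks inside the concatenated LSTM weight matrices are ordered
//     [input, forget, output, candidate];
//   - all randomness (weight init, mini-batch order) happens on the R side,
//     this file is fully deterministic given its arguments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

static const int N_PAR = 18;
static const char* PAR_NAMES[N_PAR] = {
  "Wx1", "Wh1", "b1",      // encoder LSTM, d -> a
  "We",  "be",             // encoder dense (sigmoid), a -> f
  "Wx2", "Wh2", "b2",      // encoder LSTM, f -> k (latent)
  "Wx3", "Wh3", "b3",      // decoder LSTM, k -> f
  "Wd",  "bd",             // decoder dense (sigmoid), f -> a
  "Wx4", "Wh4", "b4",      // decoder LSTM, a -> d
  "Wo",  "bo"              // linear readout, d -> d
};

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static std::vector<mat> params_from_list(const List& params) {
  std::vector<mat> out(N_PAR);
  for (int i = 0; i < N_PAR; ++i) {
    if (!params.containsElementNamed(PAR_NAMES[i]))
      stop("parameter list is missing '%s'", PAR_NAMES[i]);
    out[i] = Rcpp::as<mat>(params[PAR_NAMES[i]]);
  }
  return out;
}

static List params_to_list(const std::vector<mat>& p) {
  List out(N_PAR);
  Rcpp::CharacterVector nm(N_PAR);
  for (int i = 0; i < N_PAR; ++i) {
    out[i] = p[i];
    nm[i] = PAR_NAMES[i];
  }
  out.attr("names") = nm;
  return out;
}

struct LSTMLayer {
  const mat *Wx, *Wh, *b;   // b is a 1 x 4H matrix
  int H() const { return Wh->n_rows; }
};

struct LSTMCache {
  std::vector<mat> X, I, F, O, G, C, H;
};

static void lstm_forward(const LSTMLayer& L, const std::vector<mat>& X,
                         LSTMCache& S) {
  const int T = X.size();
  const int B = X[0].n_rows;
  const int Hn = L.H();
  mat h(B, Hn, fill::zeros), c(B, Hn, fill::zeros);
  S.X = X;
  S.I.resize(T); S.F.resize(T); S.O.resize(T);
  S.G.resize(T); S.C.resize(T); S.H.resize(T);
  for (int t = 0; t < T; ++t) {
    mat A = X[t] * (*L.Wx) + h * (*L.Wh);
    A.each_row() += L.b->row(0);
    mat i = sigm(A.cols(0, Hn - 1));
    mat f = sigm(A.cols(Hn, 2 * Hn - 1));
    mat o = sigm(A.cols(2 * Hn, 3 * Hn - 1));
    mat g = tanh(A.cols(3 * Hn, 4 * Hn - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    S.I[t] = i; S.F[t] = f; S.O[t] = o;
    S.G[t] = g; S.C[t] = c; S.H[t] = h;
  }
}

struct LSTMGrad { mat Wx, Wh, b; };

// Backward pass; dHext[t] is the gradient flowing into h_t from layers above.
// Returns per-step gradients with respect to the layer inputs.
static std::vector<mat> lstm_backward(const LSTMLayer& L, const LSTMCache& S,
                                      const std::vector<mat>& dHext,
                                      LSTMGrad& g) {
  const int T = S.X.size();
  const int B = S.X[0].n_rows;
  const int Hn = L.H();
  g.Wx = zeros(size(*L.Wx));
  g.Wh = zeros(size(*L.Wh));
  g.b  = zeros(1, 4 * Hn);
  std::vector<mat> dX(T);
  mat dh(B, Hn, fill::zeros), dc(B, Hn, fill::zeros);
  const mat zB = zeros(B, Hn);
  for (int t = T - 1; t >= 0; --t) {
    dh += dHext[t];
    mat tc  = tanh(S.C[t]);
    mat do_ = dh % tc;
    mat dct = dc + dh % S.O[t] % (1.0 - square(tc));
    mat di  = dct % S.G[t];
    mat dg  = dct % S.I[t];
    const mat& cprev = (t > 0) ? S.C[t - 1] : zB;
    mat df  = dct % cprev;
    dc = dct % S.F[t];
    mat dA(B, 4 * Hn);
    dA.cols(0, Hn - 1)          = di  % S.I[t] % (1.0 - S.I[t]);
    dA.cols(Hn, 2 * Hn - 1)     = df  % S.F[t] % (1.0 - S.F[t]);
    dA.cols(2 * Hn, 3 * Hn - 1) = do_ % S.O[t] % (1.0 - S.O[t]);
    dA.cols(3 * Hn, 4 * Hn - 1) = dg  % (1.0 - square(S.G[t]));
    g.Wx += S.X[t].t() * dA;
    const mat& hprev = (t > 0) ? S.H[t - 1] : zB;
    g.Wh += hprev.t() * dA;
    g.b  += sum(dA, 0);
    dX[t] = dA * L.Wx->t();
    dh = dA * L.Wh->t();
  }
  return dX;
}

struct AEResult {
  double loss;
  mat z;                    // B x k latent points
  std::vector<mat> Y;       // reconstructed steps, each B x d
  vec per_case;             // per-case mean squared error
};

// Full forward pass; when grads != NULL also runs backpropagation and fills
// the gradient vector (same ordering as PAR_NAMES).
static AEResult ae_pass(const std::vector<mat>& p, const cube& X,
                        bool reverse_target, std::vector<mat>* grads) {
  const int B = X.n_rows;
  const int d = X.n_cols;
  const int T = X.n_slices;
  const mat& Wx1 = p[0],  &Wh1 = p[1],  &b1 = p[2];
  const mat& We  = p[3],  &be  = p[4];
  const mat& Wx2 = p[5],  &Wh2 = p[6],  &b2 = p[7];
  const mat& Wx3 = p[8],  &Wh3 = p[9],  &b3 = p[10];
  const mat& Wd  = p[11], &bd  = p[12];
  const mat& Wx4 = p[13], &Wh4 = p[14], &b4 = p[15];
  const mat& Wo  = p[16], &bo  = p[17];
  if ((int) Wx1.n_rows != d)
    stop("batch item dimension (%d) does not match model input_dim (%d)",
         d, (int) Wx1.n_rows);

  LSTMLayer L1 = {&Wx1, &Wh1, &b1};
  LSTMLayer L2 = {&Wx2, &Wh2, &b2};
  LSTMLayer L3 = {&Wx3, &Wh3, &b3};
  LSTMLayer L4 = {&Wx4, &Wh4, &b4};
  const int k = L2.H();

  std::vector<mat> Xs(T);
  for (int t = 0; t < T; ++t) Xs[t] = X.slice(t);

  // --- encoder ---
  LSTMCache c1;
  lstm_forward(L1, Xs, c1);
  std::vector<mat> E(T);
  for (int t = 0; t < T; ++t) {
    mat A = c1.H[t] * We;
    A.each_row() += be.row(0);
    E[t] = sigm(A);
  }
  LSTMCache c2;
  lstm_forward(L2, E, c2);
  mat z = c2.H[T - 1];                       // B x k bottleneck

  // --- decoder: latent repeated across all steps ---
  std::vector<mat> D(T, z);
  LSTMCache c3;
  lstm_forward(L3, D, c3);
  std::vector<mat> Gd(T);
  for (int t = 0; t < T; ++t) {
    mat A = c3.H[t] * Wd;
    A.each_row() += bd.row(0);
    Gd[t] = sigm(A);
  }
  LSTMCache c4;
  lstm_forward(L4, Gd, c4);

  AEResult res;
  res.z = z;
  res.Y.resize(T);
  res.per_case = zeros<vec>(B);
  const double denom = (double) B * T * d;
  std::vector<mat> dY(T);
  double loss = 0.0;
  for (int t = 0; t < T; ++t) {
    mat Y = c4.H[t] * Wo;
    Y.each_row() += bo.row(0);
    res.Y[t] = Y;
    const mat& R = reverse_target ? Xs[T - 1 - t] : Xs[t];
    mat diff = Y - R;
    res.per_case += sum(square(diff), 1);
    loss += accu(square(diff));
    if (grads) dY[t] = (2.0 / denom) * diff;
  }
  res.loss = loss / denom;
  res.per_case /= (double) T * d;
  if (!grads) return res;

  // --- backward ---
  std::vector<mat>& g = *grads;
  g.assign(N_PAR, mat());
  mat gWo = zeros(size(Wo));
  mat gbo = zeros(1, d);
  std::vector<mat> dH4(T);
  for (int t = 0; t < T; ++t) {
    gWo += c4.H[t].t() * dY[t];
    gbo += sum(dY[t], 0);
    dH4[t] = dY[t] * Wo.t();
  }
  LSTMGrad g4;
  std::vector<mat> dGd = lstm_backward(L4, c4, dH4, g4);
  mat gWd = zeros(size(Wd));
  mat gbd = zeros(1, Wd.n_cols);
  std::vector<mat> dH3(T);
  for (int t = 0; t < T; ++t) {
    mat dpre = dGd[t] % Gd[t] % (1.0 - Gd[t]);
    gWd += c3.H[t].t() * dpre;
    gbd += sum(dpre, 0);
    dH3[t] = dpre * Wd.t();
  }
  LSTMGrad g3;
  std::vector<mat> dD = lstm_backward(L3, c3, dH3, g3);
  mat dz = zeros(B, k);
  for (int t = 0; t < T; ++t) dz += dD[t];

  std::vector<mat> dH2(T, zeros(B, k));
  dH2[T - 1] = dz;
  LSTMGrad g2;
  std::vector<mat> dE = lstm_backward(L2, c2, dH2, g2);
  mat gWe = zeros(size(We));
  mat gbe = zeros(1, We.n_cols);
  std::vector<mat> dH1(T);
  for (int t = 0; t < T; ++t) {
    mat dpre = dE[t] % E[t] % (1.0 - E[t]);
    gWe += c1.H[t].t() * dpre;
    gbe += sum(dpre, 0);
    dH1[t] = dpre * We.t();
  }
  LSTMGrad g1;
  lstm_backward(L1, c1, dH1, g1);

  g[0] = g1.Wx; g[1] = g1.Wh; g[2] = g1.b;
  g[3] = gWe;   g[4] = gbe;
  g[5] = g2.Wx; g[6] = g2.Wh; g[7] = g2.b;
  g[8] = g3.Wx; g[9] = g3.Wh; g[10] = g3.b;
  g[11] = gWd;  g[12] = gbd;
  g[13] = g4.Wx; g[14] = g4.Wh; g[15] = g4.b;
  g[16] = gWo;  g[17] = gbo;
  return res;
}

// [[Rcpp::export]]
List ae_forward_cpp(List params, arma::cube X, bool reverse_target) {
  std::vector<mat> p = params_from_list(params);
  AEResult res = ae_pass(p, X, reverse_target, nullptr);
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  for (unsigned int t = 0; t < X.n_slices; ++t) Y.slice(t) = res.Y[t];
  return List::create(Named("loss") = res.loss,
                      Named("z") = res.z,
                      Named("per_case") = res.per_case,
                      Named("Y") = Y);
}

// [[Rcpp::export]]
List ae_grad_cpp(List params, arma::cube X, bool reverse_target) {
  std::vector<mat> p = params_from_list(params);
  std::vector<mat> g;
  AEResult res = ae_pass(p, X, reverse_target, &g);
  return List::create(Named("loss") = res.loss,
                      Named("grads") = params_to_list(g));
}

// One epoch of Adam updates. idx is a 1-based (iterations x batch_size)
// matrix of case indices prepared (and seeded) on the R side.
// [[Rcpp::export]]
List ae_train_epoch_cpp(List params, List m, List v, int step0,
                        arma::cube X, arma::umat idx, double lr,
                        double beta1, double beta2, double eps,
                        bool reverse_target) {
  std::vector<mat> p  = params_from_list(params);
  std::vector<mat> am = params_from_list(m);
  std::vector<mat> av = params_from_list(v);
  const int n_iter = idx.n_rows;
  int step = step0;
  double loss_sum = 0.0;
  for (int it = 0; it < n_iter; ++it) {
    uvec rows = idx.row(it).t() - 1;
    cube Xb(rows.n_elem, X.n_cols, X.n_slices);
    for (unsigned int t = 0; t < X.n_slices; ++t)
      Xb.slice(t) = X.slice(t).rows(rows);
    std::vector<mat> g;
    AEResult res = ae_pass(p, Xb, reverse_target, &g);
    loss_sum += res.loss;
    if (!std::isfinite(res.loss)) {
      return List::create(Named("params") = params_to_list(p),
                          Named("m") = params_to_list(am),
                          Named("v") = params_to_list(av),
                          Named("step") = step,
                          Named("loss") = res.loss);
    }
    ++step;
    const double bc1 = 1.0 - std::pow(beta1, step);
    const double bc2 = 1.0 - std::pow(beta2, step);
    for (int j = 0; j < N_PAR; ++j) {
      am[j] = beta1 * am[j] + (1.0 - beta1) * g[j];
      av[j] = beta2 * av[j] + (1.0 - beta2) * square(g[j]);
      p[j] -= lr * (am[j] / bc1) / (sqrt(av[j] / bc2) + eps);
    }
  }
  return List::create(Named("params") = params_to_list(p),
                      Named("m") = params_to_list(am),
                      Named("v") = params_to_list(av),
                      Named("step") = step,
                      Named("loss") = loss_sum / n_iter);
}
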