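// 1-D convolutional text classifier: embedding layer -> single convolution
// (n_filters x kernel_size, ReLU) -> global max pool -> dropout -> sigmoid.
// Trained with minibatch Adam or Adadelta, binary cross-entropy with
// per-class example weights, a max-norm constraint on each filter, and an
// optional L1 penalty on the output layer.  Single-threaded and seeded.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

static inline double sigm(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

struct AdamState {
  arma::mat m, v;
  AdamState(arma::uword r, arma::uword c)
    : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
};

static void adam_step(arma::mat& w, const arma::mat& g, AdamState& s,
                      double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  s.m = b1 * s.m + (1.0 - b1) * g;
  s.v = b2 * s.v + (1.0 - b2) * arma::square(g);
  double c1 = 1.0 - std::pow(b1, (double)t);
  double c2 = 1.0 - std::pow(b2, (double)t);
  w -= lr * (s.m / c1) / (arma::sqrt(s.v / c2) + eps);
}

struct AdadeltaState {
  arma::mat eg, ex;
  AdadeltaState(arma::uword r, arma::uword c)
    : eg(r, c, arma::fill::zeros), ex(r, c, arma::fill::zeros) {}
};

static void adadelta_step(arma::mat& w, const arma::mat& g, AdadeltaState& s,
                          double lr) {
  const double rho = 0.95, eps = 1e-6;
  s.eg = rho * s.eg + (1.0 - rho) * arma::square(g);
  arma::mat upd = arma::sqrt(s.ex + eps) / arma::sqrt(s.eg + eps) % g;
  s.ex = rho * s.ex + (1.0 - rho) * arma::square(upd);
  w -= lr * upd;
}

// forward pass for one sequence; returns pooled vector, argmax positions and
// the materialized window matrix (kd x P)
static void conv_forward(const arma::imat& seqs, int i, const arma::mat& E,
                         const arma::mat& Wc, const arma::vec& bc,
                         int kernel, arma::mat& Umat, arma::vec& pooled,
                         arma::ivec& poolpos) {
  const int L = seqs.n_cols, dim = E.n_cols, P = L - kernel + 1;
  const int kd = kernel * dim;
  arma::mat X(dim, L);
  for (int p = 0; p < L; ++p)
    X.col(p) = E.row(seqs(i, p)).t();   // row 0 is the padding vector
  Umat.set_size(kd, P);
  const double* xm = X.memptr();
  for (int p = 0; p < P; ++p)
    std::memcpy(Umat.colptr(p), xm + (size_t)p * dim, sizeof(double) * kd);
  arma::mat S = Wc.t() * Umat;            // F x P pre-activations
  S.each_col() += bc;
  S.transform([](double v) { return v > 0.0 ? v : 0.0; });  // ReLU
  const int F = Wc.n_cols;
  pooled.set_size(F);
  poolpos.set_size(F);
  for (int f = 0; f < F; ++f) {
    arma::uword idx;
    pooled(f) = S.row(f).max(idx);
    poolpos(f) = (int)idx;
  }
}

// [[Rcpp::export]]
List cpp_train_cnn(IntegerMatrix seqs_r, NumericVector y,
                   NumericMatrix emb0, int n_filters, int kernel,
                   double dropout, double lr, int batch_size, int n_epochs,
                   double maxnorm, double w_neg, double w_pos,
                   double l1_strength, bool train_embedding,
                   std::string optimizer, int seed) {
  const int n = seqs_r.nrow(), L = seqs_r.ncol();
  const int dim = emb0.ncol(), F = n_filters, kd = kernel * dim;
  if (L < kernel) stop("max_length shorter than kernel size");

  arma::imat seqs(n, L);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j) seqs(i, j) = seqs_r(i, j);

  arma::mat E(emb0.begin(), emb0.nrow(), dim);
  E.row(0).zeros();                      // padding/unknown row stays zero

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  std::normal_distribution<double> rnorm_(0.0, 1.0);

  // Glorot-uniform conv kernel, zero biases, Glorot output layer
  arma::mat Wc(kd, F), wo(F, 1);
  double lim_c = std::sqrt(6.0 / (kd + F));
  for (int a = 0; a < kd; ++a)
    for (int f = 0; f < F; ++f) Wc(a, f) = (2.0 * runif(rng) - 1.0) * lim_c;
  double lim_o = std::sqrt(6.0 / (F + 1));
  for (int f = 0; f < F; ++f) wo(f, 0) = (2.0 * runif(rng) - 1.0) * lim_o;
  arma::vec bc(F, arma::fill::zeros);
  arma::mat bo(1, 1, arma::fill::zeros);

  const bool use_adam = (optimizer != "adadelta");
  AdamState aWc(kd, F), abc(F, 1), awo(F, 1), abo(1, 1), aE(E.n_rows, dim);
  AdadeltaState dWc(kd, F), dbc(F, 1), dwo(F, 1), dbo(1, 1), dE(E.n_rows, dim);
  const double lr_eff = use_adam ? lr : 1.0;   // adadelta scales internally

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  arma::mat Umat;
  arma::vec pooled;
  arma::ivec poolpos;
  arma::mat gWc(kd, F), gE(E.n_rows, dim);
  arma::mat gbc(F, 1), gwo(F, 1), gbo(1, 1);
  const double keep = 1.0 - dropout, scale = keep > 0 ? 1.0 / keep : 0.0;
  long tstep = 0;

  for (int ep = 0; ep < n_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += batch_size) {
      int bend = std::min(start + batch_size, n);
      int bs = bend - start;
      gWc.zeros(); gbc.zeros(); gwo.zeros(); gbo.zeros();
      if (train_embedding) gE.zeros();
      for (int bi = start; bi < bend; ++bi) {
        int i = order[bi];
        conv_forward(seqs, i, E, Wc, bc, kernel, Umat, pooled, poolpos);
        arma::vec mask(F);
        for (int f = 0; f < F; ++f)
          mask(f) = (dropout > 0.0 && runif(rng) < dropout) ? 0.0 : scale;
        arma::vec pdrop = pooled % mask;
        double logit = arma::dot(wo.col(0), pdrop) + bo(0, 0);
        double prob = sigm(logit);
        double wclass = y[i] > 0.5 ? w_pos : w_neg;
        double delta = (prob - y[i]) * wclass;     // d loss / d logit
        gwo.col(0) += delta * pdrop;
        gbo(0, 0) += delta;
        for (int f = 0; f < F; ++f) {
          double gp = delta * wo(f, 0) * mask(f);
          if (gp == 0.0 || pooled(f) <= 0.0) continue;  // ReLU gate
          int p = poolpos(f);
          gWc.col(f) += gp * Umat.col(p);
          gbc(f, 0) += gp;
          if (train_embedding) {
            for (int kk = 0; kk < kernel; ++kk) {
              int tok = seqs(i, p + kk);
              if (tok == 0) continue;
              gE.row(tok) += gp * Wc.col(f).subvec(kk * dim, (kk + 1) * dim - 1).t();
            }
          }
        }
      }
      double inv = 1.0 / bs;
      gWc *= inv; gbc *= inv; gwo *= inv; gbo *= inv;
      if (l1_strength > 0.0) gwo += l1_strength * arma::sign(wo);
      ++tstep;
      if (use_adam) {
        adam_step(Wc, gWc, aWc, lr_eff, tstep);
        { arma::mat bcm(bc.memptr(), F, 1, false); adam_step(bcm, gbc, abc, lr_eff, tstep); }
        adam_step(wo, gwo, awo, lr_eff, tstep);
        adam_step(bo, gbo, abo, lr_eff, tstep);
        if (train_embedding) { gE *= inv; adam_step(E, gE, aE, lr_eff, tstep); }
      } else {
        adadelta_step(Wc, gWc, dWc, lr_eff);
        { arma::mat bcm(bc.memptr(), F, 1, false); adadelta_step(bcm, gbc, dbc, lr_eff); }
        adadelta_step(wo, gwo, dwo, lr_eff);
        adadelta_step(bo, gbo, dbo, lr_eff);
        if (train_embedding) { gE *= inv; adadelta_step(E, gE, dE, lr_eff); }
      }
      if (train_embedding) E.row(0).zeros();
      // max-norm constraint on each filter's kernel weights
      for (int f = 0; f < F; ++f) {
        double nrm = arma::norm(Wc.col(f), 2);
        if (nrm > maxnorm) Wc.col(f) *= maxnorm / nrm;
      }
    }
  }

  arma::rowvec fnorms(F);
  for (int f = 0; f < F; ++f) fnorms(f) = arma::norm(Wc.col(f), 2);

  return List::create(
    _["Wc"] = wrap(Wc), _["bc"] = wrap(arma::vec(bc)),
    _["wo"] = wrap(arma::vec(wo.col(0))), _["bo"] = bo(0, 0),
    _["embedding"] = wrap(E), _["filter_norms"] = wrap(fnorms));
}

// [[Rcpp::export]]
NumericVector cpp_predict_cnn(IntegerMatrix seqs_r, NumericMatrix emb,
                              NumericMatrix Wc_r, NumericVector bc_r,
                              NumericVector wo_r, double bo, int kernel) {
  const int n = seqs_r.nrow(), L = seqs_r.ncol();
  arma::mat E(emb.begin(), emb.nrow(), emb.ncol());
  arma::mat Wc(Wc_r.begin(), Wc_r.nrow(), Wc_r.ncol());
  arma::vec bc(bc_r.begin(), bc_r.size());
  arma::vec wo(wo_r.begin(), wo_r.size());
  arma::imat seqs(n, L);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j) seqs(i, j) = seqs_r(i, j);
  NumericVector out(n);
  arma::mat Umat; arma::vec pooled; arma::ivec poolpos;
  for (int i = 0; i < n; ++i) {
    conv_forward(seqs, i, E, Wc, bc, kernel, Umat, pooled, poolpos);
    out[i] = sigm(arma::dot(wo, pooled) + bo);
  }
  return out;
}
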