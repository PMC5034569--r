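// Fast path for the missing-data E-step: emission log-densities restricted
// to observed dimensions, scaled forward-backward per patient, and pooled
// expected sufficient statistics with conditional-Gaussian completion of the
// missing entries. Rows are grouped by missingness pattern so the
// per-pattern Cholesky factors and regression matrices are computed once per
// state. The R functions marginal_emission_loglik(), forward_backward() and
// e_step(engine = "r") implement the same contract and serve as the
// reference in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// [[Rcpp::export]]
Rcpp::List hmm_estep_core(const arma::mat& obs, const arma::imat& mask,
                          const arma::ivec& lens, const arma::vec& pi,
                          const arma::mat& A, const arma::mat& mu,
                          const arma::cube& sigma) {
  const uword N = obs.n_rows, d = obs.n_cols, K = pi.n_elem;
  const uword S = lens.n_elem;
  if (d > 31) Rcpp::stop("observation dimension too large for pattern keys");

  // group rows by missingness pattern (bitmask over observed dims)
  std::map<uint32_t, std::vector<uword>> groups;
  for (uword n = 0; n < N; ++n) {
    uint32_t key = 0;
    for (uword j = 0; j < d; ++j) if (mask(n, j)) key |= (1u << j);
    groups[key].push_back(n);
  }

  struct Pattern {
    uvec rows, o, m;
  };
  std::vector<Pattern> pats;
  pats.reserve(groups.size());
  for (auto& kv : groups) {
    Pattern p;
    p.rows = uvec(kv.second);
    std::vector<uword> o, m;
    for (uword j = 0; j < d; ++j)
      ((kv.first >> j) & 1u ? o : m).push_back(j);
    p.o = uvec(o);
    p.m = uvec(m);
    pats.push_back(std::move(p));
  }

  // emission log-densities, pattern by pattern
  mat logB(N, K, fill::zeros);
  for (const Pattern& p : pats) {
    const uword no = p.o.n_elem;
    if (no == 0) continue;          // unit emission factor
    mat Xo = obs.submat(p.rows, p.o);    // r x no
    for (uword k = 0; k < K; ++k) {
      mat Soo = sigma.slice(k).submat(p.o, p.o);
      mat R;
      if (!chol(R, Soo))
        Rcpp::stop("non-positive-definite observed-block covariance in "
                   "state %d", (int) (k + 1));
      const double logdet = 2.0 * accu(log(R.diag()));
      const vec muk = mu.row(k).t();
      const vec muo = muk.elem(p.o);
      mat D = Xo.each_row() - muo.t();
      // solve R^T Z^T = D^T
      mat Z = solve(trimatl(R.t()), D.t());
      vec q = sum(square(Z), 0).t();
      vec ll = -0.5 * (no * LOG2PI + logdet + q);
      for (uword r = 0; r < p.rows.n_elem; ++r)
        logB(p.rows(r), k) = ll(r);
    }
  }

  // scaled forward-backward per sequence
  mat gamma(N, K, fill::zeros);
  vec start_w(K, fill::zeros);
  mat trans_w(K, K, fill::zeros);
  double loglik = 0.0;
  uword off = 0;
  for (uword s = 0; s < S; ++s) {
    const uword T = (uword) lens(s);
    mat B(T, K);
    vec shift(T);
    for (uword t = 0; t < T; ++t) {
      shift(t) = logB.row(off + t).max();
      B.row(t) = exp(logB.row(off + t) - shift(t));
    }
    mat alpha(T, K);
    vec cvec(T);
    rowvec a = pi.t() % B.row(0);
    cvec(0) = accu(a);
    alpha.row(0) = a / cvec(0);
    for (uword t = 1; t < T; ++t) {
      a = (alpha.row(t - 1) * A) % B.row(t);
      cvec(t) = accu(a);
      alpha.row(t) = a / cvec(t);
    }
    mat beta(T, K, fill::ones);
    for (uword t = T - 1; t-- > 0;)
      beta.row(t) = (A * (B.row(t + 1) % beta.row(t + 1)).t()).t() /
                    cvec(t + 1);
    mat g = alpha % beta;
    g.each_col() /= sum(g, 1);
    gamma.rows(off, off + T - 1) = g;
    start_w += g.row(0).t();
    for (uword t = 0; t + 1 < T; ++t) {
      mat M = (alpha.row(t).t() * (B.row(t + 1) % beta.row(t + 1))) % A;
      trans_w += M / accu(M);
    }
    loglik += accu(log(cvec)) + accu(shift);
    off += T;
  }

  // pooled expected completed moments, pattern by pattern
  vec w = sum(gamma, 0).t();
  mat m1(K, d, fill::zeros);
  cube m2(d, d, K, fill::zeros);
  for (const Pattern& p : pats) {
    const uword no = p.o.n_elem, nm = p.m.n_elem, r = p.rows.n_elem;
    mat G = gamma.rows(p.rows);          // r x K
    vec gsum = sum(G, 0).t();
    if (nm == 0) {
      // fully observed: moments come straight from the data
      mat X = obs.rows(p.rows);
      for (uword k = 0; k < K; ++k) {
        m1.row(k) += G.col(k).t() * X;
        mat Xw = X.each_col() % sqrt(G.col(k));
        m2.slice(k) += Xw.t() * Xw;
      }
      continue;
    }
    mat Xo = (no > 0) ? obs.submat(p.rows, p.o) : mat(r, 0);
    for (uword k = 0; k < K; ++k) {
      const vec muk = mu.row(k).t();
      mat C(r, d);                       // conditional means per row
      mat ccov(d, d, fill::zeros);       // shared conditional covariance
      if (no == 0) {
        C = repmat(muk.t(), r, 1);
        ccov = sigma.slice(k);
      } else {
        const mat& Sk = sigma.slice(k);
        mat Soo = Sk.submat(p.o, p.o);
        mat Smo = Sk.submat(p.m, p.o);
        mat W;
        if (!solve(W, Soo, Smo.t(), solve_opts::likely_sympd))
          Rcpp::stop("singular observed block in state %d", (int) (k + 1));
        W = W.t();                       // nm x no
        const vec muo = muk.elem(p.o), mum = muk.elem(p.m);
        mat Do = Xo.each_row() - muo.t();
        mat Cm = Do * W.t();             // r x nm
        Cm.each_row() += mum.t();
        C.cols(p.o) = Xo;
        C.cols(p.m) = Cm;
        ccov.submat(p.m, p.m) = Sk.submat(p.m, p.m) - W * Smo.t();
      }
      m1.row(k) += G.col(k).t() * C;
      mat Cw = C.each_col() % sqrt(G.col(k));
      m2.slice(k) += Cw.t() * Cw + gsum(k) * ccov;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("gamma") = gamma,
    Rcpp::Named("start_w") = start_w,
    Rcpp::Named("trans_w") = trans_w,
    Rcpp::Named("w") = w,
    Rcpp::Named("m1") = m1,
    Rcpp::Named("m2") = m2);
}
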