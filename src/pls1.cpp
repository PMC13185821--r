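#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// PLS1 regression coefficients via the Krylov-space characterization:
// with centered predictors X and response y, the k-component PLS1
// coefficient vector is the least-squares solution restricted to the
// Krylov space span{s, Cs, ..., C^{k-1} s}, C = X'X, s = X'y. The basis is
// built by Lanczos iteration with full reorthogonalization (stable at the
// small component counts used here); on breakdown the last valid solution
// is carried forward (PLS has converged to the restricted OLS solution).

static mat krylov_basis(const mat& C, const vec& s, int K, int& k_eff) {
  const uword p = C.n_rows;
  K = std::min<int>(K, (int)p);
  mat V(p, K, fill::zeros);
  double ns = norm(s);
  if (ns < 1e-300) { k_eff = 0; return V; }
  V.col(0) = s / ns;
  k_eff = 1;
  for (int k = 1; k < K; ++k) {
    vec w = C * V.col(k - 1);
    for (int pass = 0; pass < 2; ++pass)
      for (int j = 0; j < k_eff; ++j)
        w -= dot(V.col(j), w) * V.col(j);
    double nw = norm(w);
    if (nw < 1e-10 * norm(C * V.col(0))) break;
    V.col(k) = w / nw;
    k_eff = k + 1;
  }
  return V;
}

// Coefficient vectors for components 1..Kmax (p x Kmax matrix).
// [[Rcpp::export(name = ".pls1_beta_all")]]
arma::mat pls1_beta_all(const arma::mat& C, const arma::vec& s, int Kmax) {
  const uword p = C.n_rows;
  mat B(p, (uword)Kmax, fill::zeros);
  int k_eff = 0;
  mat V = krylov_basis(C, s, Kmax, k_eff);
  if (k_eff == 0) return B;
  mat CV = C * V.cols(0, k_eff - 1);
  mat T = V.cols(0, k_eff - 1).t() * CV;
  vec g = V.cols(0, k_eff - 1).t() * s;
  vec beta_last(p, fill::zeros);
  for (int k = 1; k <= Kmax; ++k) {
    int kk = std::min(k, k_eff);
    vec a;
    bool ok = solve(a, symmatu(T.submat(0, 0, kk - 1, kk - 1)),
                    g.subvec(0, kk - 1), solve_opts::no_approx);
    if (ok) beta_last = V.cols(0, kk - 1) * a;
    B.col(k - 1) = beta_last;
  }
  return B;
}

// Batched solve: one coefficient vector per column of S at a fixed
// component count K, optionally thresholded to the `keep` largest
// absolute coefficients (keep <= 0 disables thresholding).
// [[Rcpp::export(name = ".pls1_beta_batch")]]
arma::mat pls1_beta_batch(const arma::mat& C, const arma::mat& S, int K,
                          int keep) {
  const uword p = C.n_rows, nb = S.n_cols;
  mat B(p, nb, fill::zeros);
  for (uword b = 0; b < nb; ++b) {
    mat Ball = pls1_beta_all(C, S.col(b), K);
    vec beta = Ball.col(K - 1);
    if (keep > 0 && (uword)keep < p) {
      uvec ord = sort_index(abs(beta), "descend");
      vec out(p, fill::zeros);
      for (int j = 0; j < keep; ++j) out(ord(j)) = beta(ord(j));
      beta = out;
    }
    B.col(b) = beta;
  }
  return B;
}
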