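#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update loop for orthogonal projective NMF.
//
// Minimizes ||X - W W' X||_F over W >= 0 using the update
//   W <- W o (X X' W) / (W (W' X X' W)),
// renormalizing W by its spectral norm after every step. Only the item
// Gram matrix XXt = X X' (M x M) is needed inside the loop, so cost per
// iteration is independent of the number of subjects: with L the symmetric
// square root of XXt, ||X - W W' X||_F = ||L - W W' L||_F, which is also
// how the objective is evaluated (residual form, no cancellation, accurate
// down to machine precision for exactly representable data).
//
// The heuristic multiplicative step carries no descent guarantee; a
// safeguard damps the elementwise multiplier by successive square roots
// whenever the full step would increase the objective, which keeps the
// recorded trace monotone. If no damped step decreases the objective the
// iterate is numerically stationary and the loop stops.
//
// Returns the final W (not yet column-normalized), the objective trace
// evaluated after each accepted update, the iteration count and a
// convergence flag (relative Frobenius change of W below tol, or
// stationarity).
// [[Rcpp::export(name = ".opnmf_engine")]]
Rcpp::List opnmf_engine(const arma::mat& XXt, const arma::mat& W0,
                        int max_iter, double tol, double eps) {
  mat W = W0;
  W /= norm(W, 2);

  // symmetric PSD square root of the Gram matrix
  vec lam;
  mat U;
  eig_sym(lam, U, symmatu(XXt));
  lam.transform([](double v) { return v > 0 ? std::sqrt(v) : 0.0; });
  mat L = U * diagmat(lam) * U.t();

  auto obj_of = [&](const mat& Wc) {
    return norm(L - Wc * (Wc.t() * L), "fro");
  };

  std::vector<double> trace;
  trace.reserve(std::min(max_iter, 4096));
  bool converged = false;
  int iter = 0;
  double obj = obj_of(W);
  const double slack = 1e-12 * obj;  // absolute monotonicity slack

  for (iter = 1; iter <= max_iter; ++iter) {
    mat XXtW  = XXt * W;              // M x r
    mat WtXXtW = W.t() * XXtW;        // r x r
    mat denom = W * WtXXtW;
    denom.transform([eps](double v) { return v + eps; });
    mat ratio = XXtW / denom;

    mat W_new;
    double obj_new = 0;
    bool accepted = false;
    for (int attempt = 0; attempt < 8; ++attempt) {
      W_new = W % ratio;
      double sn = norm(W_new, 2);
      if (sn > 0) W_new /= sn;
      obj_new = obj_of(W_new);
      if (obj_new <= obj + slack) { accepted = true; break; }
      ratio = sqrt(ratio);
    }
    if (!accepted) {             // numerically stationary
      trace.push_back(obj);
      converged = true;
      break;
    }

    double diff = norm(W_new - W, "fro") / (norm(W, "fro") + eps);
    trace.push_back(obj_new);
    W = W_new;
    obj = obj_new;
    if (diff < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("n_iter") = iter,
      Rcpp::Named("converged") = converged);
}
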