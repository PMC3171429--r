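// Variational EM core for Bayesian PCA imputation with ARD priors.
// Data points are gene rows (dimension = number of samples). Per
// iteration: posterior factor scores and missing-entry expectations for
// every gene given its observed samples, then MAP updates of the
// loadings (with the ARD ridge), the mean, the residual variance and
// the ARD precisions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List bpca_em(arma::mat Y,          // N genes x d samples, pre-filled
                   const arma::umat M,   // 1 = missing
                   arma::mat W,          // d x q initial loadings
                   arma::vec mu,         // d
                   double sigma2,
                   arma::vec alpha,      // q
                   double tol, int max_iter) {
  const uword N = Y.n_rows, d = Y.n_cols;
  uvec miss_idx = find(M);
  std::vector<uvec> miss_of, obs_of;
  uvec miss_rows = find(sum(M, 1) > 0);
  miss_of.reserve(miss_rows.n_elem);
  obs_of.reserve(miss_rows.n_elem);
  for (uword k = 0; k < miss_rows.n_elem; ++k) {
    miss_of.push_back(find(M.row(miss_rows(k)) == 1));
    obs_of.push_back(find(M.row(miss_rows(k)) == 0));
  }

  mat Z(W.n_cols, N, fill::zeros);
  bool converged = false;
  int iter = 0;
  double delta = 0.0;
  while (iter < max_iter) {
    ++iter;
    const uword q = W.n_cols;
    mat G = W.t() * W;
    mat Pf = eye(q, q) + G / sigma2;
    mat Yc = Y;
    Yc.each_row() -= mu.t();
    Z = solve(Pf, W.t() * Yc.t(), solve_opts::likely_sympd) / sigma2;
    mat covf = inv_sympd(Pf);
    mat covsum = double(N - miss_rows.n_elem) * covf;
    vec old_fill = Y.elem(miss_idx);
    for (uword k = 0; k < miss_rows.n_elem; ++k) {
      const uword i = miss_rows(k);
      const uvec &m = miss_of[k], &o = obs_of[k];
      mat Wm = W.rows(m);
      vec yo = Y.row(i).t();
      vec rhs = W.rows(o).t() * (yo(o) - mu(o));
      mat Pinv;
      if (2 * m.n_elem < q) {
        // Woodbury downdate of the complete-row posterior precision:
        // P = Pf - Wm'Wm / sigma2, so
        // Pinv = covf + covf Wm' (sigma2 I - Wm covf Wm')^{-1} Wm covf.
        mat WmC = Wm * covf;                               // m x q
        mat S = sigma2 * eye(m.n_elem, m.n_elem) - WmC * Wm.t();
        Pinv = covf + WmC.t() * solve(S, WmC);
      } else {
        mat P = Pf - (Wm.t() * Wm) / sigma2;
        Pinv = inv_sympd(P);
      }
      vec z = Pinv * rhs / sigma2;
      Z.col(i) = z;
      rowvec fillv = (Wm * z + mu(m)).t();
      for (uword t = 0; t < m.n_elem; ++t) Y(i, m(t)) = fillv(t);
      covsum += Pinv;
    }
    // M-step.
    mat Zt = Z.t();                       // N x q
    mat pred = Zt * W.t();                // N x d
    mu = mean(Y - pred, 0).t();
    Yc = Y;
    Yc.each_row() -= mu.t();
    mat Szz = Z * Zt + covsum;
    W = (Yc.t() * Zt) * inv(Szz + sigma2 * diagmat(alpha));
    G = W.t() * W;
    mat resid = Yc - Zt * W.t();
    sigma2 = (accu(resid % resid) + accu(G % covsum)) / double(N * d);
    if (sigma2 < 1e-12) sigma2 = 1e-12;
    vec norms = sum(W % W, 0).t();
    alpha = double(d) / (norms + 1e-10);

    // Drop factors the ARD prior has fully suppressed: once a loading
    // norm is 1e-8 of the largest, its contribution to any fill is far
    // below the convergence tolerance. Keeps later iterations cheap.
    uvec keep = find(norms >= 1e-8 * norms.max());
    if (keep.n_elem >= 1 && keep.n_elem < W.n_cols) {
      W = W.cols(keep);
      alpha = alpha(keep);
      Z = Z.rows(keep);
    }

    if (miss_idx.n_elem == 0) { converged = true; break; }
    vec new_fill = Y.elem(miss_idx);
    delta = std::sqrt(mean(square(new_fill - old_fill)));
    if (delta < tol) { converged = true; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("mu") = mu,
      Rcpp::Named("sigma2") = sigma2, Rcpp::Named("alpha") = alpha,
      Rcpp::Named("scores") = Z, Rcpp::Named("filled") = Y,
      Rcpp::Named("n_iter") = iter, Rcpp::Named("converged") = converged,
      Rcpp::Named("last_delta") = delta);
}
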