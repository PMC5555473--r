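#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-site Gibbs sampler for the Gaussian single-step marker effects
// model with fixed (known) variance components:
//
//   y = W beta + U eps + e,   e ~ N(0, I sigma2_e)
//
// W holds the dense effect columns (intercept, optional J covariate, and the
// marker covariates); `lambda_w` is the ridge penalty sigma2_e / sigma2_alpha
// per column (0 for unpenalised fixed effects).  `eps_map` gives, for each
// phenotype record, the 1-based index of the imputation residual of the
// (nongenotyped) individual it belongs to, or 0 for genotyped individuals.
// The prior on eps is N(0, Q^{-1} sigma2_g) with Q the nn-block of the
// inverse numerator relationship matrix, passed in CSC form (both triangles);
// lambda_g = sigma2_e / sigma2_g.
//
// All updates keep an adjusted residual vector e so that each full sweep is
// linear in the number of nonzeros.  Uses R's RNG (seed with set.seed()).
// [[Rcpp::export]]
List gibbs_ssbr_cpp(NumericVector y, NumericMatrix W, NumericVector lambda_w,
                    IntegerVector eps_map, int n_eps,
                    IntegerVector Qp, IntegerVector Qi, NumericVector Qx,
                    double lambda_g, double sigma2_e,
                    int n_iter, int burn_in, int n_batch) {
  int n = y.size(), k = W.ncol();
  if (n_iter <= burn_in) stop("chain_length must exceed burn_in");
  int n_keep = n_iter - burn_in;
  if (n_batch > n_keep) n_batch = n_keep;

  // rows of the phenotype vector attached to each imputation residual
  std::vector< std::vector<int> > eps_rows(n_eps);
  for (int r = 0; r < n; ++r)
    if (eps_map[r] > 0) eps_rows[eps_map[r] - 1].push_back(r);

  NumericVector xtx(k);
  for (int j = 0; j < k; ++j) {
    double s = 0;
    for (int r = 0; r < n; ++r) s += W(r, j) * W(r, j);
    xtx[j] = s;
  }
  NumericVector qdiag(n_eps);
  for (int c = 0; c < n_eps; ++c)
    for (int t = Qp[c]; t < Qp[c + 1]; ++t)
      if (Qi[t] == c) qdiag[c] = Qx[t];

  NumericVector beta(k), eps(n_eps), e = clone(y);
  NumericMatrix beta_chain(n_keep, k);
  NumericVector eps_mean(n_eps);
  NumericMatrix eps_batch(n_eps, n_batch);
  int batch_size = n_keep / n_batch;

  for (int it = 0; it < n_iter; ++it) {
    // effect columns (fixed effects + markers)
    for (int j = 0; j < k; ++j) {
      double old = beta[j];
      double num = 0;
      for (int r = 0; r < n; ++r) num += W(r, j) * e[r];
      num += xtx[j] * old;
      double prec = xtx[j] + lambda_w[j];
      if (prec <= 0) continue;
      double bnew = R::rnorm(num / prec, sqrt(sigma2_e / prec));
      double d = bnew - old;
      if (d != 0) for (int r = 0; r < n; ++r) e[r] -= W(r, j) * d;
      beta[j] = bnew;
    }
    // imputation residuals, coupled through Q
    for (int c = 0; c < n_eps; ++c) {
      double old = eps[c];
      double num = 0;
      int ni = (int) eps_rows[c].size();
      for (size_t u = 0; u < eps_rows[c].size(); ++u) num += e[eps_rows[c][u]];
      num += ni * old;
      double qdot = 0; // Q[c,] . eps  (symmetric: walk column c)
      for (int t = Qp[c]; t < Qp[c + 1]; ++t) qdot += Qx[t] * eps[Qi[t]];
      num -= lambda_g * (qdot - qdiag[c] * old);
      double prec = ni + lambda_g * qdiag[c];
      double enew = R::rnorm(num / prec, sqrt(sigma2_e / prec));
      double d = enew - old;
      if (d != 0)
        for (size_t u = 0; u < eps_rows[c].size(); ++u) e[eps_rows[c][u]] -= d;
      eps[c] = enew;
    }
    if (it >= burn_in) {
      int kept = it - burn_in;
      for (int j = 0; j < k; ++j) beta_chain(kept, j) = beta[j];
      int b = kept / batch_size; if (b >= n_batch) b = n_batch - 1;
      for (int c = 0; c < n_eps; ++c) {
        eps_mean[c] += eps[c];
        eps_batch(c, b) += eps[c];
      }
    }
  }
  for (int c = 0; c < n_eps; ++c) eps_mean[c] /= n_keep;
  // last batch may be longer when n_keep % n_batch != 0
  for (int b = 0; b < n_batch; ++b) {
    int len = (b == n_batch - 1) ? (n_keep - batch_size * (n_batch - 1)) : batch_size;
    for (int c = 0; c < n_eps; ++c) eps_batch(c, b) /= len;
  }
  return List::create(_["beta_chain"] = beta_chain,
                      _["eps_mean"] = eps_mean,
                      _["eps_batch_means"] = eps_batch);
}
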