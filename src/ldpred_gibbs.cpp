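#include <Rcpp.h>
using namespace Rcpp;

// One LD block's point-normal Gibbs chain. Consumes R's RNG in exactly the
// same order as the reference R implementation (one uniform per variant
// visit, one normal draw only when the variant is included), so chains are
// identical seed-for-seed across the two engines.
// [[Rcpp::export]]
NumericVector gibbs_block_cpp(const NumericMatrix& R_ld,
                              const NumericVector& beta_hat,
                              const NumericVector& se2,
                              double s2, double p,
                              int n_iter, int burn_in, double w_bound) {
  const int m = R_ld.nrow();
  NumericVector w(m), Dw(m), acc(m);
  const double log_prior_odds = (p < 1.0) ? std::log(p) - std::log1p(-p) : 0.0;
  RNGScope scope;
  for (int sweep = 1; sweep <= n_iter; ++sweep) {
    for (int j = 0; j < m; ++j) {
      const double r_j = beta_hat[j] - (Dw[j] - R_ld(j, j) * w[j]);
      const double v1 = s2 + se2[j];
      const double post_var = s2 * se2[j] / v1;
      const double post_mean = r_j * s2 / v1;
      double pip;
      if (p >= 1.0) {
        pip = 1.0;
      } else {
        const double lo = log_prior_odds
          + R::dnorm(r_j, 0.0, std::sqrt(v1), 1)
          - R::dnorm(r_j, 0.0, std::sqrt(se2[j]), 1);
        pip = 1.0 / (1.0 + std::exp(-lo));
      }
      const double u = unif_rand();
      double w_new = 0.0;
      if (u < pip) {
        w_new = post_mean + std::sqrt(post_var) * norm_rand();
      }
      if (std::abs(w_new) > w_bound) {
        stop("Gibbs divergence: |weight| %g exceeds bound %g",
             std::abs(w_new), w_bound);
      }
      if (w_new != w[j]) {
        const double delta = w_new - w[j];
        for (int k = 0; k < m; ++k) Dw[k] += R_ld(k, j) * delta;
        w[j] = w_new;
      }
      if (sweep > burn_in) acc[j] += pip * post_mean;
    }
  }
  const double denom = n_iter - burn_in;
  for (int j = 0; j < m; ++j) acc[j] /= denom;
  return acc;
}

// AR(1) latent-Gaussian haplotype threshold sampler: two haplotypes per
// individual, allele carried when the latent value is below qnorm(maf),
// dosage = sum. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
IntegerMatrix draw_dosages_cpp(int n, const NumericVector& thr,
                               const IntegerVector& block, double rho) {
  const int m = thr.size();
  IntegerMatrix dos(n, m);
  const double a = std::sqrt(1.0 - rho * rho);
  std::vector<double> z(n), zprev(n);
  RNGScope scope;
  for (int h = 0; h < 2; ++h) {
    int prev_block = -1;
    for (int j = 0; j < m; ++j) {
      const bool cont = (block[j] == prev_block);
      for (int i = 0; i < n; ++i) {
        const double e = norm_rand();
        const double zi = cont ? rho * zprev[i] + a * e : e;
        z[i] = zi;
        if (zi < thr[j]) dos(i, j) += 1;
      }
      std::swap(z, zprev);
      prev_block = block[j];
    }
  }
  return dos;
}
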