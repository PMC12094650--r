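#' LDpred-inf posterior mean effect sizes
#'
#' Closed-form posterior means under the infinitesimal model: per LD block,
#' solves `(D + (M / (N h2)) I) w = beta_hat` on the standardized-genotype
#' scale. With an identity LD matrix this reduces to shrinking each marginal
#' estimate by `1 / (1 + M/(N h2))`.
#'
#' @param sumstats aligned summary statistics (data.frame with `beta`, `se`,
#'   `n` in the LD matrix's variant order).
#' @param ld an `ld_matrix`.
#' @param h2 assumed SNP heritability (> 0), e.g. from [ldsc_h2()].
#' @param M effective variant count; defaults to the number of variants.
#' @param N GWAS sample size; defaults to the median of `sumstats$n`.
#' @return an object of class `prs_weights`: list with `weights`, `ids`,
#'   `method = "inf"` and the hyperparameters used.
#' @export
ldpred_inf_weights <- function(sumstats, ld, h2, M = NULL, N = NULL) {
  check_ld_alignment(sumstats, ld)
  if (h2 <= 0) stop("`h2` must be positive")
  M <- M %||% nrow(sumstats)
  N <- N %||% stats::median(sumstats$n)
  if (N <= 0) stop("`N` must be positive")
  lam <- M / (N * h2)
  w <- numeric(nrow(sumstats))
  offset <- 0L
  for (R in ld$blocks) {
    m <- nrow(R)
    idx <- offset + seq_len(m)
    A <- R + diag(lam, m)
    sol <- tryCatch(solve(A, sumstats$beta[idx]),
                    error = function(e) stop("singular LD system in block: ",
                                             conditionMessage(e)))
    w[idx] <- sol
    offset <- offset + m
  }
  new_prs_weights(w, sumstats$snp, method = "inf",
                  h2 = h2, p = 1, M = M, N = N)
}

#' Point-normal (spike-and-slab) Gibbs posterior mean effect sizes
#'
#' The LDpred MCMC reweighting: each variant's standardized effect has prior
#' `N(0, h2/(M p))` with probability `p` and a point mass at zero otherwise.
#' Per sweep, each variant in turn is sampled from its conditional posterior
#' given the residualized marginal estimate
#' `r_j = beta_hat_j - sum_{k != j} D_jk w_k`: inclusion with probability
#' given by the point-normal posterior odds, and, if included, a normal draw
#' with mean `r_j s2/(s2 + se_j^2)` and variance `s2 se_j^2/(s2 + se_j^2)`
#' where `s2 = h2/(M p)`. The returned weight is the Rao-Blackwellized
#' posterior mean (inclusion probability times conditional mean) averaged
#' over post-burn-in sweeps. At `p = 1` the chain's mean converges to the
#' LDpred-inf solution.
#'
#' @inheritParams ldpred_inf_weights
#' @param p causal fraction in (0, 1].
#' @param n_iter total Gibbs sweeps (default 500).
#' @param burn_in sweeps discarded (default 100); must be < `n_iter`.
#' @param seed RNG seed; the chain is reproducible given the seed.
#' @param w_bound divergence guard: error if any sampled weight exceeds this
#'   magnitude.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both consume R's RNG in the same order and give
#'   identical chains for the same seed.
#' @return a `prs_weights` object with `method = "gibbs"`.
#' @export
ldpred_gibbs_weights <- function(sumstats, ld, h2, p,
                                 n_iter = 500L, burn_in = 100L, seed = 1L,
                                 M = NULL, N = NULL, w_bound = 5,
                                 engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_ld_alignment(sumstats, ld)
  if (h2 <= 0) stop("`h2` must be positive")
  if (p <= 0 || p > 1) stop("`p` must lie in (0, 1]")
  if (burn_in < 0 || n_iter <= burn_in) stop("need n_iter > burn_in >= 0")
  M <- M %||% nrow(sumstats)
  N <- N %||% stats::median(sumstats$n)
  s2 <- h2 / (M * p)
  w <- with_seed(seed, {
    acc <- numeric(nrow(sumstats))
    offset <- 0L
    for (R in ld$blocks) {
      m <- nrow(R)
      idx <- offset + seq_len(m)
      acc[idx] <- if (engine == "cpp") {
        gibbs_block_cpp(R, sumstats$beta[idx], sumstats$se[idx]^2,
                        s2, p, as.integer(n_iter), as.integer(burn_in),
                        w_bound)
      } else {
        gibbs_block_r(R, sumstats$beta[idx], sumstats$se[idx]^2,
                      s2, p, n_iter, burn_in, w_bound)
      }
      offset <- offset + m
    }
    acc
  })
  new_prs_weights(w, sumstats$snp, method = "gibbs",
                  h2 = h2, p = p, M = M, N = N,
                  n_iter = n_iter, burn_in = burn_in, seed = seed)
}

# Reference R implementation of one block's Gibbs chain. Draw order per
# variant: one uniform (inclusion), then one normal only if included —
# mirrored exactly by the C++ engine.
gibbs_block_r <- function(R, beta_hat, se2, s2, p, n_iter, burn_in, w_bound) {
  m <- nrow(R)
  w <- numeric(m)
  Dw <- numeric(m)
  acc <- numeric(m)
  log_prior_odds <- log(p) - log1p(-p + (p == 1))  # +Inf guard unused at p=1
  for (sweep in seq_len(n_iter)) {
    for (j in seq_len(m)) {
      r_j <- beta_hat[j] - (Dw[j] - R[j, j] * w[j])
      v1 <- s2 + se2[j]
      post_var <- s2 * se2[j] / v1
      post_mean <- r_j * s2 / v1
      if (p >= 1) {
        pip <- 1
      } else {
        lo <- log_prior_odds +
          stats::dnorm(r_j, 0, sqrt(v1), log = TRUE) -
          stats::dnorm(r_j, 0, sqrt(se2[j]), log = TRUE)
        pip <- 1 / (1 + exp(-lo))
      }
      u <- stats::runif(1)
      w_new <- if (u < pip) stats::rnorm(1, post_mean, sqrt(post_var)) else 0
      if (abs(w_new) > w_bound) {
        stop(sprintf("Gibbs divergence: |weight| %.3g exceeds bound %.3g",
                     abs(w_new), w_bound))
      }
      if (w_new != w[j]) {
        Dw <- Dw + R[, j] * (w_new - w[j])
        w[j] <- w_new
      }
      if (sweep > burn_in) acc[j] <- acc[j] + pip * post_mean
    }
  }
  acc / (n_iter - burn_in)
}

new_prs_weights <- function(weights, ids, method, h2, p, M, N,
                            n_iter = NA_integer_, burn_in = NA_integer_,
                            seed = NA_integer_) {
  if (any(!is.finite(weights))) stop("non-finite posterior weights")
  structure(
    list(weights = as.numeric(weights), ids = ids, method = method,
         h2 = h2, p = p, M = M, N = N,
         n_iter = n_iter, burn_in = burn_in, seed = seed),
    class = "prs_weights"
  )
}

#' @export
print.prs_weights <- function(x, ...) {
  cat(sprintf("PRS weights (%s): %d variants, p = %g, h2 = %.3f\n",
              x$method, length(x$weights), x$p, x$h2))
  invisible(x)
}

check_ld_alignment <- function(sumstats, ld) {
  if (!inherits(ld, "ld_matrix")) stop("`ld` must be an ld_matrix")
  if (nrow(sumstats) != length(ld$ids)) {
    stop("sumstats and LD matrix cover different variant counts; align first")
  }
  if (!identical(as.character(sumstats$snp), as.character(ld$ids))) {
    stop("sumstats variant order does not match the LD matrix")
  }
  if (any(sumstats$se <= 0)) stop("standard errors must be strictly positive")
  invisible(TRUE)
}
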