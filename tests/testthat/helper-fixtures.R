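# Shared fixtures, built in code at load time.

# Wrap per-block correlation matrices into an ld_matrix object.
make_ld <- function(blocks, n = 1000L) {
  if (is.matrix(blocks)) blocks <- list(blocks)
  ids <- unlist(lapply(seq_along(blocks), function(b) {
    paste0("snp_", b, "_", seq_len(nrow(blocks[[b]])))
  }))
  structure(
    list(blocks = blocks,
         block_index = rep(seq_along(blocks),
                           vapply(blocks, nrow, integer(1))),
         ids = ids, n = n, lambda = 0),
    class = "ld_matrix"
  )
}

# Minimal sumstats data.frame matching an ld_matrix.
make_sumstats <- function(beta, se = NULL, N = 10000, ld = NULL) {
  m <- length(beta)
  ids <- if (!is.null(ld)) ld$ids else sprintf("snp_%05d", seq_len(m))
  data.frame(snp = ids, a1 = "A", a2 = "G", beta = beta,
             se = se %||% rep(1 / sqrt(N), m), n = N,
             freq = 0.3, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small simulated world reused by several PRS tests.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(master_seed = 42, M = 200, n_ref = 400,
                        block_size = 20, n_case = 120, n_control = 80,
                        K = 0.05, h2 = 0.4, p_causal = 0.1)
      panel <- simulate_panel(cfg)
      ss <- simulate_sumstats(panel, cfg)
      cohort <- simulate_cohort(panel, ss, cfg)
      cache <<- list(cfg = cfg, panel = panel, ss = ss, cohort = cohort)
    }
    cache
  }
})

# A fake converged logistic model_fit with given coefficients/covariance,
# for formula-level tests of downstream metrics.
fake_fit <- function(coef, vcov, loglik = -50, null_loglik = -60, n = 100) {
  geiprs:::new_model_fit(coef, vcov, loglik, null_loglik, n,
                         family = "binomial")
}
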