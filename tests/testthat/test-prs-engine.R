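test_that("allele alignment flips, drops and reports correctly", {
  w <- small_world()
  ss <- w$ss$sumstats
  # identity coding passes through unchanged
  al <- align_alleles(ss, w$panel)
  expect_equal(al$sumstats$beta, ss$beta)
  expect_identical(al$report$n_flipped, 0L)
  # swapped alleles for one variant: beta negated, freq complemented
  ss2 <- ss
  ss2$a1[3] <- "G"; ss2$a2[3] <- "A"
  al2 <- align_alleles(ss2, w$panel)
  expect_equal(al2$sumstats$beta[3], -ss$beta[3])
  expect_equal(al2$sumstats$freq[3], 1 - ss$freq[3])
  expect_identical(al2$report$n_flipped, 1L)
  # mismatched allele pair dropped with count 1
  ss3 <- ss
  ss3$a1[5] <- "C"
  al3 <- align_alleles(ss3, w$panel)
  expect_identical(al3$report$n_dropped_mismatch, 1L)
  expect_identical(nrow(al3$sumstats), nrow(ss) - 1L)
  # strand-ambiguous pair dropped only under the flag
  ss4 <- ss
  ss4$a1[7] <- "C"; ss4$a2[7] <- "G"
  expect_identical(align_alleles(ss4, w$panel)$report$n_dropped_ambiguous, 0L)
  expect_identical(align_alleles(ss4, w$panel, drop_ambiguous = TRUE)$report$n_dropped_ambiguous, 1L)
  # zero overlap
  ss5 <- ss
  ss5$snp <- paste0("other_", ss5$snp)
  expect_error(align_alleles(ss5, w$panel), "no overlapping")
})

test_that("LD estimation matches the Pearson formula and flags degeneracy", {
  # hand-written 5 x 3 dosage matrix against a from-scratch Pearson oracle
  X <- matrix(c(0, 1, 2, 1, 0,
                2, 2, 1, 0, 1,
                1, 0, 0, 2, 2), ncol = 3)
  panel <- structure(list(
    dosage = X,
    variants = data.frame(id = c("v1", "v2", "v3"), block = c(1L, 1L, 1L),
                          a1 = "A", a2 = "G", freq = 0.5)),
    class = "genotype_panel")
  ld <- estimate_ld(panel, lambda = 0)
  pearson <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(ld$blocks[[1]][i, j], pearson(X[, i], X[, j]),
                 tolerance = 1e-12)
  }
  # duplicated variant column: off-diagonal r = 1
  panel$dosage <- cbind(X[, 1], X[, 1], X[, 3])
  ld_dup <- estimate_ld(panel, lambda = 0)
  expect_equal(ld_dup$blocks[[1]][1, 2], 1)
  # zero-variance variant errors and names the variant
  panel$dosage <- cbind(X[, 1:2], rep(1, 5))
  expect_error(estimate_ld(panel), "v3")
  # variants in different blocks of a rho=0 panel are uncorrelated
  cfg <- sim_config(master_seed = 31, M = 40, n_ref = 3000, block_size = 4,
                    rho = 0)
  p0 <- simulate_panel(cfg)
  R_ld <- stats::cor(p0$dosage[, c(1, 5)])
  expect_lt(abs(R_ld[1, 2]), 3 / sqrt(3000))
})

test_that("LDpred-inf has the identity-LD closed form and matches a dense solve", {
  # identity LD: w = beta / (1 + M/(N h2)); M=100, N=10000, h2=0.5 -> 1/1.02
  ld_id <- make_ld(diag(100))
  beta <- withr::with_seed(1, stats::rnorm(100, 0, 0.01))
  ss <- make_sumstats(beta, N = 10000, ld = ld_id)
  w <- ldpred_inf_weights(ss, ld_id, h2 = 0.5, M = 100, N = 10000)
  expect_equal(w$weights, beta / 1.02, tolerance = 1e-12)
  # zero signal in, zero weights out
  w0 <- ldpred_inf_weights(make_sumstats(rep(0, 100), ld = ld_id), ld_id,
                           h2 = 0.5)
  expect_true(all(w0$weights == 0))
  # dense-solve oracle on a random 20-variant correlated block
  A <- withr::with_seed(2, {
    Z <- matrix(stats::rnorm(40 * 20), 40, 20)
    stats::cor(Z %*% diag(20) + 0.5 * Z[, c(2:20, 1)])
  })
  ld_r <- make_ld(A)
  beta_r <- withr::with_seed(3, stats::rnorm(20, 0, 0.02))
  ss_r <- make_sumstats(beta_r, N = 5000, ld = ld_r)
  w_r <- ldpred_inf_weights(ss_r, ld_r, h2 = 0.3, M = 20, N = 5000)
  oracle <- solve(A + diag(20 / (5000 * 0.3), 20), beta_r)
  expect_lt(max(abs(w_r$weights - oracle)), 1e-10)
})

test_that("Gibbs sampler is reproducible, engine-consistent and null-stable", {
  w <- small_world()
  al <- align_alleles(w$ss$sumstats, w$panel)
  ld <- estimate_ld(w$panel)
  g1 <- ldpred_gibbs_weights(al$sumstats, ld, h2 = 0.3, p = 0.1,
                             n_iter = 120, burn_in = 20, seed = 5)
  g2 <- ldpred_gibbs_weights(al$sumstats, ld, h2 = 0.3, p = 0.1,
                             n_iter = 120, burn_in = 20, seed = 5)
  expect_identical(g1$weights, g2$weights)
  # R reference engine draws the same chain
  g_r <- ldpred_gibbs_weights(al$sumstats, ld, h2 = 0.3, p = 0.1,
                              n_iter = 120, burn_in = 20, seed = 5,
                              engine = "r")
  expect_equal(g1$weights, g_r$weights, tolerance = 1e-12)
  # two seeds agree up to Monte-Carlo noise
  g3 <- ldpred_gibbs_weights(al$sumstats, ld, h2 = 0.3, p = 0.1,
                             n_iter = 400, burn_in = 100, seed = 6)
  g4 <- ldpred_gibbs_weights(al$sumstats, ld, h2 = 0.3, p = 0.1,
                             n_iter = 400, burn_in = 100, seed = 7)
  expect_gt(stats::cor(g3$weights, g4$weights), 0.95)
  # null summary statistics give near-zero posterior means
  ld_id <- make_ld(diag(50))
  ss0 <- make_sumstats(rep(0, 50), N = 10000, ld = ld_id)
  g0 <- ldpred_gibbs_weights(ss0, ld_id, h2 = 0.2, p = 0.1,
                             n_iter = 300, burn_in = 50, seed = 1)
  expect_lt(max(abs(g0$weights)), 5 * sqrt(0.2 / (50 * 0.1) / 250))
})

test_that("single-variant Gibbs posterior mean matches numerical quadrature", {
  # one variant per block: the Rao-Blackwellized chain mean is the exact
  # point-normal posterior mean, which quadrature computes independently
  for (bh in c(0.005, 0.02)) {
    ld1 <- make_ld(matrix(1, 1, 1))
    N <- 10000; h2 <- 0.1; M <- 1; p <- 0.3
    ss1 <- make_sumstats(bh, N = N, ld = ld1)
    g <- ldpred_gibbs_weights(ss1, ld1, h2 = h2, p = p, M = M, N = N,
                              n_iter = 200, burn_in = 50, seed = 2)
    s2 <- h2 / (M * p); se2 <- 1 / N
    post <- function(b) {
      (p * stats::dnorm(bh, b, sqrt(se2)) * stats::dnorm(b, 0, sqrt(s2)))
    }
    num <- stats::integrate(function(b) b * post(b), -2, 2,
                            rel.tol = 1e-12)$value
    den <- stats::integrate(post, -2, 2, rel.tol = 1e-12)$value +
      (1 - p) * stats::dnorm(bh, 0, sqrt(se2))
    expect_equal(g$weights, num / den, tolerance = 1e-8)
  }
})

test_that("Gibbs divergence guard trips on absurd bounds", {
  ld1 <- make_ld(diag(5))
  ss <- make_sumstats(rep(0.5, 5), N = 10000, ld = ld1)
  expect_error(
    ldpred_gibbs_weights(ss, ld1, h2 = 0.5, p = 1, n_iter = 50,
                         burn_in = 10, seed = 1, w_bound = 1e-4),
    "divergence")
})

test_that("scoring is a standardized dot product with scale invariance", {
  X <- matrix(c(0, 2,
                1, 0,
                2, 1), nrow = 2, ncol = 3)
  panel <- structure(list(
    dosage = X,
    variants = data.frame(id = paste0("v", 1:3), block = 1L, a1 = "A",
                          a2 = "G", freq = 0.5)),
    class = "genotype_panel")
  wts <- c(0.5, -1, 2)
  sc <- score_individuals(panel, wts)
  # hand oracle: standardize each column over the 2 individuals, dot with w
  oracle <- sapply(1:2, function(i) {
    sum(wts * (X[i, ] - colMeans(X)) / apply(X, 2, stats::sd))
  })
  expect_equal(sc$raw, oracle, tolerance = 1e-12)
  # positive rescaling leaves the standardized score unchanged
  sc2 <- score_individuals(panel, 7 * wts)
  expect_equal(sc$standardized, sc2$standardized, tolerance = 1e-12)
  # all-zero weights give all-zero raw scores
  expect_warning(sc0 <- score_individuals(panel, rep(0, 3)), "constant")
  expect_true(all(sc0$raw == 0))
  expect_error(score_individuals(panel, c(1, 2)), "length")
})

test_that("AUC-based p selection returns the exhaustive argmax", {
  expect_equal(default_p_grid(), c(1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 1))
  w <- small_world()
  al <- align_alleles(w$ss$sumstats, w$panel)
  ld <- estimate_ld(w$panel)
  analysis_panel <- structure(
    list(dosage = w$cohort$dosage, variants = w$panel$variants),
    class = "genotype_panel")
  grid <- c(0.01, 0.1, 1)
  cands <- lapply(grid, function(p) {
    ldpred_gibbs_weights(al$sumstats, ld, h2 = 0.4, p = p,
                         n_iter = 150, burn_in = 50, seed = 11)
  })
  sel <- select_p_by_auc(cands, analysis_panel, w$cohort$cohort$status)
  expect_identical(nrow(sel$auc_table), 3L)
  # exhaustive oracle: rescore every candidate, count concordant pairs
  pair_auc <- function(s, y) {
    cs <- s[y == 1]; ct <- s[y == 0]
    m <- outer(cs, ct, `-`)
    (sum(m > 0) + 0.5 * sum(m == 0)) / length(m)
  }
  oracle_auc <- vapply(cands, function(cand) {
    pair_auc(score_individuals(analysis_panel, cand)$standardized,
             w$cohort$cohort$status)
  }, numeric(1))
  expect_equal(sel$auc_table$auc, oracle_auc, tolerance = 1e-12)
  expect_identical(sel$best$p, grid[which.max(oracle_auc)])
  # single candidate returned unconditionally
  one <- select_p_by_auc(cands[2], analysis_panel, w$cohort$cohort$status)
  expect_identical(one$best$p, 0.1)
  expect_error(select_p_by_auc(cands, analysis_panel,
                               rep(1, nrow(w$cohort$cohort))), "both classes")
})

test_that("covariate residualization matches the normal equations", {
  set.seed(4)
  n <- 60
  cov1 <- stats::rnorm(n)
  scores <- 0.5 * cov1 + stats::rnorm(n)
  adj <- residualize_covariates(scores, cbind(cov1))
  X <- cbind(1, cov1)
  oracle <- scores - X %*% solve(crossprod(X), crossprod(X, scores))
  expect_equal(adj, standardize_scores(drop(oracle)), tolerance = 1e-10)
  # scores exactly linear in the covariate: residuals all zero
  lin <- residualize_covariates(2 * cov1 + 3, cbind(cov1))
  expect_true(all(abs(lin) < 1e-10))
  # orthogonal covariate leaves standardized scores unchanged
  s <- standardize_scores(stats::rnorm(n))
  orth <- residuals(stats::lm(stats::rnorm(n) ~ s))
  adj2 <- residualize_covariates(s, cbind(orth))
  expect_equal(adj2, standardize_scores(s), tolerance = 1e-8)
  expect_error(residualize_covariates(scores, cbind(cov1, cov1)),
               "rank")
})

test_that("LD score regression behaves at the null and scales in N", {
  ld <- make_ld(lapply(1:10, function(b) diag(10)), n = 1000)
  # chi-square exactly 1 everywhere: h2 = 0, intercept 1
  ss_null <- make_sumstats(rep(1 / sqrt(10000), 100), N = 10000, ld = ld)
  fit0 <- ldsc_h2(ss_null, ld)
  expect_equal(fit0$h2, 0, tolerance = 1e-12)
  expect_equal(fit0$intercept, 1)
  # free-intercept null needs LD-score spread to identify the slope
  w0 <- small_world()
  ld_sw <- estimate_ld(w0$panel, lambda = 0)
  ss_null2 <- make_sumstats(rep(1 / sqrt(10000), length(ld_sw$ids)),
                            N = 10000, ld = ld_sw)
  free0 <- ldsc_h2(ss_null2, ld_sw, intercept = "free")
  expect_equal(free0$intercept, 1, tolerance = 1e-8)
  expect_equal(free0$h2, 0, tolerance = 1e-8)
  # doubling N at fixed chi-square halves the estimate (fixed point)
  w <- small_world()
  al <- align_alleles(w$ss$sumstats, w$panel)
  ld_w <- estimate_ld(w$panel, lambda = 0)
  f1 <- ldsc_h2(al$sumstats, ld_w, N = 20000, n_iter = 40)
  f2 <- ldsc_h2(al$sumstats, ld_w, N = 40000, n_iter = 40)
  expect_equal(f2$h2, f1$h2 / 2, tolerance = 1e-6)
  expect_error(ldsc_h2(al$sumstats, ld_w, n_jackknife = 1000),
               "fewer variants")
})

test_that("discrimination of the PRS increases with true heritability", {
  aucs <- vapply(c(0.05, 0.5), function(h2) {
    cfg <- sim_config(master_seed = 50, M = 300, n_ref = 300,
                      block_size = 20, h2 = h2, p_causal = 1,
                      n_case = 250, n_control = 250, K = 0.05,
                      coef_G = sqrt(h2) * 2, coef_E = 0, coef_GE = 0)
    panel <- simulate_panel(cfg)
    ss <- simulate_sumstats(panel, cfg)
    ch <- simulate_cohort(panel, ss, cfg)
    al <- align_alleles(ss$sumstats, panel)
    ld <- estimate_ld(panel)
    wts <- ldpred_inf_weights(al$sumstats, ld, h2 = max(h2, 0.05))
    ap <- structure(list(dosage = ch$dosage, variants = panel$variants),
                    class = "genotype_panel")
    auc(score_individuals(ap, wts)$standardized, ch$cohort$status)
  }, numeric(1))
  expect_gt(aucs[2], aucs[1])
})
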