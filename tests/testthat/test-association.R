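test_that("logistic fits reproduce closed forms and detect separation", {
  # intercept-only: coefficient = log(cases/controls)
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(matrix(numeric(0), 100, 0), y)
  expect_equal(unname(fit$coef), log(30 / 70), tolerance = 1e-8)
  # single binary predictor: coefficient = log(ad/bc) of the 2x2 table
  set.seed(10)
  x <- rbinom(200, 1, 0.4)
  y2 <- rbinom(200, 1, plogis(-0.5 + 0.9 * x))
  a <- sum(y2 == 1 & x == 1); b <- sum(y2 == 1 & x == 0)
  cc <- sum(y2 == 0 & x == 1); d <- sum(y2 == 0 & x == 0)
  fit2 <- fit_logistic(cbind(x = x), y2)
  expect_equal(fit2$coef[["x"]], log(a * d / (b * cc)), tolerance = 1e-8)
  # Wald covariance equals the 2x2 closed form 1/a+1/b+1/c+1/d
  expect_equal(fit2$vcov["x", "x"], 1 / a + 1 / b + 1 / cc + 1 / d,
               tolerance = 1e-6)
  # perfectly separated data raise the separation error
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- xs
  expect_error(fit_logistic(cbind(x = xs), ys), "separation|converge")
  expect_error(fit_logistic(cbind(x = rep(1, 50)), rbinom(50, 1, 0.5)),
               "zero-variance")
  expect_error(fit_logistic(cbind(x = rnorm(50)), rep(1, 50)), "both classes")
})

test_that("design construction follows the four model types", {
  w <- small_world()
  cohort <- w$cohort$cohort
  cohort$prs_z <- cohort$z_G_true
  cohort$pers_total_z <- cohort$z_E_true
  # defaults: covariates age, sex, education
  sp <- model_spec("interaction")
  expect_identical(sp$covariates, c("age", "sex", "education"))
  d <- build_design(cohort, sp)
  expect_identical(colnames(d$X),
                   c("prs_z", "pers_total_z", "prs_z:pers_total_z",
                     "age", "sex", "education"))
  # exactly one product column, computed after standardization
  g <- standardize_scores(cohort$prs_z)
  e <- standardize_scores(cohort$pers_total_z)
  expect_equal(unname(d$X[, "prs_z:pers_total_z"]), g * e, tolerance = 1e-12)
  # genetic/environmental/independent layouts
  expect_identical(colnames(build_design(cohort, model_spec("genetic"))$X)[1],
                   "prs_z")
  expect_false("prs_z" %in%
                 colnames(build_design(cohort, model_spec("environmental"))$X))
  di <- build_design(cohort, model_spec("independent"))
  expect_false(any(grepl(":", colnames(di$X))))
  # covariate-interaction columns appear on request
  dx <- build_design(cohort, model_spec("interaction",
                                        covariate_interactions = "age"))
  expect_true(all(c("age:prs_z", "age:pers_total_z") %in% colnames(dx$X)))
  expect_error(build_design(cohort, model_spec("interaction",
                                               g_term = "nope")), "nope")
})

test_that("Nagelkerke R2 matches its formula and limits", {
  f_eq <- fake_fit(c(`(Intercept)` = 0), matrix(1), loglik = -20,
                   null_loglik = -20, n = 50)
  expect_equal(nagelkerke_r2(f_eq), 0)
  f_perfect <- fake_fit(c(`(Intercept)` = 0), matrix(1), loglik = 0,
                        null_loglik = -30, n = 50)
  expect_equal(nagelkerke_r2(f_perfect), 1)
  # worked example evaluated against the raw formula
  f <- fake_fit(c(`(Intercept)` = 0), matrix(1), loglik = -4,
                null_loglik = -6.730, n = 10)
  oracle <- (1 - exp(2 * (-6.730 - -4) / 10)) / (1 - exp(2 * -6.730 / 10))
  expect_equal(nagelkerke_r2(f), oracle, tolerance = 1e-12)
  f_bad <- fake_fit(c(`(Intercept)` = 0), matrix(1), loglik = -8,
                    null_loglik = -6, n = 10)
  expect_error(nagelkerke_r2(f_bad), "below the null")
})

test_that("information criteria are the textbook formulas", {
  f <- fake_fit(c(a = 0, b = 0), diag(2), loglik = -10, n = 100)
  expect_equal(information_criteria(f)[["aic"]], 24)
  f2 <- fake_fit(c(a = 0), matrix(1), loglik = 0, n = exp(2))
  f2$n <- exp(2)
  expect_equal(information_criteria(f2)[["bic"]], 2, tolerance = 1e-12)
})

test_that("control-quantile dichotomization uses interpolated quantiles and strict comparison", {
  vals <- c(1:100, 75, 76)  # last two are 'cases'
  ctrl <- c(rep(TRUE, 100), FALSE, FALSE)
  d <- dichotomize_by_control_quantile(vals, ctrl, q = 0.75)
  expect_equal(d$threshold, 75.25)
  expect_false(d$high[101])  # 75 is below threshold
  expect_true(d$high[102])   # 76 is above
  # default is the 75% control threshold
  expect_equal(formals(dichotomize_by_control_quantile)$q, 0.75)
  # q = 0: everyone strictly above the control minimum is high
  d0 <- dichotomize_by_control_quantile(vals, ctrl, q = 0)
  expect_identical(sum(!d0$high), 1L)
  expect_error(dichotomize_by_control_quantile(rep(1, 10), rep(TRUE, 10)),
               "degenerate")
})

test_that("subgroup OR table matches the contingency oracle without covariates", {
  set.seed(21)
  n <- 600
  g <- rbinom(n, 1, 0.4) == 1
  e <- rbinom(n, 1, 0.3) == 1
  y <- rbinom(n, 1, plogis(-1 + 0.8 * g + 1 * e + 0.7 * g * e))
  cohort <- data.frame(status = y)
  tab <- subgroup_or_table(cohort, g, e, covariates = character())
  expect_equal(tab$or[tab$cell == "lowG_lowE"], 1)
  expect_equal(sum(tab$n), n)
  # contingency oracle: each cell's odds over the reference cell's odds
  odds <- function(mask) {
    sum(y[mask] == 1) / sum(y[mask] == 0)
  }
  ref <- odds(!g & !e)
  expect_equal(tab$or[tab$cell == "highG_lowE"], odds(g & !e) / ref,
               tolerance = 1e-6)
  expect_equal(tab$or[tab$cell == "lowG_highE"], odds(!g & e) / ref,
               tolerance = 1e-6)
  expect_equal(tab$or[tab$cell == "highG_highE"], odds(g & e) / ref,
               tolerance = 1e-6)
  # empty cell errors with counts
  e_all <- rep(TRUE, n)
  expect_error(subgroup_or_table(cohort, g, e_all, covariates = character()),
               "empty subgroup")
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(rep(0.03, 4)), rep(0.03, 4))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  # order-preserving and monotone when sorted
  p <- c(0.04, 0.01, 0.02)
  expect_equal(bh_fdr(p), c(0.04, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("linear phenotype fits match the normal equations", {
  w <- small_world()
  cohort <- w$cohort$cohort
  cohort$prs_z <- cohort$z_G_true
  cohort$pers_total_z <- cohort$z_E_true
  cases <- cohort[cohort$status == 1, ]
  sp <- model_spec("interaction")
  fit <- fit_linear_phenotype(cases, sp, "panss_total")
  d <- build_design(transform(cases, panss_total = panss_total), {
    sp2 <- sp; sp2$outcome <- "panss_total"; sp2
  })
  X <- cbind(1, d$X)
  oracle <- drop(solve(crossprod(X), crossprod(X, d$y)))
  expect_equal(unname(fit$coef), unname(oracle), tolerance = 1e-10)
  # exact linear data: zero residual variance, coefficients recovered
  dat <- data.frame(status = rep(0:1, 10), age = 1:20, sex = 0,
                    y = 3 + 2 * (1:20))
  sp_lin <- model_spec("genetic", g_term = "age", covariates = character())
  fit_lin <- fit_linear_phenotype(dat, sp_lin, "y")
  expect_equal(fit_lin$sigma, 0, tolerance = 1e-8)
  # age was standardized in the design, so the slope is per SD of age
  expect_equal(fit_lin$coef[["age"]], 2 * stats::sd(dat$age),
               tolerance = 1e-8)
})

test_that("case-only exposure screen has correct shape and a calibrated null", {
  w <- small_world()
  cohort <- w$cohort$cohort
  cohort$prs_z <- cohort$z_G_true
  scr <- ge_correlation_screen(cohort, prs_col = "prs_z")
  expect_identical(nrow(scr), 6L)
  expect_true(all(scr$fdr_p >= scr$p - 1e-12))
  # constant PRS violates the fit preconditions
  cohort$flat <- 1
  expect_error(ge_correlation_screen(cohort, prs_col = "flat"),
               "zero standard deviation|zero-variance")
  # type-I calibration: independent PRS, 200 replicated case-only screens
  rates <- withr::with_seed(31, {
    hits <- 0L; total <- 0L
    for (r in 1:200) {
      n <- 250
      dat <- data.frame(status = 1, prs = rnorm(n),
                        age = rnorm(n, 35, 8), sex = rbinom(n, 1, 0.5),
                        education = rnorm(n, 13, 3))
      for (dm in c("d1", "d2", "d3")) dat[[dm]] <- rbinom(n, 1, 0.3)
      scr_r <- ge_correlation_screen(dat, prs_col = "prs",
                                     domains = c("d1", "d2", "d3"))
      hits <- hits + sum(scr_r$p < 0.05)
      total <- total + nrow(scr_r)
    }
    hits / total
  })
  se <- sqrt(0.05 * 0.95 / 600)
  expect_lt(abs(rates - 0.05), 4 * se)
})

test_that("adding a real interaction term never hurts Nagelkerke R2", {
  d <- simulate_ge_cohort(1500, 0.5, 0.7, 0.4, K = 0.05,
                          case_control_ratio = 1, seed = 40)
  d$age <- withr::with_seed(41, rnorm(1500, 35, 8))
  d$sex <- withr::with_seed(42, rbinom(1500, 1, 0.5))
  d$education <- withr::with_seed(43, rnorm(1500, 13, 3))
  sp_ind <- model_spec("independent", g_term = "g", e_term = "e")
  sp_int <- model_spec("interaction", g_term = "g", e_term = "e")
  r2_ind <- nagelkerke_r2(fit_model_spec(d, sp_ind))
  r2_int <- nagelkerke_r2(fit_model_spec(d, sp_int))
  expect_true(r2_int >= r2_ind - 1e-10)
  expect_true(r2_ind >= 0 && r2_int <= 1)
})
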