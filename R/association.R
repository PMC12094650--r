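#' Fit a logistic regression and package everything downstream needs
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (tolerance 1e-8, at most 100 iterations), returning coefficients,
#' their covariance (inverse Fisher information, which equals the observed
#' information under the canonical logit link), both log-likelihoods, and a
#' per-term odds-ratio table with Wald confidence intervals. Quasi-complete
#' separation is flagged by an explicit error when any non-intercept
#' coefficient exceeds 15 on the standardized-predictor scale.
#'
#' @param X design matrix; an intercept column is prepended unless one named
#'   `(Intercept)` is already present.
#' @param y binary outcome vector (0/1 or logical).
#' @param conf_level Wald confidence level for the OR table (default 0.95).
#' @return an object of class `model_fit`; see Details for fields.
#' @details Fields: `coef`, `vcov`, `loglik`, `null_loglik`, `n`, `k`,
#'   `converged`, `family`, and `terms` (data.frame with term, estimate, se,
#'   or, ci_low, ci_high, z, p).
#' @export
fit_logistic <- function(X, y, conf_level = 0.95) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("design or outcome contains missing values")
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (!"(Intercept)" %in% colnames(X)) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0 & colnames(X) != "(Intercept)"
  if (any(const)) {
    stop("zero-variance predictor: ", paste(colnames(X)[const], collapse = ", "))
  }
  # glm.fit's 0/1 fitted-probability warning is routine here; true
  # separation is caught below by the coefficient-magnitude guard
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) stop("logistic fit did not converge in 100 iterations")
  beta <- fit$coefficients
  # separation guard on the standardized-predictor scale
  scale_chk <- ifelse(colnames(X) == "(Intercept)", 1, sds)
  if (any(abs(beta * scale_chk)[colnames(X) != "(Intercept)"] > 15)) {
    stop("separation detected: a standardized coefficient exceeds 15")
  }
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  vc <- tryCatch(solve(info), error = function(e) {
    stop("singular information matrix: ", conditionMessage(e))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  new_model_fit(beta, vc, ll, ll0, n = length(y), family = "binomial",
                conf_level = conf_level)
}

new_model_fit <- function(beta, vcov, loglik, null_loglik, n, family,
                          conf_level = 0.95, sigma = NA_real_) {
  se <- sqrt(diag(vcov))
  z <- beta / se
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta - crit * se)),
    ci_high = exp(unname(beta + crit * se)),
    z = unname(z),
    p = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  structure(
    list(coef = beta, vcov = vcov, loglik = loglik,
         null_loglik = null_loglik, n = n, k = length(beta),
         converged = TRUE, family = family, conf_level = conf_level,
         sigma = sigma, terms = terms),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s model fit: n = %d, k = %d, logLik = %.3f\n",
              x$family, x$n, x$k, x$loglik))
  print(format(x$terms, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Specify one of the four case-control model types
#'
#' The model family used throughout: (i) genetic — the polygenic score plus
#' covariates; (ii) environmental — the environmental score plus covariates;
#' (iii) independent — both main effects; (iv) interaction — both main
#' effects and their product. Covariates default to age, sex and education.
#'
#' @param model_type one of "genetic", "environmental", "independent",
#'   "interaction".
#' @param outcome outcome column name (default "status").
#' @param g_term genetic score column name.
#' @param e_term environmental score column name.
#' @param covariates covariate column names.
#' @param covariate_interactions covariate names whose products with the
#'   (standardized) G and E terms are added — the sensitivity models probing
#'   covariate-by-G/E confounding of the interaction term.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model_type = c("genetic", "environmental",
                                      "independent", "interaction"),
                       outcome = "status",
                       g_term = "prs_z",
                       e_term = "pers_total_z",
                       covariates = c("age", "sex", "education"),
                       covariate_interactions = character()) {
  model_type <- match.arg(model_type)
  structure(
    list(model_type = model_type, outcome = outcome, g_term = g_term,
         e_term = e_term, covariates = covariates,
         covariate_interactions = covariate_interactions),
    class = "model_spec"
  )
}

#' Build the design matrix for a model specification
#'
#' Continuous G and E columns are standardized over the analyzed
#' (complete-case) rows before any product term is formed, so reported odds
#' ratios are per SD. Returns the design matrix (with intercept), the
#' outcome, and a term map naming the genetic, environmental and interaction
#' columns.
#'
#' @param cohort data.frame holding all referenced columns.
#' @param spec a [model_spec()].
#' @return list with `X`, `y`, `terms` (named list: g, e, ge, covariates)
#'   and `rows` (the complete-case row indices used).
#' @export
build_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  needed <- c(spec$outcome, spec$covariates,
              if (spec$model_type != "environmental") spec$g_term,
              if (spec$model_type != "genetic") spec$e_term)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("column(s) not found in cohort: ", paste(missing_cols, collapse = ", "))
  }
  rows <- which(stats::complete.cases(cohort[, needed, drop = FALSE]))
  dat <- cohort[rows, , drop = FALSE]
  std <- function(x) if (length(unique(x)) > 2) standardize_scores(x) else x
  cols <- list()
  terms <- list(g = NULL, e = NULL, ge = NULL, covariates = spec$covariates)
  g <- e <- NULL
  if (spec$model_type != "environmental") {
    g <- std(dat[[spec$g_term]])
    cols[[spec$g_term]] <- g
    terms$g <- spec$g_term
  }
  if (spec$model_type != "genetic") {
    e <- std(dat[[spec$e_term]])
    cols[[spec$e_term]] <- e
    terms$e <- spec$e_term
  }
  if (spec$model_type == "interaction") {
    ge_name <- paste0(spec$g_term, ":", spec$e_term)
    cols[[ge_name]] <- g * e
    terms$ge <- ge_name
  }
  for (cv in spec$covariates) cols[[cv]] <- dat[[cv]]
  for (cv in spec$covariate_interactions) {
    if (!is.null(g)) cols[[paste0(cv, ":", spec$g_term)]] <- dat[[cv]] * g
    if (!is.null(e)) cols[[paste0(cv, ":", spec$e_term)]] <- dat[[cv]] * e
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = dat[[spec$outcome]], terms = terms, rows = rows)
}

#' Fit a model specification on a cohort
#'
#' Convenience wrapper: [build_design()] then [fit_logistic()].
#'
#' @inheritParams build_design
#' @param conf_level Wald confidence level.
#' @return a `model_fit`.
#' @export
fit_model_spec <- function(cohort, spec, conf_level = 0.95) {
  d <- build_design(cohort, spec)
  fit <- fit_logistic(d$X, d$y, conf_level = conf_level)
  fit$spec <- spec
  fit$term_map <- d$terms
  fit
}

#' Nagelkerke's pseudo R-squared
#'
#' `R2 = (1 - exp(2 (ll0 - ll1) / n)) / (1 - exp(2 ll0 / n))` — the
#' Cox-Snell ratio rescaled to a maximum of 1.
#'
#' @param fit a `model_fit` carrying `loglik`, `null_loglik` and `n`.
#' @return value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  ll1 <- fit$loglik; ll0 <- fit$null_loglik; n <- fit$n
  if (ll1 < ll0 - 1e-8) stop("model log-likelihood below the null model's")
  r2 <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  min(max(r2, 0), 1)
}

#' Akaike and Bayesian information criteria
#'
#' @param fit a converged `model_fit`.
#' @return named numeric vector `c(aic = 2k - 2 ll, bic = k log(n) - 2 ll)`.
#' @export
information_criteria <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  c(aic = 2 * fit$k - 2 * fit$loglik,
    bic = fit$k * log(fit$n) - 2 * fit$loglik)
}

#' Linear regression for continuous symptom phenotypes
#'
#' Ordinary least squares of a numeric phenotype on the specification's
#' design (typically the interaction model), with coefficient standard
#' errors and t-based p-values; used for symptom-scale outcomes.
#'
#' @param cohort data.frame.
#' @param spec a [model_spec()]; its `outcome` is ignored in favour of
#'   `phenotype`.
#' @param phenotype numeric column name to regress.
#' @param conf_level confidence level for the term table.
#' @return a `model_fit` with `family = "gaussian"` (the `or` columns of its
#'   term table exponentiate the estimates and are of secondary interest).
#' @export
fit_linear_phenotype <- function(cohort, spec, phenotype, conf_level = 0.95) {
  spec$outcome <- phenotype
  d <- build_design(cohort, spec)
  X <- cbind(`(Intercept)` = 1, d$X)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- stats::lm.fit(X, d$y)
  n <- length(d$y); k <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - k)
  XtXinv <- chol2inv(qr.R(fit$qr))
  vc <- XtXinv * sigma2
  dimnames(vc) <- list(colnames(X), colnames(X))
  # Gaussian log-likelihoods at the MLE variance (rss/n)
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  tss <- sum((d$y - mean(d$y))^2)
  ll0 <- -n / 2 * (log(2 * pi * tss / n) + 1)
  out <- new_model_fit(fit$coefficients, vc, ll, ll0, n,
                       family = "gaussian", conf_level = conf_level,
                       sigma = sqrt(sigma2))
  # t-based p-values are more appropriate than normal for OLS
  df <- n - k
  out$terms$p <- 2 * stats::pt(-abs(out$terms$z), df)
  out$spec <- spec
  out$term_map <- d$terms
  out
}
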