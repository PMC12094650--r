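#' Multiplicative-scale interaction from a fitted model
#'
#' The exponentiated product-term coefficient: 1 means exactly multiplicative
#' odds ratios; the Wald CI and p-value come from the fit's covariance.
#'
#' @param fit a converged `model_fit` from the interaction model.
#' @param ge_term product-term name (defaults to the fit's recorded term).
#' @return list with `or`, `ci`, `p`, `estimate` (log scale), `se`.
#' @export
multiplicative_interaction <- function(fit, ge_term = NULL) {
  ge_term <- ge_term %||% fit$term_map$ge
  if (is.null(ge_term) || !ge_term %in% names(fit$coef)) {
    stop("interaction term not found in fit: ", ge_term %||% "<missing>")
  }
  b <- fit$coef[[ge_term]]
  se <- sqrt(fit$vcov[ge_term, ge_term])
  crit <- stats::qnorm(1 - (1 - fit$conf_level) / 2)
  list(or = exp(b), ci = exp(c(b - crit * se, b + crit * se)),
       p = 2 * stats::pnorm(-abs(b / se)), estimate = b, se = se)
}

#' Relative excess risk due to interaction, delta-method CI
#'
#' Departure from additivity of the joint effect: with `b1 = dG * coef_G`,
#' `b2 = dE * coef_E`, `b3 = dG * dE * coef_GE`, the component odds ratios
#' are `OR10 = exp(b1)`, `OR01 = exp(b2)`, `OR11 = exp(b1 + b2 + b3)` and
#' `RERI = OR11 - OR10 - OR01 + 1` (0 = exactly additive). The variance is
#' the first-order propagation `h' Sigma h` with gradient
#' `(dG (OR11 - OR10), dE (OR11 - OR01), dG dE OR11)` over the coefficient
#' covariance; the CI is the symmetric Wald interval, and the primary
#' significance rule is whether it excludes zero. For continuous scores the
#' default contrast evaluates both exposures at +1 SD.
#'
#' @param fit a converged `model_fit` with G, E and G:E terms.
#' @param g_term,e_term,ge_term coefficient names (default to the fit's
#'   recorded term map).
#' @param contrast named numeric `c(dG = , dE = )`: exposure increments at
#'   which the component ORs are evaluated.
#' @return an object of class `reri_result`.
#' @export
reri_delta <- function(fit, g_term = NULL, e_term = NULL, ge_term = NULL,
                       contrast = c(dG = 1, dE = 1)) {
  g_term <- g_term %||% fit$term_map$g
  e_term <- e_term %||% fit$term_map$e
  ge_term <- ge_term %||% fit$term_map$ge
  nm <- c(g_term, e_term, ge_term)
  if (!all(nm %in% names(fit$coef))) {
    stop("term(s) absent from fit: ",
         paste(setdiff(nm, names(fit$coef)), collapse = ", "))
  }
  Sig <- fit$vcov[nm, nm]
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("coefficient covariance submatrix is not PSD")
  dG <- contrast[["dG"]]; dE <- contrast[["dE"]]
  b1 <- dG * fit$coef[[g_term]]
  b2 <- dE * fit$coef[[e_term]]
  b3 <- dG * dE * fit$coef[[ge_term]]
  or10 <- exp(b1); or01 <- exp(b2); or11 <- exp(b1 + b2 + b3)
  reri <- or11 - or10 - or01 + 1
  h <- c(dG * (or11 - or10), dE * (or11 - or01), dG * dE * or11)
  v <- drop(h %*% Sig %*% h)
  crit <- stats::qnorm(1 - (1 - fit$conf_level) / 2)
  ci <- c(reri - crit * sqrt(v), reri + crit * sqrt(v))
  p <- 2 * stats::pnorm(-abs(reri / sqrt(v)))
  new_reri_result(reri, v, ci, p, method = "delta", contrast = contrast,
                  or10 = or10, or01 = or01, or11 = or11)
}

new_reri_result <- function(reri, variance, ci, p, method, contrast,
                            or10 = NA_real_, or01 = NA_real_,
                            or11 = NA_real_, n_dropped = 0L) {
  structure(
    list(reri = reri, variance = variance, ci = ci, p = p,
         method = method, contrast = contrast,
         or10 = or10, or01 = or01, or11 = or11,
         significant = ci[1] > 0 || ci[2] < 0,
         n_dropped = n_dropped),
    class = "reri_result"
  )
}

#' @export
print.reri_result <- function(x, ...) {
  cat(sprintf("RERI = %.3f, 95%% CI [%.3f, %.3f], p = %.3g (%s method)\n",
              x$reri, x$ci[1], x$ci[2], x$p, x$method))
  cat(sprintf("  OR10 = %.3f, OR01 = %.3f, OR11 = %.3f at contrast (dG=%g, dE=%g)\n",
              x$or10, x$or01, x$or11, x$contrast[["dG"]], x$contrast[["dE"]]))
  invisible(x)
}

#' RERI with a stratified nonparametric bootstrap CI
#'
#' Case-resampling bootstrap stratified by case/control status: the
#' interaction model is refit on each resample and the percentile interval
#' of the RERI replicates forms the CI (asymmetric, unlike the delta
#' method's). Replicates whose refit fails (e.g. the separation guard) are
#' dropped and counted; more than 10% drops is an error.
#'
#' @param cohort data.frame.
#' @param spec an interaction-model [model_spec()].
#' @param B number of bootstrap replicates (>= 200).
#' @param seed RNG seed.
#' @param contrast as in [reri_delta()].
#' @param conf_level CI level.
#' @return a `reri_result` with `method = "bootstrap"` (point estimate from
#'   the full-data fit).
#' @export
reri_bootstrap <- function(cohort, spec, B = 2000L, seed = 1L,
                           contrast = c(dG = 1, dE = 1), conf_level = 0.95) {
  if (B < 200) stop("need B >= 200 bootstrap replicates")
  if (spec$model_type != "interaction") stop("spec must be an interaction model")
  full <- fit_model_spec(cohort, spec, conf_level = conf_level)
  point <- reri_delta(full, contrast = contrast)
  d <- build_design(cohort, spec)
  dat <- cohort[d$rows, , drop = FALSE]
  case_idx <- which(dat[[spec$outcome]] == 1)
  ctrl_idx <- which(dat[[spec$outcome]] == 0)
  reri_of <- function(rows) {
    fit <- fit_model_spec(dat[rows, , drop = FALSE], spec)
    reri_delta(fit, contrast = contrast)$reri
  }
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      rows <- c(sample(case_idx, replace = TRUE),
                sample(ctrl_idx, replace = TRUE))
      tryCatch(reri_of(rows), error = function(e) NA_real_)
    }, numeric(1))
  })
  n_drop <- sum(is.na(reps))
  if (n_drop > 0.1 * B) {
    stop(sprintf("bootstrap unstable: %d of %d refits failed", n_drop, B))
  }
  reps <- reps[!is.na(reps)]
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
  p_lo <- mean(reps <= 0); p_hi <- mean(reps >= 0)
  p <- min(1, 2 * min(p_lo, p_hi))
  new_reri_result(point$reri, stats::var(reps), ci, p,
                  method = "bootstrap", contrast = contrast,
                  or10 = point$or10, or01 = point$or01, or11 = point$or11,
                  n_dropped = n_drop)
}
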