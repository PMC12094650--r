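#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, preserving input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-environment correlation screen among cases
#'
#' For each binary/ordinal exposure domain, fits a logistic regression of the
#' exposure on the polygenic score plus covariates within cases only, and
#' reports the per-SD odds ratio with an FDR-adjusted p-value. Under the
#' default generator exposures are genotype-independent, so significant
#' domains should appear at roughly the nominal rate.
#'
#' @param cohort data.frame; rows with `status == 1` are used.
#' @param prs_col polygenic score column name.
#' @param domains character vector of exposure domain column names.
#' @param covariates covariate column names.
#' @return data.frame with one row per screened domain: domain, n, or,
#'   ci_low, ci_high, p, fdr_p. Domains with a single observed level are
#'   skipped with a warning.
#' @export
ge_correlation_screen <- function(cohort, prs_col = "prs_z",
                                  domains = c("paternal_age", "pses",
                                              "obstetric", "urbanicity",
                                              "childhood_adversity",
                                              "recent_life_events"),
                                  covariates = c("age", "sex", "education")) {
  cases <- cohort[cohort$status == 1, , drop = FALSE]
  if (nrow(cases) == 0L) stop("no cases in cohort")
  rows <- list()
  for (d in domains) {
    y <- cases[[d]]
    keep <- stats::complete.cases(cases[, c(d, prs_col, covariates)])
    y <- as.numeric(y[keep])
    if (length(unique(y)) < 2L) {
      warning(sprintf("domain '%s' has a single observed level; skipped", d))
      next
    }
    prs <- standardize_scores(cases[[prs_col]][keep])
    X <- cbind(prs = prs, as.matrix(cases[keep, covariates, drop = FALSE]))
    fit <- fit_logistic(X, y)
    r <- fit$terms[fit$terms$term == "prs", ]
    rows[[d]] <- data.frame(domain = d, n = sum(keep), or = r$or,
                            ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out) && nrow(out)) out$fdr_p <- bh_fdr(out$p)
  out
}
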