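#' Dichotomize scores at a control-group quantile
#'
#' The threshold is the linear-interpolation quantile (`type = 7`) of the
#' control values at probability `q`; an individual is "high" when strictly
#' above the threshold. The primary threshold is the control 75th percentile,
#' with 50% and 25% as sensitivity settings.
#'
#' @param values numeric vector for the whole sample.
#' @param control_mask logical vector: which entries are controls.
#' @param q quantile probability (default 0.75).
#' @return list with `high` (logical, `NA` where `values` is `NA`) and
#'   `threshold`.
#' @export
dichotomize_by_control_quantile <- function(values, control_mask, q = 0.75) {
  if (length(control_mask) != length(values)) {
    stop("`control_mask` must match `values` in length")
  }
  ctrl <- values[control_mask & !is.na(values)]
  if (length(unique(ctrl)) < 2L) {
    stop("degenerate threshold: fewer than 2 distinct control values")
  }
  thr <- stats::quantile(ctrl, q, type = 7, names = FALSE)
  list(high = values > thr, threshold = thr)
}

#' Joint genetic/environmental subgroup odds-ratio table
#'
#' Cross-classifies individuals by high/low genetic and environmental scores
#' (low/low as the reference) and fits a single covariate-adjusted logistic
#' model with the three non-reference indicators, yielding one OR, CI and
#' p-value per cell.
#'
#' @param cohort data.frame containing `status` and the covariates.
#' @param g_high,e_high logical vectors from
#'   [dichotomize_by_control_quantile()].
#' @param covariates character vector of covariate column names (may be
#'   empty for the unadjusted contingency version).
#' @param conf_level Wald confidence level.
#' @return object of class `subgroup_or_table`: data.frame with one row per
#'   cell (cell, n, n_case, or, ci_low, ci_high, p), plus attributes `fit`
#'   and `threshold_q`.
#' @export
subgroup_or_table <- function(cohort, g_high, e_high,
                              covariates = c("age", "sex", "education"),
                              conf_level = 0.95) {
  keep <- !is.na(g_high) & !is.na(e_high) &
    stats::complete.cases(cohort[, c("status", covariates), drop = FALSE])
  dat <- cohort[keep, , drop = FALSE]
  g <- g_high[keep]; e <- e_high[keep]
  cell <- factor(paste0(ifelse(g, "highG", "lowG"), "_",
                        ifelse(e, "highE", "lowE")),
                 levels = c("lowG_lowE", "highG_lowE", "lowG_highE",
                            "highG_highE"))
  counts <- table(cell)
  if (any(counts == 0)) {
    stop("empty subgroup cell(s); counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  ind <- stats::model.matrix(~cell)[, -1, drop = FALSE]
  colnames(ind) <- levels(cell)[-1]
  X <- cbind(ind, as.matrix(dat[, covariates, drop = FALSE]))
  fit <- fit_logistic(X, dat$status, conf_level = conf_level)
  tt <- fit$terms
  rows <- lapply(levels(cell), function(lv) {
    n_cell <- sum(cell == lv)
    n_case <- sum(dat$status[cell == lv] == 1)
    if (lv == "lowG_lowE") {
      data.frame(cell = lv, n = n_cell, n_case = n_case, or = 1,
                 ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
    } else {
      r <- tt[tt$term == lv, ]
      data.frame(cell = lv, n = n_cell, n_case = n_case, or = r$or,
                 ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  class(out) <- c("subgroup_or_table", "data.frame")
  out
}
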