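#' Compute per-individual polygenic scores
#'
#' The raw score is the weighted sum of empirically standardized dosages,
#' `score_i = sum_j w_j (g_ij - mean_j)/sd_j`; the standardized score rescales
#' the raw scores to mean 0, SD 1 over the scored individuals (so any
#' positive rescaling of the weights leaves it unchanged).
#'
#' @param panel a `genotype_panel` (its `dosage` matrix is scored).
#' @param weights a `prs_weights` object or a bare numeric vector aligned to
#'   the panel's variants.
#' @return data.frame with columns `id`, `raw`, `standardized`.
#' @export
score_individuals <- function(panel, weights) {
  w <- if (inherits(weights, "prs_weights")) weights$weights else weights
  X <- panel$dosage
  if (length(w) != ncol(X)) {
    stop(sprintf("weight length %d does not match %d panel variants",
                 length(w), ncol(X)))
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  active <- w != 0
  if (any(sds[active] == 0)) stop("zero-variance variant with non-zero weight")
  sds[sds == 0] <- 1
  raw <- drop(sweep(X, 2, mu) %*% (w / sds))
  std <- if (stats::sd(raw) == 0) {
    warning("constant raw scores: standardized scores set to 0")
    rep(0, length(raw))
  } else {
    standardize_scores(raw)
  }
  ids <- rownames(X) %||% sprintf("ind_%05d", seq_len(nrow(X)))
  data.frame(id = ids, raw = raw, standardized = std,
             stringsAsFactors = FALSE)
}

#' Select the causal-fraction hyperparameter by AUC
#'
#' Scores every candidate weight vector on the analysis panel and returns the
#' one whose standardized score best discriminates cases from controls by
#' area under the ROC curve. Ties are broken toward the smallest `p`. This is
#' in-sample selection; for honest accuracy estimates score a held-out set.
#'
#' @param candidates list of `prs_weights` (typically one per `p` in
#'   [default_p_grid()]).
#' @param panel the `genotype_panel` holding the analysis individuals.
#' @param labels binary case/control vector (1 = case) aligned to the panel's
#'   rows.
#' @return list with `best` (the selected `prs_weights`), `auc_table`
#'   (data.frame p, method, auc) and `scores` of the selected candidate.
#' @export
select_p_by_auc <- function(candidates, panel, labels) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  if (length(unique(labels[!is.na(labels)])) < 2L) {
    stop("labels must contain both classes")
  }
  rows <- lapply(candidates, function(cand) {
    sc <- score_individuals(panel, cand)
    list(p = cand$p, method = cand$method,
         auc = auc(sc$standardized, labels), scores = sc)
  })
  tab <- data.frame(
    p = vapply(rows, `[[`, numeric(1), "p"),
    method = vapply(rows, `[[`, character(1), "method"),
    auc = vapply(rows, `[[`, numeric(1), "auc")
  )
  best_idx <- order(-tab$auc, tab$p)[1]
  list(best = candidates[[best_idx]], auc_table = tab,
       scores = rows[[best_idx]]$scores)
}

#' The standard causal-fraction grid
#'
#' @return numeric vector `c(1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 1)`.
#' @export
default_p_grid <- function() c(1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 1)

#' Residualize scores on covariates
#'
#' Regresses scores on the covariates (plus an intercept) by least squares
#' and returns the re-standardized residuals — the usual age/sex adjustment
#' applied to polygenic scores before association modelling.
#'
#' @param scores numeric vector.
#' @param covariates numeric matrix or data.frame (no intercept column).
#' @return numeric vector of adjusted, standardized scores.
#' @export
residualize_covariates <- function(scores, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
  res <- stats::lm.fit(X, scores)$residuals
  if (stats::sd(res) < 1e-10 * max(1, stats::sd(scores))) return(res)
  standardize_scores(res)
}
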