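#' Area under the ROC curve
#'
#' Mann-Whitney U statistic with midrank tie handling: the probability that a
#' randomly chosen case outscores a randomly chosen control, ties counting
#' one half.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1/TRUE = case).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.numeric(labels[keep])
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Liability threshold model parameters
#'
#' Derived quantities of the threshold model at population lifetime risk `K`
#' and sample case proportion `P`: threshold `t = qnorm(1 - K)`, mean case
#' liability `i = dnorm(t)/K` and mean control liability `v = -iK/(1-K)`.
#' Derived values are computed on construction, never cached stale.
#'
#' @param K population lifetime risk in (0, 1), default 0.01.
#' @param P sample case proportion in (0, 1); defaults to `K` (no
#'   ascertainment).
#' @return object of class `liability_params`.
#' @export
liability_params <- function(K = 0.01, P = K) {
  if (K <= 0 || K >= 1) stop("`K` must lie in (0, 1)")
  if (P <= 0 || P >= 1) stop("`P` must lie in (0, 1)")
  t <- stats::qnorm(1 - K)
  i <- stats::dnorm(t) / K
  structure(
    list(K = K, P = P, t = t, i = i, v = -i * K / (1 - K)),
    class = "liability_params"
  )
}

#' Expected AUC for a given liability-scale variance explained
#'
#' The truncated-normal forward map: a predictor explaining a fraction
#' `rho2` of liability variance has mean `rho2 * i` in cases and `rho2 * v`
#' in controls with within-group variances `rho2 (1 - rho2 i (i - t))` and
#' `rho2 (1 - rho2 v (v - t))`, giving
#' `AUC = pnorm(rho2 (i - v) / sqrt(sum of the two variances))`.
#'
#' @param rho2 liability variance explained, in `[0, 1)`.
#' @param params a [liability_params()].
#' @return expected AUC in `[0.5, 1)`.
#' @export
liability_r2_to_auc <- function(rho2, params = liability_params()) {
  if (any(rho2 < 0 | rho2 >= 1)) stop("`rho2` must lie in [0, 1)")
  if (length(rho2) > 1) {
    return(vapply(rho2, liability_r2_to_auc, numeric(1), params = params))
  }
  if (rho2 == 0) return(0.5)
  t <- params$t; i <- params$i; v <- params$v
  num <- rho2 * (i - v)
  den <- sqrt(rho2 * (1 - rho2 * i * (i - t)) + rho2 * (1 - rho2 * v * (v - t)))
  stats::pnorm(num / den)
}

#' Convert an observed AUC to liability-scale variance explained
#'
#' Inverts [liability_r2_to_auc()] by bisection on `rho2` in `[0, 1)` to
#' absolute tolerance 1e-8. An AUC of exactly 0.5 maps to 0; an AUC below
#' 0.5 indicates a reversed score direction and is an error.
#'
#' @param auc_value AUC in `[0.5, 1)`.
#' @param params a [liability_params()].
#' @return liability-scale R-squared.
#' @export
auc_to_liability_r2 <- function(auc_value, params = liability_params()) {
  if (auc_value < 0.5) stop("AUC below 0.5: fix the score direction upstream")
  if (auc_value >= 1) stop("AUC must be < 1")
  if (auc_value == 0.5) return(0)
  lo <- 0; hi <- 1 - 1e-12
  if (liability_r2_to_auc(hi, params) < auc_value) {
    stop("AUC exceeds the model's attainable maximum for this K")
  }
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (liability_r2_to_auc(mid, params) < auc_value) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Convert an observed-scale pseudo R-squared to the liability scale
#'
#' The case-control-to-liability transformation of Lee and colleagues:
#' with `t = qnorm(1-K)`, `z = dnorm(t)`, `i = z/K`, ascertainment-corrected
#' scaling `C = K^2 (1-K)^2 / (z^2 P (1-P))` and
#' `theta = i ((P-K)/(1-K)) * (i ((P-K)/(1-K)) - t)`, the liability-scale
#' value is `C R2 / (1 + C theta R2)`. With `P = K` (no ascertainment) theta
#' vanishes and the map reduces to the classical `R2 K(1-K)/z^2` rescaling.
#'
#' @param r2 observed-scale (e.g. Nagelkerke) R-squared in `[0, 1)`.
#' @param params a [liability_params()] carrying both `K` and `P`.
#' @return liability-scale R-squared.
#' @export
nagelkerke_to_liability_r2 <- function(r2, params = liability_params()) {
  if (any(r2 < 0 | r2 >= 1)) stop("`r2` must lie in [0, 1)")
  if (length(r2) > 1) {
    return(vapply(r2, nagelkerke_to_liability_r2, numeric(1), params = params))
  }
  K <- params$K; P <- params$P
  t <- params$t; z <- stats::dnorm(t); i <- params$i
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  m <- i * (P - K) / (1 - K)
  theta <- m * (m - t)
  C * r2 / (1 + C * theta * r2)
}
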