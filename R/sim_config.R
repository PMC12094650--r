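#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic data-generating process: the LD-blocked
#' reference panel, the point-normal genetic architecture behind the GWAS
#' summary statistics, the six binary environmental exposure domains plus the
#' trauma-inventory subdomains, and the case-control ascertainment model.
#' Defaults reproduce the study conditions the package is organised around: an
#' ascertained sample of 717 cases and 356 controls drawn from a population
#' with lifetime risk `K = 0.01`, and standardized log-odds coefficients
#' (0.7, 1.0, 0.3) for the genetic score, the aggregate environmental score
#' and their product.
#'
#' @param master_seed integer; expanded into independent named substreams for
#'   the panel, summary statistics, exposures and cohort stages.
#' @param M number of variants.
#' @param n_ref reference-panel size (individuals).
#' @param block_size variants per LD block; the final block may be smaller
#'   when `M` is not a multiple.
#' @param rho within-block adjacent-variant latent correlation, in `[0, 1)`.
#' @param maf_range length-2 vector in `(0, 0.5]`: minor allele frequencies
#'   are drawn uniformly from this range.
#' @param h2 liability-scale SNP heritability in `[0, 1)`.
#' @param p_causal causal fraction in `(0, 1]` of the point-normal prior.
#' @param N_gwas training GWAS sample size behind the summary statistics.
#' @param K population lifetime risk (default 0.01).
#' @param n_case,n_control target ascertained counts (defaults 717 and 356).
#' @param exposure_prevalences named probabilities for the six exposure
#'   domains. The field instruments these mirror do not publish population
#'   prevalences in accessible form; these defaults are configuration, not
#'   estimates, and should be overridden for substantive use.
#' @param env_weights named per-domain log-relative-risk weights used to form
#'   the true environmental liability score.
#' @param coef_G,coef_E,coef_GE standardized log-odds (or liability-scale)
#'   coefficients of the generating disease model.
#' @param mechanism `"logit"` (logistic disease model with calibrated
#'   intercept) or `"liability"` (threshold model on a latent liability).
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(M = 200, n_ref = 100)
#' cfg$K
#' @export
sim_config <- function(master_seed = 1L,
                       M = 1000L,
                       n_ref = 500L,
                       block_size = 50L,
                       rho = 0.6,
                       maf_range = c(0.05, 0.5),
                       h2 = 0.3,
                       p_causal = 0.03,
                       N_gwas = 50000L,
                       K = 0.01,
                       n_case = 717L,
                       n_control = 356L,
                       exposure_prevalences = c(
                         paternal_age = 0.15,
                         pses = 0.25,
                         obstetric = 0.10,
                         urbanicity = 0.50,
                         childhood_adversity = 0.30,
                         recent_life_events = 0.20
                       ),
                       env_weights = c(
                         paternal_age = 0.35,
                         pses = 0.50,
                         obstetric = 0.45,
                         urbanicity = 0.25,
                         childhood_adversity = 0.80,
                         recent_life_events = 0.40
                       ),
                       coef_G = 0.7,
                       coef_E = 1.0,
                       coef_GE = 0.3,
                       mechanism = c("logit", "liability")) {
  mechanism <- match.arg(mechanism)
  stopifnot(
    is_scalar_number(master_seed),
    is_scalar_number(M), M >= 1,
    is_scalar_number(n_ref), n_ref >= 2,
    is_scalar_number(block_size), block_size >= 1
  )
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an increasing pair in (0, 0.5]")
  }
  if (!is_scalar_number(h2) || h2 < 0 || h2 >= 1) stop("`h2` must lie in [0, 1)")
  if (!is_scalar_number(p_causal) || p_causal <= 0 || p_causal > 1) {
    stop("`p_causal` must lie in (0, 1]")
  }
  if (!is_scalar_number(K) || K <= 0 || K >= 1) stop("`K` must lie in (0, 1)")
  if (n_case < 1 || n_control < 1) stop("`n_case` and `n_control` must be positive")
  if (any(exposure_prevalences <= 0) || any(exposure_prevalences >= 1)) {
    stop("exposure prevalences must lie in (0, 1)")
  }
  if (is.null(names(exposure_prevalences)) || anyDuplicated(names(exposure_prevalences))) {
    stop("`exposure_prevalences` must have unique names")
  }
  if (!setequal(names(env_weights), names(exposure_prevalences))) {
    stop("`env_weights` must name the same domains as `exposure_prevalences`")
  }
  if (mechanism == "liability") {
    resid <- 1 - coef_G^2 - coef_E^2 - coef_GE^2
    if (resid <= 0) {
      stop("liability mechanism: coefficient variance exceeds 1, residual variance <= 0")
    }
  }
  structure(
    list(
      master_seed = as.integer(master_seed),
      M = as.integer(M), n_ref = as.integer(n_ref),
      block_size = as.integer(block_size), rho = rho,
      maf_range = maf_range, h2 = h2, p_causal = p_causal,
      N_gwas = as.integer(N_gwas), K = K,
      n_case = as.integer(n_case), n_control = as.integer(n_control),
      exposure_prevalences = exposure_prevalences,
      env_weights = env_weights[names(exposure_prevalences)],
      coef_G = coef_G, coef_E = coef_E, coef_GE = coef_GE,
      mechanism = mechanism
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  variants: %d (blocks of %d, rho = %.2f), reference n = %d\n",
              x$M, x$block_size, x$rho, x$n_ref))
  cat(sprintf("  architecture: h2 = %.2f, p_causal = %g, N_gwas = %d\n",
              x$h2, x$p_causal, x$N_gwas))
  cat(sprintf("  cohort: %d cases / %d controls, K = %g, mechanism = %s\n",
              x$n_case, x$n_control, x$K, x$mechanism))
  cat(sprintf("  coefficients: G %.2f, E %.2f, GxE %.2f\n",
              x$coef_G, x$coef_E, x$coef_GE))
  invisible(x)
}

# Block assignment for M variants in blocks of block_size (last may be short).
variant_blocks <- function(M, block_size) {
  rep(seq_len(ceiling(M / block_size)), each = block_size)[seq_len(M)]
}
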