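#' Calibrate the baseline log-odds of a logistic disease model
#'
#' Finds, by bisection, the intercept `b0` at which the population prevalence
#' of `P(case) = expit(b0 + cG*zG + cE*zE + cGE*zG*zE)` equals the target
#' lifetime risk `K`, averaging over Monte-Carlo draws of the standardized
#' genetic and environmental scores.
#'
#' @param coef_G,coef_E,coef_GE standardized log-odds coefficients.
#' @param K target prevalence in (0, 1).
#' @param z_G,z_E Monte-Carlo draws of the two standardized scores (equal
#'   length). When omitted, `n_mc` iid standard-normal draws are used.
#' @param n_mc number of draws when `z_G`/`z_E` are not supplied.
#' @param seed RNG seed for the default draws.
#' @return list with `b0`, the achieved Monte-Carlo `prevalence`, and `n_mc`.
#' @examples
#' calibrate_intercept(0, 0, 0, K = 0.01, n_mc = 1e4, seed = 1)$b0
#' log(0.01 / 0.99) # closed form when all coefficients are zero
#' @export
calibrate_intercept <- function(coef_G, coef_E, coef_GE, K,
                                z_G = NULL, z_E = NULL,
                                n_mc = 2e5, seed = 1L) {
  if (K <= 0 || K >= 1) stop("`K` must lie in (0, 1)")
  if (is.null(z_G) || is.null(z_E)) {
    draws <- with_seed(seed, list(g = stats::rnorm(n_mc), e = stats::rnorm(n_mc)))
    if (is.null(z_G)) z_G <- draws$g
    if (is.null(z_E)) z_E <- draws$e
  }
  stopifnot(length(z_G) == length(z_E))
  eta <- coef_G * z_G + coef_E * z_E + coef_GE * z_G * z_E
  prev <- function(b0) mean(expit(b0 + eta))
  lo <- -50; hi <- 20
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (prev(mid) < K) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  b0 <- (lo + hi) / 2
  list(b0 = b0, prevalence = prev(b0), n_mc = length(z_G))
}

#' Simulate an ascertained case-control cohort with genotypes and exposures
#'
#' Candidates are drawn from the population generative model — genotypes from
#' the panel's LD-blocked architecture, exposures at the configured
#' prevalences — and their disease status is generated either from a logistic
#' model on the standardized genetic score, the standardized weighted
#' environmental score and their product (intercept calibrated so the
#' population prevalence equals `K`), or from a liability-threshold model.
#' Rejection sampling then retains exactly `n_case` cases and `n_control`
#' controls, mirroring an ascertained clinical sample rather than a
#' population cohort.
#'
#' @param panel a `genotype_panel` supplying the variant table (MAFs, blocks)
#'   from which cohort genotypes are drawn.
#' @param truth a `sumstats_sim` (for its `beta_true`) or a numeric vector of
#'   true standardized effects aligned to the panel.
#' @param config a [sim_config()].
#' @param exposures optional function `(n) -> data.frame` overriding the
#'   default exposure generator (must return the same columns as
#'   [simulate_exposures()]).
#' @param keep_genotypes logical; attach the retained individuals' dosage
#'   matrix (default TRUE).
#' @param chunk_size candidates generated per rejection-sampling round.
#' @param max_draws cap on total candidates before giving up with a
#'   diagnostic error.
#' @return an object of class `cohort_sim`: list with `cohort` (data.frame:
#'   id, status, age, sex, education, exposure domains, trauma subdomains,
#'   z_G_true, z_E_true, and case-only symptom phenotypes), `dosage`
#'   (retained individuals x variants, or NULL), and `truth` (b0 or
#'   threshold, coefficients, genetic-score scale, draws used).
#' @examples
#' cfg <- sim_config(M = 40, n_ref = 100, block_size = 10,
#'                   n_case = 30, n_control = 20, K = 0.2)
#' panel <- simulate_panel(cfg)
#' ss <- simulate_sumstats(panel, cfg)
#' ch <- simulate_cohort(panel, ss, cfg)
#' table(ch$cohort$status)
#' @export
simulate_cohort <- function(panel, truth, config, exposures = NULL,
                            keep_genotypes = TRUE,
                            chunk_size = 5000L,
                            max_draws = NULL) {
  stopifnot(inherits(config, "sim_config"))
  beta_true <- if (inherits(truth, "sumstats_sim")) truth$beta_true else truth
  if (length(beta_true) != nrow(panel$variants)) {
    stop("true effect vector does not match the panel's variant count")
  }
  if (is.null(max_draws)) {
    max_draws <- ceiling(50 * (config$n_case / config$K + config$n_control))
  }
  # draws use the cohort substream's RNG state (seed = NA: no reseeding)
  gen_expo <- exposures %||% function(n) {
    simulate_exposures(n, config, seed = NA)
  }
  w <- config$env_weights
  p <- config$exposure_prevalences
  mu_E <- sum(w * p)
  sd_E <- sqrt(sum(w^2 * p * (1 - p)))
  f <- panel$variants$freq
  g_center <- 2 * f
  g_scale <- sqrt(2 * f * (1 - f))
  any_gen <- any(beta_true != 0)

  seed <- substream_seed(config$master_seed, "cohort")
  out <- with_seed(seed, {
    # scale of the raw genetic score, estimated once from calibration draws
    sd_G <- if (any_gen) {
      Xc <- draw_dosages(panel$variants, config$rho, 2000L)
      s <- drop(sweep(Xc, 2, g_center) %*% (beta_true / g_scale))
      stats::sd(s)
    } else 1
    # Monte-Carlo calibration of the baseline risk: genetic score treated as
    # standard normal (CLT over variants), environmental score drawn from its
    # actual discrete distribution
    n_mc <- 2e5
    zg_mc <- stats::rnorm(n_mc)
    ze_mc <- (drop(vapply(p, function(pk) stats::runif(n_mc) < pk,
                          logical(n_mc)) %*% w) - mu_E) / sd_E
    eta_mc <- config$coef_G * zg_mc + config$coef_E * ze_mc +
      config$coef_GE * zg_mc * ze_mc
    if (config$mechanism == "logit") {
      cal <- calibrate_intercept(config$coef_G, config$coef_E, config$coef_GE,
                                 config$K, z_G = zg_mc, z_E = ze_mc)
      b0 <- cal$b0
      threshold <- NA_real_
    } else {
      resid_sd <- sqrt(1 - config$coef_G^2 - config$coef_E^2 - config$coef_GE^2)
      liab_mc <- eta_mc + stats::rnorm(n_mc, 0, resid_sd)
      threshold <- stats::quantile(liab_mc, 1 - config$K, names = FALSE)
      b0 <- NA_real_
    }

    need_case <- config$n_case
    need_ctrl <- config$n_control
    kept <- list()
    kept_dos <- list()
    n_drawn <- 0L
    while ((need_case > 0L || need_ctrl > 0L) && n_drawn < max_draws) {
      n <- min(chunk_size, max_draws - n_drawn)
      expo <- gen_expo(n)
      dom <- as.matrix(expo[, names(p), drop = FALSE])
      z_E <- (drop(dom %*% w) - mu_E) / sd_E
      if (any_gen) {
        X <- draw_dosages(panel$variants, config$rho, n)
        z_G <- drop(sweep(X, 2, g_center) %*% (beta_true / g_scale)) / sd_G
      } else {
        X <- if (keep_genotypes) draw_dosages(panel$variants, config$rho, n) else NULL
        z_G <- stats::rnorm(n)
      }
      eta <- config$coef_G * z_G + config$coef_E * z_E +
        config$coef_GE * z_G * z_E
      status <- if (config$mechanism == "logit") {
        as.integer(stats::runif(n) < expit(b0 + eta))
      } else {
        as.integer(eta + stats::rnorm(n, 0, sqrt(
          1 - config$coef_G^2 - config$coef_E^2 - config$coef_GE^2)) > threshold)
      }
      take_case <- which(status == 1L)[seq_len(min(need_case, sum(status == 1L)))]
      take_ctrl <- which(status == 0L)[seq_len(min(need_ctrl, sum(status == 0L)))]
      take <- c(take_case, take_ctrl)
      if (length(take)) {
        kept[[length(kept) + 1L]] <- cbind(
          expo[take, , drop = FALSE],
          data.frame(status = status[take], z_G_true = z_G[take],
                     z_E_true = z_E[take])
        )
        if (keep_genotypes && !is.null(X)) {
          kept_dos[[length(kept_dos) + 1L]] <- X[take, , drop = FALSE]
        }
        need_case <- need_case - length(take_case)
        need_ctrl <- need_ctrl - length(take_ctrl)
      }
      n_drawn <- n_drawn + n
    }
    if (need_case > 0L || need_ctrl > 0L) {
      stop(sprintf(
        "case/control quota unreachable: %d cases and %d controls still needed after %d draws",
        need_case, need_ctrl, n_drawn))
    }
    tab_all <- do.call(rbind, kept)
    ord <- order(-tab_all$status)  # cases first, then controls
    tab <- tab_all[ord, , drop = FALSE]
    dosage <- if (keep_genotypes && length(kept_dos)) {
      do.call(rbind, kept_dos)[ord, , drop = FALSE]
    } else NULL
    n_tot <- nrow(tab)
    is_case <- tab$status == 1L
    # covariates: ascertained patients skew younger, as in clinical samples
    age <- round(ifelse(is_case, stats::rnorm(n_tot, 33, 9),
                        stats::rnorm(n_tot, 42, 12)))
    age <- pmax(18, pmin(75, age))
    sex <- stats::rbinom(n_tot, 1, 0.5)
    education <- pmax(6, pmin(22, round(stats::rnorm(n_tot, 13, 3))))
    # symptom phenotypes: cases only, mildly loaded on the true scores
    panss_total <- ifelse(is_case,
      round(70 + 5 * tab$z_G_true + 4 * tab$z_E_true + stats::rnorm(n_tot, 0, 15)),
      NA_real_)
    bcss_neg_self <- pmax(0, round(
      4 + 2 * tab$z_E_true + 2.5 * is_case + stats::rnorm(n_tot, 0, 3)))
    bcss_neg_others <- pmax(0, round(
      4 + 1.5 * tab$z_E_true + 2 * is_case + stats::rnorm(n_tot, 0, 3)))
    cohort <- cbind(
      data.frame(id = sprintf("ind_%05d", seq_len(n_tot)),
                 status = tab$status, age = age, sex = sex,
                 education = education, stringsAsFactors = FALSE),
      tab[, setdiff(names(tab), "status"), drop = FALSE],
      data.frame(panss_total = panss_total,
                 bcss_neg_self = bcss_neg_self,
                 bcss_neg_others = bcss_neg_others)
    )
    rownames(cohort) <- NULL
    if (!is.null(dosage)) rownames(dosage) <- cohort$id
    list(cohort = cohort, dosage = dosage,
         truth = list(b0 = b0, threshold = threshold, sd_G = sd_G,
                      coef = c(G = config$coef_G, E = config$coef_E,
                               GE = config$coef_GE),
                      n_drawn = n_drawn, seed = seed))
  })
  structure(c(out, list(config = config)), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d cases / %d controls (%s mechanism)\n",
              sum(x$cohort$status == 1), sum(x$cohort$status == 0),
              x$config$mechanism))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
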