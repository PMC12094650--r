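#' Simulate a case-control sample from standardized G and E
#'
#' The fast generative family used for power analysis and calibration
#' studies: standardized genetic and environmental scores are independent
#' standard normals, and status follows either the logistic model
#' `P(case) = expit(b0 + bG g + bE e + bGE g e)` with `b0` calibrated to the
#' population prevalence `K`, or the equivalent liability-threshold model.
#' With a case:control ratio, cases and controls are ascertained by
#' rejection sampling (the non-intercept logistic coefficients are invariant
#' to outcome-dependent sampling); otherwise a population sample of size `n`
#' is returned.
#'
#' @param n sample size (total).
#' @param b_G,b_E,b_GE standardized coefficients.
#' @param K population prevalence (default 0.01). Ignored when `b0` given.
#' @param b0 optional fixed intercept overriding calibration.
#' @param case_control_ratio optional numeric ratio cases:controls (e.g. 1
#'   for balanced, 717/356 for the default ascertained design); `NULL` for a
#'   population sample.
#' @param mechanism `"logit"` or `"liability"`.
#' @param seed optional seed; `NA` (default) draws from the current RNG
#'   state.
#' @param max_draw_factor rejection-sampling cap as a multiple of the
#'   expected required draws.
#' @return data.frame with columns `g`, `e`, `status`.
#' @export
simulate_ge_cohort <- function(n, b_G, b_E, b_GE, K = 0.01, b0 = NULL,
                               case_control_ratio = NULL,
                               mechanism = c("logit", "liability"),
                               seed = NA, max_draw_factor = 50) {
  mechanism <- match.arg(mechanism)
  run <- function() {
    draw_status <- function(m) {
      g <- stats::rnorm(m); e <- stats::rnorm(m)
      eta <- b_G * g + b_E * e + b_GE * g * e
      if (mechanism == "logit") {
        if (is.null(b0)) {
          b0 <<- calibrate_intercept(b_G, b_E, b_GE, K, n_mc = 1e5,
                                     seed = NULL,
                                     z_G = stats::rnorm(1e5),
                                     z_E = stats::rnorm(1e5))$b0
        }
        y <- as.integer(stats::runif(m) < expit(b0 + eta))
      } else {
        resid <- 1 - b_G^2 - b_E^2 - b_GE^2
        if (resid <= 0) stop("liability residual variance <= 0")
        liab <- eta + stats::rnorm(m, 0, sqrt(resid))
        y <- as.integer(liab > stats::qnorm(1 - K))
      }
      data.frame(g = g, e = e, status = y)
    }
    if (is.null(case_control_ratio)) {
      draw_status(n)
    } else {
      n_case <- round(n * case_control_ratio / (1 + case_control_ratio))
      n_ctrl <- n - n_case
      cases <- list(); ctrls <- list()
      got_case <- 0L; got_ctrl <- 0L
      drawn <- 0L
      cap <- max_draw_factor * (n_case / K + n_ctrl)
      while ((got_case < n_case || got_ctrl < n_ctrl) && drawn < cap) {
        m <- min(50000L, ceiling(cap - drawn))
        d <- draw_status(m)
        drawn <- drawn + m
        if (got_case < n_case) {
          take <- d[d$status == 1L, , drop = FALSE]
          take <- take[seq_len(min(nrow(take), n_case - got_case)), ,
                       drop = FALSE]
          cases[[length(cases) + 1L]] <- take
          got_case <- got_case + nrow(take)
        }
        if (got_ctrl < n_ctrl) {
          take <- d[d$status == 0L, , drop = FALSE]
          take <- take[seq_len(min(nrow(take), n_ctrl - got_ctrl)), ,
                       drop = FALSE]
          ctrls[[length(ctrls) + 1L]] <- take
          got_ctrl <- got_ctrl + nrow(take)
        }
      }
      if (got_case < n_case || got_ctrl < n_ctrl) {
        stop(sprintf("quota unreachable after %d draws (%d cases, %d controls short)",
                     drawn, n_case - got_case, n_ctrl - got_ctrl))
      }
      out <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
      rownames(out) <- NULL
      out
    }
  }
  if (is.na(seed)) run() else with_seed(seed, run())
}

#' Power configuration for simulation-based interaction tests
#'
#' @param b_G,b_E,b_GE standardized generating coefficients.
#' @param K population prevalence.
#' @param n total sample size per replicate.
#' @param case_control_ratio cases:controls ratio (default 717/356); `NULL`
#'   for population sampling.
#' @param n_reps Monte-Carlo replicates (>= 100 for reported results).
#' @param alpha two-sided significance level.
#' @param test `"multiplicative"` (Wald p on the product term) or
#'   `"additive"` (delta-method RERI CI excludes zero).
#' @param mechanism passed to [simulate_ge_cohort()].
#' @param seed RNG seed.
#' @return object of class `power_config`.
#' @export
power_config <- function(b_G, b_E, b_GE, K = 0.01, n = 1073L,
                         case_control_ratio = 717 / 356,
                         n_reps = 500L, alpha = 0.05,
                         test = c("multiplicative", "additive"),
                         mechanism = c("logit", "liability"),
                         seed = 1L) {
  test <- match.arg(test)
  mechanism <- match.arg(mechanism)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (n_reps < 1) stop("`n_reps` must be positive")
  structure(
    list(b_G = b_G, b_E = b_E, b_GE = b_GE, K = K, n = as.integer(n),
         case_control_ratio = case_control_ratio,
         n_reps = as.integer(n_reps), alpha = alpha, test = test,
         mechanism = mechanism, seed = as.integer(seed)),
    class = "power_config"
  )
}

#' Monte-Carlo power of a gene-environment interaction test
#'
#' Per replicate: simulate a cohort from the configured generative model,
#' refit the interaction logistic model (G, E, G x E), and record success —
#' Wald p-value below alpha on the product term for the multiplicative test,
#' or a delta-method RERI interval excluding zero for the additive test.
#' Power is the success fraction, with Monte-Carlo standard error
#' `sqrt(p(1-p)/n_reps)`. Replicates whose refit fails are counted; more
#' than 10% failures is an error.
#'
#' @param config a [power_config()].
#' @return object of class `power_result`: list with `power`, `mc_se`, `n`,
#'   `test`, `n_reps`, `n_failed`.
#' @export
estimate_power <- function(config) {
  stopifnot(inherits(config, "power_config"))
  b0 <- if (config$mechanism == "logit") {
    calibrate_intercept(config$b_G, config$b_E, config$b_GE, config$K,
                        n_mc = 1e5,
                        seed = substream_seed(config$seed, "power-calib"))$b0
  } else NULL
  crit <- stats::qnorm(1 - config$alpha / 2)
  res <- with_seed(substream_seed(config$seed, "power-reps"), {
    vapply(seq_len(config$n_reps), function(r) {
      d <- simulate_ge_cohort(config$n, config$b_G, config$b_E, config$b_GE,
                              K = config$K, b0 = b0,
                              case_control_ratio = config$case_control_ratio,
                              mechanism = config$mechanism, seed = NA)
      tryCatch({
        X <- cbind(g = d$g, e = d$e, `g:e` = d$g * d$e)
        fit <- fit_logistic(X, d$status, conf_level = 1 - config$alpha)
        if (config$test == "multiplicative") {
          z <- fit$coef[["g:e"]] / sqrt(fit$vcov["g:e", "g:e"])
          as.numeric(abs(z) > crit)
        } else {
          fit$term_map <- list(g = "g", e = "e", ge = "g:e")
          rr <- reri_delta(fit)
          as.numeric(rr$ci[1] > 0 || rr$ci[2] < 0)
        }
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  n_fail <- sum(is.na(res))
  if (n_fail > 0.1 * config$n_reps) {
    stop(sprintf("power simulation unstable: %d of %d replicate refits failed",
                 n_fail, config$n_reps))
  }
  ok <- res[!is.na(res)]
  p_hat <- mean(ok)
  structure(
    list(power = p_hat, mc_se = sqrt(p_hat * (1 - p_hat) / length(ok)),
         n = config$n, test = config$test, n_reps = length(ok),
         n_failed = n_fail, config = config),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%s-test power at n = %d: %.3f (MC SE %.3f, %d replicates, %d failed)\n",
              x$test, x$n, x$power, x$mc_se, x$n_reps, x$n_failed))
  invisible(x)
}

#' Minimum sample size reaching a target power
#'
#' Evaluates [estimate_power()] along a sorted grid of sample sizes using a
#' doubling bracket followed by bisection on the grid indices (power is
#' assumed monotone in n up to Monte-Carlo error), and returns the smallest
#' grid n whose estimated power meets the target, together with the curve of
#' all evaluated points.
#'
#' @param config a [power_config()]; its `n` is ignored.
#' @param target_power target in (0, 1), default 0.8.
#' @param n_grid sorted ascending vector of candidate sample sizes.
#' @return list with `n` (smallest adequate grid size) and `curve`
#'   (data.frame n, power, mc_se for every evaluated point).
#' @export
min_n_for_power <- function(config, target_power = 0.8, n_grid) {
  if (target_power <= 0 || target_power >= 1) stop("target must lie in (0, 1)")
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop("`n_grid` must be sorted strictly ascending")
  }
  evaluated <- new.env()
  pw <- function(i) {
    key <- as.character(i)
    if (is.null(evaluated[[key]])) {
      cfg <- config
      cfg$n <- as.integer(n_grid[i])
      cfg$seed <- substream_seed(config$seed, paste0("minn-", n_grid[i]))
      evaluated[[key]] <- estimate_power(cfg)
    }
    evaluated[[key]]$power
  }
  # doubling bracket
  i <- 1L
  if (pw(1L) < target_power) {
    repeat {
      nxt <- min(2L * i, length(n_grid))
      if (pw(nxt) >= target_power) { hi <- nxt; lo <- i; break }
      if (nxt == length(n_grid)) {
        best <- max(vapply(ls(evaluated), function(k) evaluated[[k]]$power,
                           numeric(1)))
        stop(sprintf("target power %.2f unreachable on grid (max achieved %.3f)",
                     target_power, best))
      }
      i <- nxt
    }
    # bisect on grid indices
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (pw(mid) >= target_power) hi <- mid else lo <- mid
    }
    ans <- hi
  } else {
    ans <- 1L
  }
  curve <- do.call(rbind, lapply(sort(as.integer(ls(evaluated))), function(i) {
    r <- evaluated[[as.character(i)]]
    data.frame(n = r$n, power = r$power, mc_se = r$mc_se)
  }))
  list(n = n_grid[ans], curve = curve)
}
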