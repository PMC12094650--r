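pipeline_defaults <- function() {
  list(
    master_seed = 1L,
    output_dir = "geiprs_output",
    write_genotypes = FALSE,
    stages = list(simulate = TRUE, prs = TRUE, env_score = TRUE,
                  associate = TRUE, interact = TRUE, subgroup = TRUE,
                  metrics = TRUE, power = TRUE),
    simulation = list(M = 2000L, n_ref = 500L, block_size = 50L, rho = 0.6,
                      maf_range = c(0.05, 0.5), h2 = 0.3, p_causal = 0.03,
                      N_gwas = 50000L, K = 0.01, n_case = 717L,
                      n_control = 356L, coef_G = 0.7, coef_E = 1.0,
                      coef_GE = 0.3, mechanism = "logit"),
    prs = list(p_grid = default_p_grid(), n_iter = 150L, burn_in = 50L,
               lambda = 0.01, h2 = NULL, w_bound = 5),
    env = list(weight_table = NULL),
    association = list(covariates = c("age", "sex", "education"),
                       quantiles = c(0.75, 0.5, 0.25)),
    interaction = list(bootstrap = FALSE, bootstrap_B = 1000L),
    power = list(n_reps = 200L, alpha = 0.05)
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), rejects unknown keys with their
#' full path, injects defaults for everything omitted, and checks the
#' resulting simulation block by constructing its [sim_config()].
#'
#' @param config path to a YAML file, or a (possibly partial) named list.
#' @return validated config of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  if (inherits(config, "pipeline_config")) return(config)
  defaults <- pipeline_defaults()
  merge_checked <- function(def, got, path = "") {
    if (length(got) == 0) return(def)
    unknown <- setdiff(names(got), names(def))
    if (length(unknown)) {
      stop("unknown config key: ",
           paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
    }
    for (nm in names(got)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_checked(def[[nm]], got[[nm]],
                                   paste0(path, ".", nm))
      } else {
        def[[nm]] <- got[[nm]]
      }
    }
    def
  }
  cfg <- merge_checked(defaults, config)
  cfg$simulation$maf_range <- as.numeric(unlist(cfg$simulation$maf_range))
  cfg$prs$p_grid <- as.numeric(unlist(cfg$prs$p_grid))
  cfg$association$quantiles <- as.numeric(unlist(cfg$association$quantiles))
  # constructing the sim config validates the whole simulation block
  invisible(do.call(sim_config, c(list(master_seed = cfg$master_seed),
                                  cfg$simulation)))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates every stage end to end: simulate (panel, summary statistics,
#' ascertained cohort), prs (LD estimation, point-normal Gibbs reweighting
#' over the causal-fraction grid, AUC-based selection, covariate
#' adjustment, LD score regression), env-score (weighted domain total and
#' reversed trauma total), associate (the four logistic model types for each
#' environmental measure, information criteria, covariate-interaction
#' sensitivity models, gene-environment correlation screen), interact
#' (multiplicative OR and delta-method RERI), subgroup (control-quantile
#' dichotomization at 75/50/25%), metrics (AUC and liability-scale R2), and
#' power (post hoc simulation from the fitted standardized coefficients).
#' Every random stage is seeded from the master seed, so an identical config
#' yields a byte-identical report.
#'
#' @param config a [validate_config()] result, a path to a YAML config, or a
#'   partial list of overrides.
#' @param output_dir overrides the config's output directory.
#' @return (invisibly) the report list; per-stage TSV/CSV/JSON files plus
#'   `report.json` are written under the output directory.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  cfg <- validate_config(config)
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                               sprintf(...))
  report <- list(package_version = as.character(utils::packageVersion("geiprs")),
                 master_seed = cfg$master_seed)
  state <- new.env()
  need <- function(what, stage) {
    if (is.null(state[[what]])) {
      stop(sprintf("stage '%s' requires outputs of a disabled upstream stage ('%s' missing)",
                   stage, what))
    }
    state[[what]]
  }

  if (isTRUE(cfg$stages$simulate)) {
    msg("stage simulate")
    sc <- do.call(sim_config, c(list(master_seed = cfg$master_seed),
                                cfg$simulation))
    panel <- simulate_panel(sc)
    truth <- simulate_sumstats(panel, sc)
    cohort_sim <- simulate_cohort(panel, truth, sc)
    state$sc <- sc; state$panel <- panel; state$truth <- truth
    state$cohort_sim <- cohort_sim
    state$cohort <- cohort_sim$cohort
    write_sumstats(truth$sumstats, file.path(out_dir, "sumstats.tsv"))
    write_cohort(cohort_sim$cohort, file.path(out_dir, "cohort.csv"))
    if (isTRUE(cfg$write_genotypes) && !is.null(cohort_sim$dosage)) {
      write_genotypes(cohort_sim$dosage, file.path(out_dir, "genotypes.tsv"))
    }
    jsonlite::write_json(
      list(beta_true = truth$beta_true, causal = truth$causal,
           b0 = cohort_sim$truth$b0, coef = as.list(cohort_sim$truth$coef),
           master_seed = cfg$master_seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    report$simulate <- list(
      n_case = sum(cohort_sim$cohort$status == 1),
      n_control = sum(cohort_sim$cohort$status == 0),
      M = sc$M, b0 = cohort_sim$truth$b0,
      n_drawn = cohort_sim$truth$n_drawn)
  }

  if (isTRUE(cfg$stages$prs)) {
    msg("stage prs")
    panel <- need("panel", "prs"); truth <- need("truth", "prs")
    cohort_sim <- need("cohort_sim", "prs")
    cohort <- need("cohort", "prs")
    ld <- estimate_ld(panel, lambda = cfg$prs$lambda)
    aligned <- align_alleles(truth$sumstats, panel)
    ldsc <- ldsc_h2(aligned$sumstats, ld)
    h2_use <- cfg$prs$h2 %||% max(ldsc$h2, 0.01)
    analysis_panel <- structure(
      list(dosage = cohort_sim$dosage, variants = panel$variants),
      class = "genotype_panel")
    candidates <- lapply(cfg$prs$p_grid, function(p) {
      ldpred_gibbs_weights(
        aligned$sumstats, ld, h2 = h2_use, p = p,
        n_iter = cfg$prs$n_iter, burn_in = cfg$prs$burn_in,
        seed = substream_seed(cfg$master_seed, paste0("gibbs-", p)),
        w_bound = cfg$prs$w_bound)
    })
    sel <- select_p_by_auc(candidates, analysis_panel, cohort$status)
    scores <- sel$scores
    scores$adjusted <- residualize_covariates(
      scores$standardized, cohort[, c("age", "sex")])
    cohort$prs_raw <- scores$raw
    cohort$prs_z <- scores$standardized
    cohort$prs_adj <- scores$adjusted
    state$cohort <- cohort
    state$ldsc <- ldsc; state$sel <- sel
    write_weights(sel$best, aligned$sumstats,
                  file.path(out_dir, "weights.tsv"))
    write_scores(scores, file.path(out_dir, "scores.csv"))
    utils::write.table(sel$auc_table, file.path(out_dir, "p_grid_auc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$prs <- list(
      ldsc_h2 = ldsc$h2, ldsc_h2_se = ldsc$se, ldsc_intercept = ldsc$intercept,
      h2_used = h2_use, selected_p = sel$best$p,
      auc_by_p = stats::setNames(as.list(sel$auc_table$auc),
                                 paste0("p_", sel$auc_table$p)),
      alignment = aligned$report)
  }

  if (isTRUE(cfg$stages$env_score)) {
    msg("stage env-score")
    cohort <- need("cohort", "env_score")
    wt <- if (is.null(cfg$env$weight_table)) default_weight_table() else {
      load_weight_table(cfg$env$weight_table)
    }
    pt <- pers_total(cohort, wt)
    cohort$pers_total <- pt$total
    cohort$pers_total_z <- standardize_scores(pt$total)
    et <- eti_total(cohort)
    cohort$eti_total <- et$total
    cohort$eti_total_z <- standardize_scores(et$total)
    state$cohort <- cohort
    write_cohort(cohort, file.path(out_dir, "cohort_scored.csv"))
    report$env_score <- list(
      pers_mean_case = mean(cohort$pers_total[cohort$status == 1], na.rm = TRUE),
      pers_mean_control = mean(cohort$pers_total[cohort$status == 0], na.rm = TRUE),
      eti_mean_case = mean(cohort$eti_total[cohort$status == 1], na.rm = TRUE),
      eti_mean_control = mean(cohort$eti_total[cohort$status == 0], na.rm = TRUE))
  }

  env_measures <- c(pers = "pers_total", eti = "eti_total")

  if (isTRUE(cfg$stages$associate)) {
    msg("stage associate")
    cohort <- need("cohort", "associate")
    covs <- cfg$association$covariates
    fits <- list(); rows <- list()
    for (em in names(env_measures)) {
      for (mt in c("genetic", "environmental", "independent", "interaction")) {
        spec <- model_spec(mt, g_term = "prs_adj", e_term = env_measures[[em]],
                           covariates = covs)
        fit <- fit_model_spec(cohort, spec)
        ic <- information_criteria(fit)
        model_id <- paste(em, mt, sep = "_")
        fits[[model_id]] <- fit
        tt <- fit$terms
        tt$model <- model_id
        tt$nagelkerke_r2 <- nagelkerke_r2(fit)
        tt$aic <- ic[["aic"]]; tt$bic <- ic[["bic"]]; tt$n <- fit$n
        rows[[model_id]] <- tt
        if (mt == "interaction") {
          ext_spec <- model_spec(mt, g_term = "prs_adj",
                                 e_term = env_measures[[em]],
                                 covariates = covs,
                                 covariate_interactions = covs)
          ext_fit <- fit_model_spec(cohort, ext_spec)
          fits[[paste0(model_id, "_covint")]] <- ext_fit
        }
      }
    }
    results <- do.call(rbind, rows)
    results$fdr_p <- bh_fdr(results$p)
    utils::write.table(results, file.path(out_dir, "association_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    screen <- ge_correlation_screen(cohort, prs_col = "prs_adj",
                                    covariates = covs)
    utils::write.table(screen, file.path(out_dir, "ge_correlation_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$fits <- fits
    report$associate <- list(
      n_models = length(fits),
      nagelkerke_r2 = lapply(rows, function(tt) tt$nagelkerke_r2[1]),
      aic = lapply(fits, function(f) unname(information_criteria(f)[["aic"]])),
      bic = lapply(fits, function(f) unname(information_criteria(f)[["bic"]])),
      ge_screen_min_fdr_p = if (nrow(screen)) min(screen$fdr_p) else NA)
  }

  if (isTRUE(cfg$stages$interact)) {
    msg("stage interact")
    fits <- need("fits", "interact")
    inter <- list()
    for (em in names(env_measures)) {
      fit <- fits[[paste0(em, "_interaction")]]
      mult <- multiplicative_interaction(fit)
      rd <- reri_delta(fit)
      inter[[em]] <- list(
        mult_or = mult$or, mult_ci = mult$ci, mult_p = mult$p,
        reri = rd$reri, reri_ci = rd$ci, reri_p = rd$p,
        or10 = rd$or10, or01 = rd$or01, or11 = rd$or11)
      if (isTRUE(cfg$interaction$bootstrap)) {
        cohort <- need("cohort", "interact")
        rb <- reri_bootstrap(
          cohort, model_spec("interaction", g_term = "prs_adj",
                             e_term = env_measures[[em]],
                             covariates = cfg$association$covariates),
          B = cfg$interaction$bootstrap_B,
          seed = substream_seed(cfg$master_seed, paste0("boot-", em)))
        inter[[em]]$reri_boot_ci <- rb$ci
      }
    }
    tab <- do.call(rbind, lapply(names(inter), function(em) {
      x <- inter[[em]]
      data.frame(measure = em, mult_or = x$mult_or,
                 mult_ci_low = x$mult_ci[1], mult_ci_high = x$mult_ci[2],
                 mult_p = x$mult_p, reri = x$reri,
                 reri_ci_low = x$reri_ci[1], reri_ci_high = x$reri_ci[2],
                 reri_p = x$reri_p)
    }))
    utils::write.table(tab, file.path(out_dir, "interaction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$interact <- inter
  }

  if (isTRUE(cfg$stages$subgroup)) {
    msg("stage subgroup")
    cohort <- need("cohort", "subgroup")
    sub <- list()
    for (em in names(env_measures)) {
      for (q in cfg$association$quantiles) {
        ctrl <- cohort$status == 0
        gh <- dichotomize_by_control_quantile(cohort$prs_adj, ctrl, q)
        eh <- dichotomize_by_control_quantile(cohort[[env_measures[[em]]]],
                                              ctrl, q)
        tab <- subgroup_or_table(cohort, gh$high, eh$high,
                                 covariates = cfg$association$covariates)
        key <- sprintf("%s_q%d", em, round(100 * q))
        sub[[key]] <- as.list(stats::setNames(tab$or, tab$cell))
        sub[[key]]$n <- as.list(stats::setNames(tab$n, paste0("n_", tab$cell)))
        utils::write.table(as.data.frame(tab),
                           file.path(out_dir, paste0("subgroup_", key, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    report$subgroup <- sub
  }

  if (isTRUE(cfg$stages$metrics)) {
    msg("stage metrics")
    cohort <- need("cohort", "metrics")
    fits <- need("fits", "metrics")
    K <- cfg$simulation$K
    P <- mean(cohort$status == 1)
    lp <- liability_params(K = K, P = P)
    metric_of <- function(scores) {
      a <- max(auc(scores, cohort$status), 0.5)
      list(auc = a, liability_r2_from_auc = auc_to_liability_r2(a, lp))
    }
    metrics <- list(K = K, P = P)
    metrics$prs_only <- metric_of(cohort$prs_adj)
    for (em in names(env_measures)) {
      fit <- fits[[paste0(em, "_interaction")]]
      d <- build_design(cohort, fit$spec)
      eta <- drop(cbind(1, d$X) %*% fit$coef)
      m <- list(auc = auc(eta, d$y))
      m$liability_r2_from_auc <- auc_to_liability_r2(max(m$auc, 0.5), lp)
      m$nagelkerke_r2 <- nagelkerke_r2(fit)
      m$liability_r2_from_nagelkerke <-
        nagelkerke_to_liability_r2(m$nagelkerke_r2, lp)
      metrics[[paste0("combined_", em)]] <- m
    }
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    report$metrics <- metrics
  }

  if (isTRUE(cfg$stages$power)) {
    msg("stage power")
    fits <- need("fits", "power")
    cohort <- need("cohort", "power")
    fit <- fits[["pers_interaction"]]
    b <- fit$coef
    tm <- fit$term_map
    n_case <- sum(cohort$status == 1); n_ctrl <- sum(cohort$status == 0)
    pw <- list()
    for (test in c("multiplicative", "additive")) {
      pc <- power_config(
        b_G = b[[tm$g]], b_E = b[[tm$e]], b_GE = b[[tm$ge]],
        K = cfg$simulation$K, n = n_case + n_ctrl,
        case_control_ratio = n_case / n_ctrl,
        n_reps = cfg$power$n_reps, alpha = cfg$power$alpha, test = test,
        seed = substream_seed(cfg$master_seed, paste0("power-", test)))
      pr <- estimate_power(pc)
      pw[[test]] <- list(power = pr$power, mc_se = pr$mc_se, n = pr$n,
                         n_reps = pr$n_reps)
    }
    pw$coefficients <- list(b_G = b[[tm$g]], b_E = b[[tm$e]],
                            b_GE = b[[tm$ge]])
    jsonlite::write_json(pw, file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA)
    report$power <- pw
  }

  report$config <- unclass(cfg)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  msg("pipeline complete: %s", out_dir)
  invisible(report)
}
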