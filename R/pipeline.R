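# Orchestration: simulate (or load) a paired-cohort study, compute climate
# changes and effect sizes, run the pairwise and all-subsets analyses, the
# leaf-economics axis and the ancillary regressions, and write a
# reproducible artefact bundle.

#' Pipeline run configuration
#'
#' Collects everything [run_all()] needs.  By default the pipeline runs on
#' synthetic data: per-species site climates are simulated with
#' species-varying warming offsets, precipitation trends, variability
#' inflation and hot-tail boosts, and trait cohorts are generated from the
#' configured slopes.
#'
#' @param seed master integer seed; all per-species seeds derive from it.
#' @param out_dir output directory for the artefact bundle.
#' @param n_species number of species pairs.
#' @param traits trait names to simulate and analyse.
#' @param slopes named list (by trait) of named slope vectors, or a single
#'   named vector applied to all traits (see [trait_sim_config()]).
#' @param intercept_alpha,species_sd_tau,cohort_cv,n_hist,n_mod,
#'   storage_bias_delta,missing_prob forwarded to [trait_sim_config()].
#' @param unweighted_traits traits without within-era replication (pooled
#'   assays); excluded from the variance-weighted pairwise and selection
#'   analyses but kept for the economics matrix.  Default `"leaf_n"`.
#' @param econ_traits length-3 named mapping for [econ_matrix()].
#' @param moderators_pairwise moderators for the pairwise regressions.
#' @param max_terms per-model moderator cap for the all-subsets search.
#' @param alpha significance level.
#' @param n_years climate window length in years.
#' @param warming_range,precip_ratio_range,sd_mult_range,boost_range numeric
#'   length-2 ranges the per-species site shifts are drawn from.
#' @param gap_years_range integer range of collection gaps (study: 29-40).
#' @param method coefficient estimation method for all meta-regressions.
#' @return list of class `ccre_run_config`.
#' @export
run_config <- function(seed = 1L,
                       out_dir = tempfile("ccre_run_"),
                       n_species = 32L,
                       traits = c("leaf_area", "sla", "asat", "leaf_n"),
                       slopes = list(
                         leaf_area = c(mean_temp = -0.03),
                         sla = c(mean_temp = 0.02, mean_precip = 0.05),
                         asat = c(),
                         leaf_n = c(mean_precip = 0.03)),
                       intercept_alpha = 0,
                       species_sd_tau = 0.05,
                       cohort_cv = 0.2,
                       n_hist = 10L, n_mod = 10L,
                       storage_bias_delta = 0,
                       missing_prob = 0.08,
                       unweighted_traits = "leaf_n",
                       econ_traits = c(delta_sla = "sla",
                                       delta_asat = "asat",
                                       delta_n = "leaf_n"),
                       moderators_pairwise = c("mean_temp", "mean_precip"),
                       max_terms = Inf,
                       alpha = 0.05,
                       n_years = 5L,
                       warming_range = c(0, 2),
                       precip_ratio_range = c(0.75, 1.3),
                       sd_mult_range = c(0.95, 1.2),
                       boost_range = c(0, 2),
                       gap_years_range = c(29L, 40L),
                       method = "REML") {
  stopifnot(length(traits) >= 1L, alpha > 0, alpha < 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "ccre_run_config")
}

#' Simulate a full synthetic study
#'
#' Draws per-species site climate shifts from the configured ranges,
#' simulates paired daily weather, computes the twelve climate-change
#' metrics per species, and generates paired trait cohorts whose true lnRR
#' depends linearly on the climate deltas.
#'
#' @param config a [run_config()].
#' @return list with `changes` (wide species x metric table), `trait_data`
#'   (tidy measurements), `truth` (generator sidecar), `metadata`
#'   (species-level covariates), `site_params`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "ccre_run_config"))
  set.seed(config$seed)
  n <- config$n_species
  species <- sprintf("sp%02d", seq_len(n))
  site <- data.frame(
    species = species,
    warming_offset = stats::runif(n, config$warming_range[1],
                                  config$warming_range[2]),
    precip_trend_ratio = stats::runif(n, config$precip_ratio_range[1],
                                      config$precip_ratio_range[2]),
    temp_sd_multiplier = stats::runif(n, config$sd_mult_range[1],
                                      config$sd_mult_range[2]),
    hot_extreme_boost = stats::runif(n, config$boost_range[1],
                                     config$boost_range[2]),
    gap_years = sample(seq(config$gap_years_range[1],
                           config$gap_years_range[2]), n, replace = TRUE),
    baseline_mean_temp = stats::runif(n, 12, 22),
    precip_daily_mean = stats::runif(n, 1.2, 4),
    seed = (config$seed %% 1000000L) * 1000L + seq_len(n),
    stringsAsFactors = FALSE)
  change_list <- lapply(seq_len(n), function(i) {
    ccfg <- climate_sim_config(
      baseline_mean_temp = site$baseline_mean_temp[i],
      warming_offset = site$warming_offset[i],
      temp_sd_multiplier = site$temp_sd_multiplier[i],
      hot_extreme_boost = site$hot_extreme_boost[i],
      precip_daily_mean = site$precip_daily_mean[i],
      precip_trend_ratio = site$precip_trend_ratio[i],
      years_per_window = config$n_years,
      gap_years = site$gap_years[i],
      seed = site$seed[i])
    sim <- generate_daily_climate(ccfg)
    compute_all_changes(sim$historic, sim$modern, sim$historic_date,
                        sim$modern_date, n_years = config$n_years)
  })
  names(change_list) <- species
  changes <- changes_wide(change_list)
  tcfg <- trait_sim_config(
    n_species = n, traits = config$traits, slopes = config$slopes,
    intercept_alpha = config$intercept_alpha,
    species_sd_tau = config$species_sd_tau, cohort_cv = config$cohort_cv,
    n_hist = config$n_hist, n_mod = config$n_mod,
    storage_bias_delta = config$storage_bias_delta,
    missing_prob = config$missing_prob,
    seed = config$seed + 7777L)
  cohorts <- generate_trait_cohorts(changes, tcfg)
  metadata <- generate_species_metadata(species, seed = config$seed + 99L)
  list(changes = changes, trait_data = cohorts$data, truth = cohorts$truth,
       metadata = metadata, site_params = site)
}

#' Pairwise trait-change vs mean-climate meta-regressions
#'
#' For each trait, one single-moderator variance-weighted meta-regression
#' per moderator (default: change in mean temperature and in mean
#' precipitation), with the intercept diagnostic attached.  Traits with
#' fewer than 3 complete-case species are skipped with a message.
#'
#' @param effects effect-size data frame with a `trait` column.
#' @param changes wide species x metric change table.
#' @param moderators moderator names (default the two means).
#' @param alpha significance level for flags.
#' @param method estimation method (default REML).
#' @return data frame, one row per trait x moderator.
#' @export
run_pairwise <- function(effects, changes,
                         moderators = c("mean_temp", "mean_precip"),
                         alpha = 0.05, method = "REML") {
  if ("usable" %in% names(effects)) effects <- effects[effects$usable, ]
  rows <- list()
  for (tr in unique(effects$trait)) {
    ef <- effects[effects$trait == tr, ]
    for (mo in moderators) {
      dat <- merge(ef[, c("species", "yi", "vi")],
                   changes[, c("species", mo)], by = "species")
      dat <- dat[stats::complete.cases(dat), ]
      if (nrow(dat) < 3L) {
        message(sprintf("trait '%s' x '%s': k = %d < 3, skipped",
                        tr, mo, nrow(dat)))
        next
      }
      X <- cbind(intrcpt = 1, dat[[mo]])
      colnames(X)[2] <- mo
      fit <- fit_meta_regression(dat$yi, dat$vi, X, method = method)
      ic <- intercept_diagnostic(fit, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, moderator = mo, k = fit$k,
        slope = unname(fit$beta[mo]), se = unname(fit$se[mo]),
        zval = unname(fit$zval[mo]), p = unname(fit$pval[mo]),
        significant = unname(fit$pval[mo]) < alpha,
        pseudo_R2 = fit$pseudo_R2, tau2 = fit$tau2,
        intercept = ic$estimate, intercept_p = ic$p,
        intercept_significant = ic$significant,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' All-subsets selection for every trait
#'
#' @param effects effect-size data frame with a `trait` column.
#' @param changes wide species x metric change table.
#' @param traits traits to analyse (default: all present).
#' @param max_terms per-model moderator cap.
#' @param method estimation method.
#' @return list with `results` (named list of `ccre_model_selection`) and
#'   `table` (the [importance_table()] assembly).
#' @export
run_selection <- function(effects, changes, traits = NULL, max_terms = Inf,
                          method = "REML") {
  if ("usable" %in% names(effects)) effects <- effects[effects$usable, ]
  if (is.null(traits)) traits <- unique(effects$trait)
  results <- lapply(traits, function(tr) {
    enumerate_and_fit(effects[effects$trait == tr, ], changes,
                      max_terms = max_terms, method = method)
  })
  names(results) <- traits
  list(results = results, table = importance_table(results))
}

#' Ancillary ordinary-least-squares regressions
#'
#' Unweighted OLS of `ln(overall_change)` on each species-level covariate
#' separately (growth form, reproductive-maturity age, lifespan, CO2
#' change).  Adjusted R-squared may legitimately be negative.  Covariates
#' with fewer than 3 complete cases are skipped.
#'
#' @param overall data frame from [overall_species_change()].
#' @param metadata species-level covariate table.
#' @param covariates covariate column names.
#' @return data frame `covariate, n, adj_R2, p` (overall F-test p).
#' @export
ancillary_regression <- function(overall, metadata,
                                 covariates = c("growth_form",
                                                "maturity_age", "lifespan",
                                                "co2_lnrr")) {
  dat <- merge(overall, metadata, by = "species")
  dat <- dat[is.finite(dat$overall_change) & dat$overall_change > 0, ]
  dat$log_change <- log(dat$overall_change)
  rows <- list()
  for (cv in covariates) {
    sub <- dat[stats::complete.cases(dat[, c("log_change", cv)]), ]
    if (nrow(sub) < 3L || length(unique(sub[[cv]])) < 2L) {
      message(sprintf("ancillary covariate '%s': insufficient data, skipped",
                      cv))
      next
    }
    if (stats::var(sub$log_change) == 0) {
      # degenerate response: no variance to explain
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, n = nrow(sub), adj_R2 = 0, p = 1,
        stringsAsFactors = FALSE)
      next
    }
    fit <- stats::lm(stats::reformulate(cv, "log_change"), data = sub)
    sm <- summary(fit)
    p <- if (is.null(sm$fstatistic)) NA_real_ else {
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv, n = nrow(sub), adj_R2 = sm$adj.r.squared,
      p = unname(p), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis and write the artefact bundle
#'
#' Executes climate simulation (or ingestion), effect sizes, pairwise
#' regressions, all-subsets selection, the leaf-economics axis and the
#' ancillary regressions, and writes every table plus a machine-readable
#' manifest (seeds, decisions, versions) to `config$out_dir`.  Outputs are
#' byte-stable for a fixed seed.
#'
#' @param config a [run_config()]; if `config$inputs` is a list with
#'   elements `changes`, `trait_data` and `metadata` (data frames), those
#'   are used instead of simulation.
#' @return invisibly, a list with all intermediate objects and the output
#'   paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "ccre_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- if (!is.null(config$inputs)) config$inputs else
    simulate_study(config)

  eff <- effect_sizes(study$trait_data)
  weighted <- setdiff(config$traits, config$unweighted_traits)
  eff_w <- eff[eff$trait %in% weighted, ]

  pw <- run_pairwise(eff_w, study$changes,
                     moderators = config$moderators_pairwise,
                     alpha = config$alpha, method = config$method)
  sel <- run_selection(eff_w, study$changes, traits = weighted,
                       max_terms = config$max_terms, method = config$method)

  # leaf-economics axis
  M <- econ_matrix(eff, traits = config$econ_traits)
  Mc <- impute_pca(M, n_comp = 1L)
  pca <- econ_pca(Mc, scale_columns = FALSE)
  horn <- horn_parallel(Mc, n_iter = 500L, percentile_rule = "mean",
                        seed = config$seed + 17L)
  scores <- econ_scores_as_response(pca,
                                    components = seq_len(min(2L,
                                                             ncol(pca$scores))))
  econ_eff <- do.call(rbind, lapply(
    grep("^PC", names(scores), value = TRUE), function(pc) {
      data.frame(species = scores$species, trait = paste0("econ_", pc),
                 yi = scores[[pc]], vi = 1, usable = TRUE, reason = "",
                 stringsAsFactors = FALSE)
    }))
  econ_pw <- run_pairwise(econ_eff, study$changes,
                          moderators = config$moderators_pairwise,
                          alpha = config$alpha, method = config$method)

  overall <- overall_species_change(eff)
  anc <- ancillary_regression(overall, study$metadata)

  # ---- write bundle ----
  out <- function(f) file.path(config$out_dir, f)
  write_stable_csv(study$changes, out("climate_changes.csv"))
  write_stable_csv(eff, out("effect_sizes.csv"))
  write_stable_csv(pw, out("pairwise.csv"))
  models <- do.call(rbind, lapply(names(sel$results), function(tr) {
    cbind(trait = tr, sel$results[[tr]]$models)
  }))
  write_stable_csv(models, out("selection_models.csv"))
  imp <- data.frame(metric = rownames(sel$table$importance),
                    group = unname(sel$table$groups),
                    sel$table$importance, stringsAsFactors = FALSE)
  write_stable_csv(imp, out("importance_matrix.csv"))
  write_stable_csv(sel$table$best, out("best_models.csv"))
  write_stable_csv(data.frame(species = rownames(Mc), Mc),
                   out("econ_completed.csv"))
  write_stable_csv(scores, out("econ_scores.csv"))
  write_stable_csv(econ_pw, out("econ_pairwise.csv"))
  writeLines(c(sprintf("retained_components: %d", horn$retained),
               sprintf("rule: %s", horn$rule),
               sprintf("explained_pct: %s",
                       paste(formatC(pca$explained, digits = 10,
                                     format = "g"), collapse = ","))),
             out("econ_retention.txt"))
  write_stable_csv(overall, out("overall_change.csv"))
  write_stable_csv(anc, out("ancillary.csv"))
  manifest <- list(
    package = "ccre",
    version = as.character(utils::packageVersion("ccre")),
    seed = config$seed,
    n_species = config$n_species,
    traits = config$traits,
    weighted_traits = weighted,
    method = config$method,
    max_terms = if (is.finite(config$max_terms)) config$max_terms else
      "unlimited",
    alpha = config$alpha,
    decisions = list(
      scalings = as.list(metric_scaling()),
      duration_offset = "+1 day inside duration log-ratios",
      heatwave = list(window_len = 3, pct = 0.95, accl_days = 30,
                      min_run = 3),
      drought = list(agg_days = 30, pct = 0.10),
      month_prior = "30-day trailing window before each anniversary",
      imputation_rank = 1,
      pca_scale_columns = FALSE,
      averaging = "zero-substitution",
      aicc_likelihood = "ML"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(study = study, effects = eff, pairwise = pw,
                 selection = sel, econ = list(matrix = M, completed = Mc,
                                              pca = pca, horn = horn,
                                              pairwise = econ_pw),
                 overall = overall, ancillary = anc,
                 out_dir = config$out_dir))
}
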