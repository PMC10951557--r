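# Synthetic paired climate series and trait cohorts with known ground
# truth.  This is the stand-in for the study design's real inputs: daily
# gridded weather at each collection site and paired historic/modern
# seed-cohort trait measurements.  Every generator is governed by a single
# integer seed and is bit-reproducible.

#' Climate simulation configuration
#'
#' Describes one site's weather process and the historic -> modern shift
#' applied to it.  Temperature is a sinusoidal seasonal cycle (southern-
#' hemisphere phase: warmest mid-January) plus AR(1) noise; precipitation is
#' zero-inflated Gamma; relative humidity is Gaussian, clipped to [0, 100].
#' The modern window adds `warming_offset`, inflates daily noise by
#' `temp_sd_multiplier`, adds `hot_extreme_boost` to its upper-tail (top 5%)
#' days, and scales precipitation by `precip_trend_ratio`.
#'
#' @param baseline_mean_temp annual mean temperature, degrees C.
#' @param seasonal_amplitude seasonal half-range, degrees C.
#' @param warming_offset modern minus historic mean shift, degrees C.
#' @param temp_sd_multiplier modern daily-noise inflation (1 = none).
#' @param hot_extreme_boost degrees C added to modern upper-tail days.
#' @param temp_daily_sd marginal SD of daily temperature noise, degrees C.
#' @param ar1_phi AR(1) autocorrelation of daily temperature noise.
#' @param precip_daily_mean overall mean daily precipitation, mm.
#' @param precip_trend_ratio multiplicative modern/historic precipitation
#'   change.
#' @param wet_day_prob probability a day is wet.
#' @param precip_shape Gamma shape of wet-day amounts.
#' @param rh_mean,rh_sd relative humidity mean (percent) and SD.
#' @param years_per_window years per collection window (default 5).
#' @param gap_years years between historic and modern collections (the study
#'   design uses 29-40).
#' @param collection_date modern collection date (ISO string or `Date`).
#' @param margin_days extra days generated before each window so the
#'   extreme-event indices have their acclimatisation history (default 60).
#' @param seed integer seed.
#' @return object of class `climate_sim_config`.
#' @export
climate_sim_config <- function(baseline_mean_temp = 17,
                               seasonal_amplitude = 6,
                               warming_offset = 1,
                               temp_sd_multiplier = 1,
                               hot_extreme_boost = 0,
                               temp_daily_sd = 3,
                               ar1_phi = 0.7,
                               precip_daily_mean = 2.5,
                               precip_trend_ratio = 1,
                               wet_day_prob = 0.35,
                               precip_shape = 0.8,
                               rh_mean = 65,
                               rh_sd = 8,
                               years_per_window = 5L,
                               gap_years = 35L,
                               collection_date = "2020-03-01",
                               margin_days = 60L,
                               seed = 1L) {
  cfg <- list(baseline_mean_temp = baseline_mean_temp,
              seasonal_amplitude = seasonal_amplitude,
              warming_offset = warming_offset,
              temp_sd_multiplier = temp_sd_multiplier,
              hot_extreme_boost = hot_extreme_boost,
              temp_daily_sd = temp_daily_sd,
              ar1_phi = ar1_phi,
              precip_daily_mean = precip_daily_mean,
              precip_trend_ratio = precip_trend_ratio,
              wet_day_prob = wet_day_prob,
              precip_shape = precip_shape,
              rh_mean = rh_mean, rh_sd = rh_sd,
              years_per_window = as.integer(years_per_window),
              gap_years = as.integer(gap_years),
              collection_date = as.Date(collection_date),
              margin_days = as.integer(margin_days),
              seed = as.integer(seed))
  for (nm in c("baseline_mean_temp", "seasonal_amplitude", "warming_offset",
               "hot_extreme_boost")) {
    check_finite_scalar(cfg[[nm]], nm)
  }
  check_finite_scalar(cfg$temp_sd_multiplier, "temp_sd_multiplier", min = 0)
  check_finite_scalar(cfg$temp_daily_sd, "temp_daily_sd", min = 0)
  check_finite_scalar(cfg$ar1_phi, "ar1_phi", min = -0.999, max = 0.999)
  check_finite_scalar(cfg$precip_daily_mean, "precip_daily_mean",
                      min = .Machine$double.xmin)
  check_finite_scalar(cfg$precip_trend_ratio, "precip_trend_ratio", min = 0)
  check_finite_scalar(cfg$wet_day_prob, "wet_day_prob", min = 0, max = 1)
  check_finite_scalar(cfg$precip_shape, "precip_shape",
                      min = .Machine$double.xmin)
  check_finite_scalar(cfg$rh_mean, "rh_mean", min = 0, max = 100)
  check_finite_scalar(cfg$rh_sd, "rh_sd", min = 0)
  check_finite_scalar(cfg$years_per_window, "years_per_window", min = 1,
                      integer = TRUE)
  check_finite_scalar(cfg$gap_years, "gap_years", min = 1, integer = TRUE)
  check_finite_scalar(cfg$margin_days, "margin_days", min = 32,
                      integer = TRUE)
  check_finite_scalar(cfg$seed, "seed", integer = TRUE)
  structure(cfg, class = "climate_sim_config")
}

# simulate one collection window ending the day before end_date
.sim_window <- function(cfg, end_date, warm, sd_mult, boost, precip_scale) {
  start <- anniversary_date(end_date, cfg$years_per_window) - cfg$margin_days
  dates <- seq(start, end_date - 1L, by = "day")
  n <- length(dates)
  doy <- as.numeric(format(dates, "%j"))
  seasonal <- cfg$baseline_mean_temp +
    cfg$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  # AR(1) noise with marginal SD temp_daily_sd * sd_mult
  phi <- cfg$ar1_phi
  marg_sd <- cfg$temp_daily_sd * sd_mult
  innov_sd <- marg_sd * sqrt(1 - phi^2)
  eps <- numeric(n)
  eps[1] <- stats::rnorm(1, 0, marg_sd)
  shocks <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1L)) eps[i + 1L] <- phi * eps[i] + shocks[i]
  tmean <- seasonal + warm + eps
  if (boost != 0) {
    thr <- stats::quantile(tmean, 0.95, names = FALSE, type = 7)
    tmean[tmean > thr] <- tmean[tmean > thr] + boost
  }
  wet <- stats::runif(n) < cfg$wet_day_prob
  wet_mean <- if (cfg$wet_day_prob > 0) {
    cfg$precip_daily_mean / cfg$wet_day_prob
  } else 0
  amounts <- stats::rgamma(n, shape = cfg$precip_shape,
                           scale = precip_scale * wet_mean / cfg$precip_shape)
  precip <- ifelse(wet, amounts, 0)
  rh <- pmin(100, pmax(0, stats::rnorm(n, cfg$rh_mean, cfg$rh_sd)))
  data.frame(date = dates, tmean_c = tmean, precip_mm = precip, rh_pct = rh)
}

#' Generate a paired historic/modern daily climate series
#'
#' Simulates one site's daily weather over the `years_per_window` years
#' (plus an acclimatisation margin) preceding each of two collections
#' separated by `gap_years`.  The historic window uses the baseline
#' parameters; the modern window applies the configured warming offset,
#' variability inflation, hot-tail boost and precipitation trend.
#'
#' @param cfg a [climate_sim_config()].
#' @return list with elements `historic`, `modern` (daily-series data
#'   frames), `historic_date`, `modern_date` and `config`.
#' @export
generate_daily_climate <- function(cfg) {
  stopifnot(inherits(cfg, "climate_sim_config"))
  set.seed(cfg$seed)
  mod_date <- cfg$collection_date
  hist_date <- anniversary_date(mod_date, cfg$gap_years)
  hist <- .sim_window(cfg, hist_date, warm = 0, sd_mult = 1, boost = 0,
                      precip_scale = 1)
  mod <- .sim_window(cfg, mod_date, warm = cfg$warming_offset,
                     sd_mult = cfg$temp_sd_multiplier,
                     boost = cfg$hot_extreme_boost,
                     precip_scale = cfg$precip_trend_ratio)
  list(historic = as_daily_series(hist), modern = as_daily_series(mod),
       historic_date = hist_date, modern_date = mod_date, config = cfg)
}

#' Trait simulation configuration
#'
#' Generative model for paired-cohort trait data: for species s and trait t,
#' the true log ratio of means is
#' `lnRR = alpha + sum_j beta_j * delta_c_sj + u_st`,
#' `u_st ~ N(0, tau^2)` drawn independently per species x trait (traits are
#' analysed in separate univariate models).  The historic cohort mean is
#' additionally multiplied by `exp(-delta)` (uniform storage/maternal bias),
#' which shifts every observed lnRR by `+delta` without touching the climate
#' deltas.  Individuals are `Normal(mu, (cv mu)^2)` truncated at 0 with
#' redraw.  Cohorts go missing independently with probability
#' `missing_prob`.
#'
#' @param n_species number of species pairs (default 32, the study size).
#' @param traits character vector of trait names.
#' @param slopes named numeric of per-metric slopes beta (log-ratio units
#'   per metric unit), applied to every trait; or a named list of such
#'   vectors keyed by trait.
#' @param intercept_alpha common intercept alpha (log-ratio units).
#' @param species_sd_tau between-species SD tau (log-ratio units).
#' @param cohort_cv within-cohort coefficient of variation.
#' @param n_hist,n_mod individuals per historic / modern cohort.
#' @param storage_bias_delta uniform historic storage bias delta.
#' @param missing_prob probability a species x trait cohort pair is absent.
#' @param baseline_means named numeric of historic trait means (recycled
#'   default 100).
#' @param seed integer seed.
#' @return object of class `trait_sim_config`.
#' @export
trait_sim_config <- function(n_species = 32L,
                             traits = "leaf_area",
                             slopes = c(mean_temp = 0.05),
                             intercept_alpha = 0,
                             species_sd_tau = 0.02,
                             cohort_cv = 0.2,
                             n_hist = 25L, n_mod = 25L,
                             storage_bias_delta = 0,
                             missing_prob = 0,
                             baseline_means = NULL,
                             seed = 1L) {
  if (!is.list(slopes)) slopes <- stats::setNames(
    rep(list(slopes), length(traits)), traits)
  for (tr in names(slopes)) {
    bad <- setdiff(names(slopes[[tr]]), climate_metric_names())
    if (length(bad)) {
      stop(sprintf("slope key '%s' is not a known climate metric", bad[1]),
           call. = FALSE)
    }
  }
  if (is.null(baseline_means)) {
    baseline_means <- stats::setNames(rep(100, length(traits)), traits)
  }
  cfg <- list(n_species = as.integer(n_species), traits = traits,
              slopes = slopes, intercept_alpha = intercept_alpha,
              species_sd_tau = species_sd_tau, cohort_cv = cohort_cv,
              n_hist = as.integer(n_hist), n_mod = as.integer(n_mod),
              storage_bias_delta = storage_bias_delta,
              missing_prob = missing_prob, baseline_means = baseline_means,
              seed = as.integer(seed))
  check_finite_scalar(cfg$n_species, "n_species", min = 2, integer = TRUE)
  check_finite_scalar(cfg$intercept_alpha, "intercept_alpha")
  check_finite_scalar(cfg$species_sd_tau, "species_sd_tau", min = 0)
  check_finite_scalar(cfg$cohort_cv, "cohort_cv", min = .Machine$double.xmin)
  check_finite_scalar(cfg$n_hist, "n_hist", min = 2, integer = TRUE)
  check_finite_scalar(cfg$n_mod, "n_mod", min = 2, integer = TRUE)
  check_finite_scalar(cfg$storage_bias_delta, "storage_bias_delta")
  check_finite_scalar(cfg$missing_prob, "missing_prob", min = 0,
                      max = 1 - 1e-12)
  check_finite_scalar(cfg$seed, "seed", integer = TRUE)
  structure(cfg, class = "trait_sim_config")
}

# truncated-at-zero standardised draws: value = mu * (1 + cv * z), so
# truncation (z <= -1/cv) and the whole RNG stream are independent of mu.
# This is what makes the storage-bias construction exact: scaling mu leaves
# every z (and every redraw) identical.
.draw_cohort_z <- function(n, cv) {
  z <- stats::rnorm(n)
  bad <- z <= -1 / cv
  while (any(bad)) {
    z[bad] <- stats::rnorm(sum(bad))
    bad <- z <= -1 / cv
  }
  z
}

#' Generate paired historic/modern trait cohorts with known truth
#'
#' @param changes wide species x metric change table (see [changes_wide()]);
#'   one row per species.
#' @param cfg a [trait_sim_config()].
#' @return list with `data` (tidy data frame `species,era,trait,value`),
#'   `truth` (sidecar data frame of per-species/trait ground truth:
#'   `u`, `lnrr_true`, `observed`) and `config`.  The truth table is never
#'   written into the measurement file.
#' @export
generate_trait_cohorts <- function(changes, cfg) {
  stopifnot(inherits(cfg, "trait_sim_config"))
  changes <- as.data.frame(changes)
  if (nrow(changes) != cfg$n_species) {
    stop(sprintf("changes has %d rows but n_species = %d",
                 nrow(changes), cfg$n_species), call. = FALSE)
  }
  set.seed(cfg$seed)
  species <- as.character(changes$species)
  rows <- vector("list", cfg$n_species * length(cfg$traits) * 2L)
  truth <- vector("list", cfg$n_species * length(cfg$traits))
  ri <- 0L; ti <- 0L
  for (si in seq_len(cfg$n_species)) {
    for (tr in cfg$traits) {
      beta <- cfg$slopes[[tr]]
      if (is.null(beta)) beta <- numeric(0)
      dsum <- if (length(beta)) {
        sum(beta * as.numeric(changes[si, names(beta)]))
      } else 0
      u <- stats::rnorm(1, 0, cfg$species_sd_tau)
      lnrr_true <- cfg$intercept_alpha + dsum + u
      mu_hist <- cfg$baseline_means[[tr]] * exp(-cfg$storage_bias_delta)
      mu_mod <- cfg$baseline_means[[tr]] * exp(lnrr_true)
      drop <- stats::runif(1) < cfg$missing_prob
      zh <- .draw_cohort_z(cfg$n_hist, cfg$cohort_cv)
      zm <- .draw_cohort_z(cfg$n_mod, cfg$cohort_cv)
      ti <- ti + 1L
      truth[[ti]] <- data.frame(species = species[si], trait = tr, u = u,
                                lnrr_true = lnrr_true, observed = !drop,
                                stringsAsFactors = FALSE)
      if (!drop) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(species = species[si], era = "historic",
                                 trait = tr,
                                 value = mu_hist * (1 + cfg$cohort_cv * zh),
                                 stringsAsFactors = FALSE)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(species = species[si], era = "modern",
                                 trait = tr,
                                 value = mu_mod * (1 + cfg$cohort_cv * zm),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  data <- do.call(rbind, rows[seq_len(ri)])
  truth <- do.call(rbind, truth)
  rownames(data) <- rownames(truth) <- NULL
  attr(truth, "alpha") <- cfg$intercept_alpha
  attr(truth, "slopes") <- cfg$slopes
  attr(truth, "delta") <- cfg$storage_bias_delta
  list(data = data, truth = truth, config = cfg)
}

#' Synthetic species-level metadata for the ancillary regressions
#'
#' Growth form (herb/shrub/shrub-tree/tree in the study's 4/10/7/11
#' proportions), age of reproductive maturity and lifespan (each observed
#' for only a subset of species, as in the study), and a per-species
#' atmospheric CO2 change on the log-ratio scale.
#'
#' @param species character vector of species names.
#' @param seed integer seed.
#' @return data frame `species, growth_form, maturity_age, lifespan,
#'   co2_lnrr`.
#' @export
generate_species_metadata <- function(species, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(species)
  forms <- sample(rep(c("herb", "shrub", "shrub_tree", "tree"),
                      times = ceiling(n * c(4, 10, 7, 11) / 32))[seq_len(n)])
  maturity <- round(stats::rlnorm(n, log(5), 0.6), 1)
  maturity[stats::runif(n) > 15 / 32] <- NA  # observed for ~15/32 species
  lifespan <- round(stats::rlnorm(n, log(40), 0.7))
  lifespan[stats::runif(n) > 9 / 32] <- NA   # observed for ~9/32 species
  co2 <- log(stats::runif(n, 395, 415) / stats::runif(n, 335, 345))
  data.frame(species = species, growth_form = forms,
             maturity_age = maturity, lifespan = lifespan, co2_lnrr = co2,
             stringsAsFactors = FALSE)
}
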