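# Climate metrics: twelve per-era summaries of a site's daily weather over
# the 5 years preceding a seed collection, plus their historic -> modern
# change under two scalings (additive difference for temperature metrics,
# log ratio for precipitation-like metrics and event durations).

#' Canonical climate metric names
#'
#' The twelve metrics, in the canonical reporting order: means, variability
#' (coefficient of variation), annual ranges, seasonal precipitation
#' extremes, atmospheric aridity (VPD) and extreme-event durations.
#'
#' @return character vector of length 12.
#' @export
climate_metric_names <- function() {
  c("mean_temp", "mean_precip",
    "temp_var", "precip_var",
    "temp_range", "precip_range",
    "max_seasonal_precip", "min_seasonal_precip",
    "vpd",
    "max_drought_dur", "max_heatwave_dur", "max_dryspell_dur")
}

#' Change scaling used for each climate metric
#'
#' Temperature metrics change additively (modern minus historic); all
#' precipitation metrics, VPD and the event durations change as a log ratio
#' of means.  Durations use `ln((d_mod + 1)/(d_hist + 1))` so that zero-day
#' durations remain admissible.
#'
#' @param metric metric name (see [climate_metric_names()]), or `NULL` for
#'   the full named registry.
#' @return `"difference"`, `"log_ratio"` or `"log_ratio_p1"`.
#' @export
metric_scaling <- function(metric = NULL) {
  reg <- c(mean_temp = "difference", temp_var = "difference",
           temp_range = "difference",
           mean_precip = "log_ratio", precip_var = "log_ratio",
           precip_range = "log_ratio",
           max_seasonal_precip = "log_ratio", min_seasonal_precip = "log_ratio",
           vpd = "log_ratio",
           max_drought_dur = "log_ratio_p1", max_heatwave_dur = "log_ratio_p1",
           max_dryspell_dur = "log_ratio_p1")
  if (is.null(metric)) return(reg)
  if (!metric %in% names(reg)) {
    stop(sprintf("unknown climate metric '%s'", metric), call. = FALSE)
  }
  unname(reg[metric])
}

#' Validate a daily climate series
#'
#' A daily series is a data frame with a `date` column (coercible to `Date`,
#' strictly increasing with a one-day step), `tmean_c` (mean temperature,
#' degrees C), `precip_mm` (non-negative precipitation) and either `rh_pct`
#' (relative humidity, 0-100) or `vpd_kpa` (non-negative vapour pressure
#' deficit), or both.
#'
#' @param df data frame as above.
#' @return the validated data frame with `date` as `Date`, sorted.
#' @export
as_daily_series <- function(df) {
  df <- as.data.frame(df)
  need <- c("date", "tmean_c", "precip_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("daily series missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!("rh_pct" %in% names(df)) && !("vpd_kpa" %in% names(df))) {
    stop("daily series needs an 'rh_pct' or 'vpd_kpa' column", call. = FALSE)
  }
  df$date <- as.Date(df$date)
  df <- df[order(df$date), , drop = FALSE]
  d <- diff(as.integer(df$date))
  if (any(d != 1L)) {
    stop("daily series must have strictly increasing dates with a 1-day step",
         call. = FALSE)
  }
  if (any(df$precip_mm < 0, na.rm = TRUE)) {
    stop("precip_mm must be non-negative", call. = FALSE)
  }
  if ("rh_pct" %in% names(df) &&
      any(df$rh_pct < 0 | df$rh_pct > 100, na.rm = TRUE)) {
    stop("rh_pct must lie in [0, 100]", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a daily climate series from CSV
#'
#' Expects columns `date,tmean_c,precip_mm,rh_pct[,vpd_kpa]` with ISO dates.
#'
#' @param path CSV path.
#' @return validated daily-series data frame.
#' @export
read_daily_series <- function(path) {
  as_daily_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pre-collection anniversary year windows
#'
#' Splits the `n_years` years before a collection date into consecutive
#' anniversary-to-anniversary windows: window k runs from the k-th
#' anniversary (counting back) to the day before the (k-1)-th.  Windows are
#' contiguous, non-overlapping, and their union spans exactly `n_years`
#' years ending the day before collection.
#'
#' @param series daily series (see [as_daily_series()]).
#' @param collection_date collection `Date`.
#' @param n_years number of year windows (default 5).
#' @return data frame with columns `start`, `end` (both `Date`), most recent
#'   window first.
#' @export
window_years <- function(series, collection_date, n_years = 5L) {
  collection_date <- as.Date(collection_date)
  ends <- vapply(seq_len(n_years) - 1L, function(k) {
    as.integer(anniversary_date(collection_date, k) - 1L)
  }, integer(1))
  starts <- vapply(seq_len(n_years), function(k) {
    as.integer(anniversary_date(collection_date, k))
  }, integer(1))
  win <- data.frame(start = as.Date(starts, origin = "1970-01-01"),
                    end = as.Date(ends, origin = "1970-01-01"))
  if (!is.null(series)) {
    series <- as_daily_series(series)
    lo <- min(series$date); hi <- max(series$date)
    if (min(win$start) < lo || max(win$end) > hi) {
      stop(sprintf(
        "series spans %s..%s but windows require %s..%s",
        lo, hi, min(win$start), max(win$end)), call. = FALSE)
    }
  }
  win
}

# extract a date-bounded slice of one variable
.slice <- function(series, start, end, variable) {
  sel <- series$date >= start & series$date <= end
  series[[variable]][sel]
}

#' Month-prior window statistic averaged over anniversary years
#'
#' For each of the `n_years` collection anniversaries, takes the 30 daily
#' values immediately preceding the anniversary ("month prior", a 30-day
#' trailing window), computes `stat` over them, and returns the mean of the
#' yearly statistics.  `cv` is the sample SD (n-1 denominator) divided by
#' the mean; a zero-mean window makes the cv undefined and the result is
#' returned as `NA` (flagged missing, not 0 or Inf).
#'
#' @param series daily series.
#' @param collection_date collection `Date`.
#' @param variable column name, e.g. `"tmean_c"`.
#' @param stat one of `"median"`, `"mean"`, `"cv"`.
#' @param n_years anniversaries to average over (default 5).
#' @param window_days trailing window length (default 30).
#' @return scalar (possibly `NA` for an undefined cv).
#' @export
monthly_window_stat <- function(series, collection_date, variable,
                                stat = c("median", "mean", "cv"),
                                n_years = 5L, window_days = 30L) {
  stat <- match.arg(stat)
  series <- as_daily_series(series)
  collection_date <- as.Date(collection_date)
  vals <- vapply(seq_len(n_years) - 1L, function(k) {
    ann <- anniversary_date(collection_date, k)
    x <- .slice(series, ann - window_days, ann - 1L, variable)
    if (length(x) != window_days) {
      stop(sprintf("month-prior window before %s not fully inside series",
                   format(ann)), call. = FALSE)
    }
    switch(stat,
           median = stats::median(x),
           mean = mean(x),
           cv = if (mean(x) == 0) NA_real_ else stats::sd(x) / mean(x))
  }, numeric(1))
  mean(vals)  # NA propagates: any undefined yearly cv flags the metric
}

#' Mean annual range of a daily variable
#'
#' Per anniversary-year window, the difference between the maximum and the
#' minimum daily value; averaged across the `n_years` windows.
#'
#' @inheritParams monthly_window_stat
#' @export
annual_range <- function(series, collection_date, variable, n_years = 5L) {
  series <- as_daily_series(series)
  win <- window_years(series, collection_date, n_years)
  r <- mapply(function(s, e) {
    x <- .slice(series, s, e, variable)
    max(x) - min(x)
  }, win$start, win$end)
  mean(r)
}

#' Seasonal precipitation extremes
#'
#' For each collection anniversary, totals precipitation over each of the 4
#' calendar months preceding the anniversary month, takes the maximum and
#' minimum of the 4 monthly totals, and averages each across the
#' anniversaries.
#'
#' @inheritParams monthly_window_stat
#' @return named numeric: `max_seasonal_precip`, `min_seasonal_precip`.
#' @export
seasonal_precip_extremes <- function(series, collection_date, n_years = 5L) {
  series <- as_daily_series(series)
  collection_date <- as.Date(collection_date)
  mo <- format(series$date, "%Y-%m")
  res <- vapply(seq_len(n_years) - 1L, function(k) {
    ann <- anniversary_date(collection_date, k)
    y <- as.integer(format(ann, "%Y"))
    m <- as.integer(format(ann, "%m"))
    tot <- vapply(1:4, function(back) {
      mm <- m - back
      yy <- y
      if (mm < 1L) { mm <- mm + 12L; yy <- yy - 1L }
      key <- sprintf("%04d-%02d", yy, mm)
      # whole calendar month must be covered by the series
      first <- as.Date(paste0(key, "-01"))
      last <- anniversary_date(as.Date(paste0(
        sprintf("%04d-%02d", if (mm == 12L) yy + 1L else yy,
                if (mm == 12L) 1L else mm + 1L), "-01")), 0) - 1L
      if (first < min(series$date) || last > max(series$date)) {
        stop(sprintf("calendar month %s not fully inside series", key),
             call. = FALSE)
      }
      sum(series$precip_mm[mo == key])
    }, numeric(1))
    c(max(tot), min(tot))
  }, numeric(2))
  c(max_seasonal_precip = mean(res[1, ]),
    min_seasonal_precip = mean(res[2, ]))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' Tetens saturation vapour pressure
#' `e_s = 0.6108 exp(17.27 T / (T + 237.3))` (kPa) and
#' `VPD = e_s (1 - rh/100)`.
#'
#' @param tmean temperature, degrees C (vectorised).
#' @param rh relative humidity, percent in \[0, 100\].
#' @return VPD in kPa.
#' @export
vpd_from_t_rh <- function(tmean, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("rh must lie in [0, 100]", call. = FALSE)
  }
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))
  es * (1 - rh / 100)
}

# daily VPD column: use vpd_kpa if present, else derive from tmean/rh
.daily_vpd <- function(series) {
  if ("vpd_kpa" %in% names(series)) return(series$vpd_kpa)
  vpd_from_t_rh(series$tmean_c, series$rh_pct)
}

# Excess-heat-factor style run machinery shared by the heatwave and
# dry-spell indices.  x is the full daily vector aligned with series dates;
# idx the positions inside the n-year window.  For each window day i:
#   sig(i)  = mean(x[i-2..i]) - P95 of all 3-day trailing means in window
#   accl(i) = mean(x[i-2..i]) - mean(x[i-32..i-3])
#   EHF(i)  = sig(i) * max(1, accl(i))
# An event is a run of >= min_run consecutive days with EHF > 0.
.ehf_max_run <- function(x, idx, window_len = 3L, pct = 0.95,
                         accl_days = 30L, min_run = 3L) {
  need <- window_len - 1L + accl_days
  if (min(idx) <= need) {
    stop(sprintf(
      "extreme index needs %d days of data before the window (have %d)",
      need, min(idx) - 1L), call. = FALSE)
  }
  m3 <- vapply(idx, function(i) mean(x[(i - window_len + 1L):i]), numeric(1))
  accl <- vapply(idx, function(i) {
    mean(x[(i - window_len + 1L - accl_days):(i - window_len)])
  }, numeric(1))
  thr <- stats::quantile(m3, pct, names = FALSE, type = 7)
  ehf <- (m3 - thr) * pmax(1, m3 - accl)
  longest_run(ehf > 0, min_run = min_run)
}

#' Maximum heatwave duration (excess heat factor)
#'
#' Longest run (>= `min_run` days) of positive daily Excess Heat Factor in
#' the `n_years` pre-collection window.  EHF combines a climatological
#' significance term (3-day trailing mean temperature vs the in-window 95th
#' percentile of such means) with an acclimatisation term (3-day mean vs the
#' preceding 30-day mean).  Requires 32 days of data before the window.
#'
#' @inheritParams monthly_window_stat
#' @param window_len trailing-mean length in days (default 3).
#' @param pct significance percentile (default 0.95).
#' @param accl_days acclimatisation window in days (default 30).
#' @param min_run minimum run length counted as an event (default 3).
#' @return integer duration in days (0 if no event).
#' @export
max_heatwave_duration <- function(series, collection_date, n_years = 5L,
                                  window_len = 3L, pct = 0.95,
                                  accl_days = 30L, min_run = 3L) {
  series <- as_daily_series(series)
  win <- window_years(series, collection_date, n_years)
  idx <- which(series$date >= min(win$start) & series$date <= max(win$end))
  .ehf_max_run(series$tmean_c, idx, window_len, pct, accl_days, min_run)
}

#' Maximum dry-spell duration (extreme dryness index)
#'
#' Identical run machinery to [max_heatwave_duration()] with daily VPD
#' substituted for temperature.
#'
#' @inheritParams max_heatwave_duration
#' @export
max_dryspell_duration <- function(series, collection_date, n_years = 5L,
                                  window_len = 3L, pct = 0.95,
                                  accl_days = 30L, min_run = 3L) {
  series <- as_daily_series(series)
  win <- window_years(series, collection_date, n_years)
  idx <- which(series$date >= min(win$start) & series$date <= max(win$end))
  .ehf_max_run(.daily_vpd(series), idx, window_len, pct, accl_days, min_run)
}

#' Maximum drought duration
#'
#' Longest run of consecutive days in the pre-collection window whose
#' trailing `agg_days`-day precipitation total falls strictly below the
#' `pct` quantile of all such totals in the window.  This construction is a
#' documented stand-in: the source analysis reports the metric without
#' defining it, so both the aggregation length and the threshold quantile
#' are exposed as arguments.
#'
#' @inheritParams monthly_window_stat
#' @param agg_days trailing aggregation length in days (default 30).
#' @param pct threshold quantile (default 0.10).
#' @return integer duration in days (0 if no day falls below threshold).
#' @export
max_drought_duration <- function(series, collection_date, n_years = 5L,
                                 agg_days = 30L, pct = 0.10) {
  series <- as_daily_series(series)
  win <- window_years(series, collection_date, n_years)
  idx <- which(series$date >= min(win$start) & series$date <= max(win$end))
  if (min(idx) <= agg_days - 1L) {
    stop(sprintf("drought index needs %d days of data before the window",
                 agg_days - 1L), call. = FALSE)
  }
  cs <- c(0, cumsum(series$precip_mm))
  tot <- cs[idx + 1L] - cs[idx - agg_days + 1L]
  thr <- stats::quantile(tot, pct, names = FALSE, type = 7)
  longest_run(tot < thr, min_run = 1L)
}

#' All twelve climate metrics for one era
#'
#' @inheritParams monthly_window_stat
#' @param ... passed through to the extreme-event indices.
#' @return named numeric vector over [climate_metric_names()].
#' @export
climate_metric_set <- function(series, collection_date, n_years = 5L, ...) {
  series <- as_daily_series(series)
  vpd_series <- series
  vpd_series$vpd_daily <- .daily_vpd(series)
  seas <- seasonal_precip_extremes(series, collection_date, n_years)
  out <- c(
    mean_temp = monthly_window_stat(series, collection_date, "tmean_c",
                                    "median", n_years),
    mean_precip = monthly_window_stat(series, collection_date, "precip_mm",
                                      "mean", n_years),
    temp_var = monthly_window_stat(series, collection_date, "tmean_c",
                                   "cv", n_years),
    precip_var = monthly_window_stat(series, collection_date, "precip_mm",
                                     "cv", n_years),
    temp_range = annual_range(series, collection_date, "tmean_c", n_years),
    precip_range = annual_range(series, collection_date, "precip_mm", n_years),
    max_seasonal_precip = unname(seas["max_seasonal_precip"]),
    min_seasonal_precip = unname(seas["min_seasonal_precip"]),
    vpd = monthly_window_stat(vpd_series, collection_date, "vpd_daily",
                              "mean", n_years),
    max_drought_dur = max_drought_duration(series, collection_date, n_years),
    max_heatwave_dur = max_heatwave_duration(series, collection_date,
                                             n_years, ...),
    max_dryspell_dur = max_dryspell_duration(series, collection_date,
                                             n_years, ...)
  )
  out[climate_metric_names()]
}

#' Historic to modern change for one metric
#'
#' Applies the registry scaling (see [metric_scaling()]): additive
#' difference for temperature metrics, `ln(modern/historic)` for
#' precipitation-like metrics, and `ln((modern+1)/(historic+1))` for the
#' event durations.  A non-positive input to a log-ratio metric yields `NA`
#' with a `reason` attribute.
#'
#' @param historic,modern per-era metric values.
#' @param metric metric name.
#' @return scalar delta (possibly `NA`).
#' @export
change_metric <- function(historic, modern, metric) {
  sc <- metric_scaling(metric)
  if (is.na(historic) || is.na(modern)) {
    return(structure(NA_real_, reason = "missing input"))
  }
  if (sc == "difference") return(modern - historic)
  if (sc == "log_ratio_p1") {
    historic <- historic + 1
    modern <- modern + 1
  }
  if (historic <= 0 || modern <= 0) {
    return(structure(NA_real_,
                     reason = "non-positive value for log-ratio metric"))
  }
  log(modern / historic)
}

#' Full historic to modern climate change set
#'
#' Computes all twelve metrics for each era and their per-metric change.
#'
#' @param hist_series,mod_series per-era daily series.
#' @param hist_date,mod_date per-era collection dates.
#' @param n_years window length in years (default 5).
#' @return data frame `metric, historic, modern, delta, scaling, missing,
#'   reason`, one row per metric in canonical order.
#' @export
compute_all_changes <- function(hist_series, mod_series, hist_date, mod_date,
                                n_years = 5L) {
  h <- climate_metric_set(hist_series, hist_date, n_years)
  m <- climate_metric_set(mod_series, mod_date, n_years)
  nm <- climate_metric_names()
  delta <- numeric(length(nm))
  reason <- character(length(nm))
  for (i in seq_along(nm)) {
    d <- change_metric(h[[i]], m[[i]], nm[i])
    delta[i] <- as.numeric(d)
    reason[i] <- if (is.na(d)) attr(d, "reason") %||% "undefined" else ""
  }
  data.frame(metric = nm, historic = unname(h), modern = unname(m),
             delta = delta, scaling = unname(metric_scaling()[nm]),
             missing = is.na(delta), reason = reason,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stack per-species change sets into a wide species x metric table
#'
#' @param change_list named list (by species) of [compute_all_changes()]
#'   outputs.
#' @return data frame with a `species` column and one column per metric.
#' @export
changes_wide <- function(change_list) {
  stopifnot(length(change_list) >= 1L, !is.null(names(change_list)))
  nm <- climate_metric_names()
  rows <- lapply(names(change_list), function(sp) {
    ch <- change_list[[sp]]
    v <- stats::setNames(ch$delta, ch$metric)[nm]
    as.data.frame(c(list(species = sp), as.list(v)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collinearity screen over species-level metric changes
#'
#' Pairwise Pearson correlations of the metric deltas across species
#' (pairwise-complete observations), with flags where `|r|` meets the
#' threshold.  A metric constant across species has undefined correlations
#' and is flagged as such.
#'
#' @param changes wide table from [changes_wide()].
#' @param threshold flag threshold on `|r|` (default 0.6).
#' @return list with `correlations` (matrix), `flagged` (data frame of pairs
#'   with `|r| >= threshold`), `constant` (metric names with zero variance).
#' @export
collinearity_screen <- function(changes, threshold = 0.6) {
  nm <- intersect(climate_metric_names(), names(changes))
  if (nrow(changes) < 3L) stop("need at least 3 species", call. = FALSE)
  M <- as.matrix(changes[, nm, drop = FALSE])
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  constant <- nm[!is.na(sds) & sds == 0]
  suppressWarnings(r <- stats::cor(M, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(r) & !is.na(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(metric_a = nm[pairs[, 1]], metric_b = nm[pairs[, 2]],
                        r = r[pairs], stringsAsFactors = FALSE)
  list(correlations = r, flagged = flagged, constant = constant)
}
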