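# Window arithmetic, the twelve metrics, change scalings and the screen.

test_that("window_years: calendar arithmetic, leap days, span errors", {
  w <- window_years(NULL, "2020-03-01", 5)
  expect_equal(w$end[1], as.Date("2020-02-29"))
  expect_equal(w$start[1], as.Date("2019-03-01"))
  expect_equal(w$end[5], as.Date("2016-02-29"))
  expect_equal(w$start[5], as.Date("2015-03-01"))
  # contiguous, non-overlapping, exact 5-year union
  expect_true(all(diff(rev(w$start)) == as.integer(rev(w$end)[-5] -
                                                     rev(w$start)[-5]) + 1))
  expect_equal(as.integer(w$end[1] - w$start[5]) + 1,
               as.integer(as.Date("2020-03-01") - as.Date("2015-03-01")))

  w1 <- window_years(NULL, "2020-03-01", 1)
  expect_equal(as.integer(w1$end - w1$start) + 1, 366)  # leap year window

  # leap-day collection: prior anniversaries map to 02-28
  wl <- window_years(NULL, "2020-02-29", 3)
  expect_equal(wl$end[1], as.Date("2020-02-28"))
  expect_equal(wl$start[1], as.Date("2019-02-28"))
  expect_equal(wl$start[2], as.Date("2018-02-28"))

  s <- make_series(n = 400)
  expect_error(window_years(s, FIX_COLLECTION, 5), "series spans")
})

test_that("monthly_window_stat: constants, tiled cv oracle, zero-mean guard", {
  s <- make_series(tmean = 20)
  expect_equal(monthly_window_stat(s, FIX_COLLECTION, "tmean_c", "median"), 20)
  expect_equal(monthly_window_stat(s, FIX_COLLECTION, "tmean_c", "cv"), 0)

  # 30-day windows tiled with {8,10,12}: cv = sd(30 values)/mean, per the
  # direct-evaluation oracle
  s2 <- make_series(tmean = rep(c(8, 10, 12), length.out = 365 * 6))
  expected <- local({
    win <- rep(c(8, 10, 12), 10)
    sd(win) / mean(win)
  })
  got <- monthly_window_stat(s2, FIX_COLLECTION, "tmean_c", "cv")
  # every 30-day window is a permutation of the same tiled multiset
  expect_equal(got, expected, tolerance = 1e-12)

  # all-dry month: mean 0, cv flagged missing (NA, not 0 or Inf)
  s3 <- make_series(precip = 0)
  expect_equal(monthly_window_stat(s3, FIX_COLLECTION, "precip_mm", "mean"), 0)
  expect_true(is.na(monthly_window_stat(s3, FIX_COLLECTION, "precip_mm",
                                        "cv")))
})

test_that("annual_range: constant, sinusoid and spike oracles", {
  expect_equal(annual_range(make_series(20), FIX_COLLECTION, "tmean_c"), 0)

  n <- 365 * 6
  doy <- as.numeric(format(seq(as.Date("2014-01-01"), by = "day",
                               length.out = n), "%j"))
  A <- 7
  s <- make_series(tmean = 15 + A * sin(2 * pi * doy / 365.25), n = n)
  expect_equal(annual_range(s, FIX_COLLECTION, "tmean_c"), 2 * A,
               tolerance = 0.01)

  # +10 spike in exactly one year-window: that range +10, 5-year mean +2
  s2 <- make_series(20)
  spike_day <- as.Date("2017-01-15")
  s2$tmean_c[s2$date == spike_day] <- 30
  expect_equal(annual_range(s2, FIX_COLLECTION, "tmean_c"), 2)
})

test_that("seasonal_precip_extremes: uniform, single-month and monsoon", {
  s <- make_series(precip = 2)
  r <- seasonal_precip_extremes(s, FIX_COLLECTION)
  # collection June: preceding months Feb-May; Feb has 28/29 days
  expect_equal(unname(r["max_seasonal_precip"]), 2 * 31)
  feb_days <- mean(c(28, 28, 28, 29, 28))  # 2015..2019 Februaries
  expect_equal(unname(r["min_seasonal_precip"]), 2 * feb_days)

  # rain only in March (90 mm total) each year -> max 90, min 0
  s2 <- make_series(precip = 0)
  mar <- format(s2$date, "%m") == "03" & format(s2$date, "%d") %in%
    sprintf("%02d", 1:30)
  s2$precip_mm[mar] <- 3
  r2 <- seasonal_precip_extremes(s2, FIX_COLLECTION)
  expect_equal(unname(r2["max_seasonal_precip"]), 90)
  expect_equal(unname(r2["min_seasonal_precip"]), 0)

  # synthetic monsoon profile: Feb..May totals {10, 200, 150, 5}
  s3 <- make_series(precip = 0)
  mo <- as.integer(format(s3$date, "%m"))
  dom <- as.integer(format(s3$date, "%d"))
  s3$precip_mm[mo == 2 & dom <= 10] <- 1     # 10
  s3$precip_mm[mo == 3 & dom <= 20] <- 10    # 200
  s3$precip_mm[mo == 4 & dom <= 15] <- 10    # 150
  s3$precip_mm[mo == 5 & dom <= 5] <- 1      # 5
  r3 <- seasonal_precip_extremes(s3, FIX_COLLECTION)
  expect_equal(unname(r3["max_seasonal_precip"]), 200)
  expect_equal(unname(r3["min_seasonal_precip"]), 5)
})

test_that("vpd_from_t_rh: Tetens values, saturation, monotonicity, guards", {
  expect_equal(vpd_from_t_rh(25, 100), 0)
  expect_equal(vpd_from_t_rh(0, 100), 0)
  expect_equal(vpd_from_t_rh(25, 50),
               0.6108 * exp(17.27 * 25 / (25 + 237.3)) * 0.5,
               tolerance = 1e-12)
  expect_equal(vpd_from_t_rh(25, 50), 1.584, tolerance = 1e-3)
  temps <- seq(0, 45, by = 5)
  expect_true(all(diff(vpd_from_t_rh(temps, 60)) > 0))
  expect_error(vpd_from_t_rh(25, 101), "rh")
  expect_error(vpd_from_t_rh(25, -1), "rh")
})

test_that("heatwave duration: enumeration oracle, runs, invariances", {
  n <- 365 * 6
  base <- rep(20, n)
  cases <- list(
    constant = base,
    block5 = {x <- base; x[1200:1204] <- 30; x},
    runs_3_and_6 = {x <- base; x[1000:1002] <- 30; x[1300:1305] <- 30; x},
    short_run_only = {x <- base; x[1100] <- 35; x}
  )
  expected_const <- c(constant = 0, block5 = 7)
  for (nm in names(cases)) {
    s <- make_series(tmean = cases[[nm]], n = n)
    got <- max_heatwave_duration(s, FIX_COLLECTION)
    want <- oracle_ehf_duration(cases[[nm]], s$date, FIX_COLLECTION)
    expect_identical(as.integer(got), as.integer(want), label = nm)
    if (nm %in% names(expected_const)) {
      expect_identical(as.integer(got), as.integer(expected_const[nm]))
    }
  }
  # longest of two runs is returned (6-day block -> 8 EHF-positive days,
  # 3-day block -> 5, by the same trailing convention that maps 5 -> 7)
  s <- make_series(tmean = cases$runs_3_and_6, n = n)
  expect_identical(max_heatwave_duration(s, FIX_COLLECTION), 8L)

  # shift invariance
  s2 <- make_series(tmean = cases$block5 + 11.3, n = n)
  expect_identical(max_heatwave_duration(s2, FIX_COLLECTION),
                   max_heatwave_duration(make_series(tmean = cases$block5,
                                                     n = n), FIX_COLLECTION))
  # insufficient pre-window history errors
  short <- make_series(tmean = 20, n = 1826, start = "2014-06-01")
  expect_error(max_heatwave_duration(short, FIX_COLLECTION), "before the")
})

test_that("dry-spell duration mirrors the EHF machinery on VPD", {
  n <- 365 * 6
  v <- rep(1, n); v[1200:1207] <- 3
  s <- make_series(n = n, vpd = v)
  expect_identical(max_dryspell_duration(s, FIX_COLLECTION), 10L)
  expect_identical(as.integer(oracle_ehf_duration(v, s$date, FIX_COLLECTION)),
                   10L)
  expect_identical(max_dryspell_duration(make_series(n = n, vpd = 1),
                                         FIX_COLLECTION), 0L)
  # shift invariance
  s2 <- make_series(n = n, vpd = v + 4.2)
  expect_identical(max_dryspell_duration(s2, FIX_COLLECTION), 10L)
  # falls back to Tetens VPD when no vpd column is present
  s3 <- make_series(tmean = 20, rh = 60, n = n)
  s3$tmean_c[1200:1207] <- 35
  expect_gt(max_dryspell_duration(s3, FIX_COLLECTION), 0)
})

test_that("drought duration: constant series, enumeration, scale invariance", {
  n <- 365 * 6
  expect_identical(max_drought_duration(make_series(precip = 1, n = n),
                                        FIX_COLLECTION), 0L)
  s <- make_series(precip = 1, n = n)
  s$precip_mm[1200:1319] <- 0  # 120 rainless days
  got <- max_drought_duration(s, FIX_COLLECTION)
  # brute-force oracle: trailing 30-day totals + type-7 decile threshold
  oracle <- local({
    win <- window_years(s, FIX_COLLECTION, 5)
    idx <- which(s$date >= min(win$start) & s$date <= max(win$end))
    tot <- sapply(idx, function(i) sum(s$precip_mm[(i - 29):i]))
    thr <- quantile(tot, 0.10, names = FALSE)
    r <- rle(tot < thr)
    max(c(0, r$lengths[r$values]))
  })
  expect_identical(as.integer(got), as.integer(oracle))
  expect_gt(got, 0)
  # doubling precipitation leaves the duration unchanged
  s2 <- s; s2$precip_mm <- s2$precip_mm * 2
  expect_identical(max_drought_duration(s2, FIX_COLLECTION), got)
})

test_that("change_metric: registry, identity, antisymmetry, guards", {
  expect_equal(change_metric(18.0, 19.5, "mean_temp"), 1.5)
  expect_equal(change_metric(50, 100, "mean_precip"), log(2))
  expect_equal(change_metric(0, 0, "max_heatwave_dur"), 0)
  expect_equal(change_metric(0, 2, "max_heatwave_dur"), log(3))
  for (m in climate_metric_names()) {
    expect_equal(as.numeric(change_metric(3.7, 3.7, m)), 0, label = m)
    a <- as.numeric(change_metric(2, 5, m))
    b <- as.numeric(change_metric(5, 2, m))
    expect_equal(a, -b, label = paste("antisym", m))
  }
  bad <- change_metric(-1, 5, "mean_precip")
  expect_true(is.na(bad))
  expect_match(attr(bad, "reason"), "non-positive")
  expect_error(change_metric(1, 2, "not_a_metric"), "unknown")
})

test_that("compute_all_changes: self-comparison gives all-zero deltas", {
  s <- generate_daily_climate(climate_sim_config(seed = 3))
  ch <- compute_all_changes(s$historic, s$historic, s$historic_date,
                            s$historic_date)
  expect_identical(ch$metric, climate_metric_names())
  expect_true(all(ch$delta == 0))
  expect_false(any(ch$missing))
  expect_identical(ch$scaling, unname(metric_scaling()[ch$metric]))
})

test_that("collinearity screen: duplicates, symmetry, constants, guards", {
  ch <- make_changes(32)
  ch$precip_var <- ch$mean_precip  # duplicated metric under two names
  ch$vpd <- 1                      # constant across species
  scr <- collinearity_screen(ch)
  expect_true(any(scr$flagged$metric_a == "mean_precip" &
                    scr$flagged$metric_b == "precip_var" |
                  scr$flagged$metric_a == "precip_var" &
                    scr$flagged$metric_b == "mean_precip"))
  r <- scr$correlations
  expect_equal(r["mean_precip", "precip_var"], 1)
  expect_equal(r, t(r))
  expect_true(all(diag(r)[setdiff(rownames(r), "vpd")] == 1))
  expect_identical(scr$constant, "vpd")
  expect_true(all(is.na(r["vpd", setdiff(colnames(r), "vpd")])))
  expect_error(collinearity_screen(ch[1:2, ]), "3 species")
})

test_that("metric set on a constant series matches closed forms", {
  s <- make_series(tmean = 20, precip = 2, rh = 60)
  m <- climate_metric_set(s, FIX_COLLECTION)
  expect_equal(unname(m["mean_temp"]), 20)
  expect_equal(unname(m["mean_precip"]), 2)
  expect_equal(unname(m["temp_var"]), 0)
  expect_equal(unname(m["precip_var"]), 0)
  expect_equal(unname(m["temp_range"]), 0)
  expect_equal(unname(m["precip_range"]), 0)
  expect_equal(unname(m["vpd"]), vpd_from_t_rh(20, 60))
  expect_equal(unname(m["max_heatwave_dur"]), 0)
  expect_equal(unname(m["max_dryspell_dur"]), 0)
  expect_equal(unname(m["max_drought_dur"]), 0)
})
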