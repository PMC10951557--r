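# Shared fixtures and independent oracles.  Oracles here are deliberately
# written with different machinery than the package code paths they check.

# constant-parameter daily series long enough for a 5-year window + margin
make_series <- function(tmean = 20, precip = 1, rh = 60, n = 365 * 6,
                        start = "2014-01-01", vpd = NULL) {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  df <- data.frame(date = dates,
                   tmean_c = rep_len(tmean, n),
                   precip_mm = rep_len(precip, n),
                   rh_pct = rep_len(rh, n))
  if (!is.null(vpd)) df$vpd_kpa <- rep_len(vpd, n)
  df
}

FIX_COLLECTION <- as.Date("2019-06-01")

# Independent EHF oracle: explicit day-by-day loop over the window, filter()
# free, using sort()-based percentile (type-7 quantile reimplemented).
oracle_ehf_duration <- function(x, dates, collection, n_years = 5) {
  end <- collection - 1
  start <- seq(collection, by = "-1 year", length.out = n_years + 1)[n_years + 1]
  idx <- which(dates >= start & dates <= end)
  m3 <- sapply(idx, function(i) (x[i - 2] + x[i - 1] + x[i]) / 3)
  # type-7 quantile by hand
  s <- sort(m3)
  h <- (length(s) - 1) * 0.95 + 1
  t95 <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  best <- 0; run <- 0
  for (j in seq_along(idx)) {
    i <- idx[j]
    accl <- mean(x[(i - 32):(i - 3)])
    ehf <- (m3[j] - t95) * max(1, m3[j] - accl)
    if (ehf > 0) run <- run + 1 else {
      if (run >= 3 && run > best) best <- run
      run <- 0
    }
  }
  if (run >= 3 && run > best) best <- run
  best
}

# closed-form inverse-variance WLS oracle (uses lm machinery, not the
# package's scoring code)
oracle_wls <- function(yi, vi, X) {
  fit <- lm.wfit(X, yi, w = 1 / vi)
  beta <- fit$coefficients
  XtWX <- crossprod(X, X / vi)
  se <- sqrt(diag(solve(XtWX)))
  list(beta = beta, se = se)
}

# independent subset iterator for model selection: binary expansion via
# expand.grid, own AICc arithmetic
oracle_all_subsets <- function(yi, vi, Z) {
  m <- ncol(Z)
  k <- length(yi)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  out <- lapply(seq_len(nrow(grid)), function(r) {
    s <- which(grid[r, ])
    X <- cbind(1, Z[, s, drop = FALSE])
    fit <- ccre::fit_meta_regression(yi, vi, X, method = "REML")
    np <- length(s) + 2
    ic <- -2 * fit$loglik_ml + 2 * np + 2 * np * (np + 1) / (k - np - 1)
    list(s = s, ic = ic)
  })
  ics <- sapply(out, `[[`, "ic")
  w <- exp(-(ics - min(ics)) / 2)
  w <- w / sum(w)
  imp <- sapply(seq_len(m), function(j) {
    sum(w[sapply(out, function(o) j %in% o$s)])
  })
  list(aicc = ics, weight = w, importance = setNames(imp, colnames(Z)))
}

# small deterministic species x metric change table with spread deltas
make_changes <- function(n_species, seed = 42, metrics = NULL) {
  set.seed(seed)
  if (is.null(metrics)) metrics <- climate_metric_names()
  ch <- data.frame(species = sprintf("sp%02d", seq_len(n_species)))
  for (m in metrics) ch[[m]] <- runif(n_species, -1, 1)
  ch$mean_temp <- seq(0, 2, length.out = n_species)  # spread per the design
  ch
}
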