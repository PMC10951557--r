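# All-subsets AICc model selection over the climate-change moderators with
# Akaike weights, per-moderator importance and zero-substitution
# model-averaged coefficients.

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 loglik + 2 p + 2 p (p + 1) / (k - p - 1)` where `p` counts
#' the intercept, the moderators and tau2.  Undefined (`NA`) when the
#' correction denominator is not positive; such models are excluded from
#' candidate sets.
#'
#' @param loglik maximised (ML) log-likelihood.
#' @param n_params parameter count including intercept and tau2.
#' @param k_obs number of observations (species).
#' @return scalar AICc, `NA_real_` if `k_obs - n_params - 1 <= 0`.
#' @export
aicc <- function(loglik, n_params, k_obs) {
  if (k_obs - n_params - 1 <= 0) return(NA_real_)
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) /
    (k_obs - n_params - 1)
}

# all index subsets of 1..m with size <= max_terms, empty set first,
# ordered by size then lexicographically
.subset_list <- function(m, max_terms = Inf) {
  out <- list(integer(0))
  for (sz in seq_len(min(m, max_terms))) {
    cmb <- utils::combn(m, sz)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

#' Exhaustive AICc model selection over moderator subsets
#'
#' Fits every subset of the named moderators (including the intercept-only
#' model) with [fit_meta_regression()], ranks models by AICc computed from
#' their ML log-likelihoods, and derives Akaike weights, per-moderator
#' importance (summed weight of models containing the moderator) and
#' zero-substitution model-averaged coefficients.  Species with a missing
#' value on any named moderator (or an unusable effect) are dropped first
#' (complete-case analysis); the retained count is reported as `k`.
#'
#' @param effects effect-size data frame (`species, yi, vi`, optionally
#'   `usable`).
#' @param changes wide species x metric change table.
#' @param moderators moderator (metric) names; default all 12.
#' @param max_terms cap on moderators per model (default unlimited).
#' @param method coefficient estimation method passed to
#'   [fit_meta_regression()] (default REML; AICc always uses ML
#'   likelihoods).
#' @param m_guard refuse unbounded enumeration beyond this many moderators.
#' @return object of class `ccre_model_selection`: list with `models` (data
#'   frame: `model, size, n_params, loglik, aicc, delta, weight`),
#'   `importance` (named vector), `averaged_coefficients`, `best` (moderator
#'   names of the minimum-AICc model), `best_fit` (its `ccre_meta_fit`),
#'   `k`, `excluded` (data frame of skipped models with reasons).
#' @export
enumerate_and_fit <- function(effects, changes, moderators = NULL,
                              max_terms = Inf, method = "REML",
                              m_guard = 14L) {
  if (is.null(moderators)) moderators <- climate_metric_names()
  miss <- setdiff(moderators, names(changes))
  if (length(miss)) {
    stop("moderator(s) absent from changes table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- length(moderators)
  if (m > m_guard && is.infinite(max_terms)) {
    stop(sprintf(
      "%d moderators would need 2^%d fits; set max_terms to bound the search",
      m, m), call. = FALSE)
  }
  if ("usable" %in% names(effects)) effects <- effects[effects$usable, ]
  dat <- merge(effects[, c("species", "yi", "vi")],
               changes[, c("species", moderators)], by = "species")
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, ]
  k <- nrow(dat)
  if (k < 3L) stop("fewer than 3 complete-case species", call. = FALSE)
  Z <- as.matrix(dat[, moderators, drop = FALSE])

  subsets <- .subset_list(m, max_terms)
  n_mod <- length(subsets)
  model_lab <- vapply(subsets, function(s) {
    if (!length(s)) "(intercept only)" else paste(moderators[s],
                                                  collapse = "+")
  }, character(1))

  fits <- vector("list", n_mod)
  loglik <- n_params <- ic <- rep(NA_real_, n_mod)
  excl_reason <- character(n_mod)
  for (i in seq_len(n_mod)) {
    s <- subsets[[i]]
    np <- length(s) + 2  # intercept + moderators + tau2
    if (k - np - 1 <= 0) {
      excl_reason[i] <- "AICc undefined (k - p - 1 <= 0)"
      next
    }
    X <- cbind(intrcpt = 1, Z[, s, drop = FALSE])
    fit <- tryCatch(fit_meta_regression(dat$yi, dat$vi, X, method = method),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      excl_reason[i] <- fit
      next
    }
    if (!fit$converged) {
      excl_reason[i] <- "non-convergent fit"
      next
    }
    fits[[i]] <- fit
    loglik[i] <- fit$loglik_ml
    n_params[i] <- np
    ic[i] <- aicc(fit$loglik_ml, np, k)
  }
  ok <- !is.na(ic)
  if (!any(ok)) stop("no candidate model could be fitted", call. = FALSE)
  delta <- ic - min(ic[ok])
  weight <- rep(NA_real_, n_mod)
  weight[ok] <- exp(-delta[ok] / 2) / sum(exp(-delta[ok] / 2))

  importance <- stats::setNames(numeric(m), moderators)
  averaged <- stats::setNames(numeric(m), moderators)
  for (i in which(ok)) {
    s <- subsets[[i]]
    if (!length(s)) next
    importance[moderators[s]] <- importance[moderators[s]] + weight[i]
    averaged[moderators[s]] <- averaged[moderators[s]] +
      weight[i] * fits[[i]]$beta[moderators[s]]
  }
  best_i <- which(ok)[which.min(ic[ok])]

  models <- data.frame(model = model_lab,
                       size = vapply(subsets, length, integer(1)),
                       n_params = n_params, loglik = loglik, aicc = ic,
                       delta = delta, weight = weight,
                       stringsAsFactors = FALSE)
  excluded <- data.frame(model = model_lab[!ok],
                         reason = excl_reason[!ok],
                         stringsAsFactors = FALSE)
  structure(list(models = models, importance = importance,
                 averaged_coefficients = averaged,
                 best = moderators[subsets[[best_i]]],
                 best_label = model_lab[best_i],
                 best_fit = fits[[best_i]], k = k,
                 moderators = moderators, excluded = excluded),
            class = "ccre_model_selection")
}

#' @export
print.ccre_model_selection <- function(x, ...) {
  cat(sprintf("AICc all-subsets selection: %d models, k = %d species\n",
              nrow(x$models), x$k))
  cat("best model:", x$best_label, "\n")
  top <- utils::head(x$models[order(x$models$aicc), ], 5)
  print(top, digits = 4, row.names = FALSE)
  cat("importance:\n")
  print(round(sort(x$importance, decreasing = TRUE), 3))
  invisible(x)
}

# significance stars per the reporting convention (.0001/.001/.01)
.stars <- function(p) {
  if (!is.finite(p)) return("")
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**"
  else ""
}

#' Importance matrix across traits
#'
#' Assembles per-trait selection results into the canonical reporting
#' shape: rows are the 12 climate metrics grouped as Mean / Variability /
#' Range / Seasonal precip. / Aridity / Climate extremes, columns are
#' traits, cells are Akaike-weight importances.  Best-model membership,
#' label, pseudo-R2 and significance stars ride along.
#'
#' @param results named list (by trait) of `ccre_model_selection` objects.
#' @return list with `importance` (12 x n_traits matrix), `in_best`
#'   (logical matrix), `best` (data frame `trait, best_model, k, pseudo_R2,
#'   stars`), `groups` (metric -> group label).
#' @export
importance_table <- function(results) {
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  nm <- climate_metric_names()
  traits <- names(results)
  imp <- matrix(NA_real_, length(nm), length(traits),
                dimnames = list(nm, traits))
  inb <- matrix(FALSE, length(nm), length(traits),
                dimnames = list(nm, traits))
  best <- vector("list", length(traits))
  for (j in seq_along(traits)) {
    r <- results[[j]]
    stopifnot(inherits(r, "ccre_model_selection"))
    imp[r$moderators, j] <- r$importance[r$moderators]
    inb[r$best, j] <- TRUE
    bf <- r$best_fit
    min_p <- if (length(r$best)) min(bf$pval[r$best]) else NA_real_
    best[[j]] <- data.frame(
      trait = traits[j],
      best_model = if (length(r$best)) r$best_label else "Intercept only",
      k = r$k,
      pseudo_R2 = if (length(r$best)) bf$pseudo_R2 else NA_real_,
      stars = .stars(min_p),
      stringsAsFactors = FALSE)
  }
  groups <- c(mean_temp = "Mean", mean_precip = "Mean",
              temp_var = "Variability", precip_var = "Variability",
              temp_range = "Range", precip_range = "Range",
              max_seasonal_precip = "Seasonal precip.",
              min_seasonal_precip = "Seasonal precip.",
              vpd = "Aridity",
              max_drought_dur = "Climate extremes",
              max_heatwave_dur = "Climate extremes",
              max_dryspell_dur = "Climate extremes")
  list(importance = imp, in_best = inb, best = do.call(rbind, best),
       groups = groups[nm])
}
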