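# Per-species trait-change effect sizes: the log ratio of cohort means
# (lnRR) with its delta-method sampling variance.  These are the units the
# meta-regressions weight and model.

#' Summarise a measurement cohort
#'
#' @param values numeric vector of individual measurements (>= 2 finite
#'   positive values required for a usable cohort).
#' @return list `mean, sd, n, usable, reason` (`sd` uses the n-1
#'   denominator).
#' @export
summarize_cohort <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    return(list(mean = NA_real_, sd = NA_real_, n = length(values),
                usable = FALSE, reason = "fewer than 2 finite values"))
  }
  list(mean = mean(values), sd = stats::sd(values), n = length(values),
       usable = TRUE, reason = "")
}

#' Log ratio of means effect size
#'
#' `yi = ln(mean_mod / mean_hist)` with delta-method sampling variance
#' `vi = sd_mod^2 / (n_mod mean_mod^2) + sd_hist^2 / (n_hist mean_hist^2)`.
#' Non-positive means (lnRR is undefined) or two zero SDs (vi degenerate)
#' flag the effect as unusable rather than erroring.
#'
#' @param hist,mod cohort summaries: lists or one-row data frames with
#'   `mean`, `sd`, `n`.
#' @return list `yi, vi, usable, reason`.
#' @export
lnrr <- function(hist, mod) {
  bad <- function(reason) list(yi = NA_real_, vi = NA_real_, usable = FALSE,
                               reason = reason)
  if (isFALSE(hist$usable) || isFALSE(mod$usable)) {
    return(bad("unusable cohort"))
  }
  if (is.na(hist$mean) || is.na(mod$mean)) return(bad("missing cohort mean"))
  if (hist$mean <= 0 || mod$mean <= 0) return(bad("non-positive cohort mean"))
  if (hist$sd == 0 && mod$sd == 0) return(bad("both cohort SDs are zero"))
  yi <- log(mod$mean / hist$mean)
  vi <- mod$sd^2 / (mod$n * mod$mean^2) + hist$sd^2 / (hist$n * hist$mean^2)
  list(yi = yi, vi = vi, usable = TRUE, reason = "")
}

#' Intrinsic water-use efficiency per individual
#'
#' `iWUE = A_sat / g_s`, computed per individual before cohort
#' summarisation.  Individuals with non-positive stomatal conductance are
#' dropped (returned as `NA`).
#'
#' @param a_sat light-saturated photosynthetic rate, umol CO2 m-2 s-1.
#' @param g_s stomatal conductance, mol H2O m-2 s-1.
#' @return numeric vector of iWUE values (`NA` where `g_s <= 0`).
#' @export
compute_iwue <- function(a_sat, g_s) {
  out <- a_sat / g_s
  out[!is.finite(g_s) | g_s <= 0] <- NA_real_
  out
}

#' Effect sizes from a tidy measurement table
#'
#' Groups `species, era, trait, value` rows into per-era cohorts and emits
#' one lnRR effect per species x trait with both eras present.  Species x
#' trait combinations with an unusable cohort are kept with
#' `usable = FALSE` and a reason.
#'
#' @param data tidy data frame with columns `species, era, trait, value`;
#'   `era` must be `"historic"` or `"modern"`.
#' @return data frame `species, trait, yi, vi, usable, reason`.
#' @export
effect_sizes <- function(data) {
  stopifnot(all(c("species", "era", "trait", "value") %in% names(data)))
  if (!all(data$era %in% c("historic", "modern"))) {
    stop("era must be 'historic' or 'modern'", call. = FALSE)
  }
  keys <- unique(data[, c("species", "trait")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sp <- keys$species[i]; tr <- keys$trait[i]
    sub <- data[data$species == sp & data$trait == tr, ]
    h <- summarize_cohort(sub$value[sub$era == "historic"])
    m <- summarize_cohort(sub$value[sub$era == "modern"])
    es <- lnrr(h, m)
    data.frame(species = sp, trait = tr, yi = es$yi, vi = es$vi,
               usable = es$usable, reason = es$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect sizes from a cohort-summary table
#'
#' For traits measured on already-averaged inputs, an explicit `mean`, `sd`
#' and `n` per cohort are required (no silent defaults).
#'
#' @param summaries data frame `species, era, trait, mean, sd, n`.
#' @return as [effect_sizes()].
#' @export
effect_sizes_from_summaries <- function(summaries) {
  need <- c("species", "era", "trait", "mean", "sd", "n")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) {
    stop("summary table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(summaries[, c("species", "trait")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sp <- keys$species[i]; tr <- keys$trait[i]
    sub <- summaries[summaries$species == sp & summaries$trait == tr, ]
    get <- function(era) {
      r <- sub[sub$era == era, ]
      if (nrow(r) != 1L || is.na(r$mean) || is.na(r$sd) || is.na(r$n)) {
        return(list(usable = FALSE))
      }
      list(mean = r$mean, sd = r$sd, n = r$n, usable = r$n >= 2)
    }
    es <- lnrr(get("historic"), get("modern"))
    data.frame(species = sp, trait = tr, yi = es$yi, vi = es$vi,
               usable = es$usable, reason = es$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overall species change score
#'
#' The absolute value of the average lnRR across a species' traits (missing
#' traits excluded): a single magnitude-of-change score per species.
#'
#' @param effects effect-size data frame for one or more species (columns
#'   `species, yi`, optionally `usable`).
#' @return data frame `species, overall_change`.
#' @export
overall_species_change <- function(effects) {
  if ("usable" %in% names(effects)) effects <- effects[effects$usable, ]
  effects <- effects[is.finite(effects$yi), ]
  if (nrow(effects) == 0L) stop("no usable effects", call. = FALSE)
  agg <- stats::aggregate(yi ~ species, data = effects,
                          FUN = function(y) abs(mean(y)))
  names(agg)[2] <- "overall_change"
  agg
}
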