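#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Anniversary of a date, k years earlier
#'
#' Maps a calendar date to the same month/day `k` years back.  A 29 February
#' anniversary falls back to 28 February in non-leap years.
#'
#' @param date a `Date`.
#' @param k non-negative integer number of years to count back.
#' @return a `Date`.
#' @keywords internal
#' @noRd
anniversary_date <- function(date, k) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y")) - as.integer(k)
  md <- format(date, "%m-%d")
  out <- as.Date(sprintf("%04d-%s", y, md), format = "%Y-%m-%d")
  if (is.na(out) && md == "02-29") {
    out <- as.Date(sprintf("%04d-02-28", y))
  }
  out
}

# stop() with the offending parameter named, used by config validators
check_finite_scalar <- function(x, name, min = -Inf, max = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a finite numeric scalar", name),
         call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("parameter '%s' = %g outside allowed range [%g, %g]",
                 name, x, min, max), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("parameter '%s' must be an integer", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Stable CSV writer: numeric columns rendered with %.*g so repeated runs on
# the same platform produce byte-identical files (used for golden outputs).
write_stable_csv <- function(df, path, digits = 10L) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = digits, format = "g")
    out[is.na(x)] <- "NA"
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# longest run of TRUE in a logical vector, counting only runs >= min_run
longest_run <- function(flag, min_run = 1L) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  lens <- r$lengths[r$values]
  lens <- lens[lens >= min_run]
  if (length(lens) == 0L) 0L else as.integer(max(lens))
}
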