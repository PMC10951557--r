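# The leaf-economics change axis: iterative-PCA imputation of the
# three-variable change matrix (delta SLA, delta photosynthetic rate,
# delta leaf nitrogen), PCA with a fixed sign convention, and Horn's
# parallel analysis for component retention.

#' Build the leaf-economics change matrix
#'
#' Rows are species, columns the lnRR changes of SLA, light-saturated
#' photosynthetic rate and leaf nitrogen.  Missing species x variable
#' effects become `NA` (imputed later).
#'
#' @param effects effect-size data frame (`species, trait, yi`, optionally
#'   `usable`).
#' @param traits length-3 named character vector mapping the matrix columns
#'   `delta_sla, delta_asat, delta_n` to trait names in `effects`.
#' @return numeric matrix with species rownames and the three columns.
#' @export
econ_matrix <- function(effects,
                        traits = c(delta_sla = "sla", delta_asat = "asat",
                                   delta_n = "leaf_n")) {
  stopifnot(length(traits) == 3L, !is.null(names(traits)))
  if ("usable" %in% names(effects)) effects <- effects[effects$usable, ]
  sp <- sort(unique(effects$species))
  M <- matrix(NA_real_, length(sp), 3L,
              dimnames = list(sp, names(traits)))
  for (j in seq_along(traits)) {
    sub <- effects[effects$trait == traits[j], ]
    M[match(sub$species, sp), j] <- sub$yi
  }
  M[rowSums(!is.na(M)) > 0, , drop = FALSE]
}

#' Iterative-PCA imputation of missing cells
#'
#' Initialises missing cells with column means, then iterates
#' centre -> rank-`n_comp` SVD reconstruction -> overwrite missing cells,
#' until the largest absolute change in an imputed cell drops below `tol`.
#' Observed cells are never altered.  `n_comp = 0` degenerates to mean
#' imputation.
#'
#' @param M numeric matrix with `NA`s allowed.
#' @param n_comp reconstruction rank (< min(dim(M)); default 1).
#' @param max_iter iteration cap (default 1000).
#' @param tol convergence tolerance on imputed cells (default 1e-8).
#' @return completed matrix with attributes `iterations` and `converged`.
#' @export
impute_pca <- function(M, n_comp = 1L, max_iter = 1000L, tol = 1e-8) {
  M <- as.matrix(M)
  if (n_comp >= min(dim(M))) {
    stop("n_comp must be smaller than both matrix dimensions", call. = FALSE)
  }
  bad_row <- rowSums(!is.na(M)) == 0
  bad_col <- colSums(!is.na(M)) == 0
  if (any(bad_row)) {
    stop("all-missing row(s): ",
         paste(rownames(M)[bad_row] %||% which(bad_row), collapse = ", "),
         call. = FALSE)
  }
  if (any(bad_col)) {
    stop("all-missing column(s): ",
         paste(colnames(M)[bad_col] %||% which(bad_col), collapse = ", "),
         call. = FALSE)
  }
  miss <- is.na(M)
  X <- M
  for (j in seq_len(ncol(X))) {
    X[miss[, j], j] <- mean(M[, j], na.rm = TRUE)
  }
  if (!any(miss)) {
    return(structure(X, iterations = 0L, converged = TRUE))
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    mu <- colMeans(X)
    C <- sweep(X, 2, mu)
    recon <- if (n_comp == 0L) {
      matrix(0, nrow(X), ncol(X))
    } else {
      s <- svd(C, nu = n_comp, nv = n_comp)
      s$u %*% (diag(s$d[seq_len(n_comp)], n_comp) %*% t(s$v))
    }
    fitted <- sweep(recon, 2, mu, "+")
    change <- max(abs(fitted[miss] - X[miss]))
    X[miss] <- fitted[miss]
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  structure(X, iterations = it, converged = converged)
}

#' Principal components of the economics change matrix
#'
#' Column-centred (optionally unit-scaled) PCA via singular value
#' decomposition, with the sign of each loading column fixed so its
#' largest-magnitude entry is positive.
#'
#' @param M completed numeric matrix (no `NA`s).
#' @param scale_columns scale columns to unit variance (default `FALSE`).
#' @return object of class `ccre_pca`: list with `loadings`, `scores`,
#'   `explained` (percent per component, sums to 100), `center`, `scale`.
#' @export
econ_pca <- function(M, scale_columns = FALSE) {
  M <- as.matrix(M)
  if (any(is.na(M))) stop("matrix has missing cells; impute first",
                          call. = FALSE)
  if (scale_columns && any(apply(M, 2, stats::sd) == 0)) {
    stop("zero-variance column with scale_columns = TRUE", call. = FALSE)
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = scale_columns)
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(loadings = pc$rotation, scores = pc$x,
                 explained = 100 * ev / sum(ev),
                 center = pc$center,
                 scale = if (scale_columns) pc$scale else FALSE),
            class = "ccre_pca")
}

#' @export
print.ccre_pca <- function(x, ...) {
  cat("PCA:", paste(sprintf("PC%d %.2f%%", seq_along(x$explained),
                            x$explained), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Horn's parallel analysis for component retention
#'
#' Compares the observed correlation-matrix eigenvalues with those of
#' `n_iter` random matrices of the same shape with independent standard
#' normal columns.  Under the `mean` rule a component is retained while its
#' adjusted eigenvalue (observed - random mean + 1) exceeds 1; under `p95`
#' the observed eigenvalue must exceed the random 95th percentile.
#' Retention is sequential: it stops at the first failing component.
#'
#' @param M completed numeric matrix.
#' @param n_iter random matrices to draw (>= 100; default 500).
#' @param percentile_rule `"mean"` or `"p95"`.
#' @param seed integer seed for the random reference eigenvalues.
#' @return list with `retained` (count), `observed` (eigenvalues),
#'   `reference` (per-rank random mean or percentile), `adjusted`.
#' @export
horn_parallel <- function(M, n_iter = 500L, percentile_rule = c("mean", "p95"),
                          seed = 1L) {
  percentile_rule <- match.arg(percentile_rule)
  M <- as.matrix(M)
  if (any(is.na(M))) stop("matrix has missing cells; impute first",
                          call. = FALSE)
  if (n_iter < 100L) stop("n_iter must be >= 100", call. = FALSE)
  n <- nrow(M); p <- ncol(M)
  obs <- eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
  set.seed(as.integer(seed))
  rand <- matrix(NA_real_, n_iter, p)
  for (b in seq_len(n_iter)) {
    R <- matrix(stats::rnorm(n * p), n, p)
    rand[b, ] <- eigen(stats::cor(R), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  ref <- if (percentile_rule == "mean") {
    colMeans(rand)
  } else {
    apply(rand, 2, stats::quantile, probs = 0.95, names = FALSE, type = 7)
  }
  adjusted <- obs - ref + 1
  keep <- adjusted > 1
  retained <- if (all(keep)) p else which.min(keep) - 1L
  list(retained = as.integer(retained), observed = obs, reference = ref,
       adjusted = adjusted, rule = percentile_rule)
}

#' Component scores as meta-regression responses
#'
#' Emits the requested component scores keyed by species.  Scores carry no
#' sampling variance, so downstream fits use equal weights (`vi = 1`).
#'
#' @param pca a `ccre_pca`.
#' @param components component indices (default `1:2`).
#' @return data frame `species, PC<j>...` plus a `vi` column of ones.
#' @export
econ_scores_as_response <- function(pca, components = 1:2) {
  stopifnot(inherits(pca, "ccre_pca"))
  if (max(components) > ncol(pca$scores)) {
    stop("requested component not present", call. = FALSE)
  }
  out <- data.frame(species = rownames(pca$scores),
                    pca$scores[, components, drop = FALSE],
                    vi = 1, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
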