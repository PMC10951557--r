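# Random-effects meta-regression, from scratch.
#
# Model: yi = X beta + u_i + e_i,  u_i ~ N(0, tau2),  e_i ~ N(0, vi) with
# known per-species sampling variances vi.  Weights are 1/(vi + tau2); tau2
# is estimated by Fisher scoring on the (restricted) likelihood score,
# truncated at zero.  Inference is Wald-normal.  ML log-likelihoods are
# always reported so AICc comparisons across fixed-effect structures are
# valid even when coefficients come from REML fits.

# Fisher scoring for tau2.  restricted = TRUE gives REML.  Returns the
# estimate, convergence flag and iteration count.  Scores:
#   REML: U = (y'PPy - tr(P)) / 2,  P = W - WX (X'WX)^-1 X'W
#   ML:   U = (r'W^2 r - tr(W)) / 2, r = y - X beta_hat(W)
.tau2_scoring <- function(y, v, X, restricted = TRUE, tol = 1e-10,
                          max_iter = 100L) {
  k <- length(y)
  score_info <- function(tau2) {
    w <- 1 / (v + tau2)
    B <- X * w
    A <- crossprod(X, B)
    if (restricted) {
      P <- diag(w, nrow = k) - B %*% solve(A, t(B))
      Py <- drop(P %*% y)
      list(sc = 0.5 * (sum(Py^2) - sum(diag(P))),
           info = 0.5 * sum(P * P))
    } else {
      beta <- solve(A, crossprod(B, y))
      r <- drop(y - X %*% beta)
      list(sc = 0.5 * (sum(w^2 * r^2) - sum(w)),
           info = 0.5 * sum(w^2))
    }
  }
  tau2 <- max(0, stats::var(y) - mean(v))
  converged <- FALSE
  iter <- 0L
  for (i in seq_len(max_iter)) {
    iter <- i
    si <- score_info(tau2)
    step <- si$sc / si$info
    tau2_new <- max(0, tau2 + step)
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  if (!converged && tau2 == 0 && score_info(0)$sc <= 0) converged <- TRUE
  list(tau2 = tau2, converged = converged, iter = iter)
}

#' Fit a variance-weighted meta-regression
#'
#' Fits `yi = X beta + u + e` with `u ~ N(0, tau2)` and `e ~ N(0, vi)`.
#' `method = "REML"` (default) estimates tau2 by restricted maximum
#' likelihood, `"ML"` by maximum likelihood, `"FE"` fixes tau2 = 0 (the fit
#' is then ordinary inverse-variance weighted least squares).  The ML
#' log-likelihood for the same fixed-effect structure is always computed
#' and stored as `loglik_ml` for information-criterion comparisons.
#' Pseudo-R2 is the percentage reduction in REML tau2 relative to the
#' intercept-only model, truncated to \[0, 100\].
#'
#' @param yi effect sizes.
#' @param vi sampling variances (> 0).
#' @param X moderator design matrix including the intercept column; `NULL`
#'   for intercept-only.
#' @param method `"REML"`, `"ML"` or `"FE"`.
#' @param tol tau2 convergence tolerance (default 1e-10).
#' @param max_iter scoring iteration cap (default 100).
#' @return object of class `ccre_meta_fit`: list with `beta`, `se`, `zval`,
#'   `pval`, `tau2`, `pseudo_R2`, `loglik_ml`, `k`, `p_dim`, `converged`,
#'   `method`.
#' @export
fit_meta_regression <- function(yi, vi, X = NULL,
                                method = c("REML", "ML", "FE"),
                                tol = 1e-10, max_iter = 100L) {
  method <- match.arg(method)
  yi <- as.numeric(yi); vi <- as.numeric(vi)
  k <- length(yi)
  if (length(vi) != k) stop("yi and vi lengths differ", call. = FALSE)
  if (!all(is.finite(yi))) stop("yi must be finite", call. = FALSE)
  if (!all(is.finite(vi)) || any(vi <= 0)) {
    stop("vi must be finite and > 0", call. = FALSE)
  }
  if (is.null(X)) {
    X <- matrix(1, k, 1, dimnames = list(NULL, "intrcpt"))
  }
  X <- as.matrix(X)
  p <- ncol(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- rep("", p)
  defaults <- ifelse(seq_len(p) == 1L, "intrcpt",
                     paste0("x", seq_len(p) - 1L))
  cn[!nzchar(cn)] <- defaults[!nzchar(cn)]
  colnames(X) <- cn
  qx <- qr(X)
  if (qx$rank < p) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("moderator matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (method != "FE" && k < p + 1L) {
    stop(sprintf("need k >= p + 1 for random-effects fit (k = %d, p = %d)",
                 k, p), call. = FALSE)
  }
  if (method == "FE" && k < p) {
    stop("need k >= p for a fixed-effect fit", call. = FALSE)
  }

  est <- switch(method,
    FE = list(tau2 = 0, converged = TRUE, iter = 0L),
    REML = .tau2_scoring(yi, vi, X, restricted = TRUE, tol, max_iter),
    ML = .tau2_scoring(yi, vi, X, restricted = FALSE, tol, max_iter))
  tau2 <- est$tau2
  w <- 1 / (vi + tau2)
  A <- crossprod(X, X * w)
  Ainv <- solve(A)
  beta <- drop(Ainv %*% crossprod(X * w, yi))
  names(beta) <- colnames(X)
  se <- sqrt(diag(Ainv))
  names(se) <- colnames(X)
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  # ML log-likelihood at the ML tau2 for this fixed-effect structure
  ml <- if (method == "ML") est
        else if (method == "FE") list(tau2 = 0, converged = TRUE)
        else .tau2_scoring(yi, vi, X, restricted = FALSE, tol, max_iter)
  wml <- 1 / (vi + ml$tau2)
  bml <- drop(solve(crossprod(X, X * wml), crossprod(X * wml, yi)))
  rml <- yi - drop(X %*% bml)
  loglik_ml <- -0.5 * (k * log(2 * pi) + sum(log(vi + ml$tau2)) +
                         sum(wml * rml^2))

  pseudo_R2 <- NA_real_
  if (method != "FE" && p > 1L) {
    X0 <- matrix(1, k, 1)
    t0 <- .tau2_scoring(yi, vi, X0, restricted = (method == "REML"),
                        tol, max_iter)$tau2
    pseudo_R2 <- if (t0 <= 0) 0 else 100 * max(0, (t0 - tau2) / t0)
  }

  structure(list(beta = beta, se = se, zval = zval, pval = pval,
                 tau2 = tau2, pseudo_R2 = pseudo_R2,
                 loglik_ml = loglik_ml, k = k, p_dim = p,
                 converged = est$converged && ml$converged,
                 iterations = est$iter %||% 0L, method = method),
            class = "ccre_meta_fit")
}

#' @export
print.ccre_meta_fit <- function(x, ...) {
  cat(sprintf("Meta-regression (%s), k = %d, tau2 = %.6g\n",
              x$method, x$k, x$tau2))
  if (is.finite(x$pseudo_R2)) {
    cat(sprintf("pseudo-R2 = %.2f%%\n", x$pseudo_R2))
  }
  tab <- data.frame(estimate = x$beta, se = x$se, z = x$zval, p = x$pval)
  print(tab, digits = 4)
  invisible(x)
}

#' Intercept diagnostic for the storage-bias check
#'
#' Two-sided Wald test of the fitted intercept.  In the Climate Contrast
#' design a uniform storage/maternal bias lands in the intercept, so a
#' non-significant intercept is evidence the trait changes are not driven
#' by such artefacts.
#'
#' @param fit a `ccre_meta_fit` containing an `intrcpt` term.
#' @param alpha significance level (default 0.05).
#' @return list `estimate, se, p, significant`.
#' @export
intercept_diagnostic <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "ccre_meta_fit"))
  if (!"intrcpt" %in% names(fit$beta)) {
    stop("model has no intercept term", call. = FALSE)
  }
  p <- unname(fit$pval["intrcpt"])
  list(estimate = unname(fit$beta["intrcpt"]),
       se = unname(fit$se["intrcpt"]),
       p = p, significant = p < alpha)
}
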