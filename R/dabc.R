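#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment with monotonicity enforcement, capped at
#' 1. (Equivalent to `p.adjust(p, "BH")`; kept as an explicit primitive so
#' the multiplicity control used by the differential-abundance engine is
#' fully specified and testable against the base implementation.)
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Exact mean and variance of log(Y + pseudo) for Y ~ Poisson(lambda),
# tabulated on a log-lambda grid and interpolated; asymptotic expressions
# above the grid. The mean bias E[log(Y + pseudo)] - log(lambda) is what
# the pseudo-count transform adds to the log-linear mean; the variance
# drives the per-cell weights.
log_pseudo_moments <- function(pseudo = 1, lam_max = 50, y_max = 300) {
  grid <- exp(seq(log(1e-6), log(lam_max), length.out = 400))
  ys <- 0:y_max
  lg <- log(ys + pseudo)
  mom <- vapply(grid, function(l) {
    pr <- stats::dpois(ys, l)
    m <- sum(pr * lg)
    c(m, sum(pr * lg^2) - m^2)
  }, numeric(2))
  list(
    bias = function(lam) {
      lam <- pmax(lam, 1e-6)
      out <- numeric(length(lam))
      sm <- lam < lam_max
      out[sm] <- stats::approx(log(grid), mom[1, ], xout = log(lam[sm]),
                               rule = 2)$y - log(lam[sm])
      if (any(!sm)) {
        l <- lam[!sm]
        out[!sm] <- log(l + pseudo) - l / (2 * (l + pseudo)^2) - log(l)
      }
      out
    },
    var = function(lam) {
      lam <- pmax(lam, 1e-6)
      out <- numeric(length(lam))
      sm <- lam < lam_max
      out[sm] <- stats::approx(log(grid), mom[2, ], xout = log(lam[sm]),
                               rule = 2)$y
      if (any(!sm)) out[!sm] <- 1 / lam[!sm]
      out
    })
}

#' Sampling-fraction bias-corrected differential abundance
#'
#' Per-feature log-linear model of absolute abundance with a shared
#' per-sample nuisance, the log sampling fraction, linking true abundances
#' to observed counts:
#' `log(count_ij + pseudo) = d_i + x_i' beta_j + e_ij`.
#'
#' Estimation alternates (1) per-feature least squares of the
#' offset-corrected logs on the design and (2) updating `d_i` as the mean
#' over features of the residual `y_ij - fitted_ij`, until the maximum
#' change in `d` falls below `tol` (`d` is identified only up to an
#' additive constant and is centred each iteration). With
#' `bias_correct = TRUE` (the default) the fit is then refined: the exact
#' Poisson transform bias `E[log(Y + pseudo)] - log(lambda)`, evaluated at
#' the fitted means, is subtracted from the responses (it otherwise
#' attenuates strong effects through low-count cells), and the per-feature
#' regressions are re-estimated by weighted least squares with weights
#' from the Poisson log-scale variance at the fitted mean plus a
#' per-feature lognormal dispersion estimated from the residuals;
#' bias and weights are iterated to a fixed point.
#'
#' Because the sampling fraction can be confounded with the covariates,
#' each predictor's cross-feature coefficient vector is finally centred on
#' its mode, estimated by a 20%-trimmed mean: under the premise that most
#' features are not differentially abundant, the mode is the shared
#' sampling-fraction bias. Wald statistics use the (weighted)
#' least-squares standard errors with normal p-values; Benjamini-Hochberg
#' adjustment is applied within each predictor, across features.
#'
#' @param x a `count_table` (features with all-zero counts are removed
#'   with a message).
#' @param design numeric design matrix (samples x predictors) including an
#'   intercept column; must have full column rank and fewer columns than
#'   samples.
#' @param pseudo pseudo-count added before the log (default 1).
#' @param trim trim fraction for the cross-feature mode estimate
#'   (default 0.2).
#' @param tol,max_iter convergence tolerance on `max |delta d|`
#'   (default 1e-6) and iteration cap (default 100) for the alternating
#'   stage.
#' @param bias_correct logical; apply the transform-bias and
#'   variance-weighting refinement (default `TRUE`).
#' @param log_sampling_fraction optional known per-sample log sampling
#'   fractions; when supplied, `d` is fixed at these values (no iteration,
#'   no refinement, no mode centring), so estimates reduce exactly to
#'   per-feature ordinary least squares on offset-corrected logs.
#' @return An object of class `dabc_fit`: list with matrices `beta`, `se`,
#'   `W`, `p`, `p_bh`, `significant` (features x predictors),
#'   `log_sampling_fraction` (per sample, mean-centred), `delta` (the
#'   per-predictor bias estimates removed), `features`, `predictors`,
#'   `n_iter`, `converged`.
#' @export
fit_dabc <- function(x, design, pseudo = 1, trim = 0.2,
                     tol = 1e-6, max_iter = 100, bias_correct = TRUE,
                     log_sampling_fraction = NULL) {
  stopifnot(inherits(x, "count_table"))
  X <- as.matrix(design)
  if (nrow(X) != nrow(x$counts)) stop("design rows must match samples")
  if (nrow(X) <= ncol(X)) stop("need more samples than design columns")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  counts <- x$counts
  keep <- colSums(counts) > 0
  if (any(!keep)) {
    message(sum(!keep), " all-zero feature(s) removed before fitting")
    counts <- counts[, keep, drop = FALSE]
  }
  Y <- log(counts + pseudo)                    # samples x features
  n <- nrow(Y); J <- ncol(Y); p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  H <- XtXinv %*% t(X)                         # p x n projector
  P <- X %*% H

  fixed_d <- !is.null(log_sampling_fraction)
  if (fixed_d) {
    if (length(log_sampling_fraction) != n) {
      stop("log_sampling_fraction must have one value per sample")
    }
    d <- as.numeric(log_sampling_fraction)
    B <- H %*% (Y - d)
    E <- (Y - d) - X %*% B
    SE <- sqrt(outer(diag(XtXinv), colSums(E^2) / (n - p)))
    n_iter <- 0L; converged <- TRUE
    delta <- stats::setNames(rep(0, p), colnames(X))
  } else {
    # ---- alternating estimation of d and per-feature coefficients -------
    d <- rep(0, n)
    converged <- FALSE
    for (n_iter in seq_len(max_iter)) {
      B <- H %*% (Y - d)
      d_new <- rowMeans(Y - X %*% B)
      d_new <- d_new - mean(d_new)             # identified up to a constant
      if (max(abs(d_new - d)) < tol) { d <- d_new; converged <- TRUE; break }
      d <- d_new
    }
    if (!converged) {
      stop("sampling-fraction estimation did not converge in ", max_iter,
           " iterations")
    }
    B <- H %*% (Y - d)
    E <- (Y - d) - X %*% B
    SE <- sqrt(outer(diag(XtXinv), colSums(E^2) / (n - p)))

    if (bias_correct) {
      mom <- log_pseudo_moments(pseudo)
      bias_m <- 0
      for (pass in 1:3) {                      # transform-bias fixed point (OLS)
        Ya <- Y - bias_m
        d <- rowMeans(Ya - P %*% Ya); d <- d - mean(d)
        B <- H %*% (Ya - d)
        eta <- sweep(X %*% B, 1, d, "+")
        bias_m <- matrix(mom$bias(exp(eta)), n, J)
      }
      for (round in 1:2) {                     # variance-weighted refinement
        Ya <- Y - bias_m
        d <- rowMeans(Ya - P %*% Ya); d <- d - mean(d)
        E <- (Ya - d) - X %*% B
        vpois <- matrix(mom$var(exp(eta)), n, J)
        sig2 <- pmax(colSums(E^2) / (n - p) - colMeans(vpois), 0.01)
        Wm <- 1 / (vpois + rep(sig2, each = n))
        SE <- matrix(0, p, J)
        for (j in seq_len(J)) {
          Xw <- X * Wm[, j]
          Vinv <- solve(crossprod(X, Xw))
          B[, j] <- Vinv %*% crossprod(Xw, Ya[, j] - d)
          SE[, j] <- sqrt(diag(Vinv))
        }
        eta <- sweep(X %*% B, 1, d, "+")
        bias_m <- matrix(mom$bias(exp(eta)), n, J)
      }
    }
    # centre each non-intercept predictor's coefficients on the
    # cross-feature mode (trimmed mean): most features are assumed null
    delta <- stats::setNames(rep(0, p), colnames(X))
    for (k in seq_len(p)) {
      if (colnames(X)[k] == "(Intercept)") next
      delta[k] <- mean(B[k, ], trim = trim)
      B[k, ] <- B[k, ] - delta[k]
    }
  }

  W <- B / SE
  P_ <- 2 * stats::pnorm(-abs(W))
  Pbh <- t(apply(P_, 1, bh_adjust))
  tr <- function(m) {
    m <- t(m)
    dimnames(m) <- list(colnames(Y), colnames(X))
    m
  }
  structure(list(beta = tr(B), se = tr(SE), W = tr(W), p = tr(P_),
                 p_bh = tr(Pbh), significant = tr(Pbh < 0.05),
                 log_sampling_fraction = d - mean(d), delta = delta,
                 features = colnames(Y), predictors = colnames(X),
                 n_iter = n_iter, converged = converged),
            class = "dabc_fit")
}

#' @export
print.dabc_fit <- function(x, ...) {
  cat(sprintf("bias-corrected differential-abundance fit: %d features x %d predictors (%d iterations)\n",
              length(x$features), length(x$predictors), x$n_iter))
  print(colSums(x$significant))
  invisible(x)
}

#' Significant features for one predictor
#'
#' Features whose BH-adjusted p-value for the predictor is below alpha,
#' with the percentage of all analysed features reported to one decimal.
#'
#' @param fit a `dabc_fit`.
#' @param predictor predictor (design column) name.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return list with `features`, `n_significant`, `n_total`, `pct`
#'   (one-decimal percentage of analysed features).
#' @export
significant_features <- function(fit, predictor, alpha = 0.05) {
  stopifnot(inherits(fit, "dabc_fit"))
  if (!predictor %in% fit$predictors) stop("unknown predictor: ", predictor)
  sig <- fit$p_bh[, predictor] < alpha
  list(features = fit$features[sig],
       n_significant = sum(sig),
       n_total = length(fit$features),
       pct = round(100 * sum(sig) / length(fit$features), 1))
}
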