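#' Firmicutes/Bacteroidota ratio records
#'
#' Builds the ratio of the two dominant phyla from a phylum-level
#' relative-abundance table (typically one row per individual-season after
#' replicate merging). Records with zero Bacteroidota (or zero Firmicutes,
#' whose log ratio is likewise undefined at -Inf) are excluded with a
#' warning.
#'
#' @param rel matrix of phylum relative abundances (rows = analysis units,
#'   columns include `Firmicutes` and `Bacteroidota`).
#' @param firmicutes,bacteroidota column names of the two phyla.
#' @return data.frame with `unit`, `firmicutes_rel`, `bacteroidota_rel`,
#'   `ratio`, `log_ratio`.
#' @export
compute_fb <- function(rel, firmicutes = "Firmicutes", bacteroidota = "Bacteroidota") {
  if (!all(c(firmicutes, bacteroidota) %in% colnames(rel))) {
    stop("relative-abundance table must contain columns '", firmicutes,
         "' and '", bacteroidota, "'")
  }
  f <- rel[, firmicutes]
  b <- rel[, bacteroidota]
  if (all(f == 0) || all(b == 0)) stop("all-zero phylum column")
  ok <- f > 0 & b > 0
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with a zero phylum proportion excluded")
  }
  data.frame(unit = rownames(rel)[ok],
             firmicutes_rel = f[ok], bacteroidota_rel = b[ok],
             ratio = f[ok] / b[ok], log_ratio = log(f[ok] / b[ok]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# log-likelihood based LRT between two nested lm fits (ML variance)
lm_lrt <- function(full, reduced) {
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(reduced))))
  df <- length(stats::coef(full)) - length(stats::coef(reduced))
  list(chi2 = chi2, df = df,
       p = if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE))
}

fit_ols <- function(y, X) {
  dat <- data.frame(y = y, X, check.names = FALSE)
  form <- stats::as.formula(paste("y ~ 0 +",
                                  paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  stats::lm(form, data = dat)
}

#' Linear model on the log F/B ratio with single-term-deletion LRTs
#'
#' Ordinary least squares on the natural-log ratio against the standard
#' predictor set (with GC-by-age interactions). For each deletable term, a
#' likelihood-ratio test (2 * delta log-likelihood, df = 1) against the
#' model without it; marginality is respected, so main effects contained
#' in a retained interaction are not tested alone. A full-vs-null
#' (intercept-only) comparison and a pseudo-R^2 (squared correlation of
#' fitted and observed values) are also reported.
#'
#' @param records data.frame from [compute_fb()] (or any data.frame with a
#'   `log_ratio` column) whose rows match the design.
#' @param design numeric design matrix with an `"(Intercept)"` column.
#' @return An object of class `fb_fit`: list with `coefficients`
#'   (data.frame: term, estimate, se, ci_lo, ci_hi, lrt, df, p; LRT fields
#'   `NA` for non-deletable terms), `full_null` (chi2/df/p), `pseudo_r2`,
#'   `loglik`, `n`, `design`, `response` and the `lm` fit (`model`).
#' @export
fit_fb_model <- function(records, design) {
  y <- records$log_ratio
  X <- as.matrix(design)
  if (length(y) != nrow(X)) stop("records/design length mismatch")
  if (length(y) <= ncol(X)) stop("need more records than parameters")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  full <- fit_ols(y, X)
  est <- stats::coef(full)
  se <- sqrt(diag(stats::vcov(full)))
  terms <- colnames(X)
  names(est) <- names(se) <- terms
  inter_parts <- strsplit(grep(":", terms, value = TRUE, fixed = TRUE), ":", fixed = TRUE)
  in_interaction <- unique(unlist(inter_parts))
  deletable <- vapply(terms, function(tm) {
    if (tm == "(Intercept)") return(FALSE)
    if (grepl(":", tm, fixed = TRUE)) return(TRUE)
    !(tm %in% in_interaction)
  }, logical(1))
  lrt <- df <- p <- rep(NA_real_, length(terms))
  for (k in which(deletable)) {
    red <- fit_ols(y, X[, -k, drop = FALSE])
    t3 <- lm_lrt(full, red)
    lrt[k] <- t3$chi2; df[k] <- t3$df; p[k] <- t3$p
  }
  null <- fit_ols(y, X[, "(Intercept)", drop = FALSE])
  structure(list(
    coefficients = data.frame(term = terms, estimate = unname(est),
                              se = unname(se),
                              ci_lo = unname(est - 1.96 * se),
                              ci_hi = unname(est + 1.96 * se),
                              lrt = lrt, df = df, p = p,
                              stringsAsFactors = FALSE),
    full_null = lm_lrt(full, null),
    pseudo_r2 = stats::cor(stats::fitted(full), y)^2,
    loglik = as.numeric(stats::logLik(full)),
    n = length(y), design = X, response = y, model = full),
    class = "fb_fit")
}

#' @export
print.fb_fit <- function(x, ...) {
  cat(sprintf("log F/B ratio model: n = %d, pseudo-R2 = %.3f, full-null chi2 = %.2f (df = %d, p = %.3g)\n",
              x$n, x$pseudo_r2, x$full_null$chi2, x$full_null$df, x$full_null$p))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Backward elimination of non-significant interactions
#'
#' Interaction terms with LRT p >= alpha are removed one at a time
#' (largest p first), refitting after each removal; main terms are always
#' retained.
#'
#' @param fit an `fb_fit`.
#' @param alpha retention threshold (default 0.05).
#' @return list with `fit` (the reduced `fb_fit`) and `dropped` (removed
#'   term names, in elimination order).
#' @export
reduce_fb_model <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "fb_fit"))
  dropped <- character(0)
  cur <- fit
  repeat {
    co <- cur$coefficients
    cand <- co[grepl(":", co$term, fixed = TRUE) & !is.na(co$p) & co$p >= alpha, ]
    if (nrow(cand) == 0) break
    worst <- cand$term[which.max(cand$p)]
    dropped <- c(dropped, worst)
    keep <- setdiff(colnames(cur$design), worst)
    cur <- fit_fb_model(data.frame(log_ratio = cur$response),
                        cur$design[, keep, drop = FALSE])
  }
  list(fit = cur, dropped = dropped)
}
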