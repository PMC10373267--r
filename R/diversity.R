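#' Abundance-based coverage estimator (ACE) of richness
#'
#' Chao-Lee estimator with the conventional rare/abundant threshold of 10
#' individuals: ACE = S_abund + S_rare / C_ace + F1 * gamma^2 / C_ace,
#' where C_ace = 1 - F1 / N_rare is the sample coverage of the rare class
#' and gamma^2 the rare-class coefficient of variation. When no rare class
#' exists (all observed features have > 10 individuals) no correction
#' applies and ACE equals the observed richness; likewise when the rare
#' class consists solely of singletons (coverage zero) the estimator is
#' undefined and observed richness is returned.
#'
#' @param counts nonnegative integer vector of feature counts for one
#'   sample.
#' @param rare_threshold counts <= threshold form the rare class
#'   (default 10).
#' @return ACE richness estimate (scalar).
#' @export
ace_richness <- function(counts, rare_threshold = 10) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty sample")
  rare <- counts[counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) return(s_abund + s_rare)
  fi <- tabulate(rare, nbins = rare_threshold)
  i <- seq_len(rare_threshold)
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 * gamma2 / c_ace
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning the root and all
#' observed leaves of a rooted tree with branch lengths. An edge is counted
#' when at least one observed leaf descends from it, so PD is monotone
#' nondecreasing as leaves are added.
#'
#' @param observed character vector of observed leaf labels.
#' @param tree rooted `ape::phylo` tree with branch lengths; its leaf set
#'   must contain all observed leaves.
#' @return Summed branch length (>= 0).
#' @export
faith_pd <- function(observed, tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing) > 0) {
    stop("observed features absent from tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (length(observed) == 0) return(0)
  tips <- match(observed, tree$tip.label)
  ntip <- length(tree$tip.label)
  # mark every edge on a root-to-observed-leaf path
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  used <- logical(nrow(tree$edge))
  for (tip in tips) {
    node <- tip
    while (node != root && node != 0L) {
      e <- edge_of[node]
      if (used[e]) break
      used[e] <- TRUE
      node <- parent[node]
    }
  }
  sum(tree$edge.length[used])
}

#' Alpha-diversity indices for every sample
#'
#' Computes observed richness, ACE, Shannon entropy (nats), inverse Simpson
#' and (when a tree is given) Faith's phylogenetic diversity per sample.
#' Shannon and inverse Simpson are delegated to \pkg{vegan}.
#'
#' @param x a `count_table`.
#' @param tree optional rooted `ape::phylo` with branch lengths whose leaf
#'   set contains all features; required for Faith's PD.
#' @return data.frame with columns `sample_id`, `observed`, `ace`,
#'   `shannon`, `inv_simpson`, and `faith_pd` (NA without a tree).
#' @export
diversity_indices <- function(x, tree = NULL) {
  stopifnot(inherits(x, "count_table"))
  m <- x$counts
  if (any(rowSums(m) == 0)) stop("empty sample(s): ",
                                 paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  shannon <- vegan::diversity(m, index = "shannon")
  inv_simpson <- vegan::diversity(m, index = "invsimpson")
  observed <- rowSums(m > 0)
  ace <- apply(m, 1, ace_richness)
  pd <- if (!is.null(tree)) {
    apply(m, 1, function(row) faith_pd(colnames(m)[row > 0], tree))
  } else NA_real_
  data.frame(sample_id = rownames(m), observed = observed, ace = ace,
             shannon = shannon, inv_simpson = inv_simpson, faith_pd = pd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit a linear mixed model with a subject random intercept
#'
#' Gaussian mixed model fitted by maximum likelihood (so that full/null
#' likelihood-ratio comparisons are valid), with Wald z statistics, normal
#' p-values, 95% confidence intervals (estimate +/- 1.96 SE) and a
#' Nakagawa-style conditional R^2 ((fixed + random variance) / total).
#'
#' @param response numeric response vector (one alpha-diversity index).
#' @param design fixed-effects design matrix including an intercept column.
#' @param subject subject id per observation (random-intercept grouping).
#' @return An object of class `gc_lmm`: list with `coefficients`
#'   (data.frame: term, estimate, se, ci_lo, ci_hi, z, p), `loglik`,
#'   `n_obs`, `n_subjects`, `n_fixed`, `r2_conditional`, `converged`, and
#'   the underlying `lme4` fit (`model`).
#' @export
fit_lmm <- function(response, design, subject) {
  if (length(response) != nrow(design)) stop("response/design length mismatch")
  if (length(unique(subject)) < 2) stop("need >= 2 subjects")
  if (nrow(design) <= ncol(design)) stop("need more observations than fixed-effect columns")
  dat <- list(y = as.numeric(response), X = as.matrix(design),
              subject = as.factor(subject))
  fit <- lme4::lmer(y ~ 0 + X + (1 | subject), data = dat, REML = FALSE)
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(est) <- colnames(design)
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est), se = unname(se),
                      ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
                      z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(as.numeric(as.matrix(design) %*% est))
  structure(list(coefficients = coefs,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = length(response),
                 n_subjects = length(unique(subject)),
                 n_fixed = ncol(design),
                 r2_conditional = (var_fixed + var_rand) /
                   (var_fixed + var_rand + var_resid),
                 converged = converged,
                 model = fit),
            class = "gc_lmm")
}

#' @export
print.gc_lmm <- function(x, ...) {
  cat(sprintf("linear mixed model: %d obs, %d subjects, logLik %.2f, conditional R2 %.2f\n",
              x$n_obs, x$n_subjects, x$loglik, x$r2_conditional))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Full/null likelihood-ratio test for nested mixed models
#'
#' @param full,null `gc_lmm` fits of nested models on the same data (the
#'   null must have fewer fixed-effect terms, all contained in the full
#'   model's terms, and the same number of observations).
#' @return list with `chi2` (= 2 * (llik_full - llik_null), floored at 0),
#'   `df` (difference in fixed-effect count) and `p` (upper chi-square
#'   tail; 1 when df = 0).
#' @export
full_null_lrt <- function(full, null) {
  stopifnot(inherits(full, "gc_lmm"), inherits(null, "gc_lmm"))
  if (full$n_obs != null$n_obs) stop("models fit to different data")
  if (!all(null$coefficients$term %in% full$coefficients$term)) {
    stop("null model is not nested in the full model")
  }
  df <- full$n_fixed - null$n_fixed
  if (df < 0) stop("null model has more parameters than the full model")
  chi2 <- max(0, 2 * (full$loglik - null$loglik))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Drop non-significant interaction terms and refit
#'
#' Removes every predictor-by-age interaction column (names containing
#' `":"`) whose Wald p-value is >= alpha, keeps all main terms, and refits.
#'
#' @param response,design,subject as in [fit_lmm()].
#' @param alpha retention threshold for interaction terms (default 0.05).
#' @return list with `fit` (the refitted `gc_lmm`), `dropped` (removed
#'   column names) and `design` (the reduced design matrix).
#' @export
reduce_model <- function(response, design, subject, alpha = 0.05) {
  full <- fit_lmm(response, design, subject)
  co <- full$coefficients
  inter <- grepl(":", co$term, fixed = TRUE)
  drop <- co$term[inter & co$p >= alpha]
  keep <- setdiff(colnames(design), drop)
  red_design <- design[, keep, drop = FALSE]
  fit <- if (length(drop) > 0) fit_lmm(response, red_design, subject) else full
  list(fit = fit, dropped = drop, design = red_design)
}
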