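#' Configuration for age-moderation classification
#'
#' Conditional effects are evaluated at three anchors of the z-scaled age
#' used in the fitted model: -1 SD, the mean, and +1 SD. Anchor effects
#' with magnitude at most `sign_tolerance` are treated as numerical zeros
#' and take the opposing anchor's sign, preventing spurious reversals.
#'
#' @param age_anchors strictly increasing numeric anchors on the z scale
#'   (default `c(-1, 0, 1)`).
#' @param sign_tolerance nonnegative epsilon for treating an anchor effect
#'   as zero (default 1e-9).
#' @return list of class `moderation_config`.
#' @export
moderation_config <- function(age_anchors = c(-1, 0, 1), sign_tolerance = 1e-9) {
  if (length(age_anchors) != 3 || any(diff(age_anchors) <= 0)) {
    stop("age_anchors must be 3 strictly increasing values")
  }
  if (sign_tolerance < 0) stop("sign_tolerance must be >= 0")
  structure(list(age_anchors = age_anchors, sign_tolerance = sign_tolerance),
            class = "moderation_config")
}

#' Conditional (simple-slope) effects at the age anchors
#'
#' For a predictor with main-effect coefficient `beta_main` and
#' age-interaction coefficient `beta_interaction`, the conditional log-fold
#' effect at age anchor z is exactly `beta_main + z * beta_interaction`.
#'
#' @param beta_main,beta_interaction numeric vectors (recycled together).
#' @param config a [moderation_config()].
#' @return Matrix with columns `e_m1`, `e_0`, `e_p1` (effects at the three
#'   anchors), one row per coefficient pair.
#' @export
conditional_effects <- function(beta_main, beta_interaction,
                                config = moderation_config()) {
  if (any(!is.finite(beta_main)) || any(!is.finite(beta_interaction))) {
    stop("coefficients must be finite")
  }
  z <- config$age_anchors
  out <- cbind(e_m1 = beta_main + z[1] * beta_interaction,
               e_0 = beta_main + z[2] * beta_interaction,
               e_p1 = beta_main + z[3] * beta_interaction)
  rownames(out) <- names(beta_main)
  out
}

#' Classify age moderation of a conditional effect
#'
#' A feature's effect is `reverse` when the effects at the youngest and
#' oldest anchors have opposite signs (both exceeding the tolerance in
#' magnitude); with a common sign it `amplify`s when the old-age magnitude
#' exceeds the young-age magnitude and `attenuate`s when it is smaller
#' (exact ties count as attenuation). The `_pos`/`_neg` suffix follows the
#' sign of the mean-age effect (falling back to the old-age anchor when
#' that is a numerical zero).
#'
#' @param effects matrix from [conditional_effects()] (columns `e_m1`,
#'   `e_0`, `e_p1`).
#' @param config a [moderation_config()].
#' @return Character vector of classes: `amplify_pos`, `amplify_neg`,
#'   `attenuate_pos`, `attenuate_neg`, `reverse`.
#' @export
classify_moderation <- function(effects, config = moderation_config()) {
  effects <- rbind(effects)
  if (ncol(effects) != 3) stop("effects must have 3 anchor columns")
  eps <- config$sign_tolerance
  apply(effects, 1, function(e) {
    s_young <- if (abs(e[1]) > eps) sign(e[1]) else 0
    s_old <- if (abs(e[3]) > eps) sign(e[3]) else 0
    if (s_young != 0 && s_old != 0 && s_young != s_old) return("reverse")
    # epsilon-zero anchors take the other anchor's sign
    s0 <- if (abs(e[2]) > eps) sign(e[2]) else if (s_old != 0) s_old else s_young
    suffix <- if (s0 >= 0) "pos" else "neg"
    if (abs(e[3]) > abs(e[1])) paste0("amplify_", suffix)
    else paste0("attenuate_", suffix)
  })
}

#' Relevance bin for a percent-of-features-affected value
#'
#' Ordinal scale mapping the percentage of features significantly affected
#' by a predictor to a qualitative relevance label (half-open bins):
#' \[0,5) not relevant, \[5,10) slightly, \[10,20) mildly, \[20,40)
#' considerably, \[40,100\] highly relevant.
#'
#' @param pct_significant percentage in \[0, 100\] (vectorised).
#' @return Character vector of relevance labels.
#' @export
relevance_bin <- function(pct_significant) {
  if (any(pct_significant < 0 | pct_significant > 100)) {
    stop("percentage must lie in [0, 100]")
  }
  labs <- c("not relevant", "slightly relevant", "mildly relevant",
            "considerably relevant", "highly relevant")
  labs[findInterval(pct_significant, c(0, 5, 10, 20, 40), rightmost.closed = FALSE)]
}

#' Summarise moderation classes for one predictor
#'
#' @param classes character vector of moderation classes (from
#'   [classify_moderation()]) for the significantly affected features of
#'   one predictor.
#' @param n_total number of features analysed.
#' @return list of class `moderation_summary`: `n_significant`,
#'   `pct_of_total` (one decimal), `relevance`, `pct_amplify`,
#'   `pct_attenuate`, `pct_reverse` (one-decimal shares among significant
#'   features; `NA` when none are significant), and `pct_of_total_amplify`
#'   / `_attenuate` / `_reverse` (shares among all analysed features).
#' @export
summarize_predictor <- function(classes, n_total) {
  n_sig <- length(classes)
  n_amp <- sum(startsWith(classes, "amplify"))
  n_att <- sum(startsWith(classes, "attenuate"))
  n_rev <- sum(classes == "reverse")
  if (n_amp + n_att + n_rev != n_sig) stop("unrecognised class labels")
  pct_of_total <- round(100 * n_sig / n_total, 1)
  share <- function(k) if (n_sig == 0) NA_real_ else round(100 * k / n_sig, 1)
  list(n_significant = n_sig,
       n_total = n_total,
       pct_of_total = pct_of_total,
       relevance = relevance_bin(pct_of_total),
       pct_amplify = share(n_amp),
       pct_attenuate = share(n_att),
       pct_reverse = share(n_rev),
       pct_of_total_amplify = round(100 * n_amp / n_total, 1),
       pct_of_total_attenuate = round(100 * n_att / n_total, 1),
       pct_of_total_reverse = round(100 * n_rev / n_total, 1))
}

#' Moderation summary table from a differential-abundance fit
#'
#' For each requested predictor, takes the features whose age-interaction
#' term is significant (BH-adjusted p < alpha), evaluates conditional
#' effects at the age anchors from the estimated main and interaction
#' coefficients, classifies the moderation, and summarises.
#'
#' @param fit a `dabc_fit` whose design contains, for each predictor `P`,
#'   an interaction column `P:age`.
#' @param predictors main-effect predictor names to summarise.
#' @param config a [moderation_config()].
#' @param alpha significance threshold on the interaction's BH-adjusted
#'   p-value (default 0.05).
#' @return list with `summary` (data.frame, one row per predictor) and
#'   `classes` (per-predictor named character vectors of feature classes).
#' @export
moderation_summary <- function(fit, predictors, config = moderation_config(),
                               alpha = 0.05) {
  stopifnot(inherits(fit, "dabc_fit"))
  classes <- list()
  rows <- lapply(predictors, function(pr) {
    ia <- paste0(pr, ":age")
    if (!ia %in% fit$predictors) stop("fit has no interaction column ", ia)
    sig <- fit$p_bh[, ia] < alpha
    eff <- conditional_effects(fit$beta[sig, pr], fit$beta[sig, ia], config)
    cl <- if (sum(sig) > 0) classify_moderation(eff, config) else character(0)
    names(cl) <- fit$features[sig]
    classes[[pr]] <<- cl
    s <- summarize_predictor(cl, length(fit$features))
    data.frame(predictor = pr, n_significant = s$n_significant,
               n_total = s$n_total, pct_of_total = s$pct_of_total,
               relevance = s$relevance, pct_amplify = s$pct_amplify,
               pct_attenuate = s$pct_attenuate, pct_reverse = s$pct_reverse,
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), classes = classes)
}

#' Seasonal concordance of predictor effects
#'
#' For features significant for the predictor in both seasons' fits, the
#' sign of the mean-age conditional effect (the main-effect coefficient) is
#' compared; features significant in exactly one season are labelled
#' `one-season-only`.
#'
#' @param fit_rich,fit_lean `dabc_fit` objects over the same feature
#'   universe.
#' @param predictor predictor name present in both fits.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return data.frame with columns `feature`, `status` (`concordant`,
#'   `discordant`, `one-season-only`, `not-significant`).
#' @export
seasonal_concordance <- function(fit_rich, fit_lean, predictor, alpha = 0.05) {
  stopifnot(inherits(fit_rich, "dabc_fit"), inherits(fit_lean, "dabc_fit"))
  if (!identical(sort(fit_rich$features), sort(fit_lean$features))) {
    stop("fits must share the same feature universe")
  }
  feats <- fit_rich$features
  il <- match(feats, fit_lean$features)
  sr <- fit_rich$p_bh[, predictor] < alpha
  sl <- fit_lean$p_bh[il, predictor] < alpha
  status <- rep("not-significant", length(feats))
  status[xor(sr, sl)] <- "one-season-only"
  both <- sr & sl
  same <- sign(fit_rich$beta[, predictor]) == sign(fit_lean$beta[il, predictor])
  status[both & same] <- "concordant"
  status[both & !same] <- "discordant"
  data.frame(feature = feats, status = status, stringsAsFactors = FALSE)
}
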