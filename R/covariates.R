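#' Assign a gestation day to a developmental window
#'
#' Gestation is split at day 82: days 1-82 form the early window, day 83 to
#' the day of birth the late window. With the average 164-day gestation this
#' divides pregnancy into two equal halves.
#'
#' @param timing_day integer day(s) relative to conception (day 1 = first
#'   day of gestation).
#' @param gestation_length length of gestation in days (default 164).
#' @return Character vector, `"early"` or `"late"` per day.
#' @export
assign_gestation_window <- function(timing_day, gestation_length = 164) {
  if (gestation_length < 83) stop("gestation_length must be >= 83 so both windows are nonempty")
  if (any(timing_day < 1 | timing_day > gestation_length)) {
    stop("timing_day outside gestation (1..", gestation_length, ")")
  }
  ifelse(timing_day <= 82, "early", "late")
}

#' Aggregate raw GC measurements into developmental-window means
#'
#' Maternal samples during gestation are averaged separately over the early
#' (days 1-82) and late (day 83-birth) windows; maternal samples after birth
#' are restricted to the first six months of lactation (days 0-182
#' inclusive) and averaged; offspring samples are averaged separately per
#' season. All means are plain arithmetic means of the concentrations
#' (ng/g).
#'
#' @param gc_samples data.frame with columns `subject_id`, `role`
#'   (`"mother"`/`"offspring"`), `timing_day` (day relative to conception
#'   for gestation samples, relative to birth for lactation samples; may be
#'   `NA` for offspring), `season` (`"rich"`/`"lean"`; used for offspring
#'   samples), `concentration` (ng/g, > 0), and for maternal samples a
#'   `phase` column (`"gestation"`/`"lactation"`).
#' @param gestation_length gestation length in days.
#' @param postnatal_window_days upper bound (inclusive, days after birth)
#'   for lactation samples entering the postnatal mean; default 182
#'   ("first 6 months").
#' @return data.frame with one row per mother-offspring dyad:
#'   `subject_id`, `early_pre_gc`, `late_pre_gc`, `post_gc`,
#'   `offspring_gc_rich`, `offspring_gc_lean` (NA when the offspring has no
#'   sample in that season).
#' @export
window_means <- function(gc_samples, gestation_length = 164,
                         postnatal_window_days = 182) {
  need <- c("subject_id", "role", "timing_day", "season", "concentration")
  if (!all(need %in% names(gc_samples))) {
    stop("gc_samples must have columns: ", paste(need, collapse = ", "))
  }
  if (any(gc_samples$concentration <= 0)) stop("concentration must be > 0")
  if (!"phase" %in% names(gc_samples)) {
    stop("gc_samples must have a 'phase' column (gestation/lactation) for maternal samples")
  }
  mom <- gc_samples[gc_samples$role == "mother", , drop = FALSE]
  off <- gc_samples[gc_samples$role == "offspring", , drop = FALSE]
  if (any(is.na(mom$timing_day))) stop("timing_day must be defined for maternal samples")
  subjects <- unique(gc_samples$subject_id)

  one <- function(sid) {
    m <- mom[mom$subject_id == sid, , drop = FALSE]
    ges <- m[m$phase == "gestation", , drop = FALSE]
    lac <- m[m$phase == "lactation", , drop = FALSE]
    win <- if (nrow(ges) > 0) assign_gestation_window(ges$timing_day, gestation_length) else character(0)
    early <- ges$concentration[win == "early"]
    late <- ges$concentration[win == "late"]
    post <- lac$concentration[lac$timing_day >= 0 & lac$timing_day <= postnatal_window_days]
    for (w in c("early", "late", "post")) {
      v <- switch(w, early = early, late = late, post = post)
      if (length(v) == 0) {
        stop(sprintf("subject %s has no maternal GC sample in window '%s'", sid, w))
      }
    }
    o <- off[off$subject_id == sid, , drop = FALSE]
    orich <- o$concentration[o$season == "rich"]
    olean <- o$concentration[o$season == "lean"]
    data.frame(subject_id = sid,
               early_pre_gc = mean(early), late_pre_gc = mean(late),
               post_gc = mean(post),
               offspring_gc_rich = if (length(orich)) mean(orich) else NA_real_,
               offspring_gc_lean = if (length(olean)) mean(olean) else NA_real_,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(subjects, one))
}

#' Natural-log then z-transform of a positive covariate
#'
#' Covariates are log-transformed and then standardised so each enters the
#' models with mean 0 and SD 1; the transform metadata (log-scale mean and
#' sample SD) is retained so the mapping can be inverted.
#'
#' @param values positive numeric vector, length >= 2, non-constant.
#' @return list with `z` (transformed values) and `meta`
#'   (`log_mean`, `log_sd`).
#' @export
log_z_transform <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) stop("values must be positive and finite")
  if (length(values) < 2) stop("need at least 2 values")
  lv <- log(values)
  mu <- mean(lv)
  s <- stats::sd(lv)
  if (s == 0) stop("zero variance after log transform")
  list(z = (lv - mu) / s, meta = c(log_mean = mu, log_sd = s))
}

#' Invert a log-z transform using its stored metadata
#'
#' @param z z-scaled values.
#' @param meta metadata from [log_z_transform()].
#' @return Original-scale (ng/g) values.
#' @export
inv_log_z <- function(z, meta) {
  exp(z * meta[["log_sd"]] + meta[["log_mean"]])
}

#' Build the standard model design matrix
#'
#' Assembles the fixed-effects design used throughout the analyses: the four
#' GC covariates (early gestation, late gestation, lactation, offspring
#' seasonal mean), each natural-log then z-transformed; sex (reference
#' "F"); age either as z-scaled continuous years or as class dummies
#' (reference "infant"); optionally group (reference = first level) and
#' season (reference "lean"); plus requested GC-by-age interaction columns.
#' z-scaling is always computed over the rows actually supplied, so each
#' fitted model's covariates have mean 0 and SD 1.
#'
#' @param covariates data.frame with one row per analysis unit and columns
#'   `early_pre_gc`, `late_pre_gc`, `post_gc`, `offspring_gc` (ng/g, > 0),
#'   `sex` ("F"/"M"), and `age_years` or `age_class`, optionally `group`
#'   and `season`.
#' @param age `"continuous"` (z-scaled years; used by the differential
#'   abundance and ratio models) or `"class"` (infant/juvenile/adult
#'   dummies; used by the diversity models).
#' @param interactions character vector of GC covariates whose
#'   interaction-with-age columns are added (empty for none).
#' @param include_group,include_season logical; add the group / season
#'   dummy columns.
#' @param intercept logical; prepend an intercept column.
#' @return Numeric design matrix with attributes `transform_meta` (per
#'   log-z column) and `age_meta` (mean/SD of `age_years` when continuous).
#' @export
build_design <- function(covariates,
                         age = c("continuous", "class"),
                         interactions = c("early_pre_gc", "late_pre_gc",
                                          "post_gc", "offspring_gc"),
                         include_group = FALSE,
                         include_season = FALSE,
                         intercept = TRUE) {
  age <- match.arg(age)
  gc_cols <- c("early_pre_gc", "late_pre_gc", "post_gc", "offspring_gc")
  need <- c(gc_cols, "sex", if (age == "continuous") "age_years" else "age_class")
  if (include_group) need <- c(need, "group")
  if (include_season) need <- c(need, "season")
  for (cc in need) {
    if (!cc %in% names(covariates)) stop("missing covariate column: ", cc)
    if (anyNA(covariates[[cc]])) {
      stop("missing values in covariate '", cc, "' for unit(s): ",
           paste(utils::head(which(is.na(covariates[[cc]])), 5), collapse = ", "))
    }
  }
  n <- nrow(covariates)
  meta <- list()
  cols <- list()
  for (cc in gc_cols) {
    tr <- log_z_transform(covariates[[cc]])
    cols[[cc]] <- tr$z
    meta[[cc]] <- tr$meta
  }
  cols[["sexM"]] <- as.numeric(covariates$sex == "M")
  age_meta <- NULL
  if (age == "continuous") {
    av <- covariates$age_years
    age_meta <- c(mean = mean(av), sd = stats::sd(av))
    if (age_meta[["sd"]] == 0) stop("age_years has zero variance")
    cols[["age"]] <- (av - age_meta[["mean"]]) / age_meta[["sd"]]
    age_terms <- "age"
  } else {
    ac <- factor(covariates$age_class, levels = c("infant", "juvenile", "adult"))
    if (anyNA(ac)) stop("age_class must be infant/juvenile/adult")
    cols[["age_juv"]] <- as.numeric(ac == "juvenile")
    cols[["age_adu"]] <- as.numeric(ac == "adult")
    age_terms <- c("age_juv", "age_adu")
  }
  if (include_group) {
    g <- factor(covariates$group)
    for (lev in levels(g)[-1]) cols[[paste0("group", lev)]] <- as.numeric(g == lev)
  }
  if (include_season) {
    cols[["seasonRich"]] <- as.numeric(covariates$season == "rich")
  }
  for (cc in interactions) {
    if (!cc %in% gc_cols) stop("interactions must name GC covariates; got: ", cc)
    for (at in age_terms) {
      cols[[paste0(cc, ":", at)]] <- cols[[cc]] * cols[[at]]
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- if (!is.null(covariates$sample_id)) covariates$sample_id else rownames(covariates)
  if (intercept) X <- cbind(`(Intercept)` = rep(1, n), X)
  attr(X, "transform_meta") <- meta
  attr(X, "age_meta") <- age_meta
  X
}

#' Variance-inflation-factor screen for collinear predictors
#'
#' VIF for column k is 1/(1 - R^2) from regressing it on all other
#' non-intercept columns; columns exceeding the threshold (default 5) are
#' flagged for exclusion.
#'
#' @param design numeric design matrix (an intercept column named
#'   `"(Intercept)"` is ignored in the screen).
#' @param threshold VIF above which a column is flagged (default 5).
#' @return list with `vif` (named vector; `Inf` for exactly collinear
#'   columns), `flagged` (column names with VIF > threshold) and
#'   `retained` (the rest).
#' @export
vif_screen <- function(design, threshold = 5) {
  X <- design[, setdiff(colnames(design), "(Intercept)"), drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 non-intercept columns")
  if (nrow(X) <= ncol(X)) stop("need more rows than columns")
  vif <- vapply(seq_len(ncol(X)), function(k) {
    y <- X[, k]
    Z <- cbind(1, X[, -k, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  flagged <- names(vif)[vif > threshold]
  list(vif = vif, flagged = flagged, retained = setdiff(names(vif), flagged))
}
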