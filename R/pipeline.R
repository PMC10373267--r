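#' Run configuration for the end-to-end pipeline
#'
#' A single list drives the whole run; there are no hidden defaults
#' outside these fields. Input may be a simulated cohort (via `sim`) or a
#' fixture directory written by [write_cohort()] (via `input_dir`).
#'
#' @param out_dir output directory for report tables.
#' @param sim a [sim_config()] (used when `input_dir` is `NULL`).
#' @param input_dir optional cohort fixture directory.
#' @param seed integer seed for the run; overrides the seed in `sim`.
#' @param ranks taxonomic ranks analysed by the differential-abundance
#'   stage.
#' @param seasons seasons analysed separately.
#' @param bh_q BH significance threshold (default 0.05).
#' @param vif_threshold VIF above which a predictor is excluded
#'   (default 5).
#' @param alpha significance threshold for interaction retention
#'   (default 0.05).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(), input_dir = NULL,
                       seed = sim$seed, ranks = c("phylum", "family", "genus"),
                       seasons = c("rich", "lean"), bh_q = 0.05,
                       vif_threshold = 5, alpha = 0.05) {
  for (nm in c("bh_q", "alpha")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v >= 1) stop("threshold '", nm, "' must lie in (0, 1)")
  }
  if (vif_threshold <= 0) stop("vif_threshold must be > 0")
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  structure(list(out_dir = out_dir, sim = sim, input_dir = input_dir,
                 seed = as.integer(seed), ranks = ranks, seasons = seasons,
                 bh_q = bh_q, vif_threshold = vif_threshold, alpha = alpha),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; keys under
#' `sim:` are passed to [sim_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$effect_sizes)) {
    sim_args$effect_sizes <- as.data.frame(sim_args$effect_sizes)
  }
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

log_msg <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> developmental-window covariates ->
#' alpha diversity with mixed models -> replicate merging and rank
#' aggregation -> per-rank, per-season bias-corrected differential
#' abundance -> age-moderation summaries and relevance labels ->
#' Firmicutes/Bacteroidota ratio models, and writes the report tables as
#' TSV into the output directory. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with all in-memory results (`cohort`,
#'   `diversity`, `lmm_summaries`, `dabc_fits`, `pct_grid`,
#'   `moderation`, `fb`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  logfile <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logfile), add = TRUE)

  # ---- stage: cohort -----------------------------------------------------
  cohort <- tryCatch({
    if (is.null(config$input_dir)) {
      sim <- config$sim
      sim$seed <- config$seed
      log_msg(logfile, "simulate: %d dyads, %d features, seed %d",
              sim$n_dyads, sim$n_features, sim$seed)
      simulate_cohort(sim)
    } else {
      log_msg(logfile, "load: %s", config$input_dir)
      read_cohort(config$input_dir)
    }
  }, error = function(e) stop("stage 'cohort' failed: ", conditionMessage(e)))

  md <- cohort$metadata
  covs <- cohort$covariates

  # ---- stage: alpha diversity + mixed models -----------------------------
  res_div <- tryCatch({
    div <- diversity_indices(cohort$counts, cohort$tree)
    Xdiv <- build_design(covs, age = "class", interactions = character(0),
                         include_group = TRUE, include_season = TRUE)
    lmm_rows <- list()
    for (index in c("observed", "ace", "shannon", "inv_simpson", "faith_pd")) {
      y <- div[[index]][match(covs$sample_id, div$sample_id)]
      fit <- fit_lmm(y, Xdiv, md$individual)
      null <- fit_lmm(y, Xdiv[, "(Intercept)", drop = FALSE], md$individual)
      lrt <- full_null_lrt(fit, null)
      co <- fit$coefficients
      co$index <- index
      co$full_null_chi2 <- lrt$chi2; co$full_null_df <- lrt$df
      co$full_null_p <- lrt$p; co$r2_conditional <- fit$r2_conditional
      lmm_rows[[index]] <- co
      log_msg(logfile, "diversity %s: full-null chi2 = %.2f (df = %d, p = %.3g)",
              index, lrt$chi2, lrt$df, lrt$p)
    }
    list(div = div, table = do.call(rbind, lmm_rows))
  }, error = function(e) stop("stage 'diversity' failed: ", conditionMessage(e)))
  write_tsv_table(res_div$div, file.path(config$out_dir, "diversity_indices.tsv"))
  write_tsv_table(res_div$table, file.path(config$out_dir, "diversity_models.tsv"))

  # ---- stage: merge + aggregate + differential abundance -----------------
  preds <- c("early_pre_gc", "late_pre_gc", "post_gc", "offspring_gc")
  inter <- paste0(preds, ":age")
  res_dabc <- tryCatch({
    merged <- merge_replicates(cohort$counts, md)
    fits <- list()
    grid_rows <- list()
    for (season in config$seasons) {
      rows <- rownames(merged$rel)[merged$keys$season == season]
      if (length(rows) == 0) {
        log_msg(logfile, "dabc: no samples in season %s, skipped", season)
        next
      }
      mcov <- covs[match(paste0(merged$keys[rows, "individual"], ".", season, ".1"),
                         covs$sample_id), , drop = FALSE]
      Xm <- build_design(mcov, age = "continuous", interactions = preds)
      for (rank in config$ranks) {
        agg <- aggregate_rank(merged$counts, rank)
        agg_season <- subset_samples(agg, rows)
        fit <- fit_dabc(agg_season, Xm)
        fits[[paste(rank, season, sep = ".")]] <- fit
        for (pr in c(preds, inter)) {
          sf <- significant_features(fit, pr, alpha = config$bh_q)
          grid_rows[[length(grid_rows) + 1]] <- data.frame(
            season = season, rank = rank, predictor = pr,
            n_significant = sf$n_significant, n_total = sf$n_total,
            pct = sf$pct, relevance = relevance_bin(sf$pct),
            stringsAsFactors = FALSE)
        }
        log_msg(logfile, "dabc %s/%s: %d features, %d samples", rank, season,
                length(fit$features), length(rows))
      }
    }
    list(merged = merged, fits = fits, grid = do.call(rbind, grid_rows))
  }, error = function(e) stop("stage 'dabc' failed: ", conditionMessage(e)))
  write_tsv_table(res_dabc$grid, file.path(config$out_dir, "pct_significant_grid.tsv"))

  # ---- stage: moderation -------------------------------------------------
  res_mod <- tryCatch({
    tabs <- list()
    for (nm in names(res_dabc$fits)) {
      ms <- moderation_summary(res_dabc$fits[[nm]], preds, alpha = config$bh_q)
      tab <- ms$summary
      tab$analysis <- nm
      tabs[[nm]] <- tab
    }
    do.call(rbind, tabs)
  }, error = function(e) stop("stage 'moderation' failed: ", conditionMessage(e)))
  write_tsv_table(res_mod, file.path(config$out_dir, "moderation_summary.tsv"))

  # ---- stage: F/B ratio --------------------------------------------------
  res_fb <- tryCatch({
    phy <- aggregate_rank(res_dabc$merged$counts, "phylum")
    rel_phy <- relative_abundance(phy)
    fb_rows <- list()
    for (season in config$seasons) {
      rows <- rownames(rel_phy)[res_dabc$merged$keys[rownames(rel_phy), "season"] == season]
      if (length(rows) < 12) {
        log_msg(logfile, "fb: season %s has %d records, model skipped",
                season, length(rows))
        next
      }
      rec <- compute_fb(rel_phy[rows, , drop = FALSE])
      mcov <- covs[match(paste0(res_dabc$merged$keys[rec$unit, "individual"],
                                ".", season, ".1"), covs$sample_id), , drop = FALSE]
      Xf <- build_design(mcov, age = "continuous", interactions = preds)
      fit <- fit_fb_model(rec, Xf)
      red <- reduce_fb_model(fit, alpha = config$alpha)
      co <- red$fit$coefficients
      co$season <- season
      co$pseudo_r2 <- red$fit$pseudo_r2
      co$full_null_chi2 <- red$fit$full_null$chi2
      co$full_null_df <- red$fit$full_null$df
      co$full_null_p <- red$fit$full_null$p
      fb_rows[[season]] <- co
      log_msg(logfile, "fb %s: n = %d, dropped [%s]", season, red$fit$n,
              paste(red$dropped, collapse = ", "))
    }
    do.call(rbind, fb_rows)
  }, error = function(e) stop("stage 'fb_ratio' failed: ", conditionMessage(e)))
  if (!is.null(res_fb)) {
    write_tsv_table(res_fb, file.path(config$out_dir, "fb_ratio_models.tsv"))
  }

  # ---- manifest ----------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.yaml")
  cfg_dump <- config
  cfg_dump$sim$effect_sizes <- as.list(cfg_dump$sim$effect_sizes)
  yaml::write_yaml(unclass_deep(cfg_dump), cfg_path)
  manifest <- data.frame(
    key = c("package_version", "seed", "config_md5", "n_samples", "n_features"),
    value = c(as.character(utils::packageVersion("gcmicro")),
              config$seed, unname(tools::md5sum(cfg_path)),
              nrow(cohort$counts$counts), ncol(cohort$counts$counts)),
    stringsAsFactors = FALSE)
  write_tsv_table(manifest, file.path(config$out_dir, "manifest.tsv"))

  invisible(list(cohort = cohort, diversity = res_div,
                 dabc_fits = res_dabc$fits, pct_grid = res_dabc$grid,
                 moderation = res_mod, fb = res_fb, manifest = manifest))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
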