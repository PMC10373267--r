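# Shared fixtures built in code.
#
# The recovery study (50 seeded cohorts of 200 samples x 150 features, 20%
# of features carrying designed GC effects) is used by several tests;
# compute it once per session and cache.

.recovery_cache <- new.env(parent = emptyenv())

recovery_study <- function(n_seeds = 50, seed_base = 1000) {
  key <- paste0("s", n_seeds, "_", seed_base)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  mae <- numeric(n_seeds)
  covered <- logical(0)
  mod_recovered <- numeric(n_seeds)
  d_cor <- numeric(n_seeds)
  fpr_hits <- NULL
  fpr_tot <- NULL
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_dyads = 50, n_offspring_samples_per_season = 2,
                      n_features = 150, seed = seed_base + s)
    co <- simulate_cohort(cfg)
    gt <- co$ground_truth
    fit <- fit_dabc(co$counts, gt$design)
    nn <- which(gt$classes$class != "null")
    prd <- gt$classes$predictor[nn]
    im <- cbind(nn, match(prd, colnames(gt$beta)))
    ii <- cbind(nn, match(paste0(prd, ":age"), colnames(gt$beta)))
    err_main <- fit$beta[im] - gt$beta[im]
    err_int <- fit$beta[ii] - gt$beta[ii]
    mae[s] <- mean(abs(c(err_main, err_int)))
    covered <- c(covered,
                 abs(err_main) <= 1.96 * fit$se[im],
                 abs(err_int) <= 1.96 * fit$se[ii])
    nulls <- which(gt$classes$class == "null")
    pn <- fit$p[nulls, setdiff(colnames(fit$p), "(Intercept)"), drop = FALSE]
    if (is.null(fpr_hits)) {
      fpr_hits <- colSums(pn < 0.05)
      fpr_tot <- rep(nrow(pn), ncol(pn))
    } else {
      fpr_hits <- fpr_hits + colSums(pn < 0.05)
      fpr_tot <- fpr_tot + nrow(pn)
    }
    cl <- classify_moderation(conditional_effects(fit$beta[im], fit$beta[ii]))
    mod_recovered[s] <- mean(cl == gt$classes$class[nn])
    d_cor[s] <- stats::cor(fit$log_sampling_fraction, gt$log_sampling_fraction)
  }
  out <- list(mae = mae, coverage = mean(covered),
              fpr = fpr_hits / fpr_tot, mod_recovered = mod_recovered,
              d_cor = d_cor)
  .recovery_cache[[key]] <- out
  out
}

# minimal hand-built differential-abundance fit for tests of downstream
# summaries (only the fields those functions read)
fake_dabc_fit <- function(p_bh, beta = NULL) {
  feats <- rownames(p_bh)
  if (is.null(beta)) beta <- p_bh * 0
  structure(list(beta = beta, se = p_bh * 0 + 1, W = beta, p = p_bh,
                 p_bh = p_bh, significant = p_bh < 0.05,
                 features = feats, predictors = colnames(p_bh),
                 n_iter = 0L, converged = TRUE),
            class = "dabc_fit")
}

# small deterministic count table
toy_table <- function() {
  cnt <- rbind(s1 = c(3, 4, 60, 40), s2 = c(1, 0, 30, 20), s3 = c(0, 1, 10, 80))
  colnames(cnt) <- paste0("ASV", 1:4)
  lin <- data.frame(
    feature = paste0("ASV", 1:4),
    phylum = c("Firmicutes", "Firmicutes", "Firmicutes", "Bacteroidota"),
    family = c("Lachnospiraceae", "Lachnospiraceae", "Ruminococcaceae", "Prevotellaceae"),
    genus = c("Blautia", "Blautia", "UN", "Prevotella"),
    stringsAsFactors = FALSE)
  count_table(cnt, lin)
}
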