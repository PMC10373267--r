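#' Configuration for the synthetic mother-offspring cohort simulator
#'
#' The generator emulates the structure of a cross-sectional wild-primate
#' study: mother-offspring dyads with maternal faecal GC series across a
#' 164-day gestation (split at day 82) and a 6-month lactation, offspring
#' sampled in a rich and a lean season as infants, juveniles or adults,
#' and amplicon count tables whose log absolute abundances follow a
#' log-linear model with GC-by-age interaction effects distorted by
#' sample-specific sampling fractions. Counts are Poisson-lognormal:
#' Poisson draws around `exp(log s_i + alpha_j + x_i' beta_j + e_ij)` with
#' `e_ij ~ N(0, dispersion^2)`, keeping the log-linear mean structure the
#' differential-abundance engine assumes.
#'
#' @param n_dyads number of mother-offspring dyads (default 30).
#' @param gestation_length_days gestation length (default 164; must be
#'   >= 83 so both windows are nonempty).
#' @param n_gc_samples_per_window maternal GC samples per window (early
#'   gestation, late gestation, lactation; default 6).
#' @param n_offspring_samples_per_season offspring faecal samples per
#'   season (default 4).
#' @param n_features number of features (ASVs) in the count table
#'   (default 319).
#' @param effect_sizes data.frame with columns `class`, `main`,
#'   `interaction`: designed log-fold coefficients per moderation class.
#'   The defaults place modest main effects (1 log-fold) with half-sized
#'   interactions, and a reversal class whose conditional effects flip
#'   sign between the age anchors.
#' @param prop_nonnull fraction of features carrying a designed GC effect
#'   (default 0.2); the rest are null with zero GC coefficients.
#' @param dispersion SD of the per-sample-per-feature lognormal noise on
#'   the log mean (>= 0, default 0.5).
#' @param sampling_fraction_sd SD of the per-sample log sampling fraction
#'   (>= 0, default 0.5).
#' @param depth_mean expected library size at unit sampling fraction
#'   (default 61517, a typical deeply-sequenced amplicon run).
#' @param gc_window_means geometric mean maternal GC concentration (ng/g)
#'   per window (early/late gestation, lactation).
#' @param offspring_gc_means geometric mean offspring GC (ng/g) per season
#'   (lean above rich: the lean season is the energetic bottleneck).
#' @param gc_between_sd,gc_within_sd log-scale SD between mothers and
#'   between samples within a mother.
#' @param feature_abund_sd log-scale SD of baseline feature abundances.
#' @param age_class_probs probabilities of an offspring being infant /
#'   juvenile / adult.
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   cohorts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_dyads = 30,
                       gestation_length_days = 164,
                       n_gc_samples_per_window = 6,
                       n_offspring_samples_per_season = 4,
                       n_features = 319,
                       effect_sizes = default_effect_sizes(),
                       prop_nonnull = 0.2,
                       dispersion = 0.5,
                       sampling_fraction_sd = 0.5,
                       depth_mean = 61517,
                       gc_window_means = c(early = 180, late = 210, post = 165),
                       offspring_gc_means = c(rich = 380, lean = 430),
                       gc_between_sd = 0.32,
                       gc_within_sd = 0.25,
                       feature_abund_sd = 1.5,
                       age_class_probs = c(infant = 16, juvenile = 7, adult = 7) / 30,
                       seed = 1L) {
  chk_count <- function(v, nm, min = 1) {
    if (length(v) != 1 || !is.finite(v) || v < min || v != round(v)) {
      stop("invalid config field '", nm, "': must be an integer >= ", min)
    }
  }
  chk_count(n_dyads, "n_dyads")
  chk_count(gestation_length_days, "gestation_length_days", min = 83)
  chk_count(n_gc_samples_per_window, "n_gc_samples_per_window")
  chk_count(n_offspring_samples_per_season, "n_offspring_samples_per_season")
  chk_count(n_features, "n_features", min = 5)
  chk_count(seed, "seed", min = -.Machine$integer.max)
  if (dispersion < 0) stop("invalid config field 'dispersion': must be >= 0")
  if (sampling_fraction_sd < 0) stop("invalid config field 'sampling_fraction_sd': must be >= 0")
  if (!is.finite(depth_mean) || depth_mean <= 0) stop("invalid config field 'depth_mean': must be > 0")
  if (prop_nonnull < 0 || prop_nonnull > 1) stop("invalid config field 'prop_nonnull': must be in [0, 1]")
  if (!all(c("class", "main", "interaction") %in% names(effect_sizes))) {
    stop("invalid config field 'effect_sizes': needs columns class, main, interaction")
  }
  structure(as.list(environment())[c(
    "n_dyads", "gestation_length_days", "n_gc_samples_per_window",
    "n_offspring_samples_per_season", "n_features", "effect_sizes",
    "prop_nonnull", "dispersion", "sampling_fraction_sd", "depth_mean",
    "gc_window_means", "offspring_gc_means", "gc_between_sd",
    "gc_within_sd", "feature_abund_sd", "age_class_probs", "seed")],
    class = "sim_config")
}

#' Default designed moderation classes
#'
#' @return data.frame of (class, main, interaction) log-fold coefficient
#'   pairs whose conditional effects at age anchors -1/0/+1 realise each
#'   class exactly.
#' @export
default_effect_sizes <- function() {
  data.frame(
    class = c("amplify_pos", "amplify_neg", "attenuate_pos",
              "attenuate_neg", "reverse"),
    main = c(1, -1, 1, -1, 1),
    interaction = c(0.5, -0.5, -0.5, 0.5, -2),
    stringsAsFactors = FALSE)
}

# phylum pool with assignment probabilities shaped like a typical
# catarrhine gut community (two dominant phyla, a long tail)
sim_phyla <- function() {
  c(Firmicutes = 0.55, Bacteroidota = 0.20, Spirochaetota = 0.09,
    Proteobacteria = 0.05, Verrucomicrobiota = 0.04,
    Actinobacteriota = 0.04, Cyanobacteria = 0.03)
}

#' Simulate a mother-offspring cohort with known ground truth
#'
#' Generates (1) maternal GC series over the three developmental windows
#' and offspring GC samples per season, (2) per-sample metadata (subject,
#' age, age class, sex, group, season), (3) a sample-by-feature count
#' table following the log-linear model with designed GC and GC-by-age
#' effects and per-sample sampling fractions, (4) a feature lineage table
#' and a rooted random phylogeny, and (5) the ground truth (true
#' coefficient matrix, true log sampling fractions, designed moderation
#' classes, and the true design matrix).
#'
#' @param config a [sim_config()].
#' @return list of class `gc_cohort` with elements `gc_samples`,
#'   `metadata`, `counts` (a `count_table`), `tree`, `covariates` (per
#'   offspring-sample design covariates), `ground_truth` (list: `beta`,
#'   `log_sampling_fraction`, `classes`, `design`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nd <- config$n_dyads
  moms <- sprintf("M%03d", seq_len(nd))
  offs <- sprintf("O%03d", seq_len(nd))

  # ---- offspring traits --------------------------------------------------
  age_class <- sample(c("infant", "juvenile", "adult"), nd, replace = TRUE,
                      prob = config$age_class_probs)
  age_years <- ifelse(age_class == "infant", stats::runif(nd, 0.3, 0.95),
               ifelse(age_class == "juvenile", stats::runif(nd, 4, 5.5),
                      stats::runif(nd, 6, 10)))
  sex <- sample(c("M", "F"), nd, replace = TRUE, prob = c(17, 13) / 30)
  group <- sample(c("MOT", "MST", "SST"), nd, replace = TRUE)

  # ---- maternal GC series ------------------------------------------------
  ngw <- config$n_gc_samples_per_window
  gl <- config$gestation_length_days
  gc_rows <- list()
  for (i in seq_len(nd)) {
    mom_lvl <- log(config$gc_window_means) +
      stats::rnorm(3, 0, config$gc_between_sd)
    days <- list(early = sample(1:82, ngw, replace = ngw > 82),
                 late = sample(83:gl, ngw, replace = ngw > (gl - 82)),
                 post = sample(0:182, ngw, replace = ngw > 183))
    for (w in c("early", "late", "post")) {
      conc <- stats::rlnorm(ngw, mom_lvl[[match(w, c("early", "late", "post"))]],
                            config$gc_within_sd)
      gc_rows[[length(gc_rows) + 1]] <- data.frame(
        subject_id = offs[i], role = "mother",
        phase = if (w == "post") "lactation" else "gestation",
        timing_day = days[[w]], season = NA_character_,
        concentration = conc, stringsAsFactors = FALSE)
    }
  }

  # ---- offspring samples (GC + microbiome aliquots) ----------------------
  nos <- config$n_offspring_samples_per_season
  md_rows <- list()
  for (i in seq_len(nd)) {
    off_lvl <- log(config$offspring_gc_means) +
      stats::rnorm(2, 0, config$gc_between_sd)
    for (s in c("rich", "lean")) {
      conc <- stats::rlnorm(nos, off_lvl[[match(s, c("rich", "lean"))]],
                            config$gc_within_sd)
      gc_rows[[length(gc_rows) + 1]] <- data.frame(
        subject_id = offs[i], role = "offspring", phase = NA_character_,
        timing_day = NA_integer_, season = s, concentration = conc,
        stringsAsFactors = FALSE)
      md_rows[[length(md_rows) + 1]] <- data.frame(
        sample_id = sprintf("%s.%s.%d", offs[i], s, seq_len(nos)),
        individual = offs[i], season = s, age_years = age_years[i],
        age_class = age_class[i], sex = sex[i], group = group[i],
        stringsAsFactors = FALSE)
    }
  }
  gc_samples <- do.call(rbind, gc_rows)
  metadata <- do.call(rbind, md_rows)

  # ---- design covariates (same path the analysis uses) -------------------
  wm <- window_means(gc_samples, gestation_length = gl)
  idx <- match(metadata$individual, wm$subject_id)
  covariates <- data.frame(
    sample_id = metadata$sample_id,
    early_pre_gc = wm$early_pre_gc[idx],
    late_pre_gc = wm$late_pre_gc[idx],
    post_gc = wm$post_gc[idx],
    offspring_gc = ifelse(metadata$season == "rich",
                          wm$offspring_gc_rich[idx], wm$offspring_gc_lean[idx]),
    sex = metadata$sex, age_years = metadata$age_years,
    age_class = metadata$age_class, group = metadata$group,
    season = metadata$season, stringsAsFactors = FALSE)
  X <- build_design(covariates, age = "continuous")

  # ---- features: lineage, baseline abundance, designed effects -----------
  nf <- config$n_features
  feats <- sprintf("ASV%04d", seq_len(nf))
  phyla <- sim_phyla()
  f_phy <- sample(names(phyla), nf, replace = TRUE, prob = phyla)
  n_gen <- max(2, ceiling(0.8 * nf))
  gen_pool <- sprintf("Genus_%03d", seq_len(n_gen))
  gen_phy <- sample(names(phyla), n_gen, replace = TRUE, prob = phyla)
  f_gen <- vapply(f_phy, function(ph) {
    cand <- gen_pool[gen_phy == ph]
    if (length(cand) == 0) gen_pool[1] else sample(cand, 1)
  }, character(1))
  fam_of_gen <- paste0("Family_", sprintf("%03d", (match(gen_pool, gen_pool) - 1) %/% 3 + 1))
  names(fam_of_gen) <- gen_pool
  f_fam <- fam_of_gen[f_gen]
  # a slice of features is unclassified at genus (or entirely)
  un_gen <- seq_len(nf) %in% sample(nf, round(0.05 * nf))
  un_all <- seq_len(nf) %in% sample(nf, round(0.02 * nf))
  lineages <- data.frame(
    feature = feats,
    phylum = ifelse(un_all, "UN", f_phy),
    family = ifelse(un_all, "UN", f_fam),
    genus = ifelse(un_all | un_gen, "UN", f_gen),
    stringsAsFactors = FALSE)

  base_w <- stats::rlnorm(nf, 0, config$feature_abund_sd)
  alpha <- log(config$depth_mean * base_w / sum(base_w))

  preds <- c("early_pre_gc", "late_pre_gc", "post_gc", "offspring_gc")
  beta <- matrix(0, nf, ncol(X), dimnames = list(feats, colnames(X)))
  beta[, "(Intercept)"] <- alpha
  n_nonnull <- round(config$prop_nonnull * nf)
  classes <- data.frame(feature = feats, predictor = NA_character_,
                        class = "null", stringsAsFactors = FALSE)
  if (n_nonnull > 0) {
    slots <- expand.grid(class = config$effect_sizes$class, predictor = preds,
                         stringsAsFactors = FALSE)
    pick <- sample(nf, n_nonnull)
    for (k in seq_len(n_nonnull)) {
      sl <- slots[(k - 1) %% nrow(slots) + 1, ]
      es <- config$effect_sizes[config$effect_sizes$class == sl$class, ]
      j <- pick[k]
      beta[j, sl$predictor] <- es$main
      beta[j, paste0(sl$predictor, ":age")] <- es$interaction
      classes$predictor[j] <- sl$predictor
      classes$class[j] <- sl$class
    }
  }

  # ---- counts: overdispersed Poisson around the log-linear mean ----------
  ns <- nrow(X)
  log_s <- stats::rnorm(ns, 0, config$sampling_fraction_sd)
  log_mu <- matrix(log_s, ns, nf) + X %*% t(beta)
  if (config$dispersion > 0) {
    log_mu <- log_mu + matrix(stats::rnorm(ns * nf, 0, config$dispersion), ns, nf)
  }
  counts <- matrix(stats::rpois(ns * nf, exp(log_mu)), ns, nf,
                   dimnames = list(metadata$sample_id, feats))

  tree <- ape::rtree(nf, tip.label = feats)

  structure(list(
    gc_samples = gc_samples,
    metadata = metadata,
    counts = count_table(counts, lineages),
    tree = tree,
    covariates = covariates,
    ground_truth = list(beta = beta, log_sampling_fraction = log_s,
                        classes = classes, design = X),
    config = config), class = "gc_cohort")
}

#' @export
print.gc_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d dyads, %d samples x %d features, seed %d\n",
              x$config$n_dyads, nrow(x$counts$counts), ncol(x$counts$counts),
              x$config$seed))
  invisible(x)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a cohort to a directory of plain-text fixtures
#'
#' Writes TSV count, lineage, metadata, covariate and GC-sample tables, a
#' newick tree, and ground-truth TSVs (coefficients at full precision).
#' Files round-trip losslessly through [read_cohort()].
#'
#' @param cohort a `gc_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "lineages.tsv", "metadata.tsv",
                            "covariates.tsv", "gc_samples.tsv", "tree.nwk",
                            "truth_beta.tsv", "truth_classes.tsv",
                            "truth_sampling_fractions.tsv"))
  names(paths) <- c("counts", "lineages", "metadata", "covariates",
                    "gc_samples", "tree", "beta", "classes", "fractions")
  write_count_table(cohort$counts, paths["counts"], paths["lineages"])
  write_tsv_table(cohort$metadata, paths["metadata"])
  write_tsv_table(cohort$covariates, paths["covariates"])
  write_tsv_table(cohort$gc_samples, paths["gc_samples"])
  ape::write.tree(cohort$tree, paths["tree"])
  gt <- cohort$ground_truth
  bdf <- data.frame(feature = rownames(gt$beta),
                    apply(gt$beta, 2, fmt_full),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(bdf, paths["beta"])
  write_tsv_table(gt$classes, paths["classes"])
  write_tsv_table(data.frame(sample_id = rownames(gt$design),
                             log_sampling_fraction = fmt_full(gt$log_sampling_fraction),
                             stringsAsFactors = FALSE),
                  paths["fractions"])
  invisible(paths)
}

#' Read a cohort fixture directory written by [write_cohort()]
#'
#' @param dir directory containing the fixture files.
#' @return list with `counts` (a `count_table`), `metadata`, `covariates`,
#'   `gc_samples`, `tree`, and `ground_truth` (`beta`, `classes`,
#'   `log_sampling_fraction`).
#' @export
read_cohort <- function(dir) {
  counts <- read_count_table(file.path(dir, "counts.tsv"),
                             file.path(dir, "lineages.tsv"))
  bdf <- read_tsv_table(file.path(dir, "truth_beta.tsv"))
  beta <- as.matrix(bdf[, -1, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- bdf$feature
  fr <- read_tsv_table(file.path(dir, "truth_sampling_fractions.tsv"))
  list(counts = counts,
       metadata = read_tsv_table(file.path(dir, "metadata.tsv")),
       covariates = read_tsv_table(file.path(dir, "covariates.tsv")),
       gc_samples = read_tsv_table(file.path(dir, "gc_samples.tsv")),
       tree = ape::read.tree(file.path(dir, "tree.nwk")),
       ground_truth = list(
         beta = beta,
         classes = read_tsv_table(file.path(dir, "truth_classes.tsv")),
         log_sampling_fraction = as.numeric(fr$log_sampling_fraction)))
}
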