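---
title: "Developmental glucocorticoid windows and the offspring gut microbiota: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental glucocorticoid windows and the offspring gut microbiota: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmicro)
```

## The scientific problem

Maternal glucocorticoids (GCs) reach the developing offspring during
gestation and, via milk and maternal care, during lactation. Whether such
exposure leaves a lasting mark on the offspring's gut bacterial community —
and whether the mark depends on *when* the exposure happened — is a question
about developmental programming. `gcmicro` implements an analysis pipeline
for cross-sectional mother–offspring studies built around three
developmental windows:

* **early gestation** — days 1–82 of a 164-day gestation,
* **late gestation** — day 83 to birth,
* **lactation** — the first 6 months (days 0–182) after birth,

plus the offspring's own seasonal GC level as a fourth, concurrent
covariate. For each window the maternal faecal GC metabolite concentrations
(ng/g) are averaged arithmetically; all GC covariates are
natural-log-transformed and z-scaled before modelling, so a coefficient is
the effect of a 1-SD increase on the log scale.

The downstream questions are asked of three aspects of the microbiota:

1. **Alpha diversity** — observed richness, ACE, Shannon entropy, inverse
   Simpson, and Faith's phylogenetic diversity, modelled with Gaussian
   linear mixed models (subject random intercept, maximum likelihood) and
   full/null likelihood-ratio comparisons.
2. **Composition** — per-feature differential abundance under a
   sampling-fraction bias-corrected log-linear model (below), run
   separately per taxonomic rank and season, with BH false-discovery
   control within each predictor.
3. **The Firmicutes/Bacteroidota ratio** — ordinary linear models on the
   log ratio with single-term-deletion likelihood-ratio tests.

The package's distinctive piece is the **age-moderation classification**:
for every feature whose GC-by-age interaction is significant, the
conditional (simple-slope) effect of the GC predictor is evaluated at three
anchors of z-scaled age (−1 SD, mean, +1 SD) and classified as
*amplified*, *attenuated*, or *reversed* with age; per-predictor summaries
report the shares of each class and map the percentage of features affected
onto an ordinal relevance scale ([0,5) not relevant, [5,10) slightly,
[10,20) mildly, [20,40) considerably, ≥40 highly relevant).

## The differential-abundance model

Observed counts confound true absolute abundance with a sample-specific
*sampling fraction* (DNA yield, library size, efficiency). The engine
models, for sample $i$ and feature $j$,

$$\log(c_{ij} + 1) = d_i + \mathbf{x}_i^\top \boldsymbol\beta_j + \varepsilon_{ij},$$

where $d_i$ is the log sampling fraction (identified only up to an additive
constant) and $\mathbf{x}_i$ holds the four GC covariates, sex, z-scaled
age, and the GC-by-age interactions. Estimation alternates per-feature
least squares with updating $d_i$ as the feature-mean residual; because
$d$ can be confounded with the covariates, each predictor's cross-feature
coefficient vector is centred on its mode (a 20%-trimmed mean), which is
the shared bias under the premise that most features are null.

Two refinements matter at realistic depths:

* **Transform bias.** $E[\log(Y+1)] \ne \log\lambda$ for Poisson counts;
  the discrepancy grows as $\lambda \to 0$ and attenuates strong effects
  through their low-count cells. The engine subtracts the exact Poisson
  transform bias evaluated at the fitted means and iterates to a fixed
  point.
* **Heteroscedasticity.** The log-scale counting noise shrinks with
  abundance. The final coefficients come from weighted least squares with
  weights from the exact Poisson log-scale variance at the fitted mean
  plus a per-feature lognormal dispersion estimated from the residuals.

Wald statistics use the weighted least-squares standard errors with normal
p-values; BH adjustment is applied within predictor, across features. With
known (true) sampling fractions the fit intentionally reduces to plain
per-feature least squares on offset-corrected logs — that path is the
equivalence oracle in the test suite. Structural-zero screening is not
implemented; the pseudo-count (default 1) is a configuration option.

## The synthetic cohort generator

Because the original field data require the raw sequence archive, all
validation runs on synthetic cohorts with known ground truth
(`simulate_cohort()`). The generator emulates the study conditions:

* 30 mother–offspring dyads by default; maternal GC series across a
  164-day gestation (split at day 82) and a 6-month lactation; offspring
  sampled in a rich (March–October) and a lean (November–February) season.
* Offspring ages in three clusters — infants (0.3–0.95 y), juveniles
  (4–5.5 y), adults (6–10 y) — drawn with weights 16/7/7, the cohort
  composition of a cross-sectional primate study; sex ratio 17:13; three
  social groups. Continuous age is also emitted.
* GC concentrations are log-normal: window geometric means of 180/210/165
  ng/g (early/late gestation, lactation) and 380/430 ng/g for offspring in
  the rich/lean season, with between-mother log-SD 0.32 and within-mother
  log-SD 0.25. These give window-mean SDs of roughly 55–70 ng/g across
  mothers — the order of magnitude reported for faecal
  11β-hydroxyetiocholanolone in wild macaques — and ensure the log-z
  transforms are well defined.
* Counts are **Poisson-lognormal**: Poisson draws around
  $\exp(\log s_i + \alpha_j + \mathbf{x}_i^\top\boldsymbol\beta_j +
  e_{ij})$ with $e_{ij} \sim N(0, \text{dispersion}^2)$ (default 0.5) and
  $\log s_i \sim N(0, \text{sampling\_fraction\_sd}^2)$ (default 0.5).
  This keeps the log-linear mean structure the estimator assumes, rather
  than a negative binomial whose log-mean is not linear in the design.
  Baseline abundances $\alpha_j$ are log-normal (log-SD 1.5) scaled to an
  expected depth of 61,517 reads — a typical deeply-sequenced amplicon
  library.
* 20% of features carry a designed effect: one GC predictor, one
  moderation class. The default coefficient pairs (main, interaction) are
  (1, ±0.5) for amplification/attenuation and (1, −2) for reversal, whose
  conditional effects at the age anchors realise each class exactly — the
  reversal pair flips sign between −1 SD and +1 SD of age, mirroring the
  magnitude of published log-fold effects (a few units).
* Features get a nested genus/family/phylum lineage with a
  Firmicutes-dominant community (55%/20% for the two major phyla), ~5% of
  features unclassified at genus and ~2% entirely unclassified, exercising
  the "UN:parent" pooling; the phylogeny is a random rooted tree over the
  features.

What the generator does **not** emulate: read-level artifacts (chimeras,
denoising), phylogenetic signal in the effects, true seasonal shifts in
composition, and compositional closure effects beyond the sampling
fraction. Passing recovery tests therefore demonstrate statistical
correctness of the machinery under its own model, not robustness to every
feature of real amplicon data.

## Numerical and design choices

* **Windows.** A day-82 sample is *early* (the boundary follows the
  printed day range); the postnatal window is days 0–182 inclusive
  (6 × ~30.4 days).
* **z-scaling** is computed over the rows actually fitted in each model,
  so every model's covariates have mean 0, SD 1 exactly; the transform
  metadata is stored for inversion.
* **Age** enters diversity models as a 3-level class (reference
  *infant*) and the differential-abundance and ratio models as z-scaled
  continuous age, whose ±1 SD anchors define the moderation classification.
* **ACE** uses the conventional rare/abundant threshold of 10; with no
  rare class (or a rare class of only singletons, where the coverage
  estimate degenerates) it falls back to observed richness.
* **Faith's PD** is the branch-length sum of the minimal subtree spanning
  the root and all observed leaves, computed by edge marking; it handles
  polytomous roots and is cross-checked against an independent
  implementation on binary trees.
* **Mixed models** are fitted by ML (not REML) so full/null LRTs are
  valid; random slopes are omitted (an acknowledged fallback when they
  prevent convergence in datasets of this size); Wald CIs are ±1.96 SE and
  the conditional R² is Nakagawa-style ((fixed + random)/total variance).
* **Model reduction** drops GC-by-age interactions with p ≥ 0.05 (all at
  once in the mixed models; largest-p-first backward elimination in the
  ratio models, respecting marginality: main terms inside retained
  interactions are never tested alone).
* **Moderation tolerance.** An anchor effect with |e| ≤ 1e-9 takes the
  opposing anchor's sign, so numerical zeros never produce spurious
  reversals; classification uses point estimates only, with significance
  taken from the interaction term's BH-adjusted p-value.
* **Replicate merging** averages per-sample relative abundances (library
  depth varies); rounded mean counts are emitted for the count-based
  differential-abundance fit — the choice between merged counts and
  rescaled proportions is genuinely open, and rounded mean counts keep the
  count model applicable.
* **Pseudo-R²** for the ratio models is the squared correlation of fitted
  and observed values (the conventional definition when none is stated).
* **VIF screening** flags predictors with VIF > 5 (exact collinearity is
  reported as infinite VIF); in practice this excludes *group* from the
  merged per-individual designs.
* **BH scope**: within predictor, across features, separately per rank ×
  season analysis; no global FDR across ranks.

## Problem sizes used in validation

The bundled tests and the acceptance script validate parameter recovery on
50 seeded cohorts of 200 samples × 150 features (50 dyads, 2 samples per
season, 20% non-null features), the scale at which the engine's mean
absolute coefficient error, CI coverage, null false-positive rate, and
moderation-label recovery are measured; likelihood-ratio calibration uses
200 simulated null replicates per test. These sizes were chosen to make
the Monte Carlo error of each metric small relative to its acceptance
band.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_dyads = 30, n_features = 319, seed = 1)
res <- run_pipeline(run_config(out_dir = "gc_run", sim = cfg))
res$moderation            # per-predictor moderation summaries
res$pct_grid              # percent significant per predictor x rank x season
```

## Known limitations

* The engine shares the framework's premise that most features are null;
  with a majority of truly affected features the trimmed-mean mode
  correction would absorb real signal.
* Very rare features (a handful of reads across the cohort) remain hard:
  the transform-bias correction removes most, but not all, attenuation at
  near-zero means, and their intervals are honest mostly through the
  variance weighting.
* Sampling fractions are estimated up to an additive constant; absolute
  abundance levels are not identified, only contrasts.
* The diversity models assume a Gaussian response; counts-like indices
  (observed richness) are treated on the raw scale, which is adequate at
  the depths simulated but not for shallow libraries.
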