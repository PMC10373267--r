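test_that("gestation days are assigned to early/late windows at the day-82 boundary", {
  expect_equal(assign_gestation_window(82), "early")
  expect_equal(assign_gestation_window(83), "late")
  expect_equal(assign_gestation_window(1), "early")
  expect_error(assign_gestation_window(0), "outside gestation")
  expect_error(assign_gestation_window(165, gestation_length = 164), "outside gestation")
  expect_error(assign_gestation_window(10, gestation_length = 80), "nonempty")
  # the two windows partition gestation for any admissible length
  for (L in c(83, 120, 164, 200)) {
    w <- assign_gestation_window(1:L, gestation_length = L)
    expect_equal(sum(w == "early"), 82)
    expect_equal(sum(w == "late"), L - 82)
  }
})

test_that("window means average per developmental window with the 6-month postnatal filter", {
  gc <- data.frame(
    subject_id = "O1", role = "mother",
    phase = c("gestation", "gestation", "gestation", "lactation", "lactation"),
    timing_day = c(40, 60, 100, 100, 200),
    season = NA_character_,
    concentration = c(50, 70, 20, 40, 400),
    stringsAsFactors = FALSE)
  off <- data.frame(subject_id = "O1", role = "offspring", phase = NA,
                    timing_day = NA, season = c("rich", "lean"),
                    concentration = c(100, 300), stringsAsFactors = FALSE)
  wm <- window_means(rbind(gc, off))
  expect_equal(wm$early_pre_gc, 60)        # mean(50, 70)
  expect_equal(wm$late_pre_gc, 20)
  expect_equal(wm$post_gc, 40)             # day-200 sample excluded (> 182 d)
  expect_equal(wm$offspring_gc_rich, 100)
  expect_equal(wm$offspring_gc_lean, 300)

  # one sample per window
  gc1 <- data.frame(subject_id = "O2", role = "mother",
                    phase = c("gestation", "gestation", "lactation"),
                    timing_day = c(10, 90, 30), season = NA,
                    concentration = c(10, 20, 30), stringsAsFactors = FALSE)
  wm1 <- window_means(gc1)
  expect_equal(unlist(wm1[, c("early_pre_gc", "late_pre_gc", "post_gc")],
                      use.names = FALSE), c(10, 20, 30))

  # missing window is an explicit error naming subject and window
  gc2 <- gc1[-1, ]
  expect_error(window_means(gc2), "O2.*early")
})

test_that("log-z transform standardises, rejects degenerate input, and inverts", {
  tr <- log_z_transform(c(1, exp(1)))
  expect_equal(tr$z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_error(log_z_transform(c(2, 2, 2)), "zero variance")
  expect_error(log_z_transform(c(1, -1, 3)), "positive")
  set.seed(5)
  for (r in 1:20) {
    v <- rlnorm(sample(3:40, 1), meanlog = rnorm(1), sdlog = runif(1, 0.1, 2))
    tr <- log_z_transform(v)
    expect_equal(mean(tr$z), 0, tolerance = 1e-10)
    expect_equal(sd(tr$z), 1, tolerance = 1e-10)
    expect_equal(inv_log_z(tr$z, tr$meta), v, tolerance = 1e-12)
  }
})

test_that("design matrix has reference codings, interactions, and is order-equivariant", {
  covs <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    early_pre_gc = c(100, 150, 220, 180), late_pre_gc = c(90, 120, 300, 200),
    post_gc = c(50, 60, 80, 70), offspring_gc = c(300, 500, 420, 350),
    sex = c("F", "M", "M", "F"), age_years = c(0.5, 4.5, 8, 6),
    age_class = c("infant", "juvenile", "adult", "adult"),
    group = c("MOT", "MST", "SST", "MOT"),
    season = c("lean", "rich", "rich", "lean"),
    stringsAsFactors = FALSE)
  X <- build_design(covs, age = "continuous")
  expect_equal(unname(X[, "early_pre_gc:age"]),
               unname(X[, "early_pre_gc"] * X[, "age"]))
  expect_equal(unname(X[, "sexM"]), c(0, 1, 1, 0))
  expect_equal(mean(X[, "age"]), 0, tolerance = 1e-10)
  expect_equal(sd(X[, "early_pre_gc"]), 1, tolerance = 1e-10)
  Xs <- build_design(covs, age = "class", interactions = character(0),
                     include_group = TRUE, include_season = TRUE)
  expect_equal(unname(Xs[, "seasonRich"]), c(0, 1, 1, 0))
  expect_equal(unname(Xs[, "age_juv"]), c(0, 1, 0, 0))
  expect_equal(unname(Xs[, "age_adu"]), c(0, 0, 1, 1))
  # permutation equivariance: rows follow input order, values unchanged
  perm <- c(3, 1, 4, 2)
  Xp <- build_design(covs[perm, ], age = "continuous")
  expect_equal(Xp, X[perm, ], ignore_attr = TRUE)
  # missing covariate is a named error
  covs_bad <- covs
  covs_bad$post_gc[2] <- NA
  expect_error(build_design(covs_bad, age = "continuous"), "post_gc")
})

test_that("VIF screen computes 1/(1-R2) and flags collinear columns", {
  # orthogonal design -> all VIF 1
  X <- cbind(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))
  v <- vif_screen(X)
  expect_equal(unname(v$vif), c(1, 1))
  expect_length(v$flagged, 0)
  # constructed R^2 = 0.9 -> VIF = 10, flagged
  x1 <- c(-1, -1, -1, -1, 1, 1, 1, 1) * sqrt(90 / 8)
  e <- c(-1, 1, -1, 1, 1, -1, 1, -1) * sqrt(10 / 8)
  X2 <- cbind(x1 = x1, x2 = x1 + e)
  v2 <- vif_screen(X2)
  expect_equal(unname(v2$vif), c(10, 10), tolerance = 1e-9)
  expect_setequal(v2$flagged, c("x1", "x2"))
  # duplicated column -> infinite VIF, flagged
  X3 <- cbind(a = rnorm(10), b = rnorm(10))
  X3 <- cbind(X3, dup = X3[, "a"])
  v3 <- vif_screen(X3)
  expect_true(all(is.infinite(v3$vif[c("a", "dup")])))
  expect_true(all(c("a", "dup") %in% v3$flagged))
})
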