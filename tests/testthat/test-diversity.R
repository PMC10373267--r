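star_tree <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::stree(n, type = "star", tip.label = labels)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

test_that("diversity indices match closed forms on constructed samples", {
  cnt <- rbind(u = c(t1 = 5, t2 = 5, t3 = 5, t4 = 5),
               one = c(t1 = 12, t2 = 0, t3 = 0, t4 = 0),
               mix = c(t1 = 8, t2 = 4, t3 = 4, t4 = 0))
  div <- diversity_indices(count_table(cnt), tree = star_tree(4, colnames(cnt)))
  expect_equal(div$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(div$inv_simpson[1], 4, tolerance = 1e-12)
  expect_equal(div$shannon[2], 0)
  expect_equal(div$inv_simpson[2], 1)
  # proportions (0.5, 0.25, 0.25)
  expect_equal(div$shannon[3], -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(round(div$shannon[3], 4), 1.0397)
  expect_equal(div$observed, c(4, 1, 3))
  expect_equal(div$faith_pd, c(4, 1, 3))  # unit-branch star tree
  expect_error(diversity_indices(count_table(rbind(s = c(a = 0)))), "empty sample")
})

test_that("ACE equals observed richness without a rare class and matches vegan otherwise", {
  expect_equal(ace_richness(c(20, 30, 40, 50)), 4)   # all counts > 10
  x <- c(1, 1, 2, 3, 5, 8, 13, 21, 40, 100)
  expect_equal(ace_richness(x), unname(vegan::estimateR(x)["S.ACE"]),
               tolerance = 1e-8)
  set.seed(31)
  for (r in 1:10) {
    y <- rpois(60, rlnorm(60, 1, 1.5))
    y <- y[y > 0]
    if (all(y > 10) || sum(y <= 10) == sum(y == 1)) next
    expect_equal(ace_richness(y), unname(vegan::estimateR(y)["S.ACE"]),
                 tolerance = 1e-8)
  }
})

test_that("Faith's PD spans root-to-leaf paths, is monotone, and matches picante", {
  tr <- star_tree(10)
  expect_equal(faith_pd(c("t1", "t2", "t3"), tr), 3)
  expect_equal(faith_pd(character(0), tr), 0)
  expect_error(faith_pd("nope", tr), "absent from tree")
  set.seed(7)
  btr <- ape::rtree(12)
  # monotone nondecreasing as observed leaves are added
  ord <- sample(btr$tip.label)
  pds <- vapply(seq_along(ord), function(k) faith_pd(ord[1:k], btr), 0)
  expect_true(all(diff(pds) >= -1e-12))
  expect_equal(pds[12], sum(btr$edge.length))
  # independent implementation agrees on rooted binary trees
  skip_if_not_installed("picante")
  comm <- matrix(0, 1, 12, dimnames = list("s", btr$tip.label))
  comm[1, ord[1:5]] <- 1
  expect_equal(faith_pd(ord[1:5], btr),
               picante::pd(comm, btr, include.root = TRUE)$PD,
               tolerance = 1e-10)
})

test_that("mixed model recovers means, known effects, and degenerate variance", {
  set.seed(21)
  subj <- rep(1:12, each = 4)
  y <- rnorm(12, 10, 2)[subj] + rnorm(48)
  X <- cbind(`(Intercept)` = rep(1, 48))
  fit <- fit_lmm(y, X, subj)
  expect_equal(fit$coefficients$estimate[1], mean(y), tolerance = 1e-6)
  expect_true(fit$r2_conditional > 0 && fit$r2_conditional < 1)
  # zero between-subject variance: random-intercept variance near 0
  set.seed(91)
  subj0 <- rep(1:25, each = 8)
  y0 <- rnorm(200)
  fit0 <- suppressMessages(fit_lmm(y0, cbind(`(Intercept)` = rep(1, 200)), subj0))
  vc <- as.data.frame(lme4::VarCorr(fit0$model))
  expect_lt(vc$vcov[vc$grp != "Residual"] / sum(vc$vcov), 0.1)
  # parameter recovery: known fixed effect within 3 SE in >= 95% of replicates
  set.seed(12)
  hits <- 0
  for (r in 1:100) {
    subj <- rep(1:20, each = 3)
    x <- rnorm(60)
    yy <- 2 * x + rnorm(20, 0, 0.7)[subj] + rnorm(60)
    Xr <- cbind(`(Intercept)` = 1, x = x)
    fr <- suppressMessages(fit_lmm(yy, Xr, subj))
    co <- fr$coefficients[fr$coefficients$term == "x", ]
    hits <- hits + (abs(co$estimate - 2) <= 3 * co$se)
  }
  expect_gte(hits, 95)
})

test_that("full/null LRT does the chi-square bookkeeping and rejects non-nested models", {
  set.seed(33)
  subj <- rep(1:15, each = 4)
  n <- 60
  X <- cbind(`(Intercept)` = 1,
             matrix(rnorm(n * 11), n, 11, dimnames = list(NULL, paste0("v", 1:11))))
  y <- rnorm(15)[subj] + rnorm(n) + X[, "v1"]
  full <- fit_lmm(y, X, subj)
  null <- fit_lmm(y, X[, 1, drop = FALSE], subj)
  lrt <- full_null_lrt(full, null)
  expect_equal(lrt$df, 11)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$chi2, 2 * (full$loglik - null$loglik), tolerance = 1e-10)
  # identical models: chi2 = 0, p = 1
  same <- full_null_lrt(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  other <- fit_lmm(y, cbind(`(Intercept)` = 1, w = rnorm(n)), subj)
  expect_error(full_null_lrt(full, other), "not nested")
})

test_that("model reduction drops only non-significant interaction terms", {
  set.seed(55)
  subj <- rep(1:25, each = 4)
  n <- 100
  a <- rnorm(n); age <- rnorm(n); b <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, a = a, b = b, age = age,
             `a:age` = a * age, `b:age` = b * age)
  y <- a + 0.5 * age + 2 * a * age + rnorm(25, 0, 0.5)[subj] + rnorm(n)
  red <- reduce_model(y, X, subj)
  expect_true("b:age" %in% red$dropped)        # true coefficient 0
  expect_false("a:age" %in% red$dropped)       # strong true interaction
  expect_true(all(c("a", "b", "age") %in% colnames(red$design)))
  # all interactions null -> main-effects-only model
  y2 <- a + b + rnorm(25, 0, 0.5)[subj] + rnorm(n)
  red2 <- reduce_model(y2, X, subj)
  expect_setequal(red2$dropped, c("a:age", "b:age"))
})
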