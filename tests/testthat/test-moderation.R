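test_that("conditional effects are exactly linear in the age anchors", {
  expect_equal(unname(conditional_effects(-2.24, -2.36)[1, ]),
               c(0.12, -2.24, -4.60), tolerance = 1e-12)
  expect_equal(unname(conditional_effects(0.7, 0)[1, ]), rep(0.7, 3))
  expect_equal(unname(conditional_effects(0, 1)[1, ]), c(-1, 0, 1))
  expect_equal(unname(conditional_effects(1, -2)[1, ]), c(3, 1, -1))
  set.seed(17)
  bm <- rnorm(50); bi <- rnorm(50)
  e <- conditional_effects(bm, bi)
  expect_equal(e[, "e_0"], (e[, "e_m1"] + e[, "e_p1"]) / 2, tolerance = 1e-12)
  expect_error(conditional_effects(NA, 1), "finite")
})

test_that("moderation classes follow the sign/magnitude rules", {
  cls <- function(...) classify_moderation(rbind(c(...)))
  expect_equal(unname(cls(e_m1 = 0.12, e_0 = -2.24, e_p1 = -4.60)), "reverse")
  expect_equal(unname(cls(1, 2, 3)), "amplify_pos")
  expect_equal(unname(cls(-3, -2, -1)), "attenuate_neg")
  expect_equal(unname(cls(-1, -2, -3)), "amplify_neg")
  expect_equal(unname(cls(3, 2, 1)), "attenuate_pos")
  # epsilon-zero anchor takes the other anchor's sign instead of reversing
  expect_equal(unname(cls(0, 0.5, 1)), "amplify_pos")
  expect_equal(unname(cls(1, 0.5, 0)), "attenuate_pos")
  expect_equal(unname(cls(-1e-12, -0.5, -1)), "amplify_neg")
})

test_that("relevance bins use half-open boundaries", {
  expect_equal(relevance_bin(23.2), "considerably relevant")
  expect_equal(relevance_bin(0), "not relevant")
  expect_equal(relevance_bin(10), "mildly relevant")
  expect_equal(relevance_bin(c(4.9, 5, 9.9, 19.9, 20, 39.9, 40, 100)),
               c("not relevant", "slightly relevant", "slightly relevant",
                 "mildly relevant", "considerably relevant",
                 "considerably relevant", "highly relevant", "highly relevant"))
  expect_error(relevance_bin(101), "\\[0, 100\\]")
})

test_that("predictor summaries report one-decimal shares that total 100", {
  s <- summarize_predictor(c(rep("amplify_pos", 1)), 10)
  expect_equal(s$pct_amplify, 100.0)
  expect_equal(s$pct_of_total, 10.0)
  s0 <- summarize_predictor(character(0), 50)
  expect_equal(s0$n_significant, 0)
  expect_true(is.na(s0$pct_amplify))
  expect_equal(s0$pct_of_total, 0)
  set.seed(19)
  for (r in 1:20) {
    cl <- sample(c("amplify_pos", "amplify_neg", "attenuate_pos",
                   "attenuate_neg", "reverse"), sample(1:200, 1), replace = TRUE)
    s <- summarize_predictor(cl, 400)
    expect_equal(s$pct_amplify + s$pct_attenuate + s$pct_reverse, 100,
                 tolerance = 0.1)
    # invariant to feature ordering
    s2 <- summarize_predictor(sample(cl), 400)
    expect_equal(s[names(s) != "relevance"], s2[names(s2) != "relevance"])
  }
})

test_that("designed classes are recovered exactly from true coefficients", {
  co <- simulate_cohort(sim_config(n_dyads = 12, n_features = 100, seed = 23))
  gt <- co$ground_truth
  nn <- which(gt$classes$class != "null")
  prd <- gt$classes$predictor[nn]
  eff <- conditional_effects(gt$beta[cbind(nn, match(prd, colnames(gt$beta)))],
                             gt$beta[cbind(nn, match(paste0(prd, ":age"),
                                                     colnames(gt$beta)))])
  expect_equal(unname(classify_moderation(eff)), gt$classes$class[nn])
})

test_that("moderation summaries from a fit use the interaction's significance", {
  feats <- sprintf("f%02d", 1:20)
  preds <- c("gc", "gc:age")
  p_bh <- matrix(1, 20, 2, dimnames = list(feats, preds))
  beta <- matrix(0, 20, 2, dimnames = list(feats, preds))
  p_bh[1:6, "gc:age"] <- 0.001
  beta[1:2, "gc"] <- 1; beta[1:2, "gc:age"] <- 0.5    # amplify_pos
  beta[3:4, "gc"] <- 3; beta[3:4, "gc:age"] <- -1     # attenuate_pos
  beta[5:6, "gc"] <- 1; beta[5:6, "gc:age"] <- -2     # reverse
  ms <- moderation_summary(fake_dabc_fit(p_bh, beta), "gc")
  expect_equal(ms$summary$n_significant, 6)
  expect_equal(ms$summary$pct_of_total, 30.0)
  expect_equal(ms$summary$pct_amplify, 33.3)
  expect_equal(ms$summary$pct_attenuate, 33.3)
  expect_equal(ms$summary$pct_reverse, 33.3)
  expect_equal(ms$summary$relevance, "considerably relevant")
})

test_that("seasonal concordance compares mean-age effect signs for shared hits", {
  feats <- c("f1", "f2", "f3", "f4")
  mk <- function(p, b) {
    p_bh <- matrix(p, 4, 1, dimnames = list(feats, "gc"))
    beta <- matrix(b, 4, 1, dimnames = list(feats, "gc"))
    fake_dabc_fit(p_bh, beta)
  }
  rich <- mk(c(0.01, 0.01, 0.01, 0.8), c(1, -1, 2, 1))
  lean <- mk(c(0.01, 0.01, 0.9, 0.9), c(2, 1, 1, 1))
  sc <- seasonal_concordance(rich, lean, "gc")
  expect_equal(sc$status, c("concordant", "discordant", "one-season-only",
                            "not-significant"))
  lean_bad <- mk(c(0.5, 0.5, 0.5, 0.5), 0)
  lean_bad$features <- c("f1", "f2", "f3", "zz")
  expect_error(seasonal_concordance(rich, lean_bad, "gc"), "feature universe")
})

test_that("estimated coefficients recover designed moderation labels", {
  st <- recovery_study()
  expect_gte(mean(st$mod_recovered), 0.9)
})
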