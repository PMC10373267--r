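test_that("taxonomy gate accepts hits with mean identity/coverage >= 93", {
  expect_true(accept_hit(93, 93))
  expect_false(accept_hit(100, 85))   # mean 92.5
  expect_true(accept_hit(96, 90))     # mean 93
  expect_error(accept_hit(101, 90), "\\[0, 100\\]")
  hits <- data.frame(feature = c("f1", "f2"),
                     percent_identity = c(100, 100), percent_coverage = c(85, 90),
                     phylum = "Firmicutes", family = "Lachnospiraceae",
                     genus = "Blautia", stringsAsFactors = FALSE)
  lin <- lineages_from_hits(hits)
  expect_equal(lin$genus, c("UN", "Blautia"))
  expect_equal(lin$phylum, c("UN", "Firmicutes"))
})

test_that("rank aggregation sums within labels, pools UN under parents, conserves totals", {
  ct <- toy_table()
  gen <- aggregate_rank(ct, "genus")
  # two ASVs of the same genus combine
  expect_equal(unname(gen$counts["s1", "Blautia"]), 7)
  # ASV classified to family only contributes to the UN:<family> genus row
  expect_true("UN:Ruminococcaceae" %in% colnames(gen$counts))
  expect_equal(unname(gen$counts[, "UN:Ruminococcaceae"]),
               unname(ct$counts[, "ASV3"]))
  # per-sample totals conserved at every rank
  for (rk in c("phylum", "family", "genus")) {
    agg <- aggregate_rank(ct, rk)
    expect_equal(rowSums(agg$counts), rowSums(ct$counts))
  }
  # also on a simulated cohort with unclassified features
  co <- simulate_cohort(sim_config(n_dyads = 4, n_features = 40, seed = 9))
  for (rk in c("phylum", "family", "genus")) {
    expect_equal(rowSums(aggregate_rank(co$counts, rk)$counts),
                 rowSums(co$counts$counts))
  }
})

test_that("relative abundances sum to one and average per group", {
  ct <- count_table(rbind(s1 = c(a = 60, b = 40)))
  expect_equal(unname(relative_abundance(ct)[1, ]), c(0.6, 0.4))
  ct2 <- count_table(rbind(s1 = c(a = 1, b = 0), s2 = c(a = 0, b = 1)))
  g <- relative_abundance(ct2, group_by = c("g", "g"))
  expect_equal(unname(g$mean["g", ]), c(0.5, 0.5))
  co <- simulate_cohort(sim_config(n_dyads = 4, n_features = 30, seed = 2))
  prop <- relative_abundance(co$counts)
  expect_true(all(abs(rowSums(prop) - 1) < 1e-12))
  # zero-depth sample excluded with a warning
  ct3 <- count_table(rbind(s1 = c(a = 3, b = 1), s2 = c(a = 0, b = 0)))
  expect_warning(p3 <- relative_abundance(ct3), "zero-depth")
  expect_equal(rownames(p3), "s1")
  # top-k selection returns the k largest mean-abundance features
  expect_equal(top_features(prop, 3),
               names(sort(colMeans(prop), decreasing = TRUE))[1:3])
})

test_that("replicate merging averages proportions per individual-season and is idempotent", {
  cnt <- rbind(x1 = c(a = 20, b = 80), x2 = c(a = 40, b = 60),
               x3 = c(a = 10, b = 90))
  ct <- count_table(cnt)
  md <- data.frame(sample_id = c("x1", "x2", "x3"),
                   individual = c("I1", "I1", "I2"),
                   season = c("lean", "lean", "lean"), stringsAsFactors = FALSE)
  m <- merge_replicates(ct, md)
  expect_equal(unname(m$rel["I1.lean", "a"]), 0.3)   # mean(0.2, 0.4)
  expect_equal(unname(m$rel["I2.lean", "a"]), 0.1)   # single replicate unchanged
  expect_equal(unname(m$counts$counts["I1.lean", "a"]), 30)
  # idempotence: merging the merged table changes nothing
  md2 <- data.frame(sample_id = rownames(m$rel), individual = m$keys$individual,
                    season = m$keys$season, stringsAsFactors = FALSE)
  m2 <- merge_replicates(m$counts, md2)
  expect_equal(m2$counts$counts, m$counts$counts)
  # row count follows per-season sampling coverage
  co <- simulate_cohort(sim_config(n_dyads = 6, n_features = 25, seed = 4))
  keep <- !(co$metadata$individual %in% c("O001", "O002") & co$metadata$season == "rich")
  ct_sub <- subset_samples(co$counts, co$metadata$sample_id[keep])
  ms <- merge_replicates(ct_sub, co$metadata[keep, ])
  expect_equal(sum(ms$keys$season == "lean"), 6)
  expect_equal(sum(ms$keys$season == "rich"), 4)
})

test_that("read statistics use n-1 SD and a truncated mean", {
  ct <- count_table(rbind(s1 = c(a = 10), s2 = c(a = 20), s3 = c(a = 30)))
  rs <- read_stats(ct)
  expect_equal(rs$total, 60)
  expect_equal(rs$mean, 20)
  expect_equal(rs$median, 20)
  expect_equal(rs$range, c(10, 30))
  expect_equal(rs$sd, sd(c(10, 20, 30)))
  # truncation toward zero, not rounding
  ct2 <- count_table(rbind(s1 = c(a = 62), s2 = c(a = 63)))
  expect_equal(read_stats(ct2)$mean, 62)   # 62.5 truncates to 62
  # single sample: SD undefined
  expect_true(is.na(read_stats(count_table(rbind(s1 = c(a = 5))))$sd))
})
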