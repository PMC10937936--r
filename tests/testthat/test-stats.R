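test_that("the normality gate selects the right test branch", {
  set.seed(41)
  x <- rnorm(18); y <- rnorm(13) + 5
  r <- select_test(x, y)
  expect_equal(r$test_used, "independent_t")
  expect_lt(r$p, 1e-4)
  expect_equal(r$direction, -1)

  # heavy log-normal sample fails the gate
  xl <- exp(rnorm(30, 0, 1.5)); yl <- exp(rnorm(30, 0, 1.5))
  rl <- select_test(xl, yl)
  expect_equal(rl$test_used, "mann_whitney_u")

  # paired identical samples: rank test, p = 1
  z <- rnorm(10)
  rp <- select_test(z, z, paired = TRUE)
  expect_equal(rp$test_used, "wilcoxon_signed_rank")
  expect_equal(rp$p, 1)

  expect_error(select_test(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(select_test(1:2, 3:4), "at least 3")
})

test_that("parametric branches reproduce the reference library exactly", {
  set.seed(42)
  x <- rnorm(18, 1); y <- rnorm(13)
  r <- select_test(x, y)
  ref <- t.test(x, y)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)

  d1 <- rnorm(15, 0.5); d2 <- rnorm(15)
  rp <- select_test(d1, d2, paired = TRUE)
  refp <- t.test(d1, d2, paired = TRUE)
  expect_equal(rp$p, refp$p.value, tolerance = 1e-10)
})

test_that("Pratt signed-rank agrees with the reference on zero-free data", {
  # without zero differences the Pratt and standard conventions coincide;
  # compare against the normal-approximation signed-rank test
  set.seed(43)
  for (i in 1:20) {
    d <- round(rnorm(25, 0.3), 2)
    d <- d[d != 0]
    ours <- vowelpap:::.wilcoxon_pratt(d)
    ref <- wilcox.test(d, exact = FALSE, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  }
  # all-zero differences: p = 1 by convention
  expect_equal(vowelpap:::.wilcoxon_pratt(rep(0, 8))$p, 1)
})

test_that("one-way ANOVA matches the closed-form F decomposition", {
  set.seed(44)
  vals <- rnorm(50); vw <- sample(c("i", "u", "a", "e", "o"), 50, TRUE)
  r <- anova_one_way(vals, vw)
  ref <- anova(lm(vals ~ factor(vw)))
  expect_equal(r$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # equal cell means (with within-cell spread) -> F exactly 0
  r0 <- anova_one_way(rep(c(4, 6), 10), rep(c("i", "a"), each = 10))
  expect_lt(r0$statistic, 1e-20)

  expect_error(anova_one_way(rnorm(3), c("i", "i", "a")), "fewer than 2")
})

test_that("mixed RM-ANOVA interaction equals squared t on deltas for two conditions", {
  set.seed(45)
  n1 <- 18; n2 <- 13
  dat <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:(n1 + n2)), each = 2),
    group = rep(c(rep("control", n1), rep("osa", n2)), each = 2),
    vowel = rep(c("i", "a"), n1 + n2),
    value = rnorm(2 * (n1 + n2), rep(c(25, 5), n1 + n2))
  )
  r <- anova_two_way_rm(dat)
  expect_equal(r$table$term, c("group", "vowel", "group:vowel"))
  d <- delta_table(dat, value = "value")
  tt <- t.test(delta ~ group, d, var.equal = TRUE)
  expect_equal(r$interaction_p, tt$p.value, tolerance = 1e-8)
  expect_equal(r$table$F[3], unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("RM-ANOVA excludes subjects missing a condition with a warning", {
  dat <- data.frame(
    participant_id = c("a", "a", "b", "b", "c", "c", "d", "d", "e"),
    group = c(rep("g1", 4), rep("g2", 5)),
    vowel = c("i", "a", "i", "a", "i", "a", "i", "a", "i"),
    value = rnorm(9))
  expect_warning(r <- anova_two_way_rm(dat), "excluding subject")
  expect_equal(r$n_subjects, 4)
})

test_that("feature-PAP correlation gates method on normality and flags degenerate cells", {
  set.seed(46)
  pap <- data.frame(participant_id = sprintf("P%02d", 1:31),
                    vowel = "i", pap_mm = rnorm(31, 25, 5))
  feats <- data.frame(participant_id = pap$participant_id, vowel = "i",
                      self = pap$pap_mm,
                      skewed = exp(rnorm(31, 0, 2)),
                      flat = rep(1, 31))
  expect_warning(
    cells <- correlate_features(feats, pap, feature_cols = c("self", "skewed", "flat")),
    "constant")
  self_cell <- cells[cells$feature == "self", ]
  expect_equal(self_cell$r, 1, tolerance = 1e-12)
  expect_equal(cells[cells$feature == "skewed", "method"], "spearman")
  expect_true(is.na(cells[cells$feature == "flat", "r"]))
  # wide heatmap export
  wide <- correlation_matrix(cells)
  expect_equal(names(wide), c("feature", "r_i"))
  expect_equal(nrow(wide), 3)
})

test_that("delta tables recompute See minus Sah", {
  pap <- data.frame(participant_id = rep(c("a", "b"), each = 5),
                    group = "control",
                    vowel = rep(c("i", "u", "a", "e", "o"), 2),
                    pap_mm = c(25, 22, 5, 6, 6, 20, 19, 7, 8, 7))
  d <- delta_table(pap)
  expect_equal(d$delta, d$value_see - d$value_sah)
  expect_equal(d$delta, c(20, 13))
})
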