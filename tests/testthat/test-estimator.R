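test_that("fold plans have the published 125/25 arithmetic and obey grouping", {
  fp <- make_folds(150, "by_observation", seed = 3)
  expect_equal(sort(unique(fp$fold)), 1:6)
  expect_true(all(table(fp$fold) == 25))
  for (f in 1:6) expect_equal(sum(fp$fold != f), 125)

  fp155 <- make_folds(155, "by_observation", seed = 3)
  expect_equal(sort(as.integer(table(fp155$fold))), c(25, 26, 26, 26, 26, 26))

  ids <- rep(sprintf("P%02d", 1:31), each = 5)
  fpp <- make_folds(155, "by_participant", seed = 3, participant_ids = ids)
  spans <- tapply(fpp$fold, ids, function(v) length(unique(v)))
  expect_true(all(spans == 1))

  expect_identical(make_folds(150, seed = 8)$fold, make_folds(150, seed = 8)$fold)
  expect_error(make_folds(5), "at least 6")
  expect_error(make_folds(155, "by_participant", seed = 1), "participant_ids")
})

test_that("a realizable linear target is fit exactly by the linear step", {
  set.seed(51)
  x <- matrix(rnorm(60 * 30), 60, 30)
  beta <- rnorm(30)
  y <- drop(x %*% beta) + 3
  models <- fit_step1(x, y, seed = 1,
                      config = list(rf_ntree = 30, mlp_epochs = 5, cnn_epochs = 5))
  pr <- predict(models, x)
  expect_lt(sqrt(mean((pr[, "linear"] - y)^2)), 1e-6)
})

test_that("constant targets are predicted exactly by every model", {
  set.seed(52)
  x <- matrix(rnorm(40 * 30), 40, 30)
  y <- rep(7, 40)
  models <- suppressWarnings(
    fit_step1(x, y, seed = 1,
              config = list(rf_ntree = 30, mlp_epochs = 20, cnn_epochs = 20)))
  pr <- predict(models, x)
  expect_lt(max(abs(pr - 7)), 1e-6)
})

test_that("fit_step1 validates its inputs", {
  expect_error(fit_step1(matrix(rnorm(10 * 5), 10, 5), rnorm(10)),
               "at least 20")
  x <- matrix(rnorm(30 * 30), 30, 30, dimnames = list(NULL, paste0("c", 1:30)))
  x[, 2] <- NA
  expect_error(fit_step1(x, rnorm(30)), "c2")
  x[, 2] <- 1; x[3, 5] <- Inf
  expect_error(fit_step1(x, rnorm(30)), "c5")
})

test_that("the combiner rejects misaligned inputs and tracks an informative model", {
  set.seed(53)
  n <- 600
  y <- rnorm(n, 20, 5)
  oof <- cbind(linear = y + rnorm(n, 0, 2), forest = rnorm(n, 20, 5),
               ann = rnorm(n, 20, 5), cnn = rnorm(n, 20, 5))
  expect_error(fit_step2(oof[1:100, ], y), "misaligned")
  expect_error(fit_step2(oof[, c(2, 1, 3, 4)], y), "expected columns")

  # train on half, evaluate on the other half: the combiner should track
  # the informative input closely despite three noise inputs
  tr <- 1:(n / 2); te <- (n / 2 + 1):n
  comb <- fit_step2(oof[tr, ], y[tr], seed = 2, ntree = 400)
  pred <- predict(comb, oof[te, ])
  r_comb <- cor(pred, y[te])
  r_info <- cor(oof[te, "linear"], y[te])
  expect_gt(r_comb, r_info - 0.05)
})

test_that("evaluation metrics follow their closed forms", {
  y <- c(10, 15, 20, 25, 30, 35)
  p0 <- data.frame(fold = rep(1:2, 3), pap_mm = y, stacked = y)
  e0 <- evaluate_estimation(p0)
  expect_equal(e0$overall$rmse, 0)
  expect_equal(e0$overall$r, 1)

  p2 <- data.frame(fold = rep(1:2, 3), pap_mm = y, stacked = y + 2)
  e2 <- evaluate_estimation(p2)
  expect_equal(e2$overall$rmse, 2)
  expect_equal(e2$overall$r, 1)

  pc <- data.frame(fold = rep(1:2, 3), pap_mm = y, stacked = rep(mean(y), 6))
  expect_warning(ec <- evaluate_estimation(pc), "zero-variance")
  expect_true(is.na(ec$overall$r))
  expect_equal(ec$overall$rmse, sqrt(mean((y - mean(y))^2)))
})

test_that("the stack learns PAP on a default cohort and stacking does no harm", {
  fx <- fixture_cohort_features()
  est <- estimate_pap(fx$features, fx$cohort$pap, seed = 17)
  ov <- est$overall
  step1 <- ov[ov$model %in% c("linear", "forest", "ann", "cnn"), ]
  expect_true(all(step1$r > 0.5),
              info = paste(step1$model, round(step1$r, 3), collapse = "; "))
  r_stack <- ov$r[ov$model == "stacked"]
  expect_gte(r_stack, max(step1$r) - 0.05)
  expect_lt(ov$rmse[ov$model == "stacked"], sd(fx$cohort$pap$pap_mm))
  # pooled metrics recompute from the per-sample predictions
  pr <- est$predictions
  expect_equal(ov$rmse[ov$model == "stacked"],
               sqrt(mean((pr$stacked - pr$pap_mm)^2)))
})

test_that("test-fold statistics never influence training", {
  fx <- fixture_cohort_features()
  m <- merge(fx$features,
             fx$cohort$pap[, c("participant_id", "vowel", "pap_mm")],
             by = c("participant_id", "vowel"))
  x <- as.matrix(m[, intersect(feature_names(), names(m))])
  y <- m$pap_mm
  fp <- make_folds(nrow(x), seed = 7)
  tr <- fp$fold != 1
  f1 <- fit_step1(x[tr, ], y[tr], seed = 9, config = light_config)
  # corrupt the held-out fold; the fitted state must be unchanged
  x2 <- x
  x2[!tr, ] <- 1e6
  f2 <- fit_step1(x2[tr, ], y[tr], seed = 9, config = light_config)
  expect_identical(f1$linear, f2$linear)
  expect_identical(f1$standardize$mu, f2$standardize$mu)
  expect_identical(predict(f1, x[!tr, ]), predict(f2, x[!tr, ]))
})

test_that("estimation is deterministic under a fixed seed", {
  fx <- fixture_cohort_features()
  sub <- fx$features[fx$features$vowel %in% c("i", "a"), ]
  e1 <- estimate_pap(sub, fx$cohort$pap, seed = 23, config = light_config)
  e2 <- estimate_pap(sub, fx$cohort$pap, seed = 23, config = light_config)
  expect_identical(e1$predictions, e2$predictions)
})
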