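# Recoverable-target fixture: many weak correlated edges whose aggregate
# signal dominates the fixed penalties.
linear_age_features <- function(n = 400, p = 50, noise = 0.01, seed = 21) {
  set.seed(seed)
  age <- runif(n, 15, 80)
  slopes <- rep(c(0.3, -0.3), length.out = p)
  x <- outer(age - 47, slopes) + matrix(rnorm(n * p, 0, noise), n, p)
  list(features = make_features(x), age = age)
}

test_that("stratified folds partition subjects and cover the age span", {
  set.seed(2)
  ages <- runif(137, 12, 82)
  fold <- make_folds(ages, k = 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(max(table(fold)) - min(table(fold)) <= 1)
  # every fold spans most of the age range thanks to decile stratification
  for (f in 1:5) expect_gt(diff(range(ages[fold == f])), 40)
  expect_identical(fold, make_folds(ages, k = 5, seed = 3))
})

test_that("out-of-fold discipline: each subject predicted by a model that never saw them", {
  d <- linear_age_features(n = 60, p = 10)
  fit <- fit_base(d$features, d$age, kind = "ridge", seed = 4)
  for (f in seq_len(fit$k)) {
    held <- fit$oof$subject_id[fit$fold == f]
    expect_length(intersect(held, fit$train_ids[[f]]), 0)
    expect_setequal(c(held, fit$train_ids[[f]]), fit$oof$subject_id)
  }
  expect_true(all(!is.na(fit$oof$oof_pred)))
})

test_that("all three learners recover a noiseless linear target (OOF MAE < 0.1)", {
  d <- linear_age_features()
  for (kind in c("elastic_net", "ridge", "bayesian_ridge")) {
    fit <- fit_base(d$features, d$age, kind = kind, seed = 5)
    expect_lt(mean(abs(fit$oof$oof_pred - d$age)), 0.1)
  }
})

test_that("ridge matches its closed form on a tiny system", {
  x <- matrix(c(1, -1, 0.5, 2, 0, -2), nrow = 3) # 3 subjects x 2 edges
  xc <- sweep(x, 2, colMeans(x))
  y <- c(1, 2, 4)
  yc <- y - mean(y)
  lambda <- 1.3
  oracle <- solve(crossprod(xc) + lambda * diag(2), crossprod(xc, yc))
  fit <- brainpad:::ridge_solve(x, y, lambda = lambda)
  expect_equal(fit$coef, drop(oracle), tolerance = 1e-10)
  # dual (p > n) path agrees with the primal closed form
  set.seed(6)
  x2 <- matrix(rnorm(5 * 9), 5, 9)
  y2 <- rnorm(5)
  fit2 <- brainpad:::ridge_solve(x2, y2, lambda = 2)
  xc2 <- sweep(x2, 2, colMeans(x2))
  oracle2 <- solve(crossprod(xc2) + 2 * diag(9), crossprod(xc2, y2 - mean(y2)))
  expect_equal(fit2$coef, drop(oracle2), tolerance = 1e-8)
})

test_that("bayesian ridge approaches OLS on well-determined noiseless data", {
  set.seed(7)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- drop(x %*% c(2, -1, 0.5)) + 10
  fit <- brainpad:::bayesian_ridge_solve(x, y)
  expect_equal(fit$coef, c(2, -1, 0.5), tolerance = 1e-3)
  expect_equal(fit$intercept, 10, tolerance = 1e-2)
})

test_that("identical subject order and seed give identical predictions; permuted order preserves accuracy", {
  d <- linear_age_features(n = 100, p = 20, noise = 2)
  f1 <- fit_base(d$features, d$age, kind = "ridge", seed = 8)
  f2 <- fit_base(d$features, d$age, kind = "ridge", seed = 8)
  expect_identical(f1$oof$oof_pred, f2$oof$oof_pred)
  perm <- sample(seq_along(d$age))
  f3 <- fit_base(d$features[perm, ], d$age[perm], kind = "ridge", seed = 8)
  mae1 <- mean(abs(f1$oof$oof_pred - d$age))
  mae3 <- mean(abs(f3$oof$oof_pred - d$age[perm]))
  expect_lt(abs(mae1 - mae3), 0.25 * mae1 + 0.1)
})

test_that("fit_base rejects invalid inputs", {
  d <- linear_age_features(n = 12, p = 4)
  expect_error(fit_base(d$features[1:8, ], d$age[1:8], k = 5), "folds|subjects")
  expect_error(fit_base(d$features, rep(30, 12)), "constant")
  expect_error(fit_base(d$features, c(d$age[-1], NA)), "finite")
})

test_that("stacking is OLS on out-of-fold columns; degenerate cases behave", {
  set.seed(9)
  age <- runif(80, 20, 70)
  oof <- cbind(a = age + rnorm(80), b = age + rnorm(80, 0, 5),
               c = rnorm(80, 45, 10))
  st <- fit_stacking(oof, age)
  oracle <- coef(lm(age ~ oof))
  expect_equal(unname(c(st$intercept, st$weights)), unname(oracle),
               tolerance = 1e-8)
  # identical columns -> warning + least-norm fit, predictions unchanged
  oof2 <- cbind(a = age + rnorm(80), b = 0, c = 0)
  oof2[, "b"] <- oof2[, "a"]; oof2[, "c"] <- oof2[, "a"]
  expect_warning(st2 <- fit_stacking(oof2, age), "rank-deficient")
  pred2 <- drop(oof2 %*% st2$weights) + st2$intercept
  cal <- lm(age ~ oof2[, "a"])
  expect_equal(pred2, unname(fitted(cal)), tolerance = 1e-6)
})

test_that("a perfect base learner keeps the stack near-perfect despite noise learners", {
  set.seed(10)
  n <- 200
  age <- runif(n, 15, 80)
  oof <- cbind(good = age, noise1 = rnorm(n, 45, 15), noise2 = rnorm(n, 45, 15))
  st <- fit_stacking(oof, age)
  new_age <- runif(100, 15, 80)
  new_base <- cbind(good = new_age, noise1 = rnorm(100, 45, 15),
                    noise2 = rnorm(100, 45, 15))
  pred <- drop(new_base %*% st$weights) + st$intercept
  expect_lte(mean(abs(pred - new_age)), 0 + 0.1) # good learner's MAE is 0
})

test_that("evaluate matches naive loop oracles and definitional cases", {
  expect_equal(evaluate(c(20, 30), c(25, 25)),
               tibble::tibble(mae = 5, mse = 25, r2 = -Inf))
  truth <- c(10, 20, 30)
  expect_equal(evaluate(truth, truth)$mae, 0)
  expect_equal(evaluate(truth, truth)$r2, 1)
  expect_equal(evaluate(rep(20, 3), truth)$r2, 0)
  set.seed(11)
  pred <- rnorm(50, 40, 10); truth <- rnorm(50, 40, 10)
  m <- evaluate(pred, truth)
  mae_o <- 0; mse_o <- 0
  for (i in 1:50) {
    mae_o <- mae_o + abs(pred[i] - truth[i]) / 50
    mse_o <- mse_o + (pred[i] - truth[i])^2 / 50
  }
  r2_o <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
  expect_equal(m$mae, mae_o, tolerance = 1e-12)
  expect_equal(m$mse, mse_o, tolerance = 1e-12)
  expect_equal(m$r2, r2_o, tolerance = 1e-12)
  expect_error(evaluate(1:3, 1:4), "length")
})

test_that("feature importance is normalized, rank-consistent and finds planted signal", {
  d <- linear_age_features(n = 100, p = 10, noise = 1)
  fit <- fit_base(d$features, d$age, kind = "ridge", seed = 12)
  imp <- feature_importance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$importance[order(imp$rank)]) <= 1e-15))

  # planted signal: only 10 designated edges carry age information
  set.seed(13)
  n <- 800; p <- 60
  age <- runif(n, 15, 80)
  x <- matrix(rnorm(n * p, 0, 0.5), n, p)
  designated <- 1:10
  x[, designated] <- x[, designated] + outer(age - 47, rep(0.1, 10))
  ft <- make_features(cbind(x, matrix(0, n, 6)) [, 1:66]) # 66 edges -> R = 12
  model <- fit_brainage(ft, age, seed = 13)
  top10 <- feature_importance(model, top_n = 10)
  hits <- sum(top10$edge %in% edge_names(12)[designated])
  expect_gte(hits, 8)
})

test_that("stacked model beats or matches its best base learner out of fold", {
  cohort <- generate_cohort(small_config(n_controls = 250, n_patients = 1,
                                         seed = 44))
  ctrl <- cohort$phenotypes$group == "control"
  model <- fit_brainage(cohort$features[ctrl, ], cohort$phenotypes$age[ctrl],
                        seed = 44)
  td <- tidy(model)
  stacked <- td$oof_mae[td$learner == "stacked"]
  best_base <- min(td$oof_mae[td$learner != "stacked"])
  expect_lte(stacked, best_base + 0.5)
  g <- glance(model)
  expect_equal(g$n, 250)
  expect_lt(g$mae, 0.6 * sd(cohort$phenotypes$age[ctrl]))
})

test_that("edge_age_correlations partitions edges and flags constants", {
  set.seed(14)
  n <- 120
  age <- runif(n, 15, 80)
  x <- cbind(age, -age + rnorm(n, 0, 30), rep(1, n),
             matrix(rnorm(n * 3), n, 3))
  ft <- make_features(x) # 6 edges -> R = 4
  eac <- edge_age_correlations(ft, age)
  s <- eac$summary
  expect_equal(s$n_positive + s$n_negative + s$n_zero, 6)
  expect_equal(s$max_r, 1, tolerance = 1e-12)
  expect_equal(s$max_edge, eac$edges$edge[1])
  expect_true(eac$edges$constant[3])
  expect_equal(eac$edges$r[3], 0)
  td <- tidy(eac)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(glance(eac)), 1)
})

test_that("per-fold prediction matrix feeds fold-wise metrics", {
  d <- linear_age_features(n = 80, p = 12, noise = 3)
  model <- fit_brainage(d$features, d$age, seed = 15)
  per <- predict(model, d$features, per_fold = TRUE)
  expect_equal(dim(per), c(80, 5))
  avg <- predict(model, d$features)
  expect_equal(rowMeans(per), avg, tolerance = 1e-10, ignore_attr = TRUE)
  m <- brainpad:::metrics_by_fold(model, d$features, d$age, "validation")
  expect_equal(nrow(m), 4) # 3 base + stacked
  expect_true(all(m$mae > 0 & m$mae_sd >= 0))
})
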