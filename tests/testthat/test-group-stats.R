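test_that("compare_groups reproduces the hand-computed effect size", {
  d <- tibble::tibble(pad = c(1, 2, 3, 3, 4, 5), g = rep(c("a", "b"), each = 3))
  cmp <- compare_groups(d, pad, g)
  expect_equal(cmp$difference, 2)
  expect_equal(cmp$cohens_d, 2) # pooled SD is exactly 1
  expect_equal(cmp$means, c(2, 4))
  td <- tidy(cmp)
  expect_equal(td$n_a, 3)
  expect_true(td$conf_low < 2 && td$conf_high > 2)
  # identical groups: zero difference and d
  d0 <- tibble::tibble(pad = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  cmp0 <- compare_groups(d0, pad, g)
  expect_equal(cmp0$difference, 0)
  expect_equal(cmp0$cohens_d, 0)
  # degenerate: both groups constant and equal
  dc <- tibble::tibble(pad = rep(5, 6), g = rep(c("a", "b"), each = 3))
  expect_error(compare_groups(dc, pad, g), "undefined")
})

test_that("welch test agrees with t.test and a permutation oracle", {
  set.seed(23)
  a <- rnorm(12, 0, 1)
  b <- rnorm(12, 1, 1.5)
  d <- tibble::tibble(pad = c(a, b), g = rep(c("a", "b"), each = 12))
  cmp <- compare_groups(d, pad, g)
  ref <- t.test(b, a)
  expect_equal(cmp$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-12)
  # permutation distribution of the Welch statistic
  obs <- abs(cmp$t)
  pooled <- c(a, b)
  perm_p <- mean(replicate(4000, {
    idx <- sample(24, 12)
    abs(t.test(pooled[idx], pooled[-idx])$statistic) >= obs
  }))
  expect_lt(abs(perm_p - cmp$p_value), 0.05)
  # pooled-variance variant matches var.equal t.test
  cmp_s <- compare_groups(d, pad, g, var_equal = TRUE)
  ref_s <- t.test(b, a, var.equal = TRUE)
  expect_equal(cmp_s$p_value, ref_s$p.value, tolerance = 1e-12)
})

test_that("compare_groups is calibrated under the null", {
  set.seed(24)
  rej <- replicate(400, {
    d <- tibble::tibble(pad = rnorm(60), g = rep(c("a", "b"), 30))
    compare_groups(d, pad, g)$p_value < 0.05
  })
  # 99% binomial band around 0.05 at 400 draws
  expect_gte(mean(rej), 0.05 - 2.576 * sqrt(0.05 * 0.95 / 400))
  expect_lte(mean(rej), 0.05 + 2.576 * sqrt(0.05 * 0.95 / 400))
})

test_that("GLM intercept-only model returns the mean with SD/sqrt(n) error", {
  set.seed(25)
  d <- tibble::tibble(brain_pad = rnorm(40, 2, 3), one = 0)
  fit <- glm_brainpad(d, terms = "1")
  expect_equal(fit$coefficients$estimate[1], mean(d$brain_pad), tolerance = 1e-10)
  expect_equal(fit$coefficients$std_error[1], sd(d$brain_pad) / sqrt(40),
               tolerance = 1e-10)
})

test_that("GLM coefficients equal a normal-equations oracle on random designs", {
  set.seed(26)
  for (rep in 1:5) {
    n <- 60
    d <- tibble::tibble(
      brain_pad = rnorm(n, 0, 4),
      sex = sample(c("female", "male"), n, replace = TRUE),
      group = sample(c("control", "mdd"), n, replace = TRUE),
      age = runif(n, 15, 80)
    )
    fit <- glm_brainpad(d, terms = c("sex", "group", "age", "age2"))
    x <- cbind(1, d$sex == "male", d$group == "mdd", d$age, d$age^2)
    oracle <- solve(crossprod(x), crossprod(x, d$brain_pad))
    expect_equal(fit$coefficients$estimate, drop(oracle), tolerance = 1e-8)
  }
})

test_that("GLM recovers a planted diagnosis effect with honest coverage", {
  set.seed(27)
  covered <- replicate(100, {
    n <- 120
    diagnosis <- rep(c(0, 1), each = n / 2)
    d <- tibble::tibble(
      brain_pad = 2 * diagnosis + rnorm(n, 0, 3),
      group = ifelse(diagnosis == 1, "mdd", "control"),
      age = runif(n, 15, 80)
    )
    fit <- glm_brainpad(d, terms = c("group", "age"))
    row <- fit$coefficients[fit$coefficients$term == "groupmdd", ]
    row$conf_low <= 2 && row$conf_high >= 2
  })
  expect_gte(mean(covered), 0.90)
})

test_that("GLM rejects singular designs and logs dropped incomplete rows", {
  d <- tibble::tibble(brain_pad = rnorm(30), group = "mdd",
                      age = runif(30, 20, 60))
  expect_error(glm_brainpad(d, terms = c("group", "age")), "constant")
  d2 <- tibble::tibble(brain_pad = rnorm(30), age = runif(30, 20, 60),
                       education_years = c(NA, rnorm(29, 12, 3)))
  fit <- glm_brainpad(d2, terms = c("age", "education_years"))
  expect_equal(fit$n_dropped, 1)
  expect_equal(fit$n_used, 29)
})

test_that("BH adjustment matches the hand computation and brute force", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  # brute-force BH oracle on random vectors of length 1..8
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(28)
  for (n in 1:8) {
    for (rep in 1:20) {
      p <- round(runif(n), 3)
      expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("spearman handles monotone and tie-laden data", {
  d_up <- tibble::tibble(x = 1:10, y = (1:10)^3)
  expect_equal(spearman_cor(d_up, x, y)$rho, 1)
  d_dn <- tibble::tibble(x = 1:10, y = -(1:10)^3)
  expect_equal(spearman_cor(d_dn, x, y)$rho, -1)
  # ties: oracle = Pearson correlation of average ranks
  d_tie <- tibble::tibble(x = c(1, 2, 2, 3, 3, 3, 4),
                          y = c(2, 1, 3, 3, 5, 4, 4))
  res <- spearman_cor(d_tie, x, y)
  expect_equal(res$rho, cor(rank(d_tie$x), rank(d_tie$y)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(d_tie$x, d_tie$y, method = "spearman",
                                   exact = FALSE))
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_cor(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               "constant")
})

test_that("median_split sends the boundary to the upper group", {
  d <- tibble::tibble(x = c(10, 12, 14))
  out <- median_split(d, x)
  expect_equal(attr(out, "threshold"), 12)
  expect_equal(as.character(out$subgroup), c("below", "at_or_above", "at_or_above"))
  # education-at-12 convention: < 12 vs >= 12
  set.seed(29)
  edu <- sample(c(6, 9, 12, 12, 12, 15, 16, 19), 200, replace = TRUE)
  out2 <- median_split(tibble::tibble(x = edu), x)
  expect_true(all(out2$x[out2$subgroup == "below"] < 12))
  expect_true(all(out2$x[out2$subgroup == "at_or_above"] >= 12))
  expect_error(median_split(tibble::tibble(x = rep(3, 5)), x), "distinct")
})
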