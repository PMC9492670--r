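# Two-site cohort with controllable shift/scale, no biology.
two_site_features <- function(n_per_site = 50, p = 12, shift = 0, scale = 1,
                              seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_site * p), 2 * n_per_site, p)
  idx_b <- (n_per_site + 1):(2 * n_per_site)
  x[idx_b, ] <- x[idx_b, ] * scale + shift
  ph <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(2 * n_per_site)),
    site = rep(c("a", "b"), each = n_per_site),
    age = runif(2 * n_per_site, 20, 60),
    sex = sample(c("female", "male"), 2 * n_per_site, replace = TRUE),
    group = "control"
  )
  list(features = make_features(x, ph$subject_id), phenotypes = ph)
}

test_that("single-site input is returned unchanged", {
  d <- two_site_features(20)
  d$phenotypes$site <- "only"
  out <- harmonize_combat(d$features, d$phenotypes, protect = NULL)
  expect_equal(as.matrix(out$features[-1]), as.matrix(d$features[-1]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a pure additive two-site shift is removed exactly (closed form, no shrinkage)", {
  d <- two_site_features(40, shift = 3)
  out <- harmonize_combat(d$features, d$phenotypes, protect = NULL,
                          shrink = FALSE)
  x <- as.matrix(out$features[-1])
  ma <- colMeans(x[d$phenotypes$site == "a", ])
  mb <- colMeans(x[d$phenotypes$site == "b", ])
  expect_equal(ma, mb, tolerance = 1e-6)
})

test_that("site scale differences are equalized on a synthetic cohort", {
  cfg <- small_config(n_controls = 400, n_patients = 1, n_sites = 2,
                      site_scale_sd = 0.6, site_shift_sd = 0.1,
                      noise_sd = 0.3, seed = 55)
  cohort <- generate_cohort(cfg)
  site <- cohort$phenotypes$site
  site_var_ratio <- function(features) {
    x <- as.matrix(features[-1])
    v1 <- apply(x[site == unique(site)[1], ], 2, var)
    v2 <- apply(x[site == unique(site)[2], ], 2, var)
    v1 / v2
  }
  # generating log-scales have SD 0.6 per (site, edge): raw ratios vary wildly
  expect_gt(max(abs(log(site_var_ratio(cohort$features)))), log(1.5))
  out <- harmonize_combat(cohort$features, cohort$phenotypes,
                          protect = c("age"), shrink = FALSE)
  ratio <- site_var_ratio(out$features)
  expect_true(all(ratio > 0.8 & ratio < 1.25))
  # EB mode also tightens the spread even if not exactly
  out_eb <- harmonize_combat(cohort$features, cohort$phenotypes,
                             protect = c("age"))
  expect_lt(mean(abs(log(site_var_ratio(out_eb$features)))),
            mean(abs(log(site_var_ratio(cohort$features)))))
})

test_that("protected covariate slopes survive harmonization (site independent of age)", {
  set.seed(66)
  n <- 300; p <- 10
  age <- runif(n, 20, 70)
  site <- rep(c("a", "b", "c"), length.out = n)
  slopes <- seq(-0.05, 0.05, length.out = p)
  x <- outer(age, slopes) + matrix(rnorm(n * p, 0, 0.5), n, p) +
    outer(site == "b", rnorm(p, 2, 0.5)) + outer(site == "c", rnorm(p, -1, 0.5))
  ph <- tibble::tibble(subject_id = sprintf("s%03d", 1:n), site = site,
                       age = age, group = "control")
  ft <- make_features(x, ph$subject_id)
  out <- harmonize_combat(ft, ph, protect = "age")
  xh <- as.matrix(out$features[-1])
  # site-adjusted age slopes before vs after (site and age independent by
  # construction; the site term absorbs chance confounding)
  slope_before <- apply(x, 2, function(col) coef(lm(col ~ age + site))[2])
  slope_after <- apply(xh, 2, function(col) coef(lm(col ~ age + site))[2])
  expect_true(all(abs(slope_after - slope_before) <= 0.1 * max(abs(slopes))))
})

test_that("no-shrinkage harmonization is idempotent to 1e-6", {
  d <- two_site_features(40, shift = 2, scale = 1.6)
  once <- harmonize_combat(d$features, d$phenotypes, protect = NULL,
                           shrink = FALSE)
  twice <- harmonize_combat(once$features, d$phenotypes, protect = NULL,
                            shrink = FALSE)
  expect_equal(as.matrix(twice$features[-1]), as.matrix(once$features[-1]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("refitting on harmonized output estimates site effects near zero", {
  d <- two_site_features(60, shift = 2, scale = 1.5)
  once <- harmonize_combat(d$features, d$phenotypes, protect = NULL)
  refit <- harmonize_combat(once$features, d$phenotypes, protect = NULL,
                            shrink = FALSE)
  gam <- refit$site_model$gamma_hat
  expect_lt(max(abs(gam)), 0.15) # standardized units; raw effect was ~2 SD
  d2 <- refit$site_model$delta2_hat
  expect_true(all(abs(d2 - 1) < 0.3))
})

test_that("degenerate designs are rejected with diagnostics", {
  d <- two_site_features(10)
  ph1 <- d$phenotypes
  ph1$site[1] <- "lonely"
  expect_error(harmonize_combat(d$features, ph1, protect = NULL), "single subject")
  # covariate constant within every site -> confounded
  ph2 <- d$phenotypes
  ph2$cov <- ifelse(ph2$site == "a", 1, 2)
  expect_error(harmonize_combat(d$features, ph2, protect = "cov"), "confounded")
})

test_that("implementation agrees with the reference ComBat on a shared instance", {
  skip_if_not_installed("sva")
  d <- two_site_features(80, p = 20, shift = 1.5, scale = 1.4, seed = 9)
  ours <- harmonize_combat(d$features, d$phenotypes, protect = "age")
  x <- t(as.matrix(d$features[-1]))
  mod <- model.matrix(~ age, data = d$phenotypes)
  ref <- suppressMessages(
    t(sva::ComBat(dat = x, batch = d$phenotypes$site, mod = mod))
  )
  xo <- as.matrix(ours$features[-1])
  # same algorithm family; small divisor/EB-iteration differences allowed
  expect_gt(cor(as.vector(xo), as.vector(ref)), 0.999)
  expect_lt(mean(abs(xo - ref)), 0.05)
})

test_that("harmonization_report quantifies site-effect reduction", {
  d <- two_site_features(50, shift = 2)
  out <- harmonize_combat(d$features, d$phenotypes, protect = NULL)
  rep0 <- harmonization_report(d$features, d$features, d$phenotypes)
  expect_equal(rep0$summary$mean_f_before, rep0$summary$mean_f_after)
  rep1 <- harmonization_report(d$features, out$features, d$phenotypes)
  expect_lt(rep1$summary$mean_f_after, rep1$summary$mean_f_before)
  # downstream comparison produces two MAEs and a better label
  rep2 <- harmonization_report(d$features, out$features, d$phenotypes,
                               downstream = TRUE, seed = 2)
  expect_true(is.numeric(rep2$summary$mae_before))
  expect_true(rep2$summary$better %in% c("before", "after"))
  expect_error(harmonization_report(d$features[1:10, ], out$features,
                                    d$phenotypes), "aligned|align")
})
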