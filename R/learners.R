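# Base learners for the age model. All fit an unpenalized intercept and
# return list(coef, intercept). Penalty conventions are pinned numerically:
#   elastic net: (1/(2n))||y - Xb||^2 + lambda * (mix*|b|_1 + (1-mix)/2*|b|_2^2),
#                lambda = 1, mix = 0.5 (glmnet, standardize = FALSE)
#   ridge:       ||y - Xb||^2 + lambda * |b|_2^2, lambda = 1 (absolute penalty)
#   bayesian ridge: evidence maximization, gamma hyperpriors all 1e-6

# Ridge with unpenalized intercept; dual (kernel) form when p > n.
ridge_solve <- function(x, y, lambda = 1) {
  x <- as.matrix(x)
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm, "-")
  yc <- y - ym
  n <- nrow(xc)
  p <- ncol(xc)
  if (p <= n) {
    a <- crossprod(xc) # p x p
    diag(a) <- diag(a) + lambda
    b <- drop(solve(a, crossprod(xc, yc)))
  } else {
    k <- tcrossprod(xc) # n x n
    diag(k) <- diag(k) + lambda
    b <- drop(crossprod(xc, solve(k, yc)))
  }
  list(coef = b, intercept = ym - sum(xm * b))
}

# Bayesian ridge via evidence maximization (thin SVD, centered data).
# alpha_ = noise precision, lambda_ = weight precision; hyperpriors
# alpha_1 = alpha_2 = lambda_1 = lambda_2 = 1e-6; tol on coefficient change.
bayesian_ridge_solve <- function(x, y, n_iter = 300, tol = 1e-3,
                                 alpha_1 = 1e-6, alpha_2 = 1e-6,
                                 lambda_1 = 1e-6, lambda_2 = 1e-6) {
  x <- as.matrix(x)
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm, "-")
  yc <- y - ym
  n <- nrow(xc)
  p <- ncol(xc)
  sv <- svd(xc)
  d <- sv$d
  d2 <- d^2
  uty <- drop(crossprod(sv$u, yc))
  vy <- var(yc)
  alpha_ <- if (is.na(vy) || vy == 0) 1 else 1 / vy
  lambda_ <- 1
  coef_old <- rep(Inf, p)
  coef <- rep(0, p)
  for (it in seq_len(n_iter)) {
    shrink <- d / (d2 + lambda_ / alpha_)
    coef <- drop(sv$v %*% (shrink * uty))
    if (max(abs(coef - coef_old)) < tol) break
    coef_old <- coef
    gamma_ <- sum(alpha_ * d2 / (lambda_ + alpha_ * d2))
    rss <- sum((yc - drop(sv$u %*% (shrink * d * uty)))^2)
    lambda_ <- (gamma_ + 2 * lambda_1) / (sum(coef^2) + 2 * lambda_2)
    alpha_ <- (n - gamma_ + 2 * alpha_1) / (rss + 2 * alpha_2)
  }
  list(coef = coef, intercept = ym - sum(xm * coef),
       alpha = alpha_, lambda = lambda_)
}

elastic_net_solve <- function(x, y, lambda = 1, mix = 0.5) {
  fit <- glmnet::glmnet(as.matrix(x), y, alpha = mix, lambda = lambda,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-9, maxit = 1e6)
  b <- as.numeric(coef(fit))
  list(coef = b[-1], intercept = b[1])
}

fit_learner <- function(x, y, kind,
                        params = list(en_lambda = 1, en_mix = 0.5, ridge_lambda = 1)) {
  switch(kind,
    elastic_net = elastic_net_solve(x, y, lambda = params$en_lambda %||% 1,
                                    mix = params$en_mix %||% 0.5),
    ridge = ridge_solve(x, y, lambda = params$ridge_lambda %||% 1),
    bayesian_ridge = bayesian_ridge_solve(x, y),
    abort(sprintf("unknown learner kind '%s'", kind))
  )
}

learner_kinds <- function() c("elastic_net", "ridge", "bayesian_ridge")
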