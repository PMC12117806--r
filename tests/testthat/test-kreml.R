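test_that("rotated restricted likelihood equals the dense-matrix oracle", {
  for (case in 1:5) {
    set.seed(30 + case)
    n <- sample(8:50, 1)
    K <- rand_kernel(n, seed = 9300 + case)
    X <- cbind(1, rnorm(n))
    y <- rnorm(n)
    s2u <- runif(1, 0.1, 2)
    s2e <- runif(1, 0.1, 2)
    V <- s2u * K + s2e * diag(n)
    expect_equal(kreml_loglik(y, X, K, s2u, s2e),
                 dense_reml_loglik(y, X, V), tolerance = 1e-8)
  }
})

test_that("REML estimates are invariant to animal order and trait scale", {
  set.seed(31)
  n <- 120
  K <- rand_kernel(n, seed = 9310)
  sim <- simulate_kernel_trait(K, ratio = 0.4)
  d <- data.frame(y = sim$y)
  fit <- kreml(y ~ 1, d, K, se = FALSE)

  perm <- sample(n)
  fit_p <- kreml(y ~ 1, d[perm, , drop = FALSE], K[perm, perm], se = FALSE)
  expect_equal(fit_p$ratio, fit$ratio, tolerance = 1e-6)
  expect_equal(fit_p$logLik, fit$logLik, tolerance = 1e-6)

  # scaling y by c scales components by c^2, leaves the ratio unchanged
  fit_s <- kreml(y ~ 1, data.frame(y = d$y * 100), K, se = FALSE)
  expect_equal(fit_s$ratio, fit$ratio, tolerance = 1e-5)
  expect_equal(fit_s$sigma2_u, fit$sigma2_u * 1e4, tolerance = 1e-3)
  expect_equal(fit_s$sigma2_e, fit$sigma2_e * 1e4, tolerance = 1e-3)
})

test_that("a zero-variance kernel effect is estimated at the boundary", {
  K <- rand_kernel(500, seed = 9320)
  ek <- kernel_eigen(K)
  set.seed(32)
  est <- sapply(1:20, function(r) {
    y <- rnorm(500)  # sigma2_u = 0
    kreml(y ~ 1, data.frame(y = y), ek, se = FALSE)$ratio
  })
  expect_lte(mean(est), 0.02)
})

test_that("variance-ratio recovery is unbiased across a grid of truths", {
  K <- rand_kernel(400, seed = 9330)
  ek <- kernel_eigen(K)
  set.seed(33)
  for (truth in c(0.1, 0.3, 0.6)) {
    est <- sapply(1:8, function(r)
      kreml(y ~ 1,
            data.frame(y = simulate_kernel_trait(ek, ratio = truth)$y),
            ek, se = FALSE)$ratio)
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - truth), 2 * mc_se + 0.02)
  }
})

test_that("delta-method ratio SE agrees with a parametric bootstrap", {
  K <- rand_kernel(300, seed = 9340)
  set.seed(34)
  sim <- simulate_kernel_trait(K, ratio = 0.4)
  fit <- kreml(y ~ 1, data.frame(y = sim$y), K)
  boot <- simulate(fit, nsim = 60, seed = 99)
  ratios <- vapply(boot, function(yb)
    kreml(y ~ 1, data.frame(y = yb), fit$eigenK, se = FALSE)$ratio,
    numeric(1))
  expect_lt(abs(fit$se$ratio - sd(ratios)) / sd(ratios), 0.25)
})

test_that("out-of-sample BLUP equals the MVN conditional mean", {
  set.seed(35)
  n <- 30
  K <- rand_kernel(n, seed = 9350)
  dimnames(K) <- list(paste0("a", 1:n), paste0("a", 1:n))
  sim <- simulate_kernel_trait(K, ratio = 0.5)
  tr <- paste0("a", 1:22)
  va <- paste0("a", 23:30)
  fit <- kreml(y ~ 1, data.frame(y = sim$y[1:22]), K[tr, tr], se = FALSE)

  pred <- blup_predict(fit, K, tr, va)
  Vtt <- fit$sigma2_u * K[tr, tr] + fit$sigma2_e * diag(22)
  resid <- sim$y[1:22] - fit$beta
  oracle <- drop(fit$sigma2_u * K[va, tr] %*% solve(Vtt, resid))
  expect_equal(unname(pred), unname(oracle), tolerance = 1e-8)

  # a target unrelated to every training animal is predicted at zero
  K0 <- K
  K0[va[1], tr] <- 0
  K0[tr, va[1]] <- 0
  expect_equal(unname(blup_predict(fit, K0, tr, va[1])), 0)

  expect_error(blup_predict(fit, K, tr, c("a1", "a25")), "overlap")
})

test_that("kreml accessors expose coefficients, likelihood and residuals", {
  set.seed(36)
  K <- rand_kernel(60, seed = 9360)
  d <- data.frame(y = simulate_kernel_trait(K, 0.4)$y,
                  x = rnorm(60))
  fit <- kreml(y ~ x, d, K)
  expect_named(coef(fit), c("(Intercept)", "x"))
  expect_s3_class(summary(fit), "summary.kreml")
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_equal(residuals(fit), d$y - fitted(fit))
  expect_true(is.finite(fit$se$ratio))
  expect_output(print(fit), "variance ratio")
})
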