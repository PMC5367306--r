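test_that("with no between-group variance the fit collapses to OLS", {
  set.seed(2)
  g <- rep(1:8, each = 50)
  X <- cbind(a = stats::rnorm(400), b = stats::rnorm(400))
  y <- 1 + 0.5 * X[, "a"] + stats::rnorm(400)
  f <- lmm_random_intercept(y, X, g)
  expect_lte(f$var_between, 1e-6)
  ols <- stats::lm(y ~ X)
  expect_equal(f$fixed_effects$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
  expect_equal(f$fixed_effects$chi2,
               (f$fixed_effects$estimate / f$fixed_effects$se)^2,
               tolerance = 1e-12)
  # optimum log-likelihood is never below the OLS submodel
  ll_ols <- as.numeric(stats::logLik(ols))
  expect_gte(f$logLik, ll_ols - 1e-8)
})

test_that("slope tests are invariant to shifting the response", {
  set.seed(3)
  g <- rep(1:5, each = 20)
  X <- cbind(p1 = stats::rnorm(100), p2 = stats::rnorm(100))
  y <- 0.3 * X[, 1] + rep(stats::rnorm(5, 0, 0.5), each = 20) +
    stats::rnorm(100)
  f1 <- lmm_random_intercept(y, X, g)
  f2 <- lmm_random_intercept(y + 7, X, g)
  expect_equal(f1$fixed_effects$estimate[-1], f2$fixed_effects$estimate[-1],
               tolerance = 1e-9)
  expect_equal(f1$fixed_effects$chi2[-1], f2$fixed_effects$chi2[-1],
               tolerance = 1e-6)
})

test_that("the fit recovers known parameters and is order-invariant", {
  set.seed(4)
  ok <- 0; runs <- 60
  for (i in seq_len(runs)) {
    g <- rep(1:8, each = 25)
    x <- stats::rnorm(200)
    y <- 1 + 0.5 * x + rep(stats::rnorm(8, 0, 1), each = 25) +
      stats::rnorm(200)
    f <- lmm_random_intercept(y, cbind(x = x, z = stats::rnorm(200)), g)
    est <- f$fixed_effects$estimate[2]
    se <- f$fixed_effects$se[2]
    if (abs(est - 0.5) <= 3 * se) ok <- ok + 1
  }
  expect_gte(ok / runs, 0.9)
  # reordering individuals leaves the fit unchanged
  set.seed(5)
  g <- rep(1:4, each = 15); x <- stats::rnorm(60)
  y <- 0.4 * x + rep(stats::rnorm(4), each = 15) + stats::rnorm(60)
  o <- sample(60)
  f1 <- lmm_random_intercept(y, cbind(x = x), g)
  f2 <- lmm_random_intercept(y[o], cbind(x = x[o]), g[o])
  expect_equal(f1$fixed_effects$estimate, f2$fixed_effects$estimate,
               tolerance = 1e-6)
  expect_equal(f1$var_between, f2$var_between, tolerance = 1e-6)
  expect_error(lmm_random_intercept(y, cbind(x, x), g), "collinear|singular")
})

test_that("association wiring reports per-PC tests and honours exclusions", {
  set.seed(6)
  npop <- 6; nper <- 20; n <- npop * nper
  pop <- rep(paste0("pop", 1:npop), each = nper)
  pcs <- cbind(stats::rnorm(n), stats::rnorm(n))
  phen <- 0.8 * pcs[, 1] + stats::rnorm(n, 0, 0.5)
  res <- run_association(phen, pcs, pop)
  expect_lte(res$results$p[res$results$term == "PC1"], 0.01)
  expect_equal(res$n_used, n)
  res2 <- run_association(phen, pcs, pop, exclude = "pop3")
  expect_equal(res2$n_used, n - nper)
  expect_error(run_association(phen, pcs, rep(c("a", "b", "c"), each = 40),
                               exclude = c("a")), "fewer than 3")
})

test_that("per-PC type-I error of the association test is calibrated", {
  set.seed(8)
  n_rep <- 200; rej <- 0
  for (i in seq_len(n_rep)) {
    pop <- rep(paste0("p", 1:5), each = 12)
    pcs <- cbind(stats::rnorm(60), stats::rnorm(60))
    phen <- rep(stats::rnorm(5, 0, 0.3), each = 12) + stats::rnorm(60)
    r <- run_association(phen, pcs, pop)
    if (r$results$p[r$results$term == "PC1"] <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.045)
})
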