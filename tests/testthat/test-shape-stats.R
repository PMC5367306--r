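test_that("shape PCA matches a covariance eigen-decomposition oracle", {
  set.seed(3)
  X <- matrix(stats::rnorm(50 * 60), 50, 60)
  p <- shape_pca(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(p$eigenvalues, ev[seq_along(p$eigenvalues)],
               tolerance = 1e-8)
  expect_true(all(diff(p$varfrac) <= 1e-12))
  # reconstruction from all components reproduces the centered matrix
  Xc <- scale(X, scale = FALSE)
  expect_lt(max(abs(p$scores %*% t(p$loadings) - Xc)), 1e-8)
  # score columns mutually orthogonal
  G <- crossprod(p$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-6)
  # rank-1 data
  u <- stats::rnorm(20); v <- stats::rnorm(7)
  p1 <- shape_pca(outer(u, v))
  expect_equal(p1$varfrac[1], 1, tolerance = 1e-10)
  expect_warning(shape_pca(matrix(1, 5, 3)), "constant")
})

test_that("component retention respects the cumulative variance threshold", {
  expect_equal(retain_components(c(0.6, 0.4), 0.95), 2L)
  expect_equal(retain_components(c(0.96, 0.04), 0.95), 1L)
  expect_equal(retain_components(c(0.5, 0.3, 0.15, 0.05), 0.95), 3L)
  expect_error(retain_components(c(0.5, 0.5), 0), "threshold")
})

test_that("Wilks MANOVA reduces to one-way ANOVA for p = 1 and matches stats::manova", {
  set.seed(11)
  y <- stats::rnorm(30)
  gr <- rep(letters[1:3], each = 10)
  mw <- manova_wilks(matrix(y), gr)
  av <- summary(stats::aov(y ~ gr))[[1]]
  expect_equal(mw$statistic, av[["F value"]][1], tolerance = 1e-10)
  expect_equal(mw$p, av[["Pr(>F)"]][1], tolerance = 1e-10)
  ssw <- sum(tapply(y, gr, function(z) sum((z - mean(z))^2)))
  ssb <- sum(tapply(y, gr, function(z) length(z) * (mean(z) - mean(y))^2))
  expect_equal(mw$lambda, ssw / (ssw + ssb), tolerance = 1e-12)
  # multi-response cross-check against the reference implementation
  Y <- matrix(stats::rnorm(40 * 4), 40, 4)
  Y[1:10, 1] <- Y[1:10, 1] + 1
  g4 <- rep(letters[1:4], each = 10)
  mw4 <- manova_wilks(Y, g4)
  sm <- summary(stats::manova(Y ~ factor(g4)), test = "Wilks")$stats
  expect_equal(mw4$lambda, unname(sm[1, "Wilks"]), tolerance = 1e-10)
  expect_equal(mw4$statistic, unname(sm[1, "approx F"]), tolerance = 1e-8)
  expect_equal(mw4$p, unname(sm[1, "Pr(>F)"]), tolerance = 1e-10)
  # lambda tends to 1 with identical group means and tiny jitter
  Z <- matrix(rep(stats::rnorm(2), each = 20), 20, 2) +
    matrix(stats::rnorm(40, 0, 1e-3), 20, 2)
  base_means <- matrix(stats::rnorm(40), 20, 2) * 0  # no structure
  mwz <- manova_wilks(Z + base_means, rep(c("a", "b"), each = 10))
  expect_gt(mwz$lambda, 0.5)
  expect_lte(mwz$lambda, 1)
})

test_that("Wilks lambda is invariant to non-singular linear transforms of the responses", {
  set.seed(21)
  Y <- matrix(stats::rnorm(36 * 3), 36, 3)
  gr <- rep(1:3, each = 12)
  A <- matrix(stats::rnorm(9), 3, 3) + diag(3)
  expect_equal(manova_wilks(Y, gr)$lambda,
               manova_wilks(Y %*% A, gr)$lambda, tolerance = 1e-8)
})

test_that("MANOVA type-I error is calibrated under the null", {
  set.seed(31)
  n_rep <- 400
  rej <- 0
  for (i in seq_len(n_rep)) {
    Y <- matrix(stats::rnorm(30 * 3), 30, 3)
    if (manova_wilks(Y, rep(1:3, each = 10))$p <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.035)
})

test_that("thin-plate splines interpolate exactly and are affine-null", {
  ref <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  idn <- tps_deformation(ref, ref, grid_n = 6)
  expect_equal(idn$bending_energy, 0, tolerance = 1e-9)
  expect_equal(idn$mapped_grid, idn$source_grid, tolerance = 1e-8)
  tr <- tps_deformation(ref, ref + 2.5, grid_n = 6)
  expect_lt(tr$bending_energy, 1e-9)
  expect_equal(tr$mapped_grid, tr$source_grid + 2.5, tolerance = 1e-8)
  # displaced corner: grid values equal an independently solved system
  tar <- ref; tar[3, ] <- c(1.4, 1.3)
  td <- tps_deformation(ref, tar, grid_n = 5)
  expect_lt(max(abs(td$mapped_ref - tar)), 1e-8)
  U <- function(d2) ifelse(d2 == 0, 0, d2 * log(d2))
  K <- U(as.matrix(stats::dist(ref))^2)
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(L, rbind(tar, matrix(0, 3, 2)))
  src <- td$source_grid
  d2g <- outer(rowSums(src^2), rowSums(ref^2), `+`) - 2 * src %*% t(ref)
  mapped_oracle <- cbind(1, src) %*% sol[5:7, ] + U(pmax(d2g, 0)) %*% sol[1:4, ]
  expect_lt(max(abs(td$mapped_grid - mapped_oracle)), 1e-8)
  expect_gt(td$bending_energy, 0)
  # collinear reference is singular
  bad <- cbind(0:3, 0:3)
  expect_error(tps_deformation(bad, bad + 1), "collinear|singular")
})
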