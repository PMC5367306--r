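test_that("drift leaves frequencies untouched at t = 0 and fixed alleles fixed", {
  base <- base_frequencies(5, "microsat", seed = 3)
  scen <- drift_scenario(Ne = 500, t = 0, n_subpops = 3, seed = 1)
  fr <- drift_frequencies(base, scen)
  for (s in 1:3) for (l in 1:5)
    expect_identical(fr[[s]][[l]], base$freqs[[l]])

  fixed <- structure(list(freqs = list(c(1, 0)),
                          loci = data.frame(id = "l1", type = "snp")),
                     class = "base_frequencies")
  fr2 <- drift_frequencies(fixed, drift_scenario(50, 25, 4, seed = 2))
  for (s in 1:4) expect_equal(fr2[[s]][[1]], c(1, 0))

  expect_error(drift_scenario(Ne = 0, t = 1), "Ne")
  expect_error(drift_scenario(Ne = 10, t = -1), "t must")
})

test_that("drift variance matches the closed-form expectation 1-(1-1/(2Ne))^t", {
  base <- structure(list(freqs = rep(list(c(0.5, 0.5)), 10000),
                         loci = data.frame(id = paste0("l", 1:10000),
                                           type = "snp")),
                    class = "base_frequencies")
  scen <- drift_scenario(50, 10, n_subpops = 10, n_per_subpop = 1, seed = 7)
  fr <- drift_frequencies(base, scen)
  P <- vapply(fr, function(s) vapply(s, function(f) f[2], 0),
              numeric(10000))
  ratio <- apply(P, 1, stats::var) / 0.25
  expect_equal(mean(ratio), 1 - (1 - 1 / 100)^10, tolerance = 0.01 /
                 (1 - (1 - 1 / 100)^10))
})

test_that("drift is reproducible under a fixed seed", {
  base <- base_frequencies(4, "microsat", seed = 9)
  scen <- drift_scenario(100, 5, 3, seed = 11)
  expect_identical(drift_frequencies(base, scen),
                   drift_frequencies(base, scen))
})

test_that("genotype sampling follows Hardy-Weinberg proportions", {
  # fixed allele: everyone homozygous
  g0 <- sample_genotypes(list(list(c(1, 0))), 20, seed = 1)
  expect_true(all(g0$allele1 == 1 & g0$allele2 == 1))
  # p = 0.5: heterozygote fraction near 2pq = 0.5
  g <- sample_genotypes(list(list(c(0.5, 0.5))), 10000, seed = 3)
  expect_equal(mean(g$allele1[, 1] != g$allele2[, 1]), 0.5,
               tolerance = 0.015 / 0.5)
  # determinism
  g2 <- sample_genotypes(list(list(c(0.5, 0.5))), 10000, seed = 3)
  expect_identical(g, g2)
  expect_error(sample_genotypes(list(list()), 5), "no loci")
})

test_that("call sets carry depths, tags and the right call counts", {
  base <- base_frequencies(1000, "snp", seed = 2)
  gt <- sample_genotypes(list(base$freqs), 45, seed = 4, loci = base$loci)
  cs0 <- make_snp_callset(gt, missing_rate = 0, seed = 5)
  expect_true(all(colSums(!is.na(cs0$gt$allele1)) == 45))
  expect_true(all(cs0$depth >= 1))
  cs2 <- make_snp_callset(gt, missing_rate = 0, snps_per_tag = 2, seed = 5)
  expect_true(all(table(cs2$tag) == 2))
  cs <- make_snp_callset(gt, missing_rate = 0.1, seed = 6)
  expect_equal(mean(colSums(!is.na(cs$gt$allele1))), 40.5, tolerance = 1 / 40.5)
  expect_error(make_snp_callset(gt, missing_rate = 0.1,
                                depth_dist = function(n) rep(0L, n)),
               "support")
})

test_that("shell populations reproduce their population mean coefficients", {
  model <- default_shell_model(2, effect = 0.1, coeff_sd = 0)
  sp <- make_shell_population(model, 3, seed = 1)
  # zero noise: identical outlines within a population
  expect_equal(sp$outlines[[1]]$points, sp$outlines[[2]]$points)
  expect_equal(sp$outlines[[1]]$points, sp$outlines[[3]]$points)
  # different populations differ
  expect_gt(max(abs(sp$outlines[[1]]$points - sp$outlines[[4]]$points)), 1e-4)

  model2 <- default_shell_model(1, coeff_sd = 0.02)
  sp2 <- make_shell_population(model2, 200, seed = 8)
  co <- t(vapply(sp2$coeffs, function(cf) as.vector(cf$harmonics),
                 numeric(4 * model2$n_harmonics)))
  mu <- as.vector(model2$pop_mean_coeffs[[1]]$harmonics)
  se <- 0.02 / sqrt(200)
  expect_true(all(abs(colMeans(co) - mu) < 3.9 * se))
  expect_error(make_shell_population(model2, 0), "n_per_pop")
})

test_that("colour images hit their pigment extent and intensity targets", {
  m0 <- pigment_model(80, 0, c(48, 48))
  expect_equal(colour_index(make_colour_image(m0, seed = 1))$colour_index, 0)
  m1 <- pigment_model(100, 1, c(64, 64))
  ci <- colour_index(make_colour_image(m1, seed = 2))
  expect_equal(ci$colour_index, 10, tolerance = 0.2 / 10)
  m <- pigment_model(70, 0.4, c(96, 96))
  img <- make_colour_image(m, seed = 3)
  ci2 <- colour_index(img)
  expect_equal(ci2$pigment_fraction, 0.4, tolerance = 0.02 / 0.4)
  expect_equal(ci2$mean_pigment_grey, 70, tolerance = 2 / 70)
  # unpigmented shell pixels stay above the window
  shell <- img$pixels[img$mask]
  expect_true(all(shell[shell > 110] > 110))
  expect_identical(make_colour_image(m, seed = 3), img)
  expect_error(pigment_model(70, 1.2), "extent")
  expect_error(pigment_model(150, 0.5), "mean_pigment_grey")
})
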