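test_that("summary statistics match hand-computed Ho and unbiased He", {
  # all heterozygous
  gt <- genotype_table(matrix(rep(1L, 5)), matrix(rep(2L, 5)),
                       pop = rep("a", 5))
  s <- summary_stats(gt)
  expect_equal(s$Ho, 1)
  # monomorphic
  gt2 <- genotype_table(matrix(rep(1L, 5)), matrix(rep(1L, 5)),
                        pop = rep("a", 5))
  s2 <- summary_stats(gt2)
  expect_equal(s2$He, 0)
  expect_equal(s2$Ho, 0)
  expect_equal(s2$n_alleles, 1)
  # AA=4, AB=4, BB=2: p_A = 0.6, Ho = 0.4, He = (20/19)(1 - 0.36 - 0.16)
  gt3 <- gt_from_counts(c(AA = 4, AB = 4, BB = 2))
  s3 <- summary_stats(gt3)
  expect_equal(s3$Ho, 0.4)
  expect_equal(s3$He, (20 / 19) * (1 - 0.36 - 0.16), tolerance = 1e-12)
})

test_that("Weir-Cockerham theta agrees with the ANOVA-route oracle", {
  # identical arrays: no differentiation
  gt0 <- gt_from_counts(c(AA = 5, AB = 10, BB = 5), c(AA = 5, AB = 10, BB = 5))
  expect_lte(wc_theta(gt0)$theta, 0.01)
  # fixed difference
  gt1 <- gt_from_counts(c(AA = 20, AB = 0, BB = 0), c(AA = 0, AB = 0, BB = 20))
  expect_equal(wc_theta(gt1)$theta, 1)
  # toy table, frozen value + oracle equality to 1e-12
  gt2 <- gt_from_counts(c(AA = 6, AB = 3, BB = 1), c(AA = 1, AB = 3, BB = 6))
  th <- wc_theta(gt2)$theta
  expect_equal(th, 0.36, tolerance = 1e-12)
  expect_equal(th, wc_theta_anova_oracle(gt2), tolerance = 1e-12)
  # multiallelic, several populations, missing data
  b <- base_frequencies(5, "microsat", seed = 5)
  g <- sample_genotypes(drift_frequencies(b, drift_scenario(200, 8, 4, 12,
                                                            seed = 2)),
                        12, seed = 3, loci = b$loci)
  g$allele1[seq(1, 48, by = 9), 2] <- NA
  g$allele2[is.na(g$allele1[, 2]), 2] <- NA
  g <- genotype_table(g$allele1, g$allele2, g$pop, g$ids, g$loci)
  expect_equal(wc_theta(g)$theta, wc_theta_anova_oracle(g),
               tolerance = 1e-12)
})

test_that("theta is symmetric and invariant to allele relabelling", {
  b <- base_frequencies(6, "snp", seed = 13)
  g <- sample_genotypes(drift_frequencies(b, drift_scenario(100, 15, 2, 15,
                                                            seed = 4)),
                        15, seed = 5, loci = b$loci)
  th <- wc_theta(g)$theta
  # swap population order
  o <- order(g$pop, decreasing = TRUE)
  g_swap <- genotype_table(g$allele1[o, ], g$allele2[o, ], g$pop[o],
                           g$ids[o], g$loci)
  expect_equal(wc_theta(g_swap)$theta, th, tolerance = 1e-12)
  # relabel alleles 1<->2
  g_rel <- genotype_table(3L - g$allele2, 3L - g$allele1, g$pop, g$ids,
                          g$loci)
  expect_equal(wc_theta(g_rel)$theta, th, tolerance = 1e-12)
})

test_that("pairwise F_ST handles the 2-population case and flags the outlier", {
  b <- base_frequencies(80, "snp", seed = 21)
  g2 <- sample_genotypes(list(b$freqs, b$freqs), 12, seed = 6, loci = b$loci)
  f <- pairwise_fst(g2, n_perm = 99, seed = 7)
  expect_equal(dim(f$theta), c(2, 2))
  expect_equal(f$theta, t(f$theta))
  expect_equal(diag(f$theta), c(pop1 = 0, pop2 = 0))
  expect_true(all(f$p[upper.tri(f$p)] > 0 & f$p[upper.tri(f$p)] <= 1))
  # permutation p never zero even under maximal divergence
  g3 <- gt_from_counts(c(AA = 15, AB = 0, BB = 0), c(AA = 0, AB = 0, BB = 15))
  f3 <- pairwise_fst(g3, n_perm = 99, seed = 8)
  expect_equal(f3$p[1, 2], 1 / 100)
})

test_that("Storey q-values reduce to Benjamini-Hochberg with pi0 = 1", {
  expect_identical(storey_q(numeric(0)), numeric(0))
  expect_equal(storey_q(rep(1, 6)), rep(1, 6))
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(storey_q(p, pi0 = 1), rep(0.04, 4))
  set.seed(4)
  for (i in 1:20) {
    pv <- stats::runif(30)^1.5
    expect_equal(storey_q(pv, pi0 = 1), stats::p.adjust(pv, "BH"),
                 tolerance = 1e-14)
    q <- storey_q(pv)
    pi0 <- min(1, mean(pv > 0.5) / 0.5)
    expect_gte(min(q), pi0 * min(pv) - 1e-14)
    expect_true(all(q[order(pv)] == cummax(q[order(pv)])))
  }
  expect_error(storey_q(c(0.5, 1.2)), "p-values")
})

test_that("microsatellite HWE-deviation filter follows the 5/7-population rule", {
  sig <- matrix(FALSE, 4, 9,
                dimnames = list(c("locA", "locB", "locC", "locD"), NULL))
  sig["locA", 1:7] <- TRUE   # deviates in 7 of 9: excluded
  sig["locB", 1:5] <- TRUE   # deviates in 5 of 9: excluded
  sig["locC", 1] <- TRUE     # 1 of 9: kept
  res <- filter_microsat_loci(sig)
  expect_setequal(res$excluded, c("locA", "locB"))
  expect_setequal(res$kept, c("locC", "locD"))
  expect_equal(unname(res$n_deviating), c(7, 5, 1, 0))
  # untestable cells count as non-significant
  sig["locD", ] <- NA
  expect_true("locD" %in% filter_microsat_loci(sig)$kept)
})

test_that("SNP call filters apply call-count, per-tag and depth rules", {
  base <- base_frequencies(6, "snp", seed = 31)
  gt <- sample_genotypes(list(base$freqs), 45, seed = 9, loci = base$loci)
  cs <- make_snp_callset(gt, missing_rate = 0, snps_per_tag = 2, seed = 10)
  # engineer: SNP 1 called in 39 (dropped), SNP 2 in 44, SNP 3 in 41
  # (same tag as 4: keep the better), depth < 5 masks a genotype
  cs$gt$allele1[1:6, 1] <- NA; cs$gt$allele2[1:6, 1] <- NA
  cs$gt$allele1[1, 2] <- NA; cs$gt$allele2[1, 2] <- NA
  cs$tag <- c(1L, 1L, 2L, 2L, 3L, 3L)
  cs$gt$allele1[1:4, 3] <- NA; cs$gt$allele2[1:4, 3] <- NA
  cs$depth[is.na(cs$gt$allele1)] <- NA
  cs$depth[!is.na(cs$depth)] <- 10L
  cs$depth[7, 5] <- 4L   # below depth threshold: must go missing
  cs$depth[8, 5] <- 5L   # exactly at threshold: retained
  res <- filter_snp_calls(cs, min_individuals = 40, min_depth = 5)
  ids <- res$gt$loci$id
  expect_false("loc_1" %in% ids)            # 39 < 40 calls
  expect_true("loc_2" %in% ids)             # 44 calls, best of tag 1
  expect_false("loc_3" %in% ids)            # 41 calls, loses tag 2 to loc_4
  expect_true("loc_4" %in% ids)
  l5 <- match("loc_5", ids)
  expect_true(is.na(res$gt$allele1[7, l5]))
  expect_false(is.na(res$gt$allele1[8, l5]))
  # idempotence: re-running the filter on its own output is a no-op
  res2 <- filter_snp_calls(res$callset, 40, 5)
  expect_identical(res$gt$allele1, res2$gt$allele1)
  expect_identical(res$gt$loci$id, res2$gt$loci$id)
  # empty call set
  empty <- structure(list(gt = subset_genotypes(gt, loci = integer(0)),
                          depth = cs$depth[, integer(0), drop = FALSE],
                          tag = integer(0)),
                     class = "snp_callset")
  expect_equal(unname(filter_snp_calls(empty, 40, 5)$report["final"]), 0)
})

test_that("Mantel statistic equals direct Pearson correlation of the triangles", {
  d_geo <- matrix(c(0, 2, 5, 9,
                    2, 0, 4, 7,
                    5, 4, 0, 3,
                    9, 7, 3, 0), 4, 4)
  d_gen <- matrix(c(0, 1, 6, 8,
                    1, 0, 5, 9,
                    6, 5, 0, 2,
                    8, 9, 2, 0), 4, 4)
  ut <- upper.tri(d_geo)
  m <- mantel_test(d_gen, d_geo, n_perm = 99, seed = 2)
  expect_equal(m$r, stats::cor(d_gen[ut], d_geo[ut]), tolerance = 1e-12)
  expect_equal(mantel_test(d_geo, d_geo, n_perm = 99, seed = 3)$r, 1)
  expect_error(mantel_test(d_geo[1:2, 1:2], d_geo[1:2, 1:2]), "at least 3")
})

test_that("Mantel agrees with vegan on statistic and permutation scale", {
  skip_if_not_installed("vegan")
  set.seed(12)
  xy <- matrix(stats::rnorm(20), 10)
  d1 <- as.matrix(stats::dist(xy))
  d2 <- as.matrix(stats::dist(xy + stats::rnorm(20, 0, 0.8)))
  m <- mantel_test(d1, d2, n_perm = 999, seed = 5)
  v <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                     permutations = 999)
  expect_equal(m$r, unname(v$statistic), tolerance = 1e-10)
  expect_lt(abs(m$p - v$signif), 0.05)
})

test_that("genotype PCA matches a dense eigen-decomposition oracle", {
  b <- base_frequencies(50, "snp", seed = 41)
  gt <- sample_genotypes(list(b$freqs, b$freqs), 10, seed = 11,
                         loci = b$loci)
  p <- genetic_pca(gt)
  ad <- shellpop:::allele_dosage(gt)
  Xc <- scale(ad$X * 1, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$values
  expect_equal(p$eigenvalues, ev[seq_along(p$eigenvalues)],
               tolerance = 1e-8)
  expect_lt(max(abs(colSums(p$scores))), 1e-8)
  expect_equal(sum(p$varfrac), 1, tolerance = 1e-10)
  # two internally identical clusters: PC1 separates, zero spread within
  a1 <- cbind(rep(c(1L, 2L), each = 6))
  gt2 <- genotype_table(a1, a1, pop = rep(c("x", "y"), each = 6))
  p2 <- genetic_pca(gt2)
  expect_lt(max(tapply(p2$scores[, 1], gt2$pop, stats::sd)), 1e-10)
  expect_gt(abs(diff(tapply(p2$scores[, 1], gt2$pop, mean))), 0.5)
})

test_that("all-missing loci are dropped from the PCA with a warning", {
  a1 <- matrix(c(1L, 2L, 1L, 2L, NA, NA, NA, NA), 4, 2)
  gt <- genotype_table(a1, a1, pop = c("a", "a", "b", "b"))
  expect_warning(p <- genetic_pca(gt), "all-missing")
  expect_equal(nrow(p$scores), 4)
})
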