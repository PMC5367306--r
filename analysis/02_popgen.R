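#!/usr/bin/env Rscript
# Population-genetic analysis of both panels: ddRAD filters, diversity
# summaries, HWE exact tests with q-values, locus exclusion, linkage
# tests, pairwise F_ST with permutation significance, genotype PCA, and a
# Mantel test against a synthetic coastline distance matrix.

source("analysis/00_config.R")

study <- simulate_study()

## ddRAD filtering of the SNP call set
callset <- make_snp_callset(study$gt_snp, missing_rate = CFG$missing_rate,
                            snps_per_tag = CFG$snps_per_tag,
                            seed = derive_seed(GLOBAL_SEED, "callset"))
filt <- filter_snp_calls(callset, CFG$min_individuals, CFG$min_depth)
cat("SNP filters:", paste(names(filt$report), filt$report, collapse = ", "),
    "\n")
gt_snp <- filt$gt

## summaries + HWE on the microsatellite panel
summ <- summary_stats(study$gt_ms)
write.csv(summ, file.path(RESULTS_DIR, "summary_stats.csv"),
          row.names = FALSE)
cat("Mean alleles/locus:",
    round(mean(tapply(summ$n_alleles, summ$locus, max, na.rm = TRUE)), 1),
    "\n")

hwe <- hwe_table(study$gt_ms, dememorization = CFG$hwe_dememorization,
                 batches = CFG$hwe_batches,
                 iterations_per_batch = CFG$hwe_iterations,
                 seed = derive_seed(GLOBAL_SEED, "hwe"))
write.csv(hwe, file.path(RESULTS_DIR, "hwe.csv"), row.names = FALSE)
sig <- with(hwe, tapply(q <= CFG$alpha, list(locus, pop),
                        function(z) any(z, na.rm = TRUE)))
excl <- filter_microsat_loci(sig, CFG$max_deviating_pops)
cat("Loci excluded for repeated HWE deviation:",
    if (length(excl$excluded)) paste(excl$excluded, collapse = ", ")
    else "none", "\n")
gt_ms <- subset_genotypes(study$gt_ms,
                          loci = sort(match(excl$kept, study$gt_ms$loci$id)))

## pairwise F_ST with 1000 permutations + table-wide q-values
for (panel in list(list(gt = gt_ms, name = "microsat"),
                   list(gt = gt_snp, name = "snp"))) {
  f <- pairwise_fst(panel$gt, n_perm = CFG$n_perm_fst,
                    seed = derive_seed(GLOBAL_SEED,
                                       paste0("fst_", panel$name)))
  write.csv(round(f$theta, 5),
            file.path(RESULTS_DIR, paste0("fst_theta_", panel$name, ".csv")))
  write.csv(round(f$q, 4),
            file.path(RESULTS_DIR, paste0("fst_q_", panel$name, ".csv")))
  others <- setdiff(f$labels, CFG$outlier_pop)
  cat(sprintf("[%s] outlier pairs FDR-significant: %d/%d; mean theta %.4f\n",
              panel$name, sum(f$q[CFG$outlier_pop, others] <= 0.05),
              length(others), mean(f$theta[CFG$outlier_pop, others])))
}

## genotype PCA (SNPs resolve the outlier; microsats barely do)
pca <- genetic_pca(gt_snp)
write.csv(data.frame(id = pca$ids, pop = pca$pop, pca$scores[, 1:4]),
          file.path(RESULTS_DIR, "pca_snp_scores.csv"), row.names = FALSE)
cat("SNP PCA: PC1 explains", round(100 * pca$varfrac[1], 1), "% of variance\n")

## isolation by distance: Mantel test against coastline-like distances
pops <- unique(gt_ms$pop)
set.seed(derive_seed(GLOBAL_SEED, "geo"))
coast <- cumsum(runif(length(pops), 10, 60))   # positions along a coast, km
d_geo <- as.matrix(dist(coast))
dimnames(d_geo) <- list(pops, pops)
f_ms <- pairwise_fst(gt_ms, n_perm = 99,
                     seed = derive_seed(GLOBAL_SEED, "fst_mantel"))
d_gen <- f_ms$theta / (1 - f_ms$theta)         # linearized F_ST
mt <- mantel_test(d_gen, d_geo, n_perm = 999,
                  seed = derive_seed(GLOBAL_SEED, "mantel"))
cat(sprintf("Mantel: r = %.3f, p = %.3f\n", mt$r, mt$p))
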