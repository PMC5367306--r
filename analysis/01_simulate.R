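#!/usr/bin/env Rscript
# Generate the synthetic study: two genotype panels (13 microsatellites,
# 300 SNPs with depths/tags) for nine localities with one drifted outlier
# population, plus shell outlines and pigmentation images that differ
# between localities (the "plasticity" setting: phenotype structure
# without genome-wide divergence).

source("analysis/00_config.R")

study <- simulate_study()

write_genepop(study$gt_ms, file.path(RESULTS_DIR, "microsats.gen"),
              title = "synthetic microsatellite panel")
write_genepop(study$gt_snp, file.path(RESULTS_DIR, "snps.gen"),
              title = "synthetic SNP panel")

callset <- make_snp_callset(study$gt_snp, missing_rate = CFG$missing_rate,
                            snps_per_tag = CFG$snps_per_tag,
                            seed = derive_seed(GLOBAL_SEED, "callset"))
depth_df <- data.frame(mean_depth = colMeans(callset$depth, na.rm = TRUE),
                       calls = colSums(!is.na(callset$gt$allele1)),
                       tag = callset$tag)
write.csv(depth_df, file.path(RESULTS_DIR, "snp_callset_summary.csv"),
          row.names = FALSE)

shells <- make_shell_population(
  default_shell_model(CFG$n_pops, effect = CFG$shape_effect,
                      coeff_sd = CFG$coeff_sd),
  CFG$n_per_pop, seed = derive_seed(GLOBAL_SEED, "shells"))
for (i in seq_len(5))   # a few example outlines for inspection
  write_outline_csv(shells$outlines[[i]],
                    file.path(RESULTS_DIR, sprintf("outline_%02d.csv", i)))

img <- make_colour_image(pigment_model(70, 0.4, CFG$image_size),
                         seed = derive_seed(GLOBAL_SEED, "img_demo"))
write_pgm(img$pixels, file.path(RESULTS_DIR, "example_shell.pgm"))

cat("Simulated", length(unique(study$gt_ms$pop)), "populations:",
    ncol(study$gt_ms$allele1), "microsats,",
    ncol(study$gt_snp$allele1), "SNPs,",
    length(shells$outlines), "shell outlines.\n")
cat("Outlier population:", CFG$outlier_pop, "(drift t =", CFG$outlier_t,
    ", Ne =", CFG$outlier_Ne, "-> expected F_ST",
    round(expected_fst(CFG$outlier_Ne, CFG$outlier_t), 3), "from base)\n")
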