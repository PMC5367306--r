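#!/usr/bin/env Rscript
# Outline morphometrics: smooth, resample to 1000 pseudo-landmarks, align
# by generalized Procrustes superimposition, decompose by elliptic Fourier
# analysis (harmonic count calibrated to 98% of residual harmonic power),
# run shape PCA, test population differences by MANOVA, and draw the TPS
# deformation between the two extreme population mean shapes.

source("analysis/00_config.R")

shells <- make_shell_population(
  default_shell_model(CFG$n_pops, effect = CFG$shape_effect,
                      coeff_sd = CFG$coeff_sd),
  CFG$n_per_pop, seed = derive_seed(GLOBAL_SEED, "shells"))

smoothed <- lapply(shells$outlines, smooth_outline,
                   n_iters = CFG$smooth_iters)
configs <- lapply(smoothed, resample_equal, k = CFG$n_landmarks)
gpa <- gpa_align(configs)
cat("GPA converged in", gpa$iterations, "iterations\n")

coeffs <- lapply(gpa$aligned, efa_coefficients, n_harmonics = 15)
cal <- harmonic_power_calibration(coeffs, threshold = CFG$harmonic_threshold)
cat("Harmonics for", 100 * CFG$harmonic_threshold,
    "% residual power:", cal$n_selected, "\n")

desc <- efa_descriptor_matrix(coeffs, n_harmonics = cal$n_selected)
write.csv(data.frame(pop = shells$pop, desc),
          file.path(RESULTS_DIR, "efa_coefficients.csv"), row.names = FALSE)

spca <- shape_pca(desc)
k <- min(retain_components(spca$varfrac, CFG$pc_threshold),
         length(shells$pop) - CFG$n_pops - 1)
cat("Retained", k, "PCs holding",
    round(100 * sum(spca$varfrac[1:k]), 1), "% of shape variance;",
    "PC1-3 explain", paste(round(100 * spca$varfrac[1:3], 1), collapse = "/"),
    "%\n")
write.csv(data.frame(pop = shells$pop, spca$scores[, 1:min(5, ncol(spca$scores))]),
          file.path(RESULTS_DIR, "shape_pca_scores.csv"), row.names = FALSE)

mw <- manova_wilks(spca$scores[, 1:k, drop = FALSE], shells$pop)
cat(sprintf("MANOVA: Wilks lambda = %.3f, approx F(%d, %.0f) = %.2f, p = %.2g\n",
            mw$lambda, mw$df[1], mw$df[2], mw$statistic, mw$p))

## TPS deformation between the extreme population mean shapes along PC1
pc1 <- tapply(spca$scores[, 1], shells$pop, mean)
p_lo <- names(which.min(pc1)); p_hi <- names(which.max(pc1))
mean_cfg <- function(p) {
  sel <- which(shells$pop == p)
  Reduce(`+`, lapply(gpa$aligned[sel], function(cf) cf$points)) / length(sel)
}
sub <- seq(1, CFG$n_landmarks, by = 25)   # every 25th pseudo-landmark
td <- tps_deformation(mean_cfg(p_lo)[sub, ], mean_cfg(p_hi)[sub, ],
                      grid_n = 20)
cat(sprintf("TPS %s -> %s: bending energy %.4g\n", p_lo, p_hi,
            td$bending_energy))
write.csv(data.frame(src_x = td$source_grid[, 1], src_y = td$source_grid[, 2],
                     map_x = td$mapped_grid[, 1], map_y = td$mapped_grid[, 2]),
          file.path(RESULTS_DIR, "tps_grid.csv"), row.names = FALSE)
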