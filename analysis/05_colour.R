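#!/usr/bin/env Rscript
# Shell pigmentation: colour index (sqrt of mean pigment grey x pigmented
# fraction, pigment window 0-110) per shell, population means, and a
# one-way ANOVA across localities.

source("analysis/00_config.R")

pops <- paste0("pop", seq_len(CFG$n_pops))
ci <- numeric(0); pop <- character(0)
for (i in seq_len(CFG$n_pops)) {
  u <- (i - 1) / (CFG$n_pops - 1)
  pm <- pigment_model(mean_pigment_grey = 55 + 40 * u,
                      extent = 0.2 + 0.4 * u, image_size = CFG$image_size)
  for (j in seq_len(CFG$n_per_pop)) {
    img <- make_colour_image(pm, seed = derive_seed(GLOBAL_SEED,
                                                    paste0("img", i, "_", j)))
    res <- colour_index(img, threshold = CFG$colour_threshold)
    ci <- c(ci, res$colour_index); pop <- c(pop, pops[i])
  }
}

write.csv(data.frame(pop = pop, colour_index = ci),
          file.path(RESULTS_DIR, "colour_index.csv"), row.names = FALSE)

means <- aggregate(ci, list(pop = pop),
                   function(z) c(mean = mean(z),
                                 se = sd(z) / sqrt(length(z))))
tab <- data.frame(pop = means$pop, mean = means$x[, "mean"],
                  se = means$x[, "se"])
write.csv(tab, file.path(RESULTS_DIR, "colour_population_means.csv"),
          row.names = FALSE)
print(tab, digits = 3)

oa <- oneway_anova(ci, pop)
cat(sprintf("ANOVA: F(%d, %d) = %.2f, p = %.2g\n",
            oa$df[1], oa$df[2], oa$statistic, oa$p))
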