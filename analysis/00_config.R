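# Shared settings for the analysis drivers. Each numbered script is a thin
# narrative over the package functions: it regenerates its inputs from the
# global seed (generation is cheap and deterministic), runs one stage, and
# writes its tables under results/.

library(shellpop)

GLOBAL_SEED <- 20260924
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# the study layout: nine localities, 20 shells each; SNP panel scaled to
# 300 loci for desk-scale runtimes (the full study used 10,539)
CFG <- pipeline_config(seed = GLOBAL_SEED,
                       n_pops = 9L, n_per_pop = 20L,
                       n_snp_loci = 300L, n_microsat_loci = 13L,
                       outlier_pop = "pop9",
                       n_landmarks = 1000L,
                       hwe_batches = 100L, hwe_iterations = 1000L)

simulate_study <- function(cfg = CFG) {
  # regenerate the synthetic study deterministically (see run_pipeline for
  # the same wiring end to end)
  pop_names <- paste0("pop", seq_len(cfg$n_pops))
  outlier_i <- match(cfg$outlier_pop, pop_names)
  panel <- function(base, stage) {
    drifted <- drift_frequencies(
      base, drift_scenario(cfg$outlier_Ne, cfg$outlier_t, 2, 1,
                           seed = derive_seed(cfg$seed, stage)))[[1]]
    freqs <- lapply(seq_len(cfg$n_pops), function(i)
      if (i == outlier_i) drifted else base$freqs)
    sample_genotypes(freqs, cfg$n_per_pop,
                     seed = derive_seed(cfg$seed, paste0(stage, "_gt")),
                     loci = base$loci, pop_names = pop_names)
  }
  base_snp <- base_frequencies(cfg$n_snp_loci, "snp",
                               seed = derive_seed(cfg$seed, "snp_base"))
  base_ms <- base_frequencies(cfg$n_microsat_loci, "microsat",
                              mean_alleles = cfg$mean_alleles,
                              seed = derive_seed(cfg$seed, "ms_base"))
  list(base_snp = base_snp, base_ms = base_ms,
       gt_snp = panel(base_snp, "snp"), gt_ms = panel(base_ms, "microsat"),
       pop_names = pop_names)
}
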