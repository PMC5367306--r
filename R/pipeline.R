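#' Build a validated pipeline configuration
#'
#' Returns the full configuration for [run_pipeline()], starting from
#' defaults that mirror the reference analysis settings (1000 F_ST
#' permutations, harmonic calibration at 98% power, pigment threshold 110,
#' SNP filters at 40 individuals / depth 5, 500 power replicates, alpha
#' 0.05). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    outdir = NULL,
    # synthetic study layout
    n_pops = 9L, n_per_pop = 20L,
    n_snp_loci = 300L, n_microsat_loci = 13L, mean_alleles = 11,
    outlier_pop = "pop9", outlier_Ne = 100, outlier_t = 200,
    # ddRAD call set + filters
    missing_rate = 0.1, snps_per_tag = 2L,
    min_individuals = 40L, min_depth = 5L,
    # popgen testing
    n_perm_fst = 1000L, n_perm_ld = 200L,
    hwe_dememorization = 10000L, hwe_batches = 1000L,
    hwe_iterations = 10000L,
    max_deviating_pops = 4L, lambda = 0.5, alpha = 0.05,
    # power stage
    run_power = FALSE, power_n_reps = 500L,
    power_t = c(10, 20), power_ne = c(1000, 2000, 3000),
    # morphometrics
    n_landmarks = 1000L, n_harmonics = NULL, harmonic_threshold = 0.98,
    smooth_iters = 10L, pc_threshold = 0.95,
    shape_effect = 0.06, coeff_sd = 0.01,
    # colour
    colour_threshold = 110L, image_size = c(96L, 96L),
    # stage toggles
    do_popgen = TRUE, do_fst = TRUE, do_pca = TRUE, do_morpho = TRUE,
    do_colour = TRUE, do_assoc = TRUE, do_hwe = TRUE, do_ld = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

# Per-population pigment models for the plasticity scenario: intensity and
# extent both vary smoothly between localities.
plasticity_pigment_models <- function(cfg) {
  i <- seq_len(cfg$n_pops)
  u <- (i - 1) / max(1, cfg$n_pops - 1)
  lapply(i, function(j)
    pigment_model(mean_pigment_grey = 55 + 40 * u[j],
                  extent = 0.2 + 0.4 * u[j],
                  image_size = cfg$image_size))
}

#' Run the end-to-end synthetic "plasticity scenario" pipeline
#'
#' Generates a synthetic study in which shell shape and pigmentation differ
#' between populations while the populations are genetically homogeneous
#' except for one drifted outlier; then runs the full analysis chain:
#' ddRAD filtering, diversity summaries, HWE and LD tests with q-values,
#' pairwise F_ST with permutation significance, genotype PCA, outline
#' morphometrics (resampling, Procrustes alignment, elliptic Fourier
#' decomposition, shape PCA, MANOVA, TPS grid), colour index ANOVA and the
#' genotype-phenotype mixed-model association. When `outdir` is set, every
#' stage writes CSV outputs plus the resolved configuration.
#'
#' @param config A [pipeline_config()].
#' @return Named list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  out <- list(config = cfg)
  emit <- function(name, df) {
    if (!is.null(cfg$outdir)) {
      dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(df, file.path(cfg$outdir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(cfg),
                         file.path(cfg$outdir, "config.json"),
                         auto_unbox = TRUE, null = "null")
  }

  ## --- simulate genotypes: homogeneous pops + one drifted outlier -------
  pop_names <- paste0("pop", seq_len(cfg$n_pops))
  outlier_i <- match(cfg$outlier_pop, pop_names)
  if (is.na(outlier_i)) stop("outlier_pop must be one of the populations")
  sim_panel <- function(base, stage) {
    scen_out <- drift_scenario(cfg$outlier_Ne, cfg$outlier_t, 2, 1,
                               seed = derive_seed(cfg$seed, stage))
    drifted <- drift_frequencies(base, scen_out)[[1]]
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
  gt_snp_raw <- sim_panel(base_snp, "snp")
  gt_ms <- sim_panel(base_ms, "microsat")
  out$gt_microsat <- gt_ms

  ## --- ddRAD call set and filters --------------------------------------
  callset <- make_snp_callset(gt_snp_raw, missing_rate = cfg$missing_rate,
                              snps_per_tag = cfg$snps_per_tag,
                              seed = derive_seed(cfg$seed, "callset"))
  filt <- filter_snp_calls(callset, cfg$min_individuals, cfg$min_depth)
  gt_snp <- filt$gt
  out$filter_report <- filt$report
  emit("filter_report", data.frame(step = names(filt$report),
                                   n = as.integer(filt$report)))

  ## --- summary statistics, HWE, LD, locus exclusion --------------------
  if (cfg$do_popgen) {
    out$summary <- summary_stats(gt_ms)
    emit("summary_stats", out$summary)
    if (cfg$do_hwe) {
      out$hwe <- hwe_table(gt_ms, cfg$hwe_dememorization, cfg$hwe_batches,
                           cfg$hwe_iterations,
                           seed = derive_seed(cfg$seed, "hwe"),
                           lambda = cfg$lambda)
      emit("hwe", out$hwe)
      sig <- with(out$hwe, tapply(q <= cfg$alpha, list(locus, pop),
                                  function(z) any(z, na.rm = TRUE)))
      excl <- filter_microsat_loci(sig, cfg$max_deviating_pops)
      out$microsat_filter <- excl
      keep_idx <- match(excl$kept, gt_ms$loci$id)
      gt_ms <- subset_genotypes(gt_ms, loci = sort(keep_idx))
    }
    if (cfg$do_ld && n_loci(gt_ms) >= 2) {
      pairs <- utils::combn(n_loci(gt_ms), 2)
      ld <- lapply(seq_len(ncol(pairs)), function(pi) {
        r <- ld_perm_test(gt_ms, pairs[1, pi], pairs[2, pi],
                          n_perm = cfg$n_perm_ld,
                          seed = derive_seed(cfg$seed, paste0("ld", pi)))
        data.frame(locus_a = gt_ms$loci$id[pairs[1, pi]],
                   locus_b = gt_ms$loci$id[pairs[2, pi]],
                   statistic = r$combined$statistic,
                   df = r$combined$df, p = r$combined$p)
      })
      ld <- do.call(rbind, ld)
      ok <- !is.na(ld$p)
      ld$q <- NA_real_
      if (any(ok)) ld$q[ok] <- storey_q(ld$p[ok], lambda = cfg$lambda)
      out$ld <- ld
      emit("ld", ld)
    }
  }

  ## --- pairwise F_ST ----------------------------------------------------
  if (cfg$do_fst) {
    out$fst_snp <- pairwise_fst(gt_snp, n_perm = cfg$n_perm_fst,
                                seed = derive_seed(cfg$seed, "fst_snp"),
                                lambda = cfg$lambda)
    out$fst_microsat <- pairwise_fst(gt_ms, n_perm = cfg$n_perm_fst,
                                     seed = derive_seed(cfg$seed, "fst_ms"),
                                     lambda = cfg$lambda)
    emit("fst_snp_theta", data.frame(pop = rownames(out$fst_snp$theta),
                                     out$fst_snp$theta))
    emit("fst_snp_q", data.frame(pop = rownames(out$fst_snp$q),
                                 out$fst_snp$q))
  }

  ## --- genotype PCA ------------------------------------------------------
  if (cfg$do_pca) {
    out$pca_snp <- genetic_pca(gt_snp)
    emit("pca_snp_scores",
         data.frame(id = out$pca_snp$ids, pop = out$pca_snp$pop,
                    out$pca_snp$scores[, 1:min(5, ncol(out$pca_snp$scores)),
                                       drop = FALSE]))
  }

  ## --- power grid (optional; heavy) -------------------------------------
  if (cfg$run_power) {
    out$power <- power_grid(base_ms, panel = "microsat",
                            t_values = cfg$power_t,
                            ne_values = cfg$power_ne,
                            n_per_subpop = cfg$n_per_pop,
                            n_reps = cfg$power_n_reps, alpha = cfg$alpha,
                            seed = derive_seed(cfg$seed, "power"))
    emit("power", out$power)
  }

  ## --- morphometrics -----------------------------------------------------
  if (cfg$do_morpho) {
    shells <- make_shell_population(
      default_shell_model(cfg$n_pops, effect = cfg$shape_effect,
                          coeff_sd = cfg$coeff_sd),
      cfg$n_per_pop, seed = derive_seed(cfg$seed, "shells"))
    smoothed <- lapply(shells$outlines, smooth_outline,
                       n_iters = cfg$smooth_iters)
    configs <- lapply(smoothed, resample_equal, k = cfg$n_landmarks)
    gpa <- gpa_align(configs)
    coeffs <- lapply(gpa$aligned, efa_coefficients,
                     n_harmonics = max(15L, cfg$n_pops))
    nh <- if (is.null(cfg$n_harmonics))
      harmonic_power_calibration(coeffs,
                                 threshold = cfg$harmonic_threshold)$n_selected
    else cfg$n_harmonics
    desc <- efa_descriptor_matrix(coeffs, n_harmonics = nh)
    spca <- shape_pca(desc)
    kpc <- retain_components(spca$varfrac, cfg$pc_threshold)
    kpc <- min(kpc, length(shells$pop) - cfg$n_pops - 1)
    out$morpho <- list(pop = shells$pop, n_harmonics = nh,
                       pca = spca, retained = kpc,
                       manova = manova_wilks(spca$scores[, seq_len(kpc),
                                                         drop = FALSE],
                                             shells$pop))
    emit("shape_scores", data.frame(pop = shells$pop,
                                    spca$scores[, 1:min(5, ncol(spca$scores)),
                                                drop = FALSE]))
    # TPS between the two extreme population means along shape PC1
    pc1 <- tapply(spca$scores[, 1], shells$pop, mean)
    p_lo <- names(which.min(pc1)); p_hi <- names(which.max(pc1))
    mean_cfg <- function(p) {
      sel <- which(shells$pop == p)
      Reduce(`+`, lapply(gpa$aligned[sel],
                         function(cf) cf$points)) / length(sel)
    }
    sub <- seq(1, cfg$n_landmarks, by = max(1, cfg$n_landmarks %/% 40))
    out$tps <- tps_deformation(mean_cfg(p_lo)[sub, ],
                               mean_cfg(p_hi)[sub, ])
  }

  ## --- colour ------------------------------------------------------------
  if (cfg$do_colour) {
    pm <- plasticity_pigment_models(cfg)
    ci <- numeric(0); cpop <- character(0)
    for (i in seq_len(cfg$n_pops)) for (j in seq_len(cfg$n_per_pop)) {
      img <- make_colour_image(pm[[i]],
                               seed = derive_seed(cfg$seed,
                                                  paste0("img", i, "_", j)))
      res <- colour_index(img, threshold = cfg$colour_threshold)
      ci <- c(ci, res$colour_index)
      cpop <- c(cpop, pop_names[i])
    }
    out$colour <- list(index = ci, pop = cpop,
                       anova = oneway_anova(ci, cpop))
    emit("colour_index", data.frame(pop = cpop, colour_index = ci))
  }

  ## --- association -------------------------------------------------------
  if (cfg$do_assoc && cfg$do_pca && cfg$do_colour) {
    out$assoc_colour <- run_association(out$colour$index,
                                        out$pca_snp$scores[, 1:2],
                                        out$pca_snp$pop,
                                        exclude = cfg$outlier_pop)
    emit("assoc_colour", out$assoc_colour$results)
    if (cfg$do_morpho) {
      out$assoc_shape <- run_association(out$morpho$pca$scores[, 1],
                                         out$pca_snp$scores[, 1:2],
                                         out$pca_snp$pop,
                                         exclude = cfg$outlier_pop)
      emit("assoc_shape", out$assoc_shape$results)
    }
  }
  out
}
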