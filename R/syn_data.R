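#' Draw base allele frequencies for a marker panel
#'
#' Generates the ancestral allele-frequency spectrum that the drift
#' simulator diverges. Microsatellite loci draw their allele number from
#' `2 + Poisson(mean_alleles - 2)` (so panels average `mean_alleles`
#' alleles per locus) and frequencies from a symmetric Dirichlet(1); SNP
#' loci are biallelic with minor-allele frequency Uniform(`maf_range`).
#'
#' @param n_loci Number of loci.
#' @param type `"microsat"` or `"snp"`.
#' @param mean_alleles Target mean allele count for microsatellite loci.
#' @param maf_range Range of the SNP minor-allele frequency.
#' @param seed Integer seed.
#' @return A `base_frequencies` object: list with `freqs` (list of numeric
#'   frequency vectors) and `loci` (data frame of locus records).
#' @export
base_frequencies <- function(n_loci, type = c("snp", "microsat"),
                             mean_alleles = 11, maf_range = c(0.05, 0.5),
                             seed = 1L) {
  type <- match.arg(type)
  stopifnot(n_loci >= 1)
  with_seed(derive_seed(seed, "base_frequencies"), {
    freqs <- if (type == "snp") {
      maf <- stats::runif(n_loci, maf_range[1], maf_range[2])
      lapply(maf, function(p) c(1 - p, p))
    } else {
      k <- 2L + stats::rpois(n_loci, max(0, mean_alleles - 2))
      lapply(k, function(ki) {
        g <- stats::rgamma(ki, shape = 1)  # symmetric Dirichlet(1)
        g / sum(g)
      })
    }
    structure(list(freqs = freqs,
                   loci = data.frame(id = paste0("loc_", seq_len(n_loci)),
                                     type = type, stringsAsFactors = FALSE)),
              class = "base_frequencies")
  })
}

validate_base <- function(base) {
  stopifnot(is.list(base$freqs), length(base$freqs) >= 1)
  for (p in base$freqs) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("each allele frequency vector must be non-negative and sum to 1")
    if (length(p) < 2) stop("loci must have at least 2 alleles")
  }
  invisible(TRUE)
}

#' Define a drift scenario
#'
#' @param Ne Effective (diploid) size of each subpopulation.
#' @param t Generations since separation from the common base population.
#' @param n_subpops Number of subpopulations.
#' @param n_per_subpop Diploid individuals sampled per subpopulation.
#' @param seed Integer seed.
#' @return A `drift_scenario` list.
#' @export
drift_scenario <- function(Ne, t, n_subpops = 9, n_per_subpop = 20,
                           seed = 1L) {
  if (Ne < 1) stop("Ne must be >= 1")
  if (t < 0) stop("t must be >= 0")
  if (n_subpops < 2) stop("n_subpops must be >= 2")
  if (n_per_subpop < 1) stop("n_per_subpop must be >= 1")
  structure(list(Ne = Ne, t = t, n_subpops = n_subpops,
                 n_per_subpop = n_per_subpop, seed = seed),
            class = "drift_scenario")
}

#' Diverge subpopulation allele frequencies by Wright-Fisher drift
#'
#' Each subpopulation starts at the base frequencies and, independently per
#' locus, undergoes `t` successive multinomial resamplings of `2 Ne` gene
#' copies. The expected standardized divergence after `t` generations is
#' `1 - (1 - 1/(2 Ne))^t`.
#'
#' @param base A `base_frequencies` object.
#' @param scen A `drift_scenario`.
#' @return List of length `n_subpops`; each element a list of per-locus
#'   frequency vectors.
#' @export
drift_frequencies <- function(base, scen) {
  validate_base(base)
  stopifnot(inherits(scen, "drift_scenario"))
  two_ne <- round(2 * scen$Ne)
  with_seed(derive_seed(scen$seed, "drift_frequencies"), {
    snp <- all(vapply(base$freqs, length, 1L) == 2L)
    if (snp) {
      # biallelic fast path: one rbinom stream per generation
      p0 <- vapply(base$freqs, function(f) f[2], 0)
      L <- length(p0); s <- scen$n_subpops
      p <- matrix(rep(p0, each = s), nrow = s)  # subpop x locus
      if (scen$t > 0) for (g in seq_len(scen$t))
        p <- matrix(stats::rbinom(s * L, two_ne, p), nrow = s) / two_ne
      lapply(seq_len(s), function(i) lapply(seq_len(L), function(l)
        c(1 - p[i, l], p[i, l])))
    } else {
      lapply(seq_len(scen$n_subpops), function(i)
        lapply(base$freqs, function(f) {
          p <- f
          if (scen$t > 0) for (g in seq_len(scen$t))
            p <- as.vector(stats::rmultinom(1, two_ne, p)) / two_ne
          p
        }))
    }
  })
}

#' Sample diploid genotypes from subpopulation allele frequencies
#'
#' Individuals are drawn under Hardy-Weinberg proportions within each
#' subpopulation: two independent allele draws per individual per locus.
#'
#' @param subpop_freqs Per-subpopulation frequency lists, as returned by
#'   [drift_frequencies()].
#' @param n_per_subpop Individuals per subpopulation.
#' @param seed Integer seed.
#' @param loci Optional locus data frame (id, type).
#' @param pop_names Optional population names.
#' @return A [genotype_table()] with no missing data.
#' @export
sample_genotypes <- function(subpop_freqs, n_per_subpop, seed = 1L,
                             loci = NULL, pop_names = NULL) {
  s <- length(subpop_freqs)
  L <- length(subpop_freqs[[1]])
  if (L == 0) stop("no loci to sample")
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(s))
  n <- s * n_per_subpop
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  biallelic <- all(vapply(subpop_freqs, function(sp)
    all(vapply(sp, length, 1L) == 2L), TRUE))
  with_seed(derive_seed(seed, "sample_genotypes"), {
    if (biallelic) {
      # dosage of allele 2 is Binomial(2, p) under HWE
      for (i in seq_len(s)) {
        rows <- (i - 1L) * n_per_subpop + seq_len(n_per_subpop)
        p2 <- vapply(subpop_freqs[[i]], function(f) f[2], 0)
        if (any(p2 < 0 | p2 > 1)) stop("invalid allele frequencies")
        D <- matrix(stats::rbinom(n_per_subpop * L, 2, rep(p2, each = n_per_subpop)),
                    n_per_subpop, L)
        a1[rows, ] <- 1L + (D == 2L)
        a2[rows, ] <- 1L + (D >= 1L)
      }
    } else {
      for (i in seq_len(s)) {
        rows <- (i - 1L) * n_per_subpop + seq_len(n_per_subpop)
        for (l in seq_len(L)) {
          p <- subpop_freqs[[i]][[l]]
          if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
            stop("invalid allele frequencies")
          draws <- sample.int(length(p), 2L * n_per_subpop, replace = TRUE,
                              prob = p)
          a1[rows, l] <- draws[seq_len(n_per_subpop)]
          a2[rows, l] <- draws[n_per_subpop + seq_len(n_per_subpop)]
        }
      }
    }
  })
  genotype_table(a1, a2, pop = rep(pop_names, each = n_per_subpop),
                 loci = loci)
}

#' Attach stack depths, missingness and tag grouping to a genotype table
#'
#' Emulates a ddRAD call set: every called genotype carries an integer
#' stack depth (>= 1), genotypes go missing independently with
#' `missing_rate`, and SNPs are grouped into tags of `snps_per_tag`
#' consecutive loci.
#'
#' @param gt A [genotype_table()] (typically SNPs, no missing data).
#' @param missing_rate Per-genotype missingness probability in `[0, 1)`.
#' @param depth_dist Function `n -> integer depths >= 1`; the default is a
#'   shifted negative binomial (`1 + rnbinom(mu = 19, size = 5)`, mean 20).
#' @param snps_per_tag SNPs per tag (integer, or vector recycled over tags).
#' @param seed Integer seed.
#' @return A `snp_callset`: list with `gt` (missing applied), `depth`
#'   (matrix, `NA` where missing) and `tag` (integer tag id per locus).
#' @export
make_snp_callset <- function(gt, missing_rate = 0.1, depth_dist = NULL,
                             snps_per_tag = 1L, seed = 1L) {
  stopifnot(inherits(gt, "genotype_table"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (is.null(depth_dist))
    depth_dist <- function(n) 1L + stats::rnbinom(n, mu = 19, size = 5)
  n <- n_ind(gt); L <- n_loci(gt)
  with_seed(derive_seed(seed, "make_snp_callset"), {
    depth <- matrix(as.integer(depth_dist(n * L)), n, L)
    if (any(depth < 1)) stop("depth distribution must have support >= 1")
    miss <- matrix(stats::runif(n * L) < missing_rate, n, L)
    a1 <- gt$allele1; a2 <- gt$allele2
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    depth[miss | is.na(gt$allele1)] <- NA_integer_
    k_tag <- pmax(1L, as.integer(snps_per_tag))
    tag <- if (length(k_tag) == 1L)
      rep(seq_len(ceiling(L / k_tag)), each = k_tag)[seq_len(L)]
    else rep(seq_along(k_tag), times = k_tag)[seq_len(L)]
    structure(list(gt = genotype_table(a1, a2, gt$pop, gt$ids, gt$loci),
                   depth = depth, tag = tag),
              class = "snp_callset")
  })
}

#' Shell shape model for synthetic outline populations
#'
#' @param pop_mean_coeffs List (one per population) of `efa_coefficients`
#'   objects, all with the same harmonic count.
#' @param coeff_sd Gaussian noise SD added to every coefficient (scalar or
#'   per-coefficient matrix matching the harmonic layout).
#' @return A `shell_shape_model` list.
#' @export
shell_shape_model <- function(pop_mean_coeffs, coeff_sd = 0.01) {
  nh <- unique(vapply(pop_mean_coeffs, function(cf) nrow(cf$harmonics), 1L))
  if (length(nh) != 1) stop("all populations must share n_harmonics")
  if (any(coeff_sd < 0)) stop("coeff_sd must be >= 0")
  structure(list(pop_mean_coeffs = pop_mean_coeffs, coeff_sd = coeff_sd,
                 n_harmonics = nh),
            class = "shell_shape_model")
}

#' Default scallop-like shell shape model
#'
#' A fan-shaped base outline (ellipse plus low-order harmonic detail) whose
#' per-population means differ smoothly in harmonics 2 and 3, emulating
#' hinge-angle and hinge-height variation between localities.
#'
#' @param n_pops Number of populations.
#' @param effect Scale of the between-population coefficient differences.
#' @param coeff_sd Within-population coefficient SD.
#' @param n_harmonics Harmonic count of the model.
#' @return A [shell_shape_model()].
#' @export
default_shell_model <- function(n_pops = 9, effect = 0.06, coeff_sd = 0.01,
                                n_harmonics = 10) {
  base <- matrix(0, n_harmonics, 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  base[1, ] <- c(1, 0, 0, 0.8)            # near-circular valve
  base[2, ] <- c(0.05, 0.02, -0.03, 0.04) # mild asymmetry
  base[3, ] <- c(0.03, -0.01, 0.02, 0.02) # auricle detail
  if (n_harmonics >= 4) base[4, ] <- c(0.01, 0.005, -0.005, 0.01)
  means <- lapply(seq_len(n_pops), function(i) {
    u <- (i - (n_pops + 1) / 2) / n_pops  # centred population gradient
    m <- base
    m[2, "a"] <- m[2, "a"] + effect * u
    m[2, "d"] <- m[2, "d"] - effect * u
    m[3, "c"] <- m[3, "c"] + effect * u / 2
    efa_coefficients_object(m, a0 = 0, c0 = 0)
  })
  shell_shape_model(means, coeff_sd = coeff_sd)
}

#' Generate synthetic shell outline populations
#'
#' Each individual outline is the inverse elliptic-Fourier reconstruction of
#' its population's mean coefficients plus independent Gaussian coefficient
#' noise.
#'
#' @param model A [shell_shape_model()].
#' @param n_per_pop Individuals per population.
#' @param n_points Points per reconstructed outline.
#' @param seed Integer seed.
#' @return List with `outlines` (list of `outline_shape`), `pop` (labels)
#'   and `coeffs` (the noisy coefficient objects actually used).
#' @export
make_shell_population <- function(model, n_per_pop, n_points = 360,
                                  seed = 1L) {
  stopifnot(inherits(model, "shell_shape_model"))
  if (n_per_pop < 1) stop("n_per_pop must be >= 1")
  npop <- length(model$pop_mean_coeffs)
  with_seed(derive_seed(seed, "make_shell_population"), {
    outlines <- vector("list", npop * n_per_pop)
    coeffs <- vector("list", npop * n_per_pop)
    pop <- character(npop * n_per_pop)
    k <- 0L
    for (i in seq_len(npop)) {
      mu <- model$pop_mean_coeffs[[i]]$harmonics
      for (j in seq_len(n_per_pop)) {
        k <- k + 1L
        noise <- matrix(stats::rnorm(length(mu), 0, model$coeff_sd),
                        nrow(mu), 4)
        cf <- efa_coefficients_object(mu + noise,
                                      a0 = model$pop_mean_coeffs[[i]]$a0,
                                      c0 = model$pop_mean_coeffs[[i]]$c0)
        coeffs[[k]] <- cf
        outlines[[k]] <- inverse_efa(cf, n_points)
        pop[k] <- paste0("pop", i)
      }
    }
    list(outlines = outlines, pop = pop, coeffs = coeffs)
  })
}

#' Pigmentation model for synthetic shell images
#'
#' @param mean_pigment_grey Target mean grey of pigmented pixels (0-110).
#' @param extent Target pigmented fraction of the shell area, in `[0, 1]`.
#' @param image_size `(height, width)` in pixels.
#' @return A `pigment_model` list.
#' @export
pigment_model <- function(mean_pigment_grey = 70, extent = 0.4,
                          image_size = c(96, 96)) {
  if (mean_pigment_grey < 0 || mean_pigment_grey > 110)
    stop("mean_pigment_grey must be in [0, 110]")
  if (extent < 0 || extent > 1) stop("extent must be in [0, 1]")
  structure(list(mean_pigment_grey = mean_pigment_grey, extent = extent,
                 image_size = as.integer(image_size)),
            class = "pigment_model")
}

#' Generate a synthetic grey shell image with pigment patches
#'
#' The shell is an elliptical mask; a blob-shaped subset of `extent` of its
#' pixels is pigmented with grey values jittered around
#' `mean_pigment_grey` (never above 110); the rest of the shell is pale
#' (grey 150-230) and the background is white.
#'
#' @param model A [pigment_model()].
#' @param seed Integer seed.
#' @return A [grey_image()] (pixels + mask).
#' @export
make_colour_image <- function(model, seed = 1L) {
  stopifnot(inherits(model, "pigment_model"))
  h <- model$image_size[1]; w <- model$image_size[2]
  yc <- (h + 1) / 2; xc <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w); xx <- matrix(rep(seq_len(w), each = h), h, w)
  mask <- ((yy - yc) / (0.45 * h))^2 + ((xx - xc) / (0.45 * w))^2 <= 1
  px <- matrix(255L, h, w)
  with_seed(derive_seed(seed, "make_colour_image"), {
    shell_idx <- which(mask)
    ns <- length(shell_idx)
    px[shell_idx] <- as.integer(round(stats::runif(ns, 150, 230)))
    n_pig <- round(model$extent * ns)
    if (n_pig > 0) {
      # low-frequency random field: pigment forms contiguous patches
      ncent <- 4L
      cy <- stats::runif(ncent, 1, h); cx <- stats::runif(ncent, 1, w)
      f <- rep(0, ns)
      for (ci in seq_len(ncent))
        f <- f - exp(-(((yy[shell_idx] - cy[ci]) / (0.3 * h))^2 +
                       ((xx[shell_idx] - cx[ci]) / (0.3 * w))^2))
      pig <- shell_idx[order(f)[seq_len(n_pig)]]
      g <- model$mean_pigment_grey
      d <- floor(min(8, g, 110 - g))
      jit <- if (d > 0) sample.int(2L * d + 1L, n_pig, replace = TRUE) -
        d - 1L else 0L
      px[pig] <- as.integer(round(g) + jit)
    }
  })
  grey_image(px, mask)
}
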