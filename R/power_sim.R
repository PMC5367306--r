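#' Expected F_ST under pure drift
#'
#' After `t` generations of Wright-Fisher drift at effective size `Ne`, the
#' expected standardized divergence is `1 - (1 - 1/(2 Ne))^t`.
#'
#' @param Ne Effective (diploid) subpopulation size.
#' @param t Generations since separation.
#' @return Numeric.
#' @export
expected_fst <- function(Ne, t) {
  stopifnot(Ne >= 1, t >= 0)
  1 - (1 - 1 / (2 * Ne))^t
}

# chi-square homogeneity test of a subpop x allele count table; alleles
# whose minimum per-subpopulation expected count falls below 1 are merged
# into the next-rarest class first.
chisq_homogeneity <- function(tab) {
  repeat {
    if (ncol(tab) < 2) return(c(stat = NA_real_, df = NA_real_))
    rowtot <- rowSums(tab); coltot <- colSums(tab); ntot <- sum(tab)
    if (ntot == 0 || any(rowtot == 0)) return(c(stat = NA_real_, df = NA_real_))
    e <- outer(rowtot, coltot) / ntot
    if (min(e) >= 1 || ncol(tab) == 2) break
    o <- order(coltot)
    tab[, o[2]] <- tab[, o[2]] + tab[, o[1]]
    tab <- tab[, -o[1], drop = FALSE]
  }
  coltot <- colSums(tab)
  if (any(coltot == 0)) {
    tab <- tab[, coltot > 0, drop = FALSE]
    if (ncol(tab) < 2) return(c(stat = NA_real_, df = NA_real_))
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  c(stat = sum((tab - e)^2 / e),
    df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

#' Drift-based power simulation for a marker panel
#'
#' Estimates the power of a panel to detect divergence generated by drift:
#' per replicate, all subpopulations drift from the base frequencies
#' ([drift_frequencies()]), genotypes are sampled under Hardy-Weinberg
#' proportions ([sample_genotypes()]), and allele-frequency homogeneity
#' across subpopulations is tested per locus, summing the statistics and
#' degrees of freedom over loci. Power is the fraction of replicates
#' significant at `alpha`. At `t = 0` the procedure estimates the type-I
#' error.
#'
#' @param base A [base_frequencies()] panel.
#' @param scen A [drift_scenario()].
#' @param n_reps Replicates (default 500).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param method `"chisq"` (Pearson chi-square summed over loci, default)
#'   or `"fisher"` (per-locus Monte-Carlo exact tests combined by Fisher's
#'   method).
#' @param fisher_b Monte-Carlo table draws for the Fisher variant.
#' @param record_theta Also record the mean multilocus Weir-Cockerham theta
#'   across replicates (slower).
#' @return A `power_result`: list with `power`, `n_reps`, `alpha`, `mc_se`,
#'   `expected_fst`, and `mean_theta` when requested.
#' @export
powsim_power <- function(base, scen, n_reps = 500, alpha = 0.05, seed = 1L,
                         method = c("chisq", "fisher"), fisher_b = 1000,
                         record_theta = FALSE) {
  method <- match.arg(method)
  validate_base(base)
  stopifnot(inherits(scen, "drift_scenario"), n_reps >= 1,
            alpha > 0, alpha < 1)
  if (all(vapply(base$freqs, function(f) max(f) == 1, TRUE)))
    stop("base panel has no polymorphic locus")
  L <- length(base$freqs)
  sig <- logical(n_reps)
  thetas <- rep(NA_real_, n_reps)
  for (rep_i in seq_len(n_reps)) {
    scen_i <- scen
    scen_i$seed <- derive_seed(seed, paste0("powsim_rep_", rep_i))
    freqs <- drift_frequencies(base, scen_i)
    gt <- sample_genotypes(freqs, scen$n_per_subpop, seed = scen_i$seed,
                           loci = base$loci)
    s <- scen$n_subpops
    pop_of <- rep(seq_len(s), each = scen$n_per_subpop)
    biallelic <- all(vapply(base$freqs, length, 1L) == 2L)
    if (method == "chisq" && biallelic) {
      # vectorized path for SNP panels: s x 2 tables per locus
      C2 <- rowsum((gt$allele1 == 2L) + (gt$allele2 == 2L), pop_of)
      rowtot <- rep(2 * scen$n_per_subpop, s)
      N <- sum(rowtot)
      col2 <- colSums(C2)
      poly <- col2 > 0 & col2 < N
      stat_tot <- 0; df_tot <- 0
      if (any(poly)) {
        C2p <- C2[, poly, drop = FALSE]
        col2p <- col2[poly]
        E2 <- outer(rowtot, col2p) / N
        E1 <- outer(rowtot, N - col2p) / N
        C1p <- rowtot - C2p
        # (N-1)/N rescaling gives the statistic its exact conditional mean
        # (E[X^2] = df * N/(N-1) under fixed margins), which matters when
        # thousands of sparse per-locus tables are summed
        stat_l <- colSums((C2p - E2)^2 / E2 + (C1p - E1)^2 / E1) *
          (N - 1) / N
        stat_tot <- sum(stat_l)
        df_tot <- (s - 1) * sum(poly)
      }
      pval <- if (df_tot > 0)
        stats::pchisq(stat_tot, df_tot, lower.tail = FALSE) else 1
    } else if (method == "chisq") {
      stat_tot <- 0; df_tot <- 0
      for (l in seq_len(L)) {
        al <- c(gt$allele1[, l], gt$allele2[, l])
        pop2 <- c(pop_of, pop_of)
        codes <- sort(unique(al))
        if (length(codes) < 2) next  # fixed in all subpopulations
        tab <- table(factor(pop2, levels = seq_len(s)),
                     factor(al, levels = codes))
        res <- chisq_homogeneity(unclass(tab))
        if (is.finite(res["stat"])) {
          ntab <- 2 * scen$n_per_subpop * s
          stat_tot <- stat_tot + res["stat"] * (ntab - 1) / ntab
          df_tot <- df_tot + res["df"]
        }
      }
      pval <- if (df_tot > 0)
        stats::pchisq(stat_tot, df_tot, lower.tail = FALSE) else 1
    } else {
      pl <- c()
      for (l in seq_len(L)) {
        al <- c(gt$allele1[, l], gt$allele2[, l])
        pop2 <- c(pop_of, pop_of)
        codes <- sort(unique(al))
        if (length(codes) < 2) next
        tab <- table(factor(pop2, levels = seq_len(s)),
                     factor(al, levels = codes))
        ft <- stats::fisher.test(unclass(tab), simulate.p.value = TRUE,
                                 B = fisher_b)
        pl <- c(pl, ft$p.value)
      }
      pval <- if (length(pl) > 0)
        stats::pchisq(-2 * sum(log(pmax(pl, 1e-300))), 2 * length(pl),
                      lower.tail = FALSE) else 1
    }
    sig[rep_i] <- pval <= alpha
    if (record_theta) thetas[rep_i] <- wc_theta(gt)$theta
  }
  pw <- mean(sig)
  structure(list(power = pw, n_reps = n_reps, alpha = alpha,
                 mc_se = sqrt(pw * (1 - pw) / n_reps),
                 expected_fst = expected_fst(scen$Ne, scen$t),
                 mean_theta = if (record_theta) mean(thetas) else NULL,
                 method = method),
            class = "power_result")
}

#' Run a grid of power scenarios
#'
#' Convenience wrapper producing a long table (panel, t, Ne, power, mc_se,
#' expected_fst) over the cross of `t_values` and `ne_values`.
#'
#' @param base A [base_frequencies()] panel.
#' @param panel Label for the panel column.
#' @param t_values,ne_values Scenario grids.
#' @param n_subpops,n_per_subpop Sampling design.
#' @param n_reps,alpha,seed,method Passed to [powsim_power()].
#' @return Data frame.
#' @export
power_grid <- function(base, panel = "panel", t_values = c(10, 20),
                       ne_values = c(1000, 2000, 3000), n_subpops = 9,
                       n_per_subpop = 20, n_reps = 500, alpha = 0.05,
                       seed = 1L, method = "chisq") {
  grid <- expand.grid(t = t_values, Ne = ne_values, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    scen <- drift_scenario(grid$Ne[i], grid$t[i], n_subpops, n_per_subpop,
                           seed = derive_seed(seed, paste0("grid_", i)))
    pr <- powsim_power(base, scen, n_reps = n_reps, alpha = alpha,
                       seed = scen$seed, method = method)
    data.frame(panel = panel, t = grid$t[i], Ne = grid$Ne[i],
               power = pr$power, mc_se = pr$mc_se,
               expected_fst = pr$expected_fst)
  })
  do.call(rbind, rows)
}
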