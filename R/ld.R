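#' Genotypic linkage-disequilibrium permutation test
#'
#' Tests independence of the genotype classes at two loci. The statistic is
#' the log-likelihood ratio (G) of the genotypic contingency table within
#' each population; significance comes from permuting one locus's genotypes
#' across individuals within the population. Per-population p-values are
#' combined across populations with Fisher's method (`-2 sum log p`,
#' chi-square with 2k df).
#'
#' @param gt A [genotype_table()].
#' @param locus_a,locus_b Locus indices (or ids).
#' @param n_perm Number of permutations per population (default 999).
#' @param seed Integer seed.
#' @return List with `per_pop` (data frame: pop, G, p, testable) and
#'   `combined` (Fisher chi-square statistic, df, p).
#' @export
ld_perm_test <- function(gt, locus_a, locus_b, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.character(locus_a)) locus_a <- match(locus_a, gt$loci$id)
  if (is.character(locus_b)) locus_b <- match(locus_b, gt$loci$id)
  pops <- unique(gt$pop)
  g_stat <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    2 * sum(tab[nz] * log(tab[nz] / e[nz]))
  }
  geno_class <- function(l, sel) {
    a1 <- gt$allele1[sel, l]; a2 <- gt$allele2[sel, l]
    ifelse(is.na(a1), NA_character_, paste(a1, a2, sep = "/"))
  }
  res <- data.frame(pop = pops, G = NA_real_, p = NA_real_,
                    testable = FALSE, stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, "ld_perm_test"), {
    for (i in seq_along(pops)) {
      sel <- which(gt$pop == pops[i])
      ga <- geno_class(locus_a, sel)
      gb <- geno_class(locus_b, sel)
      ok <- !is.na(ga) & !is.na(gb)
      ga <- factor(ga[ok]); gb <- factor(gb[ok])
      if (nlevels(ga) < 2 || nlevels(gb) < 2 || length(ga) < 2) next
      obs <- g_stat(table(ga, gb))
      perm <- vapply(seq_len(n_perm), function(b)
        g_stat(table(ga, sample(gb))), 0)
      res$G[i] <- obs
      res$p[i] <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
      res$testable[i] <- TRUE
    }
  })
  k <- sum(res$testable)
  combined <- if (k > 0) {
    stat <- -2 * sum(log(res$p[res$testable]))
    list(statistic = stat, df = 2 * k,
         p = stats::pchisq(stat, 2 * k, lower.tail = FALSE))
  } else list(statistic = NA_real_, df = 0L, p = NA_real_)
  list(per_pop = res, combined = combined)
}
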