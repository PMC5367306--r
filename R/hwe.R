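#' Markov-chain exact test of Hardy-Weinberg proportions
#'
#' Monte-Carlo estimate of the exact probability-test p-value for one
#' locus in one population: the summed conditional probability (given the
#' allele counts) of all genotype tables no more probable than the observed
#' one. The sampler is a switch chain on the pairing of gene copies whose
#' stationary distribution is exactly the conditional null
#' `P(table) proportional to 2^H / prod n_ij!`. The defaults mirror
#' conventional settings: dememorization 10,000, then 1,000 batches of
#' 10,000 iterations, with the Monte-Carlo standard error taken from the
#' between-batch variance.
#'
#' @param counts Genotype counts: either a square matrix (allele x allele,
#'   upper triangle or symmetric) or a data frame with columns `a1`, `a2`,
#'   `count` as returned by the internal genotype tally.
#' @param dememorization Burn-in switch steps.
#' @param batches Number of batches.
#' @param iterations_per_batch Switch steps per batch.
#' @param seed Integer seed.
#' @return List with `p`, `mc_se`, `statistic` (relative log-probability of
#'   the observed table), `n` (genotypes) and the settings used.
#' @export
hwe_exact_mc <- function(counts, dememorization = 10000, batches = 1000,
                         iterations_per_batch = 10000, seed = 1L) {
  if (is.data.frame(counts)) {
    al <- sort(unique(c(counts$a1, counts$a2)))
    k <- length(al)
    m <- matrix(0L, k, k)
    for (r in seq_len(nrow(counts))) {
      i <- match(counts$a1[r], al); j <- match(counts$a2[r], al)
      m[min(i, j), max(i, j)] <- m[min(i, j), max(i, j)] +
        as.integer(counts$count[r])
    }
    counts <- m
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  # fold to upper triangle
  k <- nrow(counts)
  for (i in seq_len(k)) for (j in seq_len(k)) if (j < i) {
    counts[j, i] <- counts[j, i] + counts[i, j]
    counts[i, j] <- 0L
  }
  n <- sum(counts)
  if (n < 1) stop("need at least one genotype")
  # alleles actually present
  present <- which(rowSums(counts) + colSums(counts) > 0)
  counts <- counts[present, present, drop = FALSE]
  settings <- list(dememorization = dememorization, batches = batches,
                   iterations_per_batch = iterations_per_batch)
  if (nrow(counts) < 2) {
    return(list(p = 1, mc_se = 0, statistic = 0, n = n,
                settings = settings))
  }
  stopifnot(dememorization >= 0, batches >= 1, iterations_per_batch >= 1)
  res <- with_seed(derive_seed(seed, "hwe_exact_mc"),
                   .hwe_chain_cpp(matrix(as.integer(counts), nrow(counts)),
                                  as.integer(dememorization),
                                  as.integer(batches),
                                  as.integer(iterations_per_batch)))
  list(p = res$p, mc_se = res$mc_se, statistic = res$S_obs, n = n,
       settings = settings)
}

#' HWE tests for every locus-population cell of a genotype table
#'
#' Runs [hwe_exact_mc()] per locus per population and attaches table-wide
#' Storey q-values across all testable cells.
#'
#' @param gt A [genotype_table()].
#' @param dememorization,batches,iterations_per_batch Chain settings
#'   passed to [hwe_exact_mc()].
#' @param seed Integer seed.
#' @param lambda Storey lambda.
#' @return Data frame: locus, pop, p, mc_se, q (NA where untestable).
#' @export
hwe_table <- function(gt, dememorization = 10000, batches = 1000,
                      iterations_per_batch = 10000, seed = 1L,
                      lambda = 0.5) {
  pops <- unique(gt$pop)
  grid <- expand.grid(locus = seq_len(n_loci(gt)), pop = pops,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$p <- grid$mc_se <- NA_real_
  for (r in seq_len(nrow(grid))) {
    cnts <- genotype_counts(gt, grid$locus[r],
                            which(gt$pop == grid$pop[r]))
    if (nrow(cnts) == 0) next
    res <- hwe_exact_mc(cnts, dememorization, batches,
                        iterations_per_batch,
                        seed = derive_seed(seed, paste0("hwe_", r)))
    grid$p[r] <- res$p; grid$mc_se[r] <- res$mc_se
  }
  grid$q <- NA_real_
  ok <- !is.na(grid$p)
  if (any(ok)) grid$q[ok] <- storey_q(grid$p[ok], lambda = lambda)
  grid$locus <- gt$loci$id[grid$locus]
  grid
}
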