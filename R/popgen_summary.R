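#' Per-locus, per-population diversity summaries
#'
#' Allele counts, observed heterozygosity (fraction of non-missing
#' genotypes that are heterozygous) and unbiased expected heterozygosity
#' `He = 2n/(2n-1) * (1 - sum p^2)` for every locus-population cell.
#' Monomorphic cells report `He = Ho = 0`; cells with no non-missing
#' genotypes are `NA`.
#'
#' @param gt A [genotype_table()].
#' @return Data frame with columns locus, pop, n (non-missing genotypes),
#'   n_alleles, Ho, He.
#' @export
summary_stats <- function(gt) {
  pops <- unique(gt$pop)
  L <- n_loci(gt)
  out <- expand.grid(locus = gt$loci$id, pop = pops,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- out$n_alleles <- out$Ho <- out$He <- NA_real_
  row <- 0L
  for (p in pops) for (l in seq_len(L)) {
    row <- which(out$locus == gt$loci$id[l] & out$pop == p)
    sel <- gt$pop == p
    a1 <- gt$allele1[sel, l]; a2 <- gt$allele2[sel, l]
    ok <- !is.na(a1)
    n <- sum(ok)
    out$n[row] <- n
    if (n == 0) next
    al <- c(a1[ok], a2[ok])
    freqs <- as.vector(table(al)) / (2 * n)
    out$n_alleles[row] <- length(freqs)
    out$Ho[row] <- mean(a1[ok] != a2[ok])
    out$He[row] <- if (length(freqs) < 2) 0 else
      (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
  }
  out[, c("locus", "pop", "n", "n_alleles", "Ho", "He")]
}

#' Storey q-values at a single lambda
#'
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))`; on sorted p-values,
#' `q(i) = min over j >= i of pi0 * m * p(j) / j`. With `pi0 = 1` this is
#' exactly the Benjamini-Hochberg step-up adjustment.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param lambda Tuning parameter for the null-proportion estimate.
#' @param pi0 Optional override of the estimated null proportion.
#' @return Numeric q-values, same order as `pvals`.
#' @export
storey_q <- function(pvals, lambda = 0.5, pi0 = NULL) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]")
  m <- length(pvals)
  if (is.null(pi0)) pi0 <- min(1, mean(pvals > lambda) / (1 - lambda))
  o <- order(pvals)
  ranked <- pi0 * m * pvals[o] / seq_len(m)
  qs <- rev(cummin(rev(ranked)))
  qs <- pmin(qs, 1)
  out <- numeric(m)
  out[o] <- qs
  out
}

#' Exclude microsatellite loci deviating from HWE in too many populations
#'
#' A locus significant (after FDR correction) in more than
#' `max_deviating_pops` populations is excluded; untestable cells count as
#' non-significant.
#'
#' @param sig Logical matrix loci x populations of post-FDR significance
#'   (`NA` = untestable, treated as `FALSE`).
#' @param max_deviating_pops Maximum tolerated number of deviating
#'   populations (default 4: loci deviating in 5+ populations go).
#' @return List with `kept`, `excluded` (locus names) and `n_deviating`
#'   (named counts).
#' @export
filter_microsat_loci <- function(sig, max_deviating_pops = 4) {
  sig <- as.matrix(sig)
  sig[is.na(sig)] <- FALSE
  ndev <- rowSums(sig)
  if (is.null(rownames(sig))) rownames(sig) <- paste0("loc_", seq_len(nrow(sig)))
  names(ndev) <- rownames(sig)
  keep <- ndev <= max_deviating_pops
  list(kept = rownames(sig)[keep], excluded = rownames(sig)[!keep],
       n_deviating = ndev)
}

#' Filter a ddRAD SNP call set
#'
#' Applies, in order: (1) keep only biallelic SNPs genotyped in at least
#' `min_individuals` individuals; (2) within each tag keep only the SNP
#' genotyped in the largest number of individuals (ties: first); (3) set
#' individual genotypes with stack depth below `min_depth` to missing.
#' The call-count and biallelic predicates are re-applied once after depth
#' masking so the filter is idempotent: re-running it on its own output
#' changes nothing.
#'
#' @param callset A `snp_callset` (see [make_snp_callset()]).
#' @param min_individuals Minimum genotyped individuals per SNP.
#' @param min_depth Minimum stack depth of an individual genotype.
#' @param biallelic_only Require exactly two observed alleles.
#' @return List with `callset` (filtered `snp_callset`), `gt` (its
#'   genotype table) and `report` (counts surviving each step).
#' @export
filter_snp_calls <- function(callset, min_individuals = 40, min_depth = 5,
                             biallelic_only = TRUE) {
  gt <- callset$gt
  L <- n_loci(gt)
  report <- c(input = L)
  if (L == 0) {
    return(list(callset = callset, gt = gt,
                report = c(input = 0, call_count = 0, per_tag = 0,
                           final = 0)))
  }
  calls <- colSums(!is.na(gt$allele1))
  nall <- vapply(seq_len(L), function(l) {
    a <- c(gt$allele1[, l], gt$allele2[, l])
    length(unique(a[!is.na(a)]))
  }, 0L)
  step1 <- calls >= min_individuals & (!biallelic_only | nall == 2)
  report["call_count"] <- sum(step1)
  # step 2: best SNP per tag by call count among survivors of step 1
  keep2 <- rep(FALSE, L)
  for (tg in unique(callset$tag)) {
    cand <- which(callset$tag == tg & step1)
    if (length(cand) > 0) keep2[cand[which.max(calls[cand])]] <- TRUE
  }
  report["per_tag"] <- sum(keep2)
  idx <- which(keep2)
  a1 <- gt$allele1[, idx, drop = FALSE]
  a2 <- gt$allele2[, idx, drop = FALSE]
  depth <- callset$depth[, idx, drop = FALSE]
  low <- !is.na(depth) & depth < min_depth
  a1[low] <- NA_integer_; a2[low] <- NA_integer_
  depth[low] <- NA_integer_
  # re-apply the step-1 predicate post-masking (keeps the filter idempotent)
  calls2 <- colSums(!is.na(a1))
  nall2 <- vapply(seq_len(ncol(a1)), function(l) {
    a <- c(a1[, l], a2[, l])
    length(unique(a[!is.na(a)]))
  }, 0L)
  final <- calls2 >= min_individuals & (!biallelic_only | nall2 == 2)
  report["final"] <- sum(final)
  gt_out <- genotype_table(a1[, final, drop = FALSE],
                           a2[, final, drop = FALSE],
                           gt$pop, gt$ids, gt$loci[idx[final], , drop = FALSE])
  cs_out <- structure(list(gt = gt_out,
                           depth = depth[, final, drop = FALSE],
                           tag = callset$tag[idx[final]]),
                      class = "snp_callset")
  list(callset = cs_out, gt = gt_out, report = report)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the upper-triangle off-diagonal entries, with a
#' one-sided (greater) permutation p-value from simultaneous row/column
#' permutation of one matrix, using the add-one estimator.
#'
#' @param d_gen,d_geo Symmetric distance matrices with matching labels.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d_gen, d_geo, n_perm = 999, seed = 1L) {
  d_gen <- as.matrix(d_gen); d_geo <- as.matrix(d_geo)
  if (!identical(dim(d_gen), dim(d_geo)))
    stop("distance matrices must have the same dimension")
  n <- nrow(d_gen)
  if (n < 3) stop("mantel test needs at least 3 objects")
  if (n_perm < 1) stop("n_perm must be >= 1")
  ut <- upper.tri(d_gen)
  r_obs <- stats::cor(d_gen[ut], d_geo[ut])
  with_seed(derive_seed(seed, "mantel_test"), {
    r_perm <- vapply(seq_len(n_perm), function(b) {
      o <- sample.int(n)
      stats::cor(d_gen[ut], d_geo[o, o][ut])
    }, 0)
  })
  list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Principal component analysis of genotypes
#'
#' Individuals are encoded as per-allele dosage vectors (0/1/2, one column
#' per allele per locus); missing entries are mean-imputed per column, the
#' columns are centered (not scaled) and the matrix decomposed by singular
#' values.
#'
#' @param gt A [genotype_table()].
#' @param n_components Number of components to return (default: full rank).
#' @return List with `scores`, `loadings`, `varfrac` (variance fractions
#'   over the retained rank), `pop` and `ids`.
#' @export
genetic_pca <- function(gt, n_components = NULL) {
  if (n_ind(gt) < 2) stop("need at least 2 individuals")
  ad <- allele_dosage(gt)
  empty_loci <- setdiff(seq_len(n_loci(gt)), unique(ad$lidx))
  if (length(empty_loci) > 0)
    warning(sprintf("dropping %d all-missing loci", length(empty_loci)))
  X <- ad$X * 1
  M <- ad$Ml[, ad$lidx, drop = FALSE]
  X[!M] <- NA_real_
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) X <- X[, !all_missing, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (is.null(n_components)) n_components <- rank
  n_components <- min(n_components, rank)
  ev <- sv$d[seq_len(rank)]^2
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(n_components)) {
    i0 <- which.max(abs(loadings[, j]))
    if (loadings[i0, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores, loadings = loadings,
       varfrac = ev[seq_len(n_components)] / sum(ev),
       eigenvalues = ev, pop = gt$pop, ids = gt$ids)
}
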