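# Weir & Cockerham (1984) variance components.
#
# Internal engine: everything is laid out per "allele column" — each allele
# of each locus is one column — so the components can be computed with
# dense matrix arithmetic for thousands of loci and many permutations at
# once.

# Expand a genotype table into per-allele-column dosage structures.
# Returns: X (n x A dosage 0/1/2), Hh (n x A, 1 when heterozygous carrying
# that allele), Ml (n x L non-missing indicator), lidx (locus of each
# allele column), alleles (allele code of each column).
allele_dosage <- function(gt, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(n_loci(gt))
  n <- n_ind(gt)
  Xs <- list(); Hs <- list(); lidx <- integer(0); acode <- integer(0)
  Ml <- matrix(FALSE, n, length(loci))
  for (j in seq_along(loci)) {
    l <- loci[j]
    a1 <- gt$allele1[, l]; a2 <- gt$allele2[, l]
    ok <- !is.na(a1)
    Ml[, j] <- ok
    al <- sort(unique(c(a1[ok], a2[ok])))
    if (length(al) == 0) next
    for (a in al) {
      d <- (a1 == a) + (a2 == a)
      d[!ok] <- 0L
      Xs[[length(Xs) + 1L]] <- d
      Hs[[length(Hs) + 1L]] <- as.integer(d == 1L & a1 != a2)
      lidx <- c(lidx, j)
      acode <- c(acode, a)
    }
  }
  list(X = do.call(cbind, Xs), Hh = do.call(cbind, Hs), Ml = Ml,
       lidx = lidx, alleles = acode)
}

# Core variance-components computation from per-population summaries.
# All inputs are A x m matrices (allele columns x scenarios): C* allele
# counts (sum of dosages), H* heterozygote counts, N* non-missing genotype
# counts per population, expanded to allele columns. r = 2 populations.
wc_components_pair <- function(C1, C2, H1, H2, N1, N2) {
  r <- 2
  nbar <- (N1 + N2) / r
  ntot <- N1 + N2
  nc <- ntot - (N1^2 + N2^2) / ntot           # (r*nbar - sum n^2/(r nbar))/(r-1)
  p1 <- C1 / (2 * N1); p2 <- C2 / (2 * N2)
  pbar <- (C1 + C2) / (2 * ntot)
  s2 <- (N1 * (p1 - pbar)^2 + N2 * (p2 - pbar)^2) / nbar  # /((r-1)*nbar)
  hbar <- (H1 + H2) / ntot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- !is.finite(a) | !is.finite(b) | !is.finite(cc) |
    N1 < 1 | N2 < 1 | nbar <= 1 | nc <= 0
  a[bad] <- 0; b[bad] <- 0; cc[bad] <- 0
  list(a = a, b = b, c = cc)
}

# General r-population components for one locus (small, loop-friendly).
# freqs: r x k allele frequency matrix; het: r x k heterozygote-carrier
# proportions; nvec: per-population genotype counts.
wc_components_multi <- function(freqs, het, nvec) {
  r <- length(nvec)
  nbar <- mean(nvec)
  nc <- (r * nbar - sum(nvec^2) / (r * nbar)) / (r - 1)
  k <- ncol(freqs)
  a <- b <- cc <- numeric(k)
  for (u in seq_len(k)) {
    p <- freqs[, u]
    pbar <- sum(nvec * p) / (r * nbar)
    s2 <- sum(nvec * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(nvec * het[, u]) / (r * nbar)
    a[u] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b[u] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc[u] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham theta (F_ST)
#'
#' Per-locus and multilocus Weir & Cockerham (1984) estimator of F_ST from
#' genotype data. Variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) are computed
#' per allele per locus; the multilocus estimate is the ratio of summed
#' components, with per-locus sample sizes honouring missing data. Loci
#' monomorphic across the chosen populations contribute nothing. Theta can
#' be negative in the absence of differentiation.
#'
#' @param gt A [genotype_table()].
#' @param populations Character subset of population labels (default: all).
#' @param loci Integer/logical subset of loci (default: all).
#' @return List with `theta` (multilocus), `per_locus` (named vector, `NA`
#'   for uninformative loci) and the summed components `a`, `b`, `c`.
#' @export
wc_theta <- function(gt, populations = NULL, loci = NULL) {
  if (is.null(populations)) populations <- unique(gt$pop)
  if (length(populations) < 2) stop("need at least 2 populations")
  keep <- gt$pop %in% populations
  gt2 <- subset_genotypes(gt, individuals = keep, loci = loci)
  pops <- unique(gt2$pop)
  r <- length(pops)
  L <- n_loci(gt2)
  asum <- bsum <- csum <- 0
  per_locus <- rep(NA_real_, L)
  names(per_locus) <- gt2$loci$id
  for (l in seq_len(L)) {
    a1 <- gt2$allele1[, l]; a2 <- gt2$allele2[, l]
    ok <- !is.na(a1)
    nvec <- vapply(pops, function(p) sum(ok & gt2$pop == p), 0)
    if (any(nvec < 1) || mean(nvec) <= 1) next
    al <- sort(unique(c(a1[ok], a2[ok])))
    if (length(al) < 2) next
    freqs <- matrix(0, r, length(al))
    het <- matrix(0, r, length(al))
    for (i in seq_len(r)) {
      sel <- ok & gt2$pop == pops[i]
      for (u in seq_along(al)) {
        d <- (a1[sel] == al[u]) + (a2[sel] == al[u])
        freqs[i, u] <- sum(d) / (2 * nvec[i])
        het[i, u] <- sum(d == 1) / nvec[i]
      }
    }
    comp <- wc_components_multi(freqs, het, nvec)
    tot <- sum(comp$a + comp$b + comp$c)
    if (is.finite(tot) && tot > 0) per_locus[l] <- sum(comp$a) / tot
    asum <- asum + sum(comp$a); bsum <- bsum + sum(comp$b)
    csum <- csum + sum(comp$c)
  }
  denom <- asum + bsum + csum
  list(theta = if (denom > 0) asum / denom else NA_real_,
       per_locus = per_locus, a = asum, b = bsum, c = csum)
}

#' Pairwise F_ST matrix with permutation significance
#'
#' Computes Weir-Cockerham theta for every population pair, with one-sided
#' permutation p-values obtained by permuting whole individuals (both
#' alleles together) between the two populations of a pair, and table-wide
#' Storey q-values over all pairs. The add-one estimator
#' `p = (1 + #{theta_perm >= theta_obs}) / (n_perm + 1)` is used, so
#' permutation p-values are never zero.
#'
#' @param gt A [genotype_table()].
#' @param n_perm Number of permutations per pair (default 1000).
#' @param seed Integer seed.
#' @param lambda Storey lambda for the q-value computation.
#' @return An `fst_matrix`: list with `labels`, `theta`, `p`, `q`
#'   (symmetric matrices, zero/NA diagonal) and `untestable` (logical).
#' @export
pairwise_fst <- function(gt, n_perm = 1000, seed = 1L, lambda = 0.5) {
  pops <- unique(gt$pop)
  npop <- length(pops)
  if (npop < 2) stop("need at least 2 populations")
  if (n_perm < 1) stop("n_perm must be >= 1")
  sizes <- table(gt$pop)[pops]
  ad <- allele_dosage(gt)
  theta_m <- matrix(0, npop, npop, dimnames = list(pops, pops))
  p_m <- matrix(NA_real_, npop, npop, dimnames = list(pops, pops))
  untestable <- matrix(FALSE, npop, npop, dimnames = list(pops, pops))
  pvec <- c(); pair_idx <- list()
  with_seed(derive_seed(seed, "pairwise_fst"), {
    for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
      sel <- which(gt$pop %in% pops[c(i, j)])
      if (sizes[i] < 2 || sizes[j] < 2) {
        untestable[i, j] <- untestable[j, i] <- TRUE
        next
      }
      X <- ad$X[sel, , drop = FALSE]
      Hh <- ad$Hh[sel, , drop = FALSE]
      Ml <- ad$Ml[sel, , drop = FALSE] * 1
      in1 <- gt$pop[sel] == pops[i]
      n12 <- length(sel); n1 <- sum(in1)
      # observed + permuted membership indicators, one column each
      Z <- matrix(0, n12, n_perm + 1L)
      Z[in1, 1] <- 1
      for (b in seq_len(n_perm)) Z[sample.int(n12, n1), b + 1L] <- 1
      C1 <- crossprod(X, Z)              # A x (n_perm+1)
      H1 <- crossprod(Hh, Z)
      N1l <- crossprod(Ml, Z)            # L x (n_perm+1)
      Ctot <- colSums(X); Htot <- colSums(Hh); Ntotl <- colSums(Ml)
      C2 <- Ctot - C1; H2 <- Htot - H1; N2l <- Ntotl - N1l
      N1 <- N1l[ad$lidx, , drop = FALSE]
      N2 <- N2l[ad$lidx, , drop = FALSE]
      comp <- wc_components_pair(C1, C2, H1, H2, N1, N2)
      th <- colSums(comp$a) / colSums(comp$a + comp$b + comp$c)
      th[!is.finite(th)] <- NA_real_
      obs <- th[1]
      perm <- th[-1]
      theta_m[i, j] <- theta_m[j, i] <- obs
      pv <- (1 + sum(perm >= obs, na.rm = TRUE)) / (sum(!is.na(perm)) + 1)
      p_m[i, j] <- p_m[j, i] <- pv
      pvec <- c(pvec, pv)
      pair_idx[[length(pair_idx) + 1L]] <- c(i, j)
    }
  })
  q_m <- matrix(NA_real_, npop, npop, dimnames = list(pops, pops))
  if (length(pvec) > 0) {
    qv <- storey_q(pvec, lambda = lambda)
    for (k in seq_along(pair_idx)) {
      ij <- pair_idx[[k]]
      q_m[ij[1], ij[2]] <- q_m[ij[2], ij[1]] <- qv[k]
    }
  }
  structure(list(labels = pops, theta = theta_m, p = p_m, q = q_m,
                 untestable = untestable, n_perm = n_perm),
            class = "fst_matrix")
}
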