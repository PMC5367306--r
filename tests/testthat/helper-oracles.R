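# Independent oracles used to check the package's estimators against
# alternative computational routes.

# Exact Hardy-Weinberg probability-test p-value for a biallelic genotype
# table, by complete enumeration of all tables with the observed allele
# counts (heterozygote counts of matching parity).
hwe_enum_biallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    h * log(2) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
  }, 0)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- which(hs == nAB)
  sum(pr[pr <= pr[obs] * (1 + 1e-10)])
}

# Weir-Cockerham theta via the ANOVA (mean-squares) route: per allele,
# gene copies are 0/1 indicators analysed in a nested ANOVA
# (populations / individuals / copies); a, b, c follow from the mean
# squares. A deliberately different computational path from the package's
# frequency-based variance components.
wc_theta_anova_oracle <- function(gt, populations = NULL) {
  if (is.null(populations)) populations <- unique(gt$pop)
  keep <- gt$pop %in% populations
  a1m <- gt$allele1[keep, , drop = FALSE]
  a2m <- gt$allele2[keep, , drop = FALSE]
  pops <- gt$pop[keep]
  upop <- unique(pops)
  r <- length(upop)
  asum <- bsum <- csum <- 0
  for (l in seq_len(ncol(a1m))) {
    a1 <- a1m[, l]; a2 <- a2m[, l]
    ok <- !is.na(a1)
    nvec <- vapply(upop, function(p) sum(ok & pops == p), 0)
    if (any(nvec < 1) || mean(nvec) <= 1) next
    ntot <- sum(nvec)
    nc <- (ntot - sum(nvec^2) / ntot) / (r - 1)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) < 2) next
    for (u in alleles) {
      y1 <- as.numeric(a1[ok] == u)   # copy 1 indicator per individual
      y2 <- as.numeric(a2[ok] == u)
      pop_ok <- pops[ok]
      ybar_ind <- (y1 + y2) / 2
      ybar_pop <- vapply(upop, function(p) mean(ybar_ind[pop_ok == p]), 0)
      ybar <- sum(nvec * ybar_pop) / ntot
      ssg <- sum((y1 - ybar_ind)^2 + (y2 - ybar_ind)^2)
      ssi <- 2 * sum((ybar_ind - ybar_pop[match(pop_ok, upop)])^2)
      ssp <- 2 * sum(nvec * (ybar_pop - ybar)^2)
      msg <- ssg / ntot
      msi <- ssi / (ntot - r)
      msp <- ssp / (r - 1)
      asum <- asum + (msp - msi) / (2 * nc)
      bsum <- bsum + (msi - msg) / 2
      csum <- csum + msg
    }
  }
  asum / (asum + bsum + csum)
}

# Build a genotype table from per-population genotype count vectors at one
# biallelic locus: counts named AA, AB, BB.
gt_from_counts <- function(...) {
  pops <- list(...)
  a1 <- integer(0); a2 <- integer(0); lab <- character(0)
  for (i in seq_along(pops)) {
    cnt <- pops[[i]]
    a1 <- c(a1, rep(1L, cnt["AA"]), rep(1L, cnt["AB"]), rep(2L, cnt["BB"]))
    a2 <- c(a2, rep(1L, cnt["AA"]), rep(2L, cnt["AB"]), rep(2L, cnt["BB"]))
    lab <- c(lab, rep(paste0("pop", i), sum(cnt)))
  }
  genotype_table(matrix(a1, ncol = 1), matrix(a2, ncol = 1), pop = lab)
}

# Total absolute turning angle of a closed polyline (discrete curvature).
total_curvature <- function(points) {
  n <- nrow(points)
  nxt <- points[c(2:n, 1), ] - points
  ang <- atan2(nxt[, 2], nxt[, 1])
  d <- diff(c(ang, ang[1]))
  d <- (d + pi) %% (2 * pi) - pi
  sum(abs(d))
}

# A small wiggly test shape (closed, non-self-intersecting).
wiggly_shape <- function(n = 200, amp = 0.15) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- 1 + amp * cos(5 * th)
  cbind(r * cos(th), r * sin(th))
}

rot2 <- function(p, angle) {
  p %*% matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
}
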