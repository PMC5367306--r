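#' PCA of shape descriptors
#'
#' Columns are centered (not scaled) and the matrix decomposed by singular
#' values. Signs are fixed deterministically: the largest-magnitude loading
#' of each component is positive.
#'
#' @param coeff_matrix Specimens x descriptors numeric matrix.
#' @return List with `scores`, `loadings`, `varfrac` (non-increasing
#'   variance fractions) and `eigenvalues`.
#' @export
shape_pca <- function(coeff_matrix) {
  X <- as.matrix(coeff_matrix)
  if (nrow(X) < 2) stop("need at least 2 specimens")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10)
  if (rank == 0) {
    warning("constant matrix: no variable components")
    return(list(scores = matrix(0, nrow(X), 0),
                loadings = matrix(0, ncol(X), 0),
                varfrac = numeric(0), eigenvalues = numeric(0)))
  }
  d <- sv$d[seq_len(rank)]
  scores <- sv$u[, seq_len(rank), drop = FALSE] %*% diag(d, rank)
  loadings <- sv$v[, seq_len(rank), drop = FALSE]
  for (j in seq_len(rank)) {
    i0 <- which.max(abs(loadings[, j]))
    if (loadings[i0, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(rank))
  list(scores = scores, loadings = loadings,
       varfrac = d^2 / sum(sv$d^2), eigenvalues = d^2 / (nrow(X) - 1))
}

#' Number of components reaching a cumulative variance threshold
#'
#' @param variance_fractions Non-negative variance fractions.
#' @param threshold Target cumulative fraction in (0, 1].
#' @return Integer: smallest k with cumulative fraction >= threshold.
#' @export
retain_components <- function(variance_fractions, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (any(variance_fractions < 0)) stop("variance fractions must be >= 0")
  cs <- cumsum(variance_fractions) / sum(variance_fractions)
  as.integer(which(cs >= threshold - 1e-12)[1])
}

#' One-way MANOVA with Wilks' lambda
#'
#' `Lambda = det(E) / det(E + H)` with E and H the within- and
#' between-group cross-product matrices; the F approximation is Rao's,
#' which reduces exactly to the one-way ANOVA F when there is a single
#' response variable. Bartlett's chi-square approximation is available as
#' an alternative.
#'
#' @param scores Specimens x p response matrix.
#' @param groups Group labels, one per specimen.
#' @param approx `"rao"` (default) or `"bartlett"`.
#' @return List with `lambda`, `statistic`, `df` (pair), `p`, `approx`.
#' @export
manova_wilks <- function(scores, groups, approx = c("rao", "bartlett")) {
  approx <- match.arg(approx)
  X <- as.matrix(scores)
  groups <- factor(groups)
  n <- nrow(X); p <- ncol(X); g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 specimens")
  if (p >= n - g) stop("too many response variables for the group sizes; ",
                       "retain fewer components")
  grand <- colMeans(X)
  E <- matrix(0, p, p); H <- matrix(0, p, p)
  for (lev in levels(groups)) {
    xg <- X[groups == lev, , drop = FALSE]
    mg <- colMeans(xg)
    Cg <- sweep(xg, 2, mg)
    E <- E + crossprod(Cg)
    H <- H + nrow(xg) * tcrossprod(mg - grand)
  }
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0)
    stop("within-group cross-product matrix is singular; ",
         "retain fewer components")
  lambda <- detE / det(E + H)
  q <- g - 1          # hypothesis df
  v <- n - g          # error df
  if (approx == "rao") {
    s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
    df1 <- p * q
    w <- v + q - (p + q + 1) / 2
    df2 <- w * s - df1 / 2 + 1
    lam_s <- lambda^(1 / s)
    stat <- (1 - lam_s) / lam_s * df2 / df1
    pval <- stats::pf(stat, df1, df2, lower.tail = FALSE)
    list(lambda = lambda, statistic = stat, df = c(df1, df2), p = pval,
         approx = "rao")
  } else {
    stat <- -(v + q - (p + q + 1) / 2) * log(lambda)
    df1 <- p * q
    pval <- stats::pchisq(stat, df1, lower.tail = FALSE)
    list(lambda = lambda, statistic = stat, df = c(df1, NA), p = pval,
         approx = "bartlett")
  }
}

# thin-plate spline kernel U(r) = r^2 log(r^2), U(0) = 0
tps_kernel <- function(d2) {
  out <- d2 * log(d2)
  out[d2 == 0] <- 0
  out
}

# Solve the TPS interpolation system for one target dimension set.
# ref: k x 2, target: k x m. Returns list(W (k x m), A (3 x m), K).
tps_solve <- function(ref, target) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- tps_kernel(d2)
  P <- cbind(1, ref)
  Lmat <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(as.matrix(target), matrix(0, 3, ncol(target)))
  cond_ok <- rcond(Lmat)
  if (!is.finite(cond_ok) || cond_ok < 1e-14)
    stop("singular TPS system: reference landmarks are collinear or ",
         "degenerate")
  sol <- solve(Lmat, rhs)
  list(W = sol[seq_len(k), , drop = FALSE],
       A = sol[k + 1:3, , drop = FALSE], K = K)
}

# Evaluate a solved spline at new points (n x 2).
tps_eval <- function(ref, fit, pts) {
  d2 <- outer(rowSums(pts^2), rowSums(ref^2), `+`) -
    2 * pts %*% t(ref)
  d2[d2 < 0] <- 0
  U <- tps_kernel(d2)
  cbind(1, pts) %*% fit$A + U %*% fit$W
}

#' Thin-plate spline deformation grid between two landmark sets
#'
#' Fits the pair of interpolating thin-plate splines (kernel
#' `U(r) = r^2 log r^2`) mapping the reference landmarks exactly onto the
#' target landmarks, maps a square grid spanning the reference bounding
#' box through the spline, and reports the bending energy (the kernel
#' quadratic form, zero exactly for affine maps).
#'
#' @param ref_landmarks,target_landmarks Matching k x 2 matrices (k >= 3,
#'   non-collinear reference).
#' @param grid_n Grid nodes per side (default 20).
#' @return A `deformation_grid`: list with `source_grid`, `mapped_grid`
#'   (both grid_n^2 x 2), `bending_energy`, and `mapped_ref` (the images
#'   of the reference landmarks).
#' @export
tps_deformation <- function(ref_landmarks, target_landmarks, grid_n = 20) {
  ref <- as.matrix(ref_landmarks); tar <- as.matrix(target_landmarks)
  if (!identical(dim(ref), dim(tar)))
    stop("reference and target must share the landmark count")
  if (nrow(ref) < 3) stop("need at least 3 landmarks")
  fit <- tps_solve(ref, tar)
  be <- sum(diag(t(fit$W) %*% fit$K %*% fit$W))
  be <- max(be, 0)
  rx <- range(ref[, 1]); ry <- range(ref[, 2])
  gx <- seq(rx[1], rx[2], length.out = grid_n)
  gy <- seq(ry[1], ry[2], length.out = grid_n)
  src <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  mapped <- tps_eval(ref, fit, src)
  structure(list(source_grid = src, mapped_grid = mapped,
                 bending_energy = be,
                 mapped_ref = tps_eval(ref, fit, ref)),
            class = "deformation_grid")
}
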