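#' Construct an elliptic Fourier coefficient object
#'
#' Stores per-harmonic quadruples (a_n, b_n, c_n, d_n) of a closed-outline
#' Fourier decomposition plus the centre offsets (a0, c0). The harmonic
#' power is `P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`.
#'
#' @param harmonics n x 4 numeric matrix, columns a, b, c, d.
#' @param a0,c0 Centre offsets (mean x and y of the outline).
#' @return An `efa_coefficients` object.
#' @export
efa_coefficients_object <- function(harmonics, a0 = 0, c0 = 0) {
  harmonics <- as.matrix(harmonics)
  stopifnot(ncol(harmonics) == 4, nrow(harmonics) >= 1,
            all(is.finite(harmonics)))
  colnames(harmonics) <- c("a", "b", "c", "d")
  structure(list(harmonics = harmonics, a0 = a0, c0 = c0),
            class = "efa_coefficients")
}

#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes standard elliptic Fourier coefficients of the closed polygon
#' through the configuration's points. No first-ellipse normalization is
#' applied: configurations are expected to be aligned beforehand (e.g. by
#' [gpa_align()]). The curve parameter is either the cumulative chord
#' length (`param = "chord"`, constant speed along each polygon edge) or a
#' uniform per-point parameter (`param = "uniform"`, one unit per vertex,
#' appropriate for evenly sampled chains).
#'
#' @param config A `landmark_config`, `outline_shape`, or k x 2 matrix.
#' @param n_harmonics Number of harmonics (>= 1, < k/2).
#' @param param Parameterization of the outline; see Details.
#' @return An [efa_coefficients_object()].
#' @export
efa_coefficients <- function(config, n_harmonics = 15,
                             param = c("chord", "uniform")) {
  param <- match.arg(param)
  p <- if (inherits(config, "landmark_config") ||
           inherits(config, "outline_shape")) config$points else
    as.matrix(config)
  k <- nrow(p)
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  if (n_harmonics >= k / 2)
    stop("n_harmonics must be smaller than half the point count")
  # closed chain of edge vectors
  dx <- c(p[-1, 1], p[1, 1]) - p[, 1]
  dy <- c(p[-1, 2], p[1, 2]) - p[, 2]
  dt <- if (param == "chord") sqrt(dx^2 + dy^2) else rep(1, k)
  if (any(dt == 0)) stop("outline has zero-length segments")
  t2 <- cumsum(dt)           # t_i (end of segment i)
  bigT <- t2[length(t2)]
  if (bigT <= 0) stop("outline perimeter must be > 0")
  t1 <- c(0, t2[-length(t2)])  # t_{i-1}
  n <- seq_len(n_harmonics)
  w <- 2 * pi * outer(n, t2 / bigT)   # n x K phase at segment ends
  w0 <- 2 * pi * outer(n, t1 / bigT)  # n x K phase at segment starts
  dcos <- cos(w) - cos(w0)
  dsin <- sin(w) - sin(w0)
  fac <- bigT / (2 * pi^2 * n^2)
  an <- fac * as.vector(dcos %*% (dx / dt))
  bn <- fac * as.vector(dsin %*% (dx / dt))
  cn <- fac * as.vector(dcos %*% (dy / dt))
  dn <- fac * as.vector(dsin %*% (dy / dt))
  # centre offsets: average of the piecewise-linear x(t), y(t)
  xs <- p[, 1]; ys <- p[, 2]
  xe <- c(p[-1, 1], p[1, 1]); ye <- c(p[-1, 2], p[1, 2])
  a0 <- sum((xs + xe) / 2 * dt) / bigT
  c0 <- sum((ys + ye) / 2 * dt) / bigT
  efa_coefficients_object(cbind(an, bn, cn, dn), a0 = a0, c0 = c0)
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` equally spaced
#' parameter values over one period.
#'
#' @param coeffs An [efa_coefficients_object()].
#' @param n_points Number of points (>= 3).
#' @return An [outline_shape()].
#' @export
inverse_efa <- function(coeffs, n_points = 360) {
  if (n_points < 3) stop("n_points must be >= 3")
  H <- coeffs$harmonics
  n <- seq_len(nrow(H))
  theta <- 2 * pi * (seq_len(n_points) - 1) / n_points
  ang <- outer(theta, n)        # n_points x n_harmonics
  x <- coeffs$a0 + cos(ang) %*% H[, "a"] + sin(ang) %*% H[, "b"]
  y <- coeffs$c0 + cos(ang) %*% H[, "c"] + sin(ang) %*% H[, "d"]
  outline_shape(cbind(x, y))
}

#' Per-harmonic power of an elliptic Fourier decomposition
#'
#' @param coeffs An [efa_coefficients_object()].
#' @return Numeric vector `P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`.
#' @export
harmonic_power <- function(coeffs) {
  rowSums(coeffs$harmonics^2) / 2
}

#' Choose a harmonic count by cumulative power
#'
#' Returns the smallest harmonic count N whose mean cumulative power
#' fraction across specimens reaches `threshold`. With `exclude_first =
#' TRUE` (the default) harmonic 1 — which for aligned, ellipse-like
#' outlines holds nearly all raw power — is excluded from the baseline, so
#' the criterion acts on the residual (shape-detail) spectrum.
#'
#' @param coeff_set List of [efa_coefficients_object()]s sharing a maximal
#'   harmonic count.
#' @param threshold Target cumulative power fraction in (0, 1].
#' @param exclude_first Exclude harmonic 1 from the power baseline.
#' @return List with `n_selected` and `cumulative` (mean cumulative power
#'   fraction per harmonic).
#' @export
harmonic_power_calibration <- function(coeff_set, threshold = 0.98,
                                       exclude_first = TRUE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  H <- unique(vapply(coeff_set, function(cf) nrow(cf$harmonics), 1L))
  if (length(H) != 1) stop("all coefficient sets must share max harmonics")
  pw <- vapply(coeff_set, harmonic_power, numeric(H))
  pw <- matrix(pw, nrow = H)
  first <- if (exclude_first) 2L else 1L
  if (first > H) stop("need at least 2 harmonics to exclude the first")
  sub <- pw[first:H, , drop = FALSE]
  tot <- colSums(sub)
  tot[tot == 0] <- NA_real_
  cumfrac <- apply(sub, 2, function(z) cumsum(z)) / rep(tot, each = H - first + 1)
  meancum <- rowMeans(matrix(cumfrac, nrow = H - first + 1), na.rm = TRUE)
  hit <- which(meancum >= threshold - 1e-12)
  n_sel <- if (length(hit) == 0) H else (first - 1L) + hit[1]
  cumulative <- rep(NA_real_, H)
  cumulative[first:H] <- meancum
  list(n_selected = as.integer(n_sel), cumulative = cumulative)
}

#' Flatten elliptic Fourier coefficients to a descriptor matrix
#'
#' One row per specimen, columns ordered a1, b1, c1, d1, a2, ... — the
#' layout used for shape PCA (e.g. 15 harmonics give 60 descriptors).
#'
#' @param coeff_set List of [efa_coefficients_object()]s.
#' @param n_harmonics Number of harmonics to keep (default: all shared).
#' @return Numeric matrix specimens x (4 * n_harmonics).
#' @export
efa_descriptor_matrix <- function(coeff_set, n_harmonics = NULL) {
  H <- min(vapply(coeff_set, function(cf) nrow(cf$harmonics), 1L))
  if (is.null(n_harmonics)) n_harmonics <- H
  stopifnot(n_harmonics <= H)
  out <- t(vapply(coeff_set, function(cf)
    as.vector(t(cf$harmonics[seq_len(n_harmonics), , drop = FALSE])),
    numeric(4 * n_harmonics)))
  colnames(out) <- paste0(rep(c("a", "b", "c", "d"), n_harmonics),
                          rep(seq_len(n_harmonics), each = 4))
  out
}
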