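#' Generalized Procrustes superimposition
#'
#' Translates every configuration to a zero centroid, scales it to unit
#' centroid size, and rotates it to minimize the summed squared distance to
#' an iteratively re-estimated mean shape (full GPA with rotation, no
#' reflection). Iteration stops when the mean shape moves less than `tol`
#' or after `max_iter` rounds.
#'
#' @param configs List of `landmark_config` objects (or k x 2 matrices),
#'   all with the same landmark count.
#' @param tol Convergence tolerance on the mean-shape change.
#' @param max_iter Maximum number of alignment rounds.
#' @return List with `aligned` (list of `landmark_config`), `mean_shape`
#'   (k x 2 matrix, unit centroid size), `iterations`, `converged`.
#' @export
gpa_align <- function(configs, tol = 1e-8, max_iter = 100) {
  pts <- lapply(configs, function(cf)
    if (inherits(cf, "landmark_config")) cf$points else as.matrix(cf))
  k <- unique(vapply(pts, nrow, 1L))
  if (length(k) != 1) stop("all configurations must share the landmark count")
  norm1 <- lapply(pts, function(p) {
    p <- scale(p, scale = FALSE)
    cs <- sqrt(sum(p^2))
    if (cs <= 0) stop("degenerate configuration: all points identical")
    p / cs
  })
  rotate_to <- function(p, m) {
    # rotation (det +1) minimizing ||p R - m||
    s <- svd(crossprod(p, m))
    r <- s$u %*% diag(c(1, det(s$u %*% t(s$v)))) %*% t(s$v)
    p %*% r
  }
  mean_sh <- norm1[[1]]
  aligned <- norm1
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    aligned <- lapply(norm1, rotate_to, m = mean_sh)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_sh)^2))
    mean_sh <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  aligned <- lapply(norm1, rotate_to, m = mean_sh)
  list(aligned = lapply(aligned, landmark_config),
       mean_shape = mean_sh, iterations = it, converged = converged)
}
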