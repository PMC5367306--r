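#' Construct an outline shape
#'
#' An ordered chain of (x, y) coordinates describing a closed outline; the
#' last point connects implicitly back to the first. Image-derived outlines
#' use pixel coordinates (origin top-left, x rightward, y downward).
#'
#' @param points Two-column numeric matrix of (x, y) coordinates.
#' @return An `outline_shape` object.
#' @export
outline_shape <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 3)
  if (nrow(points) > 1) {
    dup <- rowSums(abs(points - points[c(nrow(points), seq_len(nrow(points) - 1)), ])) == 0
    dup[1] <- FALSE
    if (any(dup)) points <- points[!dup, , drop = FALSE]
  }
  if (all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3) stop("outline needs at least 3 distinct points")
  colnames(points) <- c("x", "y")
  structure(list(points = points), class = "outline_shape")
}

# Signed (shoelace) area; positive = counterclockwise in standard x/y axes.
signed_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

outline_perimeter <- function(points) {
  d <- points[c(seq_len(nrow(points))[-1], 1), ] - points
  sum(sqrt(rowSums(d^2)))
}

#' Normalize outline orientation and starting point
#'
#' Orientation is made counterclockwise (positive shoelace area) and the
#' chain is rotated so it starts at the point of maximal x after centering
#' (ties broken by minimal y), making chains from different images
#' comparable.
#'
#' @param outline An [outline_shape()].
#' @return An [outline_shape()].
#' @export
normalize_outline <- function(outline) {
  p <- outline$points
  if (signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  cent <- colMeans(p)
  xc <- p[, 1] - cent[1]; yc <- p[, 2] - cent[2]
  start <- order(-xc, yc)[1]
  if (start > 1) p <- p[c(start:nrow(p), 1:(start - 1)), , drop = FALSE]
  outline_shape(p)
}

# 8-connected component count by vectorized flood fill. The mask is padded
# with a background border so neighbour index arithmetic never wraps rows
# into adjacent columns.
count_components <- function(mask) {
  if (sum(mask) == 0) return(0L)
  h <- nrow(mask) + 2L; w <- ncol(mask) + 2L
  m <- matrix(FALSE, h, w)
  m[2:(h - 1L), 2:(w - 1L)] <- mask
  lab <- matrix(FALSE, h, w)
  off <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  comp <- 0L
  todo <- which(m & !lab)
  while (length(todo) > 0) {
    comp <- comp + 1L
    frontier <- todo[1]
    lab[frontier] <- TRUE
    while (length(frontier) > 0) {
      nb <- unique(as.vector(outer(frontier, off, `+`)))
      nb <- nb[m[nb] & !lab[nb]]
      lab[nb] <- TRUE
      frontier <- nb
    }
    todo <- which(m & !lab)
  }
  comp
}

#' Trace the boundary of a binary mask
#'
#' Moore-neighbour (8-connected) boundary tracing of the single foreground
#' component of a binary mask, returning an ordered closed pixel chain.
#' Coordinates are pixel units: x = column, y = row. By default the chain
#' is normalized with [normalize_outline()].
#'
#' @param mask Logical (or 0/1) matrix; `TRUE` = foreground.
#' @param normalize Normalize orientation and start point (default `TRUE`).
#' @return An [outline_shape()].
#' @export
trace_outline <- function(mask, normalize = TRUE) {
  mask <- mask > 0
  if (sum(mask) < 3) stop("foreground area must be at least 3 pixels")
  ncomp <- count_components(mask)
  if (ncomp != 1)
    stop(sprintf("mask must contain exactly 1 foreground component, found %d",
                 ncomp))
  h <- nrow(mask); w <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]
  # start: first foreground pixel in row-major scan; entered from the left
  start <- NULL
  for (r in seq_len(h)) {
    cs <- which(mask[r, ])
    if (length(cs) > 0) { start <- c(r, cs[1]); break }
  }
  # Moore neighbourhood in clockwise order beginning west
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  chain_r <- integer(0); chain_c <- integer(0)
  cur <- start
  backtrack <- 1L  # came from the west
  first_dir <- NA_integer_
  repeat {
    chain_r <- c(chain_r, cur[1]); chain_c <- c(chain_c, cur[2])
    found <- FALSE
    d <- backtrack
    for (step in seq_len(8)) {
      d <- (d %% 8L) + 1L
      rr <- cur[1] + dr[d]; cc <- cur[2] + dc[d]
      if (at(rr, cc)) {
        if (length(chain_r) == 1L) first_dir <- d
        # next backtrack: direction pointing back towards current pixel,
        # advanced so the scan resumes just past the previous background
        backtrack <- ((d + 3L) %% 8L) + 1L
        cur <- c(rr, cc)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel cluster fully traced
    if (cur[1] == start[1] && cur[2] == start[2]) {
      # Jacob's criterion: stop when re-entering the start the same way
      d2 <- backtrack
      nxt <- NA_integer_
      for (step in seq_len(8)) {
        d2 <- (d2 %% 8L) + 1L
        rr <- cur[1] + dr[d2]; cc <- cur[2] + dc[d2]
        if (at(rr, cc)) { nxt <- d2; break }
      }
      if (is.na(first_dir) || is.na(nxt) || nxt == first_dir) break
    }
    if (length(chain_r) > 4L * (h * w)) stop("boundary tracing failed")
  }
  out <- outline_shape(cbind(x = chain_c, y = chain_r))
  if (normalize) normalize_outline(out) else out
}

#' Smooth an outline by cyclic moving average
#'
#' Each iteration replaces point i by the mean of points i-1, i, i+1
#' (cyclically), damping pixel-level digitization noise while preserving
#' the point count.
#'
#' @param outline An [outline_shape()].
#' @param n_iters Number of smoothing iterations (>= 0).
#' @return An [outline_shape()].
#' @export
smooth_outline <- function(outline, n_iters = 10) {
  stopifnot(n_iters >= 0)
  p <- outline$points
  n <- nrow(p)
  if (n_iters > 0) for (it in seq_len(n_iters)) {
    prev <- p[c(n, seq_len(n - 1)), , drop = FALSE]
    nxt <- p[c(seq_len(n)[-1], 1), , drop = FALSE]
    p <- (prev + p + nxt) / 3
  }
  structure(list(points = p), class = "outline_shape")
}

#' Resample an outline at equal arc-length spacing
#'
#' Places `k` pseudo-landmarks at equal arc-length intervals along the
#' closed polyline, starting from the outline's first point.
#'
#' @param outline An [outline_shape()].
#' @param k Number of pseudo-landmarks (default 1000).
#' @return A `landmark_config`: list with `points` (k x 2) and
#'   `centroid_size`.
#' @export
resample_equal <- function(outline, k = 1000) {
  if (k < 3) stop("k must be >= 3")
  p <- outline$points
  n <- nrow(p)
  closed <- rbind(p, p[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                       closed[-(n + 1), , drop = FALSE])^2))
  per <- sum(seg)
  if (per <= 0) stop("outline perimeter must be > 0")
  s <- c(0, cumsum(seg))
  target <- (seq_len(k) - 1) * per / k
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (target - s[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  pts <- closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
  landmark_config(pts)
}

#' Construct a landmark configuration
#'
#' @param points k x 2 coordinate matrix.
#' @return A `landmark_config` with centroid size attached.
#' @export
landmark_config <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 3)
  cs <- sqrt(sum(scale(points, scale = FALSE)^2))
  structure(list(points = points, centroid_size = cs),
            class = "landmark_config")
}

#' Rasterize a closed outline to a binary mask
#'
#' Even-odd (crossing-number) scanline fill on an integer pixel grid; no
#' anti-aliasing, so the mask is strictly binary. Pixel (r, c) is filled
#' when its centre (x = c, y = r) lies inside the polygon.
#'
#' @param outline An [outline_shape()] in pixel coordinates.
#' @param size `(height, width)` of the raster.
#' @return Logical matrix.
#' @export
rasterize_outline <- function(outline, size) {
  h <- size[1]; w <- size[2]
  p <- outline$points
  n <- nrow(p)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  mask <- matrix(FALSE, h, w)
  rows_all <- integer(0); xs_all <- numeric(0)
  for (e in seq_len(n)) {
    ylo <- min(y1[e], y2[e]); yhi <- max(y1[e], y2[e])
    if (ylo == yhi) next
    rr <- seq.int(ceiling(ylo), floor(yhi))
    # half-open rule: include lower endpoint, exclude upper, so shared
    # vertices are counted once
    rr <- rr[rr >= ylo & rr < yhi & rr >= 1 & rr <= h]
    if (length(rr) == 0) next
    xc <- x1[e] + (rr - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
    rows_all <- c(rows_all, rr); xs_all <- c(xs_all, xc)
  }
  if (length(rows_all) == 0) return(mask)
  for (r in unique(rows_all)) {
    xs <- sort(xs_all[rows_all == r])
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c1 <- ceiling(xs[i]); c2 <- floor(xs[i + 1])
      if (c2 >= c1) mask[r, max(1, c1):min(w, c2)] <- TRUE
    }
  }
  mask
}
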