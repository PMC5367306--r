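test_that("Moore tracing recovers the boundary of simple masks", {
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
  o <- trace_outline(m)
  expect_equal(nrow(o$points), 36)
  # mirror image: chains are mirror images after orientation normalization
  o2 <- trace_outline(m[, 14:1])
  p <- o$points; p2 <- o2$points
  p2_mirror <- cbind(15 - p2[, 1], p2[, 2])
  o2n <- normalize_outline(outline_shape(p2_mirror))
  expect_equal(o2n$points, o$points)
  # error cases
  expect_error(trace_outline(matrix(c(TRUE, rep(FALSE, 8)), 3, 3)),
               "at least 3")
  m3 <- m; m3[1, 1] <- TRUE; m3[1, 2] <- TRUE; m3[2, 1] <- TRUE
  expect_error(trace_outline(m3), "found 2")
})

test_that("smoothing is the identity at 0 iterations, isotropic on circles, and reduces curvature", {
  w <- outline_shape(wiggly_shape())
  expect_equal(smooth_outline(w, 0)$points, w$points)
  th <- 2 * pi * (0:99) / 100
  circ <- outline_shape(cbind(cos(th), sin(th)))
  sm <- smooth_outline(circ, 1)
  radii <- sqrt(rowSums(sm$points^2))
  expect_lt(diff(range(radii)), 1e-9)
  expect_equal(radii[1], (1 + 2 * cos(2 * pi / 100)) / 3, tolerance = 1e-9)
  # high-frequency zig-zag: total curvature strictly decreases
  zig <- wiggly_shape(120, amp = 0.3)
  zig <- zig + 0.05 * cbind(cos(30 * atan2(zig[, 2], zig[, 1])), 0)
  k0 <- total_curvature(zig)
  k1 <- total_curvature(smooth_outline(outline_shape(zig), 3)$points)
  expect_lt(k1, k0)
})

test_that("equal-arc resampling places landmarks exactly on simple geometry", {
  sq <- outline_shape(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  r8 <- resample_equal(sq, 8)
  expect_equal(r8$points,
               cbind(c(0, 0.5, 1, 1, 1, 0.5, 0, 0),
                     c(0, 0, 0, 0.5, 1, 1, 1, 0.5)),
               ignore_attr = TRUE, tolerance = 1e-12)
  # identity on an equispaced circle when k equals the input size
  th <- 2 * pi * (0:199) / 200
  circ <- outline_shape(cbind(cos(th), sin(th)))
  rc <- resample_equal(circ, 200)
  expect_equal(rc$points, circ$points, ignore_attr = TRUE,
               tolerance = 1e-9)
  # perimeter preserved exactly when refinement lands on the vertices
  # (uniform chords, k a multiple of the input size) and never inflated
  # otherwise (resampled points stay on the polyline; corners may be cut)
  circ150 <- outline_shape(cbind(cos(2 * pi * (0:149) / 150),
                                 sin(2 * pi * (0:149) / 150)))
  rc4 <- resample_equal(circ150, 600)
  per <- function(p) sum(sqrt(rowSums((p[c(2:nrow(p), 1), ] - p)^2)))
  expect_lt(abs(per(circ150$points) - per(rc4$points)), 1e-9)
  w <- outline_shape(wiggly_shape(150))
  rw <- resample_equal(w, 600)
  expect_lte(per(rw$points), per(w$points) + 1e-12)
  expect_gt(per(rw$points), 0.99 * per(w$points))
  expect_error(resample_equal(sq, 2), "k must")
})

test_that("Procrustes alignment is invariant to similarity transforms and idempotent", {
  S <- wiggly_shape()
  configs <- list(S, rot2(S, 37 * pi / 180),
                  sweep(S, 2, c(5, -2), "+"), 3 * S)
  g <- gpa_align(configs)
  for (i in 2:4)
    expect_lt(max(abs(g$aligned[[i]]$points - g$aligned[[1]]$points)),
              1e-7)
  m <- scale(S, scale = FALSE); m <- m / sqrt(sum(m^2))
  expect_lt(max(abs(abs(g$mean_shape) - abs(m))), 1e-6)
  # idempotence
  g2 <- gpa_align(lapply(g$aligned, function(cf) cf$points))
  for (i in 1:4)
    expect_lt(max(abs(g2$aligned[[i]]$points - g$aligned[[i]]$points)),
              1e-9)
  # centroid and size constraints
  for (cf in g$aligned) {
    expect_lt(max(abs(colMeans(cf$points))), 1e-9)
    expect_equal(sqrt(sum(cf$points^2)), 1, tolerance = 1e-9)
  }
  expect_error(gpa_align(list(S, matrix(1, 200, 2))), "degenerate")
})

test_that("two-shape alignment residual equals the closed-form Procrustes distance", {
  set.seed(5)
  S <- wiggly_shape()
  S2 <- S + matrix(stats::rnorm(400, 0, 0.05), ncol = 2)
  c1 <- scale(S, scale = FALSE); c1 <- c1 / sqrt(sum(c1^2))
  c2 <- scale(S2, scale = FALSE); c2 <- c2 / sqrt(sum(c2^2))
  M <- crossprod(c2, c1)
  sv <- svd(M)
  s <- sv$d[1] + sv$d[2] * sign(det(M))
  d_closed <- sqrt(max(0, 2 - 2 * s))
  g <- gpa_align(list(S, S2))
  d_gpa <- sqrt(sum((g$aligned[[1]]$points - g$aligned[[2]]$points)^2))
  expect_equal(d_gpa, d_closed, tolerance = 1e-8)
})

test_that("EFA of an ellipse recovers the analytic harmonic-1 coefficients", {
  th <- 2 * pi * (0:4095) / 4096
  ell <- outline_shape(cbind(2 * cos(th), sin(th)))
  cf <- efa_coefficients(ell, 15, param = "uniform")
  expect_equal(unname(cf$harmonics[1, ]), c(2, 0, 0, 1), tolerance = 1e-6)
  expect_lt(sum(harmonic_power(cf)[-1]), 1e-10)
  # circle: P1 = r^2 up to the exact polygon-interpolation attenuation
  # sinc^4(pi/N) (linear interpolation scales harmonic n by sinc^2(pi n/N))
  circ <- outline_shape(cbind(3 * cos(th), 3 * sin(th)))
  pw <- harmonic_power(efa_coefficients(circ, 8))
  att <- (sin(pi / 4096) / (pi / 4096))^4
  expect_equal(pw[1], 9 * att, tolerance = 1e-9)
  expect_lt(sum(pw[-1]), 1e-9)
  expect_error(efa_coefficients(ell, 3000), "half the point count")
})

test_that("EFA round trips through reconstruction and scales linearly", {
  set.seed(9)
  H <- cbind(c(1.5, stats::rnorm(5, 0, 0.1) * 0.5^(1:5)),
             c(0.1, stats::rnorm(5, 0, 0.1) * 0.5^(1:5)),
             c(-0.2, stats::rnorm(5, 0, 0.1) * 0.5^(1:5)),
             c(1.1, stats::rnorm(5, 0, 0.1) * 0.5^(1:5)))
  cf <- efa_coefficients_object(H, a0 = 0.3, c0 = -0.7)
  rec <- inverse_efa(cf, 4096)
  cf2 <- efa_coefficients(rec, 6, param = "uniform")
  expect_lt(max(abs(cf2$harmonics - cf$harmonics)), 1e-6)
  expect_equal(cf2$a0, 0.3, tolerance = 1e-9)
  expect_equal(cf2$c0, -0.7, tolerance = 1e-9)
  # doubling the coefficients scales the reconstruction by 2
  cf_dbl <- efa_coefficients_object(2 * H, a0 = 0.6, c0 = -1.4)
  rec2 <- inverse_efa(cf_dbl, 128)
  expect_equal(rec2$points, 2 * inverse_efa(cf, 128)$points,
               tolerance = 1e-12)
  # zero coefficients beyond harmonic 1: an exact ellipse
  cf_e <- efa_coefficients_object(rbind(c(2, 0, 0, 1), matrix(0, 3, 4)))
  pts <- inverse_efa(cf_e, 256)$points
  expect_lt(max(abs((pts[, 1] / 2)^2 + pts[, 2]^2 - 1)), 1e-9)
})

test_that("total harmonic power is invariant to the chain starting point", {
  w <- wiggly_shape(400)
  cfg <- resample_equal(outline_shape(w), 400)
  cf1 <- efa_coefficients(cfg, 10)
  shifted <- cfg$points[c(137:400, 1:136), ]
  cf2 <- efa_coefficients(shifted, 10)
  expect_equal(sum(harmonic_power(cf1)), sum(harmonic_power(cf2)),
               tolerance = 1e-9)
})

test_that("harmonic-power calibration picks the documented harmonic count", {
  ell <- efa_coefficients_object(rbind(c(2, 0, 0, 1), matrix(0, 2, 4)))
  expect_equal(harmonic_power_calibration(list(ell),
                                          exclude_first = FALSE)$n_selected,
               1L)
  # powers (100, 49, 1): excluding harmonic 1, 49/50 = 0.98 at N = 2
  hs <- efa_coefficients_object(rbind(c(sqrt(200), 0, 0, 0),
                                      c(sqrt(98), 0, 0, 0),
                                      c(sqrt(2), 0, 0, 0)))
  cal <- harmonic_power_calibration(list(hs), threshold = 0.98,
                                    exclude_first = TRUE)
  expect_equal(cal$n_selected, 2L)
  cal_all <- harmonic_power_calibration(list(hs), threshold = 1,
                                        exclude_first = FALSE)
  expect_equal(cal_all$n_selected, 3L)
  expect_error(harmonic_power_calibration(list(hs), threshold = 1.2),
               "threshold")
})

test_that("rasterizing then tracing a synthetic outline recovers its shape", {
  th <- 2 * pi * (0:999) / 1000
  shape <- outline_shape(cbind(256 + 150 * cos(th) + 30 * cos(2 * th),
                               256 + 180 * sin(th) - 20 * sin(3 * th)))
  mask <- rasterize_outline(shape, c(512, 512))
  tr <- trace_outline(mask)
  idx <- seq(1, nrow(tr$points), by = 7)
  d <- vapply(idx, function(i)
    min(sqrt(colSums((t(shape$points) - tr$points[i, ])^2))), 0)
  expect_lt(mean(d), 1)
})
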