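#' Construct a grey image with a shell mask
#'
#' @param pixels Integer matrix with values 0-255.
#' @param mask Logical matrix of the same dimensions marking shell pixels.
#' @return A `grey_image` object.
#' @export
grey_image <- function(pixels, mask) {
  pixels <- as.matrix(pixels); mask <- as.matrix(mask) > 0
  if (!identical(dim(pixels), dim(mask)))
    stop("pixel and mask dimensions must match")
  if (any(pixels < 0 | pixels > 255)) stop("grey values must be in 0..255")
  if (!any(mask)) stop("mask must contain at least one shell pixel")
  structure(list(pixels = pixels, mask = mask), class = "grey_image")
}

#' Convert an RGB image to grey by channel averaging
#'
#' Per-pixel arithmetic mean of the three channels, `(R + G + B) / 3`,
#' rounded half-up to an integer in 0-255.
#'
#' @param rgb Height x width x 3 integer array (0-255).
#' @param mask Optional logical shell mask; defaults to the whole image.
#' @return A [grey_image()].
#' @export
rgb_to_grey <- function(rgb, mask = NULL) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be a height x width x 3 array")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  g <- matrix(floor((rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3 + 0.5), h, w)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  grey_image(g, mask)
}

#' Shell colour index
#'
#' Pigmented pixels are shell pixels with grey value at or below
#' `threshold` (inclusive). The index is
#' `sqrt(mean pigment grey x pigmented fraction of the shell area)`; an
#' empty pigmented set gives index 0 with undefined mean grey.
#'
#' @param grey A [grey_image()].
#' @param threshold Upper grey bound of the pigment window (default 110).
#' @param inclusive Include pixels exactly at the threshold (default TRUE).
#' @return List with `mean_pigment_grey`, `pigment_fraction`,
#'   `colour_index`.
#' @export
colour_index <- function(grey, threshold = 110, inclusive = TRUE) {
  stopifnot(inherits(grey, "grey_image"))
  shell <- grey$pixels[grey$mask]
  pig <- if (inclusive) shell[shell <= threshold] else shell[shell < threshold]
  frac <- length(pig) / length(shell)
  if (length(pig) == 0) {
    return(list(mean_pigment_grey = NA_real_, pigment_fraction = 0,
                colour_index = 0))
  }
  mg <- mean(pig)
  list(mean_pigment_grey = mg, pigment_fraction = frac,
       colour_index = sqrt(mg * frac))
}

#' One-way fixed-effects ANOVA
#'
#' Classical model-I ANOVA F test with `(k - 1, n - k)` degrees of freedom
#' and an upper-tail p-value.
#'
#' @param values Numeric response.
#' @param groups Group labels, one per value.
#' @return List with `statistic` (F), `df` (pair), `p`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  fstat <- tab[["F value"]][1]
  msw <- tab[["Mean Sq"]][2]
  if (msw <= 1e-12 * max(tab[["Mean Sq"]][1], 1)) fstat <- Inf
  if (!is.finite(fstat)) {
    warning("zero within-group variance: F is unbounded, p reported as 0")
    return(list(statistic = Inf, df = c(tab[["Df"]][1], tab[["Df"]][2]),
                p = 0))
  }
  list(statistic = fstat, df = c(tab[["Df"]][1], tab[["Df"]][2]),
       p = tab[["Pr(>F)"]][1])
}
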