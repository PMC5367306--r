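#' Write / read a plain-text PGM (P2) grey image
#'
#' @param pixels Integer matrix 0-255 (rows = image rows).
#' @param path Output path.
#' @return `path` invisibly (writer); integer matrix (reader).
#' @export
write_pgm <- function(pixels, path) {
  pixels <- as.matrix(pixels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), "255"), con)
  apply(pixels, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Read a binary mask image (PNG or PGM)
#'
#' Foreground is taken as dark pixels (value below half range), matching
#' the convention of dark masks on a white background.
#'
#' @param path Path to a `.png` or `.pgm` file.
#' @param invert Set `TRUE` when the foreground is light instead.
#' @return Logical matrix.
#' @export
read_mask <- function(path, invert = FALSE) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "pgm") read_pgm(path) / 255 else {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3], c(1, 2), mean)
    img
  }
  if (invert) px > 0.5 else px < 0.5
}

#' Read an RGB PNG image as a 0-255 integer array
#'
#' @param path PNG path.
#' @return Height x width x 3 integer array.
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  round(img[, , 1:3] * 255)
}

#' Write / read outline coordinates as CSV (one x,y row per point)
#'
#' @param outline An [outline_shape()].
#' @param path CSV path.
#' @return `path` invisibly (writer); an [outline_shape()] (reader).
#' @export
write_outline_csv <- function(outline, path) {
  utils::write.csv(as.data.frame(outline$points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path) {
  df <- utils::read.csv(path)
  outline_shape(as.matrix(df[, c("x", "y")]))
}

#' Percentages of the sequencing read-accounting arithmetic
#'
#' Recomputes, from raw read counts, the percentage retained after
#' quality/length filtering, the percentage of retained reads removed by
#' the subsequent filtering criterion, and the percentage of retained
#' reads flagged as PCR duplicates.
#'
#' @param total_reads Raw paired-end reads.
#' @param retained_reads Reads surviving quality and length filtering.
#' @param removed_reads Retained reads removed by subsequent criteria.
#' @param duplicate_reads PCR duplicate reads among those removed.
#' @return Named list of percentages (`pct_retained`,
#'   `pct_removed_of_retained`, `pct_duplicates_of_retained`).
#' @export
read_accounting <- function(total_reads, retained_reads, removed_reads,
                            duplicate_reads) {
  stopifnot(total_reads > 0, retained_reads > 0)
  list(pct_retained = 100 * retained_reads / total_reads,
       pct_removed_of_retained = 100 * removed_reads / retained_reads,
       pct_duplicates_of_retained = 100 * duplicate_reads / retained_reads)
}
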