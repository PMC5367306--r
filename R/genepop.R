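#' Read a Genepop genotype file
#'
#' Supports the common dialect: a title line; locus names one per line or
#' comma-separated; `Pop` separators (any capitalization); individual
#' lines `id , 0101 0102 ...` with 2- or 3-digit allele coding; `00`/`000`
#' allele codes mark missing genotypes. Each population is named after the
#' label of its last individual.
#'
#' @param path File path.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found")
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L == 0) stop("no locus names found")
  ids <- character(0); pop_id <- integer(0)
  geno <- list()
  cur_pop <- 0L
  width <- NA_integer_
  for (li in seq(first_pop, length(lines))) {
    if (is_pop[li]) { cur_pop <- cur_pop + 1L; next }
    parts <- strsplit(lines[li], ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d: expected 'id , genotypes'", li))
    id <- trimws(parts[1])
    gstr <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                     "\\s+")[[1]]
    gstr <- gstr[nzchar(gstr)]
    if (length(gstr) != L)
      stop(sprintf("line %d: %d genotypes for %d loci", li,
                   length(gstr), L))
    wl <- unique(nchar(gstr))
    if (length(wl) != 1 || !(wl %in% c(4L, 6L)))
      stop(sprintf("line %d: inconsistent allele code width", li))
    w <- wl / 2L
    if (is.na(width)) width <- w
    if (w != width)
      stop(sprintf("line %d: mixed allele code widths", li))
    a1 <- as.integer(substr(gstr, 1, width))
    a2 <- as.integer(substr(gstr, width + 1, 2 * width))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, id)
    pop_id <- c(pop_id, cur_pop)
    geno[[length(geno) + 1L]] <- rbind(a1, a2)
  }
  n <- length(ids)
  if (n == 0) stop("no individuals found")
  A1 <- t(vapply(geno, function(g) g[1, ], integer(L)))
  A2 <- t(vapply(geno, function(g) g[2, ], integer(L)))
  if (L == 1) { A1 <- matrix(A1, ncol = 1); A2 <- matrix(A2, ncol = 1) }
  # population name = id of its last individual
  pop_names <- vapply(seq_len(max(pop_id)), function(p)
    ids[max(which(pop_id == p))], "")
  genotype_table(A1, A2, pop = pop_names[pop_id], ids = ids,
                 loci = data.frame(id = loci, type = "unknown",
                                   stringsAsFactors = FALSE))
}

#' Write a genotype table as a Genepop file
#'
#' Allele codes are zero-padded to 2 digits (3 when any code exceeds 99);
#' missing genotypes become `0000`/`000000`. Population membership is
#' encoded with `Pop` separators and each population's last individual is
#' its label, so [read_genepop()] round-trips the table.
#'
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "shellpop export") {
  width <- if (max(c(gt$allele1, gt$allele2), na.rm = TRUE) > 99) 3L else 2L
  fmt <- paste0("%0", width, "d")
  lines <- c(title, gt$loci$id)
  pops <- unique(gt$pop)
  for (p in pops) {
    lines <- c(lines, "Pop")
    for (i in which(gt$pop == p)) {
      a1 <- gt$allele1[i, ]; a2 <- gt$allele2[i, ]
      gs <- paste0(sprintf(fmt, ifelse(is.na(a1), 0L, a1)),
                   sprintf(fmt, ifelse(is.na(a2), 0L, a2)))
      # encode the population label in its last individual's id
      id <- if (i == max(which(gt$pop == p))) p else gt$ids[i]
      lines <- c(lines, paste(id, ",", paste(gs, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
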