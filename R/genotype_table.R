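#' Construct a genotype table
#'
#' The central genotype container: diploid, unordered allele pairs per
#' individual per locus, with population labels and an `NA` missing sentinel.
#' Alleles are positive integer codes (microsatellites typically use allele
#' sizes or 1..k; SNPs use 1/2). Missingness is all-or-nothing per genotype:
#' either both allele slots are `NA` or neither is.
#'
#' @param allele1,allele2 Integer matrices (individuals x loci) of allele
#'   codes; `NA` marks a missing genotype (must agree between the two).
#' @param pop Character or factor of population labels, one per individual.
#' @param ids Character individual identifiers; defaults to `ind_1..n`.
#' @param loci Data frame with columns `id` and `type` (`"microsat"` or
#'   `"snp"`); defaults to `loc_1..L` of type `"snp"`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(allele1, allele2, pop, ids = NULL, loci = NULL) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  stopifnot(identical(dim(allele1), dim(allele2)))
  n <- nrow(allele1); L <- ncol(allele1)
  if (length(pop) != n) stop("pop labels must match the number of individuals")
  if (is.null(ids)) ids <- paste0("ind_", seq_len(n))
  if (length(ids) != n) stop("ids must match the number of individuals")
  if (is.null(loci)) loci <- data.frame(id = paste0("loc_", seq_len(L)),
                                        type = "snp",
                                        stringsAsFactors = FALSE)
  if (nrow(loci) != L) stop("loci records must match the number of loci")
  if (!all(c("id", "type") %in% names(loci)))
    stop("loci must have columns 'id' and 'type'")
  m1 <- is.na(allele1); m2 <- is.na(allele2)
  if (any(m1 != m2)) stop("half-called genotypes are not allowed")
  # store unordered: smaller allele first, so equality checks are canonical
  swap <- !m1 & allele2 < allele1
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  structure(list(allele1 = allele1, allele2 = allele2,
                 pop = as.character(pop), ids = as.character(ids),
                 loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci, %d populations\n",
              nrow(x$allele1), ncol(x$allele1), length(unique(x$pop))))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(x$allele1))))
  invisible(x)
}

n_ind <- function(gt) nrow(gt$allele1)
n_loci <- function(gt) ncol(gt$allele1)

#' Subset a genotype table
#'
#' @param gt A `genotype_table`.
#' @param individuals Integer or logical index over individuals (optional).
#' @param loci Integer or logical index over loci (optional).
#' @return A `genotype_table`.
#' @export
subset_genotypes <- function(gt, individuals = NULL, loci = NULL) {
  if (is.null(individuals)) individuals <- seq_len(n_ind(gt))
  if (is.null(loci)) loci <- seq_len(n_loci(gt))
  genotype_table(gt$allele1[individuals, loci, drop = FALSE],
                 gt$allele2[individuals, loci, drop = FALSE],
                 gt$pop[individuals], gt$ids[individuals],
                 gt$loci[loci, , drop = FALSE])
}

# Genotype counts for one locus in one set of individuals, as a symmetric
# upper-triangle table keyed by allele pair. Returns a data.frame
# (a1 <= a2, count), missing genotypes dropped.
genotype_counts <- function(gt, locus, individuals = NULL) {
  if (is.null(individuals)) individuals <- seq_len(n_ind(gt))
  a1 <- gt$allele1[individuals, locus]; a2 <- gt$allele2[individuals, locus]
  keep <- !is.na(a1)
  if (!any(keep)) return(data.frame(a1 = integer(), a2 = integer(),
                                    count = integer()))
  key <- paste(a1[keep], a2[keep])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  data.frame(a1 = as.integer(parts[, 1]), a2 = as.integer(parts[, 2]),
             count = as.integer(tab))
}
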