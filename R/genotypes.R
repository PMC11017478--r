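#' Diploid multi-allelic genotype table
#'
#' Container for co-dominant diploid genotypes (e.g. microsatellites) across
#' populations. Genotypes are stored as an `n x L x 2` integer array of
#' allele codes; a missing genotype has both gene copies `NA`.
#'
#' @param ind Character vector of individual identifiers.
#' @param pop Factor or character vector of population labels, one per
#'   individual.
#' @param alleles Integer array `n x L x 2` (individuals x loci x gene copy).
#'   The locus dimension must carry names.
#' @return A `genotype_table` object.
#' @examples
#' a <- array(c(1L, 1L, 1L, 2L), dim = c(1, 2, 2),
#'            dimnames = list(NULL, c("locA", "locB"), NULL))
#' genotype_table("fish1", "cave1", a)
#' @export
genotype_table <- function(ind, pop, alleles) {
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("alleles must be an n x L x 2 array")
  n <- dim(alleles)[1]
  if (length(ind) != n || length(pop) != n)
    stop("ind and pop must have one entry per row of alleles")
  if (is.null(dimnames(alleles)[[2]]))
    stop("locus dimension of alleles must be named")
  half_missing <- xor(is.na(alleles[, , 1, drop = FALSE]),
                      is.na(alleles[, , 2, drop = FALSE]))
  if (any(half_missing))
    stop("a genotype must have both gene copies present or both missing")
  pop <- factor(pop)
  if (any(table(pop) == 0)) pop <- droplevels(pop)
  out <- list(ind = as.character(ind), pop = pop,
              alleles = alleles, loci = dimnames(alleles)[[2]])
  class(out) <- "genotype_table"
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ind), "individuals,",
      length(x$loci), "loci,", nlevels(x$pop), "populations\n")
  invisible(x)
}

#' Number of individuals in a genotype table
#' @param x A `genotype_table`.
#' @return Integer count.
#' @export
n_ind <- function(x) length(x$ind)

#' Subset a genotype table by population
#'
#' @param x A `genotype_table`.
#' @param pops Character vector of population labels to keep.
#' @return A `genotype_table` restricted to those populations.
#' @export
subset_pops <- function(x, pops) {
  keep <- x$pop %in% pops
  if (!any(keep)) stop("no individuals in requested populations")
  genotype_table(x$ind[keep], droplevels(x$pop[keep]),
                 x$alleles[keep, , , drop = FALSE])
}

#' Per-population allele frequencies
#'
#' Frequencies are allele counts over `2 * (typed individuals)`; genotypes
#' with missing calls are excluded locus-wise. A population x locus cell with
#' zero typed individuals is reported as undefined (`NA` row), never as zero.
#'
#' @param x A `genotype_table`.
#' @return An `allele_freqs` object: a list with one element per locus, each
#'   holding `freq` (populations x alleles matrix, rows summing to 1 or all
#'   `NA`) and `n` (typed individuals per population).
#' @export
allele_frequencies <- function(x) {
  pops <- levels(x$pop)
  out <- lapply(x$loci, function(loc) {
    a1 <- x$alleles[, loc, 1]
    a2 <- x$alleles[, loc, 2]
    typed <- !is.na(a1)
    alleles <- sort(unique(c(a1[typed], a2[typed])))
    freq <- matrix(NA_real_, nrow = length(pops), ncol = length(alleles),
                   dimnames = list(pops, as.character(alleles)))
    nt <- setNames(integer(length(pops)), pops)
    for (p in pops) {
      sel <- typed & x$pop == p
      nt[p] <- sum(sel)
      if (nt[p] > 0) {
        cnt <- table(factor(c(a1[sel], a2[sel]), levels = alleles))
        freq[p, ] <- as.numeric(cnt) / (2 * nt[p])
      }
    }
    list(freq = freq, n = nt)
  })
  names(out) <- x$loci
  attr(out, "pops") <- pops
  class(out) <- "allele_freqs"
  out
}

# Allele count matrices (pops x alleles), locus-wise, from a genotype table.
allele_counts <- function(x) {
  af <- allele_frequencies(x)
  lapply(af, function(l) {
    cnt <- l$freq * (2 * l$n)
    cnt[is.na(cnt)] <- 0
    round(cnt)
  })
}
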