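# Within-population diversity: heterozygosities, F_IS, rarefied richness,
# Hardy-Weinberg permutation tests.

# Weir & Cockerham (1984) within-population variance components b and c for a
# single population at one locus. Returns per-allele b and c; f = 1 - Sc/S(b+c).
wc_within_components <- function(a1, a2) {
  typed <- !is.na(a1)
  n <- sum(typed)
  if (n < 2) return(NULL)
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  if (length(alleles) < 2) return(NULL)
  b <- c <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    al <- alleles[k]
    p <- (sum(a1[typed] == al) + sum(a2[typed] == al)) / (2 * n)
    hbar <- mean((a1[typed] == al) != (a2[typed] == al))
    c[k] <- hbar / 2
    b[k] <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
  }
  list(b = b, c = c)
}

#' Per-population genetic diversity summary
#'
#' Computes, for every population: sample size, mean and SD of allele counts
#' across loci, rarefied allelic richness `Ar(g)` and private allelic richness,
#' observed heterozygosity, Nei (1978) unbiased expected heterozygosity
#' `He = (2n/(2n-1)) (1 - sum p^2)`, the Weir & Cockerham (1984)
#' within-population fixation index `f` (F_IS, monomorphic loci excluded),
#' and per-locus Hardy-Weinberg permutation p-values.
#'
#' @param x A [genotype_table()].
#' @param g Number of gene copies for rarefaction (e.g. 16 genes = 8 diploids).
#' @param n_perm Permutations for the Hardy-Weinberg test; set 0 to skip.
#' @param seed Seed for the Hardy-Weinberg permutations.
#' @return A `diversity_summary`: list with `table` (data frame, one row per
#'   population) and `hwe` (populations x loci matrix of p-values, `NA` where
#'   undefined).
#' @export
diversity_summary <- function(x, g = 16, n_perm = 1000, seed = 1) {
  pops <- levels(x$pop)
  ar <- allelic_richness(x, g)
  hwe <- if (n_perm > 0) hwe_test(x, n_perm, seed = seed) else NULL
  rows <- lapply(pops, function(p) {
    idx <- x$pop == p
    na_per_locus <- ho_l <- he_l <- numeric(0)
    sb <- sc <- 0
    for (loc in x$loci) {
      a1 <- x$alleles[idx, loc, 1]; a2 <- x$alleles[idx, loc, 2]
      typed <- !is.na(a1)
      n <- sum(typed)
      if (n == 0) next
      alleles <- unique(c(a1[typed], a2[typed]))
      na_per_locus <- c(na_per_locus, length(alleles))
      ho <- mean(a1[typed] != a2[typed])
      pfr <- as.numeric(table(c(a1[typed], a2[typed]))) / (2 * n)
      he <- (2 * n / (2 * n - 1)) * (1 - sum(pfr^2))
      ho_l <- c(ho_l, ho); he_l <- c(he_l, he)
      comp <- wc_within_components(a1, a2)
      if (!is.null(comp)) { sb <- sb + sum(comp$b); sc <- sc + sum(comp$c) }
    }
    fis <- if (sb + sc > 0) 1 - sc / (sb + sc) else NA_real_
    data.frame(pop = p, N = sum(idx),
               NA_mean = mean(na_per_locus), NA_sd = sd(na_per_locus),
               Ar = ar$Ar[p], private_Ar = ar$private_Ar[p],
               Ho = mean(ho_l), He = mean(he_l), Fis = fis,
               stringsAsFactors = FALSE)
  })
  out <- list(table = do.call(rbind, rows), hwe = hwe, g = g)
  class(out) <- "diversity_summary"
  out
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Genetic diversity summary (rarefaction to", x$g, "genes)\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

# Expected allele count in a draw of g genes: sum_a [1 - C(N - N_a, g)/C(N, g)].
rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  if (g > N) return(NA_real_)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefied allelic and private allelic richness
#'
#' `Ar(g)` is the expected number of distinct alleles in a random draw of `g`
#' gene copies from the population sample (hypergeometric rarefaction).
#' Private `Ar(g)` is the expected number of alleles that appear in a g-gene
#' draw from the focal population while being absent from independent g-gene
#' draws from every other population (product of absence probabilities).
#' Both are averaged across loci. Populations with fewer than `g` typed genes
#' at some locus get `NA` there with a warning.
#'
#' @param x A [genotype_table()].
#' @param g Number of gene copies to rarefy to.
#' @return List with named vectors `Ar` and `private_Ar`, plus per-locus
#'   matrices `Ar_locus` and `private_Ar_locus`.
#' @export
allelic_richness <- function(x, g = 16) {
  cnts <- allele_counts(x)
  pops <- levels(x$pop)
  arl <- parl <- matrix(NA_real_, length(pops), length(x$loci),
                        dimnames = list(pops, x$loci))
  for (loc in x$loci) {
    cm <- cnts[[loc]]
    Ns <- rowSums(cm)
    # probability an allele with count Na is absent from a g-gene draw
    absent <- function(Na, N) {
      if (N < g) return(NA_real_)
      exp(lchoose(N - Na, g) - lchoose(N, g))
    }
    for (p in pops) {
      if (Ns[p] < g || Ns[p] == 0) next
      arl[p, loc] <- rarefied_richness(cm[p, ], g)
      others <- setdiff(pops, p)
      pa <- 0
      for (k in seq_len(ncol(cm))) {
        if (cm[p, k] == 0) next
        pres <- 1 - absent(cm[p, k], Ns[p])
        abs_others <- vapply(others, function(q) absent(cm[q, k], Ns[q]),
                             numeric(1))
        pa <- pa + pres * prod(abs_others)
      }
      parl[p, loc] <- pa
    }
  }
  if (anyNA(arl))
    warning("some population x locus cells have fewer than g typed genes; ",
            "richness reported as NA there")
  list(Ar = rowMeans(arl, na.rm = TRUE),
       private_Ar = rowMeans(parl, na.rm = TRUE),
       Ar_locus = arl, private_Ar_locus = parl)
}

#' Hardy-Weinberg permutation test
#'
#' Monte-Carlo exact-style test: within each population x locus cell the
#' observed gene copies are shuffled among individuals, and the p-value is the
#' add-one-corrected proportion of permutations whose |F_IS| is at least the
#' observed |F_IS|. Cells with fewer than 5 typed individuals or a
#' monomorphic allele pool are reported as `NA`.
#'
#' @param x A [genotype_table()].
#' @param n_perm Number of permutations (at least 100).
#' @param seed RNG seed.
#' @return Populations x loci matrix of p-values.
#' @export
hwe_test <- function(x, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  set.seed(seed)
  pops <- levels(x$pop)
  out <- matrix(NA_real_, length(pops), length(x$loci),
                dimnames = list(pops, x$loci))
  fis_of <- function(a1, a2) {
    comp <- wc_within_components(a1, a2)
    if (is.null(comp)) return(NA_real_)
    1 - sum(comp$c) / sum(comp$b + comp$c)
  }
  for (p in pops) {
    idx <- x$pop == p
    for (loc in x$loci) {
      a1 <- x$alleles[idx, loc, 1]; a2 <- x$alleles[idx, loc, 2]
      typed <- !is.na(a1)
      if (sum(typed) < 5) next
      obs <- fis_of(a1[typed], a2[typed])
      if (is.na(obs)) next
      genes <- c(a1[typed], a2[typed])
      m <- length(genes) / 2
      hits <- 0
      for (b in seq_len(n_perm)) {
        gp <- sample(genes)
        fb <- fis_of(gp[seq_len(m)], gp[m + seq_len(m)])
        if (!is.na(fb) && abs(fb) >= abs(obs) - 1e-12) hits <- hits + 1
      }
      out[p, loc] <- (hits + 1) / (n_perm + 1)
    }
  }
  out
}
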