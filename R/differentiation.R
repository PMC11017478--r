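# Among-population differentiation: Weir-Cockerham theta, Jost's Dest,
# Cavalli-Sforza & Edwards chord distance, allele-frequency heterogeneity.

# Weir & Cockerham (1984) variance components for one locus across r
# populations. a1m/a2m: gene-copy matrices restricted to the populations of
# interest; pop: factor. Returns per-allele components a, b, c.
wc_locus_components <- function(a1, a2, pop) {
  typed <- !is.na(a1)
  pop <- droplevels(pop[typed]); a1 <- a1[typed]; a2 <- a2[typed]
  r <- nlevels(pop)
  ni <- as.numeric(table(pop))
  if (r < 2 || any(ni < 2)) return(NULL)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(c(a1, a2)))
  a <- b <- cc <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    al <- alleles[k]
    cnt1 <- tapply(a1 == al, pop, sum)
    cnt2 <- tapply(a2 == al, pop, sum)
    p_i <- (cnt1 + cnt2) / (2 * ni)
    h_i <- tapply((a1 == al) != (a2 == al), pop, mean)
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a[k] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[k] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[k] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

# Per-locus (a, b, c) sums for a set of populations; NULL rows for unusable loci.
wc_components_by_locus <- function(x, pops = levels(x$pop)) {
  keep <- x$pop %in% pops
  pop <- droplevels(x$pop[keep])
  comp <- lapply(x$loci, function(loc) {
    cl <- wc_locus_components(x$alleles[keep, loc, 1],
                              x$alleles[keep, loc, 2], pop)
    if (is.null(cl)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
    c(a = sum(cl$a), b = sum(cl$b), c = sum(cl$c))
  })
  m <- do.call(rbind, comp)
  rownames(m) <- x$loci
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Multilocus Weir-Cockerham theta
#'
#' Ratio-of-sums estimator `theta = sum(a) / sum(a + b + c)` over alleles and
#' loci, for the populations present in `x` (two or more).
#'
#' @param x A [genotype_table()].
#' @return Numeric theta (can be negative for undifferentiated samples).
#' @export
wc_theta <- function(x) {
  m <- wc_components_by_locus(x)
  if (nrow(m) == 0) stop("no usable locus for theta")
  sum(m[, "a"]) / sum(m)
}

#' Pairwise Weir-Cockerham F_ST with bootstrap confidence intervals
#'
#' Multilocus theta for every unordered population pair, with a 95 percent
#' percentile CI from bootstrap resampling of loci. A pair is flagged
#' differentiated when its CI excludes zero. With a single usable locus the
#' CI is undefined and the pair is flagged accordingly.
#'
#' @param x A [genotype_table()].
#' @param n_resample Bootstrap replicates over loci.
#' @param seed RNG seed for the bootstrap.
#' @return List with `theta` (a [dist_matrix()]), `ci` (data frame per pair)
#'   and `differentiated` (logical matrix).
#' @export
pairwise_fst <- function(x, n_resample = 1000, seed = 1) {
  set.seed(seed)
  pops <- levels(x$pop)
  npop <- length(pops)
  if (npop < 2) stop("need at least two populations")
  th <- matrix(0, npop, npop, dimnames = list(pops, pops))
  sig <- matrix(NA, npop, npop, dimnames = list(pops, pops))
  rows <- list()
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    m <- wc_components_by_locus(x, c(pops[i], pops[j]))
    if (nrow(m) == 0) stop("no usable locus for pair ", pops[i], "-", pops[j])
    est <- sum(m[, "a"]) / sum(m)
    lo <- hi <- NA_real_
    if (nrow(m) >= 2) {
      boot <- replicate(n_resample, {
        s <- m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]
        sum(s[, "a"]) / sum(s)
      })
      q <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      lo <- q[1]; hi <- q[2]
      sig[i, j] <- sig[j, i] <- lo > 0 || hi < 0
    }
    th[i, j] <- th[j, i] <- est
    rows[[length(rows) + 1]] <- data.frame(
      pop1 = pops[i], pop2 = pops[j], theta = est,
      ci_lo = lo, ci_hi = hi, stringsAsFactors = FALSE)
  }
  thm <- th
  thm[thm < 0] <- 0  # distance-matrix view floors negatives
  list(theta = dist_matrix(thm), estimates = th,
       ci = do.call(rbind, rows), differentiated = sig)
}

# Jost's Dest for one locus between exactly two demes (Nei-Chesser corrected).
dest_locus <- function(freq, n) {
  ok <- !is.na(freq[, 1])
  if (sum(ok) < 2) return(NA_real_)
  r <- 2
  ntilde <- r / sum(1 / n)
  Hs <- mean(1 - rowSums(freq^2))
  pbar <- colMeans(freq)
  Ht <- 1 - sum(pbar^2)
  Hs_est <- (2 * ntilde / (2 * ntilde - 1)) * Hs
  Ht_est <- Ht + Hs_est / (2 * ntilde * r)
  if (Ht_est <= 0 || 1 - Hs_est <= 0) return(0)
  (Ht_est - Hs_est) / (1 - Hs_est) * r / (r - 1)
}

#' Pairwise Jost's Dest
#'
#' Per-locus D with Nei-Chesser bias-corrected Hs and Ht and the
#' `n/(n-1)` deme-number correction (n = 2 demes); the multilocus value is
#' the harmonic mean across loci with negative per-locus values floored at 0
#' first (a zero-D locus therefore drives the harmonic mean to 0). A pair
#' whose loci are all monomorphic has Dest 0.
#'
#' @param x A [genotype_table()].
#' @return A [dist_matrix()] of multilocus Dest values.
#' @export
pairwise_dest <- function(x) {
  af <- allele_frequencies(x)
  pops <- levels(x$pop)
  npop <- length(pops)
  out <- matrix(0, npop, npop, dimnames = list(pops, pops))
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    dl <- vapply(af, function(l) {
      f <- l$freq[c(pops[i], pops[j]), , drop = FALSE]
      n <- l$n[c(pops[i], pops[j])]
      if (any(n < 2) || anyNA(f)) return(NA_real_)
      dest_locus(f, n)
    }, numeric(1))
    dl <- dl[!is.na(dl)]
    if (length(dl) == 0) stop("no usable locus for pair ",
                              pops[i], "-", pops[j])
    dl[dl < 0] <- 0
    d <- if (any(dl == 0)) 0 else length(dl) / sum(1 / dl)
    out[i, j] <- out[j, i] <- d
  }
  dist_matrix(out)
}

#' Cavalli-Sforza and Edwards chord distance
#'
#' For each locus `f_l = 1 - sum_a sqrt(p_a q_a)` (clipped to `[0, 1]`), and
#' `Dce = (2 / (pi L)) * sum_l sqrt(2 f_l)` over the `L` loci usable for the
#' pair (both populations typed). Identical frequency vectors give 0.
#'
#' @param af An `allele_freqs` object from [allele_frequencies()].
#' @return A [dist_matrix()] of Dce values.
#' @export
chord_distance <- function(af) {
  pops <- attr(af, "pops")
  if (is.null(pops)) pops <- rownames(af[[1]]$freq)
  npop <- length(pops)
  out <- matrix(0, npop, npop, dimnames = list(pops, pops))
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    fl <- vapply(af, function(l) {
      p <- l$freq[pops[i], ]; q <- l$freq[pops[j], ]
      if (anyNA(p) || anyNA(q)) return(NA_real_)
      min(max(1 - sum(sqrt(p * q)), 0), 1)
    }, numeric(1))
    fl <- fl[!is.na(fl)]
    if (length(fl) == 0)
      stop("no shared usable locus for pair ", pops[i], "-", pops[j])
    out[i, j] <- out[j, i] <- (2 / (pi * length(fl))) * sum(sqrt(2 * fl))
  }
  dist_matrix(out)
}

# Log-linear G statistic on a 2 x k allele-count table.
g_statistic <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
}

#' Allele-frequency heterogeneity test for a population pair
#'
#' Monte-Carlo contingency test: per locus, individuals (with their two gene
#' copies) are permuted between the two populations and the G statistic on
#' the 2 x alleles count table recomputed; per-locus add-one p-values are
#' combined across loci with Fisher's method.
#'
#' @param x A [genotype_table()].
#' @param pair Character vector of two population labels.
#' @param n_perm Number of permutations (at least 1000 for reported results).
#' @param seed RNG seed.
#' @return List with the combined `p`, Fisher's `statistic`, its `df`, and
#'   the per-locus p-values.
#' @export
heterogeneity_test <- function(x, pair, n_perm = 1000, seed = 1) {
  if (length(pair) != 2) stop("pair must name two populations")
  set.seed(seed)
  sub <- subset_pops(x, pair)
  pl <- c()
  for (loc in sub$loci) {
    a1 <- sub$alleles[, loc, 1]; a2 <- sub$alleles[, loc, 2]
    typed <- !is.na(a1)
    if (sum(typed & sub$pop == pair[1]) == 0 ||
        sum(typed & sub$pop == pair[2]) == 0) next
    pop <- droplevels(sub$pop[typed]); a1 <- a1[typed]; a2 <- a2[typed]
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2) next
    tab_of <- function(grp) {
      rbind(table(factor(c(a1[grp == pair[1]], a2[grp == pair[1]]),
                         levels = alleles)),
            table(factor(c(a1[grp == pair[2]], a2[grp == pair[2]]),
                         levels = alleles)))
    }
    obs <- g_statistic(tab_of(pop))
    hits <- 0
    for (b in seq_len(n_perm)) {
      if (g_statistic(tab_of(sample(pop))) >= obs - 1e-12) hits <- hits + 1
    }
    pl <- c(pl, setNames((hits + 1) / (n_perm + 1), loc))
  }
  if (length(pl) == 0) stop("no polymorphic locus for pair")
  stat <- -2 * sum(log(pl))
  list(p = pchisq(stat, df = 2 * length(pl), lower.tail = FALSE),
       statistic = stat, df = 2 * length(pl), per_locus = pl)
}

#' Sequential Bonferroni (Holm) adjustment
#'
#' Holm's step-down procedure over a vector of p-values; equivalent to
#' `p.adjust(p, "holm")` compared against `alpha`.
#'
#' @param p Numeric vector of p-values.
#' @param alpha Family-wise significance level.
#' @return Data frame with raw and adjusted p-values and reject decisions,
#'   in the input order.
#' @export
sequential_bonferroni <- function(p, alpha = 0.05) {
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(p = p, p_adjusted = adj, reject = adj <= alpha)
}
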