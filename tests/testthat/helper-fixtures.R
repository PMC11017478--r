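# Shared fixture builders (all data generated in code).

# Genotype table from a list of per-population genotype matrices, one locus.
# genos_by_pop: list(pop1 = rbind(c(1,1), c(1,2)), ...)
gt_single_locus <- function(genos_by_pop, locus = "loc1") {
  n <- sum(vapply(genos_by_pop, nrow, integer(1)))
  arr <- array(NA_integer_, c(n, 1, 2), dimnames = list(NULL, locus, NULL))
  pop <- character(0); row <- 0
  for (p in names(genos_by_pop)) {
    g <- genos_by_pop[[p]]
    arr[row + seq_len(nrow(g)), 1, 1] <- as.integer(g[, 1])
    arr[row + seq_len(nrow(g)), 1, 2] <- as.integer(g[, 2])
    pop <- c(pop, rep(p, nrow(g)))
    row <- row + nrow(g)
  }
  genotype_table(paste0("i", seq_len(n)), pop, arr)
}

# Random multi-locus genotype table.
random_genotypes <- function(pop_sizes, n_loci = 3, n_alleles = 4, seed = 1) {
  set.seed(seed)
  n <- sum(pop_sizes)
  pops <- rep(paste0("p", seq_along(pop_sizes)), pop_sizes)
  arr <- array(sample.int(n_alleles, n * n_loci * 2, replace = TRUE),
               c(n, n_loci, 2),
               dimnames = list(NULL, paste0("loc", seq_len(n_loci)), NULL))
  genotype_table(paste0("i", seq_len(n)), pops, arr)
}

# Independently coded Weir-Cockerham theta oracle: nested ANOVA
# (populations / individuals / gene copies) on allele indicator variables.
theta_anova_oracle <- function(gt) {
  num <- den <- 0
  for (loc in gt$loci) {
    a1 <- gt$alleles[, loc, 1]; a2 <- gt$alleles[, loc, 2]
    ok <- !is.na(a1)
    pop <- droplevels(gt$pop[ok]); a1 <- a1[ok]; a2 <- a2[ok]
    ni <- as.numeric(table(pop)); r <- nlevels(pop); ntot <- sum(ni)
    nbar <- mean(ni); nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in sort(unique(c(a1, a2)))) {
      y <- rbind(as.numeric(a1 == al), as.numeric(a2 == al))
      ybar_ind <- colMeans(y)
      ybar_pop <- tapply(ybar_ind * 2, pop, sum) / (2 * ni)
      ybar <- sum(y) / (2 * ntot)
      SSP <- sum(2 * ni * (ybar_pop - ybar)^2)
      SSI <- sum(2 * (ybar_ind - ybar_pop[as.integer(pop)])^2)
      SSG <- sum((y[1, ] - ybar_ind)^2 + (y[2, ] - ybar_ind)^2)
      MSP <- SSP / (r - 1); MSI <- SSI / (ntot - r); MSG <- SSG / ntot
      num <- num + (MSP - MSI) / (2 * nc)
      den <- den + (MSP - MSI) / (2 * nc) + (MSI - MSG) / 2 + MSG
    }
  }
  num / den
}

# Exhaustive rarefaction oracle: expected distinct alleles over all g-subsets.
ar_enumeration_oracle <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  combs <- utils::combn(length(genes), g)
  mean(apply(combs, 2, function(ix) length(unique(genes[ix]))))
}

# Jost's Dest oracle for one locus, coded via explicit Hs/Ht corrections.
dest_oracle <- function(freq, n) {
  ntilde <- 2 / (1 / n[1] + 1 / n[2])
  Hs <- 1 - mean(c(sum(freq[1, ]^2), sum(freq[2, ]^2)))
  Ht <- 1 - sum(colMeans(freq)^2)
  Hs_est <- (2 * ntilde / (2 * ntilde - 1)) * Hs
  Ht_est <- Ht + Hs_est / (4 * ntilde)
  2 * (Ht_est - Hs_est) / (1 - Hs_est)
}

# Random similarity-transform of every configuration of a landmark set.
randomly_repose <- function(ls, seed) {
  set.seed(seed)
  for (i in seq_len(ls$n)) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sc <- exp(runif(1, -0.5, 0.5))
    ls$coords[i, , ] <- sweep(sc * ls$coords[i, , ] %*% R, 2, runif(2, -5, 5))
  }
  ls
}

# Small landmark set generated from the fish template with given noise.
toy_landmarks <- function(n = 30, n_pop = 3, noise_sd = 0.01, seed = 1,
                          trait = NULL) {
  set.seed(seed)
  ph <- data.frame(ind = paste0("i", seq_len(n)),
                   pop = rep(paste0("p", seq_len(n_pop)), length.out = n),
                   trait = if (is.null(trait)) rnorm(n) else trait,
                   fork_length = rnorm(n, 70, 12))
  list(phen = ph,
       lms = simulate_landmarks(ph, noise_sd = noise_sd, seed = seed + 1))
}
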