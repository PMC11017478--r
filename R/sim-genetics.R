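# Genotype generation: Dirichlet source frequencies, founder sampling and
# multinomial drift, optional symmetric migration, Hardy-Weinberg genotypes.

#' Simulate source (lake) allele frequencies
#'
#' One Dirichlet draw per locus: `n_alleles` gamma variates with shape
#' `concentration`, normalized to sum to 1.
#'
#' @param loci Data frame with `name`, `n_alleles`, `concentration`.
#' @param seed RNG seed.
#' @return Named list of per-locus frequency vectors.
#' @export
simulate_source_frequencies <- function(loci, seed = 1) {
  if (any(loci$n_alleles < 2)) stop("each locus needs at least 2 alleles")
  if (any(loci$concentration <= 0)) stop("concentrations must be positive")
  set.seed(seed)
  out <- lapply(seq_len(nrow(loci)), function(l) {
    g <- rgamma(loci$n_alleles[l], shape = loci$concentration[l])
    while (sum(g) == 0) g <- rgamma(loci$n_alleles[l],
                                    shape = loci$concentration[l])
    setNames(g / sum(g), seq_len(loci$n_alleles[l]))
  })
  names(out) <- loci$name
  out
}

# One multinomial resampling of a frequency vector to n_genes gene copies.
drift_step <- function(freq, n_genes) {
  as.numeric(rmultinom(1, n_genes, freq)) / n_genes
}

#' Simulate colonization, drift and migration
#'
#' Each population's generation-0 gene pool is a multinomial draw of
#' `2 * founders_per_pop` gene copies from the source frequencies; every
#' subsequent generation is a multinomial draw of `2 N` copies from the
#' parental frequencies (drift modelled at the frequency level). Configured
#' migration pairs exchange `migrants` individuals symmetrically before
#' reproduction (frequency blending with weight `m / N`). Final genotypes
#' are Hardy-Weinberg pairs drawn from the terminal frequencies.
#'
#' With `n_clusters > 1` an intermediate founding stage is inserted:
#' populations are grouped into contiguous subarea clusters; each cluster
#' gets its own gene pool, founded by a multinomial draw of
#' `2 * cluster_founders` copies from the source and drifting for
#' `cluster_generations` generations at size `cluster_founders` before the
#' populations split off from it. This emulates the subarea-level genetic
#' clustering that real fragmented systems show (colonization through
#' multiple routes and intermediate pools); `n_clusters = 1` reduces to
#' single-stage founding straight from the source.
#'
#' @param source Per-locus source frequencies from
#'   [simulate_source_frequencies()].
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param sample_n Individuals to genotype per population (defaults to the
#'   population size).
#' @return List with `genotypes` (a [genotype_table()]) and `truth`
#'   (terminal and per-generation frequencies, chord-distance-derived true
#'   similarity matrix).
#' @export
simulate_colonization <- function(source, config, seed = 1,
                                  sample_n = NULL) {
  npop <- config$n_populations
  if (npop < 1) stop("need at least one population")
  set.seed(seed)
  loci <- names(source)
  G <- config$generations
  N <- config$pop_size
  if (is.null(sample_n)) sample_n <- N
  sample_n <- rep_len(sample_n, npop)
  ncl <- if (is.null(config$n_clusters)) 1L else config$n_clusters
  cluster <- sort(rep_len(seq_len(ncl), npop))
  cf <- if (is.null(config$cluster_founders)) 25L else config$cluster_founders
  # freqs[[locus]] is a pops x alleles matrix, updated in place
  cg <- if (is.null(config$cluster_generations)) 25L
        else config$cluster_generations
  freqs <- lapply(source, function(f) {
    pools <- if (ncl > 1)
      lapply(seq_len(ncl), function(cl) {
        p <- drift_step(f, 2 * cf)
        for (g in seq_len(cg)) p <- drift_step(p, 2 * cf)
        p
      })
    else rep(list(f), 1)
    t(vapply(seq_len(npop), function(j) {
      pool <- if (ncl > 1) pools[[cluster[j]]] else f
      drift_step(pool, 2 * config$founders_per_pop)
    }, numeric(length(f))))
  })
  traj <- if (G > 0) lapply(loci, function(l) vector("list", G)) else NULL
  if (!is.null(traj)) names(traj) <- loci
  mig <- config$migration_pairs
  for (g in seq_len(G)) {
    if (!is.null(mig) && nrow(mig) > 0) {
      for (k in seq_len(nrow(mig))) {
        a <- mig$pop_a[k]; b <- mig$pop_b[k]
        wa <- mig$migrants[k] / N[a]; wb <- mig$migrants[k] / N[b]
        for (l in loci) {
          fa <- freqs[[l]][a, ]; fb <- freqs[[l]][b, ]
          freqs[[l]][a, ] <- (1 - wa) * fa + wa * fb
          freqs[[l]][b, ] <- (1 - wb) * fb + wb * fa
        }
      }
    }
    for (l in loci) {
      for (j in seq_len(npop))
        freqs[[l]][j, ] <- drift_step(freqs[[l]][j, ], 2 * N[j])
      traj[[l]][[g]] <- freqs[[l]]
    }
  }
  # Hardy-Weinberg genotypes from terminal frequencies
  ntot <- sum(sample_n)
  arr <- array(NA_integer_, c(ntot, length(loci), 2),
               dimnames = list(NULL, loci, NULL))
  pop <- rep(paste0("pop", seq_len(npop)), sample_n)
  row0 <- c(0, cumsum(sample_n))
  for (l in seq_along(loci)) {
    for (j in seq_len(npop)) {
      f <- freqs[[loci[l]]][j, ]
      idx <- (row0[j] + 1):row0[j + 1]
      arr[idx, l, 1] <- sample.int(length(f), sample_n[j], replace = TRUE,
                                   prob = f)
      arr[idx, l, 2] <- sample.int(length(f), sample_n[j], replace = TRUE,
                                   prob = f)
    }
  }
  gt <- genotype_table(paste0(pop, "_", sequence(sample_n)), pop, arr)
  term <- lapply(freqs, function(m) {
    rownames(m) <- paste0("pop", seq_len(npop)); m
  })
  af <- lapply(term, function(m) list(freq = m, n = NULL))
  attr(af, "pops") <- paste0("pop", seq_len(npop))
  class(af) <- "allele_freqs"
  dce <- chord_distance(af)
  truth <- list(terminal_freqs = term, trajectory = traj,
                source = source, dce = dce,
                similarity = similarity_from_distance(dce),
                cluster = cluster, pop_size = N, sample_n = sample_n)
  list(genotypes = gt, truth = truth)
}
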