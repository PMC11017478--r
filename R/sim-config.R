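# Simulation configuration: the generative analogue of the field system --
# ~24 cave populations founded from one lake source, nine microsatellite
# loci, cave temperatures around 5.5 C, 1-7 openings, 57-500 m to the lake,
# and a trait built from fixed environmental effects plus structured and
# independent population effects.

#' Trait parameters hitting target variance proportions
#'
#' Convenience constructor: with standardized covariates, a single nonzero
#' temperature effect `beta_T = sqrt(E * sigma_t2)` contributes exactly
#' `E * sigma_t2` of among-population variance, so the generative truth
#' `(E, G, O)` equals the configuration exactly.
#'
#' @param E,G,O Target proportions of among-population variance
#'   (must sum to 1).
#' @param sigma_t2 Total among-population variance.
#' @param var_resid Residual (within-population) variance.
#' @param beta_L Fixed allometric slope on standardized length.
#' @return A `trait_params` list usable in [sim_config()].
#' @export
trait_params_for_proportions <- function(E = 0.4, G = 0.4, O = 0.2,
                                         sigma_t2 = 1, var_resid = 1,
                                         beta_L = 0.3) {
  if (abs(E + G + O - 1) > 1e-12) stop("E + G + O must sum to 1")
  if (min(E, G, O) < 0) stop("proportions must be non-negative")
  list(alpha = 0, beta_L = beta_L,
       beta_T = sqrt(E * sigma_t2), beta_O = 0, beta_D = 0,
       delta_T = 0, delta_O = 0, delta_D = 0,
       var_gen = G * sigma_t2, var_cave = O * sigma_t2,
       var_resid = var_resid)
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults reflect the
#' cave-charr study system: 24 populations founded from one source, nine
#' loci, cave temperature Normal(5.52, 0.7) degrees C, 1-7 openings,
#' 57-500 m distances, and a trait whose among-population variance is split
#' 0.4/0.4/0.2 between environment, genetic structure and other sources.
#'
#' @param n_populations Number of populations.
#' @param loci Data frame with columns `name`, `n_alleles`, `concentration`
#'   (Dirichlet concentration for the source frequencies).
#' @param founders_per_pop Founding individuals per population.
#' @param generations Generations of drift after founding.
#' @param pop_size Population size (scalar or vector per population).
#' @param migration_pairs Data frame `pop_a`, `pop_b`, `migrants`
#'   (individuals exchanged per generation); default none.
#' @param n_clusters Number of subarea founding clusters (see
#'   [simulate_colonization()]); default 5, matching the subarea-level
#'   genetic clustering typical of the study system. Set 1 for single-stage
#'   founding straight from the source.
#' @param cluster_founders Founding individuals behind each cluster pool
#'   (also its drift size during the intermediate stage).
#' @param cluster_generations Generations the cluster pools drift before
#'   the populations split off.
#' @param n_per_pop Phenotyped individuals per population.
#' @param trait_params List as from [trait_params_for_proportions()].
#' @param env_ranges List with `temp_mean`, `temp_sd`, `openings_range`,
#'   `distance_range`.
#' @param capture_prob Per-session capture probability in (0, 1].
#' @param seed Root RNG seed; stage seeds are derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_populations = 24,
                       loci = data.frame(
                         name = paste0("L", 1:9),
                         n_alleles = rep(c(4L, 6L, 8L), 3),
                         concentration = 1),
                       founders_per_pop = 10,
                       generations = 50,
                       pop_size = 100,
                       migration_pairs = NULL,
                       n_clusters = 5,
                       cluster_founders = 25,
                       cluster_generations = 25,
                       n_per_pop = 30,
                       trait_params = trait_params_for_proportions(),
                       env_ranges = list(temp_mean = 5.52, temp_sd = 0.7,
                                         openings_range = c(1L, 7L),
                                         distance_range = c(57, 500)),
                       capture_prob = 0.3,
                       seed = 1) {
  if (n_populations < 1) stop("n_populations must be at least 1")
  if (any(loci$n_alleles < 2)) stop("each locus needs at least 2 alleles")
  if (any(loci$concentration <= 0)) stop("concentrations must be positive")
  if (founders_per_pop < 1 || generations < 0) stop("bad counts")
  pop_size <- rep_len(pop_size, n_populations)
  if (any(pop_size < 1)) stop("pop_size must be at least 1")
  if (any(founders_per_pop > pop_size))
    stop("founders_per_pop cannot exceed pop_size")
  if (!is.null(migration_pairs)) {
    if (any(migration_pairs$pop_a > n_populations |
            migration_pairs$pop_b > n_populations |
            migration_pairs$pop_a < 1 | migration_pairs$pop_b < 1))
      stop("migration pairs reference nonexistent populations")
  }
  tp <- trait_params
  if (any(unlist(tp[c("var_gen", "var_cave", "var_resid")]) < 0))
    stop("variances must be non-negative")
  if (capture_prob <= 0 || capture_prob > 1)
    stop("capture_prob must be in (0, 1]")
  if (n_clusters < 1 || cluster_founders < 1 || cluster_generations < 0)
    stop("bad cluster counts")
  structure(list(n_populations = n_populations, loci = loci,
                 founders_per_pop = founders_per_pop,
                 generations = generations, pop_size = pop_size,
                 migration_pairs = migration_pairs,
                 n_clusters = n_clusters, cluster_founders = cluster_founders,
                 cluster_generations = cluster_generations,
                 n_per_pop = n_per_pop,
                 trait_params = tp, env_ranges = env_ranges,
                 capture_prob = capture_prob, seed = seed),
            class = "sim_config")
}
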