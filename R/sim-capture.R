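# Two-session capture histories with optional inter-population movers.

#' Simulate two-session capture histories
#'
#' Session-1 captures are marked; session-2 captures carry recapture flags.
#' Configured movers are marked individuals relocated from `pop_a` to
#' `pop_b` between the sessions, so with `capture_prob = 1` the migrant
#' table recovers the configuration exactly.
#'
#' @param true_n Integer vector of true population sizes (named or
#'   `pop1..popK`).
#' @param capture_prob Per-session capture probability in (0, 1].
#' @param movement_pairs Optional data frame `pop_a`, `pop_b`, `movers`.
#' @param seed RNG seed.
#' @return Data frame `tag`, `pop`, `session`, `event` with attribute
#'   `true_n`.
#' @export
simulate_capture_histories <- function(true_n, capture_prob,
                                       movement_pairs = NULL, seed = 1) {
  if (capture_prob <= 0 || capture_prob > 1)
    stop("capture_prob must be in (0, 1]")
  set.seed(seed)
  pops <- names(true_n)
  if (is.null(pops)) pops <- paste0("pop", seq_along(true_n))
  tags <- lapply(seq_along(true_n),
                 function(j) paste0(pops[j], "_t", seq_len(true_n[j])))
  loc <- rep(pops, true_n)          # current population of each individual
  tag <- unlist(tags)
  caught1 <- runif(length(tag)) <= capture_prob
  rows <- data.frame(tag = tag[caught1], pop = loc[caught1],
                     session = 1L, event = "first-capture",
                     stringsAsFactors = FALSE)
  if (!is.null(movement_pairs) && nrow(movement_pairs) > 0) {
    for (k in seq_len(nrow(movement_pairs))) {
      a <- movement_pairs$pop_a[k]; b <- movement_pairs$pop_b[k]
      cand <- which(loc == a & caught1)  # marked fish can be re-identified
      if (length(cand) < movement_pairs$movers[k])
        stop("not enough marked individuals in ", a, " to move")
      mv <- cand[seq_len(movement_pairs$movers[k])]
      loc[mv] <- b
    }
  }
  caught2 <- runif(length(tag)) <= capture_prob
  rows2 <- data.frame(tag = tag[caught2], pop = loc[caught2],
                      session = 2L,
                      event = ifelse(caught1[caught2],
                                     "recapture", "first-capture"),
                      stringsAsFactors = FALSE)
  out <- rbind(rows, rows2)
  rownames(out) <- NULL
  attr(out, "true_n") <- setNames(as.integer(true_n), pops)
  out
}

#' Run the full synthetic study system
#'
#' Drives all generator stages from a single configuration, with
#' per-stage child seeds derived from the root seed: source frequencies,
#' colonization and drift, environments, phenotypes (using the true
#' chord-distance similarity), landmark configurations and capture
#' histories.
#'
#' @param config A [sim_config()].
#' @return List with `source`, `genotypes`, `truth`, `env`, `phenotypes`,
#'   `landmarks`, `histories`, `config` and the derived stage `seeds`.
#' @export
simulate_cave_system <- function(config = sim_config()) {
  seeds <- child_seeds(config$seed, 6)
  names(seeds) <- c("source", "colonize", "env", "pheno", "landmarks",
                    "capture")
  src <- simulate_source_frequencies(config$loci, seeds["source"])
  col <- simulate_colonization(src, config, seeds["colonize"],
                               sample_n = pmin(config$pop_size,
                                               config$n_per_pop))
  env <- simulate_environment(config$n_populations, config$env_ranges,
                              seeds["env"])
  phen <- simulate_phenotypes(col$truth$similarity, env, config$n_per_pop,
                              config$trait_params, seeds["pheno"])
  lms <- simulate_landmarks(phen, seed = seeds["landmarks"])
  hist <- simulate_capture_histories(
    setNames(config$pop_size, paste0("pop", seq_len(config$n_populations))),
    config$capture_prob, movement_pairs = NULL, seed = seeds["capture"])
  list(source = src, genotypes = col$genotypes, truth = col$truth,
       env = env, phenotypes = phen, landmarks = lms, histories = hist,
       config = config, seeds = seeds)
}

#' Write a simulated system to disk
#'
#' GENEPOP genotypes, TPS landmarks, CSV environment/phenotype/capture
#' tables and a JSON truth sidecar.
#'
#' @param sim Output of [simulate_cave_system()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genepop(sim$genotypes, file.path(dir, "genotypes.gen"))
  write_tps(sim$landmarks, file.path(dir, "landmarks.tps"))
  write.csv(sim$env, file.path(dir, "environment.csv"), row.names = FALSE)
  write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE)
  write.csv(sim$histories, file.path(dir, "captures.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- attr(sim$phenotypes, "truth")
    jsonlite::write_json(
      list(seeds = as.list(sim$seeds),
           proportions = truth[c("E", "G", "O")],
           variance_components = truth[c("var_env", "var_gen", "var_cave",
                                         "var_resid")],
           pop_size = sim$truth$pop_size),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
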