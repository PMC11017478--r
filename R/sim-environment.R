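# Environment and phenotype generation.

#' Simulate cave-level environmental covariates and coordinates
#'
#' Temperature is Normal, openings uniform integers, distance uniform, per
#' the configured ranges (defaults: Normal(5.52, 0.7) degrees C, 1-7
#' openings, 57-500 m). Coordinates are placed in two geographic clusters.
#' Zero-spread covariates are flagged in the `constant_columns` attribute.
#'
#' @param n_populations Number of populations.
#' @param ranges List `temp_mean`, `temp_sd`, `openings_range`,
#'   `distance_range`.
#' @param seed RNG seed.
#' @return Data frame `pop`, `temperature`, `openings`, `distance`, `lat`,
#'   `lon`, `area` with attribute `constant_columns`.
#' @export
simulate_environment <- function(n_populations,
                                 ranges = list(temp_mean = 5.52,
                                               temp_sd = 0.7,
                                               openings_range = c(1L, 7L),
                                               distance_range = c(57, 500)),
                                 seed = 1) {
  if (n_populations < 1) stop("n_populations must be at least 1")
  set.seed(seed)
  temp <- rnorm(n_populations, ranges$temp_mean, ranges$temp_sd)
  op_values <- seq.int(ranges$openings_range[1], ranges$openings_range[2])
  op <- op_values[sample.int(length(op_values), n_populations,
                             replace = TRUE)]
  dist <- runif(n_populations, ranges$distance_range[1],
                ranges$distance_range[2])
  # two clusters mimicking the two geographic areas
  n_a <- ceiling(n_populations * 0.6)
  area <- c(rep("A", n_a), rep("B", n_populations - n_a))
  centers <- rbind(A = c(65.585, -17.055), B = c(65.617, -17.070))
  lat <- centers[area, 1] + rnorm(n_populations, 0, 0.002)
  lon <- centers[area, 2] + rnorm(n_populations, 0, 0.004)
  out <- data.frame(pop = paste0("pop", seq_len(n_populations)),
                    temperature = temp, openings = op, distance = dist,
                    lat = lat, lon = lon, area = area,
                    stringsAsFactors = FALSE)
  numcols <- c("temperature", "openings", "distance")
  spread <- vapply(out[numcols], function(v) stats::sd(v), numeric(1))
  attr(out, "constant_columns") <- numcols[!is.na(spread) & spread == 0]
  out
}

#' Simulate individual phenotypes under the variance-partition model
#'
#' Generates `z_ij = alpha + beta_L L_i + beta_T T_j + beta_O O_j +
#' beta_D D_j + delta terms + g_j + c_j + e_ij`, with structured population
#' effects `g ~ N(0, var_gen S)`, independent effects
#' `c ~ N(0, var_cave I)` and residuals `e`. All covariates are
#' standardized before use (environment across populations, length across
#' individuals). The realized ground-truth proportions `(E, G, O)` are
#' recorded in the `truth` attribute.
#'
#' @param S Population similarity matrix (PSD, unit diagonal); with
#'   `var_gen > 0` and `S` the identity a warning notes that G and O are
#'   confounded.
#' @param env Environment table from [simulate_environment()].
#' @param n_per_pop Individuals per population.
#' @param trait_params List as in [sim_config()].
#' @param seed RNG seed.
#' @param fl_mean,fl_sd Fork-length distribution (mm).
#' @return Data frame `ind`, `pop`, `trait`, `fork_length`; attribute
#'   `truth` holds the realized variance components and proportions.
#' @export
simulate_phenotypes <- function(S, env, n_per_pop, trait_params, seed = 1,
                                fl_mean = 70, fl_sd = 12) {
  set.seed(seed)
  npop <- nrow(env)
  tp <- trait_params
  eS <- eigen(S, symmetric = TRUE)
  if (min(eS$values) < -1e-8) stop("S must be positive semi-definite")
  if (tp$var_gen > 0 && max(abs(S - diag(npop))) < 1e-10)
    warning("S is the identity: genetic-structure and independent cave ",
            "effects are confounded in the generated data")
  Ls <- eS$vectors %*% diag(sqrt(pmax(eS$values, 0)), npop)
  n <- npop * n_per_pop
  pop <- rep(env$pop, each = n_per_pop)
  pop_i <- rep(seq_len(npop), each = n_per_pop)
  fl <- rnorm(n, fl_mean, fl_sd)
  L <- as.numeric(scale(fl))
  Estd <- scale(as.matrix(env[, c("temperature", "openings", "distance")]))
  TT <- Estd[pop_i, 1]; OO <- Estd[pop_i, 2]; DD <- Estd[pop_i, 3]
  g <- as.numeric(Ls %*% rnorm(npop, sd = sqrt(tp$var_gen)))
  cc <- rnorm(npop, sd = sqrt(tp$var_cave))
  z <- tp$alpha + tp$beta_L * L +
    tp$beta_T * TT + tp$beta_O * OO + tp$beta_D * DD +
    (tp$delta_T * TT + tp$delta_O * OO + tp$delta_D * DD) * L +
    g[pop_i] + cc[pop_i] + rnorm(n, sd = sqrt(tp$var_resid))
  beta_env <- c(tp$beta_T, tp$beta_O, tp$beta_D)
  var_env <- as.numeric(t(beta_env) %*% cov(Estd) %*% beta_env)
  sigma_t2 <- var_env + tp$var_gen + tp$var_cave
  truth <- list(var_env = var_env, var_gen = tp$var_gen,
                var_cave = tp$var_cave, var_resid = tp$var_resid,
                E = var_env / sigma_t2, G = tp$var_gen / sigma_t2,
                O = tp$var_cave / sigma_t2,
                g_effects = g, c_effects = cc)
  out <- data.frame(ind = paste0(pop, "_", sequence(rep(n_per_pop, npop))),
                    pop = pop, trait = z, fork_length = fl,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  out
}
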