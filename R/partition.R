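# Partition of among-population phenotypic variance into environment (E),
# genetic structure (G) and other (O) components, with repeatabilities.

#' Fixed-effect environmental variance
#'
#' Quadratic form `var_env = beta' Cov_E beta`, where `Cov_E` is the
#' covariance matrix of the standardized population-level covariates across
#' populations (each population weighted equally) and `beta` the three
#' environmental partial coefficients (temperature, openings, distance).
#'
#' @param beta Numeric vector of the three environmental coefficients.
#' @param env_std Matrix of standardized covariates, one row per population.
#' @return Numeric variance.
#' @export
env_variance <- function(beta, env_std) {
  beta <- as.numeric(beta)
  env_std <- as.matrix(env_std)
  if (length(beta) != ncol(env_std))
    stop("beta length must match number of covariates")
  as.numeric(t(beta) %*% cov(env_std) %*% beta)
}

#' Partition among-population variance from a fitted mixed model
#'
#' Components: `var_env` (fixed-effect quadratic form), `var_gen`
#' (similarity-structured intercept variance), `var_cave` (independent
#' intercept variance). The among-population total is
#' `sigma_t2 = var_env + var_gen + var_cave`; the grand total adds the
#' residual. Proportions `E`, `G`, `O` divide by `sigma_t2` and sum to 1
#' exactly. Random-slope variances are reported but excluded from the
#' partition. Repeatability (total) is `sigma_t2 / sigma_T2`; the
#' conditional repeatability is `(var_gen + var_cave) / sigma_T2`.
#'
#' The naive plug-in quadratic form `beta_hat' Cov_E beta_hat` is inflated
#' by the sampling variance of the coefficients (by `tr(Cov_E Var(beta_hat))`
#' in expectation); with few populations this visibly overstates the
#' environmental share, so the trace term is subtracted by default and the
#' result floored at zero.
#'
#' @param fit A `varpart_fit` from [fit_mixed_model()].
#' @param bias_correct Subtract the quadratic-form sampling bias of
#'   `var_env` (default `TRUE`).
#' @return A `variance_partition` list.
#' @export
partition_variance <- function(fit, bias_correct = TRUE) {
  spec <- fit$spec
  envb <- fit$beta[c("T", "O", "D")]
  var_env <- env_variance(envb, spec$env_std)
  if (bias_correct && !is.null(fit$vcov_beta)) {
    covE <- cov(spec$env_std)
    var_env <- max(var_env -
                     sum(covE * fit$vcov_beta[c("T", "O", "D"),
                                              c("T", "O", "D")]), 0)
  }
  sigma_t2 <- var_env + fit$var_gen + fit$var_cave
  sigma_T2 <- sigma_t2 + fit$var_resid
  if (sigma_t2 <= 0) {
    warning("zero among-population variance: proportions undefined")
    E <- G <- O <- NA_real_
  } else {
    E <- var_env / sigma_t2
    G <- fit$var_gen / sigma_t2
    O <- fit$var_cave / sigma_t2
  }
  structure(list(var_env = var_env, var_gen = fit$var_gen,
                 var_cave = fit$var_cave, var_resid = fit$var_resid,
                 sigma_t2 = sigma_t2, sigma_T2 = sigma_T2,
                 E = E, G = G, O = O,
                 repeatability_total = sigma_t2 / sigma_T2,
                 repeatability_conditional =
                   (fit$var_gen + fit$var_cave) / sigma_T2),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Among-population variance partition:\n"))
  cat(sprintf("  E (environment)       %.3f\n", x$E))
  cat(sprintf("  G (genetic structure) %.3f\n", x$G))
  cat(sprintf("  O (other)             %.3f\n", x$O))
  cat(sprintf("  repeatability total %.3f, conditional %.3f\n",
              x$repeatability_total, x$repeatability_conditional))
  invisible(x)
}

# Simulate a response vector from a fitted model (parametric bootstrap draw).
simulate_from_fit <- function(fit) {
  spec <- fit$spec
  des <- varpart_design(spec)
  mu <- as.numeric(des$X %*% fit$beta)
  npop <- length(spec$pops)
  g <- as.numeric(des$Ls %*% rnorm(npop, sd = sqrt(max(fit$var_gen, 0))))
  cc <- rnorm(npop, sd = sqrt(max(fit$var_cave, 0)))
  gb <- as.numeric(des$Ls %*% rnorm(npop, sd = sqrt(max(fit$var_gen_slope, 0))))
  cb <- rnorm(npop, sd = sqrt(max(fit$var_cave_slope, 0)))
  pi_ <- as.integer(spec$pop)
  mu + g[pi_] + cc[pi_] + (gb[pi_] + cb[pi_]) * spec$L +
    rnorm(spec$n, sd = sqrt(fit$var_resid))
}

#' Parametric-bootstrap uncertainty for the variance partition
#'
#' Responses are simulated from the fitted model, the model refitted and
#' the partition recomputed; percentile 95 percent intervals are returned
#' for every partition quantity. Errors out if more than 20 percent of the
#' bootstrap refits fail.
#'
#' @param fit A `varpart_fit`.
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed RNG seed.
#' @return List with `intervals` (quantity x c(lower, upper)), the point
#'   `estimate` and the matrix of bootstrap `draws`.
#' @export
partition_uncertainty <- function(fit, n_boot = 200, seed = 1) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  set.seed(seed)
  point <- partition_variance(fit)
  quantities <- c("var_env", "var_gen", "var_cave", "var_resid",
                  "E", "G", "O",
                  "repeatability_total", "repeatability_conditional")
  draws <- matrix(NA_real_, n_boot, length(quantities),
                  dimnames = list(NULL, quantities))
  fails <- 0
  for (b in seq_len(n_boot)) {
    yb <- simulate_from_fit(fit)
    spb <- fit$spec
    spb$response <- yb
    fb <- tryCatch(fit_mixed_model(spb, include = fit$include,
                                   n_starts = 2, seed = b),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fb)) { fails <- fails + 1; next }
    pb <- suppressWarnings(partition_variance(fb))
    draws[b, ] <- unlist(pb[quantities])
  }
  if (fails > 0.2 * n_boot)
    stop("more than 20% of bootstrap refits failed (", fails, "/", n_boot, ")")
  ints <- t(apply(draws, 2, quantile, c(0.025, 0.975), na.rm = TRUE))
  colnames(ints) <- c("lower", "upper")
  list(intervals = ints, estimate = point, draws = draws, n_failed = fails)
}

#' Variance partition for a set of shape traits
#'
#' Runs the full mixed-model partition for each selected principal component
#' score, skipping any trait in the exclusion list (e.g. digitization
#' artefact components).
#'
#' @param scores Matrix or data frame of trait columns (e.g. PC scores).
#' @param pop Population labels per row of `scores`.
#' @param length_cov Individual covariate (fork length) per row.
#' @param env Population-level covariate table (see [varpart_spec()]).
#' @param S Similarity matrix over populations.
#' @param traits Character vector of trait column names to partition.
#' @param exclude Traits to drop from `traits` (default none).
#' @param include Random terms passed to [fit_mixed_model()].
#' @param seed RNG seed.
#' @return Data frame, one row per trait, with variance components,
#'   proportions and repeatabilities.
#' @export
run_partition_suite <- function(scores, pop, length_cov, env, S,
                                traits, exclude = character(0),
                                include = c("gen_int", "cave_int",
                                            "gen_slope", "cave_slope"),
                                seed = 1) {
  traits <- setdiff(traits, exclude)
  if (length(traits) == 0) stop("no traits selected")
  missing <- setdiff(traits, colnames(scores))
  if (length(missing)) stop("traits not found: ",
                            paste(missing, collapse = ", "))
  rows <- lapply(traits, function(tr) {
    spec <- varpart_spec(scores[, tr], pop, length_cov, env, S)
    fit <- fit_mixed_model(spec, include = include, seed = seed)
    pv <- partition_variance(fit)
    data.frame(trait = tr, var_env = pv$var_env, var_gen = pv$var_gen,
               var_cave = pv$var_cave, var_resid = pv$var_resid,
               E = pv$E, G = pv$G, O = pv$O,
               repeatability_total = pv$repeatability_total,
               repeatability_conditional = pv$repeatability_conditional,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
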