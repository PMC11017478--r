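test_that("similarity map handles degenerate and random distances", {
  z <- dist_matrix(matrix(0, 3, 3), letters[1:3])
  expect_warning(S0 <- similarity_from_distance(z), "indistinguishable")
  expect_equal(unclass(S0), matrix(1, 3, 3), ignore_attr = TRUE)
  m <- matrix(c(0, 1, .5, 1, 0, .5, .5, .5, 0), 3)
  S <- similarity_from_distance(dist_matrix(m, letters[1:3]))
  expect_equal(unname(S["a", "b"]), 0, tolerance = 1e-8)  # maximal distance
  expect_equal(unname(diag(S)), rep(1, 3))
  set.seed(4)
  r <- matrix(runif(400, 0, 2), 20); r <- (r + t(r)) / 2; diag(r) <- 0
  Sr <- similarity_from_distance(dist_matrix(r, paste0("p", 1:20)))
  expect_gte(min(eigen(Sr, symmetric = TRUE)$values), -1e-10)
  expect_equal(unname(diag(Sr)), rep(1, 20))
})

test_that("environmental variance equals the brute-force quadratic form", {
  env_std <- scale(matrix(rnorm(72), 24, 3) %*%
                     matrix(c(1, .5, 0, 0, 1, .4, 0, 0, 1), 3))
  expect_equal(env_variance(c(0, 0, 0), env_std), 0)
  id <- scale(matrix(rnorm(300), 100, 3))
  # beta (1,0,0) with near-identity covariance: variance 1 exactly by
  # construction of the first standardized column
  expect_equal(env_variance(c(1, 0, 0), id), 1, tolerance = 1e-12)
  beta <- c(0.5, -0.3, 0.2)
  expect_equal(env_variance(beta, env_std),
               var(as.numeric(env_std %*% beta)), tolerance = 1e-12)
  expect_error(env_variance(c(1, 0), env_std), "match")
})

test_that("REML fit agrees with lme4 for the random-intercept special case", {
  skip_if_not_installed("lme4")
  set.seed(11)
  npop <- 12
  env <- simulate_environment(npop, seed = 4)
  tp <- trait_params_for_proportions(0.3, 0, 0.7, sigma_t2 = 0.8)
  ph <- suppressWarnings(
    simulate_phenotypes(diag(npop), env, 15, tp, seed = 5))
  spec <- varpart_spec(ph$trait, ph$pop, ph$fork_length,
                       env[, c("pop", "temperature", "openings", "distance")])
  fit <- fit_mixed_model(spec, include = "cave_int")
  pi_ <- as.integer(factor(ph$pop, levels = spec$pops))
  d <- data.frame(y = ph$trait, pop = ph$pop, L = spec$L,
                  T = spec$env_std[pi_, 1], O = spec$env_std[pi_, 2],
                  D = spec$env_std[pi_, 3])
  m <- lme4::lmer(y ~ L + T + O + D + T:L + O:L + D:L + (1 | pop),
                  data = d, REML = TRUE)
  expect_equal(fit$var_cave, as.numeric(lme4::VarCorr(m)$pop),
               tolerance = 1e-6)
  expect_equal(fit$var_resid, sigma(m)^2, tolerance = 1e-6)
  expect_equal(fit$reml_loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)[
    c("(Intercept)", "L", "T", "O", "D", "L:T", "L:O", "L:D")]),
    tolerance = 1e-6)
})

test_that("the restricted likelihood is locally optimal at the fit", {
  set.seed(21)
  env <- simulate_environment(10, seed = 14)
  cl <- sort(rep_len(1:3, 10))
  S <- outer(cl, cl, function(a, b) ifelse(a == b, 0.7, 0.1)); diag(S) <- 1
  dimnames(S) <- list(env$pop, env$pop)
  ph <- simulate_phenotypes(S, env, 12, trait_params_for_proportions(),
                            seed = 15)
  spec <- varpart_spec(ph$trait, ph$pop, ph$fork_length,
                       env[, c("pop", "temperature", "openings", "distance")],
                       S)
  fit <- fit_mixed_model(spec, include = c("gen_int", "cave_int"))
  crit_opt <- cavecharr:::reml_criterion(fit, fit$theta)
  set.seed(3)
  for (k in 1:20) {
    expect_gte(cavecharr:::reml_criterion(
      fit, runif(length(fit$theta), -8, 4)) + 1e-8, crit_opt)
  }
})

test_that("fixed effects are invariant to duplicating every individual", {
  set.seed(31)
  env <- simulate_environment(8, seed = 24)
  ph <- suppressWarnings(simulate_phenotypes(
    diag(8), env, 10, trait_params_for_proportions(0.5, 0, 0.5), seed = 25))
  mk <- function(ph) {
    spec <- varpart_spec(ph$trait, ph$pop, ph$fork_length,
                         env[, c("pop", "temperature", "openings",
                                 "distance")])
    fit_mixed_model(spec, include = "cave_int")
  }
  f1 <- mk(ph)
  f2 <- mk(rbind(ph, ph))
  # duplication rebalances the between/within weighting slightly, so the
  # generalized-least-squares estimates agree closely but not bit-for-bit
  expect_lt(max(abs(f1$beta - f2$beta)), 0.02)
})

test_that("a null simulation leaves little among-population variance", {
  set.seed(41)
  vals <- replicate(20, {
    env <- simulate_environment(12, seed = sample.int(1e6, 1))
    tp <- trait_params_for_proportions(0, 0, 1, sigma_t2 = 0)
    tp$beta_L <- 0
    ph <- suppressWarnings(simulate_phenotypes(diag(12), env, 20, tp,
                                               seed = sample.int(1e6, 1)))
    spec <- varpart_spec(ph$trait, ph$pop, ph$fork_length,
                         env[, c("pop", "temperature", "openings",
                                 "distance")])
    fit <- suppressWarnings(
      fit_mixed_model(spec, include = c("gen_int", "cave_int")))
    (fit$var_gen + fit$var_cave) / fit$var_resid
  })
  expect_lt(median(vals), 0.05)
})

test_that("variance partition proportions are exact bookkeeping", {
  set.seed(51)
  env <- simulate_environment(12, seed = 34)
  cl <- sort(rep_len(1:4, 12))
  S <- outer(cl, cl, function(a, b) ifelse(a == b, 0.8, 0.1)); diag(S) <- 1
  dimnames(S) <- list(env$pop, env$pop)
  ph <- simulate_phenotypes(S, env, 15, trait_params_for_proportions(),
                            seed = 35)
  spec <- varpart_spec(ph$trait, ph$pop, ph$fork_length,
                       env[, c("pop", "temperature", "openings", "distance")],
                       S)
  fit <- fit_mixed_model(spec, include = c("gen_int", "cave_int"))
  pv <- partition_variance(fit)
  expect_equal(pv$E + pv$G + pv$O, 1, tolerance = 1e-12)
  expect_true(all(c(pv$E, pv$G, pv$O) >= 0))
  expect_equal(pv$sigma_t2, pv$var_env + pv$var_gen + pv$var_cave)
  expect_true(pv$repeatability_total >= 0 && pv$repeatability_total <= 1)
  expect_gte(pv$repeatability_total, pv$repeatability_conditional)
  # pure independent-cave truth: the partition mass lands on O
  env24 <- simulate_environment(24, seed = 37)
  tp0 <- trait_params_for_proportions(0, 0, 1)
  S24 <- diag(24); dimnames(S24) <- list(env24$pop, env24$pop)
  ph0 <- simulate_phenotypes(S24, env24, 40, tp0, seed = 37)
  spec0 <- varpart_spec(ph0$trait, ph0$pop, ph0$fork_length,
                        env24[, c("pop", "temperature", "openings",
                                  "distance")])
  fit0 <- suppressWarnings(fit_mixed_model(spec0, include = "cave_int"))
  pv0 <- partition_variance(fit0)
  expect_gt(pv0$O, 0.6)
  expect_lt(pv0$G, 0.2)
})

test_that("generated phenotype truth matches its configuration exactly", {
  env <- simulate_environment(24, seed = 44)
  cl <- sort(rep_len(1:5, 24))
  S <- outer(cl, cl, function(a, b) ifelse(a == b, 0.7, 0)); diag(S) <- 1
  dimnames(S) <- list(env$pop, env$pop)
  ph <- simulate_phenotypes(S, env, 10,
                            trait_params_for_proportions(0.4, 0.4, 0.2),
                            seed = 45)
  tr <- attr(ph, "truth")
  expect_equal(c(tr$E, tr$G, tr$O), c(0.4, 0.4, 0.2), tolerance = 1e-12)
  expect_equal(tr$E + tr$G + tr$O, 1, tolerance = 1e-12)
  # identity S with genetic variance flags the confound
  expect_warning(simulate_phenotypes(diag(24), env, 5,
                                     trait_params_for_proportions(),
                                     seed = 46), "confounded")
  # pure-residual configuration: among-population variance is tiny
  tpr <- trait_params_for_proportions(0, 0, 1, sigma_t2 = 0)
  tpr$beta_L <- 0
  phr <- suppressWarnings(simulate_phenotypes(diag(24), env, 200, tpr,
                                              seed = 47))
  gm <- tapply(phr$trait, phr$pop, mean)
  expect_lt(var(gm), 3 * 1 / 200)  # between-group variance ~ var_resid / n
  # unit environmental effect on standardized covariate: Var(z) near 1
  tp1 <- trait_params_for_proportions(1, 0, 0)
  tp1$beta_L <- 0; tp1$var_resid <- 0
  ph1 <- simulate_phenotypes(diag(24), env, 5, tp1, seed = 48)
  expect_equal(var(tapply(ph1$trait, ph1$pop, mean)), 1, tolerance = 1e-9)
})

test_that("bootstrap intervals bracket the point partition reproducibly", {
  set.seed(61)
  env <- simulate_environment(10, seed = 54)
  cl <- sort(rep_len(1:3, 10))
  S <- outer(cl, cl, function(a, b) ifelse(a == b, 0.7, 0.1)); diag(S) <- 1
  dimnames(S) <- list(env$pop, env$pop)
  ph <- simulate_phenotypes(S, env, 12, trait_params_for_proportions(),
                            seed = 55)
  spec <- varpart_spec(ph$trait, ph$pop, ph$fork_length,
                       env[, c("pop", "temperature", "openings", "distance")],
                       S)
  fit <- fit_mixed_model(spec, include = c("gen_int", "cave_int"))
  pu <- partition_uncertainty(fit, n_boot = 100, seed = 7)
  pv <- partition_variance(fit)
  for (q in c("E", "G", "O")) {
    expect_gte(pv[[q]], pu$intervals[q, "lower"] - 1e-9)
    expect_lte(pv[[q]], pu$intervals[q, "upper"] + 1e-9)
  }
  pu2 <- partition_uncertainty(fit, n_boot = 100, seed = 7)
  expect_equal(pu$intervals, pu2$intervals)
  expect_error(partition_uncertainty(fit, n_boot = 50), "100")
})

test_that("the partition suite runs per trait and honours exclusions", {
  set.seed(71)
  env <- simulate_environment(8, seed = 64)
  S <- diag(8); dimnames(S) <- list(env$pop, env$pop)
  scores <- matrix(rnorm(8 * 20 * 4), 160, 4,
                   dimnames = list(NULL, paste0("PC", 1:4)))
  pop <- rep(env$pop, each = 20)
  fl <- rnorm(160, 70, 10)
  out <- suppressWarnings(run_partition_suite(
    scores, pop, fl, env[, c("pop", "temperature", "openings", "distance")],
    S, traits = c("PC1", "PC2", "PC3"), exclude = "PC2",
    include = "cave_int"))
  expect_equal(out$trait, c("PC1", "PC3"))
  out2 <- suppressWarnings(run_partition_suite(
    scores, pop, fl, env[, c("pop", "temperature", "openings", "distance")],
    S, traits = c("PC1", "PC3"), include = "cave_int"))
  expect_equal(out, out2)
  expect_error(run_partition_suite(scores, pop, fl, env, S,
                                   traits = "PC9"), "not found")
  expect_error(run_partition_suite(scores, pop, fl, env, S,
                                   traits = character(0)), "no traits")
})
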