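test_that("source frequencies are normalized, reproducible Dirichlet draws", {
  loci <- data.frame(name = paste0("L", 1:9),
                     n_alleles = rep(c(4L, 6L, 8L), 3), concentration = 1)
  f1 <- simulate_source_frequencies(loci, seed = 5)
  expect_length(f1, 9)
  for (fv in f1) expect_equal(sum(fv), 1, tolerance = 1e-12)
  expect_identical(f1, simulate_source_frequencies(loci, seed = 5))
  one <- data.frame(name = "L1", n_alleles = 2L, concentration = 3)
  fv <- simulate_source_frequencies(one, seed = 2)$L1
  expect_equal(sum(fv), 1, tolerance = 1e-12)
  bad <- data.frame(name = "L1", n_alleles = 2L, concentration = 0)
  expect_error(simulate_source_frequencies(bad), "positive")
  bad2 <- data.frame(name = "L1", n_alleles = 1L, concentration = 1)
  expect_error(simulate_source_frequencies(bad2), "2 alleles")
})

test_that("colonization keeps frequencies normalized and reproducible", {
  cfg <- sim_config(n_populations = 6, pop_size = 30, generations = 10,
                    n_clusters = 2, seed = 3)
  src <- simulate_source_frequencies(cfg$loci, 3)
  col <- simulate_colonization(src, cfg, seed = 4)
  for (l in names(col$truth$terminal_freqs)) {
    expect_equal(unname(rowSums(col$truth$terminal_freqs[[l]])),
                 rep(1, 6), tolerance = 1e-12)
    for (g in seq_along(col$truth$trajectory[[l]])) {
      expect_equal(unname(rowSums(col$truth$trajectory[[l]][[g]])),
                   rep(1, 6), tolerance = 1e-12)
    }
  }
  expect_s3_class(col$genotypes, "genotype_table")
  expect_equal(n_ind(col$genotypes), 6 * 30)
  col2 <- simulate_colonization(src, cfg, seed = 4)
  expect_identical(col$genotypes$alleles, col2$genotypes$alleles)
  expect_equal(unclass(col$truth$similarity),
               t(unclass(col$truth$similarity)), ignore_attr = TRUE)
  expect_equal(unname(diag(col$truth$similarity)), rep(1, 6))
})

test_that("without drift generations the gene pool tracks the source", {
  # founders = pop_size and zero generations: sampled genotype frequencies
  # match the source in expectation (averaged over many populations)
  cfg <- sim_config(n_populations = 40, pop_size = 50, founders_per_pop = 50,
                    generations = 0, n_clusters = 1, seed = 6,
                    loci = data.frame(name = "L1", n_alleles = 4L,
                                      concentration = 5))
  src <- simulate_source_frequencies(cfg$loci, 11)
  col <- simulate_colonization(src, cfg, seed = 12)
  pooled <- colMeans(col$truth$terminal_freqs$L1)
  se <- sqrt(src$L1 * (1 - src$L1) / (40 * 100))
  expect_true(all(abs(pooled - src$L1) < 4 * se + 1e-3))
})

test_that("migration homogenizes connected population pairs", {
  base <- list(n_populations = 4, pop_size = 25, founders_per_pop = 25,
               generations = 50, n_clusters = 1)
  mig <- data.frame(pop_a = 1L, pop_b = 2L, migrants = 19L)
  th <- sapply(1:8, function(r) {
    cfg <- do.call(sim_config, c(base, list(migration_pairs = mig,
                                            seed = 100 + r)))
    src <- simulate_source_frequencies(cfg$loci, 200 + r)
    col <- simulate_colonization(src, cfg, seed = 300 + r)
    con <- wc_theta(subset_pops(col$genotypes, c("pop1", "pop2")))
    iso <- wc_theta(subset_pops(col$genotypes, c("pop3", "pop4")))
    c(connected = con, isolated = iso)
  })
  expect_lt(mean(th["connected", ]), mean(th["isolated", ]))
  expect_lt(mean(th["connected", ]), 0.1)
})

test_that("environments follow the configured field distributions", {
  env <- simulate_environment(24, seed = 8)
  expect_equal(nrow(env), 24)
  expect_true(all(env$openings %in% 1:7))
  expect_true(all(env$distance >= 57 & env$distance <= 500))
  expect_true(all(c("temperature", "openings", "distance", "lat", "lon")
                  %in% names(env)))
  expect_length(unique(env$area), 2)
  expect_identical(env, simulate_environment(24, seed = 8))
  rz <- list(temp_mean = 5.52, temp_sd = 0, openings_range = c(3L, 3L),
             distance_range = c(100, 100))
  envz <- simulate_environment(10, rz, seed = 9)
  expect_setequal(attr(envz, "constant_columns"),
                  c("temperature", "openings", "distance"))
})

test_that("landmark generation is template plus basis deformation", {
  ph0 <- data.frame(ind = paste0("i", 1:4), pop = "p1", trait = 0,
                    fork_length = 70)
  lms0 <- simulate_landmarks(ph0, noise_sd = 0, seed = 4)
  expect_equal(lms0$k, 21)
  ss0 <- gpa(lms0, slide = FALSE)
  # zero trait, zero noise: every configuration is similarity-equivalent
  # to the template
  tpl <- fish_template()$coords
  tpl <- sweep(tpl, 2, colMeans(tpl)); tpl <- tpl / sqrt(sum(tpl^2))
  arr <- array(NA_real_, c(2, 21, 2))
  arr[1, , ] <- ss0$aligned[1, , ]; arr[2, , ] <- tpl
  both <- gpa(landmark_set(arr), slide = FALSE)
  expect_lt(procrustes_distance(both$aligned[1, , ], both$aligned[2, , ]),
            1e-9)
  bad_basis <- matrix(rnorm(42 * 2), 42, 2)
  expect_error(simulate_landmarks(ph0, basis = bad_basis), "orthonormal")
})

test_that("the full synthetic system runs and writes readable artefacts", {
  cfg <- sim_config(n_populations = 5, pop_size = 20, generations = 5,
                    n_clusters = 2, n_per_pop = 8, seed = 17)
  sim <- simulate_cave_system(cfg)
  expect_equal(nlevels(sim$genotypes$pop), 5)
  expect_equal(nrow(sim$phenotypes), 40)
  expect_equal(sim$landmarks$n, 40)
  tr <- attr(sim$phenotypes, "truth")
  expect_equal(tr$E + tr$G + tr$O, 1, tolerance = 1e-12)
  sim2 <- simulate_cave_system(cfg)
  expect_identical(sim$phenotypes$trait, sim2$phenotypes$trait)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "genotypes.gen")))
  back <- read_genepop(file.path(dir, "genotypes.gen"))
  expect_equal(nlevels(back$pop), 5)
  expect_equal(unname(back$alleles), unname(sim$genotypes$alleles))
  lback <- read_tps(file.path(dir, "landmarks.tps"))
  expect_equal(lback$coords, sim$landmarks$coords, tolerance = 1e-9)
})
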