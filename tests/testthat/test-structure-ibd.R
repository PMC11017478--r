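test_that("neighbour joining is exact on 3 taxa and additive distances", {
  d <- dist_matrix(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3),
                   c("A", "B", "C"))
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  # additive 5-taxon distances: exact topology and branch lengths
  set.seed(5)
  tree0 <- ape::rtree(5, br = function(n) runif(n, 0.2, 1))
  d5 <- ape::cophenetic.phylo(tree0)
  tr5 <- neighbor_joining(dist_matrix(d5))
  back <- ape::cophenetic.phylo(tr5)[rownames(d5), colnames(d5)]
  expect_lt(max(abs(back - d5)), 1e-10)
  expect_equal(ape::dist.topo(ape::unroot(tree0), tr5), 0,
               ignore_attr = TRUE)
  # agreement with an independent implementation on a random matrix
  set.seed(9)
  m <- matrix(runif(49, 0.1, 1), 7); m <- (m + t(m)) / 2; diag(m) <- 0
  dm <- dist_matrix(m, LETTERS[1:7])
  mine <- neighbor_joining(dm)
  apes <- ape::nj(as.dist(unclass(dm)))
  expect_equal(ape::dist.topo(mine, ape::unroot(apes)), 0,
               ignore_attr = TRUE)
})

test_that("degenerate equal distances resolve deterministically", {
  d <- dist_matrix(matrix(1, 4, 4) - diag(4), letters[1:4])
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("bootstrap consensus supports separate simulated clusters", {
  # two divergent population groups built from fixed allele pools
  set.seed(21)
  n_loci <- 8
  mk_pop <- function(base) {
    t(replicate(12, sample(base, n_loci * 2, replace = TRUE)))
  }
  arr <- array(NA_integer_, c(48, n_loci, 2),
               dimnames = list(NULL, paste0("L", 1:n_loci), NULL))
  pops <- rep(c("a1", "a2", "b1", "b2"), each = 12)
  for (i in 1:4) {
    base <- if (i <= 2) 1:2 else 3:4
    rows <- (i - 1) * 12 + 1:12
    g <- mk_pop(base)
    arr[rows, , 1] <- g[, seq_len(n_loci)]
    arr[rows, , 2] <- g[, n_loci + seq_len(n_loci)]
  }
  gt <- genotype_table(paste0("i", 1:48), pops, arr)
  bc <- bootstrap_consensus(gt, n_boot = 200, seed = 3)
  sup <- bc$supports[!is.na(bc$supports)]
  expect_gt(max(sup), 90)  # the a-vs-b bipartition
  # reproducibility under a fixed seed
  bc2 <- bootstrap_consensus(gt, n_boot = 200, seed = 3)
  expect_equal(bc$supports, bc2$supports)
  # a single locus makes every replicate identical
  gt1 <- genotype_table(gt$ind, gt$pop, gt$alleles[, 1, , drop = FALSE])
  expect_warning(bc1 <- bootstrap_consensus(gt1, n_boot = 100, seed = 1),
                 "fewer than 2 loci")
  expect_true(all(bc1$supports[!is.na(bc1$supports)] == 100))
})

test_that("degree-decimal-minute coordinates parse and distances are great-circle", {
  expect_equal(parse_coord("65°34′802″"), 65.58003, tolerance = 1e-7)
  coords <- data.frame(pop = c("x", "y"), lat = c(65, 66), lon = c(17, 17))
  d <- geographic_distances(coords)
  expect_equal(unname(d["x", "y"]), 111.19, tolerance = 1e-3)
  same <- data.frame(pop = c("x", "y"), lat = c(65, 65), lon = c(17, 17))
  expect_equal(unname(geographic_distances(same)["x", "y"]), 0)
  bad <- data.frame(pop = c("x", "y"), lat = c("65°34′802″", "junk"),
                    lon = c("17°03′032″", "17°03′035″"))
  expect_error(geographic_distances(bad), "2")
})

test_that("survey coordinates from the field table yield sane distances", {
  path <- system.file("extdata", "cave_survey.csv", package = "cavecharr")
  surv <- read.csv(path, check.names = FALSE)
  caves <- surv[complete.cases(surv$lat) & surv$lat != "", ]
  d <- geographic_distances(data.frame(pop = caves$cave, lat = caves$lat,
                                       lon = caves$lon))
  expect_true(all(d[lower.tri(d)] >= 0))
  expect_lt(max(d[caves$area == "H", caves$area == "H"]), 10)
})

test_that("Mantel statistics hit their exact limits and match vegan", {
  set.seed(12)
  m <- matrix(runif(100), 10); m <- (m + t(m)) / 2; diag(m) <- 0
  a <- dist_matrix(m, letters[1:10])
  r1 <- mantel(a, a, n_perm = 99)
  expect_equal(r1$r, 1)
  b <- dist_matrix(2 * max(m) - unclass(a), letters[1:10])
  diag(b) <- 0
  expect_equal(mantel(a, dist_matrix(b), n_perm = 99,
                      tail = "two-sided")$r, -1)
  # statistic agrees with the vegan implementation
  set.seed(3)
  m2 <- matrix(runif(100), 10); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  bm <- dist_matrix(m2, letters[1:10])
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(unclass(a)), as.dist(unclass(bm)),
                      permutations = 0)
  expect_equal(mantel(a, bm, n_perm = 99)$r, unname(vg$statistic),
               tolerance = 1e-12)
})

test_that("partial Mantel residualizes on the conditioning matrix", {
  set.seed(14)
  m <- function() {
    x <- matrix(runif(144), 12); x <- (x + t(x)) / 2; diag(x) <- 0
    dist_matrix(x, letters[1:12])
  }
  a <- m(); b <- m(); cc <- m()
  skip_if_not_installed("vegan")
  vg <- vegan::mantel.partial(as.dist(unclass(a)), as.dist(unclass(b)),
                              as.dist(unclass(cc)), permutations = 0)
  expect_equal(partial_mantel(a, b, cc, n_perm = 99)$r,
               unname(vg$statistic), tolerance = 1e-12)
  # constant conditioning matrix reduces to the plain Mantel statistic
  k <- dist_matrix(matrix(1, 12, 12) - diag(12), letters[1:12])
  expect_equal(partial_mantel(a, b, k, n_perm = 99)$r,
               mantel(a, b, n_perm = 99)$r, tolerance = 1e-12)
  expect_error(partial_mantel(a, b, b, n_perm = 99), "collinear")
})

test_that("area coding and IBD transform behave as documented", {
  acm <- area_coding_matrix(c(p1 = "H", p2 = "H", p3 = "V"))
  expect_equal(acm[lower.tri(acm)], c(0, 1, 1))
  d <- dist_matrix(matrix(c(0, 0.5, 0.5, 0), 2), c("a", "b"))
  expect_equal(unname(ibd_transform(d)["a", "b"]), 1)
  expect_equal(unname(ibd_transform(dist_matrix(matrix(0, 2, 2),
                                                c("a", "b")))["a", "b"]), 0)
  dd <- matrix(c(0, 1, 1, 0), 2)
  expect_error(ibd_transform(dist_matrix(dd, c("a", "b"))), "1")
  # monotone: ranking of entries preserved
  set.seed(2)
  m <- matrix(runif(36, 0, 0.9), 6); m <- (m + t(m)) / 2; diag(m) <- 0
  dm <- dist_matrix(m, letters[1:6])
  ti <- ibd_transform(dm)
  expect_equal(order(ti[lower.tri(ti)]), order(dm[lower.tri(dm)]))
})
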