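# Landmark generation: a fish-like 21-landmark template deformed along
# shape basis vectors, then re-posed by random similarity transforms.

#' Default 21-landmark fish template
#'
#' 15 fixed landmarks and 6 sliding semilandmarks on a stylized charr
#' outline (body length 1). Sliders sit on four neighbour chains (dorsal
#' head, dorsal peduncle, ventral flank, lower jaw). The head subset used
#' for head-shape analyses is landmarks 1 and 13-21.
#'
#' @return List with `coords` (21 x 2), `sliders`, `curves`, `head_subset`.
#' @export
fish_template <- function() {
  coords <- matrix(c(
    0.00,  0.00,   # 1  snout tip
    0.12,  0.10,   # 2  top of head
    0.35,  0.14,   # 3  dorsal-fin origin
    0.55,  0.13,   # 4  dorsal-fin end
    0.80,  0.06,   # 5  dorsal peduncle
    0.95,  0.08,   # 6  upper caudal base
    1.00,  0.00,   # 7  fork
    0.95, -0.08,   # 8  lower caudal base
    0.80, -0.06,   # 9  ventral peduncle
    0.55, -0.12,   # 10 anal-fin end
    0.40, -0.13,   # 11 anal-fin origin
    0.22, -0.11,   # 12 pectoral-fin base
    0.10, -0.08,   # 13 lower head
    0.05, -0.03,   # 14 maxilla tip
    0.08,  0.03,   # 15 eye
    0.18,  0.12,   # 16 slider: dorsal head
    0.26,  0.13,   # 17 slider: dorsal head
    0.68,  0.095,  # 18 slider: dorsal peduncle
    0.33, -0.125,  # 19 slider: ventral flank
    0.28, -0.118,  # 20 slider: ventral flank
    0.075,-0.055), # 21 slider: lower jaw
    ncol = 2, byrow = TRUE)
  list(coords = coords,
       sliders = 16:21,
       curves = list(c(2L, 16L, 17L, 3L), c(4L, 18L, 5L),
                     c(11L, 19L, 20L, 12L), c(13L, 21L, 14L)),
       head_subset = c(1L, 13:21))
}

# Similarity-transform directions at a template (flattened x1..xk, y1..yk
# ordering is (x, y) interleaved per landmark to match aligned arrays).
similarity_directions <- function(template) {
  k <- nrow(template)
  ctr <- sweep(template, 2, colMeans(template))
  tx <- as.numeric(t(cbind(rep(1, k), rep(0, k))))
  ty <- as.numeric(t(cbind(rep(0, k), rep(1, k))))
  sc <- as.numeric(t(ctr))
  rot <- as.numeric(t(cbind(-ctr[, 2], ctr[, 1])))
  cbind(tx, ty, sc, rot)
}

#' Shape basis vectors orthogonal to similarity transforms
#'
#' Gram-Schmidt-orthonormalizes seeded random directions in the flattened
#' coordinate space against translation, scaling and rotation at the
#' template (and against each other), so that deformation along the basis
#' cannot leak into the nuisance transforms removed by superimposition.
#'
#' @param template `k x 2` coordinate matrix.
#' @param n_basis Number of basis vectors.
#' @param seed RNG seed.
#' @return `2k x n_basis` matrix with orthonormal columns.
#' @export
make_shape_basis <- function(template, n_basis = 2, seed = 99) {
  set.seed(seed)
  k <- nrow(template)
  nuis <- similarity_directions(template)
  nuis <- qr.Q(qr(nuis))
  out <- matrix(NA_real_, 2 * k, n_basis)
  for (j in seq_len(n_basis)) {
    v <- rnorm(2 * k)
    v <- v - nuis %*% crossprod(nuis, v)
    if (j > 1) {
      prev <- out[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    out[, j] <- v / sqrt(sum(v^2))
  }
  out
}

#' Simulate landmark configurations from phenotypes
#'
#' Each specimen is the template deformed by its (standardized) trait value
#' along the first basis vector and by its standardized fork length along
#' the second (allometry), plus isotropic Gaussian landmark noise, then
#' randomly rotated, translated and scaled. The true trait is recoverable
#' (up to sign) by GPA + PCA.
#'
#' @param phenotypes Data frame from [simulate_phenotypes()].
#' @param template List as from [fish_template()].
#' @param basis `2k x 2` orthonormal basis (default [make_shape_basis()]);
#'   an error is raised if the basis is not orthonormal and orthogonal to
#'   the template's similarity directions.
#' @param noise_sd Landmark noise SD as a fraction of template centroid
#'   size (default 0.01).
#' @param trait_scale,allometry_scale Deformation magnitudes (fraction of
#'   centroid size per SD of the covariate).
#' @param seed RNG seed.
#' @return A [landmark_set()].
#' @export
simulate_landmarks <- function(phenotypes, template = fish_template(),
                               basis = NULL, noise_sd = 0.01,
                               trait_scale = 0.05, allometry_scale = 0.02,
                               seed = 1) {
  set.seed(seed)
  tpl <- template$coords
  k <- nrow(tpl)
  if (is.null(basis)) basis <- make_shape_basis(tpl, 2)
  gram <- crossprod(basis)
  nuis <- qr.Q(qr(similarity_directions(tpl)))
  leak <- max(abs(crossprod(nuis, basis)))
  if (max(abs(gram - diag(ncol(basis)))) > 1e-8 || leak > 1e-8)
    stop("basis must be orthonormal and orthogonal to similarity directions")
  cs <- centroid_size(tpl)
  n <- nrow(phenotypes)
  z <- as.numeric(scale(phenotypes$trait))
  if (anyNA(z)) z <- rep(0, n)  # constant trait degenerates to template
  fl <- as.numeric(scale(phenotypes$fork_length))
  if (anyNA(fl)) fl <- rep(0, n)
  coords <- array(NA_real_, c(n, k, 2))
  for (i in seq_len(n)) {
    flat <- as.numeric(t(tpl)) +
      z[i] * trait_scale * cs * basis[, 1] +
      fl[i] * allometry_scale * cs * basis[, 2] +
      rnorm(2 * k, sd = noise_sd * cs)
    m <- matrix(flat, ncol = 2, byrow = TRUE)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sc <- exp(runif(1, -0.4, 0.4))
    shift <- runif(2, -2, 2)
    coords[i, , ] <- sweep(sc * m %*% R, 2, -shift)
  }
  landmark_set(coords, id = phenotypes$ind, pop = phenotypes$pop,
               fork_length = phenotypes$fork_length,
               sliders = template$sliders, curves = template$curves)
}
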