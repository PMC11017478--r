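# Shared helpers for labelled symmetric distance matrices.

#' Construct a labelled distance matrix
#'
#' Thin wrapper that validates and classes a symmetric non-negative matrix
#' with a zero diagonal, the common currency for genetic, geographic and
#' morphological distances in this package.
#'
#' @param m Square numeric matrix.
#' @param labels Optional character vector of row/column labels; defaults to
#'   the existing dimnames.
#' @return A `dist_matrix` object (a plain matrix with class attribute).
#' @export
dist_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (!is.null(labels)) {
    if (length(labels) != nrow(m)) stop("labels length must match dimension")
    dimnames(m) <- list(labels, labels)
  }
  if (is.null(rownames(m))) {
    dimnames(m) <- list(seq_len(nrow(m)), seq_len(nrow(m)))
  }
  if (any(is.na(m))) stop("distance matrix contains NA")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (any(m < -1e-12)) stop("distance matrix must be non-negative")
  m[m < 0] <- 0
  class(m) <- c("dist_matrix", "matrix")
  m
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix with", nrow(x), "labels\n")
  print(unclass(x), ...)
  invisible(x)
}

# Lower-triangle vector of a symmetric matrix (column-major, excludes diagonal).
lower_tri <- function(m) m[lower.tri(m)]

# Check two labelled matrices are conformable; reorder B to A's labels.
align_dist <- function(a, b, what = "matrices") {
  if (!setequal(rownames(a), rownames(b)))
    stop("label sets of ", what, " differ")
  b[rownames(a), rownames(a)]
}

# Deterministic child seeds derived from one root seed (kept below 2^31).
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
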