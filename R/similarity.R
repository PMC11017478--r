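# Distance-to-similarity map used to structure random-effect covariance.

#' Similarity matrix from a genetic distance matrix
#'
#' Maps a chord-distance (or other) matrix to a similarity matrix used to
#' structure the covariance of population random effects:
#' `S = 1 - D / max(D)` (linear, default) or `exp(-D / mean(D))`
#' (exponential kernel). The result is repaired to positive
#' semi-definiteness by raising eigenvalues below zero to 1e-8 and rescaling
#' to a unit diagonal; the method and the repair magnitude are recorded as
#' attributes.
#'
#' @param d A [dist_matrix()].
#' @param method `"linear"` or `"exponential"`.
#' @return Symmetric PSD matrix with unit diagonal and attributes `method`,
#'   `min_eigen_before`, `repaired`.
#' @export
similarity_from_distance <- function(d, method = c("linear", "exponential")) {
  method <- match.arg(method)
  d <- dist_matrix(d)
  m <- unclass(d)
  mx <- max(m)
  if (mx == 0) {
    warning("all distances are zero: populations indistinguishable, ",
            "returning all-ones similarity")
    S <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
    attr(S, "method") <- method
    attr(S, "min_eigen_before") <- 0
    attr(S, "repaired") <- FALSE
    return(S)
  }
  S <- switch(method,
              linear = 1 - m / mx,
              exponential = exp(-m / mean(m[upper.tri(m)])))
  diag(S) <- 1
  e <- eigen(S, symmetric = TRUE)
  min_ev <- min(e$values)
  repaired <- min_ev < 0
  if (repaired) {
    vals <- pmax(e$values, 1e-8)
    S <- e$vectors %*% (vals * t(e$vectors))
    dsc <- 1 / sqrt(diag(S))
    S <- S * tcrossprod(dsc)
  }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- dimnames(m)
  attr(S, "method") <- method
  attr(S, "min_eigen_before") <- min_ev
  attr(S, "repaired") <- repaired
  S
}
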