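# Generalized Procrustes analysis with sliding semilandmarks.

# Optimal rotation (reflection forbidden) aligning X onto target C.
procrustes_rotation <- function(X, C) {
  s <- svd(crossprod(X, C))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition: configurations are centred, scaled to unit
#' centroid size and rotated (SVD orthogonal Procrustes, reflection
#' forbidden) to the running consensus; declared semilandmarks slide along
#' the chord between their chain neighbours to minimise Procrustes distance
#' to the consensus at every outer iteration. Iteration stops when the
#' consensus moves less than `tol` (root summed squared change), when the
#' total Procrustes sum of squares stops decreasing (relative change below
#' `slide_tol`; the relevant criterion when sliding is active), or after
#' `max_iter` iterations. The final alignment is rotated to a canonical
#' orientation (consensus principal axes, deterministic sign), so the output
#' does not depend on the arbitrary pose of the input configurations.
#'
#' @param x A [landmark_set()] with at least 2 specimens and 3 landmarks.
#' @param tol Convergence tolerance on the consensus (default 1e-10).
#' @param max_iter Maximum outer iterations (default 100).
#' @param slide Slide semilandmarks (default `TRUE` when sliders declared).
#' @param slide_tol Relative decrease of the total Procrustes sum of squares
#'   below which the sliding superimposition is declared converged (the
#'   slider/consensus coordinate descent approaches its optimum only
#'   geometrically, so a looser criterion than `tol` is appropriate).
#' @return A `shape_space`: list with `aligned` (`n x k x 2`), `consensus`,
#'   `centroid_size` (original sizes), metadata carried from `x`, and an
#'   iteration log.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100,
                slide = length(x$sliders) > 0, slide_tol = 1e-4) {
  n <- x$n; k <- x$k
  if (n < 2 || k < 3) stop("need at least 2 specimens and 3 landmarks")
  conf <- vector("list", n)
  cs <- numeric(n)
  for (s in seq_len(n)) {
    m <- x$coords[s, , ]
    m <- sweep(m, 2, colMeans(m))
    cs[s] <- sqrt(sum(m^2))
    if (cs[s] < 1e-12)
      stop("degenerate (coincident) configuration for specimen ", x$id[s])
    conf[[s]] <- m / cs[s]
  }
  consensus <- conf[[1]]
  log_change <- log_Q <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (s in seq_len(n)) conf[[s]] <- conf[[s]] %*%
        procrustes_rotation(conf[[s]], consensus)
    if (slide && length(x$sliders)) {
      for (s in seq_len(n)) {
        m <- conf[[s]]
        for (ch in x$curves) {
          for (j in seq(2, length(ch) - 1)) {
            lm <- ch[j]
            if (!lm %in% x$sliders) next
            u <- m[ch[j + 1], ] - m[ch[j - 1], ]
            nu <- sqrt(sum(u^2))
            if (nu < 1e-12) next
            u <- u / nu
            m[lm, ] <- m[lm, ] + sum((consensus[lm, ] - m[lm, ]) * u) * u
          }
        }
        m <- sweep(m, 2, colMeans(m))
        m <- m / sqrt(sum(m^2))
        conf[[s]] <- m %*% procrustes_rotation(m, consensus)
      }
    }
    newcons <- Reduce(`+`, conf) / n
    newcons <- sweep(newcons, 2, colMeans(newcons))
    newcons <- newcons / sqrt(sum(newcons^2))
    change <- sqrt(sum((newcons - consensus)^2))
    Q <- sum(vapply(conf, function(m) sum((m - newcons)^2), numeric(1)))
    log_change <- c(log_change, change)
    consensus <- newcons
    # the slider/consensus coordinate descent converges only geometrically,
    # so with sliding active convergence is declared once the total
    # Procrustes sum of squares stops decreasing appreciably
    q_done <- slide && length(x$sliders) && it > 1 &&
      abs(log_Q[length(log_Q)] - Q) < slide_tol * max(Q, 1e-12)
    log_Q <- c(log_Q, Q)
    if (it > 1 && (change < tol || q_done)) break
  }
  # canonical orientation: consensus principal axes, sign fixed by the
  # landmark-index weighting so the pose is a function of shape alone
  ev <- eigen(cov(consensus), symmetric = TRUE)$vectors
  v1 <- ev[, 1]
  w <- seq_len(k) - (k + 1) / 2
  s1 <- sum(w * (consensus %*% v1))
  if (abs(s1) > 1e-12 && s1 < 0) v1 <- -v1
  R <- cbind(v1, c(-v1[2], v1[1]))
  conf <- lapply(conf, function(m) m %*% R)
  consensus <- consensus %*% R
  aligned <- array(NA_real_, c(n, k, 2))
  for (s in seq_len(n)) aligned[s, , ] <- conf[[s]]
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_size = cs, id = x$id, pop = x$pop,
                 fork_length = x$fork_length, n = n, k = k,
                 iterations = length(log_change), change = log_change,
                 procrustes_ss = log_Q),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("shape_space:", x$n, "aligned specimens,", x$k, "landmarks;",
      x$iterations, "GPA iterations (last change ",
      format(utils::tail(x$change, 1), digits = 3), ")\n")
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#' @param a,b `k x 2` coordinate matrices (already superimposed).
#' @return Square root of the summed squared coordinate differences.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

# Flatten aligned coordinates to an n x 2k matrix (x1, y1, x2, y2, ...).
flatten_shapes <- function(ss) {
  out <- matrix(NA_real_, ss$n, 2 * ss$k)
  for (s in seq_len(ss$n)) out[s, ] <- as.numeric(t(ss$aligned[s, , ]))
  rownames(out) <- ss$id
  out
}
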