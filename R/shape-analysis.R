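# Shape ordination, permutation linear models, discriminant classification,
# mean-shape disparity.

#' Principal component analysis of aligned shapes
#'
#' Covariance PCA of the flattened aligned coordinates. Scores are centred;
#' percent variance sums to 100 over the non-degenerate components; the sign
#' of each component is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param ss A `shape_space` from [gpa()].
#' @return List with `scores`, `loadings`, `percent` (variance percentages),
#'   `sdev` and `center`.
#' @export
shape_pca <- function(ss) {
  Y <- flatten_shapes(ss)
  if (nrow(Y) < 3) stop("need at least 3 specimens")
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  keep <- pc$sdev^2 > max(pc$sdev^2) * 1e-12
  scores <- pc$x[, keep, drop = FALSE]
  load <- pc$rotation[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]; scores[, j] <- -scores[, j]
    }
  }
  v <- pc$sdev[keep]^2
  list(scores = scores, loadings = load, percent = 100 * v / sum(v),
       sdev = sqrt(v), center = pc$center, pop = ss$pop,
       fork_length = ss$fork_length)
}

#' Procrustes linear model with permutation tests
#'
#' Sequential (type I) sums of squares of the flattened aligned coordinates
#' on the fixed term order `size`, `population`, `size:population`
#' regardless of how arguments are supplied. F per term is
#' `(SS/df) / (SS_res/df_res)`; p-values come from residual randomization
#' (permuting reduced-model residuals), add-one corrected;
#' `R^2 = SS_term / SS_total`.
#'
#' @param ss A `shape_space`.
#' @param size Numeric covariate per specimen (fork length for body models,
#'   centroid size for head models). Defaults to `ss$fork_length`.
#' @param pop Population factor; defaults to `ss$pop`.
#' @param interaction Include the size-by-population term (default `TRUE`).
#' @param n_perm Number of permutations (at least 99).
#' @param seed RNG seed.
#' @return A `procrustes_lm` data frame of per-term df, SS, MS, F, R2 and p,
#'   with residual and total rows.
#' @export
procrustes_lm <- function(ss, size = ss$fork_length, pop = ss$pop,
                          interaction = TRUE, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  set.seed(seed)
  Y <- flatten_shapes(ss)
  n <- nrow(Y)
  pop <- droplevels(factor(pop))
  if (anyNA(size)) stop("size covariate contains NA")
  if (interaction && any(table(pop) < 2))
    stop("every population needs at least 2 specimens for the interaction")
  sizec <- as.numeric(scale(size, scale = FALSE))
  Xint <- matrix(1, n, 1)
  Xp <- stats::model.matrix(~pop)[, -1, drop = FALSE]
  terms <- list(size = cbind(sizec), population = Xp)
  if (interaction) terms$`size:population` <- Xp * sizec
  dfs <- vapply(terms, ncol, integer(1))
  rss_of <- function(X, Yy) {
    f <- lm.fit(X, Yy)
    sum(f$residuals^2)
  }
  designs <- vector("list", length(terms) + 1)
  designs[[1]] <- Xint
  for (k in seq_along(terms))
    designs[[k + 1]] <- cbind(designs[[k]], terms[[k]])
  rss <- vapply(designs, rss_of, numeric(1), Yy = Y)
  ss_terms <- -diff(rss)
  ss_total <- rss[1]
  df_res <- n - ncol(designs[[length(designs)]])
  ss_res <- rss[length(rss)]
  ms_res <- ss_res / df_res
  Fv <- (ss_terms / dfs) / ms_res
  # residual randomization under the reduced model for each term
  pvals <- numeric(length(terms))
  for (k in seq_along(terms)) {
    fit_red <- lm.fit(designs[[k]], Y)
    fitted_red <- Y - fit_red$residuals
    res_red <- fit_red$residuals
    hits <- 0
    for (b in seq_len(n_perm)) {
      Yp <- fitted_red + res_red[sample.int(n), , drop = FALSE]
      ssb <- rss_of(designs[[k]], Yp) - rss_of(designs[[k + 1]], Yp)
      fb <- (ssb / dfs[k]) /
        ((rss_of(designs[[length(designs)]], Yp)) / df_res)
      if (fb >= Fv[k] - 1e-12) hits <- hits + 1
    }
    pvals[k] <- (hits + 1) / (n_perm + 1)
  }
  out <- data.frame(
    term = c(names(terms), "residual", "total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss_terms, ss_res, ss_total),
    MS = c(ss_terms / dfs, ms_res, NA),
    F = c(Fv, NA, NA),
    R2 = c(ss_terms / ss_total, ss_res / ss_total, 1),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("procrustes_lm", "data.frame")
  out
}

#' Discriminant classification of shapes
#'
#' Linear discriminant analysis on leading principal components of the
#' shapes (or on supplied score columns), with classification accuracy to
#' the a priori populations reported both by resubstitution and by
#' leave-one-out cross-validation.
#'
#' @param scores Numeric matrix of features (e.g. PCA scores) or a
#'   `shape_space` (then flattened coordinates are PCA-reduced internally).
#' @param pop Population factor.
#' @param n_components Number of leading components to use; default keeps
#'   enough to cover `var_cutoff` of the variance. Clipped with a warning if
#'   larger than available.
#' @param var_cutoff Variance fraction retained when `n_components` is NULL.
#' @return List with the lda fit, `axes`, per-group and mean accuracies for
#'   `resubstitution` and `loo`.
#' @export
dfa <- function(scores, pop, n_components = NULL, var_cutoff = 0.95) {
  pop <- droplevels(factor(pop))
  if (any(table(pop) < 2)) stop("every group needs at least 2 specimens")
  if (inherits(scores, "shape_space")) {
    pcres <- shape_pca(scores)
    scores <- pcres$scores
    cum <- cumsum(pcres$percent) / 100
    if (is.null(n_components)) n_components <- which(cum >= var_cutoff)[1]
  }
  scores <- as.matrix(scores)
  if (is.null(n_components)) n_components <- ncol(scores)
  if (n_components > ncol(scores)) {
    warning("n_components clipped to ", ncol(scores))
    n_components <- ncol(scores)
  }
  Xf <- scores[, seq_len(n_components), drop = FALSE]
  fit <- MASS::lda(Xf, grouping = pop)
  pred <- stats::predict(fit)$class
  loo <- MASS::lda(Xf, grouping = pop, CV = TRUE)$class
  acc <- function(cl) {
    tab <- table(pop, cl)
    per <- diag(tab) / rowSums(tab)
    list(per_group = per, mean = mean(per),
         overall = mean(cl == pop))
  }
  list(fit = fit, axes = fit$scaling, n_components = n_components,
       resubstitution = acc(pred), loo = acc(loo))
}

#' Pairwise distances between population mean shapes
#'
#' Euclidean distance between the per-population mean aligned coordinate
#' vectors (mean-shape disparity).
#'
#' @param ss A `shape_space`.
#' @param pop Population factor; defaults to `ss$pop`.
#' @return A [dist_matrix()].
#' @export
mean_shape_distances <- function(ss, pop = ss$pop) {
  pop <- droplevels(factor(pop))
  Y <- flatten_shapes(ss)
  means <- t(vapply(levels(pop),
                    function(p) colMeans(Y[pop == p, , drop = FALSE]),
                    numeric(ncol(Y))))
  dist_matrix(as.matrix(dist(means)), levels(pop))
}
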