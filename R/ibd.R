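# Geographic distances, Mantel / partial Mantel tests, IBD transforms.

#' Parse degree and decimal-minute coordinate strings
#'
#' Coordinates recorded as degree-minute strings in which the seconds field
#' actually holds thousandths of a minute, e.g. `65°34′802″`
#' is read as 65 degrees 34.802 minutes = 65.58003 degrees. Plain decimal
#' degrees (numeric strings) pass through unchanged.
#'
#' @param x Character vector of coordinate strings.
#' @param hemisphere `"N"`, `"S"`, `"E"` or `"W"`; `"S"` and `"W"` negate.
#' @return Numeric decimal degrees.
#' @export
parse_coord <- function(x, hemisphere = "N") {
  out <- vapply(seq_along(x), function(i) {
    s <- trimws(x[i])
    if (!nzchar(s) || is.na(x[i])) return(NA_real_)
    if (grepl("^[-+]?[0-9.]+$", s)) return(as.numeric(s))
    parts <- regmatches(s, gregexpr("[0-9]+(\\.[0-9]+)?", s))[[1]]
    if (length(parts) < 2)
      stop("cannot parse coordinate '", x[i], "' (entry ", i, ")")
    deg <- as.numeric(parts[1])
    minutes <- as.numeric(parts[2])
    if (length(parts) >= 3)
      minutes <- minutes + as.numeric(parts[3]) / 1000
    deg + minutes / 60
  }, numeric(1))
  if (hemisphere %in% c("S", "W")) out <- -out
  out
}

#' Great-circle distances between coordinates
#'
#' Haversine distances (sphere radius 6371 km) between rows of a coordinate
#' table. Coordinates may be decimal degrees or degree-decimal-minute
#' strings (see [parse_coord()]).
#'
#' @param coords Data frame with columns `lat` and `lon` (numeric or
#'   character) and optionally a label column `pop` (otherwise row names).
#' @return A [dist_matrix()] of distances in kilometres.
#' @export
geographic_distances <- function(coords) {
  lat <- if (is.character(coords$lat)) parse_coord(coords$lat, "N")
         else coords$lat
  lon <- if (is.character(coords$lon)) parse_coord(coords$lon, "W")
         else coords$lon
  bad <- which(is.na(lat) | is.na(lon))
  if (length(bad))
    stop("unparseable coordinates in rows: ", paste(bad, collapse = ", "))
  labels <- if (!is.null(coords$pop)) as.character(coords$pop)
            else rownames(coords)
  n <- length(lat)
  m <- matrix(0, n, n)
  pts <- cbind(lon, lat)
  for (i in seq_len(n))
    m[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371000) / 1000
  dist_matrix((m + t(m)) / 2, labels)
}

#' Mantel test
#'
#' Pearson correlation of the lower triangles of two labelled distance
#' matrices; the null distribution is obtained by simultaneous row/column
#' permutation of `a`. The default p-value is one-tailed for positive
#' association (the isolation-by-distance direction), add-one corrected.
#'
#' @param a,b [dist_matrix()] objects sharing labels (`b` is reordered to
#'   `a`'s labels); at least 4 labels.
#' @param n_perm Number of permutations.
#' @param tail `"positive"` (one-tailed, default) or `"two-sided"`.
#' @param seed RNG seed.
#' @return A `mantel_result` list with `r`, `p`, `n_perm`, `tail`.
#' @export
mantel <- function(a, b, n_perm = 9999, tail = c("positive", "two-sided"),
                   seed = 1) {
  tail <- match.arg(tail)
  set.seed(seed)
  a <- dist_matrix(a); b <- align_dist(a, dist_matrix(b))
  n <- nrow(a)
  if (n < 4) stop("need at least 4 labels")
  va <- lower_tri(a); vb <- lower_tri(b)
  if (sd(va) == 0 || sd(vb) == 0) stop("zero-variance lower triangle")
  r <- cor(va, vb)
  hits <- 0
  for (k in seq_len(n_perm)) {
    ord <- sample.int(n)
    rp <- cor(lower_tri(a[ord, ord]), vb)
    ok <- if (tail == "positive") rp >= r - 1e-12 else abs(rp) >= abs(r) - 1e-12
    if (ok) hits <- hits + 1
  }
  structure(list(r = r, p = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, tail = tail),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$tail, x$n_perm))
  invisible(x)
}

#' Partial Mantel test
#'
#' Correlation between the residuals of `a ~ c` and `b ~ c` on the lower
#' triangles; the permutation null permutes the residual matrix of `a`
#' (rows and columns simultaneously). A constant `c` reduces to the plain
#' Mantel statistic.
#'
#' @param a,b,c [dist_matrix()] objects on the same labels; `c` is the
#'   conditioning matrix (e.g. an [area_coding_matrix()]).
#' @inheritParams mantel
#' @return A `mantel_result`.
#' @export
partial_mantel <- function(a, b, c, n_perm = 9999,
                           tail = c("positive", "two-sided"), seed = 1) {
  tail <- match.arg(tail)
  set.seed(seed)
  a <- dist_matrix(a)
  b <- align_dist(a, dist_matrix(b))
  c <- align_dist(a, dist_matrix(c))
  n <- nrow(a)
  if (n < 4) stop("need at least 4 labels")
  va <- lower_tri(a); vb <- lower_tri(b); vc <- lower_tri(c)
  if (sd(vb) == 0) stop("zero-variance lower triangle in b")
  if (sd(vc) > 0 && abs(cor(vb, vc)) > 1 - 1e-10)
    stop("conditioning matrix is collinear with b")
  res_on <- function(y, z) {
    if (sd(z) == 0) return(y - mean(y))
    stats::residuals(stats::lm(y ~ z))
  }
  ra <- res_on(va, vc); rb <- res_on(vb, vc)
  if (sd(ra) == 0) stop("zero-variance residuals of a")
  r <- cor(ra, rb)
  # residuals of a put back into matrix form for row/column permutation
  ram <- matrix(0, n, n)
  ram[lower.tri(ram)] <- ra
  ram <- ram + t(ram)
  hits <- 0
  for (k in seq_len(n_perm)) {
    ord <- sample.int(n)
    rp <- cor(lower_tri(ram[ord, ord]), rb)
    ok <- if (tail == "positive") rp >= r - 1e-12 else abs(rp) >= abs(r) - 1e-12
    if (ok) hits <- hits + 1
  }
  structure(list(r = r, p = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, tail = tail),
            class = "mantel_result")
}

#' Binary same-area / different-area coding matrix
#'
#' Entry 0 when two labels share an area, 1 otherwise; used as the
#' conditioning matrix in partial Mantel tests.
#'
#' @param areas Named character vector (or factor) of area codes; names are
#'   the population labels (defaults to `pop1..popN`).
#' @return A [dist_matrix()].
#' @export
area_coding_matrix <- function(areas) {
  labels <- names(areas)
  if (is.null(labels)) labels <- paste0("pop", seq_along(areas))
  m <- outer(as.character(areas), as.character(areas),
             function(x, y) as.numeric(x != y))
  dist_matrix(m, labels)
}

#' Linearized differentiation transform for IBD
#'
#' Elementwise `D / (1 - D)`; negative entries are floored at 0 first.
#' Entries at or above 1 are an error (infinite transform).
#'
#' @param d A [dist_matrix()] of differentiation values below 1.
#' @return A [dist_matrix()].
#' @export
ibd_transform <- function(d) {
  d <- dist_matrix(d)
  m <- unclass(d)
  m[m < 0] <- 0
  if (any(m >= 1)) stop("entries at or above 1 cannot be linearized")
  dist_matrix(m / (1 - m), rownames(d))
}
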