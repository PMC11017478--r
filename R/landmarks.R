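# Landmark containers and TPS file input/output.

#' Landmark configuration set
#'
#' Per-specimen 2-D landmark configurations with specimen metadata. Sliding
#' semilandmarks are declared through `curves`: ordered index chains along
#' which interior points may slide during superimposition.
#'
#' @param coords Numeric array `n x k x 2` (specimens x landmarks x xy).
#' @param id Specimen identifiers.
#' @param pop Population labels.
#' @param fork_length Numeric fork lengths (mm), `NA` allowed.
#' @param sliders Integer indices of sliding semilandmarks (subset of the
#'   interior points of `curves`).
#' @param curves List of integer vectors, each an ordered neighbour chain.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(coords, id = NULL, pop = NULL, fork_length = NULL,
                         sliders = integer(0), curves = list()) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 2L)
    stop("coords must be an n x k x 2 array")
  n <- dim(coords)[1]; k <- dim(coords)[2]
  if (is.null(id)) id <- paste0("spec", seq_len(n))
  if (is.null(pop)) pop <- rep("pop1", n)
  if (is.null(fork_length)) fork_length <- rep(NA_real_, n)
  stopifnot(length(id) == n, length(pop) == n, length(fork_length) == n)
  sliders <- as.integer(sliders)
  if (length(sliders)) {
    interior <- unlist(lapply(curves, function(ch) ch[-c(1, length(ch))]))
    if (!all(sliders %in% interior))
      stop("every slider must be interior to a declared curve")
  }
  structure(list(coords = coords, id = as.character(id), pop = factor(pop),
                 fork_length = fork_length, sliders = sliders,
                 curves = curves, n = n, k = k),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set:", x$n, "specimens,", x$k, "landmarks (",
      length(x$sliders), "sliding )\n")
  invisible(x)
}

#' Subset the landmarks of every specimen
#'
#' Used e.g. to run a head-only analysis on a subset of landmark columns.
#' Sliders are kept only when their full neighbour chain context survives;
#' curve indices are remapped.
#'
#' @param x A [landmark_set()].
#' @param keep Integer indices of landmarks to keep.
#' @return A [landmark_set()] on the subset.
#' @export
subset_landmarks <- function(x, keep) {
  keep <- sort(unique(as.integer(keep)))
  remap <- match(seq_len(x$k), keep)
  curves <- list()
  for (ch in x$curves) {
    if (all(ch %in% keep)) curves[[length(curves) + 1]] <- remap[ch]
  }
  interior <- unlist(lapply(curves, function(ch) ch[-c(1, length(ch))]))
  sliders <- intersect(remap[intersect(x$sliders, keep)], interior)
  landmark_set(x$coords[, keep, , drop = FALSE], x$id, x$pop,
               x$fork_length, sliders, curves)
}

#' Read landmark configurations from a TPS file
#'
#' Supports `LM=`, point rows, `ID=` and optional `SCALE=` records (scale is
#' applied multiplicatively to the coordinates). Curve records are not
#' supported.
#'
#' @param path Path to a TPS file.
#' @param ... Passed to [landmark_set()] (`pop`, `fork_length`, `sliders`,
#'   `curves`).
#' @return A [landmark_set()].
#' @export
read_tps <- function(path, ...) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  specs <- list(); ids <- character(0)
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i], ignore.case = TRUE))
      stop("expected LM= record at line ", i)
    k <- as.integer(sub("^LM=", "", lines[i], ignore.case = TRUE))
    pts <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      xy <- as.numeric(strsplit(lines[i + j], "[[:space:]]+")[[1]])
      pts[j, ] <- xy[1:2]
    }
    i <- i + k + 1
    id <- paste0("spec", length(specs) + 1); scale <- 1
    while (i <= length(lines) && !grepl("^LM=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID=", lines[i], ignore.case = TRUE))
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      if (grepl("^SCALE=", lines[i], ignore.case = TRUE))
        scale <- as.numeric(sub("^SCALE=", "", lines[i], ignore.case = TRUE))
      i <- i + 1
    }
    specs[[length(specs) + 1]] <- pts * scale
    ids <- c(ids, id)
  }
  k <- nrow(specs[[1]])
  if (!all(vapply(specs, nrow, integer(1)) == k))
    stop("landmark count differs across specimens")
  coords <- array(NA_real_, c(length(specs), k, 2))
  for (s in seq_along(specs)) coords[s, , ] <- specs[[s]]
  landmark_set(coords, id = ids, ...)
}

#' Write a landmark set to a TPS file
#'
#' @param x A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in seq_len(x$n)) {
    writeLines(paste0("LM=", x$k), con)
    writeLines(sprintf("%.10g %.10g", x$coords[s, , 1], x$coords[s, , 2]), con)
    writeLines(paste0("ID=", x$id[s]), con)
  }
  invisible(path)
}

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid.
#'
#' @param m A `k x 2` coordinate matrix.
#' @return Numeric centroid size.
#' @export
centroid_size <- function(m) {
  cm <- colMeans(m)
  sqrt(sum((m[, 1] - cm[1])^2 + (m[, 2] - cm[2])^2))
}
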