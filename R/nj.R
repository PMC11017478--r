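# Neighbour-joining phenograms and bootstrap consensus over loci.

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Negative
#' branch lengths arising at a join are clamped to zero with the deficit
#' transferred to the sister branch, so all branch lengths are non-negative.
#' Ties in Q are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest tip), making the result
#' deterministic. Exact on additive distances.
#'
#' @param d A [dist_matrix()] (or plain symmetric matrix) with at least 3
#'   labels.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  d <- dist_matrix(d)
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3) stop("need at least 3 labels")
  D <- unclass(d)
  newick <- setNames(labels, labels)     # subtree strings, keyed by cluster label
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij)
      paste(sort(rownames(D)[ij]), collapse = "\r"))
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ki <- rownames(D)[i]; kj <- rownames(D)[j]
    knew <- min(ki, kj)
    sub <- paste0("(", newick[ki], ":", fmt(li), ",",
                  newick[kj], ":", fmt(lj), ")")
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D, new = newd), new = c(newd, 0))[-c(i, j), -c(i, j)]
    rn <- rownames(D); rn[rn == "new"] <- knew
    dimnames(D) <- list(rn, rn)
    newick <- newick[!names(newick) %in% c(ki, kj)]
    newick[knew] <- sub
  }
  ks <- rownames(D)
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  len <- pmax(c(lx, ly, lz), 0)
  str <- paste0("(", newick[ks[1]], ":", fmt(len[1]), ",",
                newick[ks[2]], ":", fmt(len[2]), ",",
                newick[ks[3]], ":", fmt(len[3]), ");")
  ape::read.tree(text = str)
}

# Canonical bipartition key for the clade 'side' of an edge: the side not
# containing the globally smallest label, collapsed to a string.
bipart_key <- function(side, all_labels) {
  a0 <- min(all_labels)
  if (a0 %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "\r")
}

# For each edge of a tree: canonical bipartition key and branch length.
edge_biparts <- function(tr) {
  po <- stats::reorder(tr, "postorder")
  n <- length(po$tip.label)
  desc <- vector("list", n + po$Nnode)
  for (i in seq_len(n)) desc[[i]] <- po$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- vapply(seq_len(nrow(po$edge)), function(e)
    bipart_key(desc[[po$edge[e, 2]]], po$tip.label), character(1))
  lens <- if (is.null(po$edge.length)) rep(NA_real_, nrow(po$edge))
          else po$edge.length
  data.frame(key = keys, length = lens, stringsAsFactors = FALSE)
}

#' Bootstrap consensus neighbour-joining phenogram
#'
#' Loci are resampled with replacement; the chord distance matrix and
#' neighbour-joining tree are recomputed for each replicate; the
#' majority-rule consensus is returned with node supports equal to the
#' percentage of replicates containing each bipartition. Branch lengths of
#' the consensus are averaged over the replicates that contain the
#' corresponding bipartition.
#'
#' @param x A [genotype_table()] with at least 2 loci.
#' @param n_boot Number of bootstrap replicates (warning below 100).
#' @param seed RNG seed.
#' @param support_threshold Supports below this percentage are reported as
#'   `NA` on the tree (default 50, the conventional reporting cut-off).
#' @return List with `tree` (consensus `phylo`, node labels = support
#'   percentages), `full_tree` (NJ tree from all loci) and `supports`.
#' @export
bootstrap_consensus <- function(x, n_boot = 1000, seed = 1,
                                support_threshold = 50) {
  if (length(x$loci) < 2) warning("fewer than 2 loci: degenerate resampling")
  if (n_boot < 100) warning("n_boot below 100 gives unstable supports")
  set.seed(seed)
  af <- allele_frequencies(x)
  pops <- attr(af, "pops")
  full <- neighbor_joining(chord_distance(af))
  L <- length(af)
  trees <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, replace = TRUE)
    afb <- af[idx]
    attr(afb, "pops") <- pops
    class(afb) <- "allele_freqs"
    trees[[b]] <- neighbor_joining(chord_distance(afb))
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  # accumulate bipartition counts and length sums over replicates
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    eb <- edge_biparts(tr)
    for (k in seq_len(nrow(eb))) {
      key <- eb$key[k]
      cur <- if (!is.null(counts[[key]])) counts[[key]] else c(0, 0)
      counts[[key]] <- cur + c(1, eb$length[k])
    }
  }
  ce <- edge_biparts(cons)
  lens <- supports <- numeric(nrow(ce))
  for (k in seq_len(nrow(ce))) {
    cur <- counts[[ce$key[k]]]
    if (is.null(cur)) cur <- c(0, 0)
    supports[k] <- 100 * cur[1] / n_boot
    lens[k] <- if (cur[1] > 0) cur[2] / cur[1] else 0
  }
  po <- stats::reorder(cons, "postorder")
  po$edge.length <- lens
  ntip <- length(po$tip.label)
  node_support <- rep(NA_real_, po$Nnode)
  for (k in seq_len(nrow(po$edge))) {
    ch <- po$edge[k, 2]
    if (ch > ntip) node_support[ch - ntip] <- supports[k]
  }
  shown <- ifelse(!is.na(node_support) & node_support >= support_threshold,
                  sprintf("%.0f", node_support), "")
  po$node.label <- shown
  list(tree = po, full_tree = full,
       supports = node_support, n_boot = n_boot)
}

#' Write a phenogram to a Newick file
#'
#' Node support labels (if present) are written as internal node labels.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenogram <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
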