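## Neighbour-joining (Saitou & Nei) on a labelled distance matrix.
##
## The agglomeration is implemented here so its determinism is fully
## specified: ties in the Q-criterion are broken by the lexicographically
## smallest pair of cluster keys (a cluster's key is the smallest original
## label it contains), and a negative branch length is clamped to zero with
## the deficit moved to its sister branch so the joined distance is
## preserved (the usual tree-viewer behaviour). On an additive distance
## matrix the tree reproduces every pairwise distance exactly.

#' Neighbour-joining tree from a distance matrix
#'
#' @param D symmetric distance matrix with unique labels (n >= 3).
#' @return an unrooted `phylo` tree (see \pkg{ape}) whose leaves are the
#'   labels of `D`.
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbour-joining needs at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs) || anyDuplicated(labs)) stop("D needs unique labels")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    stop("D must be symmetric with a zero diagonal")
  newick <- labs          # growing sub-tree strings
  key <- labs             # tie-break key per active cluster
  fmt <- function(b) sprintf("%.12g", b)

  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    pairKey <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(k[1L], k[2L], sep = "\r")
    })
    pick <- cand[order(pairKey)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    merged <- paste0("(", newick[i], ":", fmt(bi), ",",
                     newick[j], ":", fmt(bj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    newick <- c(newick[keep], merged)
    key <- c(key[keep], min(key[c(i, j)]))
    labsN <- c(rownames(Q)[keep], paste0("_c", n))
    dimnames(D) <- list(labsN, labsN)
    n <- n - 1L
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  txt <- paste0("(", newick[1], ":", fmt(b[1]), ",", newick[2], ":",
                fmt(b[2]), ",", newick[3], ":", fmt(b[3]), ");")
  ape::read.tree(text = txt)
}

#' Cut a tree into clusters at a height threshold
#'
#' Removes every edge longer than `h` ("tree scale" cutting as used when
#' reading dendrograms at a fixed scale) and returns the leaf partition
#' induced by the remaining connected components.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param h height threshold; edges with length > `h` are cut.
#' @return named integer vector of cluster memberships for the leaves,
#'   numbered in order of first appearance.
#' @export
cutTreeHeight <- function(tree, h) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  nNode <- max(tree$edge)
  parent <- seq_len(nNode)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  keep <- tree$edge.length <= h
  for (e in which(keep)) {
    ra <- find(tree$edge[e, 1L]); rb <- find(tree$edge[e, 2L])
    if (ra != rb) parent[rb] <- ra
  }
  ntip <- length(tree$tip.label)
  roots <- vapply(seq_len(ntip), find, integer(1))
  setNames(as.integer(factor(roots, levels = unique(roots))), tree$tip.label)
}
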