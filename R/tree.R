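#' Neighbour-joining guide tree
#'
#' Standard Saitou-Nei agglomeration on a symmetric distance matrix, with a
#' fully deterministic construction: Q-criterion ties are broken towards the
#' lexicographically smallest pair of cluster creation indices (leaves are
#' created in input order, internal nodes in join order), the final join is
#' taken as the root, and each join stores its children in creation order.
#' That creation order later fixes the traversal of the progressive
#' alignment. The pipeline symmetrises the pair matrix as
#' \code{(e[i,j] + e[j,i]) / 2} before calling this.
#'
#' @param D symmetric numeric matrix of non-negative distances with zero
#'   diagonal, or a \linkS4class{CyclicPairMatrix} (symmetrised
#'   automatically).
#' @param labels leaf labels; defaults to the matrix dimnames.
#' @return A \linkS4class{GuideTree}.
#' @examples
#' D <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4)
#' neighbourJoining(D, letters[1:4])
#' @export
neighbourJoining <- function(D, labels = NULL) {
  if (is(D, "CyclicPairMatrix")) {
    if (is.null(labels)) labels <- D@ids
    D <- (D@e + t(D@e)) / 2
  }
  D <- as.matrix(D)
  d <- nrow(D)
  if (d < 2L) stop("at least two taxa are required")
  if (ncol(D) != d || !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  if (any(diag(D) != 0)) stop("diagonal must be zero")
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(d))

  # active clusters: creation id (1..d leaves, then d+t), merge-table code
  ids <- seq_len(d)                 # creation ids
  code <- -seq_len(d)               # merge coding: negative leaf, positive row
  merges <- matrix(0L, max(d - 1L, 1L), 2L)
  elen <- matrix(0, max(d - 1L, 1L), 2L)
  t <- 0L
  while (length(ids) > 2L) {
    n <- length(ids)
    rs <- rowSums(D)
    Q <- (n - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # smallest (creation_i, creation_j) lexicographically
    ci <- pmin(ids[hits[, 1]], ids[hits[, 2]])
    cj <- pmax(ids[hits[, 1]], ids[hits[, 2]])
    pick <- order(ci, cj)[1L]
    i <- min(hits[pick, ]); j <- max(hits[pick, ])
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    t <- t + 1L
    first <- if (ids[i] <= ids[j]) i else j
    second <- if (first == i) j else i
    merges[t, ] <- c(code[first], code[second])
    elen[t, ] <- c(if (first == i) li else lj, if (first == i) lj else li)
    newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    ids <- c(ids[keep], d + t)
    code <- c(code[keep], t)
  }
  # root join of the final two clusters
  t <- t + 1L
  ord <- order(ids)
  merges[t, ] <- code[ord]
  half <- D[1L, 2L] / 2
  elen[t, ] <- c(half, half)
  new("GuideTree", merges = merges, edgeLengths = elen,
      labels = as.character(labels))
}

#' Convert a guide tree to an ape phylo object
#'
#' @param x a \linkS4class{GuideTree}.
#' @param ... unused.
#' @return An object of class \code{phylo} (rooted, binary).
#' @export
setMethod("asPhylo", "GuideTree", function(x, ...) {
  d <- length(x@labels)
  nnode <- nrow(x@merges)
  # ape numbering: tips 1..d, root d+1, then remaining internals
  nodeNum <- integer(nnode)
  nextNum <- d + 1L
  edges <- matrix(0L, 2L * nnode, 2L)
  lens <- numeric(2L * nnode)
  k <- 0L
  assign_rec <- function(row) {
    num <- nextNum
    nextNum <<- nextNum + 1L
    nodeNum[row] <<- num
    for (side in 1:2) {
      child <- x@merges[row, side]
      k <<- k + 1L
      my <- k
      lens[my] <<- x@edgeLengths[row, side]
      if (child < 0L) {
        edges[my, ] <<- c(num, -child)
      } else {
        edges[my, ] <<- c(num, 0L)  # fill after recursion
        cn <- assign_rec(child)
        edges[my, 2L] <<- cn
      }
    }
    num
  }
  assign_rec(nnode)
  tr <- list(edge = edges, edge.length = lens, tip.label = x@labels,
             Nnode = nnode)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"  # edges are emitted in preorder
  tr
})

#' Export a guide tree as a Newick string or file
#'
#' @param tree a \linkS4class{GuideTree} or \code{phylo}.
#' @param path optional file to write; when \code{NULL} the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
writeGuideTree <- function(tree, path = NULL) {
  if (is(tree, "GuideTree")) tree <- asPhylo(tree)
  if (is.null(path))
    ape::write.tree(tree)
  else
    invisible(ape::write.tree(tree, file = path))
}

setMethod("show", "GuideTree", function(object) {
  cat("GuideTree with", length(object@labels), "leaves:",
      writeGuideTree(object), "\n")
})
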