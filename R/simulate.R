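#' Simulate a family of randomly rotated circular sequences
#'
#' Emulates the synthetic evaluation protocol: a uniform-random ancestral
#' root of length \code{L} evolves into \code{d} leaves under Jukes-Cantor
#' substitutions — each site mutates with a per-branch probability to a
#' uniform choice among the other three nucleotides — with insertion and
#' deletion events at rates \code{insRate} and \code{delRate} relative to the
#' substitution rate (defaults 0.04/0.06), indel lengths 1 + Geometric(0.5)
#' capped at \code{maxIndel}. Substitutions are applied before indels on each
#' branch. Each leaf is then rotated by an independent uniform rotation,
#' recorded as the ground truth.
#'
#' By default evolution proceeds along a random bifurcating guide tree
#' (uniform topology, equal branch lengths scaled so the mean root-to-leaf
#' substitution probability equals \code{divergence}), giving the leaves the
#' hierarchical relatedness a simulator driven by a phylogeny produces —
#' without it, all leaves are equidistant and distance trees built on the
#' family carry no topological signal. \code{topology = "star"} evolves every
#' leaf independently from the root instead.
#'
#' @param d number of sequences.
#' @param L root length in bp.
#' @param divergence expected root-to-leaf per-site substitution probability
#'   (presets used in the evaluation: 0.05, 0.20, 0.35); must lie in
#'   [0, 0.75) for Jukes-Cantor identifiability.
#' @param insRate,delRate insertion/deletion rates relative to substitutions.
#' @param maxIndel indel length cap.
#' @param topology \code{"tree"} (random bifurcating guide tree) or
#'   \code{"star"} (independent leaves).
#' @param seed integer RNG seed; same seed, bit-identical family.
#' @return A \linkS4class{SimulatedFamily}; the generating guide tree (when
#'   \code{topology = "tree"}) is kept in \code{config$guideTree} as a
#'   Newick string.
#' @examples
#' fam <- simulateFamily(d = 4, L = 200, divergence = 0.05, seed = 7)
#' nchar(fam@sequences)
#' @export
simulateFamily <- function(d = 12L, L = 2500L, divergence = 0.05,
                           insRate = 0.04, delRate = 0.06, maxIndel = 20L,
                           topology = c("tree", "star"), seed = 1L) {
  topology <- match.arg(topology)
  if (divergence < 0 || divergence >= 0.75)
    stop("divergence must lie in [0, 0.75)")
  if (insRate < 0 || delRate < 0) stop("indel rates must be >= 0")
  if (d < 1L || L < 1L) stop("d and L must be positive")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  nuc <- c("A", "C", "G", "T")
  root <- sample(nuc, L, replace = TRUE)
  indelLen <- function(n) pmin(1L + stats::rgeom(n, 0.5), maxIndel)

  # one branch: substitutions at per-site probability p, then deletions and
  # insertions at delRate*p / insRate*p events per site
  evolveBranch <- function(leaf, p) {
    if (p <= 0) return(leaf)
    mut <- which(stats::runif(length(leaf)) < p)
    if (length(mut)) {
      shift <- sample.int(3L, length(mut), replace = TRUE)
      leaf[mut] <- nuc[(match(leaf[mut], nuc) - 1L + shift) %% 4L + 1L]
    }
    len <- length(leaf)
    delAt <- which(stats::runif(len) < delRate * p)
    if (length(delAt)) {
      drop <- unique(unlist(mapply(function(s, l) s:min(s + l - 1L, len),
                                   delAt, indelLen(length(delAt)),
                                   SIMPLIFY = FALSE)))
      if (length(drop) < len) leaf <- leaf[-drop]
    }
    len <- length(leaf)
    insAt <- which(stats::runif(len) < insRate * p)
    if (length(insAt)) {
      lens <- indelLen(length(insAt))
      pieces <- lapply(lens, function(l) sample(nuc, l, replace = TRUE))
      out <- vector("list", 2L * length(insAt) + 1L)
      prev <- 0L
      for (k in seq_along(insAt)) {
        out[[2L * k - 1L]] <- leaf[seq_len(insAt[k] - prev) + prev]
        out[[2L * k]] <- pieces[[k]]
        prev <- insAt[k]
      }
      out[[2L * length(insAt) + 1L]] <-
        if (prev < len) leaf[(prev + 1L):len] else character(0)
      leaf <- unlist(out)
    }
    leaf
  }

  unrot <- vector("list", d)
  guideNwk <- NULL
  if (topology == "star" || d == 1L) {
    for (i in seq_len(d)) unrot[[i]] <- evolveBranch(root, divergence)
  } else {
    gt <- ape::rtree(d, rooted = TRUE)
    gt$edge.length <- rep(1, nrow(gt$edge))
    depths <- ape::node.depth.edgelength(gt)
    p1 <- divergence / mean(depths[seq_len(d)])  # per-branch probability
    gt$edge.length <- rep(p1, nrow(gt$edge))
    guideNwk <- ape::write.tree(gt)
    rootNode <- d + 1L
    walk <- function(node, seqChars) {
      kids <- gt$edge[gt$edge[, 1] == node, 2]
      if (length(kids) == 0L) {
        unrot[[node]] <<- seqChars
        return(invisible(NULL))
      }
      for (k in kids) walk(k, evolveBranch(seqChars, p1))
    }
    walk(rootNode, root)  # tips are numbered 1..d; family member i = tip i
  }
  unrot <- vapply(unrot, paste, character(1), collapse = "")
  names(unrot) <- paste0("seq", seq_len(d))
  rot <- vapply(nchar(unrot), function(m) sample.int(m, 1L) - 1L, integer(1))
  new("SimulatedFamily",
      sequences = rotateSeq(unrot, rot),
      unrotated = unrot,
      rotations = as.integer(rot),
      root = paste(root, collapse = ""),
      config = list(d = d, L = L, divergence = divergence, insRate = insRate,
                    delRate = delRate, maxIndel = maxIndel,
                    topology = topology, guideTree = guideNwk, seed = seed))
}

#' Dataset label in A.B.C form
#'
#' Datasets are denoted A.B.C where A is the number of sequences, B the
#' average length and C the percentage of divergence; randomly rotated
#' variants carry a ".rot" suffix.
#'
#' @param d number of sequences.
#' @param L average length.
#' @param divergence substitution proportion (0.05 prints as "5").
#' @param rotated append ".rot".
#' @return Label string, e.g. \code{"12.2500.5.rot"}.
#' @examples
#' nameDataset(12, 2500, 0.05, rotated = TRUE)
#' @export
nameDataset <- function(d, L, divergence, rotated = FALSE) {
  pct <- divergence * 100
  pct <- if (pct == round(pct)) format(as.integer(round(pct))) else format(pct)
  paste0(d, ".", L, ".", pct, if (rotated) ".rot" else "")
}

#' Write a simulated family to FASTA plus a rotation TSV
#'
#' @param fam a \linkS4class{SimulatedFamily}.
#' @param fastaPath output FASTA of the rotated (observed) sequences.
#' @param rotationsPath optional TSV (id, length, rotation) of the recorded
#'   true rotations.
#' @return Invisibly, \code{fastaPath}.
#' @export
writeFamily <- function(fam, fastaPath, rotationsPath = NULL) {
  writeFasta(fam@sequences, fastaPath)
  if (!is.null(rotationsPath)) {
    utils::write.table(
      data.frame(id = names(fam@sequences),
                 length = nchar(fam@sequences),
                 rotation = fam@rotations),
      rotationsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fastaPath)
}

#' Read a simulation configuration from a JSON file
#'
#' The file may hold any subset of the \code{\link{simulateFamily}}
#' arguments.
#'
#' @param path JSON file path.
#' @return Named list of arguments for \code{\link{simulateFamily}}.
#' @export
readSimConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  allowed <- names(formals(simulateFamily))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown simulation fields: ", paste(bad, collapse = ", "))
  cfg
}

#' @describeIn SimulatedFamily-class recorded true rotations
#' @param x a \code{SimulatedFamily}.
#' @param ... unused.
#' @export
setMethod("rotations", "SimulatedFamily", function(x, ...)
  stats::setNames(x@rotations, names(x@sequences)))

setMethod("show", "SimulatedFamily", function(object) {
  cfg <- object@config
  cat("SimulatedFamily ", nameDataset(cfg$d, cfg$L, cfg$divergence, TRUE),
      ": ", cfg$d, " sequences, mean length ",
      round(mean(nchar(object@sequences))), ", seed ", cfg$seed, "\n",
      sep = "")
})
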