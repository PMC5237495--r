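#' @useDynLib circMSA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Alignment and rotation-search parameters
#'
#' Container for the tunable parameters of the rotation-refinement pipeline:
#' the q-gram length used by the blockwise rotation search, the target block
#' length from which the per-pair number of blocks \eqn{\beta} is derived, the
#' refinement extent P (window size of the spacer-based refinement, in
#' blocks), the cost model of the cyclic edit distance, the scoring matrix and
#' the gap penalties of the pairwise and profile alignment stages.
#'
#' @slot q integer, q-gram length (>= 1).
#' @slot blockLength integer, target block length in residues; per pair the
#'   number of blocks is \code{max(1, floor(min(m, n) / blockLength))}.
#' @slot refineExtent numeric, refinement extent P (> 0); the effective value
#'   used for a pair is clamped to \code{beta / 3}.
#' @slot costModel \code{"unit"} (Levenshtein, bit-parallel) or
#'   \code{"weighted"} (dynamic programming with \code{subCost}/\code{indelCost}).
#' @slot subCost,indelCost numeric costs of the weighted edit distance.
#' @slot alphabet \code{"DNA"} or \code{"PROT"}.
#' @slot subMatrix numeric similarity matrix over residues (rows/columns named
#'   by letter); defaults to +5/-4 for DNA and BLOSUM62 for protein.
#' @slot gapOpen,gapExtend numeric (<= 0) affine gap penalties of the pairwise
#'   refinement stage (Gotoh scoring of candidate rotations).
#' @slot msaGapOpen,msaGapExtend numeric (<= 0) gap penalties of the profile
#'   alignment stage; the default mode charges \code{msaGapOpen} per gapped
#'   column (linear), the affine mode additionally uses \code{msaGapExtend}.
#' @slot msaAffine logical, use affine (Gotoh-style) gap costs in the profile
#'   alignment stage instead of the literal linear recurrence.
#' @export
setClass("AlignParams",
  representation(
    q = "integer", blockLength = "integer", refineExtent = "numeric",
    costModel = "character", subCost = "numeric", indelCost = "numeric",
    alphabet = "character", subMatrix = "matrix",
    gapOpen = "numeric", gapExtend = "numeric",
    msaGapOpen = "numeric", msaGapExtend = "numeric", msaAffine = "logical"
  )
)

setValidity("AlignParams", function(object) {
  msg <- character()
  if (length(object@q) != 1L || is.na(object@q) || object@q < 1L)
    msg <- c(msg, "q must be a single integer >= 1")
  if (length(object@blockLength) != 1L || object@blockLength < 1L)
    msg <- c(msg, "blockLength must be a single integer >= 1")
  if (length(object@refineExtent) != 1L || object@refineExtent <= 0)
    msg <- c(msg, "refineExtent (P) must be > 0")
  if (!object@costModel %in% c("unit", "weighted"))
    msg <- c(msg, "costModel must be 'unit' or 'weighted'")
  if (object@subCost < 0 || object@indelCost < 0)
    msg <- c(msg, "edit costs must be non-negative")
  if (!object@alphabet %in% c("DNA", "PROT"))
    msg <- c(msg, "alphabet must be 'DNA' or 'PROT'")
  if (is.null(rownames(object@subMatrix)) ||
      !identical(rownames(object@subMatrix), colnames(object@subMatrix)))
    msg <- c(msg, "subMatrix must have identical row and column letter names")
  if (any(c(object@gapOpen, object@gapExtend,
            object@msaGapOpen, object@msaGapExtend) > 0))
    msg <- c(msg, "gap penalties must be <= 0")
  if (length(msg)) msg else TRUE
})

#' Pairwise cyclic comparison matrix
#'
#' d x d result of the pairwise stage. Cell (i, j) holds \code{e}, the edit
#' distance between the refined pair built from the best rotation of sequence
#' i against sequence j, and \code{r}, that rotation (an offset in
#' \code{[0, m_i)} in the original, ungapped coordinates of sequence i).
#'
#' @slot e numeric matrix of refined-pair edit distances (zero diagonal).
#' @slot r integer matrix of rotations (zero diagonal).
#' @slot ids character, sequence identifiers.
#' @slot seqLengths integer, sequence lengths.
#' @slot params the \linkS4class{AlignParams} used.
#' @export
setClass("CyclicPairMatrix",
  representation(e = "matrix", r = "matrix", ids = "character",
                 seqLengths = "integer", params = "AlignParams")
)

setValidity("CyclicPairMatrix", function(object) {
  d <- length(object@ids)
  msg <- character()
  if (!all(dim(object@e) == c(d, d)) || !all(dim(object@r) == c(d, d)))
    msg <- c(msg, "e and r must be d x d")
  if (length(object@seqLengths) != d)
    msg <- c(msg, "seqLengths must have one entry per sequence")
  if (d > 0) {
    if (any(diag(object@e) != 0) || any(diag(object@r) != 0))
      msg <- c(msg, "diagonal of e and r must be zero")
    if (any(object@e < 0)) msg <- c(msg, "edit distances must be >= 0")
    if (any(object@r < 0L) || any(object@r >= object@seqLengths))
      msg <- c(msg, "rotations must lie in [0, m_i)")
  }
  if (length(msg)) msg else TRUE
})

#' Neighbour-joining guide tree
#'
#' Rooted binary tree over sequence indices produced by neighbour joining on
#' the symmetrised pairwise cyclic edit distances. Stored as a merge table in
#' creation order (the hclust convention: negative entries are leaves, positive
#' entries refer to earlier rows); the final join is the root. The creation
#' order doubles as the deterministic traversal order of the progressive
#' alignment.
#'
#' @slot merges integer (d-1) x 2 matrix of joins; row t joins the two
#'   clusters named in creation order (negative = leaf index, positive =
#'   earlier row).
#' @slot edgeLengths numeric (d-1) x 2 matrix of branch lengths to each child.
#' @slot labels character, leaf labels (sequence ids).
#' @export
setClass("GuideTree",
  representation(merges = "matrix", edgeLengths = "matrix",
                 labels = "character")
)

setValidity("GuideTree", function(object) {
  d <- length(object@labels)
  m <- object@merges
  msg <- character()
  if (d < 2L) msg <- c(msg, "a guide tree needs at least two leaves")
  if (!all(dim(m) == c(d - 1L, 2L)))
    msg <- c(msg, "merges must be (d-1) x 2")
  else {
    leaves <- sort(-m[m < 0L])
    if (!identical(as.integer(leaves), seq_len(d)))
      msg <- c(msg, "every leaf index must appear exactly once")
    internal <- m[m > 0L]
    if (length(internal) && any(internal >= row(m)[m > 0L]))
      msg <- c(msg, "internal children must refer to earlier joins")
  }
  if (length(msg)) msg else TRUE
})

#' Alignment profile with rotation provenance
#'
#' An alignment viewed as a sequence of columns over the gapped alphabet
#' \eqn{\Sigma' = \Sigma \cup \{-\}}. Each row records which input sequence it
#' came from and the cumulative rotation (in original, ungapped coordinates)
#' that has been applied to it; stripping the gaps from a row recovers that
#' rotation of its source sequence. The anchor row is the reference row whose
#' cumulative rotation is zero in a standing profile; pairwise rotations
#' against the anchor are what rotation propagation transfers to whole
#' profiles.
#'
#' @slot rows character, gapped rows of equal width.
#' @slot seqIndex integer, source sequence index per row.
#' @slot rotation integer, cumulative rotation per row (original coordinates).
#' @slot anchor integer, index of the anchor row.
#' @slot seqLengths integer, ungapped length of each row's source sequence.
#' @export
setClass("AlignmentProfile",
  representation(rows = "character", seqIndex = "integer",
                 rotation = "integer", anchor = "integer",
                 seqLengths = "integer")
)

setValidity("AlignmentProfile", function(object) {
  k <- length(object@rows)
  msg <- character()
  if (k < 1L) msg <- c(msg, "a profile needs at least one row")
  if (length(unique(nchar(object@rows))) > 1L)
    msg <- c(msg, "all rows must have the same number of columns")
  if (length(object@seqIndex) != k || length(object@rotation) != k ||
      length(object@seqLengths) != k)
    msg <- c(msg, "per-row metadata must match the number of rows")
  if (length(object@anchor) != 1L || is.na(object@anchor) ||
      object@anchor < 1L || object@anchor > k)
    msg <- c(msg, "anchor must name one row")
  ungapped <- nchar(gsub("-", "", object@rows, fixed = TRUE))
  if (!all(ungapped == object@seqLengths))
    msg <- c(msg, "gap-stripped rows must match the recorded sequence lengths")
  if (length(msg)) msg else TRUE
})

#' Simulated circular sequence family
#'
#' A family of sequences evolved independently from a random ancestral root
#' under Jukes-Cantor substitutions with insertions and deletions, then each
#' randomly rotated. The pre-rotation sequences and the applied rotations are
#' recorded so rotation recovery can be scored against the truth.
#'
#' @slot sequences named character, the rotated (observed) sequences.
#' @slot unrotated named character, the same sequences before rotation.
#' @slot rotations integer, the applied rotation per sequence.
#' @slot root character, the ancestral root sequence.
#' @slot config list, the generating configuration (including the seed).
#' @export
setClass("SimulatedFamily",
  representation(sequences = "character", unrotated = "character",
                 rotations = "integer", root = "character", config = "list")
)

setValidity("SimulatedFamily", function(object) {
  d <- length(object@sequences)
  msg <- character()
  if (length(object@unrotated) != d || length(object@rotations) != d)
    msg <- c(msg, "sequences, unrotated and rotations must have equal length")
  else {
    ok <- vapply(seq_len(d), function(i) {
      identical(rotateSeq(object@unrotated[[i]], object@rotations[[i]]),
                unname(object@sequences[[i]]))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "rotating the unrotated sequences must reproduce the observed ones")
  }
  if (length(msg)) msg else TRUE
})

#' Result of the rotation-refinement pipeline
#'
#' Bundles the inputs with the computed rotation array R (one rotation per
#' input sequence, in original coordinates), the pairwise cyclic comparison
#' matrix, the guide tree, and the internal progressive alignment from which R
#' was read off.
#'
#' @slot sequences named character, the input sequences.
#' @slot rotations integer, the output rotation array R.
#' @slot pairMatrix \linkS4class{CyclicPairMatrix}.
#' @slot guideTree \linkS4class{GuideTree} (absent for a single sequence).
#' @slot msa \linkS4class{AlignmentProfile}, the internal alignment.
#' @export
setClass("RotationRefinement",
  representation(sequences = "character", rotations = "integer",
                 pairMatrix = "ANY", guideTree = "ANY", msa = "ANY")
)

setValidity("RotationRefinement", function(object) {
  d <- length(object@sequences)
  msg <- character()
  if (length(object@rotations) != d)
    msg <- c(msg, "one rotation per input sequence is required")
  else if (any(object@rotations < 0L) ||
           any(object@rotations >= nchar(object@sequences)))
    msg <- c(msg, "rotations must lie in [0, m_i)")
  if (length(msg)) msg else TRUE
})
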