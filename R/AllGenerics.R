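#' @rdname rotations
#' @export
setGeneric("rotations", function(x, ...) standardGeneric("rotations"))

#' @rdname editDistances
#' @export
setGeneric("editDistances", function(x, ...) standardGeneric("editDistances"))

#' @rdname refinedSequences
#' @export
setGeneric("refinedSequences", function(x, ...) standardGeneric("refinedSequences"))

#' @rdname asPhylo
#' @export
setGeneric("asPhylo", function(x, ...) standardGeneric("asPhylo"))

#' @rdname frequencyMatrix
#' @export
setGeneric("frequencyMatrix", function(x, ...) standardGeneric("frequencyMatrix"))

#' Accessors for pipeline results and profiles
#'
#' \code{rotations} returns the rotation array R of a pipeline result, the
#' per-row cumulative rotations of a profile, the rotation matrix of a
#' pairwise comparison, or the recorded true rotations of a simulated family.
#' \code{editDistances} returns the (refined-pair) edit distance matrix.
#' \code{refinedSequences} applies the computed rotations to the input
#' sequences. \code{profileRows}, \code{anchorRow} and \code{seqIndices}
#' expose the rows, anchor row index and source indices of a profile;
#' \code{guideTree}, \code{pairMatrix} and \code{msaProfile} the components
#' of a pipeline result.
#'
#' @param x the object.
#' @param ... unused.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("profileRows", function(x, ...) standardGeneric("profileRows"))

#' @rdname accessors
#' @export
setGeneric("anchorRow", function(x, ...) standardGeneric("anchorRow"))

#' @rdname accessors
#' @export
setGeneric("seqIndices", function(x, ...) standardGeneric("seqIndices"))

#' @rdname accessors
#' @export
setGeneric("guideTree", function(x, ...) standardGeneric("guideTree"))

#' @rdname accessors
#' @export
setGeneric("pairMatrix", function(x, ...) standardGeneric("pairMatrix"))

#' @rdname accessors
#' @export
setGeneric("msaProfile", function(x, ...) standardGeneric("msaProfile"))
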