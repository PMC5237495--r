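#' Run the full rotation-refinement pipeline
#'
#' Reads (or takes) a set of circular sequences, computes the pairwise cyclic
#' comparison matrix, builds the neighbour-joining guide tree from the
#' symmetrised refined-pair edit distances, runs the rotation-aware
#' progressive alignment, and (optionally) writes the rotated sequences plus
#' auxiliary outputs. The pipeline is fully deterministic: repeated runs on
#' the same input and parameters produce byte-identical outputs.
#'
#' @param input path to a multiFASTA file, or a named character vector of
#'   sequences.
#' @param output optional path for the rotated multiFASTA output.
#' @param params an \linkS4class{AlignParams}; alternatively pass individual
#'   parameters through \code{...}.
#' @param ... arguments forwarded to \code{\link{alignParams}} when
#'   \code{params} is missing.
#' @param rotationsOut optional TSV path (id, length, rotation).
#' @param msaOut optional gapped-FASTA path for the internal alignment.
#' @param treeOut optional Newick path for the guide tree.
#' @param verbose log per-stage progress to stderr.
#' @return A \linkS4class{RotationRefinement}, invisibly when any file output
#'   was requested.
#' @examples
#' seqs <- c(a = "TAGTAGCT", b = "AAGTAAGCTA", c = "AAGCCTTTAGT")
#' res <- runPipeline(seqs, params = alignParams(q = 2, blockLength = 50))
#' rotations(res)
#' @export
runPipeline <- function(input, output = NULL, params = NULL, ...,
                        rotationsOut = NULL, msaOut = NULL, treeOut = NULL,
                        verbose = FALSE) {
  if (is.null(params)) params <- alignParams(...)
  say <- function(...) if (verbose) message(...)
  seqs <- if (is.character(input) && length(input) == 1L &&
              file.exists(input)) readFasta(input) else input
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  d <- length(seqs)
  say("read ", d, " sequences (lengths ", min(nchar(seqs)), "-",
      max(nchar(seqs)), "); q=", params@q, " l=", params@blockLength,
      " P=", params@refineExtent)

  if (d == 1L) {
    warning("single input sequence: nothing to rotate")
    res <- new("RotationRefinement", sequences = seqs,
               rotations = stats::setNames(0L, names(seqs)),
               pairMatrix = NULL, guideTree = NULL,
               msa = sequenceProfile(seqs[[1L]], 1L))
  } else {
    say("stage 1: pairwise cyclic comparison (", d * (d - 1L), " pairs)")
    M <- buildPairMatrix(seqs, params)
    say("stage 2: neighbour-joining guide tree")
    tree <- neighbourJoining(M)
    say("stage 3: progressive alignment")
    pa <- progressiveAlign(seqs, M, tree, params)
    res <- new("RotationRefinement", sequences = seqs,
               rotations = pa$rotations, pairMatrix = M, guideTree = tree,
               msa = pa$profile)
  }
  wrote <- FALSE
  if (!is.null(output)) {
    writeRotated(seqs, res@rotations, output)
    say("wrote rotated sequences to ", output)
    wrote <- TRUE
  }
  if (!is.null(rotationsOut)) {
    utils::write.table(
      data.frame(id = names(seqs), length = nchar(seqs),
                 rotation = res@rotations),
      rotationsOut, sep = "\t", quote = FALSE, row.names = FALSE)
    wrote <- TRUE
  }
  if (!is.null(msaOut) && !is.null(res@msa)) {
    rows <- res@msa@rows
    names(rows) <- names(seqs)[res@msa@seqIndex]
    writeFasta(rows, msaOut)
    wrote <- TRUE
  }
  if (!is.null(treeOut) && !is.null(res@guideTree)) {
    writeGuideTree(res@guideTree, treeOut)
    wrote <- TRUE
  }
  if (wrote) invisible(res) else res
}

#' @describeIn RotationRefinement-class the rotation array R
#' @param x a \code{RotationRefinement}.
#' @param ... unused.
#' @export
setMethod("rotations", "RotationRefinement", function(x, ...)
  stats::setNames(x@rotations, names(x@sequences)))

#' @describeIn RotationRefinement-class rotated input sequences
#' @export
setMethod("refinedSequences", "RotationRefinement", function(x, ...)
  rotateSeq(x@sequences, x@rotations))

#' @describeIn RotationRefinement-class symmetrised pairwise edit distances
#' @export
setMethod("editDistances", "RotationRefinement", function(x, ...)
  x@pairMatrix@e)

#' @describeIn RotationRefinement-class the guide tree
#' @export
setMethod("guideTree", "RotationRefinement", function(x, ...) x@guideTree)

#' @describeIn RotationRefinement-class the pairwise comparison matrix
#' @export
setMethod("pairMatrix", "RotationRefinement", function(x, ...) x@pairMatrix)

#' @describeIn RotationRefinement-class the internal alignment profile
#' @export
setMethod("msaProfile", "RotationRefinement", function(x, ...) x@msa)

setMethod("show", "RotationRefinement", function(object) {
  d <- length(object@sequences)
  cat("RotationRefinement of", d, "circular sequences\n")
  cat("  rotations R:", paste(utils::head(object@rotations, 10L),
                              collapse = " "),
      if (d > 10L) "..." else "", "\n")
  if (!is.null(object@msa))
    cat("  internal alignment:", nchar(object@msa@rows[1L]), "columns\n")
})
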