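#' Construct alignment parameters
#'
#' The defaults (q = 5, blockLength = 50, refineExtent = 1.0, unit cost model)
#' are the settings used throughout the synthetic evaluation; for short, very
#' divergent molecules such as viroids, smaller q and blockLength are
#' appropriate (e.g. q = 4, blockLength = 25).
#'
#' @param q q-gram length of the rotation search.
#' @param blockLength target block length; the per-pair number of blocks is
#'   \code{beta = max(1, floor(min(m, n) / blockLength))}.
#' @param refineExtent refinement extent P, in blocks; the refinement windows
#'   cover P blocks at each end of a sequence. Clamped per pair to
#'   \code{beta / 3} (the largest admissible value).
#' @param costModel cost model of the cyclic edit distance stored in the pair
#'   matrix: \code{"unit"} or \code{"weighted"}.
#' @param subCost,indelCost operation costs of the weighted edit distance.
#' @param alphabet \code{"DNA"} or \code{"PROT"}.
#' @param subMatrix similarity matrix (letters as dimnames), a path to an
#'   NCBI-format matrix file, or \code{NULL} for the alphabet default
#'   (+5/-4 for DNA, BLOSUM62 for protein).
#' @param gapOpen,gapExtend affine gap penalties (<= 0) of the pairwise
#'   rotation-refinement scoring.
#' @param msaGapOpen,msaGapExtend gap penalties (<= 0) of the profile
#'   alignment stage.
#' @param msaAffine use affine gap costs in the profile stage; the default is
#'   the literal linear-gap recurrence.
#' @return An \linkS4class{AlignParams} object.
#' @examples
#' p <- alignParams()
#' p@q
#' @export
alignParams <- function(q = 5L, blockLength = 50L, refineExtent = 1.0,
                        costModel = c("unit", "weighted"),
                        subCost = 1, indelCost = 1,
                        alphabet = c("DNA", "PROT"), subMatrix = NULL,
                        gapOpen = -10, gapExtend = -1,
                        msaGapOpen = -10, msaGapExtend = -1,
                        msaAffine = FALSE) {
  costModel <- match.arg(costModel)
  alphabet <- match.arg(alphabet)
  if (is.character(subMatrix) && length(subMatrix) == 1L)
    subMatrix <- readSubstitutionMatrix(subMatrix)
  if (is.null(subMatrix))
    subMatrix <- defaultSubstitutionMatrix(alphabet)
  new("AlignParams",
      q = as.integer(q), blockLength = as.integer(blockLength),
      refineExtent = as.numeric(refineExtent), costModel = costModel,
      subCost = as.numeric(subCost), indelCost = as.numeric(indelCost),
      alphabet = alphabet, subMatrix = subMatrix,
      gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend),
      msaGapOpen = as.numeric(msaGapOpen),
      msaGapExtend = as.numeric(msaGapExtend),
      msaAffine = isTRUE(msaAffine))
}

#' Default substitution matrix for an alphabet
#'
#' DNA uses a +5 match / -4 mismatch scheme over A, C, G, T; protein uses
#' BLOSUM62.
#'
#' @param alphabet \code{"DNA"} or \code{"PROT"}.
#' @return Numeric similarity matrix with letter dimnames.
#' @export
defaultSubstitutionMatrix <- function(alphabet = c("DNA", "PROT")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "DNA") {
    letters4 <- c("A", "C", "G", "T")
    m <- matrix(-4, 4, 4, dimnames = list(letters4, letters4))
    diag(m) <- 5
    m
  } else {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    env$BLOSUM62
  }
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text format used for matrices such as EDNAFULL or
#' BLOSUM62: '#' comment lines, a header row of column letters, then one row
#' per letter.
#'
#' @param path file path.
#' @return Numeric similarity matrix with letter dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("not a substitution matrix file: ", path)
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1L]),
                   numeric(length(cols))))
  dimnames(vals) <- list(rows, cols)
  # keep the square part in a consistent order
  common <- intersect(rows, cols)
  vals[common, common, drop = FALSE]
}

# Similarity matrix over an extended symbol set, for a given stage.
#
# letters: residue letters that actually occur. gapScore: score of '-' vs a
# residue (0 for '-'/'-'); NA to omit the gap symbol. The spacer '$' scores 0
# against itself and -2*abs(gapOpenRef) against anything else, so that the two
# spacer runs of a refined pair stay aligned and only the copied sequence ends
# drive the score. Letters absent from the base matrix score as mismatches.
similarityMatrix <- function(params, letters, gapScore = NA,
                             withSpacer = FALSE, gapOpenRef = params@gapOpen) {
  base <- params@subMatrix
  mismatch <- min(base)
  syms <- unique(c(letters))
  syms <- setdiff(syms, c("-", "$"))
  n <- length(syms)
  m <- matrix(mismatch, n, n, dimnames = list(syms, syms))
  known <- intersect(syms, rownames(base))
  if (length(known))
    m[known, known] <- base[known, known]
  # unknown letters score as mismatch even against themselves (weighted
  # scoring); under the unit cost model they match only themselves.
  if (!is.na(gapScore)) {
    m <- rbind(cbind(m, "-" = gapScore), "-" = c(rep(gapScore, n), 0))
    colnames(m)[n + 1L] <- "-"
    rownames(m)[n + 1L] <- "-"
  }
  if (withSpacer) {
    k <- ncol(m)
    sp <- -2 * abs(gapOpenRef)
    m <- rbind(cbind(m, "$" = sp), "$" = c(rep(sp, k), 0))
    colnames(m)[k + 1L] <- "$"
    rownames(m)[k + 1L] <- "$"
  }
  m
}

setMethod("show", "AlignParams", function(object) {
  cat("AlignParams: q=", object@q, ", blockLength=", object@blockLength,
      ", P=", object@refineExtent, ", ", object@costModel, " costs, ",
      object@alphabet, " alphabet\n", sep = "")
  cat("  pairwise gaps open/extend: ", object@gapOpen, "/", object@gapExtend,
      "; profile gaps: ", object@msaGapOpen, "/", object@msaGapExtend,
      if (object@msaAffine) " (affine)" else " (linear)", "\n", sep = "")
})
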