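# round half away from zero, independent of the banker's rounding of round()
fround <- function(x) floor(x + 0.5)

# per-pair number of blocks and effective refinement extent
pairBeta <- function(m, n, params) {
  max(1L, min(m, n) %/% params@blockLength)
}
effectiveP <- function(P, beta) min(P, beta / 3)

#' Build a refined pair of sequences
#'
#' The refinement step compares only the two ends of each sequence: the
#' refined string is a prefix of \code{round(P * m / beta)} letters, a spacer
#' run of the same length made of the sentinel '$' (not in the residue
#' alphabet), and a suffix of the same length, so its total length is
#' \code{3 * P * m / beta}. Scoring rotations of one refined string against
#' the other re-ranks candidate rotations cheaply, because only material near
#' the current cut can change the optimal rotation by a small amount.
#'
#' @param xRot the rotated first sequence (a plain string).
#' @param y the second sequence.
#' @param beta number of blocks of the pair.
#' @param P refinement extent, \code{0 < P <= beta / 3}.
#' @return List with \code{rx}, \code{ry} (the refined strings) and
#'   \code{wx}, \code{wy} (the prefix/spacer/suffix window lengths).
#' @examples
#' buildRefinedPair("ACGTACGTACGT", "ACGTACGTACGT", beta = 4, P = 1)$rx
#' @export
buildRefinedPair <- function(xRot, y, beta, P) {
  if (P <= 0 || P > beta / 3)
    stop("P must satisfy 0 < P <= beta/3 (P = ", P, ", beta = ", beta, ")")
  m <- nchar(xRot); n <- nchar(y)
  wx <- max(1L, fround(P * m / beta))
  wy <- max(1L, fround(P * n / beta))
  rx <- paste0(substr(xRot, 1L, wx), strrep("$", wx),
               substr(xRot, m - wx + 1L, m))
  ry <- paste0(substr(y, 1L, wy), strrep("$", wy),
               substr(y, n - wy + 1L, n))
  list(rx = rx, ry = ry, wx = wx, wy = wy)
}

# integer codes (0-based) of a string's characters into the row order of sim
codeString <- function(s, symbols) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], symbols) - 1L
  if (anyNA(idx))
    stop("letter outside the similarity matrix alphabet")
  idx
}

#' Refine a pairwise rotation using sequence ends
#'
#' Builds the refined pair from \code{rotateSeq(x, r0)} and \code{y}, scores
#' global alignments (Gotoh, with the configured substitution scores and gap
#' penalties) of every admissible rotation of the first refined string
#' against the fixed second one, and maps the best refined-string offset back
#' to an adjustment of \code{r0}. An offset k cutting within the copied
#' prefix (k <= w) maps to \code{r0 + k}; an offset cutting within the copied
#' suffix (k >= 2w) maps to \code{r0 - (3w - k)}; offsets cutting inside the
#' spacer do not correspond to rotations of \code{x} and are skipped. The
#' returned rotation therefore never moves more than w = round(P * m / beta)
#' away from \code{r0}. Score ties are broken towards the smallest rotation
#' index.
#'
#' @param x,y the sequences (plain strings); \code{x} is the rotated one.
#' @param r0 initial rotation from \code{\link{bestRotationBlockwise}}.
#' @param params an \linkS4class{AlignParams}; \code{beta} is derived from
#'   \code{params@blockLength} unless given.
#' @param beta optional override of the number of blocks.
#' @return Updated rotation in \code{[0, nchar(x))}.
#' @export
refineRotation <- function(x, y, r0, params = alignParams(), beta = NULL) {
  m <- nchar(x); n <- nchar(y)
  if (is.null(beta)) beta <- pairBeta(m, n, params)
  P <- effectiveP(params@refineExtent, beta)
  rp <- buildRefinedPair(rotateSeq(x, r0), y, beta, P)
  w <- rp$wx
  len <- 3L * w
  offsets <- c(0:w, if (2L * w < len) (2L * w):(len - 1L))
  cand <- ifelse(offsets <= w, r0 + offsets, r0 - (len - offsets)) %% m
  sim <- similarityMatrix(params, unique(c(strsplit(paste0(x, y), "")[[1L]])),
                          withSpacer = TRUE, gapOpenRef = params@gapOpen)
  symbols <- rownames(sim)
  ryCode <- codeString(rp$ry, symbols)
  rxCode <- codeString(rp$rx, symbols)
  scores <- vapply(offsets, function(k) {
    rot <- if (k == 0L) rxCode else c(rxCode[(k + 1L):len], rxCode[seq_len(k)])
    cpp_gotoh_score(rot, ryCode, sim, params@gapOpen, params@gapExtend)
  }, numeric(1))
  best <- scores == max(scores)
  as.integer(min(cand[best]))
}

#' Edit distance between two strings
#'
#' Under the unit cost model this is the Levenshtein distance, computed with
#' the bit-parallel (Myers) algorithm, blocked for strings longer than the
#' machine word; under the weighted model it is the textbook dynamic
#' programme with the configured substitution and indel costs. The spacer '$'
#' is an ordinary letter here.
#'
#' @param a,b strings.
#' @param params an \linkS4class{AlignParams} supplying the cost model.
#' @return Non-negative number.
#' @examples
#' editDistance("AAGCTAAGT", "AAGCCTTTAGT") # 3
#' @export
editDistance <- function(a, b, params = alignParams()) {
  if (params@costModel == "unit")
    cpp_edit_myers(a, b)
  else
    cpp_edit_dp(a, b, params@subCost, params@indelCost)
}

#' Pairwise cyclic comparison of a sequence set
#'
#' For every ordered pair (i, j), i != j, finds the rotation of sequence i
#' best aligning it to sequence j — blockwise q-gram search followed by
#' refined-pair rescoring — and stores it together with the edit distance
#' between the final refined pair. The diagonal is zero.
#'
#' @param seqs named character vector of sequences.
#' @param params an \linkS4class{AlignParams}.
#' @param refinedE compute e on the refined pair (the default, as the
#'   pipeline's guide-tree stage does). With \code{FALSE}, e is the edit
#'   distance between the full rotated sequences \code{rotateSeq(x, r)} and
#'   \code{y} — the cyclic edit distance the matrix approximates — which is
#'   slower per pair but uses the whole sequence; useful when the distances
#'   themselves, not just the rotations, are the object of study (e.g.
#'   distance-based trees).
#' @return A \linkS4class{CyclicPairMatrix}.
#' @export
buildPairMatrix <- function(seqs, params = alignParams(), refinedE = TRUE) {
  d <- length(seqs)
  if (d < 2L) stop("at least two sequences are required")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(d))
  lens <- nchar(seqs)
  e <- matrix(0, d, d, dimnames = list(names(seqs), names(seqs)))
  r <- matrix(0L, d, d, dimnames = dimnames(e))
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      if (i == j) next
      x <- seqs[[i]]; y <- seqs[[j]]
      beta <- pairBeta(lens[i], lens[j], params)
      res <- tryCatch(
        cpp_best_rotation(x, y, beta, params@q),
        error = function(err)
          stop("pair (", names(seqs)[i], ", ", names(seqs)[j], "): ",
               conditionMessage(err), call. = FALSE))
      ri <- refineRotation(x, y, res$r, params, beta = beta)
      if (refinedE) {
        P <- effectiveP(params@refineExtent, beta)
        rp <- buildRefinedPair(rotateSeq(x, ri), y, beta, P)
        e[i, j] <- editDistance(rp$rx, rp$ry, params)
      } else {
        e[i, j] <- editDistance(rotateSeq(x, ri), y, params)
      }
      r[i, j] <- ri
    }
  }
  new("CyclicPairMatrix", e = e, r = r, ids = names(seqs),
      seqLengths = as.integer(lens), params = params)
}

#' @describeIn CyclicPairMatrix-class rotation matrix accessor
#' @param x a \code{CyclicPairMatrix}.
#' @param ... unused.
#' @export
setMethod("rotations", "CyclicPairMatrix", function(x, ...) x@r)

#' @describeIn CyclicPairMatrix-class edit distance matrix accessor
#' @export
setMethod("editDistances", "CyclicPairMatrix", function(x, ...) x@e)

setMethod("show", "CyclicPairMatrix", function(object) {
  d <- length(object@ids)
  cat("CyclicPairMatrix over", d, "sequences\n")
  cat("  mean off-diagonal refined-pair edit distance:",
      round(mean(object@e[row(object@e) != col(object@e)]), 2), "\n")
})
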