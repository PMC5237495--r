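#' Single-row profile from a sequence
#'
#' @param seq residue string (ungapped).
#' @param index source sequence index.
#' @param rotation cumulative rotation already applied to \code{seq}.
#' @return An \linkS4class{AlignmentProfile} with one row; the row is its own
#'   anchor when \code{rotation} is 0.
#' @export
sequenceProfile <- function(seq, index = 1L, rotation = 0L) {
  new("AlignmentProfile", rows = unname(seq), seqIndex = as.integer(index),
      rotation = as.integer(rotation), anchor = 1L,
      seqLengths = nchar(seq))
}

charMatrix <- function(rows) {
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

#' Frequency matrix of a profile
#'
#' \code{F[c, i]} counts occurrences of symbol c in column i over the
#' profile's rows; every column sums to the number of rows.
#'
#' @param x an \linkS4class{AlignmentProfile}, or a character vector of
#'   equal-width gapped rows.
#' @param symbols symbol set for the rows of F; defaults to the symbols
#'   observed plus the gap.
#' @param ... unused.
#' @return Integer matrix with one row per symbol and one column per
#'   alignment column.
#' @export
setMethod("frequencyMatrix", "AlignmentProfile", function(x, symbols = NULL, ...) {
  rowFrequencies(x@rows, symbols)
})

#' @rdname frequencyMatrix
#' @export
setMethod("frequencyMatrix", "character", function(x, symbols = NULL, ...) {
  rowFrequencies(x, symbols)
})

rowFrequencies <- function(rows, symbols = NULL) {
  chm <- charMatrix(rows)
  if (is.null(symbols))
    symbols <- sort(unique(c(as.vector(chm), "-")))
  f <- vapply(seq_len(ncol(chm)),
              function(j) tabulate(match(chm[, j], symbols),
                                   nbins = length(symbols)),
              integer(length(symbols)))
  f <- matrix(f, nrow = length(symbols), dimnames = list(symbols, NULL))
  if (any(colSums(f) != nrow(chm)))
    stop("rows contain symbols outside the requested symbol set")
  f
}

# Column-pair score matrix of two row sets under the profile scoring scheme:
# p[i, j] = sum over symbol pairs (c, c') of F_A[c, i] * sim(c, c') * F_B[c', j].
profilePairScores <- function(rowsA, rowsB, params, withSpacer = FALSE) {
  letters <- setdiff(unique(c(unlist(strsplit(c(rowsA, rowsB), "", fixed = TRUE)))),
                     c("-", "$"))
  sim <- similarityMatrix(params, letters, gapScore = params@msaGapOpen,
                          withSpacer = withSpacer,
                          gapOpenRef = params@msaGapOpen)
  symbols <- rownames(sim)
  fa <- rowFrequencies(rowsA, symbols)
  fb <- rowFrequencies(rowsB, symbols)
  t(fa) %*% sim %*% fb
}

#' Profile-profile alignment
#'
#' Globally aligns the columns of profile B against the columns of profile A,
#' maximising the summed column-pair scores; a gap column inserted into a
#' profile inserts '-' into all its rows. Column-pair scores weight the
#' similarity of every symbol pair by the column frequencies of both
#' profiles (the frequency-matrix form of the profile scoring recurrence);
#' gap columns cost \code{msaGapOpen} per column in the default linear mode,
#' or Gotoh-style affine costs when \code{params@msaAffine} is set. The
#' merged profile keeps A's anchor; B's rows keep their rotations. By
#' convention the caller puts the profile with more rows in A.
#'
#' @param A,B \linkS4class{AlignmentProfile}s.
#' @param params an \linkS4class{AlignParams}.
#' @return The merged \linkS4class{AlignmentProfile}, with the alignment
#'   score in \code{attr(, "alignScore")}.
#' @export
profileAlign <- function(A, B, params = alignParams()) {
  p <- profilePairScores(A@rows, B@rows, params)
  res <- cpp_profile_align(p, params@msaGapOpen, params@msaGapOpen,
                           params@msaAffine, params@msaGapExtend,
                           params@msaGapExtend, FALSE)
  ops <- res$ops
  width <- length(ops)
  chmA <- charMatrix(A@rows)
  chmB <- charMatrix(B@rows)
  newA <- matrix("-", nrow(chmA), width)
  newB <- matrix("-", nrow(chmB), width)
  aCols <- ops %in% c(1L, 2L)
  bCols <- ops %in% c(1L, 3L)
  newA[, aCols] <- chmA
  newB[, bCols] <- chmB
  rows <- c(apply(newA, 1L, paste, collapse = ""),
            apply(newB, 1L, paste, collapse = ""))
  out <- new("AlignmentProfile", rows = rows,
             seqIndex = c(A@seqIndex, B@seqIndex),
             rotation = c(A@rotation, B@rotation),
             anchor = A@anchor,
             seqLengths = c(A@seqLengths, B@seqLengths))
  attr(out, "alignScore") <- res$score
  out
}

#' Align two sequences into a profile
#'
#' The elementary (sequence-with-sequence) case of the progressive stage:
#' \code{rotateSeq(x, r)} is globally aligned with \code{y} and stored as a
#' two-row profile whose anchor is \code{y} (left unrotated).
#'
#' @param x,y residue strings; \code{x} is the rotated one.
#' @param r rotation applied to \code{x} (from the pairwise stage).
#' @param params an \linkS4class{AlignParams}.
#' @param xIndex,yIndex source sequence indices recorded in the profile.
#' @return A two-row \linkS4class{AlignmentProfile}; row order is (y, x).
#' @export
alignPair <- function(x, y, r, params = alignParams(),
                      xIndex = 1L, yIndex = 2L) {
  A <- sequenceProfile(unname(y), yIndex)
  B <- sequenceProfile(rotateSeq(unname(x), r), xIndex, rotation = r %% nchar(x))
  profileAlign(A, B, params)
}

#' Propagate a pairwise rotation to a profile
#'
#' Transfers the stored pairwise rotation between the anchors of two profiles
#' to a column rotation for the whole of profile B: gaps inserted into B's
#' anchor row shift where the anchor's residue of original index r now sits,
#' so the column rotation is \code{r + g}, with g the number of gap
#' characters strictly before that residue's column (equivalently, the
#' residue's 0-based column index minus r).
#'
#' @param A,B \linkS4class{AlignmentProfile}s; A's and B's anchors identify
#'   the unrotated sequences \eqn{s_j} and \eqn{s_{j'}}.
#' @param M the \linkS4class{CyclicPairMatrix} holding \code{r = M[j', j].r}.
#' @return Integer column rotation for B, in \code{[0, ncol(B))}.
#' @export
propagateRotation <- function(A, B, M) {
  jA <- A@seqIndex[A@anchor]
  jB <- B@seqIndex[B@anchor]
  r <- M@r[jB, jA]
  if (r == 0L) return(0L)
  chars <- strsplit(B@rows[B@anchor], "", fixed = TRUE)[[1L]]
  col <- which(chars != "-")[r + 1L]
  as.integer(col - 1L)
}

#' Cyclically rotate the columns of a profile
#'
#' Every row is shifted left by k columns; each row's cumulative rotation
#' grows by the number of its residues (non-gap symbols) among the first k
#' columns, modulo its sequence length, so gap-stripping a rotated row still
#' recovers a rotation of its source sequence.
#'
#' @param B an \linkS4class{AlignmentProfile}.
#' @param k column rotation, \code{0 <= k < ncol(B)}.
#' @return The rotated \linkS4class{AlignmentProfile}.
#' @export
rotateProfileColumns <- function(B, k) {
  cols <- nchar(B@rows[1L])
  k <- as.integer(k %% cols)
  if (k == 0L) return(B)
  shifted <- rotateSeq(B@rows, k)
  lead <- substr(B@rows, 1L, k)
  gained <- nchar(gsub("-", "", lead, fixed = TRUE))
  new("AlignmentProfile", rows = shifted, seqIndex = B@seqIndex,
      rotation = as.integer((B@rotation + gained) %% B@seqLengths),
      anchor = B@anchor, seqLengths = B@seqLengths)
}

#' Refine a propagated profile rotation using profile ends
#'
#' The profile generalisation of the pairwise refinement: end-profiles are
#' built from each profile (P blocks of leading columns, a spacer block of
#' '$' columns of the same width, and P blocks of trailing columns), and
#' admissible column rotations of B's end-profile are scored against A's
#' fixed end-profile under the profile scoring scheme. The offset-to-rotation
#' mapping and the admissible window are exactly those of the pairwise
#' refinement, so the returned rotation stays within
#' \code{round(P * ncol(B) / beta)} columns of \code{k0}. Ties prefer
#' \code{k0}, then the smallest rotation.
#'
#' @param A,B \linkS4class{AlignmentProfile}s.
#' @param k0 propagated column rotation for B.
#' @param params an \linkS4class{AlignParams}.
#' @return Refined column rotation in \code{[0, ncol(B))}.
#' @export
refineProfileRotation <- function(A, B, k0, params = alignParams()) {
  colsA <- nchar(A@rows[1L])
  colsB <- nchar(B@rows[1L])
  beta <- max(1L, min(colsA, colsB) %/% params@blockLength)
  P <- effectiveP(params@refineExtent, beta)
  wA <- max(1L, fround(P * colsA / beta))
  wB <- max(1L, fround(P * colsB / beta))
  Bp <- rotateProfileColumns(B, k0)
  endA <- paste0(substr(A@rows, 1L, wA), strrep("$", wA),
                 substr(A@rows, colsA - wA + 1L, colsA))
  endB <- paste0(substr(Bp@rows, 1L, wB), strrep("$", wB),
                 substr(Bp@rows, colsB - wB + 1L, colsB))
  pFull <- profilePairScores(endA, endB, params, withSpacer = TRUE)
  lenB <- 3L * wB
  offs <- c(0:wB, if (2L * wB < lenB) (2L * wB):(lenB - 1L))
  cand <- as.integer((k0 + ifelse(offs <= wB, offs, -(lenB - offs))) %% colsB)
  scores <- vapply(offs, function(t) {
    ord <- ((seq_len(lenB) - 1L + t) %% lenB) + 1L
    cpp_profile_align(pFull[, ord, drop = FALSE], params@msaGapOpen,
                      params@msaGapOpen, params@msaAffine,
                      params@msaGapExtend, params@msaGapExtend, TRUE)$score
  }, numeric(1))
  best <- cand[scores >= max(scores) - 1e-9]
  if (k0 %in% best) as.integer(k0) else as.integer(min(best))
}

#' Rotation-aware progressive alignment over a guide tree
#'
#' Post-order traversal of the guide tree's joins. At each join the child
#' with more rows becomes profile A (ties: two single sequences follow the
#' sequence-pair orientation, the earlier-created child rotated against the
#' later; equal-sized profiles keep the earlier-created child as A); the
#' pairwise rotation between the two anchors is propagated to a column
#' rotation for B, refined on the profile ends, applied, and the profiles are
#' merged. The rotation array R is read off the final profile: entry i is
#' the cumulative rotation of sequence i's row, in original coordinates, with
#' the final anchor left at 0.
#'
#' @param seqs named character vector of input sequences.
#' @param M \linkS4class{CyclicPairMatrix} from \code{\link{buildPairMatrix}}.
#' @param tree \linkS4class{GuideTree} from \code{\link{neighbourJoining}}.
#' @param params an \linkS4class{AlignParams}.
#' @param rotate apply rotation propagation and refinement (the default).
#'   With \code{FALSE} the traversal performs a plain progressive profile
#'   alignment with no rotations at all — the behaviour of a conventional
#'   rotation-unaware aligner, useful as a baseline.
#' @return List with \code{rotations} (named integer array R) and
#'   \code{profile} (the internal \linkS4class{AlignmentProfile}).
#' @export
progressiveAlign <- function(seqs, M, tree, params = alignParams(),
                             rotate = TRUE) {
  d <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(d))
  if (d == 1L) {
    prof <- sequenceProfile(seqs[[1L]], 1L)
    return(list(rotations = stats::setNames(0L, names(seqs)), profile = prof))
  }
  getChild <- function(code, store) {
    if (code < 0L) sequenceProfile(seqs[[-code]], -code) else store[[code]]
  }
  store <- vector("list", nrow(tree@merges))
  for (t in seq_len(nrow(tree@merges))) {
    P1 <- getChild(tree@merges[t, 1L], store)
    P2 <- getChild(tree@merges[t, 2L], store)
    k1 <- length(P1@rows); k2 <- length(P2@rows)
    if (k1 == 1L && k2 == 1L) {
      A <- P2; B <- P1          # earlier child is the rotated sequence
    } else if (k1 >= k2) {
      A <- P1; B <- P2          # more rows, or earlier-created on a tie
    } else {
      A <- P2; B <- P1
    }
    if (rotate) {
      k0 <- propagateRotation(A, B, M)
      k <- refineProfileRotation(A, B, k0, params)
      B <- rotateProfileColumns(B, k)
    }
    store[[t]] <- profileAlign(A, B, params)
  }
  final <- store[[nrow(tree@merges)]]
  R <- integer(d)
  R[final@seqIndex] <- final@rotation
  list(rotations = stats::setNames(R, names(seqs)), profile = final)
}

#' @describeIn AlignmentProfile-class gapped rows
#' @param x an \code{AlignmentProfile}.
#' @param ... unused.
#' @export
setMethod("profileRows", "AlignmentProfile", function(x, ...) {
  stats::setNames(x@rows, paste0("s", x@seqIndex))
})

#' @describeIn AlignmentProfile-class anchor row index
#' @export
setMethod("anchorRow", "AlignmentProfile", function(x, ...) x@anchor)

#' @describeIn AlignmentProfile-class source sequence indices
#' @export
setMethod("seqIndices", "AlignmentProfile", function(x, ...) x@seqIndex)

#' @describeIn AlignmentProfile-class per-row cumulative rotations
#' @export
setMethod("rotations", "AlignmentProfile", function(x, ...) x@rotation)

setMethod("show", "AlignmentProfile", function(object) {
  cat("AlignmentProfile:", length(object@rows), "rows x",
      nchar(object@rows[1L]), "columns; anchor row", object@anchor,
      "(sequence", object@seqIndex[object@anchor], ")\n")
  shown <- utils::head(object@rows, 6L)
  trunc <- nchar(shown[1L]) > 60L
  cat(paste0("  s", utils::head(object@seqIndex, 6L), ": ",
             substr(shown, 1L, 60L), if (trunc) "..." else "",
             collapse = "\n"), "\n")
  if (length(object@rows) > 6L) cat("  ...\n")
})
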