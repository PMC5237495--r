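# Fixtures and independent oracles shared across the suite.

# worked-example sequences and the printed profiles
exSeqs <- c(s0 = "TAGTAGCT", s1 = "AAGTAAGCTA", s2 = "AAGCCTTTAGT",
            s3 = "AAGTAAGCT", s4 = "TTAATATAGCC")
exProfileA <- c(s0 = "A-G-C--TTA-GT",
                s1 = "AAG-C--TAAAGT",
                s2 = "AAGCC-TTTA-GT")
exProfileB <- c(s3 = "A---AGTAAG-C--T",
                s4 = "A-ATA-TA-GCC-TT")
exProfileC <- c(s0 = "A-G-C--TT-A--GT",
                s1 = "AAG-C--TA-A-AGT",
                s2 = "AAGCC-TTT-A--GT",
                s3 = "AAG-C--TA---AGT",
                s4 = "A-GCC-TTA-ATA-T")

# parameters suited to the 8-11 bp worked-example toys: ~3-letter blocks so
# the blockwise search has locality, q-grams no longer than a block
exParams <- function(...) alignParams(q = 3, blockLength = 3, ...)

# profile objects for the printed example (cumulative rotations read off the
# original sequences; s2 / s3 are the anchors)
exProfileAObj <- function() {
  new("AlignmentProfile", rows = unname(exProfileA),
      seqIndex = c(1L, 2L, 3L), rotation = c(4L, 4L, 0L), anchor = 3L,
      seqLengths = nchar(exSeqs[1:3]))
}
exProfileBObj <- function() {
  new("AlignmentProfile", rows = unname(exProfileB),
      seqIndex = c(4L, 5L), rotation = c(0L, 2L), anchor = 1L,
      seqLengths = nchar(exSeqs[4:5]))
}

randSeq <- function(m, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, m, replace = TRUE), collapse = "")
}

# brute-force scan oracle for the blockwise rotation search
bruteBestRotation <- function(x, y, beta, q) {
  ds <- vapply(0:(nchar(x) - 1L), function(r)
    blockwiseQgramDistance(rotateSeq(x, r), y, beta, q), numeric(1))
  list(r = which.min(ds) - 1L, distance = min(ds))
}

# brute-force cyclic edit distance oracle built on utils::adist
bruteCyclicArgmin <- function(x, y) {
  ds <- vapply(0:(nchar(x) - 1L), function(r) adist(rotateSeq(x, r), y)[1, 1],
               numeric(1))
  list(r = which.min(ds) - 1L, distance = min(ds))
}

# random rooted binary tree with positive branch lengths and its additive
# (cophenetic) distance matrix
randAdditive <- function(d) {
  tr <- ape::rtree(d, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
  D <- ape::cophenetic.phylo(tr)
  ord <- order(as.integer(sub("^t", "", rownames(D))))
  list(tree = tr, D = D[ord, ord])
}
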