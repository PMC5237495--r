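test_that("frequency matrices count the printed profile's columns", {
  f <- frequencyMatrix(exProfileA)
  expect_equal(unname(f["A", 1]), 3L)
  expect_equal(unname(f["A", 2]), 2L)
  expect_equal(unname(f["-", 2]), 1L)
  expect_true(all(colSums(f) == 3L))
  # a single-row profile is a per-column indicator
  f1 <- frequencyMatrix("AC-G")
  expect_true(all(colSums(f1) == 1L))
  expect_equal(unname(f1["-", 3]), 1L)
})

test_that("column-pair scores equal the direct summation of the recurrence", {
  p <- alignParams()
  set.seed(18)
  rowsA <- c("AC-GT", "ACGGT", "A--GT")
  rowsB <- c("AC-TT", "GCATT")
  sim <- circMSA:::similarityMatrix(p, c("A", "C", "G", "T"),
                                    gapScore = p@msaGapOpen)
  got <- circMSA:::profilePairScores(rowsA, rowsB, p)
  chmA <- do.call(rbind, strsplit(rowsA, ""))
  chmB <- do.call(rbind, strsplit(rowsB, ""))
  for (i in 1:5) for (j in 1:5) {
    # pScore(i, j) = sum over B rows k and symbols c of sim(B[k,j], c) * F[c,i]
    want <- 0
    for (k in 1:2) for (c in rownames(sim)) {
      want <- want + sim[chmB[k, j], c] * sum(chmA[, i] == c)
    }
    expect_equal(got[i, j], want)
  }
  # the column score on a concrete cell: F = {A:3} against two A rows
  one <- circMSA:::profilePairScores(c("A", "A", "A"), c("A", "A"), p)
  expect_equal(one[1, 1], 2 * 5 * 3)
})

test_that("aligning a sequence pair conserves both sequences", {
  p <- alignParams()
  prof <- alignPair("ACGTACGT", "ACGTACGT", 0, p)
  expect_equal(length(prof@rows), 2L)
  expect_false(any(grepl("-", prof@rows)))
  expect_equal(msaStats(prof)$avpd, 0)
  set.seed(19)
  for (k in 1:20) {
    x <- randSeq(sample(10:60, 1)); y <- randSeq(sample(10:60, 1))
    r <- sample(0:(nchar(x) - 1), 1)
    prof <- alignPair(x, y, r, p, xIndex = 1L, yIndex = 2L)
    stripped <- gsub("-", "", prof@rows)
    expect_equal(stripped[prof@seqIndex == 1L], rotateSeq(x, r))
    expect_equal(stripped[prof@seqIndex == 2L], y)
    expect_equal(prof@seqIndex[prof@anchor], 2L)  # y is the anchor
  }
})

test_that("pairwise alignment scores match an independent aligner", {
  skip_if_not(requireNamespace("Biostrings", quietly = TRUE) &&
                "pairwiseAlignment" %in% getNamespaceExports("Biostrings"))
  p <- alignParams()  # linear profile gaps: -10 per gapped column
  mat <- defaultSubstitutionMatrix("DNA")
  set.seed(20)
  for (k in 1:100) {
    x <- randSeq(sample(5:80, 1)); y <- randSeq(sample(5:80, 1))
    prof <- alignPair(x, y, 0, p)
    ours <- attr(prof, "alignScore")
    ref <- Biostrings::pairwiseAlignment(
      x, y, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 10, scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("profile alignment degenerates to pairwise on single rows", {
  p <- alignParams()
  x <- "TTGACCGTA"; y <- "TTGCCGTAA"
  viaPair <- alignPair(x, y, 0, p, xIndex = 1L, yIndex = 2L)
  viaProf <- profileAlign(sequenceProfile(y, 2L),
                          sequenceProfile(x, 1L), p)
  expect_equal(viaPair@rows, viaProf@rows)
  expect_equal(attr(viaPair, "alignScore"), attr(viaProf, "alignScore"))
})

test_that("merged profiles strip back to their rotated sources", {
  p <- alignParams()
  A <- exProfileAObj(); B <- exProfileBObj()
  merged <- profileAlign(A, B, p)
  expect_equal(length(merged@rows), 5L)
  expect_equal(merged@anchor, A@anchor)
  for (i in seq_along(merged@rows)) {
    src <- exSeqs[[merged@seqIndex[i]]]
    expect_equal(gsub("-", "", merged@rows[i]),
                 rotateSeq(src, merged@rotation[i]))
  }
})

test_that("rotation propagation counts gaps before the anchor residue", {
  A <- exProfileAObj(); B <- exProfileBObj()
  M <- buildPairMatrix(exSeqs, exParams())
  expect_equal(rotations(M)["s3", "s2"], 4L, ignore_attr = TRUE)
  k0 <- propagateRotation(A, B, M)
  expect_equal(k0, 7L)            # r + g = 4 + 3
  expect_equal(k0 - rotations(M)["s3", "s2"], 3L, ignore_attr = TRUE)  # g
  # a gap-free anchor propagates r unchanged; r = 0 propagates 0
  gapfree <- sequenceProfile(exSeqs[["s3"]], 4L)
  expect_equal(propagateRotation(A, gapfree, M), 4L)
  Mzero <- M; Mzero@r[] <- 0L
  expect_equal(propagateRotation(A, B, Mzero), 0L)
})

test_that("column rotation reproduces the printed profile C rows", {
  B <- exProfileBObj()
  rotated <- rotateProfileColumns(B, 7L)
  expect_equal(rotated@rows[1], "AAG-C--TA---AGT")   # printed s3 row
  expect_equal(rotated@rows[2], "A-GCC-TTA-ATA-T")   # printed s4 row
  # rotation bookkeeping keeps rows consistent with their sources
  expect_equal(gsub("-", "", rotated@rows[1]),
               rotateSeq(exSeqs[["s3"]], rotated@rotation[1]))
  expect_equal(gsub("-", "", rotated@rows[2]),
               rotateSeq(exSeqs[["s4"]], rotated@rotation[2]))
  # identity and cyclic-group behaviour
  expect_equal(rotateProfileColumns(B, 0L)@rows, B@rows)
  back <- rotateProfileColumns(rotated, 15L - 7L)
  expect_equal(back@rows, B@rows)
  expect_equal(back@rotation, B@rotation)
})

test_that("profile-rotation refinement recovers exact column rotations", {
  p <- alignParams(q = 3, blockLength = 5, refineExtent = 100)
  expect_equal(refineProfileRotation(sequenceProfile("ACGTAGGA", 1L),
                                     sequenceProfile("ACGTAGGA", 2L), 0L, p),
               0L)
  set.seed(21)
  for (k in 1:10) {
    rows <- vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
      character(1))
    A <- new("AlignmentProfile", rows = rows, seqIndex = 1:3,
             rotation = c(0L, 0L, 0L), anchor = 1L,
             seqLengths = nchar(rows))
    kk <- sample(0:29, 1)
    B <- rotateProfileColumns(
      new("AlignmentProfile", rows = rows, seqIndex = 4:6,
          rotation = c(0L, 0L, 0L), anchor = 1L, seqLengths = nchar(rows)),
      kk)
    true <- (30L - kk) %% 30L
    # k0 jittered within the refinement window still converges to the truth
    k0 <- (true + sample(-2:2, 1)) %% 30L
    expect_equal(refineProfileRotation(A, B, k0, p), true)
  }
})
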