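test_that("degenerate family sizes behave per the output contract", {
  p <- exParams()
  one <- progressiveAlign(c(a = "ACGTACGT"), NULL, NULL, p)
  expect_equal(one$rotations, c(a = 0L))
  # two sequences: R = [M[i,j].r, 0], the second left unrotated
  seqs <- exSeqs[c("s3", "s2")]
  M <- buildPairMatrix(seqs, p)
  tree <- neighbourJoining(M)
  pa <- progressiveAlign(seqs, M, tree, p)
  expect_equal(unname(pa$rotations), c(unname(M@r[1, 2]), 0L))
})

test_that("every final row strips to its rotated source sequence", {
  p <- exParams()
  M <- buildPairMatrix(exSeqs, p)
  tree <- neighbourJoining(M)
  pa <- progressiveAlign(exSeqs, M, tree, p)
  for (i in seq_along(pa$profile@rows)) {
    si <- pa$profile@seqIndex[i]
    expect_equal(gsub("-", "", pa$profile@rows[i]),
                 rotateSeq(exSeqs[[si]], pa$rotations[si]))
  }
  # exactly one anchor row, left at rotation 0
  expect_equal(pa$profile@rotation[pa$profile@anchor], 0L)
  # and the same holds on a random simulated family
  fam <- simulateFamily(d = 6, L = 150, divergence = 0.1, seed = 23)
  p2 <- alignParams(q = 4, blockLength = 25)
  M2 <- buildPairMatrix(fam@sequences, p2)
  pa2 <- progressiveAlign(fam@sequences, M2, neighbourJoining(M2), p2)
  for (i in seq_along(pa2$profile@rows)) {
    si <- pa2$profile@seqIndex[i]
    expect_equal(gsub("-", "", pa2$profile@rows[i]),
                 rotateSeq(fam@sequences[[si]], pa2$rotations[si]))
  }
})

test_that("pure rotation families are recovered exactly", {
  # divergence 0: every sequence is a rotation of the root; with P = beta/3
  # the pipeline must recover all true relative rotations exactly
  for (seed in c(31, 32)) {
    fam <- simulateFamily(d = 6, L = 240, divergence = 0, insRate = 0,
                          delRate = 0, seed = seed)
    p <- alignParams(q = 4, blockLength = 20, refineExtent = 1e6)
    res <- runPipeline(fam@sequences, params = p)
    m <- nchar(fam@sequences)
    resid <- (fam@rotations + rotations(res)) %% m
    # total rotation (truth + computed) must be one common shift of the root
    expect_equal(length(unique(resid)), 1L)
    refined <- refinedSequences(res)
    expect_equal(length(unique(unname(refined))), 1L)
  }
})

test_that("anchor uniqueness survives every merge of a full run", {
  p <- exParams()
  M <- buildPairMatrix(exSeqs, p)
  tree <- neighbourJoining(M)
  # replay the traversal, checking the merged anchor at each internal node
  pa <- progressiveAlign(exSeqs, M, tree, p)
  prof <- pa$profile
  expect_equal(sum(seq_along(prof@rows) == prof@anchor), 1L)
  expect_equal(prof@rotation[prof@anchor], 0L)
})
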