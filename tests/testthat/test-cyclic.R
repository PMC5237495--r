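test_that("refined pairs are prefix + spacer + suffix of the stated length", {
  rp <- buildRefinedPair("ACGTACGTACGT", "ACGTACGTACGT", beta = 4, P = 1)
  expect_equal(rp$rx, "ACG$$$CGT")
  expect_equal(rp$ry, "ACG$$$CGT")
  set.seed(8)
  for (k in 1:15) {
    m <- sample(12:200, 1); n <- sample(12:200, 1)
    beta <- sample(3:6, 1)
    P <- runif(1, 0.3, beta / 3)
    rp <- buildRefinedPair(randSeq(m), randSeq(n), beta, P)
    w <- floor(P * m / beta + 0.5)
    expect_equal(nchar(rp$rx), 3 * max(1, w))
    mid <- substr(rp$rx, rp$wx + 1, 2 * rp$wx)
    expect_equal(mid, strrep("$", rp$wx))
  }
  # boundary P = beta/3: windows cover the first and last thirds
  x <- randSeq(12)
  rp <- buildRefinedPair(x, x, beta = 3, P = 1)
  expect_equal(rp$rx, paste0(substr(x, 1, 4), "$$$$", substr(x, 9, 12)))
  expect_error(buildRefinedPair("ACGT", "ACGT", beta = 3, P = 2),
               "P must satisfy")
})

test_that("rotation refinement is exact on pure rotations and bounded", {
  p <- alignParams(q = 3, blockLength = 8, refineExtent = 100)  # P -> beta/3
  set.seed(9)
  for (k in 1:10) {
    y <- randSeq(60)
    kk <- sample(1:12, 1)
    x <- rotateSeq(y, kk)
    r0 <- bestRotationBlockwise(x, y, q = 3, blockLength = 8)
    r <- refineRotation(x, y, r0, p)
    expect_equal(r, (60 - kk) %% 60)
    # identical strings stay at rotation 0
    expect_equal(refineRotation(y, y, 0L,
                                alignParams(q = 3, blockLength = 8)), 0L)
    # the refined rotation never leaves the window around r0
    beta <- 60 %/% 8
    w <- floor(min(p@refineExtent, beta / 3) * 60 / beta + 0.5)
    dist <- min((r - r0) %% 60, (r0 - r) %% 60)
    expect_lte(dist, w)
  }
})

test_that("edit distance matches the adist oracle under unit costs", {
  expect_equal(editDistance("GATTACA", "GATTACA"), 0)
  expect_equal(editDistance("AAGCTAAGT", "AAGCCTTTAGT"), 3)
  set.seed(10)
  for (k in 1:500) {
    a <- randSeq(sample(1:300, 1), c("A", "C", "G", "T", "N"))
    b <- randSeq(sample(1:300, 1), c("A", "C", "G", "T", "N"))
    expect_equal(editDistance(a, b), adist(a, b)[1, 1])
  }
})

test_that("weighted edit distance honours the configured costs", {
  pw <- alignParams(costModel = "weighted", subCost = 1, indelCost = 1)
  set.seed(12)
  for (k in 1:50) {
    a <- randSeq(sample(1:80, 1)); b <- randSeq(sample(1:80, 1))
    expect_equal(editDistance(a, b, pw), adist(a, b)[1, 1])
  }
  # cheap indels make substitution-free edits preferable
  p2 <- alignParams(costModel = "weighted", subCost = 2, indelCost = 0.5)
  expect_equal(editDistance("AB", "B", p2), 0.5)
  expect_equal(editDistance("AC", "GC", p2), 1)  # min(sub 2, ins+del 1)
})

test_that("the pair matrix stores consistent rotations and distances", {
  p <- exParams()
  M <- buildPairMatrix(c(a = "ACGTACGA", b = "ACGTACGA"), p)
  expect_equal(M@e[1, 2], 0)
  expect_equal(M@r[1, 2], 0L)
  # the published worked pair: rotation of s3 against s2 is 4
  M <- buildPairMatrix(exSeqs, p)
  expect_equal(rotations(M)["s3", "s2"], 4L, ignore_attr = TRUE)
  # stored e always equals an independent recomputation from stored r
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    beta <- max(1L, min(nchar(exSeqs[i]), nchar(exSeqs[j])) %/% p@blockLength)
    rp <- buildRefinedPair(rotateSeq(exSeqs[[i]], M@r[i, j]), exSeqs[[j]],
                           beta, min(p@refineExtent, beta / 3))
    expect_equal(M@e[i, j], adist(rp$rx, rp$ry)[1, 1])
  }
})

test_that("pairs violating the q-gram precondition are named in the error", {
  p <- alignParams(q = 6, blockLength = 3)
  expect_error(buildPairMatrix(c(u = "ACGTACGTACGT", v = "ACGTTCGTACGA"), p),
               "pair \\(u, v\\)")
})
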