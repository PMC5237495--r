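test_that("q-gram profiles count every factor occurrence", {
  expect_equal(qgramProfile("aaa", 2), c(aa = 2L))
  expect_equal(qgramProfile("abab", 2), c(ab = 2L, ba = 1L))
  set.seed(5)
  for (k in 1:10) {
    x <- randSeq(sample(5:60, 1))
    q <- sample(1:4, 1)
    expect_equal(sum(qgramProfile(x, q)), nchar(x) - q + 1L)
  }
  expect_error(qgramProfile("ab", 3), "shorter than q")
})

test_that("q-gram distance is an L1 profile distance", {
  expect_equal(qgramDistance("GATTACA", "GATTACA", 3), 0)
  expect_equal(qgramDistance("abab", "baba", 2), 2)
  expect_equal(qgramDistance("ab", "abb", 1), 1)
  x <- randSeq(30); y <- randSeq(25)
  expect_equal(qgramDistance(x, y, 2), qgramDistance(y, x, 2))
})

test_that("blockwise distance reduces to plain q-gram distance at beta = 1", {
  set.seed(6)
  for (k in 1:10) {
    x <- randSeq(sample(5:40, 1)); y <- randSeq(sample(5:40, 1))
    expect_equal(blockwiseQgramDistance(x, y, 1, 2), qgramDistance(x, y, 2))
  }
})

test_that("blockwise distance sums per-block distances and checks blocks", {
  expect_equal(blockwiseQgramDistance("aabb", "bbaa", 2, 1), 8)
  expect_equal(blockwiseQgramDistance("ACGTACGT", "ACGTACGT", 2, 2), 0)
  x <- randSeq(24); y <- randSeq(24)
  expect_equal(blockwiseQgramDistance(x, y, 3, 2),
               blockwiseQgramDistance(y, x, 3, 2))
  expect_error(blockwiseQgramDistance("acgtac", "acgtac", 3, 3),
               "shorter than q")
})

test_that("rotation search returns the argmin with smallest-index ties", {
  expect_equal(bestRotationBlockwise("ACGTT", "ACGTT", q = 2, beta = 1), 0L,
               ignore_attr = TRUE)
  expect_equal(bestRotationBlockwise("bbaa", "aabb", q = 2, beta = 1), 2L,
               ignore_attr = TRUE)
})

test_that("incremental rotation search agrees with the exhaustive scan", {
  set.seed(7)
  tried <- 0
  while (tried < 200) {
    m <- sample(6:48, 1); n <- sample(6:48, 1)
    q <- sample(1:3, 1); beta <- sample(1:3, 1)
    if (min(diff(floor((0:beta) * m / beta))) < q) next
    if (min(diff(floor((0:beta) * n / beta))) < q) next
    x <- randSeq(m); y <- randSeq(n)
    got <- bestRotationBlockwise(x, y, q = q, beta = beta)
    ref <- bruteBestRotation(x, y, beta, q)
    expect_equal(as.integer(got), ref$r)
    expect_equal(attr(got, "distance"), ref$distance)
    tried <- tried + 1
  }
})
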