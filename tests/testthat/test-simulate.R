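test_that("the simulator is reproducible and rotations round-trip", {
  f1 <- simulateFamily(d = 5, L = 200, divergence = 0.2, seed = 42)
  f2 <- simulateFamily(d = 5, L = 200, divergence = 0.2, seed = 42)
  expect_identical(f1@sequences, f2@sequences)
  expect_identical(f1@rotations, f2@rotations)
  f3 <- simulateFamily(d = 5, L = 200, divergence = 0.2, seed = 43)
  expect_false(identical(f1@sequences, f3@sequences))
  # stored construction: un-rotating recovers the unrotated leaves
  m <- nchar(f1@sequences)
  expect_identical(unname(rotateSeq(f1@sequences, (m - f1@rotations) %% m)),
                   unname(f1@unrotated))
})

test_that("zero divergence and zero indel rates copy the root", {
  fam <- simulateFamily(d = 4, L = 150, divergence = 0, insRate = 0,
                        delRate = 0, seed = 2)
  expect_true(all(fam@unrotated == fam@root))
})

test_that("pairwise mismatches match the Jukes-Cantor expectation", {
  # two leaves at per-site substitution probability p on independent branches
  # differ per site with probability 2p(1-p) + (2/3)p^2 = 2p - (4/3)p^2
  p <- 0.05
  mism <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  obs <- vapply(1:4, function(s) {
    fam <- simulateFamily(d = 2, L = 2500, divergence = p, insRate = 0,
                          delRate = 0, topology = "star", seed = 100 + s)
    mism(fam@unrotated[[1]], fam@unrotated[[2]])
  }, numeric(1))
  expected <- 2 * p - (4 / 3) * p^2
  # MC tolerance: sd of the mean over 4 x 2500 sites is about 0.003
  expect_lt(abs(mean(obs) - expected), 0.01)
})

test_that("leaf lengths stay near the root length under preset rates", {
  fam <- simulateFamily(d = 8, L = 2500, divergence = 0.35, seed = 5)
  expect_true(all(abs(nchar(fam@sequences) - 2500) / 2500 < 0.05))
})

test_that("dataset labels follow the A.B.C convention", {
  expect_equal(nameDataset(12, 2500, 0.05), "12.2500.5")
  expect_equal(nameDataset(12, 2500, 0.05, rotated = TRUE), "12.2500.5.rot")
  expect_equal(nameDataset(50, 2500, 0.35), "50.2500.35")
  expect_equal(nameDataset(25, 2500, 0.20), "25.2500.20")
})

test_that("family files and JSON configs round-trip", {
  fam <- simulateFamily(d = 3, L = 80, divergence = 0.1, seed = 9)
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeFamily(fam, fa, tsv)
  expect_identical(readFasta(fa), fam@sequences)
  tab <- read.delim(tsv)
  expect_equal(tab$rotation, fam@rotations)
  cfgFile <- tempfile(fileext = ".json")
  writeLines('{"d": 3, "L": 80, "divergence": 0.1, "seed": 9}', cfgFile)
  fam2 <- do.call(simulateFamily, readSimConfig(cfgFile))
  expect_identical(fam2@sequences, fam@sequences)
  writeLines('{"d": 3, "bogus": 1}', cfgFile)
  expect_error(readSimConfig(cfgFile), "unknown simulation fields")
})

test_that("invalid configurations are rejected", {
  expect_error(simulateFamily(divergence = 0.8, seed = 1), "divergence")
  expect_error(simulateFamily(insRate = -1, seed = 1), "rates")
  expect_error(simulateFamily(d = 0, seed = 1), "positive")
})
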