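test_that("rotation follows the circular-string definition", {
  expect_equal(rotateSeq("baababac", 1), "aababacb")
  expect_equal(rotateSeq("baababac", 2), "ababacba")
  expect_equal(rotateSeq("baababac", 0), "baababac")
  # reduction modulo m and letter conservation
  expect_equal(rotateSeq("ACGT", 6), rotateSeq("ACGT", 2))
  x <- randSeq(31)
  r <- sample(0:30, 1)
  expect_equal(sort(strsplit(rotateSeq(x, r), "")[[1]]),
               sort(strsplit(x, "")[[1]]))
})

test_that("rotations compose additively and are a bijection", {
  set.seed(11)
  for (k in 1:20) {
    x <- randSeq(sample(2:40, 1))
    m <- nchar(x)
    a <- sample(0:(2 * m), 1); b <- sample(0:(2 * m), 1)
    expect_equal(rotateSeq(rotateSeq(x, a), b), rotateSeq(x, (a + b) %% m))
  }
  x <- randSeq(12)
  expect_length(unique(vapply(0:11, function(r) rotateSeq(x, r),
                              character(1))), 12L)
})

test_that("FASTA round trips preserve ids, order and residues", {
  tf <- tempfile(fileext = ".fa")
  writeFasta(exSeqs, tf)
  back <- readFasta(tf)
  expect_identical(back, exSeqs)
  # lowercase input is uppercased on read
  writeLines(c(">x", "acgt"), tf)
  expect_identical(unname(readFasta(tf)), "ACGT")
  expect_equal(nchar(readFasta(tf)), c(x = 4L))
})

test_that("unreadable inputs are rejected with useful errors", {
  tf <- tempfile(fileext = ".fa")
  file.create(tf)
  expect_error(readFasta(tf), "no sequences")
  writeLines(c(">gapped", "AC-GT"), tf)
  expect_error(readFasta(tf), "gap or spacer")
})

test_that("writeRotated writes rotateSeq(s_i, R[i]) per record", {
  tf <- tempfile(fileext = ".fa")
  writeRotated(c(a = "ACGT"), 2L, tf)
  expect_identical(unname(readFasta(tf)), "GTAC")
  # zero rotations: output identical to input
  writeRotated(exSeqs, rep(0L, 5), tf)
  expect_identical(readFasta(tf), exSeqs)
  expect_error(writeRotated(exSeqs, c(0L, 1L), tf), "rotation array")
})

test_that("recorded simulator rotations invert back to the unrotated leaves", {
  fam <- simulateFamily(d = 5, L = 120, divergence = 0.1, seed = 3)
  tf <- tempfile(fileext = ".fa")
  m <- nchar(fam@sequences)
  writeRotated(fam@sequences, (m - fam@rotations) %% m, tf)
  expect_identical(unname(readFasta(tf)), unname(fam@unrotated))
})
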