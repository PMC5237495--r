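#' q-gram profile of a string
#'
#' Counts every occurrence of each length-q factor of \code{x} (linear, not
#' circular).
#'
#' @param x a string.
#' @param q q-gram length; \code{nchar(x)} must be at least q.
#' @return Named integer vector of counts; the counts sum to
#'   \code{nchar(x) - q + 1}.
#' @examples
#' qgramProfile("abab", 2) # ab: 2, ba: 1
#' @export
qgramProfile <- function(x, q) {
  m <- nchar(x)
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1")
  if (m < q) stop("string of length ", m, " is shorter than q = ", q)
  starts <- seq_len(m - q + 1L)
  grams <- substring(x, starts, starts + q - 1L)
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

#' q-gram distance between two strings
#'
#' The L1 distance between the q-gram profiles of \code{x} and \code{y}.
#'
#' @param x,y strings of length >= q.
#' @param q q-gram length.
#' @return Non-negative integer; zero iff the profiles coincide.
#' @export
qgramDistance <- function(x, y, q) {
  gx <- qgramProfile(x, q)
  gy <- qgramProfile(y, q)
  keys <- union(names(gx), names(gy))
  cx <- ifelse(keys %in% names(gx), gx[keys], 0L)
  cy <- ifelse(keys %in% names(gy), gy[keys], 0L)
  sum(abs(cx - cy))
}

# 0-based block start offsets of the "as evenly as possible" partition of a
# length-L string into beta blocks: block j spans [floor(jL/beta),
# floor((j+1)L/beta)).
blockBounds <- function(L, beta) {
  floor(seq.int(0L, beta) * L / beta)
}

#' Blockwise q-gram distance
#'
#' Both strings are partitioned into \code{beta} blocks as evenly as possible
#' (block j of a length-L string spans \code{[floor(jL/beta),
#' floor((j+1)L/beta))}) and the q-gram distances of corresponding blocks are
#' summed. With \code{beta = 1} this reduces to \code{\link{qgramDistance}}.
#' The partition enforces locality: matching material only counts when it
#' occurs in corresponding parts of the two strings.
#'
#' @param x,y strings.
#' @param beta number of blocks (>= 1).
#' @param q q-gram length; every block of both strings must be at least q
#'   long.
#' @return Non-negative integer.
#' @export
blockwiseQgramDistance <- function(x, y, beta, q) {
  beta <- as.integer(beta)
  if (beta < 1L) stop("beta must be >= 1")
  bx <- blockBounds(nchar(x), beta)
  by <- blockBounds(nchar(y), beta)
  if (min(diff(bx)) < q || min(diff(by)) < q)
    stop("a block is shorter than q = ", q,
         " (lengths ", nchar(x), "/", nchar(y), ", beta = ", beta, ")")
  total <- 0L
  for (j in seq_len(beta)) {
    xb <- substr(x, bx[j] + 1L, bx[j + 1L])
    yb <- substr(y, by[j] + 1L, by[j + 1L])
    total <- total + qgramDistance(xb, yb, q)
  }
  total
}

#' Best rotation of x against y under the blockwise q-gram distance
#'
#' Scans all \code{nchar(x)} rotations of \code{x} (with incremental q-gram
#' count updates at the block boundaries, so the scan is linear in
#' \code{nchar(x) * beta}) and returns the rotation minimising
#' \code{blockwiseQgramDistance(rotateSeq(x, r), y, beta, q)}. Ties are broken
#' towards the smallest rotation index.
#'
#' @param x,y strings; \code{x} is the one rotated.
#' @param q q-gram length.
#' @param blockLength target block length from which \code{beta} is derived as
#'   \code{max(1, floor(min(m, n) / blockLength))} when \code{beta} is not
#'   given.
#' @param beta number of blocks, overriding the derivation.
#' @return Integer rotation in \code{[0, nchar(x))}.
#' @examples
#' bestRotationBlockwise("bbaa", "aabb", q = 2, beta = 1) # 2
#' @export
bestRotationBlockwise <- function(x, y, q = 5L, blockLength = 50L,
                                  beta = NULL) {
  m <- nchar(x); n <- nchar(y)
  if (is.null(beta))
    beta <- max(1L, min(m, n) %/% as.integer(blockLength))
  beta <- as.integer(beta)
  bx <- blockBounds(m, beta); by <- blockBounds(n, beta)
  if (min(diff(bx)) < q || min(diff(by)) < q)
    stop("a block is shorter than q = ", q,
         " (lengths ", m, "/", n, ", beta = ", beta, ")")
  res <- cpp_best_rotation(x, y, beta, as.integer(q))
  structure(res$r, distance = res$distance)
}
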