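#' Standard genetic measures of a multiple sequence alignment
#'
#' Computes the evaluation measures used for alignment quality: alignment
#' length (columns); polymorphic (PM) sites, i.e. columns with at least two
#' distinct non-gap symbols; and, summed over all unordered row pairs and
#' columns: substitutions (both rows non-gap and unequal), split into
#' transitions (A/G or C/T) and transversions (all other substitutions);
#' indels (exactly one of the two rows gapped, counted per gap character, not
#' per run); and AVPD, the average pairwise distance
#' \code{(substitutions + indels) / number of row pairs}. Columns where both
#' rows are gapped contribute nothing.
#'
#' @param msa an \linkS4class{AlignmentProfile} or a character vector of
#'   equal-width gapped rows.
#' @return A one-row data.frame with columns \code{length}, \code{pmSites},
#'   \code{transitions}, \code{transversions}, \code{substitutions},
#'   \code{indels}, \code{avpd}.
#' @examples
#' msaStats(c("ACGT", "GCGT"))  # one transition, avpd 1
#' @export
msaStats <- function(msa) {
  if (is(msa, "AlignmentProfile")) msa <- msa@rows
  if (length(unique(nchar(msa))) > 1L)
    stop("alignment rows have unequal widths")
  chm <- charMatrix(msa)
  d <- nrow(chm); cols <- ncol(chm)
  pm <- sum(vapply(seq_len(cols), function(j) {
    syms <- unique(chm[, j])
    length(setdiff(syms, "-")) >= 2L
  }, logical(1)))
  ts <- tv <- ind <- 0
  if (d >= 2L) {
    isTsPair <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
    for (i in seq_len(d - 1L)) {
      for (j in (i + 1L):d) {
        a <- chm[i, ]; b <- chm[j, ]
        ga <- a == "-"; gb <- b == "-"
        sub <- !ga & !gb & a != b
        ind <- ind + sum(xor(ga, gb))
        ts <- ts + sum(sub & isTsPair(a, b))
        tv <- tv + sum(sub & !isTsPair(a, b))
      }
    }
  }
  npairs <- max(1L, d * (d - 1L) / 2L)
  data.frame(length = cols, pmSites = pm, transitions = ts,
             transversions = tv, substitutions = ts + tv, indels = ind,
             avpd = (ts + tv + ind) / npairs)
}

#' Relative Robinson-Foulds distance between two trees
#'
#' The symmetric difference of the non-trivial bipartitions of the two
#' (unrooted) trees, divided by \code{2 * (n - 3)}, so identical topologies
#' give 0 and maximally different fully resolved topologies give 1.
#'
#' @param t1,t2 \linkS4class{GuideTree}, \code{phylo}, or Newick string/file.
#' @return Relative RF distance in [0, 1].
#' @export
rfDistance <- function(t1, t2) {
  norm <- function(t) {
    if (is(t, "GuideTree")) t <- asPhylo(t)
    if (is.character(t))
      t <- if (file.exists(t)) ape::read.tree(t) else ape::read.tree(text = t)
    if (!inherits(t, "phylo")) stop("not a tree")
    ape::unroot(t)
  }
  t1 <- norm(t1); t2 <- norm(t2)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf label sets")
  n <- length(t1$tip.label)
  if (n < 4L) stop("relative RF needs at least 4 leaves")
  as.numeric(phangorn::RF.dist(t1, t2, normalize = TRUE))
}

#' Write a per-alignment stats table to TSV
#'
#' @param stats data.frame from \code{\link{msaStats}} (rows may be named by
#'   dataset).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMsaStats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(stats)))
  invisible(path)
}
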