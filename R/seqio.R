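#' Read circular sequences from a multiFASTA file
#'
#' Records are uppercased on read and returned in file order as a named
#' character vector (names are the FASTA headers). Sequences are treated as
#' circular molecules downstream; gap ('-') or spacer ('$') symbols are not
#' permitted in input residues.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of residue strings.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeFasta(c(x = "ACGT"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("no sequences in ", path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[-$]", seqs)
  if (any(bad))
    stop("record '", names(seqs)[bad][1L],
         "' contains gap or spacer symbols; not a residue sequence")
  if (any(nchar(seqs) == 0L))
    stop("record '", names(seqs)[nchar(seqs) == 0L][1L], "' is empty")
  seqs
}

#' Read a gapped alignment from a FASTA file
#'
#' Like \code{\link{readFasta}} but rows may contain '-' gap characters and
#' all rows must have equal width.
#'
#' @param path path to a gapped FASTA file.
#' @return Named character vector of equal-width rows.
#' @export
readAlignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no sequences in ", path)
  rows <- toupper(as.character(set))
  if (length(unique(nchar(rows))) > 1L)
    stop("alignment rows in ", path, " have unequal widths")
  rows
}

#' Write sequences to a multiFASTA file
#'
#' @param seqs named character vector of sequences (gapped rows allowed).
#' @param path output path. The file is written atomically (temporary file
#'   then rename), so a failure never leaves a partial output.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), tmp)
  if (!file.rename(tmp, path)) {  # cross-device fallback
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Rotate a circular sequence
#'
#' Returns the rotation \eqn{x^r = x[r..m-1]x[0..r-1]}: the letter at 0-based
#' position r moves to the front. \code{r} is reduced modulo the sequence
#' length, and both arguments recycle elementwise.
#'
#' @param x character vector of sequences.
#' @param r integer rotation offset(s).
#' @return Character vector of rotated sequences.
#' @examples
#' rotateSeq("baababac", 1) # "aababacb"
#' @export
rotateSeq <- function(x, r) {
  m <- nchar(x)
  r <- as.integer(r %% m)
  out <- ifelse(r == 0L, x,
                paste0(substr(x, r + 1L, m), substr(x, 1L, r)))
  names(out) <- names(x)
  out
}

#' Write rotated sequences to a multiFASTA file
#'
#' Record i of the output holds \code{rotateSeq(seqs[i], R[i])}; identifiers
#' are preserved. This is the tool's principal output: the refined
#' (linearised) sequences ready for any conventional MSA program.
#'
#' @param seqs named character vector of input sequences.
#' @param R integer rotation array, one entry per sequence.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeRotated <- function(seqs, R, path) {
  if (length(R) != length(seqs))
    stop("rotation array has ", length(R), " entries for ", length(seqs),
         " sequences")
  writeFasta(rotateSeq(seqs, R), path)
}
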