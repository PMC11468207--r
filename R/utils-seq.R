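# Low-level DNA string helpers shared by the index, masking and probe-design
# layers.  All k-mer handling in the package goes through these functions so
# that canonicalization is applied consistently everywhere.

IUPAC_CHARS <- "ACGTUNRYSWKMBDHV"

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement.  With odd `k` no k-mer equals its own reverse
#' complement, so the mapping is 2-to-1 everywhere.
#'
#' @param kmers Character vector of k-mers (all the same length).
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  pmin(kmers, revcomp(kmers))
}

# Decompose sequences into their sliding windows of length k.
# Returns a data.frame-free list: seq_id (integer index into `seqs`),
# pos (1-based window start), kmer (character).  Windows containing
# characters outside A/C/G/T are dropped when drop_ambiguous = TRUE.
kmerize <- function(seqs, k, drop_ambiguous = TRUE) {
  stopifnot(k >= 1)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  nwin <- pmax(lens - k + 1L, 0L)
  if (sum(nwin) == 0L) {
    return(list(seq_id = integer(0), pos = integer(0), kmer = character(0)))
  }
  seq_id <- rep.int(seq_along(seqs), nwin)
  pos <- sequence(nwin)
  kmer <- substring(seqs[seq_id], pos, pos + k - 1L)
  if (drop_ambiguous) {
    ok <- !grepl("[^ACGT]", kmer)
    seq_id <- seq_id[ok]
    pos <- pos[ok]
    kmer <- kmer[ok]
  }
  list(seq_id = seq_id, pos = pos, kmer = kmer)
}

# Hard validation of read/probe alphabets.  Names the offending element so
# malformed FASTQ records are easy to locate.
check_alphabet <- function(seqs, what = "read") {
  bad <- grep(sprintf("[^%s]", IUPAC_CHARS), toupper(seqs))
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s %d contains non-IUPAC characters: %s",
      what, bad[1L], substr(seqs[bad[1L]], 1, 40)
    ))
  }
  invisible(TRUE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] returning plain
#' character vectors named by record id.  Gzipped files are handled
#' transparently; FASTQ quality lines are ignored.
#'
#' @param path Path to a FASTA / FASTQ file (optionally `.gz`).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs Named character vector of sequences (names become record ids;
#'   unnamed vectors get `seq1..seqN`).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(paste0(">", ids, "\n", unname(seqs)), con)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  qual <- strrep("I", nchar(seqs))
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", unname(seqs), "\n+\n", qual), con)
  invisible(path)
}

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}
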