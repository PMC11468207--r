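# On-disk persistence of kmer_index objects.
#
# The .kqx container is a plain-text, versioned, tab-separated layout:
# a metadata block (magic line, k, abundance filter, flags, sample names),
# one line per monotig (id, sequence, one count per sample), and, for
# quantized indexes only, one presence line per monotig holding a 0/1
# string per sample over the monotig's constituent k-mers.  The
# k-mer-to-monotig map is rebuilt at load time from the monotig sequences,
# so a round trip is lossless.

KQX_MAGIC <- "#kqx\tv1"

#' Save / load a k-mer index
#'
#' @param index A `kmer_index`.
#' @param path File path; conventionally with extension `.kqx`.
#' @return `save_index()` returns `path` invisibly; `load_index()` returns
#'   the reconstructed `kmer_index`, which compares equal to the saved one
#'   (including sample order).
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  lines <- c(
    KQX_MAGIC,
    paste0("#k\t", index$k),
    paste0("#abundance_min\t", index$abundance_min),
    paste0("#canonical\t", index$canonical),
    paste0("#quantized\t", index$quantized),
    paste(c("#samples", index$samples), collapse = "\t")
  )
  if (nrow(index$monotigs) > 0L) {
    body <- paste(index$monotigs$id, index$monotigs$sequence,
                  apply(index$counts, 1L, paste, collapse = "\t"),
                  sep = "\t")
    lines <- c(lines, body)
    if (index$quantized && !is.null(index$kmer_presence)) {
      pres <- vapply(seq_len(nrow(index$monotigs)), function(i) {
        nodes <- monotig_nodes(index, i)
        bits <- apply(index$kmer_presence[nodes, , drop = FALSE], 2L,
                      function(b) paste(as.integer(b), collapse = ""))
        paste(c("P", index$monotigs$id[i], bits), collapse = "\t")
      }, character(1))
      lines <- c(lines, pres)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Node (k-mer row) indexes of monotig i, in sequence order.
monotig_nodes <- function(index, i) {
  s <- index$monotigs$sequence[i]
  kms <- kmerize(s, index$k)$kmer
  match(canonical_kmer(kms), index$kmers)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) abort(sprintf("index file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != KQX_MAGIC) {
    abort("not a kqx index: bad magic header")
  }
  meta <- list()
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    meta[[substring(f[1L], 2L)]] <- f[-1L]
    i <- i + 1L
  }
  for (field in c("k", "abundance_min", "canonical", "quantized", "samples")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("corrupt kqx index: missing metadata field '%s'", field))
    }
  }
  k <- as.integer(meta$k[1L])
  samples <- meta$samples
  nsamp <- length(samples)
  quantized <- as.logical(meta$quantized[1L])

  body <- lines[seq.int(i, length.out = max(0L, length(lines) - i + 1L))]
  pres_lines <- body[startsWith(body, "P\t")]
  body <- body[!startsWith(body, "P\t")]
  nmono <- length(body)
  seqs <- character(nmono)
  counts <- matrix(0L, nmono, nsamp, dimnames = list(NULL, samples))
  if (nmono > 0L) {
    f <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf != nsamp + 2L)) {
      abort(sprintf(
        "corrupt kqx index: monotig line %d has %d fields, expected %d (field 'counts')",
        which(nf != nsamp + 2L)[1L], nf[nf != nsamp + 2L][1L], nsamp + 2L))
    }
    m <- matrix(unlist(f), ncol = nsamp + 2L, byrow = TRUE)
    seqs <- m[, 2L]
    counts[] <- as.integer(m[, -(1:2), drop = FALSE])
    if (anyNA(counts)) abort("corrupt kqx index: non-integer value in field 'counts'")
  }
  kw <- kmerize(seqs, k)
  ckm <- canonical_kmer(kw$kmer)
  kmers <- sort(unique(ckm))
  monotig_of <- integer(length(kmers))
  monotig_of[match(ckm, kmers)] <- kw$seq_id
  monotigs <- tibble(id = seq_len(nmono), sequence = seqs,
                     n_kmers = pmax(nchar(seqs) - k + 1L, 0L))

  presence <- NULL
  if (quantized) {
    presence <- matrix(FALSE, length(kmers), nsamp,
                       dimnames = list(NULL, samples))
    for (pl in pres_lines) {
      f <- strsplit(pl, "\t", fixed = TRUE)[[1L]]
      if (length(f) != nsamp + 2L) {
        abort("corrupt kqx index: malformed field 'presence'")
      }
      mid <- as.integer(f[2L])
      nodes <- kw$seq_id == mid
      rows <- match(ckm[nodes], kmers)
      for (j in seq_len(nsamp)) {
        bits <- strsplit(f[2L + j], "")[[1L]] == "1"
        if (length(bits) != length(rows)) {
          abort("corrupt kqx index: presence length mismatch (field 'presence')")
        }
        presence[rows, j] <- bits
      }
    }
  }

  cfg <- index_config(k = k,
                      abundance_min = as.integer(meta$abundance_min[1L]),
                      canonical = as.logical(meta$canonical[1L]),
                      quantized = quantized)
  new_kmer_index(cfg, samples, kmers, monotig_of, monotigs, counts, presence)
}
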