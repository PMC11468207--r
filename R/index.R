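# Multi-sample k-mer count index.
#
# The index stores, for every canonical k-mer surviving the per-sample
# abundance filter, its count in each sample.  Counts are not stored per
# k-mer but per *monotig*: a maximal non-branching path of the de Bruijn
# graph over the indexed k-mers along which the per-sample count vector is
# constant.  Querying a probe therefore returns one count run ("triplet")
# per monotig touched, which is both compact and exact in lossless mode.

#' Index configuration
#'
#' @param k K-mer length.  Must be odd and at least 3 so that no k-mer is
#'   its own reverse complement (default 31, the standard choice for
#'   RNA-seq k-mer indexing).
#' @param abundance_min Minimum per-sample count a k-mer needs to be
#'   retained at build time (default 1, i.e. keep everything; large
#'   heterogeneous cohorts typically use 4 to drop sequencing-error k-mers).
#' @param canonical Index canonical k-mers (lexicographic minimum of a
#'   k-mer and its reverse complement) so that matching is strand-agnostic.
#'   Default `TRUE`.
#' @param quantized Store approximate log2-binned per-monotig counts over
#'   structural unitigs instead of exact counts over count-homogeneous
#'   runs.  Default `FALSE` (lossless).  See the methods vignette.
#' @return A list of class `kprobe_config`.
#' @export
#' @examples
#' index_config(k = 31, abundance_min = 4)
index_config <- function(k = 31L, abundance_min = 1L, canonical = TRUE,
                         quantized = FALSE) {
  k <- as.integer(k)
  abundance_min <- as.integer(abundance_min)
  if (is.na(k) || k < 3L || k %% 2L == 0L) {
    abort("`k` must be an odd integer >= 3")
  }
  if (is.na(abundance_min) || abundance_min < 1L) {
    abort("`abundance_min` must be >= 1")
  }
  structure(
    list(k = k, abundance_min = abundance_min,
         canonical = isTRUE(canonical), quantized = isTRUE(quantized)),
    class = "kprobe_config"
  )
}

#' Count k-mers in a read set
#'
#' Slides a window of length `k` over every read; windows made only of
#' A/C/G/T contribute one count to their (canonical) k-mer, windows
#' containing N or other ambiguity codes are skipped.  K-mers whose final
#' count falls below `config$abundance_min` are dropped.
#'
#' @param reads Character vector of reads (lowercase and IUPAC ambiguity
#'   codes tolerated; anything else is an error naming the read).
#' @param config An [index_config()].
#' @return A tibble with columns `kmer` and `count`, sorted by k-mer.
#' @export
#' @examples
#' count_kmers(c("ACGTACGTACGT"), index_config(k = 5))
count_kmers <- function(reads, config = index_config()) {
  stopifnot(inherits(config, "kprobe_config"))
  check_alphabet(reads, "read")
  kw <- kmerize(reads, config$k)
  if (length(kw$kmer) == 0L) {
    return(tibble(kmer = character(0), count = integer(0)))
  }
  key <- if (config$canonical) canonical_kmer(kw$kmer) else kw$kmer
  dt <- data.table::data.table(kmer = key)
  cnt <- dt[, list(count = .N), by = "kmer"]
  cnt <- cnt[cnt$count >= config$abundance_min, ]
  data.table::setorderv(cnt, "kmer")
  as_tibble(cnt)
}

#' Build a multi-sample k-mer count index
#'
#' Counts k-mers per sample, applies the abundance filter per sample, takes
#' the union of surviving k-mers, and compresses them into monotigs:
#' maximal non-branching de Bruijn paths split wherever the per-sample
#' count vector changes (lossless mode).  A k-mer absent from a sample has
#' count 0 in that sample's slot.
#'
#' @param samples Sample input, one of: a named character vector of
#'   FASTQ(.gz) paths; a named list of character vectors of reads; or a
#'   data frame with columns `sample` and either `path` or a `reads`
#'   list-column.
#' @param config An [index_config()].
#' @return An object of class `kmer_index`.
#' @export
#' @examples
#' reads <- list(s1 = c("ACGTTGCAACGTTGGA"), s2 = c("ACGTTGCAACGTTGGA"))
#' idx <- build_index(reads, index_config(k = 7))
#' idx
build_index <- function(samples, config = index_config()) {
  stopifnot(inherits(config, "kprobe_config"))
  samples <- resolve_samples(samples)
  if (anyDuplicated(names(samples))) {
    abort("duplicate sample names in `samples`")
  }
  per_sample <- lapply(samples, count_kmers, config = config)
  kmers <- sort(unique(unlist(lapply(per_sample, `[[`, "kmer"), use.names = FALSE)))
  nsamp <- length(samples)
  if (length(kmers) == 0L) {
    warn("no k-mers survived filtering; index is empty")
    return(new_kmer_index(config, names(samples), character(0),
                          integer(0),
                          tibble(id = integer(0), sequence = character(0),
                                 n_kmers = integer(0)),
                          matrix(0L, 0, nsamp,
                                 dimnames = list(NULL, names(samples))),
                          NULL))
  }
  cmat <- matrix(0L, length(kmers), nsamp,
                 dimnames = list(NULL, names(samples)))
  for (j in seq_len(nsamp)) {
    tj <- per_sample[[j]]
    cmat[match(tj$kmer, kmers), j] <- as.integer(tj$count)
  }
  mono <- build_monotigs(kmers, cmat, config$k, config$quantized)
  presence <- if (config$quantized) cmat > 0L else NULL
  new_kmer_index(config, names(samples), kmers, mono$monotig_of,
                 mono$monotigs, mono$counts, presence)
}

new_kmer_index <- function(config, sample_names, kmers, monotig_of,
                           monotigs, counts, kmer_presence) {
  structure(
    list(k = config$k, abundance_min = config$abundance_min,
         canonical = config$canonical, quantized = config$quantized,
         samples = sample_names, kmers = kmers, monotig_of = monotig_of,
         monotigs = monotigs, counts = counts,
         kmer_presence = kmer_presence),
    class = "kmer_index"
  )
}

resolve_samples <- function(samples) {
  if (is.data.frame(samples)) {
    if (!"sample" %in% names(samples)) {
      abort("sample data frame needs a `sample` column")
    }
    if ("reads" %in% names(samples)) {
      return(setNames(as.list(samples$reads), samples$sample))
    }
    if ("path" %in% names(samples)) {
      return(setNames(lapply(samples$path, read_fastq), samples$sample))
    }
    abort("sample data frame needs a `path` or `reads` column")
  }
  if (is.character(samples)) {
    if (is.null(names(samples)) || any(names(samples) == "")) {
      abort("FASTQ paths must be named by sample")
    }
    return(lapply(samples, read_fastq))
  }
  if (is.list(samples)) {
    if (is.null(names(samples)) || any(names(samples) == "")) {
      abort("read lists must be named by sample")
    }
    return(lapply(samples, function(x) {
      if (length(x) == 1L && file.exists(x) &&
          grepl("\\.(fastq|fq)(\\.gz)?$", x)) read_fastq(x) else as.character(x)
    }))
  }
  abort("unsupported `samples` input")
}

# Monotig construction.  Works on the full canonical k-mer set at once:
# successor candidates for both orientations of every k-mer are formed and
# canonicalised in one vectorised pass, unambiguous extensions become
# links, and maximal link chains are walked out as monotigs.  In lossless
# mode a link additionally requires both endpoints to share their
# per-sample count vector.
build_monotigs <- function(kmers, cmat, k, quantized = FALSE) {
  n <- length(kmers)
  rc <- revcomp(kmers)
  ostr <- c(kmers, rc)                      # oriented ids: 1..n '+', n+1..2n '-'
  node_of <- function(o) ifelse(o > n, o - n, o)
  rc_of <- function(o) ifelse(o > n, o - n, o + n)

  suf <- substr(ostr, 2L, k)
  cand <- paste0(rep(suf, 4L), rep(c("A", "C", "G", "T"), each = 2L * n))
  cnode <- match(canonical_kmer(cand), kmers)
  cand_is_canon <- cand == kmers[cnode]     # NA where candidate absent
  hit <- !is.na(cnode)
  outdeg <- rowSums(matrix(hit, nrow = 2L * n))

  # for oriented k-mers with out-degree 1, locate the single successor
  succ <- rep(NA_integer_, 2L * n)
  uniq <- which(outdeg == 1L)
  if (length(uniq) > 0L) {
    hitm <- matrix(hit, nrow = 2L * n)
    slot <- max.col(hitm[uniq, , drop = FALSE], ties.method = "first")
    flat <- uniq + (slot - 1L) * 2L * n
    s_node <- cnode[flat]
    succ[uniq] <- ifelse(cand_is_canon[flat], s_node, s_node + n)
  }

  link <- succ
  ok <- !is.na(link)
  ok[ok] <- outdeg[rc_of(link[ok])] == 1L & node_of(link[ok]) != node_of(which(ok))
  if (!quantized && ncol(cmat) > 0L && n > 0L) {
    grp <- do.call(paste, c(as.data.frame(cmat), sep = ","))
    ok[ok] <- ok[ok] & grp[node_of(link[ok])] == grp[node_of(which(ok))]
  }
  link[!ok] <- NA_integer_

  has_in <- !is.na(link[rc_of(seq_len(2L * n))])

  visited <- logical(n)
  monotig_of <- integer(n)
  paths <- vector("list", n)
  np <- 0L
  walk <- function(o) {
    path <- integer(0)
    cur <- o
    repeat {
      nd <- node_of(cur)
      if (visited[nd]) break
      visited[nd] <<- TRUE
      path[length(path) + 1L] <- cur
      nxt <- link[cur]
      if (is.na(nxt)) break
      cur <- nxt
    }
    path
  }
  for (o in which(!has_in)) {
    if (visited[node_of(o)]) next
    np <- np + 1L
    paths[[np]] <- walk(o)
  }
  for (o in seq_len(n)) {                   # circular components
    if (visited[o]) next
    np <- np + 1L
    paths[[np]] <- walk(o)
  }
  paths <- paths[seq_len(np)]

  seqs <- character(np)
  nk <- integer(np)
  counts <- matrix(0L, np, ncol(cmat), dimnames = list(NULL, colnames(cmat)))
  for (i in seq_len(np)) {
    p <- paths[[i]]
    nodes <- node_of(p)
    monotig_of[nodes] <- i
    nk[i] <- length(p)
    seqs[i] <- if (length(p) == 1L) ostr[p] else
      paste0(ostr[p[1L]], paste(substr(ostr[p[-1L]], k, k), collapse = ""))
    if (quantized) {
      for (j in seq_len(ncol(cmat))) {
        v <- cmat[nodes, j]
        v <- v[v > 0L]
        counts[i, j] <- if (length(v) == 0L) 0L else
          as.integer(2^floor(log2(mean(v))))
      }
    } else {
      counts[i, ] <- cmat[nodes[1L], ]
    }
  }
  list(monotigs = tibble(id = seq_len(np), sequence = seqs, n_kmers = nk),
       counts = counts, monotig_of = monotig_of)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "<kmer_index> k=%d, %d sample%s, %d k-mers in %d monotigs%s%s\n",
    x$k, length(x$samples), if (length(x$samples) == 1L) "" else "s",
    length(x$kmers), nrow(x$monotigs),
    if (x$quantized) " (quantized)" else "",
    if (x$abundance_min > 1L) sprintf(", abundance_min=%d", x$abundance_min) else ""
  ))
  cat(" samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy views of a k-mer index
#'
#' `tidy()` returns the monotig table in long form (one row per monotig and
#' sample); `glance()` returns a one-row summary.
#'
#' @param x A `kmer_index`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy kmer_index
tidy.kmer_index <- function(x, ...) {
  if (nrow(x$monotigs) == 0L) {
    return(tibble(id = integer(0), sequence = character(0),
                  n_kmers = integer(0), sample = character(0),
                  count = integer(0)))
  }
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(x$monotigs, as_tibble(x$counts)),
    cols = dplyr::all_of(x$samples),
    names_to = "sample", values_to = "count"
  )
  long
}

#' @rdname tidy.kmer_index
#' @export
#' @method glance kmer_index
glance.kmer_index <- function(x, ...) {
  tibble(
    k = x$k, abundance_min = x$abundance_min, quantized = x$quantized,
    n_samples = length(x$samples), n_kmers = length(x$kmers),
    n_monotigs = nrow(x$monotigs),
    mean_monotig_kmers = if (nrow(x$monotigs)) mean(x$monotigs$n_kmers) else NA_real_
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Per-k-mer count lookup used by tests and by exact query reconstruction.
kmer_counts_of <- function(index, kmers) {
  idx <- match(canonical_kmer(toupper(kmers)), index$kmers)
  out <- matrix(0L, length(kmers), length(index$samples),
                dimnames = list(NULL, index$samples))
  hitrows <- which(!is.na(idx))
  if (length(hitrows) > 0L) {
    out[hitrows, ] <- index$counts[index$monotig_of[idx[hitrows]], , drop = FALSE]
  }
  out
}
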