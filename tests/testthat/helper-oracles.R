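# Independent brute-force oracles and tiny fixture builders.  These stay
# deliberately naive (sliding windows, linear scans, multiset expansion)
# and do not touch the package's canonicalization or monotig code paths.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Plain-R reverse complement, independent of the package's Biostrings path.
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force canonical k-mer counts of a read set: sliding windows, skip
# windows with non-ACGT, table() the lexicographic minima.
brute_counts <- function(reads, k) {
  wins <- character(0)
  for (r in toupper(reads)) {
    L <- nchar(r)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    w <- substring(r, starts, starts + k - 1L)
    wins <- c(wins, w[!grepl("[^ACGT]", w)])
  }
  if (length(wins) == 0L) return(integer(0))
  keys <- pmin(wins, oracle_revcomp(wins))
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

# Brute-force per-k-mer counts of a probe; pass precomputed brute_counts()
# via `cnt` to avoid rescanning the reads for every probe.
brute_probe_counts <- function(reads, probe, k, cnt = NULL) {
  if (is.null(cnt)) cnt <- brute_counts(reads, k)
  probe <- toupper(probe)
  starts <- seq_len(nchar(probe) - k + 1L)
  w <- substring(probe, starts, starts + k - 1L)
  keys <- pmin(w, oracle_revcomp(w))
  keys[grepl("[^ACGT]", w)] <- NA
  out <- unname(cnt[keys])
  out[is.na(out)] <- 0L
  as.integer(out)
}

# Multiset expansion of a triplet tibble (non-starred runs only).
expand_triplets <- function(trip) {
  trip <- trip[!trip$starred, , drop = FALSE]
  rep(trip$count, trip$end - trip$begin + 1L)
}

# All k-mers of a sequence, in order, ambiguous windows kept.
seq_kmers <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s) - k + 1L
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

expect_snv_probe_geometry <- function(pp, k) {
  expect_true(all(nchar(pp$mutant_seq) == 2 * k - 1))
  expect_true(all(nchar(pp$wildtype_seq) == 2 * k - 1))
  for (i in seq_len(nrow(pp))) {
    m <- pp$mutant_seq[i]
    w <- pp$wildtype_seq[i]
    diff <- which(strsplit(m, "")[[1]] != strsplit(w, "")[[1]])
    expect_equal(diff, as.integer(k))         # differ exactly at center
    # mutant and wildtype k-mer sets are disjoint, i.e. every k-mer of the
    # probe covers the variant base
    expect_length(intersect(seq_kmers(m, k), seq_kmers(w, k)), 0)
  }
}
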