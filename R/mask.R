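# Probe masking: removal of non-specific and low-complexity k-mers.
#
# Two families of rules, applied per k-mer of each probe and combinable in
# a single pass:
#   * unicity rules against reference k-mer counts — "default" deletes
#     k-mers occurring more than once in the genome; "max_on_transcriptome"
#     additionally caps transcriptome occurrences at X; "chimera" deletes
#     any k-mer present at all in genome or transcriptome (used for mutant
#     and junction probes, whose informative k-mers must be absent from
#     both references);
#   * low-complexity rules — k-mers containing a >= 6-nt homopolymer, or
#     whose 3-mer complexity (distinct 3-mers / total 3-mers) is below
#     0.55, are deleted.
# Surviving runs of k-mer start positions are reassembled into fragments
# (each >= k nt); a probe with no surviving k-mer is "fully deleted".

#' Canonical k-mer occurrence counts of a reference
#'
#' Counts canonical k-mer multiplicities over all records of a reference
#' FASTA (both strands, via canonicalization).  Windows containing
#' ambiguity codes are skipped.
#'
#' @param fasta A FASTA path or named character vector of sequences.
#' @param k K-mer length (default 31).
#' @param label Free-text label recorded in the object (defaults to the
#'   file name or `"reference"`).
#' @return An object of class `ref_kmer_counts`.
#' @export
reference_kmer_counts <- function(fasta, k = 31L, label = NULL) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    label <- label %||% basename(fasta)
    fasta <- read_fasta(fasta)
  }
  label <- label %||% "reference"
  if (length(fasta) == 0L || all(nchar(fasta) == 0L)) {
    abort("empty reference FASTA")
  }
  kw <- kmerize(fasta, k)
  if (length(kw$kmer) == 0L) abort("reference holds no k-mers at this k")
  dt <- data.table::data.table(kmer = canonical_kmer(kw$kmer))
  cnt <- dt[, list(count = .N), by = "kmer"]
  data.table::setorderv(cnt, "kmer")
  structure(list(label = label, k = as.integer(k),
                 kmers = cnt$kmer, counts = as.integer(cnt$count)),
            class = "ref_kmer_counts")
}

#' @export
print.ref_kmer_counts <- function(x, ...) {
  cat(sprintf("<ref_kmer_counts> %s: %d distinct canonical %d-mers\n",
              x$label, length(x$kmers), x$k))
  invisible(x)
}

# Occurrence count of canonical k-mers in a reference (0 when absent).
ref_count <- function(ref, kmers) {
  idx <- match(canonical_kmer(kmers), ref$kmers)
  out <- integer(length(kmers))
  out[!is.na(idx)] <- ref$counts[idx[!is.na(idx)]]
  out
}

#' Low-complexity rules for single k-mers
#'
#' `homopolymer_rule()` is `TRUE` when the k-mer contains a homopolymer
#' run of 6 nt or more.  `complexity_3mer()` is the number of distinct
#' overlapping 3-mers divided by the total number of 3-mers (`k - 2`);
#' k-mers scoring below the cutoff (default 0.55) are considered low
#' complexity.
#'
#' @param kmer Character vector of k-mers.
#' @return `homopolymer_rule()`: logical vector.  `complexity_3mer()`:
#'   numeric vector in (0, 1].
#' @export
#' @examples
#' homopolymer_rule("ACGTAAAAAACGTACGTACGTACGTACGTAC")
#' complexity_3mer(strrep("A", 31))  # 1/29
homopolymer_rule <- function(kmer) {
  grepl("A{6}|C{6}|G{6}|T{6}", toupper(kmer))
}

#' @rdname homopolymer_rule
#' @export
complexity_3mer <- function(kmer) {
  kmer <- toupper(kmer)
  vapply(kmer, function(s) {
    n3 <- nchar(s) - 2L
    if (n3 < 1L) abort("k-mer shorter than 3")
    tri <- substring(s, seq_len(n3), seq_len(n3) + 2L)
    length(unique(tri)) / n3
  }, numeric(1), USE.NAMES = FALSE)
}

# Shared core: given probe sequences and a predicate returning a logical
# keep-vector over a batch of k-mers, build the masked-probe table.
mask_with <- function(probes, k, keep_fun) {
  probes <- resolve_probes(probes)
  if (any(nchar(probes$seq) < k)) {
    abort(sprintf("probe '%s' is shorter than k = %d",
                  probes$probe_id[which(nchar(probes$seq) < k)[1L]], k))
  }
  kw <- kmerize(probes$seq, k, drop_ambiguous = FALSE)
  verdict <- keep_fun(kw$kmer)              # list(keep, rule-hit counters)
  keep <- verdict$keep & !grepl("[^ACGT]", kw$kmer)

  out <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    sel <- kw$seq_id == i
    ki <- keep[sel]
    frag <- keep_runs_to_fragments(probes$seq[i], ki, k)
    out[[i]] <- tibble(
      probe_id = probes$probe_id[i],
      n_input_kmers = length(ki),
      n_retained_kmers = sum(ki),
      fully_deleted = !any(ki),
      fragments = list(frag)
    )
  }
  res <- dplyr::bind_rows(out)
  for (nm in names(verdict$hits)) {
    res[[nm]] <- vapply(seq_len(nrow(probes)), function(i) {
      sum(verdict$hits[[nm]][kw$seq_id == i])
    }, integer(1))
  }
  class(res) <- c("kprobe_masked", class(res))
  res
}

keep_runs_to_fragments <- function(seq, keep, k) {
  if (!any(keep)) return(character(0))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  on <- which(r$values)
  substring(seq, begins[on], ends[on] + k - 1L)
}

#' Unicity masking against reference k-mer counts
#'
#' Deletes probe k-mers that are too frequent in (or, in chimera mode,
#' present at all in) reference sequence sets, and reassembles the
#' retained k-mer runs into fragments.
#'
#' Modes: `"default"` deletes k-mers with genome count > `max_on_genome`
#' (default 1, i.e. anything non-unique); `"max_on_transcriptome"`
#' additionally deletes k-mers with transcriptome count >
#' `max_on_transcriptome` (`X = 0` demands absence, as used for
#' neojunction probes); `"chimera"` deletes any k-mer present in the
#' genome or the transcriptome, leaving only event-specific k-mers.
#'
#' @param probes Probes (named character vector, `probe_id`/`seq` data
#'   frame, or FASTA path).
#' @param genome_counts A [reference_kmer_counts()] over the genome.
#' @param mode One of `"default"`, `"max_on_transcriptome"`, `"chimera"`.
#' @param max_on_genome Maximum allowed genome occurrences (default 1).
#' @param transcriptome_counts A [reference_kmer_counts()] over the
#'   transcriptome; required for the last two modes.
#' @param max_on_transcriptome Maximum allowed transcriptome occurrences
#'   (mode `"max_on_transcriptome"`).
#' @return A `kprobe_masked` tibble: `probe_id`, `n_input_kmers`,
#'   `n_retained_kmers`, `fully_deleted`, a `fragments` list-column, and
#'   a `n_hit_unicity` rule counter.
#' @export
unicity_mask <- function(probes, genome_counts,
                         mode = c("default", "max_on_transcriptome", "chimera"),
                         max_on_genome = 1L, transcriptome_counts = NULL,
                         max_on_transcriptome = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome_counts, "ref_kmer_counts"))
  if (mode %in% c("max_on_transcriptome", "chimera") &&
      is.null(transcriptome_counts)) {
    abort(sprintf("mode '%s' requires `transcriptome_counts`", mode))
  }
  if (mode == "max_on_transcriptome" && is.null(max_on_transcriptome)) {
    abort("mode 'max_on_transcriptome' requires `max_on_transcriptome`")
  }
  k <- genome_counts$k
  mask_with(probes, k, function(kmers) {
    bad <- unicity_violation(kmers, genome_counts, mode, max_on_genome,
                             transcriptome_counts, max_on_transcriptome)
    list(keep = !bad, hits = list(n_hit_unicity = bad))
  })
}

unicity_violation <- function(kmers, genome_counts, mode, max_on_genome,
                              transcriptome_counts, max_on_transcriptome) {
  g <- ref_count(genome_counts, kmers)
  switch(mode,
    default = g > max_on_genome,
    max_on_transcriptome = g > max_on_genome |
      ref_count(transcriptome_counts, kmers) > max_on_transcriptome,
    chimera = g >= 1L | ref_count(transcriptome_counts, kmers) >= 1L
  )
}

#' Low-complexity masking
#'
#' Deletes probe k-mers that contain a >= 6-nt homopolymer or whose
#' 3-mer complexity is below `cutoff`, and reassembles the retained runs
#' into fragments.
#'
#' @inheritParams unicity_mask
#' @param k K-mer length (default 31).
#' @param cutoff 3-mer complexity cutoff (default 0.55).
#' @return A `kprobe_masked` tibble (see [unicity_mask()]) with a
#'   `n_hit_low_complexity` rule counter.
#' @export
low_complexity_mask <- function(probes, k = 31L, cutoff = 0.55) {
  mask_with(probes, k, function(kmers) {
    bad <- homopolymer_rule(kmers) | complexity_3mer(kmers) < cutoff
    list(keep = !bad, hits = list(n_hit_low_complexity = bad))
  })
}

#' Combined unicity and low-complexity masking
#'
#' Applies the unicity rules of [unicity_mask()] and the low-complexity
#' rules of [low_complexity_mask()] in one pass, reassembling fragments
#' once, which is how probe sets are prepared before querying.
#'
#' @inheritParams unicity_mask
#' @param low_complexity Apply the low-complexity rules too (default
#'   `TRUE`).
#' @param complexity_cutoff 3-mer complexity cutoff (default 0.55).
#' @return A `kprobe_masked` tibble with both rule counters.
#' @export
mask_probes <- function(probes, genome_counts,
                        mode = c("default", "max_on_transcriptome", "chimera"),
                        max_on_genome = 1L, transcriptome_counts = NULL,
                        max_on_transcriptome = NULL, low_complexity = TRUE,
                        complexity_cutoff = 0.55) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome_counts, "ref_kmer_counts"))
  if (mode %in% c("max_on_transcriptome", "chimera") &&
      is.null(transcriptome_counts)) {
    abort(sprintf("mode '%s' requires `transcriptome_counts`", mode))
  }
  if (mode == "max_on_transcriptome" && is.null(max_on_transcriptome)) {
    abort("mode 'max_on_transcriptome' requires `max_on_transcriptome`")
  }
  k <- genome_counts$k
  mask_with(probes, k, function(kmers) {
    uni <- unicity_violation(kmers, genome_counts, mode, max_on_genome,
                             transcriptome_counts, max_on_transcriptome)
    if (low_complexity) {
      lc <- homopolymer_rule(kmers) |
        complexity_3mer(kmers) < complexity_cutoff
    } else {
      lc <- rep(FALSE, length(kmers))
    }
    list(keep = !(uni | lc),
         hits = list(n_hit_unicity = uni, n_hit_low_complexity = lc))
  })
}

#' Fragments of masked probes as queryable records
#'
#' `masked_fragments()` returns a long tibble (one row per fragment) with
#' ids `<probe_id>|frag<i>`; `query_masked()` queries those fragments
#' against an index and merges the per-fragment means back per probe with
#' [merge_masked_query()].  Fully deleted probes are reported with `NA`
#' values and zero k-mers ("not measurable").
#'
#' @param masked A `kprobe_masked` tibble.
#' @return A tibble with columns `probe_id`, `fragment_id`, `seq`.
#' @export
masked_fragments <- function(masked) {
  stopifnot(is.data.frame(masked), "fragments" %in% names(masked))
  masked |>
    select("probe_id", "fragments") |>
    tidyr::unnest_longer("fragments", values_to = "seq") |>
    group_by(.data$probe_id) |>
    mutate(fragment_id = sprintf("%s|frag%d", .data$probe_id, row_number())) |>
    ungroup() |>
    select("probe_id", "fragment_id", "seq")
}

#' @rdname masked_fragments
#' @param index A `kmer_index`.
#' @param config A [query_config()]; the aggregation must be `"mean"`.
#' @export
query_masked <- function(index, masked, config = query_config()) {
  if (config$aggregation != "mean") {
    abort("masked-fragment merging is only possible with mean aggregation")
  }
  frags <- masked_fragments(masked)
  merged <- if (nrow(frags) > 0L) {
    merge_masked_query(
      query_probes(index,
                   tibble(probe_id = frags$fragment_id, seq = frags$seq),
                   config),
      scheme = "mean")
  } else {
    tibble(probe_id = character(0), sample = character(0),
           value = numeric(0), n_positive_kmers = integer(0),
           n_kmers = integer(0))
  }
  gone <- masked$probe_id[masked$fully_deleted]
  if (length(gone) > 0L) {
    merged <- dplyr::bind_rows(
      merged,
      tidyr::expand_grid(probe_id = gone, sample = index$samples) |>
        mutate(value = NA_real_, n_positive_kmers = 0L, n_kmers = 0L)
    )
  }
  arrange(merged, .data$probe_id, .data$sample)
}
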