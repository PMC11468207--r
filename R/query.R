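# Probe queries against a kmer_index.
#
# A query decomposes a probe into its k-mers, maps consecutive k-mers that
# fall in the same monotig to one count run ("triplet" begin-end:count, in
# 1-based k-mer ordinals), and aggregates the runs per sample.  Counts are
# exact in lossless indexes; in quantized indexes a run whose fraction of
# present constituent k-mers falls below the presence threshold is flagged
# with the star marker and treated as unreliable.

#' Query configuration
#'
#' @param presence_threshold Percentage in (0, 100]: minimum fraction of a
#'   run's constituent k-mers that must be present for its (quantized)
#'   count to be reported rather than starred.  Default 40.
#' @param aggregation One of `"mean"`, `"median"`, `"sum"`, `"max"`.
#'   Mean, median and sum are weighted by the number of k-mers in each run;
#'   max is taken over run values directly.  Default `"mean"` (the
#'   TPM-like scheme; `"sum"` is raw-count-like).
#' @param star_policy How starred (unreliable) runs enter aggregates:
#'   `"exclude"` drops them from both numerator and weight (default),
#'   `"as_zero"` counts them as zeros.
#' @return A list of class `kprobe_query_config`.
#' @export
query_config <- function(presence_threshold = 40, aggregation = "mean",
                         star_policy = "exclude") {
  if (!is.numeric(presence_threshold) || presence_threshold <= 0 ||
      presence_threshold > 100) {
    abort("`presence_threshold` must be in (0, 100]")
  }
  aggregation <- match.arg(aggregation, c("mean", "median", "sum", "max"))
  star_policy <- match.arg(star_policy, c("exclude", "as_zero"))
  structure(list(presence_threshold = presence_threshold,
                 aggregation = aggregation, star_policy = star_policy),
            class = "kprobe_query_config")
}

#' Query probes against a k-mer count index
#'
#' @param index A `kmer_index` from [build_index()].
#' @param probes Probes to query: a named character vector of sequences, a
#'   data frame with columns `probe_id` and `seq`, or a path to a FASTA
#'   file (record ids become probe ids).
#' @param config A [query_config()].
#' @return A tibble with one row per (probe, sample): `probe_id`,
#'   `sample`, `value` (the aggregate; `NA` when nothing was measurable),
#'   `n_positive_kmers`, `n_kmers`, and a `triplets` list-column of
#'   per-run tibbles (`begin`, `end`, `count`, `starred`).
#' @export
#' @examples
#' idx <- build_index(list(s1 = strrep("ACGGT", 8)), index_config(k = 7))
#' query_probes(idx, c(p1 = strrep("ACGGT", 4)))
query_probes <- function(index, probes, config = query_config()) {
  stopifnot(inherits(index, "kmer_index"),
            inherits(config, "kprobe_query_config"))
  probes <- resolve_probes(probes)
  k <- index$k
  short <- which(nchar(probes$seq) < k)
  if (length(short) > 0L) {
    abort(sprintf("probe '%s' is shorter than k = %d",
                  probes$probe_id[short[1L]], k))
  }
  check_alphabet(probes$seq, "probe")
  kw <- kmerize(probes$seq, k, drop_ambiguous = FALSE)
  # k-mers containing non-ACGT are treated as absent from the index
  ambiguous <- grepl("[^ACGT]", kw$kmer)
  node <- rep(NA_integer_, length(kw$kmer))
  node[!ambiguous] <- match(canonical_kmer(kw$kmer[!ambiguous]), index$kmers)
  mono <- ifelse(is.na(node), NA_integer_, index$monotig_of[node])

  out <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    sel <- kw$seq_id == i
    out[[i]] <- query_one(index, probes$probe_id[i], mono[sel], node[sel],
                          config)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("kprobe_query", class(res))
  res
}

#' @rdname query_probes
#' @param probe A single probe sequence.
#' @export
query_probe <- function(index, probe, config = query_config()) {
  query_probes(index, c(probe = unname(probe)), config)
}

resolve_probes <- function(probes) {
  if (is.data.frame(probes)) {
    if (!all(c("probe_id", "seq") %in% names(probes))) {
      abort("probe data frame needs `probe_id` and `seq` columns")
    }
    return(tibble(probe_id = as.character(probes$probe_id),
                  seq = toupper(probes$seq)))
  }
  if (is.character(probes) && length(probes) == 1L && file.exists(probes) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", probes)) {
    x <- read_fasta(probes)
    return(tibble(probe_id = names(x), seq = unname(x)))
  }
  if (is.character(probes)) {
    ids <- names(probes) %||% paste0("probe", seq_along(probes))
    return(tibble(probe_id = ids, seq = toupper(unname(probes))))
  }
  abort("unsupported `probes` input")
}

# Build the per-sample triplet runs and aggregates for one probe whose
# query k-mers map to monotig ids `mono` (NA = absent) and k-mer node
# indexes `node`.
query_one <- function(index, probe_id, mono, node, config) {
  n_q <- length(mono)
  r <- rle(ifelse(is.na(mono), 0L, mono))
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  run_mono <- r$values                       # 0 = absent run
  nsamp <- length(index$samples)

  rows <- vector("list", nsamp)
  for (j in seq_len(nsamp)) {
    count <- numeric(length(run_mono))
    pres <- run_mono != 0L
    count[pres] <- as.numeric(index$counts[run_mono[pres], j])
    starred <- rep(FALSE, length(run_mono))
    if (index$quantized && !is.null(index$kmer_presence)) {
      for (t in which(run_mono != 0L)) {
        frac <- mean(index$kmer_presence[node[begins[t]:ends[t]], j])
        if (frac > 0 && frac < config$presence_threshold / 100) {
          starred[t] <- TRUE
        } else if (frac == 0) {
          count[t] <- 0                      # fully absent in this sample
        }
      }
    }
    trip <- tibble(begin = begins, end = ends, count = count,
                   starred = starred)
    rows[[j]] <- tibble(
      probe_id = probe_id, sample = index$samples[j],
      value = aggregate_counts(trip, config$aggregation, config$star_policy),
      n_positive_kmers = sum((trip$end - trip$begin + 1L)[
        !trip$starred & trip$count > 0]),
      n_kmers = n_q,
      triplets = list(trip)
    )
  }
  dplyr::bind_rows(rows)
}

#' Aggregate a set of count runs
#'
#' Expands each non-starred run into `end - begin + 1` copies of its count
#' and computes the requested statistic over the expansion: the weighted
#' mean, the weighted median (lower of the two middle elements when the
#' total weight is even), the sum, or the maximum (unweighted over run
#' values).
#'
#' @param triplets A tibble with columns `begin`, `end`, `count`,
#'   `starred` as produced by [query_probes()].
#' @param scheme One of `"mean"`, `"median"`, `"sum"`, `"max"`.
#' @param star_policy `"exclude"` (drop starred runs) or `"as_zero"`.
#' @return A single number, or `NA` when every run is starred and
#'   excluded ("not measurable", distinct from 0).
#' @export
aggregate_counts <- function(triplets, scheme = "mean",
                             star_policy = "exclude") {
  scheme <- match.arg(scheme, c("mean", "median", "sum", "max"))
  star_policy <- match.arg(star_policy, c("exclude", "as_zero"))
  vals <- triplets$count
  w <- triplets$end - triplets$begin + 1L
  if (star_policy == "exclude") {
    keep <- !triplets$starred
    vals <- vals[keep]
    w <- w[keep]
  } else {
    vals[triplets$starred] <- 0
  }
  if (length(vals) == 0L) return(NA_real_)
  switch(scheme,
    mean = sum(vals * w) / sum(w),
    sum = sum(vals * w),
    max = max(vals),
    median = weighted_median_low(vals, w)
  )
}

# Median of the expansion of `vals` with integer weights `w`; the lower of
# the two middle elements when the total weight is even.
weighted_median_low <- function(vals, w) {
  o <- order(vals)
  vals <- vals[o]
  w <- w[o]
  target <- floor((sum(w) + 1) / 2)
  vals[which(cumsum(w) >= target)[1L]]
}

#' Merge per-fragment query results back to whole probes
#'
#' Masking can split a probe into several fragments that are queried
#' separately; their counts are merged back per original probe as the
#' pooled k-mer-weighted mean.  Only the mean scheme supports this merge
#' (sum/median/max of a fragmented probe are not recoverable from
#' per-fragment aggregates).
#'
#' Fragment probe ids are expected in the form `<probe_id>|frag<i>` as
#' written by [mask_probes()]; anything after the last `|` is stripped to
#' recover the parent probe id.
#'
#' @param results A query tibble from [query_probes()] over fragment
#'   probes.
#' @param scheme Aggregation scheme; must be `"mean"`.
#' @return A tibble with one row per (probe, sample): `probe_id`,
#'   `sample`, `value` (pooled mean; `NA` when no fragment had retained
#'   k-mers), `n_positive_kmers`, `n_kmers`.
#' @export
merge_masked_query <- function(results, scheme = "mean") {
  if (!identical(scheme, "mean")) {
    abort("masked-fragment merging is only possible with mean aggregation")
  }
  if (nrow(results) == 0L) {
    return(tibble(probe_id = character(0), sample = character(0),
                  value = numeric(0), n_positive_kmers = integer(0),
                  n_kmers = integer(0)))
  }
  results |>
    mutate(probe_id = sub("\\|[^|]*$", "", .data$probe_id)) |>
    group_by(.data$probe_id, .data$sample) |>
    summarise(
      value = {
        keep <- .data$n_kmers > 0 & !is.na(.data$value)
        if (!any(keep)) NA_real_ else
          sum(.data$value[keep] * .data$n_kmers[keep]) / sum(.data$n_kmers[keep])
      },
      n_positive_kmers = sum(.data$n_positive_kmers),
      n_kmers = sum(.data$n_kmers),
      .groups = "drop"
    )
}

#' Convert a summed k-mer count to an estimated read count
#'
#' A read of length `L` contributes `L - k + 1` k-mer counts, so the sum
#' of k-mer counts over a transcript overestimates the raw read count by
#' that factor; dividing restores a raw-count-like value.
#'
#' @param sum_count Summed k-mer count (from the `"sum"` scheme).
#' @param read_len Read length of the indexed library.
#' @param k K-mer length.
#' @return Estimated number of reads.
#' @export
#' @examples
#' estimate_raw_reads(300, read_len = 100, k = 31)
estimate_raw_reads <- function(sum_count, read_len, k = 31L) {
  if (any(read_len < k)) abort("`read_len` must be >= k")
  sum_count / (read_len - k + 1)
}

#' Format triplet runs as compact strings
#'
#' Renders a triplet tibble in `begin-end:count` notation, with `*` for
#' starred runs, e.g. `"1-10:5,11-12:0"`.
#'
#' @param triplets A triplet tibble from [query_probes()].
#' @return A single string.
#' @export
format_triplets <- function(triplets) {
  q <- ifelse(triplets$starred, "*",
              format(triplets$count, trim = TRUE, scientific = FALSE))
  paste(sprintf("%d-%d:%s", triplets$begin, triplets$end, q), collapse = ",")
}
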