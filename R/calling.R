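# Event calling and evaluation.
#
# A probe is called present in a sample when at least `min_hits` of its
# (masked) k-mers have a non-zero count; requiring several hits makes
# calls robust to isolated spurious k-mers while a handful of missing
# k-mers (e.g. a flanking SNP) does not kill a true call.  Variant allele
# frequency is taken from the mean counts of the masked mutant and
# wildtype probes.

#' Call events from query results
#'
#' @param results A query tibble with `probe_id`, `sample` and
#'   `n_positive_kmers` columns, from [query_probes()] or
#'   [query_masked()].  Starred (unreliable) runs never contribute to
#'   `n_positive_kmers`.  Probes with no retained k-mers (`n_kmers` 0)
#'   are dropped as not callable.
#' @param min_hits Minimum number of positive k-mers for a call
#'   (default 3).
#' @return A tibble `probe_id`, `sample`, `n_positive_kmers`, `called`.
#' @export
call_events <- function(results, min_hits = 3L) {
  stopifnot(is.data.frame(results), min_hits >= 1L)
  res <- results
  if ("n_kmers" %in% names(res)) {
    res <- filter(res, .data$n_kmers > 0L)
  }
  res |>
    mutate(called = .data$n_positive_kmers >= min_hits) |>
    select("probe_id", "sample", "n_positive_kmers", "called")
}

#' Variant allele frequency from probe counts
#'
#' VAF in percent, computed as `100 * mut / (mut + wt)` from the
#' (mean-aggregated, masked) mutant and wildtype probe counts.  When both
#' counts are 0 the site is unmeasured and the result is `NA`.
#'
#' @param mut_count,wt_count Non-negative counts (vectorised).
#' @return Numeric vector of percentages in `[0, 100]`, or `NA`.
#' @export
#' @examples
#' compute_vaf(10, 10)  # 50
compute_vaf <- function(mut_count, wt_count) {
  if (any(mut_count < 0, na.rm = TRUE) || any(wt_count < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  tot <- mut_count + wt_count
  ifelse(is.na(tot) | tot == 0, NA_real_, 100 * mut_count / tot)
}

#' Query mutation probe pairs and call mutations
#'
#' End-to-end mutation genotyping against an index: queries the masked
#' mutant and wildtype probes (fragment means merged per probe), calls a
#' mutation in a sample when the mutant probe has at least `min_hits`
#' positive k-mers, and reports the VAF.  Mutant probes are conventionally
#' masked in chimera mode and wildtype probes in max-on-transcriptome
#' mode (see [mask_probes()]).
#'
#' @param index A `kmer_index`.
#' @param masked_mut,masked_wt `kprobe_masked` tibbles for the mutant and
#'   wildtype probes; probe ids must match pairwise.
#' @param min_hits Minimum positive mutant k-mers for a call (default 3).
#' @param config A [query_config()]; must use mean aggregation.
#' @return A tibble `probe_id`, `sample`, `n_kmers`, `n_positive_kmers`,
#'   `called`, `mut_mean`, `wt_mean`, `vaf_percent`.  Probes whose mutant probe was
#'   fully deleted by masking are excluded (not callable).
#' @export
call_mutations <- function(index, masked_mut, masked_wt, min_hits = 3L,
                           config = query_config()) {
  mut <- query_masked(index, masked_mut, config)
  wt <- query_masked(index, masked_wt, config)
  calls <- call_events(mut, min_hits)
  mut |>
    dplyr::rename(mut_mean = "value") |>
    left_join(select(wt, "probe_id", "sample", wt_mean = "value"),
              by = c("probe_id", "sample")) |>
    filter(.data$n_kmers > 0L) |>
    left_join(select(calls, "probe_id", "sample", "called"),
              by = c("probe_id", "sample")) |>
    mutate(vaf_percent = compute_vaf(
      ifelse(is.na(.data$mut_mean), 0, .data$mut_mean),
      ifelse(is.na(.data$wt_mean), 0, .data$wt_mean))) |>
    select("probe_id", "sample", "n_kmers", "n_positive_kmers", "called",
           "mut_mean", "wt_mean", "vaf_percent")
}

#' Evaluate calls against a truth set
#'
#' Counts, over (probe, sample) pairs and for each requested `min_hits`
#' threshold, true positives (called and true), false positives (called,
#' not true) and false negatives (not called, true), with precision
#' `TP / (TP + FP)` and recall `TP / (TP + FN)`.  Precision is `NA`
#' (undefined, not 0) when nothing was called.
#'
#' @param results A query/call tibble with `probe_id`, `sample`,
#'   `n_positive_kmers` (not-callable probes already excluded).
#' @param truth A data frame of true-positive pairs with columns
#'   `probe_id`, `sample`.
#' @param min_hits Integer vector of thresholds to evaluate (default
#'   `c(1, 3, 5, 10)`).
#' @return A tibble of class `kprobe_eval` with one row per threshold:
#'   `min_hits`, `TP`, `FP`, `FN`, `precision`, `recall`.
#' @export
evaluate_calls <- function(results, truth, min_hits = c(1L, 3L, 5L, 10L)) {
  stopifnot(is.data.frame(results), is.data.frame(truth),
            all(c("probe_id", "sample") %in% names(truth)))
  res <- results
  if ("n_kmers" %in% names(res)) res <- filter(res, .data$n_kmers > 0L)
  truth_key <- paste(truth$probe_id, truth$sample, sep = "\r")
  res_key <- paste(res$probe_id, res$sample, sep = "\r")
  is_true <- res_key %in% truth_key
  out <- lapply(sort(as.integer(min_hits)), function(m) {
    called <- res$n_positive_kmers >= m
    tp <- sum(called & is_true)
    fp <- sum(called & !is_true)
    fn <- sum(!called & is_true)
    tibble(min_hits = m, TP = tp, FP = fp, FN = fn,
           precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
           recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("kprobe_eval", class(res))
  res
}

#' Summary of an evaluation table
#'
#' One-row summary: number of thresholds and the precision/recall at
#' the threshold with the best precision.
#'
#' @param x A `kprobe_eval` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @method glance kprobe_eval
glance.kprobe_eval <- function(x, ...) {
  best <- x[which.max(ifelse(is.na(x$precision), -1, x$precision)), ]
  tibble(n_thresholds = nrow(x),
         best_precision = best$precision,
         recall_at_best_precision = best$recall,
         min_hits_at_best_precision = best$min_hits)
}
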