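# ggplot2 displays for the main result types.

#' Plot precision/recall against the min_hits threshold
#'
#' @param object A `kprobe_eval` tibble from [evaluate_calls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot kprobe_eval
autoplot.kprobe_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$min_hits),
                                     y = .data$value,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "min_hits (minimum positive k-mers per call)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-sample probe counts
#'
#' Dot plot of aggregate counts per probe across samples, the typical
#' first look at a probe-set query.
#'
#' @param object A query tibble from [query_probes()] or
#'   [query_masked()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot kprobe_query
autoplot.kprobe_query <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample, y = .data$value,
                                       group = .data$probe_id)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~probe_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "aggregate k-mer count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
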