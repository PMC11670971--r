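#' Cluster size distributions
#'
#' Histogram of cluster sizes, faceted by algorithm when several
#' clusterings are given - the diagnostic view for the effect of the Paris
#' size cap (raw community detection yields a few huge clusters; capped
#' output yields many curation-sized ones).
#'
#' @param clusterings A cluster tibble or list of them.
#' @param binwidth Histogram bin width (default 5).
#' @return A ggplot object.
#' @export
plot_cluster_sizes <- function(clusterings, binwidth = 5) {
  if (is.data.frame(clusterings)) clusterings <- list(clusterings)
  df <- dplyr::bind_rows(clusterings)
  df$size <- lengths(df$members)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "grey20") +
    ggplot2::facet_wrap(ggplot2::vars(.data$algorithm)) +
    ggplot2::labs(x = "cluster size (nodes)", y = "clusters") +
    ggplot2::theme_minimal()
}

#' Histogram of a null distribution with the observed count marked
#'
#' @param object A `bocc_null`.
#' @param observed Optional observed rediscovery count to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bocc_null
#' @export
autoplot.bocc_null <- function(object, observed = NULL, ...) {
  df <- tibble::tibble(count = object$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar(fill = "grey60") +
    ggplot2::labs(
      x = "synthetic rediscovery count",
      y = "replicates",
      title = sprintf("%s null (%d replicates)", object$model,
                      object$replicates)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "firebrick",
                                 linetype = "dashed")
  }
  p
}

#' Rediscovered-edge overlap across algorithms
#'
#' Bar chart of the [rediscovery_overlap()] table: how many distinct edges
#' were rediscovered by exactly each subset of algorithms (the data behind
#' an upset plot).
#'
#' @param overlap Output of [rediscovery_overlap()].
#' @return A ggplot object.
#' @export
plot_rediscovery_overlap <- function(overlap) {
  overlap$algorithms <- factor(overlap$algorithms,
                               levels = rev(overlap$algorithms))
  ggplot2::ggplot(overlap,
                  ggplot2::aes(x = .data$n_edges, y = .data$algorithms)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "edges rediscovered by exactly this subset",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Empirical p-value distribution of clusters
#'
#' @param pvalues Output of [cluster_pvalues()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_pvalue_distribution <- function(pvalues, bins = 20) {
  ggplot2::ggplot(pvalues, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::labs(x = "empirical p-value", y = "clusters") +
    ggplot2::theme_minimal()
}

#' Genetic-algorithm fitness trace
#'
#' @param tune Output of [ga_tune()].
#' @return A ggplot object.
#' @export
plot_fitness_trace <- function(tune) {
  df <- tidyr::pivot_longer(tune$trace, c("generation_best", "hall_of_fame"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "F1 fitness", colour = NULL) +
    ggplot2::theme_minimal()
}
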