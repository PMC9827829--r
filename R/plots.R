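# Convenience plots (ggplot2 is Suggests-only; both functions fail with a
# clear message when it is absent).

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plotting helpers", call. = FALSE)
}

#' Plot a replicate-mean metric series
#'
#' Line plot of a `mean_*` column of a [run_replicates()] mean series, with
#' a +/- 1 SE ribbon.
#'
#' @param reps A `replicate_set`.
#' @param metric Metric name without the `mean_` prefix (e.g.
#'   `"match_prop"`, `"dist_prefA_AA"`).
#' @return A ggplot object.
#' @export
plot_metric_series <- function(reps, metric = "match_prop") {
  require_ggplot()
  ms <- reps$mean_series
  mcol <- paste0("mean_", metric)
  scol <- paste0("se_", metric)
  stopifnot(mcol %in% names(ms))
  df <- data.frame(generation = ms$generation, y = ms[[mcol]],
                   se = ms[[scol]])
  ggplot2::ggplot(df, ggplot2::aes(x = generation, y = y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = y - se, ymax = y + se),
                         alpha = 0.3, fill = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = metric)
}

#' Plot a preference-position histogram
#'
#' Bar plot of [position_histogram()] counts, faceted by chromosome class
#' and preference type.
#'
#' @param hist Data frame from [position_histogram()].
#' @return A ggplot object.
#' @export
plot_position_histogram <- function(hist) {
  require_ggplot()
  ggplot2::ggplot(hist, ggplot2::aes(x = position, y = count)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(pref_type ~ chrom_class) +
    ggplot2::labs(x = "position (distance from trait locus)",
                  y = "chromosomes")
}
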