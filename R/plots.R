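#' Per-position variant-frequency profile across pools
#'
#' The visual outlier-detection view of a screen: one point per pool and
#' position for a given substitution type, with the candidate frequency
#' threshold drawn as a horizontal line. A rare variant shows up as a small
#' set of pools lifting off the baseline at one position.
#'
#' @param freq A `frequency_table`.
#' @param amplicon Amplicon id to plot.
#' @param change Substitution to plot, e.g. `"G>A"`.
#' @param threshold Horizontal reference line (default 0.005).
#' @return A ggplot object.
#' @export
plot_frequency_profile <- function(freq, amplicon, change = "G>A",
                                   threshold = 0.005) {
  dat <- freq[freq$amplicon == amplicon & freq$change == change, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$frequency,
    colour = .data$pool)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.1f%%", 100 * x)) +
    ggplot2::labs(
      title = sprintf("%s frequencies by position (%s)", change, amplicon),
      x = "Position on amplicon (bp)", y = "Variant frequency"
    ) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Coverage along each amplicon, per pool
#'
#' @param counts An `allele_counts` tibble.
#' @return A ggplot object (one line per pool, faceted by amplicon).
#' @export
plot_pool_coverage <- function(counts) {
  dat <- as_tibble(counts) |>
    mutate(coverage = .data$A + .data$C + .data$G + .data$T)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$coverage,
    group = .data$pool, colour = .data$pool)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$amplicon), scales = "free_x") +
    ggplot2::labs(x = "Position on amplicon (bp)", y = "Coverage (reads)") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Frequency profile of a screen run's top candidate
#'
#' Plots the frequency profile for the substitution of the highest-tier
#' candidate, marking candidate positions.
#'
#' @param object A `screen_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_run <- function(object, ...) {
  cand <- object$candidates
  if (!nrow(cand)) {
    amp <- object$refs$id[1]
    return(plot_frequency_profile(object$frequencies, amp,
      threshold = object$config$caller$min_frequency_candidate))
  }
  top <- cand[1, ]
  p <- plot_frequency_profile(object$frequencies, top$amplicon, top$change,
    threshold = object$config$caller$min_frequency_candidate)
  p + ggplot2::geom_vline(xintercept = cand$position[cand$amplicon == top$amplicon &
    cand$change == top$change], linetype = "dotted", colour = "red")
}
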