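# ggplot2 helpers for the standard result graphics: per-mode overlap bars with
# the cumulative curve, weighted-average overlap vs mode window, and the
# sequence-window difference profile with the loop marked.

#' Plot per-mode overlaps and the cumulative overlap curve
#'
#' @param profile a data frame from [overlap_profile()].
#' @param n_modes how many of the softest modes to display (default 40).
#' @return A ggplot object: overlap bars per mode with the cumulative overlap
#'   as a line.
#' @export
plot_overlap_profile <- function(profile, n_modes = 40L) {
  df <- profile[profile$mode <= n_modes & profile$reference == profile$reference[1], ]
  ggplot2::ggplot(df, ggplot2::aes(x = mode)) +
    ggplot2::geom_col(ggplot2::aes(y = overlap), fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = cumulative), colour = "black") +
    ggplot2::labs(x = "ANM mode", y = "overlap / cumulative overlap",
                  title = df$reference[1]) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the weighted-average loop overlap across mode windows
#'
#' @param profile a [mode_window_profile()] result.
#' @return A ggplot object; the first (softest) window is highlighted.
#' @export
plot_mode_window_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = window_start, y = value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = profile$value[1], linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "first mode of window", y = "weighted-average loop overlap") +
    ggplot2::theme_minimal()
}

#' Plot the sequence-window difference profile
#'
#' Soft-mode minus random-baseline weighted-average overlap along the chain;
#' a dashed vertical line marks the catalytic loop position.
#'
#' @param enhancement an [enhancement_analysis()] result.
#' @return A ggplot object, one panel per chain.
#' @export
plot_difference_profile <- function(enhancement) {
  df <- enhancement$profile
  g <- ggplot2::ggplot(df, ggplot2::aes(x = window_start, y = difference)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "window start residue",
                  y = expression(Delta * " weighted-average overlap")) +
    ggplot2::theme_minimal()
  if (!is.null(enhancement$loop))
    g <- g + ggplot2::geom_vline(xintercept = enhancement$loop$start_residue,
                                 linetype = "dashed", colour = "red")
  g
}
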