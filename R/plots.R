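#' Plot a delta-index genome scan
#'
#' Per-marker delta indices as points, the sliding-window mean as a line and
#' the 95% confidence envelope as ribbon bounds, faceted by chromosome.
#'
#' @param scan A `bsa_scan` object from [bsa_scan()].
#' @param chroms Optional subset of chromosomes to show.
#' @return A ggplot object.
#' @export
plot_delta_index <- function(scan, chroms = NULL) {
  markers <- scan$markers
  windows <- dplyr::filter(scan$windows, !is.na(.data$mean_delta))
  if (!is.null(chroms)) {
    markers <- dplyr::filter(markers, .data$chrom %in% chroms)
    windows <- dplyr::filter(windows, .data$chrom %in% chroms)
  }
  bounds <- envelope_at(scan$envelope, windows$mean_depth)
  windows$ci95_upper <- bounds$ci95_upper
  windows$ci95_lower <- bounds$ci95_lower
  windows$mid <- (windows$start + windows$end) / 2
  ggplot2::ggplot(markers, ggplot2::aes(x = .data$pos, y = .data$delta)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4, colour = "grey40") +
    ggplot2::geom_line(data = windows,
                       ggplot2::aes(x = .data$mid, y = .data$mean_delta),
                       colour = "black") +
    ggplot2::geom_line(data = windows,
                       ggplot2::aes(x = .data$mid, y = .data$ci95_upper),
                       colour = "blue", linetype = 2) +
    ggplot2::geom_line(data = windows,
                       ggplot2::aes(x = .data$mid, y = .data$ci95_lower),
                       colour = "blue", linetype = 2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(Delta * " index")) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' @rdname plot_delta_index
#' @param object A `bsa_scan` object.
#' @param ... Passed to [plot_delta_index()].
#' @export
autoplot.bsa_scan <- function(object, ...) plot_delta_index(object, ...)

#' Ternary scatter plot of triad classifications
#'
#' Projects the relative-expression triples onto the 2-D simplex (LF top,
#' MF1 bottom-left, MF2 bottom-right) and colours points by category.
#'
#' @param classifications A `triad_classification` tibble from
#'   [classify_triads()].
#' @return A ggplot object.
#' @export
plot_ternary <- function(classifications) {
  # barycentric -> cartesian: x = r_mf2 + r_lf/2, y = r_lf * sqrt(3)/2
  df <- dplyr::mutate(classifications,
    x = .data$rel_mf2 + .data$rel_lf / 2,
    y = .data$rel_lf * sqrt(3) / 2
  )
  frame <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  labs <- tibble::tibble(x = c(0.5, -0.03, 1.03), y = c(sqrt(3) / 2 + 0.04, -0.04, -0.04),
                         lab = c("LF", "MF1", "MF2"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = frame, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category),
                        size = 0.8, alpha = 0.7) +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$lab), size = 3.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "category")
}

#' @rdname plot_ternary
#' @param object A `triad_classification` tibble.
#' @param ... Unused.
#' @export
autoplot.triad_classification <- function(object, ...) plot_ternary(object)

#' Delta-PSI significance plot for a DAS analysis
#'
#' Delta PSI against -log10 FDR per event, with the delta and FDR thresholds
#' drawn and DAS events highlighted.
#'
#' @param object A `das_result` from [call_das()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.das_result <- function(object, ...) {
  df <- dplyr::filter(object$events, !is.na(.data$fdr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_psi,
                                   y = -log10(.data$fdr),
                                   colour = .data$das)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$delta_threshold,
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$params$fdr_threshold),
                        linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * "PSI"), y = expression(-log[10] * " FDR"),
                  colour = "DAS") +
    ggplot2::theme_minimal()
}
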