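#' Candidate-population comet plot for one experimental map
#'
#' Shows every candidate alignment of a map in feature space - cut errors
#' against the Wilson-Hilferty transformed sizing error, sized by the number
#' of matches and coloured by p-value - with the best candidate highlighted.
#' A well-separated true alignment sits alone in the low-error corner.
#'
#' @param x An `om_alignments` object.
#' @param map_id Which map to plot (default: the first with >= 2
#'   candidates).
#' @return A ggplot object.
#' @export
plot_candidates <- function(x, map_id = NULL) {
  cands <- x$candidates
  if (is.null(map_id)) {
    tab <- table(cands$map_id)
    map_id <- names(tab)[tab >= 2][1]
  }
  d <- cands[cands$map_id == map_id, ]
  if (!nrow(d)) stop("no candidate population for map ", map_id)
  d$best <- seq_len(nrow(d)) == which.min(d$p_value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cut_errors, y = .data$wht)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_matches,
                                     colour = -log10(.data$p_value)),
                        alpha = 0.7) +
    ggplot2::geom_point(data = d[d$best, ], shape = 1, size = 5,
                        colour = "red") +
    ggplot2::scale_colour_viridis_c(name = "-log10 p") +
    ggplot2::labs(title = paste("Candidate alignments:", map_id),
                  x = "cut errors", y = "WHT(chi-square)",
                  size = "#matches") +
    ggplot2::theme_minimal()
}

#' @rdname plot_candidates
#' @param object An `om_alignments` object.
#' @param ... Passed on to [plot_candidates()].
#' @export
autoplot.om_alignments <- function(object, ...) plot_candidates(object, ...)

#' Window-size response of overlap detection
#'
#' Line plot of correct extensions (or any chosen response) against the
#' sliding-window length; the interesting feature is the interior maximum
#' where windows are long enough to separate signal from noise but short
#' enough to fit inside true overlaps.
#'
#' @param data A data frame with columns `window_l` and `n_correct_extensions`
#'   (e.g. built by mapping [overlap_align_maps()] + [score_overlap()] over
#'   window sizes).
#' @return A ggplot object.
#' @export
plot_window_response <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$window_l,
                                     y = .data$n_correct_extensions)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window length (fragments)", y = "correct extensions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
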