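# ggplot2 visualisations for the three result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot IF-AHP weights
#'
#' Horizontal bars of global weights, coloured by cluster.
#'
#' @param object An `if_ahp` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot if_ahp
#' @export
autoplot.if_ahp <- function(object, ...) {
  df <- object$weights |>
    dplyr::filter(.data$cluster != object$root_cluster |
                    dplyr::n_distinct(object$weights$cluster) == 1L)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$global,
    y = stats::reorder(.data$element, .data$global),
    fill = .data$cluster)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "global weight", y = NULL, fill = "cluster",
                  title = "IF-AHP global priorities") +
    ggplot2::theme_minimal()
}

#' Plot a DEMATEL influence map
#'
#' Prominence (D + R) against relation (D - R) per element, faceted by
#' cluster; dispatchers sit above the dashed zero line, receivers below.
#'
#' @param object An `if_dematel` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot if_dematel
#' @export
autoplot.if_dematel <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$prominence, .data$relation,
                                   colour = .data$role)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$element),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cluster), scales = "free") +
    ggplot2::labs(x = "prominence (D + R)", y = "relation (D - R)",
                  title = "Cause-effect influence map") +
    ggplot2::theme_minimal()
}

#' Plot a CoCoSo ranking
#'
#' Final compromise index per alternative, ordered by rank.
#'
#' @param object A `cocoso` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cocoso
#' @export
autoplot.cocoso <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$alternative, .data$M), y = .data$M)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$M)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "compromise index M",
                  title = sprintf("CoCoSo ranking (lambda = %g)",
                                  object$lambda)) +
    ggplot2::theme_minimal()
}
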