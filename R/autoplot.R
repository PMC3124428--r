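#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an informativeness profile with ggplot2
#'
#' Quick interactive companion to the SVG renderer: one line per locus over
#' historical time.
#'
#' @param object a `pi_profile`.
#' @param basis `"per_site"` (default) or `"net"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pi_profile
#' @export
autoplot.pi_profile <- function(object, basis = c("per_site", "net"), ...) {
  basis <- match.arg(basis)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = .data[[basis]],
                                       colour = .data$locus)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = rep(PALETTE,
      length.out = length(unique(object$locus)))) +
    ggplot2::labs(x = "time before present",
                  y = sprintf("phylogenetic informativeness (%s)",
                              gsub("_", " ", basis)),
                  colour = "locus") +
    ggplot2::theme_minimal()
}

#' Plot an epoch ranking with ggplot2
#'
#' @param object a `pi_ranking`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pi_ranking
#' @export
autoplot.pi_ranking <- function(object, ...) {
  basis <- attr(object, "basis")
  col <- if (identical(basis, "net")) "integral_net" else "integral_persite"
  ggplot2::ggplot(object, ggplot2::aes(
      x = stats::reorder(.data$locus, .data[[col]]),
      y = .data[[col]])) +
    ggplot2::geom_col(fill = PALETTE[5]) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = sprintf("informativeness integrated over [%g, %g] (%s)",
                  object$t_start[1], object$t_end[1],
                  if (identical(basis, "net")) "net" else "per site")) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
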