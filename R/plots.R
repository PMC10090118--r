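# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a distance matrix
#'
#' @param object an `stk_dist` matrix.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stk_dist <- function(object, ...) {
  long <- tidy.stk_dist(object)
  long <- dplyr::bind_rows(long,
                           dplyr::rename(long, item1 = "item2", item2 = "item1"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$item1, y = .data$item2,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "distance") +
    ggplot2::labs(x = NULL, y = NULL, title = attr(object, "method")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of samples per tree group
#'
#' @param groups tibble from [partition_groups()].
#' @return a ggplot.
#' @export
plot_group_sizes <- function(groups) {
  dat <- dplyr::count(
    dplyr::mutate(groups,
                  group = dplyr::coalesce(.data$group, "unresolved")),
    .data$group)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "tree group", y = "samples") +
    ggplot2::theme_minimal()
}

#' Per-sample ambiguity fractions
#'
#' Highlights polymorphic-flagged samples, the signature used to set aside
#' consensus sequences with many superimposed peaks.
#'
#' @param profile tibble from [ambiguity_profile()].
#' @param threshold flag threshold drawn as a dashed line.
#' @return a ggplot.
#' @export
plot_ambiguity <- function(profile, threshold = 0.005) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$id, y = .data$ambiguity_fraction,
                               fill = .data$polymorphic)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "ambiguity fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Group-size overview of a pipeline run
#'
#' @param object a `stuckenia_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stuckenia_run <- function(object, ...) {
  plot_group_sizes(object$groups)
}
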