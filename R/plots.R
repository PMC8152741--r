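#' Loading heatmap of a factor solution
#'
#' @param object A `factor_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.factor_solution <- function(object, ...) {
  d <- tidy(object)
  d$variable <- factor(d$variable, levels = rev(rownames(object$loadings)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor, y = .data$variable,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' Mean loadings with replication variability
#'
#' Dot-and-whisker view of the mean loading plus/minus one standard
#' deviation across replications, by factor.
#'
#' @param object A `replication_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.replication_summary <- function(object, ...) {
  d <- tidy(object)
  d$variable <- factor(d$variable, levels = rev(rownames(object$mean_loadings)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_loading, y = .data$variable,
                                  colour = .data$prominent)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_loading - .data$sd_loading,
                   xmax = .data$mean_loading + .data$sd_loading),
      height = 0
    ) +
    ggplot2::geom_vline(xintercept = c(-object$threshold, object$threshold),
                        linetype = 3) +
    ggplot2::facet_wrap(~factor, nrow = 1) +
    ggplot2::labs(x = "mean loading (+/- SD over replications)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Choropleth of a tract-level variable on the grid tessellation
#'
#' @param tess A [make_tessellation()] tessellation.
#' @param values Values per tract (in `tract_id` order) or a factor of
#'   classes.
#' @param name Legend title.
#' @return A ggplot object.
#' @export
plot_tract_map <- function(tess, values, name = "value") {
  stopifnot(inherits(tess, "tessellation"))
  if (length(values) != tess$n_tracts) abort("one value per tract required")
  d <- tess$tracts
  d$value <- values
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                  ymin = .data$ymin, ymax = .data$ymax,
                                  fill = .data$value)) +
    ggplot2::geom_rect(colour = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = name, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
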