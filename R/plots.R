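# ggplot2 visualizations for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a NeNA fit
#' @param object A `nena_fit`.
#' @param ... Unused.
#' @return A ggplot: nearest-neighbour distance histogram with the fitted
#'   single-emitter + background model.
#' @export
autoplot.nena_fit <- function(object, ...) {
  if (is.null(object$bins)) stop("no binned data to plot (fallback estimate)")
  d <- object$bins
  d$fit <- object$amplitude * d$d * exp(-d$d^2 / (4 * object$sigma_nena_nm^2)) +
    object$background * d$d
  ggplot2::ggplot(d, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), width = 1,
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "firebrick") +
    ggplot2::labs(x = "nearest-neighbour distance (nm)", y = "pairs",
                  title = sprintf("NeNA precision: %.1f nm",
                                  object$sigma_nena_nm)) +
    ggplot2::theme_minimal()
}

#' Plot an oligomer mixture fit
#' @param object A `mixture_fit`.
#' @param ... Unused.
#' @return A ggplot: probability-density 1/tau_d histogram with the four
#'   Gaussian components and their sum.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  b <- object$bins
  xs <- seq(0, max(b$mid), length.out = 400)
  comp <- purrr::map_dfr(1:4, function(k)
    tibble(x = xs, state = factor(k),
           y = object$amplitudes[k] *
             exp(-(xs - object$means[k])^2 / (2 * object$sigmas[k]^2))))
  total <- comp |> dplyr::group_by(.data$x) |>
    dplyr::summarise(y = sum(.data$y), .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_col(data = b, ggplot2::aes(x = .data$mid, y = .data$density),
                      width = object$bin_width, fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$state),
                       linetype = "dashed") +
    ggplot2::geom_line(data = total, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = expression(1 / tau[d] ~ (s^-1)), y = "probability density",
                  colour = "oligomer") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative proximity profile
#' @param object A `cumulative_profile`.
#' @param ... Unused.
#' @return A ggplot of the mean cumulative count vs. distance.
#' @export
autoplot.cumulative_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$edge_nm, y = .data$mean_count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance from cluster center (nm)",
                  y = "mean partner localizations within r",
                  title = sprintf("AUC = %.1f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot a cell embedding
#' @param object A `paint_embedding`.
#' @param colour `"condition"` or `"cluster"`.
#' @param ... Unused.
#' @return A ggplot of the 2-D UMAP embedding.
#' @export
autoplot.paint_embedding <- function(object, colour = c("condition", "cluster"),
                                     ...) {
  colour <- match.arg(colour)
  d <- as_tibble(unclass(object))
  d$cluster <- factor(d$cluster)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$umap1, y = .data$umap2,
                                  colour = .data[[colour]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2") +
    ggplot2::theme_minimal()
}

#' Per-condition density distribution plot
#' @param density_table Output rows of [densities()].
#' @param value Value column to plot.
#' @return A ggplot (violin + per-cell points, median line).
#' @export
plot_density_distribution <- function(density_table, value = "clusters_per_um2") {
  ggplot2::ggplot(density_table,
                  ggplot2::aes(x = .data$condition, y = .data[[value]])) +
    ggplot2::geom_violin(draw_quantiles = c(0.25, 0.5, 0.75)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
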