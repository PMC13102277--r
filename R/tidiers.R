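# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a NeNA precision fit
#' @param x A `nena_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit parameters.
#' @export
tidy.nena_fit <- function(x, ...) {
  tibble(term = c("sigma_nena_nm", "amplitude", "background"),
         estimate = c(x$sigma_nena_nm, x$amplitude %||% NA_real_,
                      x$background %||% NA_real_))
}

#' @rdname tidy.nena_fit
#' @export
glance.nena_fit <- function(x, ...) {
  tibble(sigma_nena_nm = x$sigma_nena_nm, n_pairs = x$n_pairs,
         fit_residual = x$fit_residual, flagged = x$flagged,
         source = x$source)
}

#' Tidy an oligomer mixture fit
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return Tibble with one row per oligomer state (1 = monomer ...
#'   4 = tetramer): component mean, SD, amplitude, area and fraction.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(state = 1:4,
         oligomer = c("monomer", "dimer", "trimer", "tetramer"),
         mean = x$means, sigma = x$sigmas, amplitude = x$amplitudes,
         area = x$areas, fraction = x$fractions)
}

#' @rdname tidy.mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(mu1 = x$mu1, mu1_source = x$mu1_source, n_values = x$n_values,
         bin_width = x$bin_width, fit_residual = x$fit_residual)
}

#' Tidy a cell embedding
#' @param x A `paint_embedding`.
#' @param ... Unused.
#' @return The embedding as a plain tibble.
#' @export
tidy.paint_embedding <- function(x, ...) as_tibble(unclass(x))

#' @rdname tidy.paint_embedding
#' @export
glance.paint_embedding <- function(x, ...) {
  km <- attr(x, "kmeans")
  tibble(n_cells = nrow(x), k = attr(x, "k"), seed = attr(x, "seed"),
         tot_withinss = km$tot.withinss, betweenss = km$betweenss)
}
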