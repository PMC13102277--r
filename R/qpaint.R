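# qPAINT: molecular counting from imager binding kinetics.
# The mean dark time tau_d of a cluster is inversely proportional to the
# influx rate xi = k_on * c_i and the number of available docking strands:
# N = 1 / (tau_d * xi). The 1/tau_d distribution over clusters is
# decomposed into monomer..tetramer populations by a four-Gaussian fit
# whose component means sit on the ladder k * mu1.

#' Influx rate
#'
#' @param xi_per_s Influx rate \eqn{\xi} in 1/s; if `NULL`, computed as
#'   `k_on_per_M_per_s * c_i_M`.
#' @param k_on_per_M_per_s Association rate constant.
#' @param c_i_M Imager concentration (mol/L).
#' @param source `"config"` (from known kinetic constants) or
#'   `"calibration"` (from surface traces).
#' @return A list of class `influx_rate`.
#' @export
influx_rate <- function(xi_per_s = NULL, k_on_per_M_per_s = 1e7, c_i_M = 2e-9,
                        source = c("config", "calibration")) {
  source <- match.arg(source)
  if (is.null(xi_per_s)) xi_per_s <- k_on_per_M_per_s * c_i_M
  stopifnot(xi_per_s > 0)
  structure(list(xi_per_s = xi_per_s, k_on_per_M_per_s = k_on_per_M_per_s,
                 c_i_M = c_i_M, source = source), class = "influx_rate")
}

as_xi <- function(xi) if (inherits(xi, "influx_rate")) xi$xi_per_s else as.numeric(xi)

#' Extract per-cluster binding kinetics
#'
#' Builds each cluster's bright-event sequence from its member records of a
#' linked localization table (`frame` .. `frame_last` spans), merges
#' time-overlapping events from different docking strands, and computes
#' dark times (gaps between successive events) and bright times (event
#' durations) in seconds. Clusters with fewer than 3 dark times are flagged
#' and excluded from mixture fitting.
#'
#' @param clusters Output of [dbscan_clusters()]/[kinetic_filter()].
#' @param linked A linked [loc_table()] (the one `clusters` indexes into).
#' @param exposure_s Frame time in seconds.
#' @return Tibble: `cluster_id`, `n_events`, `n_dark`, `tau_d_s`, `tau_b_s`,
#'   `inv_tau_d_per_s`, `flagged`, plus list-columns `dark_times_s` and
#'   `bright_times_s`.
#' @export
extract_kinetics <- function(clusters, linked, exposure_s) {
  has_last <- "frame_last" %in% names(linked)
  res <- purrr::map(seq_len(nrow(clusters)), function(i) {
    rows <- clusters$members[[i]]
    f0 <- linked$frame[rows]
    f1 <- if (has_last) linked$frame_last[rows] else f0
    o <- order(f0)
    f0 <- f0[o]; f1 <- f1[o]
    # merge events that overlap or touch at frame resolution
    ms <- f0[1]; me <- f1[1]; s_out <- integer(0); e_out <- integer(0)
    for (j in seq_along(f0)[-1]) {
      if (f0[j] <= me + 1L) me <- max(me, f1[j])
      else { s_out <- c(s_out, ms); e_out <- c(e_out, me); ms <- f0[j]; me <- f1[j] }
    }
    s_out <- c(s_out, ms); e_out <- c(e_out, me)
    dark <- (s_out[-1] - e_out[-length(e_out)] - 1L) * exposure_s
    bright <- (e_out - s_out + 1L) * exposure_s
    list(n_events = length(s_out), dark = dark, bright = bright)
  })
  n_dark <- vapply(res, function(r) length(r$dark), integer(1))
  tau_d <- vapply(res, function(r) if (length(r$dark) >= 1) mean(r$dark) else NA_real_,
                  numeric(1))
  tau_d[tau_d <= 0] <- NA_real_
  tibble(cluster_id = clusters$cluster_id,
         n_events = vapply(res, `[[`, integer(1), "n_events"),
         n_dark = n_dark,
         tau_d_s = tau_d,
         tau_b_s = vapply(res, function(r) mean(r$bright), numeric(1)),
         inv_tau_d_per_s = 1 / tau_d,
         flagged = n_dark < 3 | !is.finite(tau_d),
         dark_times_s = purrr::map(res, "dark"),
         bright_times_s = purrr::map(res, "bright"))
}

#' Mean dark time estimator
#'
#' `"mean"` is the maximum-likelihood estimate for exponential gaps (the
#' sample mean); `"cdf"` fits the empirical CDF with
#' \eqn{1 - e^{-t/\tau}} by least squares. The two agree within ~10% on
#' exponential data.
#'
#' @param dark_times_s Numeric vector of dark times (s); at least 3.
#' @param method `"mean"` or `"cdf"`.
#' @return Estimated \eqn{\tau_d} in seconds.
#' @export
estimate_tau_d <- function(dark_times_s, method = c("mean", "cdf")) {
  method <- match.arg(method)
  d <- dark_times_s[is.finite(dark_times_s) & dark_times_s > 0]
  if (length(d) < 3)
    stop("need at least 3 dark times (got ", length(d), ")", call. = FALSE)
  if (method == "mean") return(mean(d))
  d <- sort(d)
  ecdf_v <- seq_along(d) / length(d)
  sse <- function(tau) sum((1 - exp(-d / tau) - ecdf_v)^2)
  stats::optimize(sse, interval = c(min(d) / 10, max(d) * 10))$minimum
}

#' Molecules per cluster (qPAINT counting)
#'
#' \deqn{N = \frac{1}{\tau_d \, \xi}}
#'
#' @param tau_d_s Mean dark time(s), seconds (> 0).
#' @param xi An [influx_rate()] or numeric \eqn{\xi} in 1/s (> 0).
#' @return Estimated number of docking strands (vectorized over `tau_d_s`).
#' @export
molecules_per_cluster <- function(tau_d_s, xi) {
  x <- as_xi(xi)
  if (any(!is.finite(tau_d_s)) || any(tau_d_s <= 0))
    stop("tau_d_s must be positive and finite", call. = FALSE)
  if (!is.finite(x) || x <= 0) stop("xi must be positive", call. = FALSE)
  1 / (tau_d_s * x)
}

#' Calibrate the influx rate from surface traces
#'
#' Antibodies nonspecifically bound to the glass surface carry single
#' docking strands (N = 1), so their median dark time directly calibrates
#' \eqn{\xi = 1/\mathrm{median}(\tau_d)}.
#'
#' @param surface_tau_d_s Per-trace mean dark times (s) from surface signals.
#' @return An [influx_rate()] with `source = "calibration"`. Fewer than 10
#'   traces triggers a warning but still returns the estimate.
#' @export
calibrate_influx <- function(surface_tau_d_s) {
  d <- surface_tau_d_s[is.finite(surface_tau_d_s) & surface_tau_d_s > 0]
  if (length(d) == 0) stop("no usable surface traces", call. = FALSE)
  if (length(d) < 10)
    warning("influx calibration from only ", length(d),
            " surface traces; estimate may be unstable")
  influx_rate(xi_per_s = 1 / stats::median(d), source = "calibration")
}

fd_bin_width <- function(x) {
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(x)) / 30
  bw
}

# dominant-peak estimate of the monomer position: density peak refined by a
# local single-Gaussian least-squares fit
estimate_mu1 <- function(x) {
  dens <- stats::density(x, n = 512)
  peak <- dens$x[which.max(dens$y)]
  win <- abs(x - peak) <= 0.5 * peak
  if (sum(win) < 20) return(peak)
  h <- graphics::hist(x[win], breaks = 24, plot = FALSE)
  sse <- function(p) sum((p[1] * exp(-(h$mids - p[2])^2 / (2 * p[3]^2)) - h$density)^2)
  fit <- tryCatch(stats::optim(c(max(h$density), peak, 0.2 * peak), sse,
                               method = "L-BFGS-B",
                               lower = c(0, 0.5 * peak, 0.02 * peak),
                               upper = c(Inf, 1.5 * peak, peak)),
                  error = function(e) NULL)
  if (is.null(fit)) peak else fit$par[2]
}

#' Four-Gaussian oligomer mixture fit
#'
#' Decomposes a set of per-cluster \eqn{1/\tau_d} values into monomer,
#' dimer, trimer and tetramer populations. The probability-density-scaled
#' histogram (Freedman-Diaconis bins by default) is fitted by least squares
#' with \deqn{f(x) = \sum_{k=1}^{4} A_k \exp\!\big(-(x - k\mu_1)^2 /
#' (2\sigma_k^2)\big),} where the monomer position \eqn{\mu_1} is fixed
#' (conventionally from the resting condition) or, when absent, estimated
#' from this dataset's dominant peak. Component areas
#' \eqn{A_k \sigma_k \sqrt{2\pi}} give the oligomer fractions. The fit uses
#' a fixed multi-start grid and is deterministic.
#'
#' @param inv_tau_values Per-cluster \eqn{1/\tau_d} values (1/s); >= 50.
#' @param mu1 Fixed monomer peak position, or `NULL` to estimate.
#' @param bin_width Histogram bin width; default Freedman-Diaconis.
#' @param sigma_lower_frac Lower bound on \eqn{\sigma_k} as a fraction of
#'   \eqn{\mu_1} (guards against spike degeneracy).
#' @return An object of class `mixture_fit`: `mu1`, `means`, `sigmas`,
#'   `amplitudes`, `areas`, `fractions`, `fit_residual`, `n_values`, `bins`.
#' @export
fit_oligomer_mixture <- function(inv_tau_values, mu1 = NULL, bin_width = NULL,
                                 sigma_lower_frac = 0.1) {
  x <- inv_tau_values[is.finite(inv_tau_values) & inv_tau_values > 0]
  if (length(x) < 50)
    stop("need >= 50 values for the mixture fit (got ", length(x), ")",
         call. = FALSE)
  mu1_source <- if (is.null(mu1)) "fitted" else "fixed"
  if (is.null(mu1)) mu1 <- estimate_mu1(x)
  stopifnot(mu1 > 0)
  if (is.null(bin_width)) bin_width <- fd_bin_width(x)
  brks <- seq(0, max(x, 4.5 * mu1) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = brks, plot = FALSE)
  mids <- h$mids; dens <- h$density
  model <- function(p) {
    A <- p[1:4]; s <- p[5:8]
    rowSums(vapply(1:4, function(k)
      A[k] * exp(-(mids - k * mu1)^2 / (2 * s[k]^2)), numeric(length(mids))))
  }
  sse <- function(p) sum((model(p) - dens)^2)
  dens_at <- function(m) {
    i <- findInterval(m, brks); i <- pmin(pmax(i, 1L), length(dens))
    dens[i]
  }
  lo <- c(rep(0, 4), rep(sigma_lower_frac * mu1, 4))
  hi <- c(rep(max(dens) * 3 + 1e-12, 4), rep(2 * mu1, 4))
  best <- NULL
  for (sf in c(0.15, 0.25, 0.40)) {
    p0 <- c(pmax(dens_at((1:4) * mu1), 1e-6), rep(sf * mu1, 4))
    fit <- tryCatch(stats::optim(p0, sse, method = "L-BFGS-B",
                                 lower = lo, upper = hi,
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("oligomer mixture fit did not converge; histogram range ",
         paste(signif(range(x), 3), collapse = "-"), ", mu1 = ", signif(mu1, 3),
         call. = FALSE)
  A <- best$par[1:4]; s <- best$par[5:8]
  areas <- A * s * sqrt(2 * pi)
  fractions <- if (sum(areas) > 0) areas / sum(areas) else rep(NA_real_, 4)
  structure(list(mu1 = mu1, mu1_source = mu1_source, means = (1:4) * mu1,
                 sigmas = s, amplitudes = A, areas = areas,
                 fractions = fractions,
                 fit_residual = sqrt(best$value / length(mids)),
                 n_values = length(x), bin_width = bin_width,
                 bins = tibble(mid = mids, density = dens)),
            class = "mixture_fit")
}

#' @exportS3Method base::print
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: mu1 = %.4g /s (%s), n = %d>\n",
              x$mu1, x$mu1_source, x$n_values))
  cat("fractions:", paste(sprintf("%s %.3f", c("mono", "di", "tri", "tetra"),
                                  x$fractions), collapse = ", "), "\n")
  invisible(x)
}

#' Per-state uncertainties by leave-one-cell-out jackknife
#'
#' Refits the oligomer mixture with each cell's clusters left out in turn
#' and reports, per oligomer state, the pooled-fit fraction and its
#' jackknife standard error
#' \eqn{\sqrt{\frac{n-1}{n}\sum_i(\theta_{(i)} - \bar\theta)^2}}.
#' The monomer position is fixed at the pooled fit's \eqn{\mu_1} for all
#' refits.
#'
#' @param values_by_cell Named list: per cell, the vector of per-cluster
#'   \eqn{1/\tau_d} values.
#' @param mu1 Fixed monomer position; `NULL` to take it from the pooled fit.
#' @param ... Passed to [fit_oligomer_mixture()].
#' @return Tibble `state` (1-4), `fraction`, `sd` (jackknife SE), `n_cells`;
#'   the pooled `mixture_fit` in attribute `fit`.
#' @export
mixture_jackknife <- function(values_by_cell, mu1 = NULL, ...) {
  pooled <- fit_oligomer_mixture(unlist(values_by_cell, use.names = FALSE),
                                 mu1 = mu1, ...)
  n <- length(values_by_cell)
  loo <- vapply(seq_len(n), function(i) {
    v <- unlist(values_by_cell[-i], use.names = FALSE)
    f <- tryCatch(fit_oligomer_mixture(v, mu1 = pooled$mu1, ...),
                  error = function(e) NULL)
    if (is.null(f)) rep(NA_real_, 4) else f$fractions
  }, numeric(4))
  loo <- loo[, stats::complete.cases(t(loo)), drop = FALSE]
  m <- ncol(loo)
  se <- if (m >= 2)
    sqrt((m - 1) / m * rowSums((loo - rowMeans(loo))^2))
  else rep(NA_real_, 4)
  out <- tibble(state = 1:4, fraction = pooled$fractions, sd = se, n_cells = n)
  attr(out, "fit") <- pooled
  out
}

#' Compare oligomer-state areas between conditions
#'
#' For each oligomer state, the change in fitted area fraction relative to
#' the reference (resting) condition, its uncertainty by error propagation
#' \eqn{\sqrt{sd_{rest}^2 + sd_{stim}^2}}, the z-score, and the two-sided
#' normal p-value.
#'
#' @param rest,stim Tibbles with columns `state`, `fraction`, `sd`
#'   (e.g. from [mixture_jackknife()]).
#' @return Tibble `state`, `delta_area`, `combined_sd`, `z`, `p_two_sided`.
#'   A zero combined SD yields `z = NA` (undefined).
#' @export
compare_oligomer_areas <- function(rest, stim) {
  stopifnot(all(c("state", "fraction", "sd") %in% names(rest)),
            all(c("state", "fraction", "sd") %in% names(stim)))
  rest <- rest[order(rest$state), ]; stim <- stim[order(stim$state), ]
  stopifnot(identical(as.integer(rest$state), as.integer(stim$state)))
  delta <- stim$fraction - rest$fraction
  csd <- sqrt(rest$sd^2 + stim$sd^2)
  z <- ifelse(csd > 0, delta / csd, NA_real_)
  tibble(state = rest$state, delta_area = delta, combined_sd = csd, z = z,
         p_two_sided = 2 * stats::pnorm(-abs(z)))
}
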