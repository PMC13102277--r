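# Post-processing chain: precision estimation (NeNA), fiducial drift
# correction, consecutive-frame linking, DBSCAN cluster isolation, and the
# kinetic mean-frame filter.

#' NeNA localization precision
#'
#' Estimates localization precision from the distances between
#' nearest-neighbour localizations in consecutive frames (re-localizations
#' of the same emitter). The distance histogram is fitted with the
#' single-emitter term \deqn{p(d) = \frac{d}{2\sigma^2} e^{-d^2/(4\sigma^2)}}
#' plus a linear false-pair background \eqn{a\,d}, by bounded nonlinear
#' least squares on 1-nm bins over `fit_window_nm`.
#'
#' @param table A [loc_table()], sortable by frame, spanning >= 2 frames.
#' @param fit_window_nm Upper edge of the fitted histogram (nm).
#' @param min_pairs Minimum nearest-neighbour pairs for a trusted fit;
#'   below this the estimate is flagged and, when `lpx`/`lpy` are present,
#'   falls back to their mean.
#' @return An object of class `nena_fit`: `sigma_nena_nm`, `n_pairs`,
#'   `fit_residual`, `flagged`, plus the binned data for plotting.
#' @export
nena_precision <- function(table, fit_window_nm = 200, min_pairs = 100) {
  if (nrow(table) < 2 || length(unique(table$frame)) < 2)
    stop("need localizations in at least 2 frames", call. = FALSE)
  idx <- split(seq_len(nrow(table)), table$frame)
  frames <- as.integer(names(idx))
  dists <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    nxt <- match(frames[k] + 1L, frames)
    if (is.na(nxt)) next
    a <- idx[[k]]; b <- idx[[nxt]]
    dists[[k]] <- cpp_nn_dist(table$x[a], table$y[a], table$x[b], table$y[b], FALSE)
  }
  d <- unlist(dists, use.names = FALSE)
  d <- d[is.finite(d) & d <= fit_window_nm]
  n_pairs <- length(d)
  flagged <- n_pairs < min_pairs
  if (flagged) {
    if (all(c("lpx", "lpy") %in% names(table))) {
      sigma <- mean(c(table$lpx, table$lpy), na.rm = TRUE)
      return(structure(list(sigma_nena_nm = sigma, n_pairs = n_pairs,
                            fit_residual = NA_real_, flagged = TRUE,
                            source = "lp_fallback", bins = NULL),
                       class = "nena_fit"))
    }
    stop("only ", n_pairs, " nearest-neighbour pairs; cannot estimate NeNA",
         call. = FALSE)
  }
  h <- graphics::hist(d, breaks = seq(0, fit_window_nm, by = 1), plot = FALSE)
  dat <- data.frame(d = h$mids, count = h$counts)
  model <- function(p, d) p[1] * d * exp(-d^2 / (4 * p[2]^2)) + p[3] * d
  sse <- function(p) sum((model(p, dat$d) - dat$count)^2)
  best <- NULL
  # multi-start over a sigma grid; amplitude from histogram mass
  amp0 <- 2 * sum(dat$count) / fit_window_nm
  for (s0 in c(1, 2, 5, 8, 12, 16, 25, 40)) {
    fit <- tryCatch(
      stats::optim(c(amp0, s0, 0), sse, method = "L-BFGS-B",
                   lower = c(0, 0.05, 0), upper = c(Inf, fit_window_nm, Inf)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("NeNA fit did not converge", call. = FALSE)
  structure(list(sigma_nena_nm = best$par[2], n_pairs = n_pairs,
                 fit_residual = sqrt(best$value / nrow(dat)),
                 amplitude = best$par[1], background = best$par[3],
                 flagged = FALSE, source = "nena", bins = dat),
            class = "nena_fit")
}

#' @exportS3Method base::print
print.nena_fit <- function(x, ...) {
  cat(sprintf("<nena_fit: sigma = %.2f nm from %d pairs%s>\n",
              x$sigma_nena_nm, x$n_pairs, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

# clamped moving average (window w centred, truncated at the edges)
clamped_ma <- function(v, w) {
  n <- length(v)
  half_lo <- floor((w - 1) / 2); half_hi <- ceiling((w - 1) / 2)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half_lo, 1L); hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Extract fiducial tracks from a simulated table
#'
#' Convenience for simulator output, where fiducial localizations are
#' tagged in the `kind` column.
#' @param table A [loc_table()] with a `kind` column.
#' @return Tibble `fiducial_id`, `frame`, `x`, `y`.
#' @export
fiducial_tracks_from_kind <- function(table) {
  stopifnot("kind" %in% names(table))
  fid <- table[startsWith(table$kind, "fiducial"), c("kind", "frame", "x", "y")]
  dplyr::transmute(fid, fiducial_id = .data$kind, frame = .data$frame,
                   x = .data$x, y = .data$y)
}

#' Fiducial-based drift correction
#'
#' Per-frame drift is the mean displacement of all fiducials from their
#' first-frame positions, linearly interpolated over frames where a
#' fiducial is missing, then smoothed with a clamped moving average.
#' The smoothed drift is subtracted from every localization.
#'
#' @param table A [loc_table()].
#' @param fiducial_tracks Tibble with `fiducial_id`, `frame`, `x`, `y` (nm);
#'   every fiducial must be present in >= 90% of frames.
#' @param smooth_frames Moving-average window (frames).
#' @return The corrected table; attributes `drift` (tibble `frame`, `dx`,
#'   `dy`) and `fiducial_rms_nm` (post-correction residual).
#' @export
correct_drift <- function(table, fiducial_tracks, smooth_frames = 100) {
  if (is.null(fiducial_tracks) || nrow(fiducial_tracks) == 0)
    stop("no fiducial tracks supplied; skip drift correction explicitly ",
         "(e.g. --no-drift) if none were acquired", call. = FALSE)
  acq <- attr(table, "acq") %||% acq_metadata()
  n_frames <- max(acq$n_frames, max(table$frame) + 1L)
  cover <- tapply(fiducial_tracks$frame, fiducial_tracks$fiducial_id,
                  function(f) length(unique(f))) / n_frames
  if (all(cover < 0.9))
    stop("no fiducial present in >= 90% of frames", call. = FALSE)
  keep <- names(cover)[cover >= 0.9]
  ft <- fiducial_tracks[fiducial_tracks$fiducial_id %in% keep, ]
  frames <- 0:(n_frames - 1L)
  disp <- lapply(split(ft, ft$fiducial_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    dx <- stats::approx(tr$frame, tr$x - tr$x[1], xout = frames, rule = 2)$y
    dy <- stats::approx(tr$frame, tr$y - tr$y[1], xout = frames, rule = 2)$y
    cbind(dx, dy)
  })
  dx <- rowMeans(do.call(cbind, lapply(disp, function(m) m[, 1])))
  dy <- rowMeans(do.call(cbind, lapply(disp, function(m) m[, 2])))
  dx <- clamped_ma(dx, smooth_frames); dy <- clamped_ma(dy, smooth_frames)
  out <- table
  out$x <- out$x - dx[out$frame + 1L]
  out$y <- out$y - dy[out$frame + 1L]
  resid <- lapply(split(ft, ft$fiducial_id), function(tr) {
    cx <- tr$x - dx[tr$frame + 1L]; cy <- tr$y - dy[tr$frame + 1L]
    c((cx - mean(cx)), (cy - mean(cy)))
  })
  attr(out, "drift") <- tibble(frame = frames, dx = dx, dy = dy)
  attr(out, "fiducial_rms_nm") <- sqrt(mean(unlist(resid)^2))
  out
}

#' Link consecutive-frame localizations
#'
#' Localizations within `4 * sigma_nm` of each other in consecutive frames
#' (allowing a gap of up to `max_dark_frames` empty frames) are merged into
#' one record per emitter binding event: photon-weighted mean position,
#' summed photons, `frame` = first frame, with the bright length recorded
#' in `n_merged` and `frame_last`. Merging is transitive along chains
#' (union-find).
#'
#' @param table A [loc_table()].
#' @param sigma_nm Localization precision; merge radius is `4 * sigma_nm`.
#' @param max_dark_frames Maximum allowed dark gap inside one event.
#' @return A [loc_table()] of merged events.
#' @export
link_localizations <- function(table, sigma_nm, max_dark_frames = 1L) {
  stopifnot(sigma_nm > 0)
  if (nrow(table) == 0) return(table)
  g <- cpp_link_groups(table$x, table$y, table$frame,
                       4 * sigma_nm, as.integer(max_dark_frames))
  df <- as_tibble(table)
  df$.group <- g
  agg <- df |>
    dplyr::group_by(.data$.group) |>
    dplyr::summarise(
      x = stats::weighted.mean(.data$x, .data$photons),
      y = stats::weighted.mean(.data$y, .data$photons),
      frame_last = max(.data$frame),
      frame = min(.data$frame),
      n_merged = dplyr::n(),
      dplyr::across(dplyr::any_of(c("sx", "sy", "bg", "lpx", "lpy")), mean),
      dplyr::across(dplyr::any_of(c("kind", "target", "cell_id", "condition")),
                    dplyr::first),
      photons = sum(.data$photons),
      .groups = "drop") |>
    dplyr::select(-".group") |>
    dplyr::arrange(.data$frame, .data$x)
  loc_table(agg, acq = attr(table, "acq") %||% acq_metadata())
}

#' DBSCAN cluster isolation
#'
#' Standard DBSCAN on the (x, y) coordinates with radius `eps_nm`
#' (conventionally 1x the NeNA precision) and `min_locs` minimum
#' neighbourhood size (counting the point itself). Noise localizations are
#' excluded. Deterministic for a given row order.
#'
#' @param table A [loc_table()] (typically after [link_localizations()]).
#' @param eps_nm Neighbourhood radius in nm.
#' @param min_locs Minimum localizations per cluster (default 7).
#' @return A tibble with one row per cluster: `cluster_id`, `n_locs`,
#'   `center_x`, `center_y`, `mean_frame`, `radius_of_gyration_nm`,
#'   `convex_hull_area_nm2`, and `members` (list of row indices into
#'   `table`). The per-localization label vector (0 = noise) is attached as
#'   attribute `labels`.
#' @export
dbscan_clusters <- function(table, eps_nm, min_locs = 7L) {
  stopifnot(eps_nm > 0, min_locs >= 1)
  labels <- if (nrow(table) > 0)
    cpp_dbscan(table$x, table$y, eps_nm, as.integer(min_locs))
  else integer(0)
  keep <- labels > 0
  out <- if (any(keep)) {
    tibble(row = which(keep), cluster_id = labels[keep],
           x = table$x[keep], y = table$y[keep], frame = table$frame[keep]) |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarise(
        n_locs = dplyr::n(),
        center_x = mean(.data$x), center_y = mean(.data$y),
        mean_frame = mean(.data$frame),
        radius_of_gyration_nm = sqrt(mean((.data$x - mean(.data$x))^2 +
                                            (.data$y - mean(.data$y))^2)),
        convex_hull_area_nm2 = hull_area(.data$x, .data$y),
        members = list(.data$row),
        .groups = "drop")
  } else {
    tibble(cluster_id = integer(), n_locs = integer(),
           center_x = numeric(), center_y = numeric(), mean_frame = numeric(),
           radius_of_gyration_nm = numeric(), convex_hull_area_nm2 = numeric(),
           members = list())
  }
  attr(out, "labels") <- labels
  attr(out, "eps_nm") <- eps_nm
  attr(out, "min_locs") <- min_locs
  out
}

hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  shoelace_area(pts[h, , drop = FALSE])
}

#' Kinetic mean-frame filter
#'
#' Clusters whose localizations pile up early or late in the acquisition
#' (surface dirt, transient nonspecific binding) are rejected by their mean
#' frame index. In `"auto"` mode the population mean \eqn{\mu} and SD
#' \eqn{\sigma} of the cluster mean frames define the kept range
#' \eqn{[\mu - 2\sigma, \mu + 2\sigma]}; the `"paper"` preset keeps the
#' fixed range 1,500-8,000 frames; `"explicit"` uses `range_frames`.
#'
#' @param clusters Output of [dbscan_clusters()].
#' @param mode `"auto"`, `"paper"`, or `"explicit"`.
#' @param range_frames Length-2 kept range for `"explicit"` mode.
#' @return Kept clusters; rejected rows in attribute `rejected`, the kept
#'   range in attribute `range_frames`.
#' @export
kinetic_filter <- function(clusters, mode = c("auto", "paper", "explicit"),
                           range_frames = NULL) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    if (nrow(clusters) == 0)
      stop("auto kinetic filter needs at least one cluster", call. = FALSE)
    mu <- mean(clusters$mean_frame); sd <- stats::sd(clusters$mean_frame)
    if (is.na(sd)) sd <- 0
    rng <- c(mu - 2 * sd, mu + 2 * sd)
  } else if (mode == "paper") {
    rng <- c(1500, 8000)
  } else {
    if (is.null(range_frames) || length(range_frames) != 2)
      stop("explicit mode requires range_frames = c(lo, hi)", call. = FALSE)
    rng <- as.numeric(range_frames)
  }
  keep <- clusters$mean_frame >= rng[1] & clusters$mean_frame <= rng[2]
  out <- clusters[keep, ]
  attr(out, "rejected") <- clusters[!keep, ]
  attr(out, "range_frames") <- rng
  attr(out, "labels") <- attr(clusters, "labels")
  attr(out, "eps_nm") <- attr(clusters, "eps_nm")
  attr(out, "min_locs") <- attr(clusters, "min_locs")
  out
}
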