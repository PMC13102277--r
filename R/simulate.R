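# Kinetically realistic DNA-PAINT localization simulator.
#
# Each docking strand is an independent two-state renewal process:
# dark ~ Exp(rate xi), bright ~ Exp(rate 1/tau_b), with xi = k_on * c_i.
# Bright intervals are discretized to camera frames (one localization per
# covered frame), positions get isotropic Gaussian noise plus cumulative
# drift; nonspecific background and fiducials are added on top.

#' Simulation configuration
#'
#' Defines one simulated DNA-PAINT acquisition of one target in one cell.
#' Defaults describe a resting-state EGFR acquisition: cluster density
#' 7.8 per um^2, essentially monomeric receptors, 10.9 nm localization
#' precision, 20,000 frames at 100 ms with 2 nM imager. `k_on` and `tau_b`
#' are stated assumptions (association rate constants of DNA-PAINT imagers
#' are not part of the data model being emulated).
#'
#' @param mask A [cell_mask()] defining the cell area.
#' @param cluster_density_per_um2 Expected protein-cluster density.
#' @param oligomer_fractions Length-4 probability vector over copy numbers
#'   1..4 (monomer..tetramer); must sum to 1.
#' @param k_on_per_M_per_s Imager association rate constant.
#' @param imager_concentration_M Imager concentration \eqn{c_i}.
#' @param tau_b_s Mean bright (bound) time in seconds.
#' @param sigma_loc_nm True isotropic localization precision (SD, nm).
#'   The default `k_on` of 1e7 /M/s reflects speed-optimized docking
#'   sequences; with 2 nM imager it gives \eqn{\xi} = 0.02/s, i.e. a 50 s
#'   mean dark time and ~35 binding events per docking strand over a
#'   2,000 s acquisition — enough for both cluster detection (>= 7
#'   localizations) and dark-time statistics.
#' @param n_frames,exposure_s Acquisition length and frame time.
#' @param background_rate_per_um2_per_frame Nonspecific localization rate.
#' @param sticky_fraction Fraction of background emitters that persist for
#'   2-3 frames instead of 1 (gives kinetic filters something to reject).
#' @param drift_nm_per_frame Length-2 linear drift vector (nm per frame).
#' @param n_fiducials Number of fiducial markers (localized every frame).
#' @param cluster_radius_nm Docking strands of one oligomer are placed
#'   uniformly within this radius of the cluster center.
#' @param target,cell_id,condition Labels attached to the output table.
#' @param seed Integer seed; same seed reproduces the dataset exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mask = square_mask(10),
                       cluster_density_per_um2 = 7.8,
                       oligomer_fractions = c(0.95, 0.05, 0, 0),
                       k_on_per_M_per_s = 1e7,
                       imager_concentration_M = 2e-9,
                       tau_b_s = 0.5,
                       sigma_loc_nm = 10.9,
                       n_frames = 20000L,
                       exposure_s = 0.1,
                       background_rate_per_um2_per_frame = 1e-6,
                       sticky_fraction = 0.1,
                       drift_nm_per_frame = c(0, 0),
                       n_fiducials = 0L,
                       cluster_radius_nm = 10,
                       target = "EGFR", cell_id = "sim-1", condition = "resting",
                       seed = 1L) {
  stopifnot(cluster_density_per_um2 >= 0, all(oligomer_fractions >= 0),
            abs(sum(oligomer_fractions) - 1) < 1e-9, sigma_loc_nm >= 0,
            k_on_per_M_per_s >= 0, imager_concentration_M >= 0, tau_b_s > 0,
            n_frames > 0, exposure_s > 0,
            background_rate_per_um2_per_frame >= 0,
            length(drift_nm_per_frame) == 2)
  cfg <- as.list(environment())
  cfg$n_frames <- as.integer(n_frames)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Influx rate from a configuration
#' @param config A [sim_config()] (or any list with `k_on_per_M_per_s` and
#'   `imager_concentration_M`).
#' @return \eqn{\xi = k_{on} c_i} in 1/s.
#' @export
config_xi <- function(config) config$k_on_per_M_per_s * config$imager_concentration_M

#' Paper-style presets
#'
#' Returns a [sim_config()] for a named condition/target combination with
#' the reported cluster densities (EGFR: 7.8, 4.3, 3.4, 2.6 per um^2 for
#' resting and 1/5/15 min EGF) and precisions (EGFR 10.9 nm, Grb2 12.4 nm).
#' The Grb2 density (not reported numerically; unchanged across conditions)
#' is set to 5 per um^2.
#'
#' @param condition One of `"resting"`, `"EGF_1min"`, `"EGF_5min"`, `"EGF_15min"`.
#' @param target `"EGFR"` or `"Grb2"`.
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_preset <- function(condition = c("resting", "EGF_1min", "EGF_5min", "EGF_15min"),
                       target = c("EGFR", "Grb2"), ...) {
  condition <- match.arg(condition)
  target <- match.arg(target)
  dens <- list(EGFR = c(resting = 7.8, EGF_1min = 4.3, EGF_5min = 3.4, EGF_15min = 2.6),
               Grb2 = c(resting = 5.0, EGF_1min = 5.0, EGF_5min = 5.0, EGF_15min = 5.0))
  frac <- list(resting   = c(0.90, 0.10, 0.00, 0.00),
               EGF_1min  = c(0.75, 0.20, 0.05, 0.00),
               EGF_5min  = c(0.55, 0.30, 0.10, 0.05),
               EGF_15min = c(0.70, 0.20, 0.07, 0.03))
  sigma <- c(EGFR = 10.9, Grb2 = 12.4)
  defaults <- list(cluster_density_per_um2 = dens[[target]][[condition]],
                   oligomer_fractions = frac[[condition]],
                   sigma_loc_nm = sigma[[target]],
                   target = target, condition = condition)
  over <- list(...)
  do.call(sim_config, utils::modifyList(defaults, over))
}

#' Simulate bright-interval traces for independent docking sites
#'
#' Each site alternates exponentially distributed dark intervals
#' (mean \eqn{1/\xi}) and bright intervals (mean `tau_b_s`), starting dark.
#' Pooled over `n_sites`, the mean gap between successive binding events
#' approaches \eqn{1/(n_{sites}\,\xi)} — the generative counterpart of the
#' qPAINT relation \eqn{N = 1/(\tau_d \xi)}.
#'
#' @param n_sites Number of docking strands.
#' @param xi_per_s Influx rate \eqn{\xi} (1/s), must be > 0.
#' @param tau_b_s Mean bright time (s).
#' @param duration_s Trace duration (s), must be > 0.
#' @return List of length `n_sites`; each element a 2-column matrix of
#'   `(t_start_s, t_end_s)` bright intervals clipped to `[0, duration_s]`.
#' @export
simulate_site_trace <- function(n_sites, xi_per_s, tau_b_s, duration_s) {
  stopifnot(n_sites >= 1, xi_per_s > 0, tau_b_s > 0)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  lapply(seq_len(n_sites), function(s) {
    # draw cycles in blocks until past the acquisition window
    expected <- duration_s / (1 / xi_per_s + tau_b_s)
    block <- max(8L, ceiling(expected + 4 * sqrt(expected + 1)))
    starts <- numeric(0); ends <- numeric(0); t <- 0
    while (t < duration_s) {
      dark <- stats::rexp(block, rate = xi_per_s)
      bright <- stats::rexp(block, rate = 1 / tau_b_s)
      t0 <- t + cumsum(dark) + c(0, cumsum(bright))[seq_len(block)]
      t1 <- t0 + bright
      keep <- t0 < duration_s
      starts <- c(starts, t0[keep]); ends <- c(ends, pmin(t1[keep], duration_s))
      t <- t1[block]
    }
    cbind(t_start_s = starts, t_end_s = ends)
  })
}

# Union of possibly overlapping intervals (rows sorted by start on return).
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  o <- order(intervals[, 1])
  s <- intervals[o, 1]; e <- intervals[o, 2]
  ms <- s[1]; me <- e[1]; out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  cbind(t_start_s = c(out_s, ms), t_end_s = c(out_e, me))
}

#' Discretize bright intervals to camera frames
#'
#' A bright interval `[t0, t1)` produces one localization in every frame it
#' overlaps: frames `floor(t0/exposure)` through `ceiling(t1/exposure) - 1`,
#' clipped to `[0, n_frames - 1]`.
#'
#' @param intervals 2-column matrix of bright intervals (s).
#' @param exposure_s Frame time (s).
#' @param n_frames Number of frames.
#' @return Tibble with one row per event: `start_frame`, `end_frame`
#'   (inclusive), `n_frames_covered`.
#' @export
discretize_events <- function(intervals, exposure_s, n_frames) {
  if (is.null(dim(intervals))) intervals <- matrix(intervals, ncol = 2)
  if (nrow(intervals) == 0)
    return(tibble(start_frame = integer(), end_frame = integer(),
                  n_frames_covered = integer()))
  f0 <- pmax(0L, as.integer(floor(intervals[, 1] / exposure_s)))
  f1 <- pmin(n_frames - 1L, as.integer(ceiling(intervals[, 2] / exposure_s)) - 1L)
  keep <- f1 >= f0
  tibble(start_frame = f0[keep], end_frame = f1[keep],
         n_frames_covered = f1[keep] - f0[keep] + 1L)
}

# uniform points inside a mask polygon by rejection from the bounding box
runif_in_mask <- function(n, mask) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  poly <- mask$polygon_nm
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * 1.8) + 8
    px <- stats::runif(m, xr[1], xr[2]); py <- stats::runif(m, yr[1], yr[2])
    ok <- in_mask(px, py, mask)
    out <- rbind(out, cbind(px[ok], py[ok]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Simulate one DNA-PAINT acquisition
#'
#' Places clusters uniformly in the mask at the configured density, draws
#' each cluster's copy number from `oligomer_fractions`, simulates
#' per-docking-strand binding kinetics, discretizes to frames, and emits a
#' localization table with Gaussian position noise, linear drift,
#' nonspecific background, and fiducial markers. Seeded runs are exactly
#' reproducible.
#'
#' @param config A [sim_config()].
#' @return List with `ground_truth` (tibble: one row per cluster with true
#'   center, copy number, and event/localization counts), `sites` (one row
#'   per docking strand), `locs` (a [loc_table()]), `fiducials` (tibble of
#'   true fiducial positions), and `config`.
#' @export
simulate_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  expected <- config$cluster_density_per_um2 * config$mask$area_um2
  if (expected > 1e7)
    stop("expected cluster count ", round(expected),
         " exceeds 1e7; reduce density or mask area", call. = FALSE)
  set.seed(config$seed)
  duration_s <- config$n_frames * config$exposure_s
  xi <- config_xi(config)
  n_clusters <- stats::rpois(1, expected)
  centers <- runif_in_mask(n_clusters, config$mask)
  copy_n <- if (n_clusters > 0)
    sample.int(4L, n_clusters, replace = TRUE, prob = config$oligomer_fractions)
  else integer(0)

  # docking-strand positions within a disc around each center
  n_sites <- sum(copy_n)
  site_cluster <- rep(seq_len(n_clusters), copy_n)
  r <- config$cluster_radius_nm * sqrt(stats::runif(n_sites))
  th <- stats::runif(n_sites, 0, 2 * pi)
  site_x <- centers[site_cluster, 1] + r * cos(th)
  site_y <- centers[site_cluster, 2] + r * sin(th)

  traces <- if (n_sites > 0 && xi > 0)
    simulate_site_trace(n_sites, xi, config$tau_b_s, duration_s)
  else replicate(n_sites, cbind(t_start_s = numeric(0), t_end_s = numeric(0)),
                 simplify = FALSE)

  rows <- vector("list", n_sites)
  site_event_counts <- integer(n_sites)
  for (s in seq_len(n_sites)) {
    ev <- discretize_events(traces[[s]], config$exposure_s, config$n_frames)
    site_event_counts[s] <- nrow(ev)
    if (nrow(ev) == 0) next
    frames <- unlist(mapply(seq.int, ev$start_frame, ev$end_frame,
                            SIMPLIFY = FALSE), use.names = FALSE)
    rows[[s]] <- tibble(frame = as.integer(frames), x0 = site_x[s], y0 = site_y[s],
                        site_id = s, cluster_id = site_cluster[s], kind = "signal")
  }
  locs <- dplyr::bind_rows(rows)

  # nonspecific background: uniform Poisson field; a fraction persists 2-3 frames
  n_bg <- stats::rpois(1, config$background_rate_per_um2_per_frame *
                         config$mask$area_um2 * config$n_frames)
  if (n_bg > 0) {
    bp <- runif_in_mask(n_bg, config$mask)
    bf <- sample.int(config$n_frames, n_bg, replace = TRUE) - 1L
    span <- ifelse(stats::runif(n_bg) < config$sticky_fraction,
                   sample(2:3, n_bg, replace = TRUE), 1L)
    bg_rows <- tibble(frame = rep(bf, span),
                      x0 = rep(bp[, 1], span), y0 = rep(bp[, 2], span)) |>
      dplyr::mutate(frame = .data$frame +
                      unlist(lapply(span, seq_len), use.names = FALSE) - 1L) |>
      dplyr::filter(.data$frame < config$n_frames)
    bg_rows$site_id <- NA_integer_; bg_rows$cluster_id <- NA_integer_
    bg_rows$kind <- "background"
    locs <- dplyr::bind_rows(locs, bg_rows)
  }

  fid <- NULL
  if (config$n_fiducials > 0) {
    fp <- runif_in_mask(config$n_fiducials, config$mask)
    fid <- tibble(fiducial_id = seq_len(config$n_fiducials),
                  x = fp[, 1], y = fp[, 2])
    fid_rows <- tibble(frame = rep(0:(config$n_frames - 1L), config$n_fiducials),
                       x0 = rep(fp[, 1], each = config$n_frames),
                       y0 = rep(fp[, 2], each = config$n_frames),
                       site_id = NA_integer_, cluster_id = NA_integer_,
                       kind = rep(paste0("fiducial_", seq_len(config$n_fiducials)),
                                  each = config$n_frames))
    locs <- dplyr::bind_rows(locs, fid_rows)
  }

  if (nrow(locs) == 0)
    locs <- tibble(frame = integer(), x0 = numeric(), y0 = numeric(),
                   site_id = integer(), cluster_id = integer(), kind = character())

  # localization noise (fiducials localize ~10x more precisely), drift, photometry
  sig <- ifelse(startsWith(locs$kind %||% character(0), "fiducial"),
                config$sigma_loc_nm / 10, config$sigma_loc_nm)
  n <- nrow(locs)
  locs$x <- locs$x0 + stats::rnorm(n, 0, sig) + locs$frame * config$drift_nm_per_frame[1]
  locs$y <- locs$y0 + stats::rnorm(n, 0, sig) + locs$frame * config$drift_nm_per_frame[2]
  locs$photons <- stats::rlnorm(n, log(1000), 0.3)
  locs$sx <- stats::rnorm(n, 150, 10); locs$sy <- stats::rnorm(n, 150, 10)
  locs$bg <- stats::rlnorm(n, log(50), 0.2)
  locs$lpx <- rep(config$sigma_loc_nm, n); locs$lpy <- rep(config$sigma_loc_nm, n)
  locs <- dplyr::arrange(locs, .data$frame)

  acq <- acq_metadata(n_frames = config$n_frames, exposure_s = config$exposure_s,
                      imager_concentration_M = config$imager_concentration_M,
                      target_name = config$target)
  table <- loc_table(locs[, c("frame", "x", "y", "photons", "sx", "sy", "bg",
                              "lpx", "lpy", "kind")],
                     acq = acq, target = config$target,
                     cell_id = config$cell_id, condition = config$condition)

  gt <- tibble(cluster_id = seq_len(n_clusters),
               x = centers[, 1] %||% numeric(0), y = centers[, 2] %||% numeric(0),
               n_docking_strands = copy_n)
  if (n_clusters > 0) {
    per_cluster_events <- tapply(site_event_counts, site_cluster, sum)
    gt$n_events <- as.integer(per_cluster_events[as.character(gt$cluster_id)] %||% 0L)
    gt$n_events[is.na(gt$n_events)] <- 0L
  } else gt$n_events <- integer(0)

  sites <- tibble(site_id = seq_len(n_sites), cluster_id = site_cluster,
                  x = site_x, y = site_y, n_events = site_event_counts)

  list(ground_truth = gt, sites = sites, locs = table,
       fiducials = fid, config = config)
}

#' Apply linear drift to a localization table
#'
#' Shifts every localization by `frame * drift_nm_per_frame`; exactly
#' invertible by applying the negated vector.
#'
#' @param table A [loc_table()].
#' @param drift_nm_per_frame Length-2 drift vector (nm/frame).
#' @return The shifted table.
#' @export
apply_drift <- function(table, drift_nm_per_frame) {
  stopifnot(length(drift_nm_per_frame) == 2)
  table$x <- table$x + table$frame * drift_nm_per_frame[1]
  table$y <- table$y + table$frame * drift_nm_per_frame[2]
  table
}
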