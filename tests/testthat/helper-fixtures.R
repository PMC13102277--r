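# Programmatic fixtures shared across test files.

# localization table of immobile emitters re-localized in every frame with
# isotropic Gaussian error
make_immobile_table <- function(n_emitters = 20, n_frames = 1000,
                                sigma_nm = 10.9, field_nm = 10000,
                                seed = 1) {
  set.seed(seed)
  pos <- cbind(stats::runif(n_emitters, 0, field_nm),
               stats::runif(n_emitters, 0, field_nm))
  n <- n_emitters * n_frames
  loc_table(data.frame(
    frame = rep(0:(n_frames - 1L), each = n_emitters),
    x = rep(pos[, 1], n_frames) + stats::rnorm(n, 0, sigma_nm),
    y = rep(pos[, 2], n_frames) + stats::rnorm(n, 0, sigma_nm),
    photons = 1000), acq = acq_metadata(n_frames = n_frames))
}

# minimal cluster tibble with given centers
fake_clusters <- function(x, y) {
  tibble::tibble(cluster_id = seq_along(x), n_locs = 10L, center_x = x,
                 center_y = y, mean_frame = 5000,
                 radius_of_gyration_nm = 5, convex_hull_area_nm2 = 100,
                 members = replicate(length(x), integer(0), simplify = FALSE))
}

# per-cluster 1/tau_d values from trace-level simulation at the given copy
# numbers (vector, one entry per cluster)
sim_inv_tau <- function(copy_numbers, xi = 0.02, tau_b = 0.5,
                        duration = 2000, exposure = 0.1) {
  n_frames <- round(duration / exposure)
  vapply(copy_numbers, function(cn) {
    tr <- simulate_site_trace(cn, xi, tau_b, duration)
    iv <- paintquant:::merge_intervals(do.call(rbind, tr))
    ev <- discretize_events(iv, exposure, n_frames)
    if (nrow(ev) < 4) return(NA_real_)
    # merge events touching at frame resolution, then frame-gap dark times
    o <- order(ev$start_frame)
    s <- ev$start_frame[o]; e <- ev$end_frame[o]
    ms <- s[1]; me <- e[1]; dark <- numeric(0)
    for (j in seq_along(s)[-1]) {
      if (s[j] <= me + 1L) me <- max(me, e[j])
      else { dark <- c(dark, (s[j] - me - 1L) * exposure); ms <- s[j]; me <- e[j] }
    }
    if (length(dark) < 3) return(NA_real_)
    1 / mean(dark)
  }, numeric(1))
}
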