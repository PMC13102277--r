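test_that("NeNA recovers the true precision of immobile emitters", {
  t <- make_immobile_table(n_emitters = 10, n_frames = 5000, sigma_nm = 10.9,
                           seed = 11)
  f <- nena_precision(t)
  expect_s3_class(f, "nena_fit")
  expect_equal(f$sigma_nena_nm, 10.9, tolerance = 0.5 / 10.9)
  expect_false(f$flagged)
  expect_gt(f$n_pairs, 1000)
})

test_that("NeNA degenerates gracefully in the noiseless limit", {
  t <- make_immobile_table(n_emitters = 10, n_frames = 500, sigma_nm = 0,
                           seed = 2)
  f <- nena_precision(t)
  expect_lt(f$sigma_nena_nm, 0.5)
})

test_that("NeNA histogram fit matches a brute-force ML oracle on pure signal", {
  t <- make_immobile_table(n_emitters = 15, n_frames = 3000, sigma_nm = 12.4,
                           seed = 5)
  f <- nena_precision(t)
  # oracle: grid-search MLE of sigma on the same nearest-neighbour distances,
  # collected independently of the fit path
  idx <- split(seq_len(nrow(t)), t$frame)
  frames <- as.integer(names(idx))
  d <- unlist(lapply(seq_along(frames)[-length(frames)], function(k) {
    a <- idx[[k]]; b <- idx[[k + 1]]
    brute_nn(t$x[a], t$y[a], t$x[b], t$y[b])
  }))
  d <- d[d <= 200]
  grid <- seq(8, 18, by = 0.01)
  ll <- vapply(grid, function(s)
    sum(log(d / (2 * s^2)) - d^2 / (4 * s^2)), numeric(1))
  sigma_ml <- grid[which.max(ll)]
  expect_equal(f$sigma_nena_nm, sigma_ml, tolerance = 0.02)
  expect_equal(sigma_ml, 12.4, tolerance = 0.03)
})

test_that("NeNA tolerates a uniform background population", {
  t <- make_immobile_table(n_emitters = 12, n_frames = 2000, sigma_nm = 12.4,
                           field_nm = 5000, seed = 6)
  set.seed(7)
  n_bg <- 4000
  bg <- data.frame(frame = sample(0:1999, n_bg, TRUE),
                   x = runif(n_bg, 0, 5000), y = runif(n_bg, 0, 5000),
                   photons = 500)
  both <- loc_table(rbind(as.data.frame(t)[c("frame", "x", "y", "photons")], bg))
  f <- nena_precision(both)
  expect_equal(f$sigma_nena_nm, 12.4, tolerance = 0.15)
})

test_that("NeNA median bias is at most 5% across the 5-20 nm range", {
  for (sig in c(5, 10, 20)) {
    est <- vapply(1:5, function(s)
      nena_precision(make_immobile_table(n_emitters = 15, n_frames = 800,
                                         sigma_nm = sig, seed = 100 + s)
                     )$sigma_nena_nm, numeric(1))
    expect_lt(abs(median(est) - sig) / sig, 0.05, label = paste("sigma", sig))
  }
})

test_that("too few pairs falls back to per-localization precision or errors", {
  df <- data.frame(frame = c(0L, 1L), x = c(0, 5), y = c(0, 0), photons = 1,
                   lpx = 9, lpy = 11)
  f <- nena_precision(loc_table(df))
  expect_true(f$flagged)
  expect_equal(f$sigma_nena_nm, 10)
  df2 <- df[, setdiff(names(df), c("lpx", "lpy"))]
  expect_error(nena_precision(loc_table(df2)), "pairs")
})

test_that("fiducial drift correction inverts simulator drift", {
  set.seed(21)
  n_frames <- 2000
  drift <- c(0.05, 0.02)
  frames <- 0:(n_frames - 1)
  fid <- purrr::map_dfr(1:3, function(k)
    tibble::tibble(fiducial_id = paste0("f", k), frame = frames,
                   x = 1000 * k + frames * drift[1] + rnorm(n_frames, 0, 1),
                   y = 2000 * k + frames * drift[2] + rnorm(n_frames, 0, 1)))
  t0 <- make_immobile_table(n_emitters = 5, n_frames = n_frames, sigma_nm = 5,
                            seed = 3)
  t_drift <- apply_drift(t0, drift)
  corr <- correct_drift(t_drift, fid)
  expect_lt(attr(corr, "fiducial_rms_nm"), 2)
  # corrected positions recover the undrifted ones up to the fiducial noise
  expect_lt(sqrt(mean((corr$x - t0$x)^2)), 2)
})

test_that("drift correction is near-identity for zero drift", {
  set.seed(22)
  frames <- 0:999
  fid <- tibble::tibble(fiducial_id = "f1", frame = frames,
                        x = 500 + rnorm(1000, 0, 0.3),
                        y = 500 + rnorm(1000, 0, 0.3))
  t0 <- make_immobile_table(n_emitters = 4, n_frames = 1000, seed = 4)
  corr <- correct_drift(t0, fid)
  expect_lt(max(abs(corr$x - t0$x)), 0.5)
  drift <- attr(corr, "drift")
  expect_equal(nrow(drift), 1000)
  expect_true(all(is.finite(drift$dx)))
})

test_that("drift correction demands fiducials with sufficient coverage", {
  t0 <- make_immobile_table(n_emitters = 2, n_frames = 100, seed = 5)
  expect_error(correct_drift(t0, NULL), "no fiducial")
  sparse <- tibble::tibble(fiducial_id = "f1", frame = 0:10, x = 1, y = 1)
  expect_error(correct_drift(t0, sparse), "90%")
})

test_that("linking merges within-radius consecutive frames, with 1-frame gaps", {
  df <- data.frame(frame = c(10L, 11L), x = c(100, 100), y = c(50, 50),
                   photons = c(200, 300))
  m <- link_localizations(loc_table(df), sigma_nm = 5)
  expect_equal(nrow(m), 1)
  expect_equal(m$photons, 500)
  expect_equal(m$frame, 10L)
  expect_equal(m$frame_last, 11L)
  expect_equal(m$x, 100)

  gap1 <- loc_table(data.frame(frame = c(10L, 12L), x = c(0, 1), y = c(0, 0),
                               photons = 1))
  expect_equal(nrow(link_localizations(gap1, 5)), 1)
  gap2 <- loc_table(data.frame(frame = c(10L, 13L), x = c(0, 1), y = c(0, 0),
                               photons = 1))
  expect_equal(nrow(link_localizations(gap2, 5)), 2)
})

test_that("linking equals union-find over the brute-force pair graph", {
  set.seed(33)
  n <- 400
  df <- data.frame(frame = sample(0:80, n, TRUE),
                   x = runif(n, 0, 800), y = runif(n, 0, 800),
                   photons = runif(n, 1, 10))
  t <- loc_table(df)
  merged <- link_localizations(t, sigma_nm = 10, max_dark_frames = 1)
  comp <- brute_link_components(df$x, df$y, df$frame, 40, 1)
  expect_equal(nrow(merged), length(unique(comp)))
  # conservation laws
  expect_lte(nrow(merged), nrow(t))
  expect_equal(sum(merged$photons), sum(t$photons))
})

test_that("DBSCAN honors the minimum-localization contract", {
  co7 <- loc_table(data.frame(frame = 0:6, x = 100, y = 100, photons = 1))
  cl <- dbscan_clusters(co7, eps_nm = 10, min_locs = 7)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_locs, 7L)
  co6 <- loc_table(data.frame(frame = 0:5, x = 100, y = 100, photons = 1))
  expect_equal(nrow(dbscan_clusters(co6, 10, 7)), 0)
})

test_that("DBSCAN membership matches the brute-force reference", {
  set.seed(44)
  centers <- cbind(runif(12, 0, 2000), runif(12, 0, 2000))
  pts <- do.call(rbind, lapply(seq_len(12), function(i)
    cbind(rnorm(30, centers[i, 1], 8), rnorm(30, centers[i, 2], 8))))
  pts <- rbind(pts, cbind(runif(140, 0, 2000), runif(140, 0, 2000)))
  t <- loc_table(data.frame(frame = seq_len(nrow(pts)) - 1L, x = pts[, 1],
                            y = pts[, 2], photons = 1))
  cl <- dbscan_clusters(t, eps_nm = 12, min_locs = 7)
  ref <- brute_dbscan(pts[, 1], pts[, 2], 12, 7)
  expect_identical(partition_sets(attr(cl, "labels")), partition_sets(ref))
})

test_that("DBSCAN membership is invariant under row permutation", {
  set.seed(45)
  pts <- rbind(cbind(rnorm(40, 200, 8), rnorm(40, 200, 8)),
               cbind(rnorm(40, 600, 8), rnorm(40, 600, 8)),
               cbind(runif(60, 0, 800), runif(60, 0, 800)))
  t1 <- loc_table(data.frame(frame = 0L, x = pts[, 1], y = pts[, 2], photons = 1))
  perm <- sample(nrow(pts))
  t2 <- loc_table(data.frame(frame = 0L, x = pts[perm, 1], y = pts[perm, 2],
                             photons = 1))
  l1 <- attr(dbscan_clusters(t1, 12, 7), "labels")
  l2 <- attr(dbscan_clusters(t2, 12, 7), "labels")
  s1 <- partition_sets(l1)
  s2 <- lapply(partition_sets(l2), function(s) sort(perm[s]))
  s2 <- s2[order(vapply(s2, min, integer(1)))]
  expect_identical(s1, s2)
})

test_that("cluster recovery on clean simulations is near-complete and accurate", {
  cfg <- sim_config(mask = square_mask(5), background_rate_per_um2_per_frame = 0,
                    seed = 55)
  sim <- simulate_cell(cfg)
  linked <- link_localizations(sim$locs, cfg$sigma_loc_nm)
  cl <- dbscan_clusters(linked, cfg$sigma_loc_nm, 7)
  gt <- sim$ground_truth
  d <- nn_distances(gt, cl, mode = "cross")
  tol <- 2 * cfg$sigma_loc_nm / sqrt(7)
  expect_gte(mean(d < tol + cfg$cluster_radius_nm), 0.95)
})

test_that("kinetic filter rejects early-frame clusters and keeps steady blinkers", {
  early <- tibble::tibble(cluster_id = 1L, n_locs = 10L, center_x = 0,
                          center_y = 0, mean_frame = 25,
                          radius_of_gyration_nm = 5, convex_hull_area_nm2 = 10,
                          members = list(1:10))
  kept <- kinetic_filter(early, mode = "explicit", range_frames = c(1500, 8000))
  expect_equal(nrow(kept), 0)
  expect_equal(nrow(attr(kept, "rejected")), 1)

  mid <- dplyr::mutate(early, mean_frame = 10000)
  expect_equal(nrow(kinetic_filter(mid, "explicit",
                                   range_frames = c(1500, 8000))), 0)
  expect_equal(nrow(kinetic_filter(mid, "paper")), 0)
  ok <- dplyr::mutate(early, mean_frame = 5000)
  expect_equal(nrow(kinetic_filter(ok, "paper")), 1)
  expect_error(kinetic_filter(ok, "explicit"), "range_frames")
})

test_that("auto mode keeps the 2-sigma fraction of Gaussian mean frames", {
  set.seed(66)
  cl <- tibble::tibble(cluster_id = 1:10000, n_locs = 10L, center_x = 0,
                       center_y = 0, mean_frame = rnorm(10000, 10000, 2000),
                       radius_of_gyration_nm = 5, convex_hull_area_nm2 = 10,
                       members = replicate(10000, integer(0), simplify = FALSE))
  kept <- kinetic_filter(cl, "auto")
  expect_equal(nrow(kept) / 10000, 0.954, tolerance = 0.01 / 0.954)
})

test_that("explicit kinetic filtering is idempotent", {
  set.seed(67)
  cl <- tibble::tibble(cluster_id = 1:100, n_locs = 10L, center_x = 0,
                       center_y = 0, mean_frame = runif(100, 0, 20000),
                       radius_of_gyration_nm = 5, convex_hull_area_nm2 = 10,
                       members = replicate(100, integer(0), simplify = FALSE))
  k1 <- kinetic_filter(cl, "explicit", range_frames = c(1500, 8000))
  k2 <- kinetic_filter(k1, "explicit", range_frames = c(1500, 8000))
  expect_identical(k2$cluster_id, k1$cluster_id)
  expect_identical(k2$mean_frame, k1$mean_frame)
  expect_equal(nrow(attr(k2, "rejected")), 0)
})
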