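test_that("densities are exact counts over the mask area", {
  mask <- square_mask(10)  # 100 um^2
  set.seed(1)
  cl <- fake_clusters(runif(780, 0, 10000), runif(780, 0, 10000))
  t <- loc_table(data.frame(frame = 0L, x = runif(50, 0, 10000),
                            y = runif(50, 0, 10000), photons = 1),
                 cell_id = "c1", condition = "resting", target = "EGFR")
  d <- densities(cl, t, mask)
  expect_equal(d$clusters_per_um2, 7.8)
  expect_equal(d$locs_per_um2, 0.5)
  expect_equal(d$mask_area_um2, 100)
})

test_that("clusters outside the mask are excluded and logged", {
  mask <- square_mask(1)
  cl <- fake_clusters(c(500, 5000), c(500, 5000))
  t <- loc_table(data.frame(frame = 0L, x = 500, y = 500, photons = 1))
  d <- densities(cl, t, mask)
  expect_equal(d$n_clusters, 1L)
  expect_equal(nrow(attr(d, "excluded")), 1)
  empty <- densities(fake_clusters(numeric(0), numeric(0)), t, mask)
  expect_equal(empty$clusters_per_um2, 0)
})

test_that("nearest-neighbour distances match hand values and brute force", {
  a <- cbind(c(0, 0), c(0, 30))
  expect_equal(nn_distances(a, mode = "self"), c(30, 30))
  expect_equal(nn_distances(a, a, mode = "cross"), c(0, 0))
  expect_error(nn_distances(a, cbind(numeric(0), numeric(0)), "cross"), "empty")
  set.seed(2)
  p <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  q <- cbind(runif(150, 0, 1000), runif(150, 0, 1000))
  expect_equal(nn_distances(p, q, mode = "cross"),
               brute_nn(p[, 1], p[, 2], q[, 1], q[, 2]))
  expect_equal(nn_distances(p, mode = "self"),
               brute_nn(p[, 1], p[, 2], p[, 1], p[, 2], self = TRUE))
})

test_that("cumulative profiles handle empty and single-point cases", {
  ctr <- fake_clusters(0, 0)
  none <- cumulative_profile(ctr, data.frame(x = numeric(0), y = numeric(0)))
  expect_true(all(none$mean_count == 0))
  expect_equal(attr(none, "auc"), 0)

  one <- cumulative_profile(ctr, data.frame(x = 55, y = 0))
  expect_equal(one$mean_count[one$edge_nm < 55], rep(0, 6))
  expect_equal(one$mean_count[one$edge_nm >= 55], rep(1, 10))
  # trapezoid: half bin at the step, then full bins to 150
  expect_equal(attr(one, "auc"), 95)
  expect_error(cumulative_profile(fake_clusters(numeric(0), numeric(0)),
                                  data.frame(x = 1, y = 1)), "at least one")
})

test_that("CSR profiles follow the rho*pi*r^2 closed form", {
  set.seed(3)
  n <- 1e5; side <- 4000
  b <- data.frame(x = runif(n, 0, side), y = runif(n, 0, side))
  ctr <- fake_clusters(runif(100, 200, side - 200), runif(100, 200, side - 200))
  pr <- cumulative_profile(ctr, b)
  rho <- n / side^2
  expected <- rho * pi * pr$edge_nm^2
  big <- pr$edge_nm >= 50  # skip near-zero-count bins
  expect_lt(max(abs(pr$mean_count[big] - expected[big]) / expected[big]), 0.05)
  # monotone non-decreasing
  expect_true(all(diff(pr$mean_count) >= 0))
})

test_that("profiles and AUC are invariant under rigid translation", {
  set.seed(4)
  ctr <- fake_clusters(runif(10, 0, 1000), runif(10, 0, 1000))
  b <- data.frame(x = runif(500, 0, 1000), y = runif(500, 0, 1000))
  p1 <- cumulative_profile(ctr, b)
  ctr2 <- fake_clusters(ctr$center_x + 500, ctr$center_y + 500)
  b2 <- data.frame(x = b$x + 500, y = b$y + 500)
  p2 <- cumulative_profile(ctr2, b2)
  expect_equal(p2$mean_count, p1$mean_count)
  expect_equal(attr(p2, "auc"), attr(p1, "auc"))
})

test_that("AUC comparison flags enrichment and not identical sets", {
  set.seed(5)
  make_cell <- function(enriched) {
    ctr <- fake_clusters(runif(20, 200, 1800), runif(20, 200, 1800))
    b <- data.frame(x = runif(400, 0, 2000), y = runif(400, 0, 2000))
    if (enriched) {
      k <- sample(20, 200, TRUE)
      th <- runif(200, 0, 2 * pi); r <- 50 * sqrt(runif(200))
      b <- rbind(b, data.frame(x = ctr$center_x[k] + r * cos(th),
                               y = ctr$center_y[k] + r * sin(th)))
    }
    cumulative_profile(ctr, b)
  }
  profs <- c(lapply(1:10, function(i) make_cell(FALSE)),
             lapply(1:10, function(i) make_cell(TRUE)))
  names(profs) <- sprintf("cell%02d", 1:20)
  agg <- aggregate_profiles(profs, rep(c("resting", "EGF_1min"), each = 10))
  res <- compare_auc(agg$auc, reference = "resting")
  stim <- res[res$condition == "EGF_1min", ]
  expect_gt(stim$auc_ratio, 1)
  expect_lt(stim$p_value, 0.05)

  # identical cell sets report no difference
  aucs <- vapply(profs[1:6], function(p) attr(p, "auc"), numeric(1))
  same <- tibble::tibble(cell_id = as.character(1:12),
                         condition = rep(c("a", "b"), each = 6),
                         auc = rep(unname(aucs), 2))
  r2 <- compare_auc(same, reference = "a")
  expect_equal(r2$p_value[r2$condition == "b"], 1, tolerance = 0.01)
})

test_that("too-few-cell conditions are skipped with a notice", {
  auc <- tibble::tibble(cell_id = c("a", "b", "c"),
                        condition = c("resting", "resting", "stim"),
                        auc = c(1, 2, 3))
  res <- compare_auc(auc)
  expect_match(res$note[res$condition == "stim"], "skipped")
})

test_that("density tests match exact enumeration and label conventions", {
  d <- tibble::tibble(condition = rep(c("a", "b"), each = 3),
                      clusters_per_um2 = c(1, 2, 3, 10, 11, 12))
  res <- density_test(d)
  expect_equal(res$p_value, enum_mw_p(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$label, "n.s.")

  same <- tibble::tibble(condition = rep(c("a", "b"), each = 4),
                         clusters_per_um2 = rep(c(1, 2, 3, 4), 2))
  expect_equal(density_test(same)$p_value, 1, tolerance = 0.01)

  expect_equal(signif_label(c(0.049, 0.051, 0.009, 0.0009, NA)),
               c("*", "n.s.", "**", "***", NA))
})
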