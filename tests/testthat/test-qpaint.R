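make_clusters_for <- function(n_members) {
  tibble::tibble(cluster_id = 1L, n_locs = n_members, center_x = 0, center_y = 0,
                 mean_frame = 0, radius_of_gyration_nm = 1,
                 convex_hull_area_nm2 = 1, members = list(seq_len(n_members)))
}

test_that("dark and bright times follow the event frame arithmetic", {
  linked <- loc_table(data.frame(frame = c(10L, 20L, 40L),
                                 x = 0, y = 0, photons = 1))
  linked$frame_last <- c(12L, 21L, 45L)
  kin <- extract_kinetics(make_clusters_for(3), linked, exposure_s = 0.1)
  expect_equal(kin$dark_times_s[[1]], c(0.7, 1.8))
  expect_equal(kin$bright_times_s[[1]], c(0.3, 0.2, 0.6))
  expect_equal(kin$tau_d_s, 1.25)
  expect_true(kin$flagged)  # only 2 dark times -> excluded from mixtures
})

test_that("single-event clusters are flagged with no dark times", {
  linked <- loc_table(data.frame(frame = 5L, x = 0, y = 0, photons = 1))
  linked$frame_last <- 8L
  kin <- extract_kinetics(make_clusters_for(1), linked, 0.1)
  expect_equal(length(kin$dark_times_s[[1]]), 0)
  expect_true(kin$flagged)
})

test_that("time-overlapping events from different strands merge before gaps", {
  linked <- loc_table(data.frame(frame = c(10L, 11L, 30L), x = 0, y = 0,
                                 photons = 1))
  linked$frame_last <- c(14L, 12L, 31L)
  kin <- extract_kinetics(make_clusters_for(3), linked, 0.1)
  expect_equal(kin$n_events, 2L)
  expect_equal(kin$dark_times_s[[1]], 1.5)
})

test_that("tau_d estimators agree with closed forms and each other", {
  expect_equal(estimate_tau_d(c(1, 2, 3)), 2)
  set.seed(8)
  d <- rexp(10000, 1 / 100)
  expect_equal(estimate_tau_d(d), 100, tolerance = 0.02)
  expect_equal(estimate_tau_d(d, method = "cdf"), 100, tolerance = 0.1)
  expect_error(estimate_tau_d(c(1, 2)), "at least 3")
})

test_that("qPAINT counting formula and its guards", {
  expect_equal(molecules_per_cluster(500, 2e-3), 1)
  expect_equal(molecules_per_cluster(250, 2e-3), 2)
  expect_equal(molecules_per_cluster(50, influx_rate(xi_per_s = 0.02)), 1)
  expect_error(molecules_per_cluster(-1, 2e-3), "positive")
  expect_error(molecules_per_cluster(500, 0), "positive")
})

test_that("surface-trace calibration recovers the true influx rate", {
  set.seed(9)
  xi_true <- 2e-3
  taus <- vapply(1:50, function(i) mean(rexp(20, xi_true)), numeric(1))
  cal <- calibrate_influx(taus)
  expect_s3_class(cal, "influx_rate")
  expect_equal(cal$source, "calibration")
  expect_equal(cal$xi_per_s, xi_true, tolerance = 0.1)
  # self-consistency: counting the same population back gives N ~ 1
  expect_equal(median(molecules_per_cluster(taus, cal)), 1, tolerance = 0.1)
  expect_warning(cal1 <- calibrate_influx(500), "only 1")
  expect_equal(cal1$xi_per_s, 2e-3)
})

test_that("a pure monomer population fits as >= 95% monomer", {
  set.seed(10)
  x <- rnorm(2000, 0.02, 0.003)
  fit <- fit_oligomer_mixture(x, mu1 = 0.02)
  expect_gte(fit$fractions[1], 0.95)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-6)
})

test_that("a 70/30 monomer/dimer mixture is decomposed within 0.05", {
  set.seed(11)
  mu1 <- 0.02
  x <- c(rnorm(3500, mu1, 0.15 * mu1), rnorm(1500, 2 * mu1, 0.15 * mu1))
  fit <- fit_oligomer_mixture(x, mu1 = mu1)
  expect_equal(fit$fractions[1], 0.70, tolerance = 0.05 / 0.70)
  expect_equal(fit$fractions[2], 0.30, tolerance = 0.05 / 0.30)
  expect_lt(fit$fractions[3] + fit$fractions[4], 0.05)
})

test_that("dimer fraction rises monotonically with dimer doping", {
  set.seed(12)
  mu1 <- 0.02
  dimer_frac <- c(0.05, 0.2, 0.35)
  fitted <- vapply(dimer_frac, function(fr) {
    n <- 3000
    x <- c(rnorm(round((1 - fr) * n), mu1, 0.15 * mu1),
           rnorm(round(fr * n), 2 * mu1, 0.15 * mu1))
    fit_oligomer_mixture(x, mu1 = mu1)$fractions[2]
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("mixture fractions are stable across a factor-2 bin-width range", {
  set.seed(13)
  mu1 <- 0.02
  x <- c(rnorm(2000, mu1, 0.15 * mu1), rnorm(1000, 2 * mu1, 0.15 * mu1))
  bw0 <- paintquant:::fd_bin_width(x)
  f <- lapply(c(0.5, 1, 2), function(m)
    fit_oligomer_mixture(x, mu1 = mu1, bin_width = m * bw0)$fractions)
  expect_lt(max(abs(f[[1]] - f[[2]])), 0.05)
  expect_lt(max(abs(f[[3]] - f[[2]])), 0.05)
})

test_that("the monomer peak can be located from the data alone", {
  set.seed(14)
  mu1 <- 0.02
  x <- c(rnorm(3000, mu1, 0.15 * mu1), rnorm(600, 2 * mu1, 0.15 * mu1))
  fit <- fit_oligomer_mixture(x)
  expect_equal(fit$mu1_source, "fitted")
  expect_equal(fit$mu1, mu1, tolerance = 0.05)
})

test_that("z-scores and p-values follow the normal-CDF oracle", {
  mk <- function(frac, sd) tibble::tibble(state = 1:4, fraction = frac, sd = sd)
  rest <- mk(c(0.6, 0.3, 0.1, 0.0), 0.05)
  stim <- mk(c(0.4, 0.5, 0.1, 0.0), 0.05)
  cmp <- compare_oligomer_areas(rest, stim)
  expect_equal(cmp$z[1], -0.2 / sqrt(0.005), tolerance = 1e-9)
  expect_equal(cmp$z[2], 2.828, tolerance = 1e-3)
  expect_equal(cmp$p_two_sided[2], 2 * (1 - pnorm(0.2 / sqrt(0.005))),
               tolerance = 1e-12)
  expect_equal(cmp$p_two_sided[2], 0.00468, tolerance = 1e-3)
  # identical conditions: z = 0, p = 1
  same <- compare_oligomer_areas(rest, rest)
  expect_true(all(same$z == 0))
  expect_true(all(same$p_two_sided == 1))
  # antisymmetry: swapping conditions negates z, p unchanged
  rev <- compare_oligomer_areas(stim, rest)
  expect_equal(rev$z, -cmp$z)
  expect_equal(rev$p_two_sided, cmp$p_two_sided)
  # degenerate SD reported as undefined
  z0 <- compare_oligomer_areas(mk(c(1, 0, 0, 0), 0), mk(c(0.9, 0.1, 0, 0), 0))
  expect_true(all(is.na(z0$z)))
})

test_that("jackknife SEs shrink with cell count and carry the pooled fit", {
  set.seed(15)
  mu1 <- 0.02
  cells <- lapply(1:8, function(i) rnorm(150, mu1, 0.15 * mu1))
  jk <- mixture_jackknife(cells, mu1 = mu1)
  expect_equal(nrow(jk), 4)
  expect_true(all(jk$sd[1] >= 0))
  expect_s3_class(attr(jk, "fit"), "mixture_fit")
  expect_gte(jk$fraction[1], 0.9)
})

test_that("1/tau_d scales linearly with copy number (regression slope ~ xi)", {
  set.seed(16)
  xi <- 0.02
  means <- vapply(1:3, function(cn)
    mean(sim_inv_tau(rep(cn, 120), xi = xi), na.rm = TRUE), numeric(1))
  slope <- coef(lm(means ~ I(1:3)))[2]
  expect_equal(unname(slope), xi, tolerance = 0.1)
})
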