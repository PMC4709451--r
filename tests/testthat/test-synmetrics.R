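test_that("line profiles: binning, flat field, rotation equivariance", {
  roi <- line_roi(c(0, 0), c(1, 0), length_nm = 100, width_nm = 300)

  one <- loc_table(37, 10, intensity = 5, channel = 1)
  one <- rbind(one, loc_table(37, 10, intensity = 5, channel = 2))
  prof <- extract_line_profiles(one, roi)
  expect_equal(prof[[1]]$centers_nm, seq(5, 95, by = 10))
  expect_equal(which(prof[[1]]$values > 0), 4L)   # bin [30, 40)
  expect_equal(sum(prof[[1]]$values) * 300, 5)    # width-normalized

  # uniform field aligned to the bin grid -> exactly flat profile
  gx <- rep(seq(0.5, 99.5, by = 1), times = 21)
  gy <- rep(seq(-100, 100, by = 10), each = 100)
  unif <- rbind(loc_table(gx, gy, intensity = 1, channel = 1),
                loc_table(gx, gy, intensity = 1, channel = 2))
  pf <- extract_line_profiles(unif, roi)
  expect_lt(diff(range(pf[[1]]$values)), 1e-9)

  # rotating data and ROI together leaves the profile unchanged
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  set.seed(7)
  pts <- loc_table(runif(400, 0, 100), runif(400, -140, 140),
                   intensity = runif(400, 1, 10), channel = 1)
  pts <- rbind(pts, loc_table(runif(400, 0, 100), runif(400, -140, 140),
                              intensity = runif(400, 1, 10), channel = 2))
  rot <- pts
  xy <- as.matrix(pts[, c("x_nm", "y_nm")]) %*% t(R)
  rot$x_nm <- xy[, 1]; rot$y_nm <- xy[, 2]
  roi_rot <- line_roi(c(0, 0), R %*% c(1, 0), 100, 300)
  p1 <- extract_line_profiles(pts, roi)
  p2 <- extract_line_profiles(rot, roi_rot)
  expect_equal(p1[[1]]$values, p2[[1]]$values, tolerance = 1e-9)
  expect_equal(p1[[2]]$values, p2[[2]]$values, tolerance = 1e-9)

  # empty-channel flagging
  onlych1 <- loc_table(50, 0, intensity = 1, channel = 1)
  pe <- extract_line_profiles(onlych1, roi)
  expect_false(pe[[1]]$empty)
  expect_true(pe[[2]]$empty)
})

test_that("1D COM and COM distances follow hand-computed examples", {
  mkprof <- function(values, centers) {
    structure(list(centers_nm = centers, values = values, channel = 1,
                   empty = FALSE), class = "intensity_profile")
  }
  expect_equal(com_1d(mkprof(c(0, 1, 0), c(5, 15, 25))), 15)
  expect_equal(com_1d(mkprof(c(1, 3), c(5, 15))), 12.5)
  sym <- mkprof(c(1, 2, 7, 2, 1), c(5, 15, 25, 35, 45))
  expect_equal(com_1d(sym), 25)
  expect_error(com_1d(mkprof(c(0, 0), c(5, 15))), "zero")

  expect_equal(com_distance_1d(sym, sym), 0)
  d1 <- mkprof(c(1, 0, 0, 0, 0), c(40, 60, 80, 100, 150))
  expect_error(com_distance_1d(d1, mkprof(1, 40)), "grid")
  da <- mkprof(c(1, 0, 0), c(40, 100, 150))
  db <- mkprof(c(0, 0, 1), c(40, 100, 150))
  expect_equal(com_distance_1d(da, db), 110)
})

test_that("2D rectangle COM distance: 3-4-5, zero, empty-channel error", {
  roi <- rect_roi(c(-100, -100), c(300, 0), c(0, 300))
  tab <- rbind(loc_table(0, 0, intensity = 1, channel = 1),
               loc_table(30, 40, intensity = 1, channel = 2))
  expect_equal(com_2d_distance(tab, roi), 50)

  same <- rbind(loc_table(c(10, 60), c(5, 80), intensity = c(2, 3), channel = 1),
                loc_table(c(10, 60), c(5, 80), intensity = c(2, 3), channel = 2))
  expect_equal(com_2d_distance(same, roi), 0)

  expect_error(com_2d_distance(tab[tab$channel == 1, ], roi), "channel 2")
  expect_error(rect_roi(c(0, 0), c(100, 0), c(10, 100)), "orthogonal")
})

test_that("top-fraction estimator follows the order-statistics contract", {
  r <- top_fraction_mean(c(10, 20, 30, 40, 50), q = 0.4)
  expect_equal(r$n_used, 2L)
  expect_equal(r$mean_distance_nm, 45)
  expect_equal(r$sem_nm, sd(c(50, 40)) / sqrt(2))
  expect_equal(sum(r$histogram$count), 5)

  r7 <- top_fraction_mean(rep(7, 10), q = 0.3)
  expect_equal(r7$mean_distance_nm, 7)
  expect_equal(r7$sem_nm, 0)

  all_q <- top_fraction_mean(c(3, 1, 4, 1, 5), q = 1)
  expect_equal(all_q$mean_distance_nm, mean(c(3, 1, 4, 1, 5)))
  expect_error(top_fraction_mean(numeric()), "no distances")
})

test_that("cutoff sweep is monotone and flat for constant samples", {
  set.seed(9)
  het <- runif(200, 0, 300)
  sw <- cutoff_sweep(het, c(0.2, 0.4, 0.6, 1.0))
  expect_true(all(diff(sw$mean_distance_nm) < 0))
  expect_true(attr(sw, "monotone_nonincreasing"))
  swc <- cutoff_sweep(rep(5, 50), c(0.2, 0.5, 1.0))
  expect_equal(swc$mean_distance_nm, rep(5, 3))
})

test_that("projection factor: limits, closed form, Monte-Carlo agreement", {
  expect_equal(projection_factor(1), pi / 4)
  expect_equal(projection_factor(0.4), 0.97265, tolerance = 1e-4)
  expect_lt(abs(projection_factor(1e-6) - 1), 1e-6)
  expect_error(projection_factor(0), "q must")
  expect_error(projection_factor(1.2), "q must")

  # Monte-Carlo oracle: simulated uniform orientations, q sweep
  set.seed(11)
  u <- runif(5000)
  proj <- 100 * sqrt(1 - u^2)
  for (q in c(0.2, 0.4, 0.6, 1.0)) {
    est <- top_fraction_mean(proj, q)
    expect_lt(abs(est$mean_distance_nm / 100 - projection_factor(q)), 0.02)
  }
})

test_that("distances are invariant under rigid motion of data plus ROIs", {
  set.seed(13)
  base <- rbind(loc_table(rnorm(200, 40, 20), rnorm(200, 0, 60),
                          intensity = runif(200, 1, 5), channel = 1),
                loc_table(rnorm(200, 140, 20), rnorm(200, 0, 60),
                          intensity = runif(200, 1, 5), channel = 2))
  roi_l <- line_roi(c(-100, 0), c(1, 0), 400, 300)
  roi_r <- rect_roi(c(-100, -150), c(400, 0), c(0, 300))
  p <- extract_line_profiles(base, roi_l)
  d0 <- com_distance_1d(p[[1]], p[[2]])
  e0 <- com_2d_distance(base, roi_r)

  th <- 77 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(12345, -6789)
  mv <- base
  xy <- sweep(as.matrix(base[, c("x_nm", "y_nm")]) %*% t(R), 2, shift, "+")
  mv$x_nm <- xy[, 1]; mv$y_nm <- xy[, 2]
  roi_l2 <- line_roi(R %*% c(-100, 0) + shift, R %*% c(1, 0), 400, 300)
  roi_r2 <- rect_roi(R %*% c(-100, -150) + shift, R %*% c(400, 0),
                     R %*% c(0, 300))
  p2 <- extract_line_profiles(mv, roi_l2)
  expect_equal(com_distance_1d(p2[[1]], p2[[2]]), d0, tolerance = 1e-6)
  expect_equal(com_2d_distance(mv, roi_r2), e0, tolerance = 1e-6)
})

test_that("2D distance bias at zero separation shrinks with sampling", {
  set.seed(17)
  roi <- rect_roi(c(-400, -400), c(800, 0), c(0, 800))
  mean_dist <- vapply(c(8, 64), function(nloc) {
    d <- replicate(150, {
      tab <- rbind(loc_table(rnorm(nloc, 0, 50), rnorm(nloc, 0, 50),
                             intensity = 1, channel = 1),
                   loc_table(rnorm(nloc, 0, 50), rnorm(nloc, 0, 50),
                             intensity = 1, channel = 2))
      com_2d_distance(tab, roi)
    })
    mean(d)
  }, numeric(1))
  expect_gt(mean_dist[1], 0)
  expect_lt(mean_dist[2], mean_dist[1])
})

test_that("estimator SEM decays with sample size", {
  set.seed(19)
  sems <- vapply(c(100, 1000, 10000), function(n) {
    top_fraction_mean(runif(n, 50, 250), 0.4)$sem_nm
  }, numeric(1))
  expect_true(all(diff(sems) < 0))
})

test_that("blurred input is refused by the COM analyses", {
  tab <- rbind(loc_table(c(100, 150, 180), c(100, 300, 420),
                         intensity = 1, channel = 1),
               loc_table(c(160, 220, 140), c(100, 320, 400),
                         intensity = 1, channel = 2))
  img <- render_sr_image(tab, 10)
  bl <- sr_gaussian_blur(img, 10)
  roi <- line_roi(c(50, 100), c(1, 0), 300, 300)
  expect_error(extract_line_profiles(list(bl, bl), roi), "raw")
  # raw image path works and matches the table path roughly
  raw <- render_sr_image(tab, 10)
  raw1 <- render_sr_image(tab[tab$channel == 1, ], 10, channel = 1)
  raw2 <- render_sr_image(tab[tab$channel == 2, ], 10, channel = 2)
  pimg <- extract_line_profiles(list(raw1, raw2), roi)
  ptab <- extract_line_profiles(tab, roi)
  expect_lt(abs(com_distance_1d(pimg[[1]], pimg[[2]]) -
                com_distance_1d(ptab[[1]], ptab[[2]])), 10)
})

test_that("truth-derived ROIs measure the projected separation", {
  cfg <- synapse_config(separation_nm = 150, axis = c(1, 0, 0),
                        shape_a = shape_cloud(30), shape_b = shape_cloud(30),
                        n_labels_a = 60, n_labels_b = 60,
                        linkage_sd_nm = 0, field_size_nm = 20000)
  truths <- make_synapse_population(cfg, 6, 23)
  tabs <- lapply(truths, function(tr) {
    tab <- emit_localization_table(sample_labels(tr, 100 + tr$id),
                                   loc_precision_sd = 5,
                                   mean_locs_per_label = 20,
                                   rng_seed = 200 + tr$id)
    tab$synapse_id <- tr$id
    tab
  })
  tab <- do.call(rbind, tabs)
  rois <- rois_from_truth(truths, length_nm = 1000, width_nm = 300)
  d <- measure_line_distances(tab, rois)
  expect_equal(nrow(d), 6)
  expect_lt(max(abs(d$distance_nm - 150)), 15)
})
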