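random_affine <- function(max_rot_deg = 5, scale_range = c(0.98, 1.02),
                          shift_range = 100) {
  th <- runif(1, -max_rot_deg, max_rot_deg) * pi / 180
  s <- runif(1, scale_range[1], scale_range[2])
  A <- s * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  b <- runif(2, -shift_range, shift_range)
  list(A = A, b = b)
}

test_that("transform fitting: identity, exact recovery, degenerate errors", {
  beads <- matrix(runif(20, 0, 30000), ncol = 2)
  tm <- fit_channel_transform(beads, beads)
  expect_equal(tm$fit_rms_nm, 0, tolerance = 1e-9)
  expect_equal(unname(tm$coef), rbind(c(0, 1, 0), c(0, 0, 1)),
               tolerance = 1e-9)

  set.seed(21)
  for (i in 1:100) {
    tr <- random_affine()
    p2 <- matrix(runif(24, 0, 40000), ncol = 2)
    p1 <- t(tr$A %*% t(p2) + tr$b)
    tm <- fit_channel_transform(p1, p2)
    expect_lt(max(abs(tm$coef[, 2:3] - tr$A)), 1e-6)
    expect_lt(max(abs(tm$coef[, 1] - tr$b)), 1e-6)
    expect_lt(tm$fit_rms_nm, 1e-6)
  }

  expect_error(fit_channel_transform(beads[1:2, ], beads[1:2, ]), "too few")
  coll <- cbind(1:10 * 100, 1:10 * 50)   # collinear layout
  expect_error(fit_channel_transform(coll, coll), "degenerate")
})

test_that("bead jitter propagates to the expected fit RMS band", {
  set.seed(33)
  rms <- replicate(20, {
    tr <- random_affine()
    p2 <- matrix(runif(40, 0, 40000), ncol = 2)
    p1 <- t(tr$A %*% t(p2) + tr$b)
    # isotropic 5 nm displacement: per-axis sd 5/sqrt(2)
    p2j <- p2 + matrix(rnorm(40, sd = 5 / sqrt(2)), ncol = 2)
    fit_channel_transform(p1, p2j)$fit_rms_nm
  })
  expect_true(all(rms >= 2.5 & rms <= 7.5))
})

test_that("polynomial transform handles quadratic distortion", {
  set.seed(4)
  p2 <- matrix(runif(60, 0, 30000), ncol = 2)
  p1 <- cbind(p2[, 1] + 1e-6 * p2[, 1]^2 + 20,
              p2[, 2] - 5e-7 * p2[, 1] * p2[, 2])
  tm <- fit_channel_transform(p1, p2, kind = "polynomial")
  expect_lt(tm$fit_rms_nm, 1e-6)
  tab <- loc_table(p2[, 1], p2[, 2])
  got <- apply_transform(tab, tm)
  expect_equal(cbind(got$x_nm, got$y_nm), p1, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("apply_transform: identity, shift, inverse round-trip", {
  tab <- loc_table(c(100, 200, 300), c(10, 20, 30), intensity = 1:3)
  expect_equal(apply_transform(tab, identity_transform()), tab)

  shift <- structure(list(kind = "affine",
                          coef = rbind(c(100, 1, 0), c(0, 0, 1)),
                          fit_rms_nm = 0, n_beads = 0L),
                     class = "transform_model")
  got <- apply_transform(tab, shift)
  expect_equal(got$x_nm, tab$x_nm + 100)
  expect_equal(got$y_nm, tab$y_nm)

  set.seed(6)
  tr <- random_affine()
  pts <- matrix(runif(12, 0, 10000), ncol = 2)
  tm <- fit_channel_transform(t(tr$A %*% t(pts) + tr$b), pts)
  back <- apply_transform(apply_transform(tab, tm), invert_transform(tm))
  expect_equal(back$x_nm, tab$x_nm, tolerance = 1e-9)
  expect_equal(back$y_nm, tab$y_nm, tolerance = 1e-9)
})

test_that("mutual nearest-neighbor matching tolerates unpaired beads", {
  set.seed(10)
  p1 <- matrix(runif(30, 0, 20000), ncol = 2)
  p2 <- p1[1:10, ] + matrix(rnorm(20, sd = 20), ncol = 2)
  p2 <- rbind(p2, matrix(runif(8, 30000, 40000), ncol = 2))  # unpaired
  m <- match_beads(p1, p2, gate_nm = 500)
  expect_equal(sort(m[, 1]), 1:10)
  expect_equal(m[, 2][order(m[, 1])], 1:10)
})

# many-cluster localization field (as in a real multi-synapse FOV); the
# correlation peak is only well constrained with realistic density
cluster_field <- function(n_clusters, n_per, sd_nm, frames, seed) {
  set.seed(seed)
  cx <- runif(n_clusters, 1000, 15000)
  cy <- runif(n_clusters, 1000, 15000)
  i <- rep(seq_len(n_clusters), each = n_per)
  loc_table(rnorm(n_clusters * n_per, cx[i], sd_nm),
            rnorm(n_clusters * n_per, cy[i], sd_nm),
            frame = sample(frames, n_clusters * n_per, TRUE))
}

test_that("RCC: stationary table, two-segment brute-force oracle", {
  tab <- cluster_field(25, 2000, 50, 1:1000, seed = 12)
  tr <- estimate_drift_rcc(tab, n_segments = 4, bin_nm = 10,
                           max_shift_nm = 300)
  expect_lt(max(abs(c(tr$dx_nm, tr$dy_nm))), 5)

  # two segments with an injected shift: compare to dense correlation
  # argmax (oracle on a compact field to keep the dense search cheap)
  set.seed(18)
  k <- rep(1:6, each = 2000)
  ocx <- runif(6, 500, 2500); ocy <- runif(6, 500, 2500)
  tab2 <- loc_table(rnorm(12000, ocx[k], 40), rnorm(12000, ocy[k], 40),
                    frame = sample(1:1000, 12000, TRUE))
  late <- tab2$frame > 500
  tab2$x_nm[late] <- tab2$x_nm[late] + 37
  tab2$y_nm[late] <- tab2$y_nm[late] - 22
  tr2 <- estimate_drift_rcc(tab2, n_segments = 2, bin_nm = 10,
                            max_shift_nm = 150)
  oracle <- brute_xcorr_argmax(tab2$x_nm[!late], tab2$y_nm[!late],
                               tab2$x_nm[late], tab2$y_nm[late],
                               bin_nm = 10, m = 15)
  expect_lt(abs(tr2$dx_nm[2] - oracle[1] * 10), 10)
  expect_lt(abs(tr2$dy_nm[2] - oracle[2] * 10), 10)
  expect_lt(abs(tr2$dx_nm[2] - 37), 6)
  expect_lt(abs(tr2$dy_nm[2] + 22), 6)
})

test_that("RCC least squares reproduces a self-consistent linear drift", {
  tab <- cluster_field(25, 1200, 60, 1:6000, seed = 14)
  slope <- c(0.02, -0.01)
  tab$x_nm <- tab$x_nm + slope[1] * (tab$frame - 1)
  tab$y_nm <- tab$y_nm + slope[2] * (tab$frame - 1)
  tr <- estimate_drift_rcc(tab, n_segments = 6, bin_nm = 10,
                           max_shift_nm = 400)
  # anchor-free comparison at segment centers
  want_x <- slope[1] * (tr$centers - tr$centers[1])
  want_y <- slope[2] * (tr$centers - tr$centers[1])
  expect_lt(max(abs(tr$dx_nm - want_x)), 6)
  expect_lt(max(abs(tr$dy_nm - want_y)), 6)
})

test_that("drift correction: zero trace, additivity, range errors, spread", {
  tab <- loc_table(c(100, 200), c(50, 60), frame = c(1, 100))
  z <- drift_trace(c(1, 100), c(0, 0), c(0, 0))
  expect_equal(correct_drift(tab, z), tab)

  d1 <- drift_trace(c(1, 100), c(0, 10), c(0, -4))
  d2 <- drift_trace(c(1, 100), c(0, 6), c(0, 2))
  d12 <- drift_trace(c(1, 100), c(0, 16), c(0, -2))
  expect_equal(correct_drift(correct_drift(tab, d1), d2),
               correct_drift(tab, d12))

  expect_error(correct_drift(loc_table(1, 1, frame = 500), d1),
               "outside")

  # correcting injected drift restores the point-emitter spread; the RCC
  # estimate comes from a dense surrounding field plus the point emitter
  set.seed(15)
  n <- 4000
  stat <- loc_table(rnorm(n, 8000, 10), rnorm(n, 8000, 10),
                    frame = sample(1:10000, n, TRUE))
  field <- cluster_field(20, 1000, 60, 1:10000, seed = 16)
  stat$marker <- 1L; field$marker <- 0L
  stat <- rbind(stat, field)
  drifted <- stat
  drifted$x_nm <- drifted$x_nm + 0.02 * (drifted$frame - 1)
  tr <- estimate_drift_rcc(drifted, n_segments = 8, bin_nm = 10,
                           max_shift_nm = 400)
  fixed <- correct_drift(drifted, tr)
  s_ref <- sd(stat$x_nm[stat$marker == 1L])
  expect_lt(abs(sd(fixed$x_nm[fixed$marker == 1L]) - s_ref) / s_ref, 0.1)
  expect_gt(sd(drifted$x_nm[drifted$marker == 1L]), 2 * s_ref)
})
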