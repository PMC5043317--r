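test_that("SIED finds nothing in uniform or weak-gradient scenes", {
  g <- grid_spec(64, 64, 1.1)
  uni <- make_sst_scene(g, NULL, noise_sd = 0.05, seed = 1)
  expect_equal(sum(detect_fronts_sied(uni)$frontal), 0)
  weak <- step_scene(delta_t = 0.3, noise_sd = 0.05, seed = 2)
  expect_equal(sum(detect_fronts_sied(weak)$frontal), 0)
  expect_error(detect_fronts_sied(make_sst_scene(grid_spec(40, 40), NULL),
                                  window = 48), "window")
})

test_that("SIED localizes a clean step edge and its gradient", {
  sc <- step_scene(delta_t = 1, noise_sd = 0)
  det <- detect_fronts_sied(sc)
  expect_gt(sum(det$frontal), 0)
  cols <- which(det$frontal, arr.ind = TRUE)[, 2]
  expect_true(all(cols %in% 32:33)) # within 1 px of the step
  # central-difference gradient at the step: delta_t / (2 * pixel size)
  expect_equal(mean(det$gradient[det$frontal]), 1 / (2 * 1.1),
               tolerance = 1e-9)
  # frontal pixels are always a subset of valid pixels
  expect_true(all(det$valid[det$frontal]))
})

test_that("SIED edge recall exceeds 95% under realistic noise", {
  hits <- 0
  total <- 0
  for (s in 1:10) {
    sc <- step_scene(delta_t = 1, noise_sd = 0.05, seed = 200 + s)
    det <- detect_fronts_sied(sc)
    # a true edge pixel is recalled if a frontal pixel lies within 1 px
    for (r in 1:64) {
      total <- total + 1
      if (any(det$frontal[max(1, r - 1):min(64, r + 1), 31:34])) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("composites union flags, average gradients, propagate cloud", {
  g <- grid_spec(64, 64, 1.1)
  f1 <- matrix(FALSE, 64, 64); f1[30, 30] <- TRUE
  g1 <- matrix(NA_real_, 64, 64); g1[30, 30] <- 0.4
  d1 <- manual_detection(f1, g1, grid = g)
  # same detection repeated 7x == single detection
  c7 <- composite_window(rep(list(d1), 7))
  expect_identical(c7$frontal, d1$frontal)
  expect_equal(c7$gradient[30, 30], 0.4)
  # gradients 0.4 and 0.6 on two days -> 0.5
  g2 <- matrix(NA_real_, 64, 64); g2[30, 30] <- 0.6
  d2 <- manual_detection(f1, g2, grid = g)
  expect_equal(composite_window(list(d1, d2))$gradient[30, 30], 0.5)
  # pixel cloudy all days stays missing through Gdens
  v <- matrix(TRUE, 64, 64); v[10, 10] <- FALSE
  d3 <- manual_detection(f1, g1, valid = v, grid = g)
  comp <- composite_window(list(d3, d3))
  expect_false(comp$valid[10, 10])
  gd <- compute_gdens(comp)
  expect_true(is.na(gd$values[10, 10]))
})

test_that("Gdens smoothing is a unit-mass Gaussian", {
  g <- grid_spec(64, 64, 1.1)
  f <- matrix(FALSE, 64, 64); f[32, 32] <- TRUE
  gr <- matrix(NA_real_, 64, 64); gr[32, 32] <- 0.8
  comp <- composite_window(list(manual_detection(f, gr, grid = g)))
  gd <- compute_gdens(comp)
  # no frontal pixels -> identically zero
  empty <- composite_window(list(manual_detection(matrix(FALSE, 64, 64),
                                                  matrix(NA_real_, 64, 64),
                                                  grid = g)))
  expect_true(all(compute_gdens(empty)$values == 0))
  # peak at the frontal pixel, value = g * centre weight of a sum-1 kernel
  expect_equal(which.max(gd$values), which(f))
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  k <- exp(-(seq(-7, 7))^2 / (2 * sigma^2)); k <- k / sum(k)
  expect_equal(max(gd$values), 0.8 * k[8]^2, tolerance = 1e-9)
  # total gradient mass conserved (mass far from boundary, cloud-free)
  expect_equal(sum(gd$values), 0.8, tolerance = 1e-6)
})

test_that("Gdens ridge follows a straight front", {
  sc <- step_scene(delta_t = 1, noise_sd = 0.02, seed = 5)
  det <- detect_fronts_sied(sc)
  gd <- compute_gdens(composite_window(list(det)))
  ridge_cols <- apply(gd$values, 1, which.max)
  expect_true(all(abs(ridge_cols[5:60] - 32.5) <= 1))
})

test_that("front simplification keeps long ridges, drops blobs", {
  g <- grid_spec(64, 64, 1.1)
  f <- matrix(FALSE, 64, 64)
  f[10:60, 32] <- TRUE       # long straight front
  f[5:6, 50] <- TRUE; f[5, 51] <- TRUE # 3-px blob
  gr <- matrix(NA_real_, 64, 64); gr[f] <- 0.5
  gd <- compute_gdens(composite_window(list(manual_detection(f, gr, grid = g))))
  sf <- simplify_fronts(gd)
  expect_equal(length(sf$lines), 1)
  # vertices lie on the suprathreshold ridge
  v <- sf$lines[[1]]
  pos <- gd$values[!is.na(gd$values) & gd$values > 0]
  thr <- quantile(pos, 0.75)
  at_v <- sample_metric(gd, v[, 1], v[, 2])
  expect_true(all(at_v >= thr))
  # no fronts -> no polylines, Fdist missing
  empty <- simplify_fronts(compute_gdens(composite_window(list(
    manual_detection(matrix(FALSE, 64, 64), matrix(NA_real_, 64, 64), grid = g)))))
  expect_equal(length(empty$lines), 0)
  expect_true(is.na(compute_fdist(empty, 10, 10)))
})

test_that("Fdist reproduces perpendicular geometry", {
  g <- grid_spec(64, 64, 1.1)
  f <- matrix(FALSE, 64, 64); f[5:60, 32] <- TRUE
  gr <- matrix(NA_real_, 64, 64); gr[f] <- 0.5
  gd <- compute_gdens(composite_window(list(manual_detection(f, gr, grid = g))))
  sf <- simplify_fronts(gd)
  v1 <- sf$lines[[1]][1, ]
  expect_equal(compute_fdist(sf, v1[1], v1[2]), 0) # on a vertex
  # perpendicular offsets from the (vertical) front line
  front_x <- sf$lines[[1]][1, 1]
  for (d_km in c(3, 7.7, 15)) {
    got <- compute_fdist(sf, front_x + d_km, 30 * 1.1)
    expect_equal(got, d_km, tolerance = 1e-6)
  }
  # raster form agrees with pointwise form at pixel centres
  fr <- fdist_raster(sf, g)
  expect_equal(sample_metric(fr, front_x + 7.7, 30 * 1.1),
               compute_fdist(sf, front_x + 7.7, 30 * 1.1), tolerance = 1e-9)
})

test_that("Ffreq is an exact clear-sky percentage", {
  g <- grid_spec(64, 64, 1.1)
  f_on <- matrix(FALSE, 64, 64); f_on[20, 20] <- TRUE
  f_off <- matrix(FALSE, 64, 64)
  gr_on <- matrix(NA_real_, 64, 64); gr_on[20, 20] <- 0.5 # degC/km
  gr_na <- matrix(NA_real_, 64, 64)
  dates <- as.Date("2013-06-15") + 0:7
  dets <- c(
    lapply(1:2, function(i) manual_detection(f_on, gr_on, grid = g, date = dates[i])),
    lapply(3:8, function(i) manual_detection(f_off, gr_na, grid = g, date = dates[i]))
  )
  ff <- compute_ffreq(dets)
  expect_equal(ff$ffreq$values[20, 20], 25) # 2 of 8 clear scenes, exactly
  expect_equal(ff$n_observations$values[20, 20], 8)
  # frontal in all clear scenes -> 100
  ffall <- compute_ffreq(lapply(1:4, function(i)
    manual_detection(f_on, gr_on, grid = g, date = dates[i])))
  expect_equal(ffall$ffreq$values[20, 20], 100)
  # a sub-threshold gradient (0.03 degC across the pixel) never counts
  gr_weak <- matrix(NA_real_, 64, 64); gr_weak[20, 20] <- 0.03 / 1.1
  ffw <- compute_ffreq(c(list(manual_detection(f_on, gr_weak, grid = g,
                                               date = dates[1])), dets[3:8]))
  expect_equal(ffw$ffreq$values[20, 20], 0)
  # invariant to ordering and to duplication of fully cloudy scenes
  ff_rev <- compute_ffreq(rev(dets))
  expect_identical(ff$ffreq$values, ff_rev$ffreq$values)
  cloudy <- manual_detection(f_off, gr_na, valid = matrix(FALSE, 64, 64),
                             grid = g, date = dates[3])
  ff_dup <- compute_ffreq(c(dets, list(cloudy, cloudy)))
  expect_identical(ff$ffreq$values, ff_dup$ffreq$values)
  # never-clear pixels are missing
  allcloud <- compute_ffreq(list(cloudy))
  expect_true(all(is.na(allcloud$ffreq$values)))
  # out-of-season detections are rejected
  expect_error(compute_ffreq(list(manual_detection(f_on, gr_on, grid = g,
                                                   date = as.Date("2013-05-01")))),
               "June")
})

test_that("metric sampling is nearest-pixel with missing propagation", {
  g <- grid_spec(32, 32, 2)
  vals <- matrix(seq_len(32 * 32) + 0, 32, 32)
  r <- fd_raster(vals, g)
  # pixel centre of (row 3, col 5): exact value
  expect_equal(sample_metric(r, (5 - 0.5) * 2, (3 - 0.5) * 2), vals[3, 5])
  expect_true(is.na(sample_metric(r, -5, 10)))  # outside the grid
  vals[3, 5] <- NA
  r2 <- fd_raster(vals, g)
  expect_true(is.na(sample_metric(r2, 9, 5)))
})

test_that("simplified fronts stay within 3 px of the true front curve", {
  g <- grid_spec(96, 96, 1.1)
  fr <- front_geometry(curve = function(y) 48 + 6 * sin(y / 30),
                       delta_t = 1.0, transition_width = 0.5)
  sc <- make_sst_scene(g, fr, noise_sd = 0.1, seed = 17)
  det <- detect_fronts_sied(sc)
  gd <- compute_gdens(composite_window(list(det)))
  sf <- simplify_fronts(gd)
  expect_gt(length(sf$lines), 0)
  verts <- do.call(rbind, sf$lines)
  true_y <- seq(0.5, 95.5, 0.5)
  true_x <- 48 + 6 * sin(true_y / 30)
  # directed Hausdorff in both directions, pixel units
  d_vt <- sapply(seq_len(nrow(verts)), function(i) {
    min(sqrt((verts[i, 1] / 1.1 - true_x)^2 + (verts[i, 2] / 1.1 - true_y)^2))
  })
  interior <- true_y > 5 & true_y < 91 # skeleton endpoints retract at edges
  d_tv <- sapply(which(interior), function(i) {
    min(sqrt((true_x[i] - verts[, 1] / 1.1)^2 + (true_y[i] - verts[, 2] / 1.1)^2))
  })
  expect_lt(max(d_vt), 3)
  expect_lt(max(d_tv), 3)
})
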