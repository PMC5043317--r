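mk_fix <- function(times, lon, lat, bird = "b1") {
  xy <- utm_project(lon, lat, 30)
  structure(tibble::tibble(bird_id = bird, time = times, lon = lon, lat = lat,
                           x = xy$x, y = xy$y),
            colony = grassholm, utm_zone = 30L)
}

test_that("night stripping removes civil-night fixes at the fix location", {
  noon <- as.POSIXct("2013-07-10 13:00:00", tz = "UTC")
  midnight <- as.POSIXct("2013-07-10 01:00:00", tz = "UTC")
  fx <- mk_fix(c(noon, midnight), rep(grassholm[1], 2), rep(grassholm[2], 2))
  out <- strip_night(fx)
  expect_equal(nrow(out), 1)
  expect_equal(out$time, noon)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_error(strip_night(dplyr::mutate(fx, lon = NA_real_)), "missing")
})

test_that("a fix shortly after civil dusk is stripped (solar oracle)", {
  # bracket dusk with the coarse independent oracle, then probe 10 min later
  times <- as.POSIXct("2013-07-10 20:00:00", tz = "UTC") + seq(0, 4 * 3600, 60)
  coarse <- solar_elev_coarse(times, grassholm[1], grassholm[2])
  dusk_est <- times[which(coarse < -6)[1]]
  fx <- mk_fix(dusk_est + 600 + 360, grassholm[1], grassholm[2]) # oracle ~1 deg => +-6 min
  expect_equal(nrow(strip_night(fx)), 0)
})

test_that("colony buffer is a strict 2 km cut", {
  t0 <- as.POSIXct("2013-07-10 12:00:00", tz = "UTC")
  # move due north: 1 km, 1.99 km, 2.01 km, 10 km (exact geodesic offsets)
  dk <- c(0, 1, 1.99, 2.01, 10)
  pts <- geosphere::destPoint(grassholm, b = 0, d = dk * 1000)
  fx <- mk_fix(t0 + seq_along(dk) * 60, pts[, 1], pts[, 2])
  out <- apply_colony_buffer(fx, grassholm)
  d <- geosphere::distGeo(cbind(out$lon, out$lat), grassholm) / 1000
  expect_equal(nrow(out), 2)
  expect_true(all(d > 2))
  allin <- apply_colony_buffer(fx[1:2, ], grassholm)
  expect_equal(nrow(allin), 0)
})

test_that("night strip and buffer commute on the retained set", {
  tr <- make_track(n_trips = 1, seed = 21, trip_shape = list(max_range_km = 60))
  a <- apply_colony_buffer(strip_night(tr), grassholm)
  b <- strip_night(apply_colony_buffer(tr, grassholm))
  strip_attrs <- function(x) tibble::tibble(time = x$time, lon = x$lon,
                                            lat = x$lat)
  expect_equal(strip_attrs(a), strip_attrs(b))
})

test_that("trip splitting flags truncated trips and handles empties", {
  expect_equal(nrow(split_trips(mk_fix(as.POSIXct(character(), tz = "UTC"),
                                       numeric(), numeric()), grassholm)), 0)
  tr <- make_track(n_trips = 2, seed = 31, trip_shape = list(max_range_km = 50))
  trips <- split_trips(tr, grassholm)
  expect_equal(nrow(trips), 2)
  expect_true(all(trips$complete))
  # cut the record mid-second-trip: last trip incomplete
  cut <- attr(tr, "truth")$t_return[2] - 3600
  trips2 <- split_trips(tr, grassholm, battery_end = cut)
  expect_equal(nrow(trips2), 2)
  expect_false(trips2$complete[2])
  expect_true(trips2$complete[1])
})

test_that("spline interpolation passes through fixes and beats linear", {
  t0 <- as.POSIXct("2013-07-10 12:00:00", tz = "UTC")
  # straight constant-speed line
  tt <- t0 + (0:9) * 60
  fx <- structure(tibble::tibble(bird_id = "b", time = tt,
                                 x = 500000 + (0:9) * 600, y = 5.7e6 + (0:9) * 300,
                                 lon = NA, lat = NA),
                  utm_zone = 30L)
  dense <- interpolate_track(fx)
  pred_x <- 500000 + (as.numeric(dense$time) - as.numeric(t0)) * 10
  expect_lt(max(abs(dense$x - pred_x)), 1)
  # exact reproduction at fix timestamps
  at_fix <- interpolate_track(fx, times = fx$time)
  expect_equal(at_fix$x, fx$x, tolerance = 1e-9)
  expect_equal(at_fix$y, fx$y, tolerance = 1e-9)

  # quadratic path: spline error < linear error
  quad <- structure(tibble::tibble(bird_id = "b", time = t0 + (0:3) * 60,
                                   x = 500000 + ((0:3) * 60)^2 / 10, y = 5.7e6,
                                   lon = NA, lat = NA),
                    utm_zone = 30L)
  ds <- interpolate_track(quad)
  true_x <- 500000 + (as.numeric(ds$time) - as.numeric(t0))^2 / 10
  err_spline <- max(abs(ds$x - true_x))
  lin_x <- approx(as.numeric(quad$time), quad$x, xout = as.numeric(ds$time))$y
  err_lin <- max(abs(lin_x - true_x))
  expect_lt(err_spline, err_lin)
})

test_that("interpolation falls back to linear for short segments", {
  t0 <- as.POSIXct("2013-07-10 12:00:00", tz = "UTC")
  fx <- structure(tibble::tibble(bird_id = "b", time = t0 + (0:2) * 60,
                                 x = c(0, 600, 1200) + 5e5, y = rep(5.7e6, 3),
                                 lon = NA, lat = NA),
                  utm_zone = 30L)
  expect_warning(interpolate_track(fx), "linear")
})

test_that("dive geolocation drops mismatches and night-gap dives", {
  t0 <- as.POSIXct("2013-07-10 12:00:00", tz = "UTC")
  dense <- tibble::tibble(time = t0 + 0:600, x = 5e5 + 0:600, y = 5.7e6,
                          lon = -3, lat = 51.5)
  dives <- tibble::tibble(bird_id = "b",
                          start_time = t0 + c(100, 602.4, 300.4),
                          max_depth = c(3, 3, 3))
  out <- geolocate_dives(dives, dense)
  expect_equal(nrow(out), 2) # the +602.4 s dive is > 1 s past track end
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(out$x[1], 5e5 + 100)
  # a dive inside an excised (night) gap has no sample within 1 s
  gappy <- dense[abs(as.numeric(dense$time - t0) - 300) > 150, ]
  out2 <- geolocate_dives(dives[1, ], gappy)
  expect_equal(nrow(out2), 1) # 100 s is fine
  out3 <- geolocate_dives(tibble::tibble(bird_id = "b", start_time = t0 + 300,
                                         max_depth = 3), gappy)
  expect_equal(nrow(out3), 0)
})

test_that("geolocated synthetic dives sit on the true track", {
  tr <- make_track(n_trips = 1, seed = 41, trip_shape = list(max_range_km = 60))
  sch <- make_dive_schedule(tr, n_dives = 8, seed = 42)
  trips <- split_trips(strip_night(tr), grassholm)
  dense <- interpolate_track(structure(trips$fixes[[1]], utm_zone = 30L))
  dives <- tibble::tibble(bird_id = "b1", start_time = sch$start_time)
  located <- geolocate_dives(dives, dense)
  # schedule starts sit on fixes; the spline passes through fixes, so the
  # assigned position must match the generator's true position closely
  truth <- tr[match(located$start_time, tr$time), ]
  err <- sqrt((located$x - truth$x)^2 + (located$y - truth$y)^2)
  expect_lt(max(err), 30)
})

test_that("atypical night dives are excluded, boundary inclusive to day", {
  dives <- tibble::tibble(
    bird_id = "b",
    start_time = as.POSIXct(c("2013-07-10 13:00:00", "2013-07-10 23:30:00"),
                            tz = "UTC"),
    lon = rep(grassholm[1], 2), lat = rep(grassholm[2], 2)
  )
  out <- drop_atypical_night_dives(dives)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_removed"), 1L)
  # ~40 min after computed civil dusk -> removed
  times <- as.POSIXct("2013-07-10 20:00:00", tz = "UTC") + seq(0, 4 * 3600, 60)
  dusk <- times[which(solar_elevation(times, grassholm[1], grassholm[2]) < -6)[1]]
  late <- tibble::tibble(bird_id = "b", start_time = dusk + 40 * 60,
                         lon = grassholm[1], lat = grassholm[2])
  expect_equal(nrow(drop_atypical_night_dives(late)), 0)
})

test_that("trip statistics reproduce simple geometry", {
  t0 <- as.POSIXct("2013-07-10 12:00:00", tz = "UTC")
  single <- tibble::tibble(bird_id = "b", trip_id = 1L, complete = TRUE,
                           n_fixes = 1L, t_start = t0, t_end = t0 + 60,
                           fixes = list(tibble::tibble(lon = -5.3, lat = 51.8)))
  s1 <- trip_statistics(single, grassholm)
  expect_equal(s1$length_km, 0)

  # square path, 10 km sides, colony at one corner
  km_lat <- 1 / 110.574
  km_lon <- 1 / (111.320 * cos(grassholm[2] * pi / 180))
  corners <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  path <- tibble::tibble(lon = grassholm[1] + corners[, 1] * km_lon,
                         lat = grassholm[2] + corners[, 2] * km_lat)
  sq <- tibble::tibble(bird_id = "b", trip_id = 1L, complete = TRUE,
                       n_fixes = 5L, t_start = t0, t_end = t0 + 4 * 3600,
                       fixes = list(path))
  s2 <- trip_statistics(sq, grassholm)
  expect_equal(s2$length_km, 40, tolerance = 0.01)
  expect_equal(s2$max_displacement_km, 10 * sqrt(2), tolerance = 0.01)
  expect_equal(s2$duration_h, 4)
})

test_that("vessel matching applies both the 10 km and 1 h rules", {
  t0 <- as.POSIXct("2013-07-10 12:00:00", tz = "UTC")
  dive <- tibble::tibble(bird_id = "b", start_time = t0,
                         lon = grassholm[1], lat = grassholm[2])
  near <- function(km) grassholm[2] + km / 110.574
  expect_false(match_vessels(dive, NULL)$vessel)
  v1 <- tibble::tibble(time = t0 + 1800, lon = grassholm[1], lat = near(5))
  expect_true(match_vessels(dive, v1)$vessel)   # 5 km, 30 min
  v2 <- tibble::tibble(time = t0 + 7200, lon = grassholm[1], lat = near(5))
  expect_false(match_vessels(dive, v2)$vessel)  # 5 km but 2 h
  v3 <- tibble::tibble(time = t0 + 1800, lon = grassholm[1], lat = near(15))
  expect_false(match_vessels(dive, v3)$vessel)  # 30 min but 15 km
})
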