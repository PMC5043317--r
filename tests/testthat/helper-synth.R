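# shared fixture builders, all generated in code

# ideal dive profile: linear descent, flat (wobble-free) bottom, linear ascent
ideal_profile <- function(t, td = 3, tb = 6, ta = 4, dmax = 6,
                          descent = dmax / td, ascent = dmax / ta) {
  ifelse(t <= td, descent * t,
         ifelse(t <= td + tb, dmax, pmax(0, dmax - ascent * (t - td - tb))))
}

# wrap a depth vector sampled at dt as a continuous trace
as_trace <- function(depth, dt = 1, bird = "t1",
                     dialect = if (dt >= 0.5) "continuous_1Hz" else "triggered_10Hz",
                     t0 = as.POSIXct("2013-07-01 12:00:00", tz = "UTC")) {
  depth_trace(
    tibble::tibble(time = t0 + seq_along(depth) * dt, depth = depth),
    bird_id = bird, dialect = dialect
  )
}

# independent brute-force dive counter: scan threshold crossings sample by
# sample (oracle for detect_dives on continuous traces)
count_dives_oracle <- function(depth, min_depth = 1.5) {
  deep <- depth >= min_depth
  sum(diff(c(FALSE, deep)) == 1)
}

# a front_detection built directly from matrices (bypasses SIED) for
# composite/Ffreq arithmetic tests
manual_detection <- function(frontal, gradient, valid = NULL, grid = NULL,
                             date = as.Date("2013-07-01")) {
  if (is.null(grid)) grid <- grid_spec(ncol(frontal), nrow(frontal), 1.1)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(frontal), ncol(frontal))
  structure(list(frontal = frontal, gradient = gradient, valid = valid,
                 grid = grid, date = date),
            class = "front_detection")
}

# hard step-edge scene: exact step of delta_t between columns c and c+1
step_scene <- function(n = 64, c = 32, delta_t = 1, noise_sd = 0, seed = 1,
                       pixel_km = 1.1, date = as.Date("2013-07-01")) {
  g <- grid_spec(n, n, pixel_km)
  sst <- matrix(12, n, n)
  sst[, (c + 1):n] <- 12 + delta_t
  if (noise_sd > 0) {
    set.seed(seed)
    sst <- sst + matrix(rnorm(n * n, 0, noise_sd), n, n)
  }
  structure(list(sst = sst, cloud = matrix(FALSE, n, n), grid = g,
                 date = date, truth = list(front_col = rep(c, n))),
            class = "sst_scene")
}

# low-precision independent solar oracle: Cooper's declination plus the
# spherical elevation formula with a crude equation of time; accurate to
# about a degree, enough to bracket the civil twilight boundary
solar_elev_coarse <- function(time, lon, lat) {
  doy <- as.integer(format(time, "%j"))
  frac_day <- (as.numeric(time) %% 86400) / 86400
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365)
  b <- 2 * pi * (doy - 81) / 364
  eot_min <- 9.87 * sin(2 * b) - 7.53 * cos(b) - 1.5 * sin(b)
  solar_min <- frac_day * 1440 + 4 * lon + eot_min
  ha <- (solar_min / 4) - 180
  rad <- pi / 180
  asin(sin(lat * rad) * sin(decl * rad) +
         cos(lat * rad) * cos(decl * rad) * cos(ha * rad)) / rad
}

grassholm <- c(-5.467, 51.717)
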