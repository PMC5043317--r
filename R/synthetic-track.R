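#' Simulate central-place foraging GPS tracks
#'
#' Generates looping foraging trips from a colony as a correlated random walk
#' with an outbound phase (persistent heading away from the colony) and a
#' homeward-biased return phase, sampled at a fixed GPS interval. Trips are
#' long enough (default ~23 h) to span both day and night so night-stripping
#' downstream is exercised; between trips the bird sits at the colony.
#'
#' @param colony_lonlat c(lon, lat) of the colony.
#' @param n_trips Number of foraging trips.
#' @param trip_shape List of trip parameters: `max_range_km` (mean furthest
#'   displacement, default 140), `range_sd_km` (default 30), `speed_kmh`
#'   (default 35), `turn_sd` (heading noise, radians per step, default 0.25),
#'   `rest_h` (colony rest between trips, default 10).
#' @param fix_interval Seconds between GPS fixes (default 60).
#' @param seed Integer seed; fixed seed reproduces the track exactly.
#' @param bird_id Identifier stamped on every fix.
#' @param start First fix time (UTC POSIXct).
#' @return A tibble of fixes: `bird_id`, `time`, `lon`, `lat`, `x`, `y` (UTM
#'   metres), with attributes `colony` (lon/lat), `utm_zone`, and `truth`
#'   (tibble of scheduled departure/return times per trip).
#' @export
make_track <- function(colony_lonlat = c(-5.467, 51.717), n_trips = 1,
                       trip_shape = list(), fix_interval = 60, seed = 1,
                       bird_id = "bird01",
                       start = as.POSIXct("2013-07-01 05:00:00", tz = "UTC")) {
  stopifnot(fix_interval > 0, n_trips >= 0)
  p <- utils::modifyList(
    list(max_range_km = 140, range_sd_km = 30, speed_kmh = 35,
         turn_sd = 0.25, rest_h = 10),
    trip_shape
  )
  zone <- utm_zone(colony_lonlat[1])
  colony_xy <- utm_project(colony_lonlat[1], colony_lonlat[2], zone)

  empty <- tibble::tibble(
    bird_id = character(), time = as.POSIXct(character(), tz = "UTC"),
    lon = numeric(), lat = numeric(), x = numeric(), y = numeric()
  )
  if (n_trips == 0) {
    return(structure(empty, colony = colony_lonlat, utm_zone = zone,
                     truth = tibble::tibble(trip_id = integer(),
                                            t_depart = as.POSIXct(character(), tz = "UTC"),
                                            t_return = as.POSIXct(character(), tz = "UTC"))))
  }

  step_km <- p$speed_kmh * fix_interval / 3600
  with_seed(fd_substream(seed, 202), {
    t_cursor <- start
    fixes <- list()
    truth <- list()
    for (trip in seq_len(n_trips)) {
      range_target <- max(30, rnorm(1, p$max_range_km, p$range_sd_km))
      # a few fixes sitting at the colony before departure
      pre <- tibble::tibble(t = t_cursor + fix_interval * (0:2), dx = 0, dy = 0)
      heading <- runif(1, 0, 2 * pi)
      dx <- 0; dy <- 0
      t_now <- max(pre$t) + fix_interval
      out <- list()
      phase_out <- TRUE
      max_steps <- ceiling(3 * range_target / step_km) * 2 + 5000
      for (i in seq_len(max_steps)) {
        if (phase_out) {
          # weak persistence outward; drift the heading slowly
          heading <- heading + rnorm(1, 0, p$turn_sd)
          if (sqrt(dx^2 + dy^2) >= range_target) phase_out <- FALSE
        } else {
          home <- atan2(-dy, -dx)
          turn <- ((home - heading + pi) %% (2 * pi)) - pi
          heading <- heading + 0.3 * turn + rnorm(1, 0, p$turn_sd)
        }
        dx <- dx + step_km * cos(heading)
        dy <- dy + step_km * sin(heading)
        out[[i]] <- c(as.numeric(t_now), dx, dy)
        t_now <- t_now + fix_interval
        if (!phase_out && sqrt(dx^2 + dy^2) < 0.3) break
      }
      om <- do.call(rbind, out)
      # a few fixes back at the colony after return
      post <- tibble::tibble(t = t_now + fix_interval * (0:2), dx = 0, dy = 0)
      trip_fix <- dplyr::bind_rows(
        pre,
        tibble::tibble(t = as.POSIXct(om[, 1], tz = "UTC", origin = "1970-01-01"),
                       dx = om[, 2], dy = om[, 3]),
        post
      )
      fixes[[trip]] <- trip_fix
      truth[[trip]] <- tibble::tibble(
        trip_id = trip,
        t_depart = min(om[, 1]),
        t_return = max(om[, 1])
      )
      t_cursor <- max(post$t) + p$rest_h * 3600
    }
  })

  all_fix <- dplyr::bind_rows(fixes)
  x <- colony_xy$x + all_fix$dx * 1000
  y <- colony_xy$y + all_fix$dy * 1000
  ll <- utm_unproject(x, y, zone)
  truth_tb <- dplyr::bind_rows(truth)
  truth_tb$t_depart <- as.POSIXct(truth_tb$t_depart, tz = "UTC", origin = "1970-01-01")
  truth_tb$t_return <- as.POSIXct(truth_tb$t_return, tz = "UTC", origin = "1970-01-01")

  structure(
    tibble::tibble(bird_id = bird_id, time = all_fix$t,
                   lon = ll$lon, lat = ll$lat, x = x, y = y),
    colony = colony_lonlat, utm_zone = zone, truth = truth_tb
  )
}
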