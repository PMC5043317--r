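#' Strip night-time GPS fixes
#'
#' Removes fixes logged during civil night (solar elevation below -6 degrees
#' -- between the end of civil dusk and the beginning of civil dawn),
#' evaluated at each fix's own position so the cut is correct far from the
#' colony. Fixes exactly on the twilight boundary count as day.
#'
#' @param fixes Tibble with `time` (POSIXct UTC), `lon`, `lat`.
#' @return The day-time fixes, with attribute `n_removed`.
#' @export
strip_night <- function(fixes) {
  if (nrow(fixes) == 0) return(structure(fixes, n_removed = 0L))
  if (any(is.na(fixes$lon)) || any(is.na(fixes$lat))) {
    stop("strip_night: fixes have missing coordinates")
  }
  night <- is_civil_night(fixes$time, fixes$lon, fixes$lat)
  structure(fixes[!night, ], n_removed = sum(night),
            colony = attr(fixes, "colony"), utm_zone = attr(fixes, "utm_zone"),
            truth = attr(fixes, "truth"))
}

#' Remove activity near the colony
#'
#' Drops all fixes within `radius_km` great-circle kilometres of the colony
#' (default 2 km), removing bathing/rafting activity that is not at-sea
#' foraging.
#'
#' @param fixes Tibble with `lon`, `lat`.
#' @param colony_lonlat c(lon, lat); defaults to the track's `colony`
#'   attribute.
#' @param radius_km Buffer radius, km.
#' @return Retained fixes (distance strictly greater than the radius), with
#'   attribute `n_removed`.
#' @export
apply_colony_buffer <- function(fixes, colony_lonlat = attr(fixes, "colony"),
                                radius_km = 2) {
  if (nrow(fixes) == 0) return(structure(fixes, n_removed = 0L))
  d <- dist_to_point_km(fixes$lon, fixes$lat, colony_lonlat)
  keep <- d > radius_km
  structure(fixes[keep, ], n_removed = sum(!keep),
            colony = colony_lonlat, utm_zone = attr(fixes, "utm_zone"),
            truth = attr(fixes, "truth"))
}

#' Split a track into foraging trips
#'
#' A trip is a maximal run of consecutive fixes outside the colony buffer,
#' bounded by buffer exits/entries. A trip truncated by the end of the
#' record or by `battery_end` without an observed return to the buffer is
#' flagged `complete = FALSE`.
#'
#' @param fixes Fix tibble (may still contain in-buffer fixes; they mark the
#'   trip boundaries and are not returned inside trips).
#' @param colony_lonlat c(lon, lat).
#' @param radius_km Colony buffer radius, km (default 2).
#' @param battery_end Optional POSIXct; fixes after it are discarded before
#'   splitting (device outlived its battery).
#' @return A nested tibble, one row per trip: `bird_id`, `trip_id`,
#'   `complete`, `n_fixes`, `t_start`, `t_end`, and a `fixes` list-column.
#' @export
split_trips <- function(fixes, colony_lonlat = attr(fixes, "colony"),
                        radius_km = 2, battery_end = NULL) {
  empty <- tibble::tibble(bird_id = character(), trip_id = integer(),
                          complete = logical(), n_fixes = integer(),
                          t_start = as.POSIXct(character(), tz = "UTC"),
                          t_end = as.POSIXct(character(), tz = "UTC"),
                          fixes = list())
  if (nrow(fixes) == 0) return(empty)
  if (!is.null(battery_end)) fixes <- fixes[fixes$time <= battery_end, ]
  if (nrow(fixes) == 0) return(empty)

  out <- fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(fx) {
      fx <- fx[order(fx$time), ]
      at_sea <- dist_to_point_km(fx$lon, fx$lat, colony_lonlat) > radius_km
      if (!any(at_sea)) return(empty)
      r <- rle(at_sea)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      sea_runs <- which(r$values)
      purrr::map_dfr(seq_along(sea_runs), function(k) {
        i <- sea_runs[k]
        seg <- fx[starts[i]:ends[i], ]
        tibble::tibble(
          bird_id = seg$bird_id[1], trip_id = k,
          complete = ends[i] < nrow(fx), # a later in-buffer fix observed
          n_fixes = nrow(seg),
          t_start = min(seg$time), t_end = max(seg$time),
          fixes = list(tibble::as_tibble(seg))
        )
      })
    })
  structure(out, colony = colony_lonlat, utm_zone = attr(fixes, "utm_zone"))
}

#' Interpolate a trip to 1 s resolution
#'
#' Cubic-spline interpolation (natural boundary conditions) of the projected
#' x(t) and y(t) coordinates separately, evaluated at integer seconds
#' spanning the trip; the spline passes through every original fix exactly.
#' Gaps longer than `gap_break_min` minutes (e.g. stripped night segments)
#' break the trip into separately fitted spline segments to avoid swings
#' across unobserved intervals. Segments with fewer than 4 fixes fall back
#' to linear interpolation with a warning.
#'
#' @param trip_fixes One trip's fixes (`time`, `x`, `y` in UTM metres).
#' @param step Output resolution, seconds (default 1).
#' @param gap_break_min Gap threshold that splits spline segments, minutes.
#' @param times Optional explicit POSIXct query times (overrides the integer
#'   second grid; must lie inside a segment).
#' @return Dense tibble `time`, `x`, `y`, `lon`, `lat`.
#' @export
interpolate_track <- function(trip_fixes, step = 1, gap_break_min = 30,
                              times = NULL) {
  stopifnot(nrow(trip_fixes) >= 2)
  zone <- attr(trip_fixes, "utm_zone")
  if (is.null(zone)) zone <- utm_zone(trip_fixes$lon[1])
  tt <- as.numeric(trip_fixes$time)
  seg_id <- cumsum(c(0, diff(tt) > gap_break_min * 60))

  dense <- purrr::map_dfr(split(seq_along(tt), seg_id), function(idx) {
    if (length(idx) < 2) return(tibble::tibble())
    t_seg <- tt[idx]
    xout <- if (is.null(times)) {
      seq(ceiling(t_seg[1]), floor(t_seg[length(t_seg)]), by = step)
    } else {
      tq <- as.numeric(times)
      tq[tq >= t_seg[1] & tq <= t_seg[length(t_seg)]]
    }
    if (length(xout) == 0) return(tibble::tibble())
    if (length(idx) >= 4) {
      xs <- spline(t_seg, trip_fixes$x[idx], xout = xout, method = "natural")$y
      ys <- spline(t_seg, trip_fixes$y[idx], xout = xout, method = "natural")$y
    } else {
      warning("interpolate_track: segment with < 4 fixes, using linear interpolation")
      xs <- approx(t_seg, trip_fixes$x[idx], xout = xout)$y
      ys <- approx(t_seg, trip_fixes$y[idx], xout = xout)$y
    }
    tibble::tibble(time = as.POSIXct(xout, tz = "UTC", origin = "1970-01-01"),
                   x = xs, y = ys)
  })
  if (nrow(dense) > 0) {
    ll <- utm_unproject(dense$x, dense$y, zone)
    dense$lon <- ll$lon
    dense$lat <- ll$lat
  }
  dense
}

#' Geolocate dives on an interpolated track
#'
#' Each dive takes the dense-track position at its start timestamp. Dives
#' whose start time is more than `max_mismatch` seconds from any dense-track
#' sample (battery exhaustion, colony exclusion zone, stripped night
#' segments) are excluded, with the exclusion counted.
#'
#' @param dives Dive table (needs `start_time`).
#' @param dense_track Output of [interpolate_track()] (may be several trips'
#'   tracks bound together, with a `trip_id` column to inherit).
#' @param max_mismatch Maximum allocation mismatch, seconds (default 1).
#' @return Located dives with `x`, `y`, `lon`, `lat` (and `trip_id` if
#'   present in the track); attribute `n_removed` counts exclusions.
#' @export
geolocate_dives <- function(dives, dense_track, max_mismatch = 1) {
  if (nrow(dives) == 0) {
    return(structure(dplyr::mutate(dives, x = numeric(0), y = numeric(0),
                                   lon = numeric(0), lat = numeric(0)),
                     n_removed = 0L))
  }
  stopifnot(nrow(dense_track) > 0)
  tt <- as.numeric(dense_track$time)
  ts <- as.numeric(dives$start_time)
  nearest <- findInterval(ts, tt)
  idx <- purrr::map_int(seq_along(ts), function(i) {
    cand <- unique(pmin(pmax(c(nearest[i], nearest[i] + 1), 1), length(tt)))
    cand[which.min(abs(tt[cand] - ts[i]))]
  })
  mismatch <- abs(tt[idx] - ts)
  keep <- mismatch <= max_mismatch
  located <- dives[keep, ]
  located$x <- dense_track$x[idx[keep]]
  located$y <- dense_track$y[idx[keep]]
  located$lon <- dense_track$lon[idx[keep]]
  located$lat <- dense_track$lat[idx[keep]]
  if ("trip_id" %in% names(dense_track)) {
    located$trip_id <- dense_track$trip_id[idx[keep]]
  }
  structure(located, n_removed = sum(!keep))
}

#' Exclude atypical night-time dives
#'
#' Dives starting during civil night at the dive's own location are
#' considered atypical (shallow post-dusk activity) and removed. A dive
#' exactly at civil dawn/dusk (elevation -6) is retained.
#'
#' @param dives Located dive table (`start_time`, `lon`, `lat`).
#' @return Day-time dives, with attribute `n_removed`.
#' @export
drop_atypical_night_dives <- function(dives) {
  if (nrow(dives) == 0) return(structure(dives, n_removed = 0L))
  night <- is_civil_night(dives$start_time, dives$lon, dives$lat)
  structure(dives[!night, ], n_removed = sum(night))
}

#' Per-trip movement statistics
#'
#' @param trips Nested trip tibble from [split_trips()].
#' @param colony_lonlat c(lon, lat); defaults to the trips' `colony`
#'   attribute.
#' @return `trips` with `max_displacement_km` (furthest great-circle
#'   distance from the colony), `length_km` (cumulative path length) and
#'   `duration_h` added.
#' @export
trip_statistics <- function(trips, colony_lonlat = attr(trips, "colony")) {
  if (nrow(trips) == 0) {
    return(dplyr::mutate(trips, max_displacement_km = numeric(0),
                         length_km = numeric(0), duration_h = numeric(0)))
  }
  trips |>
    dplyr::mutate(
      max_displacement_km = purrr::map_dbl(.data$fixes, function(fx) {
        max(dist_to_point_km(fx$lon, fx$lat, colony_lonlat))
      }),
      length_km = purrr::map_dbl(.data$fixes, function(fx) {
        if (nrow(fx) < 2) return(0)
        p <- cbind(fx$lon, fx$lat)
        sum(geosphere::distGeo(p[-nrow(p), , drop = FALSE],
                               p[-1, , drop = FALSE])) / 1000
      }),
      duration_h = as.numeric(.data$t_end - .data$t_start, units = "hours")
    )
}

#' Flag dives associated with fishing vessels
#'
#' A dive is vessel-associated when some vessel fix lies within both
#' `radius_km` kilometres and `window_h` hours of the dive start (defaults
#' 10 km and 1 h).
#'
#' @param dives Located dive table (`start_time`, `lon`, `lat`).
#' @param vessel_fixes Tibble of vessel positions (`time`, `lon`, `lat`).
#' @param radius_km,window_h Association thresholds.
#' @return `dives` with logical `vessel` column.
#' @export
match_vessels <- function(dives, vessel_fixes, radius_km = 10, window_h = 1) {
  dives$vessel <- FALSE
  if (nrow(dives) == 0 || is.null(vessel_fixes) || nrow(vessel_fixes) == 0) {
    return(dives)
  }
  vt <- as.numeric(vessel_fixes$time)
  for (i in seq_len(nrow(dives))) {
    dt_ok <- abs(vt - as.numeric(dives$start_time[i])) <= window_h * 3600
    if (!any(dt_ok)) next
    d <- geosphere::distGeo(
      cbind(vessel_fixes$lon[dt_ok], vessel_fixes$lat[dt_ok]),
      c(dives$lon[i], dives$lat[i])
    ) / 1000
    dives$vessel[i] <- any(d <= radius_km)
  }
  dives
}
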