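#' Universal Transverse Mercator zone for a longitude
#'
#' @param lon Longitude in decimal degrees (WGS84).
#' @return Integer UTM zone number (1-60).
#' @export
#' @examples
#' utm_zone(-5.467) # Celtic Sea -> zone 30
utm_zone <- function(lon) {
  as.integer(floor((lon + 180) / 6) %% 60 + 1)
}

#' Project lon/lat to UTM easting/northing
#'
#' Forward transverse-Mercator projection on the WGS84 ellipsoid with the
#' standard UTM scale factor (0.9996) and 500 km false easting. All positions
#' in one analysis are projected into a single zone (the one containing the
#' colony), so distances remain Euclidean across the study area.
#'
#' @param lon,lat Numeric vectors of coordinates in decimal degrees.
#' @param zone UTM zone to project into; defaults to the zone of the first
#'   longitude.
#' @return A tibble with columns `x`, `y` in metres.
#' @export
utm_project <- function(lon, lat, zone = utm_zone(lon[1])) {
  stopifnot(length(lon) == length(lat), all(abs(lat) <= 90, na.rm = TRUE))
  a <- 6378137
  f <- 1 / 298.257223563
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lam0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180

  n <- a / sqrt(1 - e2 * sin(phi)^2)
  t2 <- tan(phi)^2
  c <- ep2 * cos(phi)^2
  aa <- cos(phi) * (lam - lam0)
  m <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
    (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
    (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
    (35 * e2^3 / 3072) * sin(6 * phi))

  x <- k0 * n * (aa + (1 - t2 + c) * aa^3 / 6 +
    (5 - 18 * t2 + t2^2 + 72 * c - 58 * ep2) * aa^5 / 120) + 500000
  y <- k0 * (m + n * tan(phi) * (aa^2 / 2 +
    (5 - t2 + 9 * c + 4 * c^2) * aa^4 / 24 +
    (61 - 58 * t2 + t2^2 + 600 * c - 330 * ep2) * aa^6 / 720))
  y <- y + ifelse(lat < 0, 1e7, 0)
  tibble::tibble(x = x, y = y)
}

#' Inverse UTM: easting/northing back to lon/lat
#'
#' Inverse of [utm_project()] on the WGS84 ellipsoid (northern hemisphere).
#' Round-trips with the forward projection to sub-millimetre accuracy.
#'
#' @param x,y Easting/northing in metres.
#' @param zone UTM zone the coordinates are in.
#' @return A tibble with columns `lon`, `lat` in decimal degrees.
#' @export
utm_unproject <- function(x, y, zone) {
  a <- 6378137
  f <- 1 / 298.257223563
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lam0 <- (zone * 6 - 183) * pi / 180

  m <- y / k0
  mu <- m / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)

  c1 <- ep2 * cos(phi1)^2
  t1 <- tan(phi1)^2
  n1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  r1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  d <- (x - 500000) / (n1 * k0)

  phi <- phi1 - (n1 * tan(phi1) / r1) * (d^2 / 2 -
    (5 + 3 * t1 + 10 * c1 - 4 * c1^2 - 9 * ep2) * d^4 / 24 +
    (61 + 90 * t1 + 298 * c1 + 45 * t1^2 - 252 * ep2 - 3 * c1^2) * d^6 / 720)
  lam <- lam0 + (d - (1 + 2 * t1 + c1) * d^3 / 6 +
    (5 - 2 * c1 + 28 * t1 - 3 * c1^2 + 8 * ep2 + 24 * t1^2) * d^5 / 120) / cos(phi1)

  tibble::tibble(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Solar elevation angle
#'
#' Geometric solar elevation (degrees above the horizon, no atmospheric
#' refraction) from the NOAA solar position algorithm. Civil twilight
#' corresponds to elevations between 0 and -6 degrees; "civil night" here is
#' elevation below -6.
#'
#' @param time POSIXct times in UTC.
#' @param lon,lat Position in decimal degrees (recycled against `time`).
#' @return Numeric vector of elevations in degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  stopifnot(inherits(time, "POSIXct"))
  if (any(is.na(lon)) || any(is.na(lat))) {
    stop("solar_elevation: missing coordinates")
  }
  rad <- pi / 180
  secs <- as.numeric(time) # seconds since epoch, UTC
  jd <- secs / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(gmas * rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * rad) * 0.000289
  stl <- gmls + seqc
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * rad)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * rad)
  declin <- asin(sin(oc * rad) * sin(sal * rad)) / rad

  vary <- tan(oc / 2 * rad)^2
  eqtime <- 4 / rad * (vary * sin(2 * gmls * rad) -
    2 * eeo * sin(gmas * rad) +
    4 * eeo * vary * sin(gmas * rad) * cos(2 * gmls * rad) -
    0.5 * vary^2 * sin(4 * gmls * rad) -
    1.25 * eeo^2 * sin(2 * gmas * rad))

  mins_utc <- (secs %% 86400) / 60
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  ha <- ifelse(ha < -180, ha + 360, ha)

  cos_zen <- sin(lat * rad) * sin(declin * rad) +
    cos(lat * rad) * cos(declin * rad) * cos(ha * rad)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  90 - acos(cos_zen) / rad
}

#' Is a time/place in civil night?
#'
#' TRUE when the sun is below -6 degrees elevation (past the end of civil
#' dusk / before the beginning of civil dawn). The boundary itself counts as
#' day.
#'
#' @inheritParams solar_elevation
#' @param threshold_deg Elevation cut, default -6 (civil twilight).
#' @return Logical vector.
#' @export
is_civil_night <- function(time, lon, lat, threshold_deg = -6) {
  solar_elevation(time, lon, lat) < threshold_deg
}

# great-circle distance to a reference point, km
dist_to_point_km <- function(lon, lat, ref_lonlat) {
  geosphere::distGeo(cbind(lon, lat), matrix(ref_lonlat, ncol = 2)) / 1000
}
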