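#' Estimate the population utilization distribution
#'
#' Bivariate Gaussian kernel density of all at-sea GPS fixes pooled across
#' birds, on the UTM plane, with per-axis reference (normal-rule) bandwidths.
#' The 95% isopleth is the density level whose suprathreshold cells enclose
#' 95% of the density mass; the 2 km colony buffer (and any supplied land
#' polygon) is clipped out before thresholding, so "available" habitat is
#' accessible at-sea area only.
#'
#' @param points Tibble of fixes with `x`, `y` in UTM metres (all birds
#'   pooled; at least 50 points).
#' @param colony_lonlat c(lon, lat) for the buffer clip (NULL to skip).
#' @param buffer_km Colony buffer radius, km (default 2).
#' @param iso Isopleth mass (default 0.95).
#' @param grid_n KDE grid resolution per axis (default 256).
#' @param bandwidth_km Optional c(hx, hy) override, km.
#' @param land Optional list of polygon matrices (x, y in km) clipped out
#'   (synthetic scenarios treat the whole grid as sea).
#' @return A `utilization_distribution`: `density` [fd_raster()]
#'   (mass per cell), `mask` (logical isopleth membership), `threshold`,
#'   `bandwidth_km`, `mass` (attained isopleth mass), `grid`.
#' @export
estimate_ud <- function(points, colony_lonlat = NULL, buffer_km = 2,
                        iso = 0.95, grid_n = 256, bandwidth_km = NULL,
                        land = NULL) {
  stopifnot(nrow(points) >= 50)
  xk <- points$x / 1000
  yk <- points$y / 1000
  if (sd(xk) == 0 || sd(yk) == 0 || abs(stats::cor(xk, yk)) > 0.9999) {
    stop("estimate_ud: degenerate (collinear) points")
  }
  h <- bandwidth_km
  if (is.null(h)) {
    h <- c(MASS::bandwidth.nrd(xk), MASS::bandwidth.nrd(yk))
  }
  pad <- 3 * max(h)
  # square cells: both axes share the larger padded span
  span <- max(diff(range(xk)), diff(range(yk))) + 2 * pad
  lims <- c(mean(range(xk)) + c(-1, 1) * span / 2,
            mean(range(yk)) + c(-1, 1) * span / 2)
  kd <- MASS::kde2d(xk, yk, h = h, n = grid_n, lims = lims)
  dx <- diff(kd$x[1:2])
  mass <- t(kd$z) * dx * dx # rows = y, cols = x
  grid <- grid_spec(grid_n, grid_n, pixel_km = dx,
                    origin = c(kd$x[1] - dx / 2, kd$y[1] - dx / 2))
  xc <- kd$x
  yc <- kd$y

  clip <- matrix(FALSE, grid_n, grid_n)
  if (!is.null(colony_lonlat)) {
    cxy <- utm_project(colony_lonlat[1], colony_lonlat[2])
    dist2 <- outer(yc - cxy$y / 1000, xc - cxy$x / 1000,
                   function(a, b) sqrt(a^2 + b^2))
    clip <- clip | dist2 <= buffer_km
  }
  if (!is.null(land)) {
    pts <- expand.grid(y = yc, x = xc)
    for (poly in land) {
      inside <- point_in_polygon(pts$x, pts$y, poly)
      clip <- clip | matrix(inside, grid_n, grid_n)
    }
  }
  mass[clip] <- 0
  mass <- mass / sum(mass)

  ord <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= iso)[1]
  threshold <- mass[ord][k]
  sel <- ord[seq_len(k)]
  msk <- matrix(FALSE, grid_n, grid_n)
  msk[sel] <- TRUE

  structure(
    list(density = fd_raster(mass, grid, "ud_mass"), mask = msk,
         threshold = threshold, bandwidth_km = h, mass = cum[k],
         grid = grid, x_centers = xc, y_centers = yc),
    class = "utilization_distribution"
  )
}

#' @export
print.utilization_distribution <- function(x, ...) {
  cat(sprintf("<utilization_distribution> %d x %d cells, isopleth mass %.4f, h = (%.2f, %.2f) km\n",
              x$grid$ny, x$grid$nx, x$mass, x$bandwidth_km[1], x$bandwidth_km[2]))
  invisible(x)
}

# even-odd ray casting; poly = matrix with columns x, y
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Membership of points in the 95% utilization polygon
#'
#' @param ud A `utilization_distribution`.
#' @param x_m,y_m Point coordinates in UTM metres.
#' @return Logical vector.
#' @export
ud_contains <- function(ud, x_m, y_m) {
  loc <- grid_locate(ud$grid, x_m / 1000, y_m / 1000)
  ok <- !is.na(loc$row)
  out <- rep(FALSE, length(x_m))
  out[ok] <- ud$mask[cbind(loc$row[ok], loc$col[ok])]
  out
}

#' Sample pseudo-absences inside the utilization distribution
#'
#' Uniform sampling within the 95% isopleth: an isopleth cell is drawn
#' uniformly, then a point uniformly within it. Each pseudo-absence inherits
#' its parent dive's bird, sex, timestamp and vessel flag (so time-varying
#' composites can be sampled for absences on the parent dive's date), with
#' `response = 0` and `parent_dive_id` recording the link.
#'
#' @param dives Located dive table; a `dive_id` column is added if absent.
#' @param ud A `utilization_distribution`.
#' @param n_per_dive Pseudo-absences per dive (default 5).
#' @param seed Integer seed; fixed seed reproduces coordinates exactly.
#' @return Tibble of absence records (`bird_id`, `sex` and `vessel` when
#'   present, `start_time`, `x`, `y` metres, `parent_dive_id`,
#'   `response = 0`).
#' @export
sample_pseudo_absences <- function(dives, ud, n_per_dive = 5, seed = 1) {
  cells <- which(ud$mask)
  if (length(cells) == 0) stop("sample_pseudo_absences: empty utilization polygon")
  if (!"dive_id" %in% names(dives)) dives$dive_id <- seq_len(nrow(dives))
  n <- nrow(dives) * n_per_dive
  g <- ud$grid
  with_seed(fd_substream(seed, 606), {
    pick <- sample(cells, n, replace = TRUE)
    row <- ((pick - 1) %% g$ny) + 1
    col <- ((pick - 1) %/% g$ny) + 1
    x_km <- g$origin[1] + (col - 1 + runif(n)) * g$pixel_km
    y_km <- g$origin[2] + (row - 1 + runif(n)) * g$pixel_km
  })
  parent <- dives[rep(seq_len(nrow(dives)), each = n_per_dive), ]
  out <- tibble::tibble(
    bird_id = parent$bird_id,
    start_time = parent$start_time,
    x = x_km * 1000, y = y_km * 1000,
    parent_dive_id = parent$dive_id,
    response = 0L
  )
  if ("sex" %in% names(parent)) out$sex <- parent$sex
  if ("vessel" %in% names(parent)) out$vessel <- parent$vessel
  out
}

# pick the raster for a record date from a metric entry: either a bare
# fd_raster (static, e.g. seasonal Ffreq) or a list of composites each
# carrying $centre_date and $raster
metric_raster_for_date <- function(entry, date) {
  if (inherits(entry, "fd_raster")) return(entry)
  stopifnot(is.list(entry), length(entry) >= 1)
  dates <- as.Date(vapply(entry, function(e) as.character(e$centre_date), ""))
  entry[[which.min(abs(as.numeric(dates - as.Date(date))))]]$raster
}

#' Assemble use-availability and dive-level analysis tables
#'
#' Attaches front-metric values to presences (dives) and pseudo-absences by
#' nearest-pixel lookup on the composite centred on each record's date, and
#' emits one use-availability table per metric (rows missing that metric are
#' dropped, with the exclusion counted) plus a dive-level table carrying
#' shape, depth, duration, decimal time and the vessel flag for the
#' dive-characteristic models.
#'
#' @param dives Located, classified dive table (with `sex` column).
#' @param absences Output of [sample_pseudo_absences()].
#' @param metrics Named list (names are metric names, e.g. `"Gdens"`); each
#'   element is an [fd_raster()] or a list of `list(centre_date=, raster=)`
#'   composites to be matched on date.
#' @return List with `tables` (one use-availability tibble per metric, with
#'   `response`, `bird_id`, `sex`, coordinates, the metric and `DecTime`),
#'   `dive_table` (dive-level tibble with all metrics, `DecTime`,
#'   `DecTime2`, `shape`, `max_depth`, `duration`, `vessel`), and
#'   `n_excluded` (rows dropped per metric for missing values).
#' @export
build_table <- function(dives, absences, metrics) {
  stopifnot(length(names(metrics)) == length(metrics))
  if (!"dive_id" %in% names(dives)) dives$dive_id <- seq_len(nrow(dives))

  dec_time <- function(t) {
    s <- as.numeric(t) %% 86400
    s / 86400
  }
  pres <- tibble::tibble(
    response = 1L, bird_id = dives$bird_id,
    sex = dives$sex, start_time = dives$start_time,
    x = dives$x, y = dives$y, dive_id = dives$dive_id,
    parent_dive_id = dives$dive_id
  )
  if ("vessel" %in% names(dives)) pres$vessel <- dives$vessel
  abs_tb <- absences
  abs_tb$dive_id <- NA_integer_
  both <- dplyr::bind_rows(pres, abs_tb)
  both$DecTime <- dec_time(both$start_time)

  dates <- as.Date(both$start_time)
  tables <- list()
  n_excluded <- integer()
  for (mname in names(metrics)) {
    vals <- rep(NA_real_, nrow(both))
    for (d in unique(dates)) {
      sel <- dates == d
      ras <- metric_raster_for_date(metrics[[mname]], d)
      vals[sel] <- sample_metric(ras, both$x[sel] / 1000, both$y[sel] / 1000)
    }
    tb <- both
    tb[[mname]] <- vals
    keep <- !is.na(vals)
    n_excluded[mname] <- sum(!keep)
    tables[[mname]] <- tb[keep, ]
  }

  dive_table <- dives
  dive_table$DecTime <- dec_time(dives$start_time)
  dive_table$DecTime2 <- (dive_table$DecTime - 0.5)^2
  for (mname in names(metrics)) {
    vals <- rep(NA_real_, nrow(dives))
    dd <- as.Date(dives$start_time)
    for (d in unique(dd)) {
      sel <- dd == d
      ras <- metric_raster_for_date(metrics[[mname]], d)
      vals[sel] <- sample_metric(ras, dives$x[sel] / 1000, dives$y[sel] / 1000)
    }
    dive_table[[mname]] <- vals
  }
  dive_table$is_u <- as.integer(dive_table$shape == "U")

  list(tables = tables, dive_table = dive_table, n_excluded = n_excluded)
}
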