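#' Define a raster grid in projected kilometres
#'
#' Grids are square-pixel rasters on the UTM plane of the analysis. `pixel_km`
#' of ~1.1 gives pixel areas of ~1.2 km^2, the native resolution of the SST
#' scenes the front-mapping stage expects. Matrix rows index y (south to
#' north), columns index x (west to east).
#'
#' @param nx,ny Grid dimensions in pixels.
#' @param pixel_km Pixel side length, km.
#' @param origin Numeric length-2: x/y of the grid's lower-left corner in
#'   projected km.
#' @param utm_zone UTM zone the projected coordinates live in (metadata).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(nx, ny, pixel_km = 1.1, origin = c(0, 0), utm_zone = 30L) {
  stopifnot(nx >= 1, ny >= 1, pixel_km > 0, length(origin) == 2)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), pixel_km = pixel_km,
         origin = as.numeric(origin), utm_zone = as.integer(utm_zone)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px @ %.3f km, origin (%.1f, %.1f) km, UTM %d\n",
              x$nx, x$ny, x$pixel_km, x$origin[1], x$origin[2], x$utm_zone))
  invisible(x)
}

#' Centre a grid on a colony location
#'
#' @param colony_lonlat Numeric c(lon, lat) of the colony.
#' @param nx,ny,pixel_km See [grid_spec()].
#' @param zone UTM zone; defaults to the colony's zone.
#' @return A `grid_spec` whose centre pixel sits on the colony.
#' @export
grid_around_colony <- function(colony_lonlat, nx = 256, ny = 256, pixel_km = 1.1,
                               zone = utm_zone(colony_lonlat[1])) {
  p <- utm_project(colony_lonlat[1], colony_lonlat[2], zone)
  origin <- c(p$x / 1000 - nx / 2 * pixel_km, p$y / 1000 - ny / 2 * pixel_km)
  grid_spec(nx, ny, pixel_km, origin, zone)
}

# pixel-centre coordinates (km) for every column / row
grid_x_centers <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$pixel_km
grid_y_centers <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$pixel_km

# nearest pixel (row, col) for points in projected km; NA outside the grid
grid_locate <- function(grid, x_km, y_km) {
  col <- floor((x_km - grid$origin[1]) / grid$pixel_km) + 1
  row <- floor((y_km - grid$origin[2]) / grid$pixel_km) + 1
  bad <- col < 1 | col > grid$nx | row < 1 | row > grid$ny
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' A single-band raster on a grid
#'
#' Thin container pairing a numeric matrix (ny x nx, `NA` = missing) with its
#' [grid_spec()].
#'
#' @param values Numeric matrix, dimensions `c(grid$ny, grid$nx)`.
#' @param grid A `grid_spec`.
#' @param name Band name, used in plots and tidied output.
#' @return An `fd_raster`.
#' @export
fd_raster <- function(values, grid, name = "value") {
  stopifnot(is.matrix(values), nrow(values) == grid$ny, ncol(values) == grid$nx)
  structure(list(values = values, grid = grid, name = name), class = "fd_raster")
}

#' @export
print.fd_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<fd_raster '%s'> %d x %d px, %.1f%% missing, range [%.4g, %.4g]\n",
              x$name, x$grid$ny, x$grid$nx, 100 * mean(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Tidy a raster into a long tibble
#'
#' @param x An `fd_raster`.
#' @param ... Unused.
#' @return Tibble with `x`, `y` (pixel-centre km), `row`, `col` and the band
#'   value.
#' @method tidy fd_raster
#' @export
tidy.fd_raster <- function(x, ...) {
  g <- x$grid
  vals <- as.vector(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(g$ny), times = g$nx),
    col = rep(seq_len(g$nx), each = g$ny),
    x = rep(grid_x_centers(g), each = g$ny),
    y = rep(grid_y_centers(g), times = g$nx),
    value = vals
  )
  names(out)[names(out) == "value"] <- x$name
  out
}

#' Sample a raster at point locations by nearest pixel
#'
#' @param raster An `fd_raster`.
#' @param x_km,y_km Point coordinates in projected km.
#' @return Numeric vector; `NA` outside the grid or on missing pixels.
#' @export
raster_sample <- function(raster, x_km, y_km) {
  loc <- grid_locate(raster$grid, x_km, y_km)
  out <- rep(NA_real_, length(x_km))
  ok <- !is.na(loc$row)
  out[ok] <- raster$values[cbind(loc$row[ok], loc$col[ok])]
  out
}

# --- masked separable Gaussian convolution ------------------------------

# 1-D Gaussian kernel, sum 1, truncated at ~3 sigma
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# band (Toeplitz) convolution matrix with zero padding at edges
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    keep <- idx >= 1 & idx <= n
    m[idx[keep], j] <- kernel[keep]
  }
  t(m)
}

#' Mask-normalized Gaussian smoothing of a matrix
#'
#' Separable Gaussian convolution in which missing pixels contribute neither
#' to the numerator nor to the local kernel mass: the result at each valid
#' pixel is a weighted mean over valid neighbours only. On a fully valid
#' interior the operation reduces to plain convolution with a sum-one kernel
#' (so total mass is conserved).
#'
#' @param values Numeric matrix; `NA` marks missing pixels.
#' @param sigma_px Gaussian sigma in pixels.
#' @param renormalize If TRUE (default) divide by the smoothed mask so values
#'   keep their original scale near gaps; if FALSE return the plain masked
#'   convolution (mass-conserving, missing treated as zero).
#' @return Matrix of the same shape; pixels missing on input stay `NA`.
#' @export
gaussian_smooth_masked <- function(values, sigma_px, renormalize = TRUE) {
  stopifnot(sigma_px > 0)
  k <- gauss_kernel(sigma_px)
  ky <- conv_matrix(nrow(values), k)
  kx <- conv_matrix(ncol(values), k)
  mask <- !is.na(values)
  v0 <- values
  v0[!mask] <- 0
  num <- ky %*% v0 %*% t(kx)
  if (renormalize) {
    den <- ky %*% (mask + 0) %*% t(kx)
    out <- num / pmax(den, .Machine$double.eps)
  } else {
    out <- num
  }
  out[!mask] <- NA_real_
  out
}

#' Plot a raster band
#'
#' @param object An `fd_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fd_raster
#' @export
autoplot.fd_raster <- function(object, ...) {
  df <- tidy(object)
  names(df)[names(df) == object$name] <- ".value"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$.value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$name, na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)")
}
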