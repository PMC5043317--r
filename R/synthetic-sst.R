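#' Parametric front geometry for synthetic SST scenes
#'
#' Describes a two-water-mass thermal front as a curve in pixel coordinates:
#' the warm side lies at larger x. Stands in for shelf-sea tidal-mixing
#' fronts: a temperature step `delta_t` across a transition zone a few pixels
#' wide, optionally drifting along x from day to day.
#'
#' @param curve Either a single number (a straight vertical front at that
#'   column, pixel units) or a function `f(y_px)` returning the front's x
#'   position (pixels) at height `y_px`.
#' @param delta_t Temperature step across the front, degrees C (>= 0).
#' @param transition_width Width of the sigmoid transition, pixels (> 0).
#' @param drift_per_day Front displacement along +x, pixels/day.
#' @return A `front_geometry` object.
#' @export
front_geometry <- function(curve, delta_t = 1, transition_width = 0.5,
                           drift_per_day = 0) {
  stopifnot(delta_t >= 0, transition_width > 0)
  curve_fun <- if (is.function(curve)) curve else {
    x0 <- as.numeric(curve)
    function(y_px) rep(x0, length(y_px))
  }
  structure(
    list(curve = curve_fun, delta_t = delta_t,
         transition_width = transition_width, drift_per_day = drift_per_day),
    class = "front_geometry"
  )
}

#' Generate a synthetic SST scene with a known front
#'
#' Builds a gridded sea-surface temperature field as
#' `base + delta_t * sigmoid(signed distance to front / width) + noise`,
#' plus a cloud mask of spatially contiguous blobs (a thresholded smoothed
#' Gaussian random field) covering the requested fraction of pixels. The true
#' front position is recorded in the scene's `truth` so edge-detection recall
#' can be scored exactly.
#'
#' @param grid A [grid_spec()]; at least 32 pixels on each side (one
#'   edge-detection window).
#' @param front A [front_geometry()] or NULL for a frontless field.
#' @param base_temp Background temperature of the cool water mass, degrees C.
#' @param noise_sd Pixel noise sd, degrees C.
#' @param cloud_fraction Fraction of pixels masked by cloud, in \[0, 1\].
#' @param seed Integer seed; fixed seed gives a bitwise-identical scene.
#' @param date Scene date (used for compositing and front drift).
#' @param day_offset Days since the front's reference position; the front
#'   shifts by `drift_per_day * day_offset` pixels.
#' @return An `sst_scene`: list with `sst` and `cloud` matrices (ny x nx),
#'   the `grid`, `date`, and a `truth` list holding the front column position
#'   per row (pixel units) or NULL.
#' @export
make_sst_scene <- function(grid, front = NULL, base_temp = 12, noise_sd = 0.05,
                           cloud_fraction = 0, seed = 1,
                           date = as.Date("2013-07-21"), day_offset = 0) {
  if (min(grid$nx, grid$ny) < 32) {
    stop("make_sst_scene: grid must be at least 32 x 32 pixels (one SIED window)")
  }
  stopifnot(cloud_fraction >= 0, cloud_fraction <= 1, noise_sd >= 0)

  x_px <- matrix(rep(seq_len(grid$nx) - 0.5, each = grid$ny), grid$ny, grid$nx)
  y_px <- matrix(rep(seq_len(grid$ny) - 0.5, times = grid$nx), grid$ny, grid$nx)

  truth_front <- NULL
  sst <- matrix(base_temp, grid$ny, grid$nx)
  if (!is.null(front)) {
    x_front <- front$curve(y_px[, 1]) + front$drift_per_day * day_offset
    truth_front <- x_front
    signed <- x_px - matrix(x_front, grid$ny, grid$nx)
    sst <- sst + front$delta_t * plogis(signed / front$transition_width)
  }

  with_seed(fd_substream(seed, 101), {
    if (noise_sd > 0) {
      sst <- sst + matrix(rnorm(length(sst), 0, noise_sd), grid$ny, grid$nx)
    }
    cloud <- matrix(FALSE, grid$ny, grid$nx)
    if (cloud_fraction >= 1) {
      cloud[] <- TRUE
    } else if (cloud_fraction > 0) {
      field <- matrix(rnorm(length(sst)), grid$ny, grid$nx)
      field <- gaussian_smooth_masked(field, sigma_px = 4)
      cloud <- field > quantile(field, 1 - cloud_fraction)
    }
  })

  structure(
    list(sst = sst, cloud = cloud, grid = grid, date = date,
         truth = list(front_col = truth_front)),
    class = "sst_scene"
  )
}

#' @export
print.sst_scene <- function(x, ...) {
  cat(sprintf("<sst_scene %s> %d x %d px, %.1f%% cloud, SST %.2f-%.2f C\n",
              format(x$date), x$grid$ny, x$grid$nx, 100 * mean(x$cloud),
              min(x$sst), max(x$sst)))
  invisible(x)
}

#' @rdname make_sst_scene
#' @param object An `sst_scene`.
#' @param ... Unused.
#' @method autoplot sst_scene
#' @export
autoplot.sst_scene <- function(object, ...) {
  v <- object$sst
  v[object$cloud] <- NA
  autoplot(fd_raster(v, object$grid, "SST (°C)"))
}
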