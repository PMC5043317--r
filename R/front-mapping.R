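# shift a matrix by (dr, dc) with zero/FALSE padding
mat_shift <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# SST gradient magnitude, degC per km, central differences (one-sided at
# edges/cloud); NA where no valid neighbour in either direction
sst_gradient <- function(sst, valid, pixel_km) {
  v <- sst
  v[!valid] <- NA
  diff_axis <- function(p1, m1) {
    # p1 = value one pixel "+", m1 one pixel "-"
    g <- (p1 - m1) / (2 * pixel_km)
    one_sided_p <- (p1 - v) / pixel_km
    one_sided_m <- (v - m1) / pixel_km
    g[is.na(g)] <- one_sided_p[is.na(g)]
    g[is.na(g)] <- one_sided_m[is.na(g)]
    g
  }
  gx <- diff_axis(mat_shift(v, 0, -1, NA), mat_shift(v, 0, 1, NA))
  gy <- diff_axis(mat_shift(v, -1, 0, NA), mat_shift(v, 1, 0, NA))
  gx2 <- ifelse(is.na(gx), 0, gx)^2
  gy2 <- ifelse(is.na(gy), 0, gy)^2
  mag <- sqrt(gx2 + gy2)
  mag[is.na(gx) & is.na(gy)] <- NA
  mag[!valid] <- NA
  mag
}

# histogram split of one window: best two-population threshold by the
# between-cluster criterion; returns NULL or list(tau, m1, m2, n1, n2)
sied_split <- function(vals, min_pop_frac) {
  n <- length(vals)
  s <- sort(vals)
  cs <- cumsum(s)
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  j <- k * (n - k) * (m1 - m2)^2
  ok <- k >= min_pop_frac * n & (n - k) >= min_pop_frac * n & s[k] < s[k + 1]
  if (!any(ok)) return(NULL)
  j[!ok] <- -Inf
  kbest <- which.max(j)
  list(tau = (s[kbest] + s[kbest + 1]) / 2, m1 = m1[kbest], m2 = m2[kbest],
       n1 = kbest, n2 = n - kbest)
}

# spatial cohesion of the A/B split inside a window (fraction of 4-neighbour
# pairs of each population whose neighbour is the same population)
sied_cohesion <- function(is_a, valid) {
  count_pairs <- function(pop) {
    same <- 0; tot <- 0
    for (sh in list(c(0, 1), c(1, 0))) {
      nb_pop <- mat_shift(pop, sh[1], sh[2], FALSE)
      nb_valid <- mat_shift(valid, sh[1], sh[2], FALSE)
      pair <- valid & nb_valid & (pop | nb_pop)        # pair involving pop
      both <- valid & nb_valid & pop & nb_pop
      mixed <- valid & nb_valid & (pop != nb_pop)
      tot <- tot + sum(both) + sum(mixed)
      same <- same + sum(both)
    }
    if (tot == 0) return(1)
    same / tot
  }
  c(a = count_pairs(is_a), b = count_pairs(!is_a & valid))
}

#' Detect thermal fronts by single-image edge detection
#'
#' Window-based histogram algorithm: the scene is scanned with
#' half-overlapping `window` x `window` frames; in each frame with at least
#' 25% cloud-free pixels the SST values are split at the threshold
#' maximizing the between-population separation, and a front is accepted
#' when the two populations differ by at least `dt_threshold` degrees C,
#' each holds at least `min_pop_frac` of the valid pixels, and both are
#' spatially cohesive. Frontal pixels are the valid pixels adjacent to the
#' boundary between the two populations; each carries the local SST
#' gradient magnitude (central differences, degC/km).
#'
#' @param scene An `sst_scene` from [make_sst_scene()] (or equivalent).
#' @param window Frame size in pixels (default 32; minimum 16).
#' @param dt_threshold Temperature difference across the front, degC
#'   (default 0.4).
#' @param min_valid_frac Minimum cloud-free fraction of a frame (0.25).
#' @param min_pop_frac Minimum size of each population (0.25 of valid).
#' @param cohesion_min Minimum spatial cohesion of both populations (0.90).
#' @return A `front_detection`: list with logical `frontal` and `valid`
#'   masks, `gradient` matrix (degC/km), `grid`, `date`.
#' @export
detect_fronts_sied <- function(scene, window = 32, dt_threshold = 0.4,
                               min_valid_frac = 0.25, min_pop_frac = 0.25,
                               cohesion_min = 0.90) {
  stopifnot(window >= 16)
  grid <- scene$grid
  if (grid$ny < window || grid$nx < window) {
    stop("detect_fronts_sied: scene smaller than one ", window, "x", window, " window")
  }
  valid <- !scene$cloud
  grad <- sst_gradient(scene$sst, valid, grid$pixel_km)
  frontal <- matrix(FALSE, grid$ny, grid$nx)

  step <- max(1, window %/% 2)
  row_starts <- unique(c(seq(1, grid$ny - window + 1, by = step), grid$ny - window + 1))
  col_starts <- unique(c(seq(1, grid$nx - window + 1, by = step), grid$nx - window + 1))

  for (r0 in row_starts) {
    for (c0 in col_starts) {
      rr <- r0:(r0 + window - 1)
      cc <- c0:(c0 + window - 1)
      wv <- valid[rr, cc]
      if (sum(wv) < min_valid_frac * window^2) next
      vals <- scene$sst[rr, cc][wv]
      sp <- sied_split(vals, min_pop_frac)
      if (is.null(sp)) next
      if (abs(sp$m2 - sp$m1) < dt_threshold) next
      is_a <- scene$sst[rr, cc] <= sp$tau & wv
      coh <- sied_cohesion(is_a, wv)
      if (any(coh < cohesion_min)) next
      # frontal pixels: valid pixels 4-adjacent to the other population
      is_b <- wv & !is_a
      near_b <- mat_shift(is_b, 0, 1, FALSE) | mat_shift(is_b, 0, -1, FALSE) |
        mat_shift(is_b, 1, 0, FALSE) | mat_shift(is_b, -1, 0, FALSE)
      near_a <- mat_shift(is_a, 0, 1, FALSE) | mat_shift(is_a, 0, -1, FALSE) |
        mat_shift(is_a, 1, 0, FALSE) | mat_shift(is_a, -1, 0, FALSE)
      fr <- (is_a & near_b) | (is_b & near_a)
      frontal[rr, cc] <- frontal[rr, cc] | fr
    }
  }
  frontal <- frontal & valid
  structure(list(frontal = frontal, gradient = grad, valid = valid,
                 grid = grid, date = scene$date),
            class = "front_detection")
}

#' Combine daily front detections into a composite front map
#'
#' Per-pixel union of frontal flags over the (typically 7-day) window;
#' the composite gradient at a pixel is the mean of its gradients over the
#' detections in which it was frontal. Pixels cloudy on every day of the
#' window are missing in all downstream metrics.
#'
#' @param detections List of `front_detection`s on a common grid.
#' @param centre_date Date the composite is centred on (metadata).
#' @return A `composite_front`: `frontal`, `gradient` (NA off-front),
#'   `valid` (clear on at least one day), `grid`, `centre_date`, `window`.
#' @export
composite_window <- function(detections, centre_date = NULL) {
  stopifnot(length(detections) >= 1)
  grid <- detections[[1]]$grid
  for (d in detections) {
    stopifnot(d$grid$nx == grid$nx, d$grid$ny == grid$ny)
  }
  frontal_any <- Reduce(`|`, lapply(detections, `[[`, "frontal"))
  valid_any <- Reduce(`|`, lapply(detections, `[[`, "valid"))
  gsum <- matrix(0, grid$ny, grid$nx)
  gcount <- matrix(0L, grid$ny, grid$nx)
  for (d in detections) {
    use <- d$frontal & !is.na(d$gradient)
    gsum[use] <- gsum[use] + d$gradient[use]
    gcount[use] <- gcount[use] + 1L
  }
  gradient <- ifelse(gcount > 0, gsum / pmax(gcount, 1), NA_real_)
  if (is.null(centre_date)) {
    centre_date <- detections[[ceiling(length(detections) / 2)]]$date
  }
  structure(list(frontal = frontal_any, gradient = gradient, valid = valid_any,
                 grid = grid, centre_date = centre_date,
                 window = length(detections)),
            class = "composite_front")
}

#' Front gradient density (Gdens)
#'
#' Spatially smoothed mean cross-front temperature gradient over all frontal
#' pixels of a composite: the composite gradient (zero at valid non-frontal
#' pixels) is convolved with a normalized Gaussian kernel whose full width
#' at half maximum is `smooth_width` pixels; missing (always-cloudy) pixels
#' are excluded by mask-normalized convolution and stay missing.
#'
#' @param composite A `composite_front`.
#' @param smooth_width Gaussian filter width, pixels (default 5).
#' @param width_is_fwhm Interpret `smooth_width` as FWHM (default) or as
#'   sigma directly.
#' @return An [fd_raster()] named `"Gdens"`, degC/km.
#' @export
compute_gdens <- function(composite, smooth_width = 5, width_is_fwhm = TRUE) {
  sigma <- if (width_is_fwhm) smooth_width / (2 * sqrt(2 * log(2))) else smooth_width
  field <- ifelse(composite$frontal, composite$gradient, 0)
  field[!composite$valid] <- NA
  field[composite$frontal & is.na(composite$gradient)] <- 0
  sm <- gaussian_smooth_masked(field, sigma)
  fd_raster(sm, composite$grid, "Gdens")
}

# Zhang-Suen thinning of a logical mask to 1-px skeleton
skeletonize <- function(mask) {
  m <- mask
  m[is.na(m)] <- FALSE
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- mat_shift(m, 1, 0, FALSE);  p3 <- mat_shift(m, 1, -1, FALSE)
      p4 <- mat_shift(m, 0, -1, FALSE); p5 <- mat_shift(m, -1, -1, FALSE)
      p6 <- mat_shift(m, -1, 0, FALSE); p7 <- mat_shift(m, -1, 1, FALSE)
      p8 <- mat_shift(m, 0, 1, FALSE);  p9 <- mat_shift(m, 1, 1, FALSE)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- Reduce(`+`, lapply(1:8, function(i) (!seqs[[i]]) & seqs[[i + 1]]))
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (sub == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# order skeleton pixels into polylines by walking 8-connected chains
link_polylines <- function(skel) {
  pix <- which(skel, arr.ind = TRUE)
  if (nrow(pix) == 0) return(list())
  key <- function(r, c) paste(r, c)
  idx <- new.env(hash = TRUE)
  for (i in seq_len(nrow(pix))) assign(key(pix[i, 1], pix[i, 2]), i, envir = idx)
  nbrs <- function(i) {
    r <- pix[i, 1]; c <- pix[i, 2]
    out <- integer()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- key(r + dr, c + dc)
      if (exists(k, envir = idx, inherits = FALSE)) {
        out <- c(out, get(k, envir = idx))
      }
    }
    out
  }
  deg <- vapply(seq_len(nrow(pix)), function(i) length(nbrs(i)), integer(1))
  visited <- rep(FALSE, nrow(pix))
  walk <- function(start) {
    path <- start
    visited[start] <<- TRUE
    cur <- start
    repeat {
      nxt <- nbrs(cur)
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0) break
      # prefer 4-connected continuation for straighter chains
      d4 <- abs(pix[nxt, 1] - pix[cur, 1]) + abs(pix[nxt, 2] - pix[cur, 2])
      cur <- nxt[order(d4)][1]
      visited[cur] <<- TRUE
      path <- c(path, cur)
    }
    path
  }
  paths <- list()
  for (start in order(-(deg == 1))) { # endpoints first, then leftovers/cycles
    if (visited[start]) next
    if (deg[start] != 1 && any(!visited & deg == 1)) next
    paths[[length(paths) + 1]] <- walk(start)
  }
  while (any(!visited)) {
    paths[[length(paths) + 1]] <- walk(which(!visited)[1])
  }
  lapply(paths, function(p) pix[p, , drop = FALSE])
}

#' Trace simplified fronts through the strongest frontal pixels
#'
#' Deterministic contour extraction standing in for the clustering step of
#' composite front mapping: the smoothed Gdens field is thresholded at the
#' `q`-th percentile of its positive values, the suprathreshold region is
#' skeletonized to one-pixel ridges, 8-connected ridge pixels are linked
#' into polylines, and polylines shorter than `min_length_px` pixels of arc
#' length are discarded.
#'
#' @param gdens Gdens [fd_raster()] from [compute_gdens()].
#' @param q Percentile (0-100) of positive Gdens defining "strongest"
#'   (default 75).
#' @param min_length_px Minimum polyline arc length in pixels (default 10,
#'   about 11 km at native resolution).
#' @return A `simplified_fronts` object: list of polylines (matrices with
#'   columns `x`, `y`, projected km) plus the grid.
#' @export
simplify_fronts <- function(gdens, q = 75, min_length_px = 10) {
  v <- gdens$values
  pos <- v[!is.na(v) & v > 0]
  lines <- list()
  if (length(pos) > 0) {
    thr <- quantile(pos, q / 100)
    mask <- !is.na(v) & v >= thr
    skel <- skeletonize(mask)
    chains <- link_polylines(skel)
    g <- gdens$grid
    for (ch in chains) {
      if (nrow(ch) < 2) next
      arc <- sum(sqrt(diff(ch[, 1])^2 + diff(ch[, 2])^2))
      if (arc < min_length_px) next
      lines[[length(lines) + 1]] <- cbind(
        x = g$origin[1] + (ch[, 2] - 0.5) * g$pixel_km,
        y = g$origin[2] + (ch[, 1] - 0.5) * g$pixel_km
      )
    }
  }
  structure(list(lines = lines, grid = gdens$grid), class = "simplified_fronts")
}

#' @export
print.simplified_fronts <- function(x, ...) {
  cat(sprintf("<simplified_fronts> %d polyline(s), %d vertices\n",
              length(x$lines), sum(vapply(x$lines, nrow, integer(1)))))
  invisible(x)
}

# distance from points to one segment, km
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  l2 <- vx^2 + vy^2
  t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / l2))
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Distance to the closest simplified front (Fdist)
#'
#' Euclidean distance in projected kilometres from each query point to the
#' nearest polyline segment. When the window produced no simplified fronts
#' the metric is missing and dependent records are excluded downstream.
#'
#' @param fronts A `simplified_fronts`.
#' @param x_km,y_km Query coordinates, projected km.
#' @return Numeric vector of distances (km); all `NA` when no fronts exist.
#' @export
compute_fdist <- function(fronts, x_km, y_km) {
  n <- length(x_km)
  if (length(fronts$lines) == 0) return(rep(NA_real_, n))
  best <- rep(Inf, n)
  for (ln in fronts$lines) {
    if (nrow(ln) == 1) {
      best <- pmin(best, sqrt((x_km - ln[1, 1])^2 + (y_km - ln[1, 2])^2))
      next
    }
    for (s in seq_len(nrow(ln) - 1)) {
      best <- pmin(best, dist_point_segment(x_km, y_km, ln[s, 1], ln[s, 2],
                                            ln[s + 1, 1], ln[s + 1, 2]))
    }
  }
  best
}

#' Fdist as a raster
#'
#' @param fronts A `simplified_fronts`.
#' @param grid Grid to evaluate on (defaults to the fronts' grid).
#' @return An [fd_raster()] named `"Fdist"`, km.
#' @export
fdist_raster <- function(fronts, grid = fronts$grid) {
  xc <- grid_x_centers(grid)
  yc <- grid_y_centers(grid)
  vals <- matrix(NA_real_, grid$ny, grid$nx)
  if (length(fronts$lines) > 0) {
    pts <- expand.grid(y = yc, x = xc)
    vals <- matrix(compute_fdist(fronts, pts$x, pts$y), grid$ny, grid$nx)
  }
  fd_raster(vals, grid, "Fdist")
}

#' Seasonal front frequency (Ffreq)
#'
#' Percentage of a pixel's clear (cloud-free) observations across a season's
#' detections, before spatial smoothing, in which the pixel was frontal with
#' a temperature gradient of at least `grad_threshold` degrees C per pixel
#' scale. Pixels never observed clear are missing.
#'
#' @param detections List of `front_detection`s for June-August of one year.
#' @param grad_threshold Minimum frontal gradient counted as a detection,
#'   degC per pixel (default 0.04); compared against gradient * pixel size
#'   so the rule is applied on the temperature-difference scale it is
#'   defined on.
#' @param check_season Validate that all scene dates fall in June-August of
#'   a single year (default TRUE).
#' @return A `seasonal_freq`: `ffreq` [fd_raster()] (percent 0-100), plus
#'   `n_detections` and `n_observations` count rasters.
#' @export
compute_ffreq <- function(detections, grad_threshold = 0.04, check_season = TRUE) {
  stopifnot(length(detections) >= 1)
  grid <- detections[[1]]$grid
  if (check_season) {
    dates <- as.Date(vapply(detections, function(d) as.character(d$date), ""))
    mo <- as.integer(format(dates, "%m"))
    yr <- unique(format(dates, "%Y"))
    if (any(mo < 6 | mo > 8) || length(yr) > 1) {
      stop("compute_ffreq: detections must span June-August of a single year")
    }
  }
  ndet <- matrix(0L, grid$ny, grid$nx)
  nobs <- matrix(0L, grid$ny, grid$nx)
  for (d in detections) {
    nobs <- nobs + d$valid
    hit <- d$frontal & !is.na(d$gradient) &
      (d$gradient * grid$pixel_km) >= grad_threshold
    ndet <- ndet + hit
  }
  ff <- ifelse(nobs > 0, 100 * ndet / pmax(nobs, 1), NA_real_)
  structure(
    list(ffreq = fd_raster(ff, grid, "Ffreq"),
         n_detections = fd_raster(ndet + 0, grid, "n_detections"),
         n_observations = fd_raster(nobs + 0, grid, "n_observations")),
    class = "seasonal_freq"
  )
}

#' Sample a front metric at point locations
#'
#' Nearest-pixel lookup on the raster of the composite centred on the
#' point's date (Gdens, Fdist) or the point's season (Ffreq). Missing raster
#' values (persistent cloud, outside grid, no simplified front) yield `NA`,
#' flagging the record for exclusion from the corresponding model.
#'
#' @param raster An [fd_raster()] (e.g. Gdens, Fdist or Ffreq band).
#' @param x_km,y_km Point coordinates, projected km.
#' @return Numeric vector with `NA` for excluded records.
#' @export
sample_metric <- function(raster, x_km, y_km) {
  raster_sample(raster, x_km, y_km)
}
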