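#' Schedule dives along a simulated track
#'
#' Picks dive start times at daytime, at-sea GPS fixes and draws per-dive
#' truth: shape (U plunge-pursuit mix), maximum depth and active swim-phase
#' duration. Scheduled U dives always receive a swim phase at or above the
#' classification threshold of both logger dialects, so shape truth is
#' unambiguous.
#'
#' @param track A track tibble from [make_track()].
#' @param n_dives Number of dives to schedule.
#' @param p_u Probability a dive is U-shaped (pursuit); default 0.25.
#' @param seed Integer seed.
#' @param min_gap Minimum spacing between dive starts, seconds.
#' @param v_depth_mean,u_depth_mean Mean maximum depths (m) for V and U dives.
#' @param u_swim_range Range (s) of scheduled U swim-phase durations; the
#'   lower bound must be >= 5 s (threshold 4 s at 10 Hz plus one sample).
#' @return A dive schedule tibble: `start_time`, `shape`, `max_depth`,
#'   `swim_phase`.
#' @export
make_dive_schedule <- function(track, n_dives = 20, p_u = 0.25, seed = 1,
                               min_gap = 120, v_depth_mean = 4,
                               u_depth_mean = 6.3, u_swim_range = c(5, 12)) {
  stopifnot(nrow(track) > 0, u_swim_range[1] >= 5)
  colony <- attr(track, "colony")
  at_sea <- track[dist_to_point_km(track$lon, track$lat, colony) > 3, ]
  daytime <- at_sea[solar_elevation(at_sea$time, at_sea$lon, at_sea$lat) > -5, ]
  if (nrow(daytime) < n_dives) {
    stop("make_dive_schedule: not enough daytime at-sea fixes for ", n_dives, " dives")
  }
  with_seed(fd_substream(seed, 303), {
    # greedy spacing: sample candidate fixes until n_dives are >= min_gap apart
    cand <- daytime[sample.int(nrow(daytime)), ]
    keep <- integer()
    for (i in seq_len(nrow(cand))) {
      ti <- as.numeric(cand$time[i])
      if (all(abs(ti - as.numeric(cand$time[keep])) >= min_gap)) keep <- c(keep, i)
      if (length(keep) == n_dives) break
    }
    if (length(keep) < n_dives) {
      stop("make_dive_schedule: could not space ", n_dives, " dives ", min_gap, " s apart")
    }
    sel <- cand[sort(keep), ]
    shape <- ifelse(runif(n_dives) < p_u, "U", "V")
    # depth floor 2.5 m: a dive must spend at least one 1 Hz sample above
    # the 1.5 m recording threshold to be observable by both logger
    # dialects (apex window = (depth - 1.5) * (1/descent + 1/ascent) >= 1 s)
    max_depth <- ifelse(
      shape == "U",
      pmin(14, pmax(2.5, rnorm(n_dives, u_depth_mean, 1.5))),
      pmin(12, pmax(2.5, rgamma(n_dives, shape = 4, scale = v_depth_mean / 4)))
    )
    swim <- ifelse(shape == "U",
                   runif(n_dives, u_swim_range[1], u_swim_range[2]), 0)
  })
  tibble::tibble(
    start_time = sel$time[order(sel$time)],
    shape = shape, max_depth = max_depth, swim_phase = swim
  )
}

#' Simulate a time-depth-recorder trace from a dive schedule
#'
#' Builds a depth time series mixing short V-shaped plunge dives (descent then
#' immediate ascent) and longer U-shaped pursuit dives (descent, a
#' near-constant-depth active phase of the scheduled duration with bounded
#' wobble, ascent), on top of surface noise. Two logger dialects are
#' emulated: `continuous_1Hz` emits the full series at 1 s intervals;
#' `triggered_10Hz` emits 0.1 s samples only while depth exceeds 1.5 m.
#'
#' @param track A track tibble (its time range defines the trace span), or a
#'   length-2 POSIXct giving the span directly.
#' @param schedule Dive schedule tibble from [make_dive_schedule()] (columns
#'   `start_time`, `shape`, `max_depth`, `swim_phase`).
#' @param dialect `"continuous_1Hz"` or `"triggered_10Hz"`.
#' @param seed Integer seed.
#' @param bird_id Identifier stamped on the trace.
#' @param surface_sd Surface noise sd, m (default 0.05).
#' @param sensor_sd Sensor noise added to submerged samples, m.
#' @param descent_rate,ascent_rate Vertical speeds, m/s (defaults 2 and 1.5).
#' @param wobble Half-amplitude of the U-dive bottom-phase depth wobble, m;
#'   must stay below what the swim-phase velocity threshold tolerates.
#' @return A `depth_trace`: tibble (`time`, `depth`) with attributes
#'   `bird_id`, `dialect`, `sampling_interval`, and `truth` (the schedule).
#' @export
make_depth_trace <- function(track, schedule,
                             dialect = c("continuous_1Hz", "triggered_10Hz"),
                             seed = 1, bird_id = NULL, surface_sd = 0.05,
                             sensor_sd = 0.05, descent_rate = 2,
                             ascent_rate = 1.5, wobble = 0.3) {
  dialect <- match.arg(dialect)
  span <- if (inherits(track, "POSIXct")) range(track) else range(track$time)
  if (is.null(bird_id)) {
    bird_id <- if (!inherits(track, "POSIXct") && nrow(track) > 0) track$bird_id[1] else "bird01"
  }
  dt <- if (dialect == "continuous_1Hz") 1 else 0.1

  sch <- schedule[order(schedule$start_time), , drop = FALSE]
  if (nrow(sch) > 0) {
    t0 <- as.numeric(sch$start_time)
    dur <- sch$max_depth / descent_rate + sch$swim_phase + sch$max_depth / ascent_rate
    if (any(t0 < as.numeric(span[1]) | t0 + dur > as.numeric(span[2]))) {
      stop("make_depth_trace: scheduled dives fall outside the track time span")
    }
    if (nrow(sch) > 1 && any(t0[-1] < (t0 + dur + 2)[-nrow(sch)])) {
      stop("make_depth_trace: scheduled dives overlap")
    }
  }

  tt <- seq(as.numeric(span[1]), as.numeric(span[2]), by = dt)
  depth <- numeric(length(tt))
  with_seed(fd_substream(seed, 404), {
    depth <- abs(rnorm(length(tt), 0, surface_sd))
    if (nrow(sch) > 0) {
      for (i in seq_len(nrow(sch))) {
        t0i <- as.numeric(sch$start_time[i])
        td <- sch$max_depth[i] / descent_rate
        tb <- sch$swim_phase[i]
        ta <- sch$max_depth[i] / ascent_rate
        idx <- which(tt >= t0i & tt <= t0i + td + tb + ta)
        rel <- tt[idx] - t0i
        prof <- ifelse(
          rel <= td, rel * descent_rate,
          ifelse(rel <= td + tb, sch$max_depth[i],
                 sch$max_depth[i] - (rel - td - tb) * ascent_rate)
        )
        if (tb > 0) {
          # smooth bounded wobble on the bottom phase, tapering to zero at
          # both ends; vertical speed stays well under the swim-phase
          # detection threshold
          bot <- rel > td & rel <= td + tb
          prof[bot] <- prof[bot] - wobble * sin(pi * (rel[bot] - td) / tb)^2
        }
        depth[idx] <- pmax(depth[idx], prof + rnorm(length(idx), 0, sensor_sd))
      }
    }
  })

  samples <- tibble::tibble(
    time = as.POSIXct(tt, tz = "UTC", origin = "1970-01-01"),
    depth = depth
  )
  if (dialect == "triggered_10Hz") samples <- samples[samples$depth > 1.5, ]

  structure(samples, class = c("depth_trace", class(samples)),
            bird_id = bird_id, dialect = dialect, sampling_interval = dt,
            truth = sch)
}

#' Plot a depth trace
#'
#' @param object A `depth_trace`.
#' @param ... Unused.
#' @return A ggplot with depth increasing downwards.
#' @method autoplot depth_trace
#' @export
autoplot.depth_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Depth (m)",
                  title = paste0(attr(object, "bird_id"), " (", attr(object, "dialect"), ")"))
}
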