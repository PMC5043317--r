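#' Default pipeline configuration
#'
#' All analysis constants in one structure: the colony, projection, the
#' detection/metric thresholds (1.5 m dive depth; 0.4 degC SIED front step;
#' 0.04 degC seasonal frequency gradient; 32 px SIED frames; 5 px Gaussian
#' smoothing; 2 km colony buffer; 10 km / 1 h vessel association; 5
#' pseudo-absences per dive; 95% utilization isopleth) and the synthetic
#' scenario (grid size, trips, dives, noise levels). Round-trips through
#' YAML unchanged.
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    colony = c(-5.467, 51.717), # Grassholm, Celtic Sea
    utm_zone = 30L,
    thresholds = list(
      min_depth = 1.5, dt_front = 0.4, grad_ffreq = 0.04,
      sied_window = 32L, smooth_width = 5, buffer_km = 2,
      vessel_km = 10, vessel_h = 1, n_pseudo = 5L, ud_iso = 0.95
    ),
    sim = list(
      n_birds = 4L, n_trips = 1L, dives_per_bird = 30L, p_u = 0.25,
      grid_n = 192L, pixel_km = 1.1, n_scenes = 7L,
      front_delta_t = 1.2, front_drift = 1.5, sst_noise = 0.05,
      cloud_fraction = 0.25, trip_range_km = 80, trip_range_sd_km = 15,
      n_vessels = 2L, start_date = "2013-07-10"
    ),
    seed = 1L
  )
}

#' Read / write a pipeline configuration
#'
#' @param path File path (YAML).
#' @param config Configuration list.
#' @return `read_config` returns the list; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$colony <- as.numeric(cfg$colony)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write / read an SST scene as long-format CSV
#'
#' Plain-text scene serialization: one row per pixel with `date`, `row`,
#' `col`, `sst`, `cloud`; grid metadata in a header comment is avoided by
#' storing it in a sidecar JSON next to the CSV. Round-trips losslessly.
#'
#' @param scene An `sst_scene`.
#' @param path CSV path; a `<path>.grid.json` sidecar is written beside it.
#' @return `write_scene_csv`: the path, invisibly. `read_scene_csv`: an
#'   `sst_scene`.
#' @export
write_scene_csv <- function(scene, path) {
  g <- scene$grid
  df <- tibble::tibble(
    date = as.character(scene$date),
    row = rep(seq_len(g$ny), times = g$nx),
    col = rep(seq_len(g$nx), each = g$ny),
    sst = as.vector(scene$sst),
    cloud = as.vector(scene$cloud)
  )
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(nx = g$nx, ny = g$ny, pixel_km = g$pixel_km, origin = g$origin,
         utm_zone = g$utm_zone),
    paste0(path, ".grid.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_scene_csv
#' @export
read_scene_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".grid.json"), simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  g <- grid_spec(meta$nx, meta$ny, meta$pixel_km, meta$origin, meta$utm_zone)
  sst <- matrix(NA_real_, g$ny, g$nx)
  cloud <- matrix(FALSE, g$ny, g$nx)
  sst[cbind(df$row, df$col)] <- df$sst
  cloud[cbind(df$row, df$col)] <- df$cloud
  structure(list(sst = sst, cloud = cloud, grid = g, date = as.Date(df$date[1]),
                 truth = NULL),
            class = "sst_scene")
}

#' Export simplified fronts as GeoJSON LineStrings
#'
#' Coordinates are projected kilometres (the analysis plane), recorded in
#' the `crs_note` property.
#'
#' @param fronts A `simplified_fronts`.
#' @param path Output path.
#' @export
write_fronts_geojson <- function(fronts, path) {
  features <- purrr::map(fronts$lines, function(ln) {
    list(type = "Feature",
         properties = list(crs_note = sprintf("UTM zone %d, km", fronts$grid$utm_zone)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(ln)),
                                              function(i) as.numeric(ln[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

record_filter <- function(manifest, stage, rows_in, rows_out) {
  manifest$filters <- dplyr::bind_rows(
    manifest$filters,
    tibble::tibble(stage = stage, rows_in = rows_in, rows_out = rows_out,
                   removed = rows_in - rows_out)
  )
  manifest
}

#' Run the full synthetic pipeline
#'
#' End-to-end orchestration on simulated data with known truth:
#' simulate (SST scenes, bird tracks, depth traces, vessels) -> detect and
#' classify dives -> filter and interpolate tracks, geolocate dives ->
#' front metrics (Gdens, Fdist, Ffreq) -> utilization distribution,
#' pseudo-absences, analysis tables -> mixed-model fits -> summary report.
#' Every filter's in/out row counts are recorded in the manifest, so record
#' conservation can be audited; a fixed seed reproduces every output
#' bitwise.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory for CSV/JSON artifacts, or NULL to skip
#'   writing.
#' @param seed Overrides `config$seed` when given.
#' @param fit_models Fit the mixed models (default TRUE; disable for a
#'   faster data-only run).
#' @return A list: `scenes`, `tracks`, `trips`, `dives`, `metrics`
#'   (rasters), `ud`, `tables`, `fits`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         seed = NULL, fit_models = TRUE) {
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed
  th <- config$thresholds
  sim <- config$sim
  manifest <- list(config = config, filters = tibble::tibble(),
                   completed = character())
  done <- function(stage) manifest$completed <<- c(manifest$completed, stage)

  # --- simulate -----------------------------------------------------------
  grid <- grid_around_colony(config$colony, sim$grid_n, sim$grid_n,
                             sim$pixel_km, config$utm_zone)
  front <- front_geometry(
    curve = function(y_px) sim$grid_n * 0.55 + 8 * sin(y_px / sim$grid_n * 2 * pi),
    delta_t = sim$front_delta_t, transition_width = 0.6,
    drift_per_day = sim$front_drift
  )
  dates <- as.Date(sim$start_date) + seq_len(sim$n_scenes) - 1
  scenes <- purrr::imap(dates, function(d, i) {
    make_sst_scene(grid, front, noise_sd = sim$sst_noise,
                   cloud_fraction = sim$cloud_fraction,
                   seed = fd_substream(seed, 1000 + i), date = d,
                   day_offset = i - 1)
  })

  start0 <- as.POSIXct(paste(sim$start_date, "05:00:00"), tz = "UTC")
  sexes <- rep(c("male", "female"), length.out = sim$n_birds)
  birds <- purrr::map(seq_len(sim$n_birds), function(b) {
    tr <- make_track(config$colony, n_trips = sim$n_trips,
                     trip_shape = list(max_range_km = sim$trip_range_km,
                                       range_sd_km = sim$trip_range_sd_km),
                     seed = fd_substream(seed, 2000 + b),
                     bird_id = sprintf("bird%02d", b),
                     start = start0 + (b - 1) * 3600)
    sch <- make_dive_schedule(tr, n_dives = sim$dives_per_bird, p_u = sim$p_u,
                              seed = fd_substream(seed, 3000 + b))
    dialect <- if (b %% 2 == 1) "continuous_1Hz" else "triggered_10Hz"
    trace <- make_depth_trace(tr, sch, dialect,
                              seed = fd_substream(seed, 4000 + b))
    list(track = tr, schedule = sch, trace = trace, sex = sexes[b],
         dialect = dialect)
  })
  vessels <- if (sim$n_vessels > 0) {
    purrr::map_dfr(seq_len(sim$n_vessels), function(v) {
      tr <- make_track(config$colony, n_trips = 1,
                       trip_shape = list(max_range_km = sim$trip_range_km / 2,
                                         speed_kmh = 10),
                       seed = fd_substream(seed, 5000 + v),
                       bird_id = sprintf("vessel%02d", v), start = start0)
      tr[c("bird_id", "time", "lon", "lat")]
    })
  } else NULL
  done("simulate")

  # --- dives --------------------------------------------------------------
  dives_raw <- purrr::map_dfr(birds, function(b) {
    d <- process_dives(b$trace, min_depth = th$min_depth)
    d$sex <- b$sex
    d
  })
  done("dives")

  # --- tracks -------------------------------------------------------------
  all_fixes <- purrr::map_dfr(birds, function(b) b$track)
  day_fixes <- strip_night(all_fixes)
  manifest <- record_filter(manifest, "strip_night", nrow(all_fixes), nrow(day_fixes))
  sea_fixes <- apply_colony_buffer(day_fixes, config$colony, th$buffer_km)
  manifest <- record_filter(manifest, "colony_buffer", nrow(day_fixes), nrow(sea_fixes))
  trips <- split_trips(day_fixes, config$colony, th$buffer_km)
  trips <- trip_statistics(trips, config$colony)

  dense <- purrr::map_dfr(seq_len(nrow(trips)), function(i) {
    # degenerate micro-trips (a lone fix straying past the buffer) carry no
    # locatable dives and cannot be interpolated
    if (trips$n_fixes[i] < 2) return(tibble::tibble())
    d <- interpolate_track(structure(trips$fixes[[i]], utm_zone = config$utm_zone))
    d$trip_id <- trips$trip_id[i]
    d$bird_id <- trips$bird_id[i]
    d
  })
  located <- purrr::map_dfr(unique(dives_raw$bird_id), function(b) {
    geolocate_dives(dives_raw[dives_raw$bird_id == b, ],
                    dense[dense$bird_id == b, ])
  })
  manifest <- record_filter(manifest, "geolocate", nrow(dives_raw), nrow(located))
  lit <- drop_atypical_night_dives(located)
  manifest <- record_filter(manifest, "night_dives", nrow(located), nrow(lit))
  dives <- match_vessels(lit, vessels, th$vessel_km, th$vessel_h)
  dives$dive_id <- seq_len(nrow(dives))
  done("tracks")

  # --- fronts -------------------------------------------------------------
  detections <- purrr::map(scenes, detect_fronts_sied,
                           window = th$sied_window, dt_threshold = th$dt_front)
  composite <- composite_window(detections, centre_date = stats::median(dates))
  gdens <- compute_gdens(composite, th$smooth_width)
  fronts <- simplify_fronts(gdens)
  fdist <- fdist_raster(fronts, grid)
  ffreq <- compute_ffreq(detections, th$grad_ffreq)$ffreq
  metrics <- list(Gdens = gdens, Fdist = fdist, Ffreq = ffreq)
  done("fronts")

  # --- habitat ------------------------------------------------------------
  ud <- estimate_ud(sea_fixes, config$colony, th$buffer_km, th$ud_iso)
  absences <- sample_pseudo_absences(dives, ud, th$n_pseudo,
                                     seed = fd_substream(seed, 6000))
  tabs <- build_table(dives, absences, metrics)
  for (m in names(tabs$tables)) {
    manifest <- record_filter(manifest, paste0("missing_", m),
                              nrow(dives) + nrow(absences), nrow(tabs$tables[[m]]))
  }
  done("habitat")

  # --- fit ----------------------------------------------------------------
  fits <- NULL
  if (fit_models) {
    fits <- list()
    for (m in names(tabs$tables)) {
      tb <- tabs$tables[[m]]
      tb$bird_id <- factor(tb$bird_id)
      tb$sex <- factor(tb$sex, levels = c("male", "female"))
      fits[[paste0("use_", m)]] <- tryCatch(
        suppressWarnings(fit_binomial_glmm(
          tb, reformulate(c(m, "sex", paste0(m, ":sex")), "response"))),
        error = function(e) structure(list(error = conditionMessage(e)),
                                      class = "fd_fit_error")
      )
    }
    dt <- tabs$dive_table
    dt$bird_id <- factor(dt$bird_id)
    dt$sex <- factor(dt$sex, levels = c("male", "female"))
    fits$duration_v <- tryCatch(
      suppressWarnings(fit_lmm(
        dt[dt$shape == "V" & !is.na(dt$Fdist), ],
        duration ~ Fdist * sex + DecTime + DecTime2)),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "fd_fit_error")
    )
    done("fit")
  }

  report <- summary_report(trips, dives)
  done("report")

  out <- list(scenes = scenes, birds = birds, tracks = all_fixes,
              trips = trips, dives = dives, vessels = vessels,
              detections = detections, metrics = metrics, fronts = fronts,
              ud = ud, absences = absences, tables = tabs$tables,
              dive_table = tabs$dive_table, fits = fits, report = report,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(dives, file.path(out_dir, "dives.csv"))
    readr::write_csv(dplyr::select(trips, -"fixes"),
                     file.path(out_dir, "trips.csv"))
    for (m in names(tabs$tables)) {
      readr::write_csv(tabs$tables[[m]],
                       file.path(out_dir, paste0("table_", m, ".csv")))
    }
    readr::write_csv(report, file.path(out_dir, "report.csv"))
    write_fronts_geojson(fronts, file.path(out_dir, "fronts.geojson"))
    jsonlite::write_json(
      list(config = config, filters = manifest$filters,
           completed = manifest$completed),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}

#' Descriptive summary report of trips and dives
#'
#' The descriptive battery of a tracking campaign: trips per bird, maximum
#' displacement / trip length / duration (mean, SE, range over complete
#' trips), dive counts by sex, dives per trip, percentage of trips with no
#' dives, inter-dive-interval percentages at 5/10/20 min, dive rate,
#' percent time underwater, the U/V split and depth/duration by shape.
#'
#' @param trips Trip table from [trip_statistics()].
#' @param dives Classified, located dive table.
#' @return A long tibble (`statistic`, `value`).
#' @export
summary_report <- function(trips, dives) {
  stat <- function(name, value) tibble::tibble(statistic = name,
                                               value = as.numeric(value))
  out <- list()
  complete <- trips[trips$complete, , drop = FALSE]
  out[[1]] <- stat("n_trips", nrow(trips))
  out[[2]] <- stat("n_complete_trips", nrow(complete))
  out[[3]] <- stat("trips_per_bird_mean",
                   nrow(complete) / max(1, length(unique(trips$bird_id))))
  for (col in c("max_displacement_km", "length_km", "duration_h")) {
    if (nrow(complete) > 0 && col %in% names(trips)) {
      ms <- mean_se(complete[[col]])
      out[[length(out) + 1]] <- stat(paste0(col, "_mean"), ms$mean)
      out[[length(out) + 1]] <- stat(paste0(col, "_se"), ms$se)
      out[[length(out) + 1]] <- stat(paste0(col, "_min"), min(complete[[col]]))
      out[[length(out) + 1]] <- stat(paste0(col, "_max"), max(complete[[col]]))
    }
  }
  ds <- dive_summary(dives, trips)
  ov <- ds$overall
  out[[length(out) + 1]] <- stat("n_dives", ov$n_dives)
  if ("sex" %in% names(dives) && nrow(dives) > 0) {
    out[[length(out) + 1]] <- stat("n_dives_male", sum(dives$sex == "male"))
    out[[length(out) + 1]] <- stat("n_dives_female", sum(dives$sex == "female"))
  }
  if (nrow(ds$per_trip) > 0) {
    per <- ds$per_trip[ds$per_trip$complete, ]
    out[[length(out) + 1]] <- stat("dives_per_trip_mean", mean(per$n_dives))
    out[[length(out) + 1]] <- stat("pct_trips_no_dives",
                                   100 * mean(per$n_dives == 0))
    out[[length(out) + 1]] <- stat("dives_per_hour_mean", mean(per$dives_per_hour))
    out[[length(out) + 1]] <- stat("pct_time_underwater_mean",
                                   mean(per$pct_time_underwater))
  } else if (nrow(dives) == 0) {
    out[[length(out) + 1]] <- stat("pct_trips_no_dives", 100)
  }
  for (col in c("pct_followed_5min", "pct_followed_10min", "pct_followed_20min",
                "pct_u", "pct_v", "mean_depth_u", "mean_depth_v",
                "mean_duration_u", "mean_duration_v")) {
    out[[length(out) + 1]] <- stat(col, ov[[col]])
  }
  dplyr::bind_rows(out)
}
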