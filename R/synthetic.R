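#' Predictor layer specification
#'
#' Describes one gridded predictor layer of a synthetic scene: continuous
#' layers have a value range, categorical layers an integer code set. The
#' spatial correlation length controls the patch size of the generated field.
#'
#' @param name short layer name (e.g. `"LAI"`, `"DTV"`, `"PD_ha"`).
#' @param kind `"continuous"` or `"categorical"`.
#' @param value_range numeric `c(low, high)` for continuous layers.
#' @param codes integer code set for categorical layers.
#' @param correlation_length spatial correlation length in meters (> 0); the
#'   sigma of the Gaussian filter applied to white noise.
#' @return a `layer_spec` object.
#' @export
layer_spec <- function(name, kind = c("continuous", "categorical"),
                       value_range = NULL, codes = NULL,
                       correlation_length = 150) {
  kind <- match.arg(kind)
  if (correlation_length <= 0) stop("correlation_length must be > 0")
  if (kind == "continuous") {
    if (is.null(value_range) || length(value_range) != 2)
      stop("continuous layer needs value_range = c(low, high)")
    if (value_range[1] > value_range[2])
      stop("value_range low must be <= high")
  } else {
    if (is.null(codes) || length(codes) == 0)
      stop("categorical layer needs a non-empty integer code set")
    codes <- as.integer(codes)
  }
  structure(list(name = name, kind = kind, value_range = value_range,
                 codes = codes, correlation_length = correlation_length),
            class = "layer_spec")
}

#' Default layer inventory
#'
#' Nine layers mirroring a typical urban land-use predictor set: leaf area
#' index (LAI), daily traffic volume (DTV), population density per hectare
#' (PD_ha) and building height (BH) as continuous layers; local climate zone
#' (LCZ), land-use class (LUC), building type (BT) and two street-type
#' classifications (street_StEP, street_RBS) as categorical layers.
#'
#' @return list of [layer_spec] objects (4 continuous + 5 categorical).
#' @export
default_layer_specs <- function() {
  # correlation lengths at urban block scale: land-use fields vary over
  # roughly 100-200 m in a European city core
  list(
    layer_spec("LAI", "continuous", c(0, 6), correlation_length = 150),
    layer_spec("DTV", "continuous", c(0, 20000), correlation_length = 100),
    layer_spec("PD_ha", "continuous", c(0, 300), correlation_length = 150),
    layer_spec("BH", "continuous", c(0, 40), correlation_length = 100),
    layer_spec("LCZ", "categorical", codes = 1:9, correlation_length = 200),
    layer_spec("LUC", "categorical", codes = 1:6, correlation_length = 200),
    layer_spec("BT", "categorical", codes = 1:5, correlation_length = 150),
    layer_spec("street_StEP", "categorical", codes = 1:4, correlation_length = 120),
    layer_spec("street_RBS", "categorical", codes = 1:6, correlation_length = 120)
  )
}

#' Ground-truth generative model for synthetic scenes
#'
#' The true concentration at a point is
#' `background + sum(effect_l * standardized(layer_l))` over the active
#' layers, plus a per-round linear drift and Gaussian noise. Raw sensor
#' readings are additionally inflated by the hygroscopic growth factor
#' implied by `kappa_true` and local relative humidity, so preprocessing can
#' recover the dry signal exactly.
#'
#' @param active_layers names of layers that truly drive concentration.
#' @param effect_sizes signed effects, ug/m3 per standardized unit, one per
#'   active layer.
#' @param background_level background concentration, ug/m3 (>= 0).
#' @param noise_sd white measurement noise, ug/m3 (>= 0).
#' @param plume_sd stationary sd of the autocorrelated local-source
#'   component (plumes, passing vehicles) that mobile transects encounter,
#'   ug/m3; reference stations do not see it.
#' @param plume_timescale e-folding time of that component, seconds.
#' @param day_sd day-to-day sd of the regional background shared by all
#'   stations (synoptic variability), ug/m3.
#' @param day_mod_sdlog log-sd of the daily multiplicative modulation of a
#'   station's local-source contribution (traffic-type stations swing more
#'   than background ones).
#' @param drift_per_round linear sensor drift, ug/m3 per round index.
#' @param kappa_true hygroscopicity kappa of the simulated aerosol.
#' @param particle_density particle density rho, g/cm3.
#' @return a `ground_truth` object.
#' @export
ground_truth <- function(active_layers = c("PD_ha", "LAI", "DTV"),
                         effect_sizes = c(PD_ha = 3, LAI = -2.5, DTV = 2.2),
                         background_level = 7,
                         noise_sd = 1,
                         plume_sd = 1.5,
                         plume_timescale = 60,
                         day_sd = 2,
                         day_mod_sdlog = 0.5,
                         drift_per_round = 0.5,
                         kappa_true = 0.4,
                         particle_density = 1.6) {
  stopifnot(length(active_layers) >= 1,
            length(effect_sizes) == length(active_layers),
            noise_sd >= 0, plume_sd >= 0, plume_timescale > 0,
            day_sd >= 0, day_mod_sdlog >= 0,
            background_level >= 0, particle_density > 0,
            kappa_true >= 0)
  names(effect_sizes) <- active_layers
  structure(list(active_layers = active_layers, effect_sizes = effect_sizes,
                 background_level = background_level, noise_sd = noise_sd,
                 plume_sd = plume_sd, plume_timescale = plume_timescale,
                 day_sd = day_sd, day_mod_sdlog = day_mod_sdlog,
                 drift_per_round = drift_per_round, kappa_true = kappa_true,
                 particle_density = particle_density),
            class = "ground_truth")
}

# Gaussian-filtered white noise on an ny x nx grid, filter sigma in cells.
# FFT-based circular convolution: cheap, seedable, no dependencies beyond
# base R; the wrap-around makes the field periodic which is harmless here.
smooth_field <- function(ny, nx, sigma_cells) {
  w <- matrix(stats::rnorm(ny * nx), ny, nx)
  if (sigma_cells <= 0) return(w)
  gy <- stats::dnorm(pmin(0:(ny - 1), ny - (0:(ny - 1))), sd = sigma_cells)
  gx <- stats::dnorm(pmin(0:(nx - 1), nx - (0:(nx - 1))), sd = sigma_cells)
  ker <- outer(gy, gx)
  ker <- ker / sum(ker)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(ker), inverse = TRUE)) / (ny * nx)
  f / stats::sd(as.vector(f))
}

#' Generate predictor grids
#'
#' Continuous layers are smoothed Gaussian random fields linearly mapped into
#' their value range (clipped at the bounds); categorical layers cut a smooth
#' latent field into equal-frequency contiguous patches, one per code.
#' Deterministic for a given seed.
#'
#' @param specs list of [layer_spec]; must be non-empty.
#' @param extent side length of the square scene in meters, origin at (0, 0).
#' @param resolution cell size in meters (> 0); the extent must divide into
#'   at least 40 x 40 cells.
#' @param seed integer seed.
#' @return named list of [lur_grid] objects.
#' @export
generate_grids <- function(specs, extent = 2000, resolution = 12.5,
                           seed = 1) {
  if (length(specs) == 0) stop("empty layer spec list")
  if (resolution <= 0) stop("resolution must be > 0")
  n <- floor(extent / resolution)
  if (n < 40) stop("extent must divide into at least 40 x 40 cells")
  with_seed(seed, {
    grids <- lapply(specs, function(sp) {
      f <- smooth_field(n, n, sp$correlation_length / resolution)
      if (sp$kind == "continuous") {
        lo <- sp$value_range[1]; hi <- sp$value_range[2]
        v <- (lo + hi) / 2 + f * (hi - lo) / 4
        v <- pmin(pmax(v, lo), hi)
        lur_grid(matrix(v, n, n), res = resolution, name = sp$name,
                 kind = "continuous")
      } else {
        k <- length(sp$codes)
        brks <- lur_quantile(as.vector(f), seq(0, 1, length.out = k + 1))
        brks[1] <- -Inf; brks[k + 1] <- Inf
        idx <- findInterval(as.vector(f), brks, rightmost.closed = TRUE,
                            left.open = TRUE)
        idx <- pmin(pmax(idx, 1L), k)
        v <- sp$codes[idx]
        lur_grid(matrix(as.numeric(v), n, n), res = resolution,
                 name = sp$name, kind = "categorical", codes = sp$codes)
      }
    })
    names(grids) <- vapply(specs, `[[`, "", "name")
    grids
  })
}

# Serpentine route polyline inside the lower part of the scene. The route
# deliberately covers only a sub-region (like a measurement campaign
# confined to a few suburbs), while stations are spread over the full
# extent - station validation is then a true spatial transfer.
make_route <- function(extent, spacing = 25, margin = 100, n_legs = 10,
                       y_cover = 0.55) {
  gap <- (y_cover * extent - 2 * margin) / (n_legs - 1)
  pts <- list()
  for (l in seq_len(n_legs)) {
    y <- margin + (l - 1) * gap
    xs <- seq(margin, extent - margin, by = spacing)
    if (l %% 2 == 0) xs <- rev(xs)
    pts[[l]] <- cbind(x = xs, y = y)
  }
  do.call(rbind, pts)
}

# standardization constants per layer, from the full grid
layer_stats <- function(grids) {
  lapply(grids, function(g) {
    v <- as.vector(g$values)
    list(mean = mean(v), sd = max(stats::sd(v), 1e-12))
  })
}

# deterministic layer-driven dry local field at points (no background/noise)
truth_field_at <- function(scene, x, y) {
  out <- numeric(length(x))
  for (nm in scene$truth$active_layers) {
    st <- scene$layer_stats[[nm]]
    z <- (grid_value_at(scene$grids[[nm]], x, y) - st$mean) / st$sd
    out <- out + scene$truth$effect_sizes[[nm]] * z
  }
  out
}

#' Simulate a synthetic measurement scene
#'
#' Builds a complete synthetic campaign on a square scene: predictor grids,
#' a serpentine bicycle route, repeated measurement rounds with sensor drift
#' and humidity-inflated raw readings, and reference-grade station records.
#' All randomness is derived from `seed`; identical inputs give identical
#' scenes.
#'
#' @param specs list of [layer_spec]s; defaults to [default_layer_specs()].
#' @param truth a [ground_truth]; defaults to `ground_truth()`.
#' @param extent square side, meters.
#' @param resolution grid cell size, meters.
#' @param n_rounds number of measurement rounds.
#' @param n_stations number of reference stations.
#' @param n_days length of each station's daily series.
#' @param route_spacing nominal spacing of the designed route, meters.
#' @param route_cover fraction of the scene's y-extent covered by the
#'   serpentine route; 1 covers the whole scene, smaller values confine the
#'   campaign to a sub-region so station validation involves spatial
#'   transfer.
#' @param seed integer seed.
#' @return an object of class `lur_scene` with elements `grids`, `routes`,
#'   `rounds`, `stations`, `truth`, `layer_stats`, `extent`, `seed`.
#' @export
simulate_scene <- function(specs = default_layer_specs(),
                           truth = ground_truth(),
                           extent = 2000, resolution = 12.5,
                           n_rounds = 6, n_stations = 12, n_days = 30,
                           route_spacing = 25, route_cover = 1, seed = 1) {
  nm <- vapply(specs, `[[`, "", "name")
  if (!all(truth$active_layers %in% nm))
    stop("active_layers must be a subset of the layer inventory")
  if (length(truth$active_layers) >= length(nm))
    stop("active_layers must be a strict subset of all layers")
  grids <- generate_grids(specs, extent, resolution, seed = seed)
  scene <- structure(list(grids = grids,
                          routes = list(A = make_route(extent, route_spacing,
                                                       y_cover = route_cover)),
                          rounds = list(), stations = list(),
                          truth = truth, layer_stats = layer_stats(grids),
                          extent = extent, seed = seed),
                     class = "lur_scene")
  scene$rounds <- lapply(seq_len(n_rounds), function(r)
    simulate_round(scene, "A", r, seed = seed + 1000L + r))
  with_seed(seed + 5000L, {
    classes <- rep(c("urban_background", "suburban", "traffic"),
                   length.out = n_stations)
    locs <- cbind(x = runif(n_stations, 100, extent - 100),
                  y = runif(n_stations, 100, extent - 100))
    scene$stations <- lapply(seq_len(n_stations), function(s)
      simulate_station(scene, locs[s, ], days = n_days,
                       station_id = sprintf("ST%02d", s),
                       classification = classes[s],
                       seed = seed + 6000L + s))
  })
  scene
}

#' @export
print.lur_scene <- function(x, ...) {
  cat(sprintf("<lur_scene> %d layers (%s active), %d rounds, %d stations, extent %g m, seed %d\n",
              length(x$grids), paste(x$truth$active_layers, collapse = "+"),
              length(x$rounds), length(x$stations), x$extent, x$seed))
  invisible(x)
}

#' Simulate one measurement round
#'
#' Samples the route at bicycle speed with a fixed logging interval. The true
#' dry concentration is the layer-driven field plus background, per-round
#' drift and Gaussian noise; the raw reading is the dry value multiplied by
#' the kappa-Koehler growth factor at the local relative humidity, so the
#' humidity correction in preprocessing is exactly invertible. Temperature
#' and relative humidity follow smooth diurnal curves.
#'
#' @param scene a `lur_scene`.
#' @param route_id route name within the scene.
#' @param round_index 1-based round number (drives drift).
#' @param logging_interval seconds between samples.
#' @param speed bicycle speed, km/h (<= 15); by default drawn per round
#'   from 10.5-14 km/h, as riding speed varies between rounds.
#' @param start_offset arc-length offset of the first sample, meters; by
#'   default drawn from 0-120 m (rounds never start at exactly the same
#'   spot).
#' @param gps_sd GPS position noise, meters.
#' @param seed integer seed.
#' @return a `data.frame` of class `lur_track` with columns `time`, `x`, `y`,
#'   `pm25_raw`, `temp_c`, `rh_pct`, `round`, `area`.
#' @export
simulate_round <- function(scene, route_id, round_index,
                           logging_interval = 2, speed = NULL,
                           start_offset = NULL, gps_sd = 3,
                           seed = NULL) {
  if (!route_id %in% names(scene$routes))
    stop("unknown route_id: ", route_id)
  if (!is.null(speed) && speed > 15)
    stop("speed exceeds the 15 km/h campaign maximum")
  route <- scene$routes[[route_id]]
  with_seed(seed, {
    if (is.null(speed)) speed <- stats::runif(1, 10.5, 14)
    if (is.null(start_offset)) start_offset <- stats::runif(1, 0, 120)
    step <- speed / 3.6 * logging_interval        # meters per sample
    pos <- resample_polyline(route, step, start = start_offset)
    n <- nrow(pos)
    x <- pos[, 1] + stats::rnorm(n, 0, gps_sd)
    y <- pos[, 2] + stats::rnorm(n, 0, gps_sd)
    e <- grid_extent(scene$grids[[1]])
    x <- pmin(pmax(x, e[1]), e[2]); y <- pmin(pmax(y, e[3]), e[4])
    tsec <- 10 * 3600 + seq_len(n) * logging_interval   # start 10:00
    rh <- 65 + 15 * sin(2 * pi * tsec / 86400 + 4) +
      2 * sin(2 * pi * seq_len(n) / 500)
    rh <- pmin(pmax(rh, 5), 95)
    temp <- 20 + 6 * sin(2 * pi * tsec / 86400 - 2)
    dry <- scene$truth$background_level + truth_field_at(scene, x, y) +
      round_index * scene$truth$drift_per_round +
      stats::rnorm(n, 0, scene$truth$noise_sd) +
      ar1_series(n, scene$truth$plume_sd,
                 exp(-logging_interval / scene$truth$plume_timescale))
    dry <- pmax(dry, 0)
    C <- 1 + (scene$truth$kappa_true / scene$truth$particle_density) /
      (1 / (rh / 100) - 1)
    track <- data.frame(time = tsec, x = x, y = y,
                        pm25_raw = dry * C, temp_c = temp, rh_pct = rh,
                        round = round_index, area = "A")
    class(track) <- c("lur_track", "data.frame")
    track
  })
}

#' Simulate a reference station record
#'
#' Daily series from the same generative model as the mobile rounds but
#' reference-grade: no sensor drift, no humidity inflation and no mobile
#' plume encounters. A day's value is
#' `bg_d + max(L, 0) * m_d + noise`, where `bg_d` is a regional background
#' day series shared by every station of the scene (synoptic variability
#' around `background_level`), `L` the deterministic layer-driven local
#' field at the station, and `m_d` a daily lognormal modulation of the
#' local-source contribution (mean 1). With all stochastic terms switched
#' off the series is constant at `background_level + max(L, 0)`.
#'
#' @param scene a `lur_scene`.
#' @param location numeric `c(x, y)` in meters, inside the grid extent.
#' @param days number of daily values.
#' @param station_id,classification station metadata.
#' @param seed integer seed (station-specific noise; the shared background
#'   day series derives from the scene seed alone).
#' @return a `station_record` list with `station_id`, `location`,
#'   `classification`, `dates`, `pm25`.
#' @export
simulate_station <- function(scene, location, days = 30,
                             station_id = "ST01",
                             classification = "urban_background",
                             seed = NULL) {
  if (!inside_extent(scene$grids[[1]], location[1], location[2]))
    stop("station location outside the grid extent")
  tr <- scene$truth
  # regional background days: shared across stations, synoptic timescale
  bg <- tr$background_level +
    with_seed(scene$seed + 4000L,
              as.numeric(ar1_series(days, tr$day_sd, exp(-1 / 5))))
  local_src <- max(truth_field_at(scene, location[1], location[2]), 0)
  with_seed(seed, {
    m <- if (tr$day_mod_sdlog > 0)
      stats::rlnorm(days, -tr$day_mod_sdlog^2 / 2, tr$day_mod_sdlog)
    else rep(1, days)
    pm <- pmax(bg + local_src * m + stats::rnorm(days, 0, tr$noise_sd), 0)
    structure(list(station_id = station_id,
                   location = c(x = location[[1]], y = location[[2]]),
                   classification = classification,
                   dates = seq_len(days), pm25 = pm),
              class = "station_record")
  })
}

# stationary AR(1) series with marginal sd `s` and lag-1 coefficient `phi`
ar1_series <- function(n, s, phi) {
  if (s <= 0) return(numeric(n))
  e <- stats::rnorm(n, 0, s * sqrt(1 - phi^2))
  e[1] <- stats::rnorm(1, 0, s)
  stats::filter(e, phi, method = "recursive")
}

# resample a polyline to points every `step` meters of arc length
resample_polyline <- function(pts, step, start = 0) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- seq(min(start, total), total, by = step)
  x <- stats::approx(s, pts[, 1], xout = at, ties = "ordered")$y
  y <- stats::approx(s, pts[, 2], xout = at, ties = "ordered")$y
  cbind(x = x, y = y)
}
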