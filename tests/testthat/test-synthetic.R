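test_that("grid generation is deterministic and honours degenerate specs", {
  specs <- list(layer_spec("A", "continuous", c(0, 10), correlation_length = 100),
                layer_spec("Z", "continuous", c(0, 0), correlation_length = 100),
                layer_spec("C", "categorical", codes = 5L, correlation_length = 100))
  g1 <- generate_grids(specs, extent = 600, resolution = 12.5, seed = 7)
  g2 <- generate_grids(specs, extent = 600, resolution = 12.5, seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_grids(specs, extent = 600, resolution = 12.5, seed = 8)
  expect_false(identical(g1$A$values, g3$A$values))
  # degenerate range -> constant zero; single code -> constant code
  expect_true(all(g1$Z$values == 0))
  expect_true(all(g1$C$values == 5))
  # values respect bounds
  expect_true(all(g1$A$values >= 0 & g1$A$values <= 10))
})

test_that("grid generation rejects invalid inputs", {
  expect_error(generate_grids(list(), 600, 12.5), "empty")
  sp <- list(layer_spec("A", "continuous", c(0, 1)))
  expect_error(generate_grids(sp, 600, -5), "resolution")
  expect_error(generate_grids(sp, 100, 12.5), "40 x 40")
  expect_error(layer_spec("A", "continuous", c(2, 1)), "low")
  expect_error(layer_spec("A", "categorical", codes = integer(0)), "non-empty")
  expect_error(layer_spec("A", "continuous", c(0, 1), correlation_length = 0),
               "correlation_length")
})

quiet_truth <- function(...) {
  ground_truth(noise_sd = 0, plume_sd = 0, drift_per_round = 0,
               kappa_true = 0, day_sd = 0, day_mod_sdlog = 0, ...)
}

test_that("round simulation: no-noise limit, drift and hygroscopic growth", {
  scene <- simulate_scene(truth = quiet_truth(), extent = 600, n_rounds = 1,
                          n_stations = 2, seed = 3)
  expect_error(simulate_round(scene, "nope", 1), "unknown route_id")
  expect_error(simulate_round(scene, "A", 1, speed = 16), "15 km/h")

  # identical seeds and kinematics -> identical tracks (determinism)
  r1 <- simulate_round(scene, "A", 1, speed = 12, start_offset = 0,
                       gps_sd = 0, seed = 11)
  r2 <- simulate_round(scene, "A", 1, speed = 12, start_offset = 0,
                       gps_sd = 0, seed = 11)
  expect_identical(r1, r2)

  # drift_per_round = 1: two rounds differ by exactly the drift step
  # (background raised so the non-negativity clamp never bites)
  scene_d <- scene
  scene_d$truth$drift_per_round <- 1
  scene_d$truth$background_level <- 30
  d1 <- simulate_round(scene_d, "A", 1, speed = 12, start_offset = 0,
                       gps_sd = 0, seed = 5)
  d2 <- simulate_round(scene_d, "A", 2, speed = 12, start_offset = 0,
                       gps_sd = 0, seed = 5)
  expect_equal(mean(d2$pm25_raw - d1$pm25_raw), 1, tolerance = 1e-9)

  # kappa_true > 0 inflates every raw reading above the dry signal
  scene_k <- scene
  scene_k$truth$kappa_true <- 0.4
  wet <- simulate_round(scene_k, "A", 1, speed = 12, start_offset = 0,
                        gps_sd = 0, seed = 5)
  dry <- simulate_round(scene, "A", 1, speed = 12, start_offset = 0,
                        gps_sd = 0, seed = 5)
  expect_true(all(wet$pm25_raw >= dry$pm25_raw))
  expect_true(all(wet$pm25_raw[dry$pm25_raw > 0] >
                  dry$pm25_raw[dry$pm25_raw > 0]))
  expect_true(all(wet$rh_pct > 0 & wet$rh_pct < 100))
})

test_that("station simulation honours its deterministic contract", {
  scene <- simulate_scene(truth = quiet_truth(), extent = 600,
                          n_rounds = 1, n_stations = 2, seed = 3)
  expect_error(simulate_station(scene, c(-50, 100)), "outside")
  st <- simulate_station(scene, c(300, 300), days = 10, seed = 1)
  # all stochastic terms off -> constant series
  expect_equal(length(unique(st$pm25)), 1)
  # determinism
  st2 <- simulate_station(scene, c(300, 300), days = 10, seed = 1)
  expect_identical(st$pm25, st2$pm25)
  # scene-level determinism, byte for byte
  sA <- simulate_scene(extent = 600, n_rounds = 2, n_stations = 3, seed = 9)
  sB <- simulate_scene(extent = 600, n_rounds = 2, n_stations = 3, seed = 9)
  expect_identical(sA, sB)
})

test_that("grid CSV round-trips exactly", {
  g <- generate_grids(list(layer_spec("LAI", "continuous", c(0, 6))),
                      extent = 600, resolution = 12.5, seed = 2)$LAI
  f <- tempfile(fileext = ".csv")
  write_grid_csv(g, f)
  g2 <- read_grid_csv(f)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_identical(g2$kind, g$kind)
  unlink(f)
})

test_that("noise-free scenes are recovered end-to-end with R2 >= 0.95", {
  # averaged over three scene draws: per-scene values fluctuate a little
  # with field roughness, the generative signal itself is fully recoverable
  r2 <- vapply(c(21, 42, 77), function(sd) {
    scene <- simulate_scene(truth = quiet_truth(), seed = sd)
    pre <- lapply(scene$rounds, preprocess_track)
    rp <- aggregate_to_route(build_ideal_route(pre), pre)
    rp <- rp[rp$n_contributing > 0, ]
    tab <- build_feature_table(rp, scene$grids)
    sp <- split_table(tab, seed = sd)
    ens <- lur_ensemble(sp$train, seeds = 0:4)
    hov_validate(ens, sp$test)$metrics$r2
  }, 0)
  expect_gte(mean(r2), 0.95)
  expect_true(all(r2 > 0.9))
  # truth bookkeeping for selection scoring
  scene <- simulate_scene(extent = 600, n_rounds = 1, n_stations = 2, seed = 1)
  expect_identical(scene$truth$active_layers, c("PD_ha", "LAI", "DTV"))
})
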