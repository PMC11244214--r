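test_that("correction factor follows the kappa-Koehler closed form", {
  expect_equal(correction_factor(0.5, kappa = 0), 1)
  expect_equal(correction_factor(0.123, kappa = 0), 1)
  # hand evaluation: (0.4/1.6)/(1/0.8 - 1) = 0.25/0.25 = 1 -> C = 2
  expect_equal(correction_factor(0.8, kappa = 0.4, rho = 1.6), 2)
  # dry limit and monotonicity
  expect_lt(correction_factor(1e-6, 0.4, 1.6) - 1, 1e-5)
  rh <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(correction_factor(rh, 0.4, 1.6)) > 0))
  expect_true(all(correction_factor(rh, 0.4, 1.6) >= 1))
  expect_error(correction_factor(0), "inside")
  expect_error(correction_factor(1), "inside")
  expect_error(correction_factor(0.5, kappa = -1), "kappa")
  expect_error(correction_factor(0.5, rho = 0), "rho")
})

test_that("correct_pm divides by C, flags missing RH, is scale-equivariant", {
  tr <- data.frame(time = 1:4, x = 0, y = 0,
                   pm25_raw = c(20, 10, 6, 8),
                   temp_c = 20, rh_pct = c(80, 80, NA, 50),
                   round = 1, area = "A")
  out <- correct_pm(tr, kappa = 0.4, rho = 1.6)
  expect_equal(nrow(out), 3)                      # NA RH dropped
  expect_equal(attr(out, "n_dropped_rh"), 1)
  expect_equal(out$pm25_corrected[1], 10)         # raw 20 at C = 2
  # kappa = 0 -> identity
  id <- correct_pm(tr[-3, ], kappa = 0)
  expect_equal(id$pm25_corrected, id$pm25_raw)
  # scale equivariance
  tr2 <- tr; tr2$pm25_raw <- tr$pm25_raw * 3
  expect_equal(correct_pm(tr2, 0.4, 1.6)$pm25_corrected,
               out$pm25_corrected * 3)
})

test_that("round-trip: humidity-inflated track corrected with true kappa", {
  scene <- simulate_scene(extent = 600, n_rounds = 1, n_stations = 2,
                          seed = 13)
  dry_scene <- scene
  dry_scene$truth$kappa_true <- 0
  wet <- simulate_round(scene, "A", 1, speed = 12, start_offset = 0,
                        gps_sd = 2, seed = 77)
  dry <- simulate_round(dry_scene, "A", 1, speed = 12, start_offset = 0,
                        gps_sd = 2, seed = 77)
  rec <- correct_pm(wet, kappa = scene$truth$kappa_true,
                    rho = scene$truth$particle_density)
  rel <- abs(rec$pm25_corrected - dry$pm25_raw) /
    pmax(abs(dry$pm25_raw), 1e-12)
  expect_lt(max(rel), 1e-9)
})

test_that("trimming matches a sort-based quantile oracle", {
  v <- 1:100
  out <- trim_outliers(v, 0.05)
  q <- c(quantile_oracle(v, 0.05), quantile_oracle(v, 0.95))
  expect_equal(q, c(5.95, 95.05))
  expect_setequal(out, v[v >= q[1] & v <= q[2]])
  expect_length(out, 90)
  # constant series unchanged; zero fraction unchanged
  expect_equal(trim_outliers(rep(3, 25), 0.05), rep(3, 25))
  expect_equal(trim_outliers(v, 0), v)
  expect_error(trim_outliers(1:10, 0.05), "short")
  expect_error(trim_outliers(v, 0.5), "trim_fraction")
  # property: 50 random series against the oracle
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(20:200, 1))
    f <- runif(1, 0, 0.2)
    lo <- quantile_oracle(x, f); hi <- quantile_oracle(x, 1 - f)
    expect_identical(trim_outliers(x, f), x[x >= lo & x <= hi])
  }
})

test_that("temporal median uses tumbling windows with center timestamps", {
  tr <- data.frame(time = seq(0, 118, by = 2), x = 1:60, y = 60:1)
  tr$pm25_corrected <- rep(5, 60)
  out <- temporal_median(tr, 30)
  expect_equal(nrow(out), 4)                      # 60 samples / 15 per window
  expect_equal(out$pm25_corrected, rep(5, 4))    # constant in, constant out
  expect_equal(out$time, c(15, 45, 75, 105))
  # medians are outlier-robust
  tr3 <- data.frame(time = c(0, 2, 4), x = 0, y = 0,
                    pm25_corrected = c(1, 2, 100))
  expect_equal(temporal_median(tr3, 30)$pm25_corrected, 2)
  # short final window kept
  tr4 <- data.frame(time = seq(0, 34, by = 2), x = 0, y = 0,
                    pm25_corrected = 1)
  expect_equal(nrow(temporal_median(tr4, 30)), 2)
  bad <- tr; bad$time[2] <- bad$time[1]
  expect_error(temporal_median(bad, 30), "increasing")
})

test_that("background subtraction is exact and shift-invariant", {
  cs <- subtract_background(rep(4, 10), 0.05)
  expect_equal(cs$background, 4)
  expect_equal(cs$local, rep(0, 10))
  # interpolated 5th percentile of [10,10,10,10,110]
  s <- subtract_background(c(10, 10, 10, 10, 110), 0.05)
  expect_equal(s$background, quantile_oracle(c(10, 10, 10, 10, 110), 0.05))
  expect_equal(s$background, 10)
  expect_equal(s$local, c(0, 0, 0, 0, 100))
  # shift invariance; negatives retained
  set.seed(1)
  x <- rnorm(100)
  a <- subtract_background(x, 0.05)
  b <- subtract_background(x + 7.3, 0.05)
  expect_equal(a$local, b$local, tolerance = 1e-12)
  expect_true(any(a$local < 0))
  expect_error(subtract_background(numeric(0)), "empty")
})

test_that("preprocess_track applies correct -> trim -> median -> subtract", {
  scene <- simulate_scene(extent = 600, n_rounds = 1, n_stations = 2,
                          seed = 5)
  tr <- scene$rounds[[1]]
  out <- preprocess_track(tr)
  # manual reproduction of the stated stage order
  c1 <- correct_pm(tr, 0.4, 1.6)
  kept <- trim_outliers(c1$pm25_corrected, 0.05)
  c2 <- c1[c1$pm25_corrected >= min(kept) & c1$pm25_corrected <= max(kept), ]
  c3 <- temporal_median(c2, 30)
  bg <- subtract_background(c3$pm25_corrected, 0.05)
  expect_equal(out$pm25_local, bg$local, tolerance = 1e-12)
  expect_equal(attr(out, "background"), bg$background)
  rep_counts <- attr(out, "report")
  expect_equal(unname(rep_counts["n_raw"]), nrow(tr))
  expect_equal(unname(rep_counts["n_windows"]), nrow(out))
  # per-round independence: same result whatever other rounds exist
  expect_identical(out, preprocess_track(tr))
})
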