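test_that("the unscrambled sequence reproduces canonical Sobol' points", {
  s <- sobol_sequence(8, 2, scramble = FALSE)
  expect_equal(s[, 1], c(0, 0.5, 0.75, 0.25, 0.375, 0.875, 0.625, 0.125))
  expect_equal(s[, 2], c(0, 0.5, 0.25, 0.75, 0.375, 0.875, 0.125, 0.625))
  # scrambling is seeded and stays in [0, 1)
  a <- sobol_sequence(64, 5, seed = 3)
  b <- sobol_sequence(64, 5, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, sobol_sequence(64, 5, seed = 4)))
  expect_true(all(a >= 0 & a < 1))
  # a digital shift preserves balance: dyadic means stay near 1/2
  expect_true(all(abs(colMeans(a) - 0.5) < 0.05))
  expect_error(sobol_sequence(8, 10000), "direction-number")
})

test_that("Saltelli designs have N*(D+2) rows within bounds", {
  expect_equal(sobol_design_size(2048, 214), 442368L)
  expect_error(sobol_design_size(2000, 214), "2\\^11 = 2048")
  sp1 <- unit_space(1)
  d1 <- saltelli_sample(sp1, N = 8, seed = 1)
  expect_equal(nrow(d1$matrix), 24)                      # 8 * (1 + 2)
  sp <- unit_space(4, lo = -2, hi = 6)
  d <- saltelli_sample(sp, N = 256, seed = 2)
  expect_equal(nrow(d$matrix), 256 * 6)
  expect_true(all(d$matrix >= -2 & d$matrix <= 6))
  # column means near the midpoint
  expect_true(all(abs(colMeans(d$matrix[1:256, ]) - 2) < 3 * 8 / sqrt(12 * 256)))
  # AB_i blocks: column i from B, others from A
  A <- d$matrix[1:256, ]
  B <- d$matrix[256 * 5 + 1:256, ]
  AB2 <- d$matrix[256 * 2 + 1:256, ]
  expect_equal(AB2[, 2], B[, 2])
  expect_equal(AB2[, -2], A[, -2])
  expect_error(saltelli_sample(sp, N = 100), "128")
})

test_that("categorical design columns round half-away and clamp to codes", {
  sp <- unit_space(2, lo = 0, hi = 10)
  sp$kind <- c("continuous", "categorical")
  sp$codes <- list(NULL, c(1L, 3L, 4L))
  d <- saltelli_sample(sp, N = 8, seed = 5)
  d$matrix[, 2] <- c(2.4, 2.6, 2.5, 0.2, 9.9, 3.4, 3.6, 1.49,
                     rep(1, nrow(d$matrix) - 8))
  r <- round_categoricals(d, sp)
  # 2.4 -> 2 -> clamps to 1 (equidistant tie to the smaller code);
  # 2.6 -> 3; 2.5 -> 3 (half away from zero); 0.2 -> 1; 9.9 -> 4
  expect_equal(r$matrix[1:8, 2], c(1, 3, 3, 1, 4, 3, 4, 1))
  expect_true(all(r$matrix[, 2] %in% c(1, 3, 4)))
  # continuous column untouched
  expect_identical(r$matrix[, 1], d$matrix[, 1])
})

test_that("index estimators match a naive-loop oracle to 1e-12", {
  set.seed(6)
  N <- 64; D <- 3
  y <- rnorm(N * (D + 2))
  got <- estimate_indices(y, D, N)
  ora <- indices_oracle(y, D, N)
  expect_equal(got$fos, ora$fos, tolerance = 1e-12)
  expect_equal(got$tos, ora$tos, tolerance = 1e-12)
  expect_error(estimate_indices(y[-1], D, N), "length")
  expect_error(estimate_indices(c(NA, y[-1]), D, N), "finite")
})

test_that("analytic test functions recover their variance decomposition", {
  # constant model: all indices exactly zero
  spc <- unit_space(3)
  dc <- saltelli_sample(spc, N = 64, seed = 1)
  expect_warning(est0 <- estimate_indices(rep(2, nrow(dc$matrix)), 3, 64),
                 "zero")
  expect_identical(est0$fos, numeric(3))
  expect_identical(est0$tos, numeric(3))

  # additive model Y = X1 + X2: FOS ~ TOS ~ (0.5, 0.5)
  spa <- unit_space(2)
  da <- saltelli_sample(spa, N = 1024, seed = 2)
  ya <- da$matrix[, 1] + da$matrix[, 2]
  ea <- estimate_indices(ya, 2, 1024)
  expect_equal(ea$fos, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(ea$tos, c(0.5, 0.5), tolerance = 0.05)
  expect_true(sum(ea$fos) > 0.9 && sum(ea$fos) < 1.1)
  # additivity: no interaction signal
  expect_true(all(abs(ea$tos - ea$fos) < 0.05))

  # pure interaction Y = X1 * X2 on [-1, 1]: FOS ~ 0, TOS ~ 1
  spi <- unit_space(2, lo = -1, hi = 1)
  di <- saltelli_sample(spi, N = 1024, seed = 3)
  yi <- di$matrix[, 1] * di$matrix[, 2]
  ei <- estimate_indices(yi, 2, 1024)
  expect_true(all(abs(ei$fos) < 0.05))
  expect_true(all(ei$tos - ei$fos > 0.1))
  # estimator-noise bound: TOS >= FOS - 0.05 everywhere
  for (e in list(ea, ei)) expect_true(all(e$tos >= e$fos - 0.05))
})

test_that("parameter spaces use observed bounds and drop constants", {
  tab <- make_linear_table(n = 50, p = 3, seed = 8)
  tab$X3 <- 5                                            # constant column
  expect_warning(sp <- build_parameter_space(tab), "constant")
  expect_equal(sp$D, 2L)
  expect_identical(sp$dropped, "X3")
  expect_equal(unname(sp$constants), 5)
  expect_equal(unname(sp$bounds["lo", "X1"]), min(tab$X1))
  expect_equal(unname(sp$bounds["hi", "X1"]), max(tab$X1))
  allc <- tab; allc$X1 <- 1; allc$X2 <- 2
  expect_error(suppressWarnings(build_parameter_space(allc)), "constant")
  # a 220-column table with 6 constant columns leaves D = 214
  big <- as.data.frame(matrix(runif(20 * 220), 20, 220))
  names(big) <- paste0("V", 1:220)
  big[, 1:6] <- 0
  big <- cbind(target = rnorm(20), big)
  class(big) <- c("lur_features", "data.frame")
  expect_warning(spb <- build_parameter_space(big), "6 constant")
  expect_equal(spb$D, 214L)
  expect_equal(sobol_design_size(2048, spb$D), 442368L)
})

test_that("ensemble aggregation averages per-model indices", {
  tab <- make_linear_table(n = 150, p = 3, k_active = 2,
                           betas = c(3, -2), noise = 0.05, seed = 12)
  ens <- lur_ensemble(tab, seeds = 0:1, num_trees = 50)
  sp <- build_parameter_space(tab)
  d <- saltelli_sample(sp, N = 128, seed = 1)
  # single-model ensemble equals that model's indices
  e1 <- ens; e1$models <- ens$models[1]
  s1 <- aggregate_over_ensemble(e1, d)
  y1 <- predict(ens$models[[1]], d$matrix, num.threads = 1)$predictions
  direct <- estimate_indices(y1, d$D, d$N)
  expect_equal(unname(s1$summary$mean_fos), direct$fos, tolerance = 1e-12)
  expect_equal(unname(s1$summary$mean_tos), direct$tos, tolerance = 1e-12)
  # duplicated model: zero across-run spread (same fixed design)
  edup <- ens; edup$models <- ens$models[c(1, 1)]
  sdup <- aggregate_over_ensemble(edup, d, rescramble = FALSE)
  expect_equal(sdup$summary$sd_fos, rep(0, 3), tolerance = 1e-12)
  # informative features dominate
  s2 <- aggregate_over_ensemble(ens, d)
  ord <- order(-s2$summary$mean_fos)
  expect_setequal(s2$summary$feature[ord[1:2]], c("X1", "X2"))
})

test_that("FOS screening applies the strict threshold and street union", {
  fake <- list(summary = data.frame(
    feature = c("A", "B", "C", "street_StEP_cat_max_25"),
    mean_fos = c(0.3, 0.005, 0.01, 0.002),
    mean_tos = c(0.4, 0.01, 0.02, 0.004),
    sd_fos = 0, sd_tos = 0))
  class(fake) <- "sensitivity_result"
  out <- screen_features(fake)
  expect_identical(out$gsa_parsimonious, "A")     # 0.01 boundary excluded
  expect_identical(out$gsa_streets, c("A", "street_StEP_cat_max_25"))
  none <- fake
  none$summary$mean_fos <- c(0.001, 0.001, 0.001, 0.001)
  expect_warning(o2 <- screen_features(none), "empty")
  expect_length(o2$gsa_parsimonious, 0)
})
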