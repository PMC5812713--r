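test_that("stimulus drive follows the aperture and gain rules", {
  grid <- tiny_grid()
  lin <- norm_model(drive_exponent = 1)

  # zero contrast -> all-zero field
  z <- build_stimulus_drive(stimulus_spec(0, 2), grid, lin)
  expect_true(all(z$values == 0))

  # high contrast at centre; far outside the aperture essentially zero
  d <- build_stimulus_drive(stimulus_spec(0.98, 2), grid, lin)
  ic <- which.min(abs(grid$positions))
  expect_equal(d$values[ic, 1], 0.98, tolerance = 1e-3)
  ifar <- which.min(abs(grid$positions - 4))  # diameter*2 from centre
  expect_lt(d$values[ifar, 1], 0.01 * 0.98)
  expect_true(all(d$values >= 0 & d$values <= 1))

  # multiplicative contrast gain (linear drive)
  g <- norm_model(drive_exponent = 1, contrast_gain = 0.5)
  dg <- build_stimulus_drive(stimulus_spec(0.03, 2), grid, g)
  expect_equal(dg$values[ic, 1], 0.015, tolerance = 1e-4)

  # energy drive squares the effective contrast
  sq <- build_stimulus_drive(stimulus_spec(0.5, 2), grid, norm_model())
  expect_equal(sq$values[ic, 1], 0.25, tolerance = 1e-3)

  # stimulus larger than the grid is a hard error naming the extent
  expect_error(build_stimulus_drive(stimulus_spec(0.5, 30), grid, lin),
               "half_extent")
})

test_that("stimulus_spec and norm_model enforce their invariants", {
  expect_error(stimulus_spec(1.5, 2), "0, 1")
  expect_error(stimulus_spec(0.5, -1), "diameter")
  expect_error(norm_model(sup_space_width = 0.2), "broader")
  expect_error(norm_model(sigma = 0), "sigma")
  m <- norm_model(preset = "lorazepam_response_gain")
  expect_equal(m$response_gain, 0.5)
  expect_equal(norm_model(preset = "baseline")$contrast_gain, 1)
})

test_that("pooled_drive matches the brute-force convolution oracle", {
  grid <- tiny_grid(half_extent = 5, spacing = 0.1, n_feature = 6)
  expect_lte(length(grid$positions), 200)
  m <- norm_model(drive_exponent = 1)

  # delta-like input -> Gaussian profile, checked against direct summation
  drv <- build_stimulus_drive(stimulus_spec(0.9, 1, edge_sd = 0.1), grid, m)
  drv$values[] <- 0
  ic <- which.min(abs(grid$positions))
  drv$values[ic, 2] <- 1
  got <- pooled_drive(drv, 0.5, 40)
  want <- oracle_pool(drv, 0.5, 40)
  expect_lt(max(abs(got$values - want)), 1e-10)

  # structured stimulus field
  drv2 <- build_stimulus_drive(stimulus_spec(0.7, 2, edge_sd = 0.3), grid, m)
  got2 <- pooled_drive(drv2, 0.7, 25)
  want2 <- oracle_pool(drv2, 0.7, 25)
  expect_lt(max(abs(got2$values - want2)), 1e-10)

  # all-zero drive stays zero; sum is conserved for compact support
  z <- drv; z$values[] <- 0
  expect_true(all(pooled_drive(z, 0.5, 30)$values == 0))
  expect_equal(sum(pooled_drive(drv2, 0.4, 30)$values), sum(drv2$values),
               tolerance = 1e-3)

  # uniform field maps to itself away from the spatial padding
  u <- drv; u$values[] <- 0.37
  pu <- pooled_drive(u, 0.3, 30)
  interior <- abs(grid$positions) < 3
  expect_equal(unname(pu$values[interior, 1]),
               rep(0.37, sum(interior)), tolerance = 1e-6)

  # kernel wider than the grid is a hard error
  expect_error(pooled_drive(drv2, 10, 30), "kernel")
})

test_that("normalized_response implements R = gain * E / (S + sigma)", {
  grid <- tiny_grid()
  m <- norm_model()
  # zero contrast in, zero response out
  r0 <- normalized_response(stimulus_spec(0, 2), grid, m)
  expect_true(all(r0$values == 0))
  # direct substitution against separately computed E and S
  stim <- stimulus_spec(0.5, 3)
  drv <- build_stimulus_drive(stim, grid, m)
  e <- pooled_drive(drv, m$exc_space_width, m$exc_feature_width)$values
  s <- pooled_drive(drv, m$sup_space_width, m$sup_feature_width)$values
  r <- normalized_response(stim, grid, m)
  expect_equal(r$values, m$response_gain * e / (s + m$sigma),
               tolerance = 1e-12)
  expect_true(all(is.finite(r$values)) && all(r$values >= 0))
  # response gain scales the response field linearly
  m2 <- norm_model(response_gain = 3)
  r2 <- normalized_response(stim, grid, m2)
  expect_equal(r2$values, 3 * r$values, tolerance = 1e-12)
})

test_that("peak responses reproduce the size-contrast interplay", {
  m <- norm_model()
  grid <- spatial_grid(half_extent = 13)
  pk <- function(ct, dm)
    readout_peak(normalized_response(stimulus_spec(ct, dm), grid, m))
  # high contrast: response falls as size grows (suppression)
  expect_gt(pk(0.98, 1), pk(0.98, 2))
  expect_gt(pk(0.98, 2), pk(0.98, 12))
  # low contrast: response rises from 1 to 2 deg (summation)
  expect_lt(pk(0.03, 1), pk(0.03, 2))
})

test_that("readout_peak returns the centre response and flags asymmetry", {
  grid <- tiny_grid()
  m <- norm_model()
  r <- normalized_response(stimulus_spec(0.5, 2), grid, m)
  ic <- which.min(abs(grid$positions))
  expect_identical(readout_peak(r), max(r$values[ic, ]))
  # uniform field -> that value; zero field -> 0
  u <- r; u$values[] <- 0.7
  expect_equal(readout_peak(u), 0.7)
  z <- r; z$values[] <- 0
  expect_equal(readout_peak(z), 0)
  # asymmetric field warns
  a <- r; a$values[1, ] <- a$values[1, ] + 1
  expect_warning(readout_peak(a), "asymmetric")
})

test_that("predicted thresholds follow the criterion rule", {
  expect_equal(predict_threshold(2, 1), 0.5)
  expect_equal(predict_threshold(1, 2), 2.0)
  expect_error(predict_threshold(0, 1), "unresponsive")
  expect_error(predict_threshold(1, -1), "criterion")
  # strictly monotone in both arguments
  expect_gt(predict_threshold(1, 2), predict_threshold(2, 2))
  expect_gt(predict_threshold(1, 3), predict_threshold(1, 2))
})

test_that("the condition table shows suppression at high and summation at low contrast", {
  pred <- predict(norm_model())
  si <- pred$si
  expect_true(all(si$si[si$contrast == 0.98] < 0))
  expect_true(all(si$si[si$contrast == 0.03] > 0))
  expect_equal(nrow(pred$thresholds), 6)
  expect_true(all(pred$thresholds$predicted_threshold_ms > 0))
})

test_that("size indices are invariant to criterion and response-gain scaling", {
  base <- predict(norm_model())
  # doubling every criterion doubles thresholds, SIs bit-identical
  double_c <- predict(norm_model(), criteria = c(4.8, 188))
  expect_identical(base$si$si, double_c$si$si)
  expect_equal(double_c$thresholds$predicted_threshold_ms,
               2 * base$thresholds$predicted_threshold_ms, tolerance = 1e-12)
  # halving response gain doubles thresholds, SIs bit-identical
  half_g <- predict(norm_model(response_gain = 0.5))
  expect_identical(base$si$si, half_g$si$si)
  expect_equal(half_g$thresholds$predicted_threshold_ms,
               2 * base$thresholds$predicted_threshold_ms, tolerance = 1e-12)
})

test_that("summation flips to suppression as sigma shrinks below the suppressive drive", {
  # sweep sigma at low contrast: SI sign goes positive -> negative
  sis <- sapply(c(0.1, 1e-5), function(sg) {
    pred <- predict(norm_model(sigma = sg), contrasts = 0.03)
    pred$si$si[pred$si$pair == "1-12"]
  })
  expect_gt(sis[1], 0)
  expect_lt(sis[2], 0)
})

test_that("model configuration files round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"preset": "lorazepam_response_gain", "model": {"sigma": 0.05}}',
             path)
  m <- read_model_config(path)
  expect_equal(m$sigma, 0.05)
  expect_equal(m$response_gain, 0.5)   # from the preset
  expect_equal(m$sup_space_width, 2)   # package default
  writeLines('{"model": {"nonsense": 1}}', path)
  expect_error(read_model_config(path), "unknown model config")
})
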