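make_axis <- function(n = 2048) seq(-3.33, 12.16, length.out = n)

test_that("artifact rejection applies the mean + 3 SD rule once", {
  expect_true(all(!reject_artifacts(rep(1, 50))))       # SD = 0
  set.seed(11)
  cp <- rnorm(320)
  cp[100] <- mean(cp) + 10 * sd(cp)
  mask <- reject_artifacts(cp)
  expect_length(mask, 320)
  # agrees with direct mean/SD computation
  expect_identical(mask, cp > mean(cp) + 3 * sd(cp))
  expect_true(mask[100])
  expect_error(reject_artifacts(1))
})

test_that("line broadening is a unit-area Lorentzian convolution", {
  x <- make_axis()
  # delta-like peak becomes a Lorentzian of FWHM lb/field ppm
  amp <- numeric(length(x)); amp[1024] <- 1
  sp <- edited_spectrum(x, amp, field_mhz = 127.7)
  out <- line_broaden(sp, lb_hz = 3)
  gam <- (3 / 127.7) / 2
  lor <- gam / (pi * ((x - x[1024])^2 + gam^2))
  lor <- lor / sum(lor)
  expect_lt(max(abs(out$amplitude - lor)), 0.005 * max(lor))
  # total integral conserved within 0.1%
  sp2 <- edited_spectrum(x, 4 * exp(-(x - 3)^2 / (2 * 0.03^2)))
  out2 <- line_broaden(sp2, 3)
  expect_equal(sum(out2$amplitude), sum(sp2$amplitude), tolerance = 1e-3)
  # non-positive lb returns input unchanged with a warning
  expect_warning(same <- line_broaden(sp2, 0), "unchanged")
  expect_identical(same$amplitude, sp2$amplitude)
})

test_that("the GABA+ Gaussian fit recovers closed-form integrals", {
  x <- make_axis()
  truth <- 5 * exp(-(x - 3)^2 / (2 * 0.03^2))
  sp <- edited_spectrum(x, truth)
  g <- fit_gaba_peak(sp)
  expect_true(g$valid)
  expect_equal(g$integral, 5 * 0.03 * sqrt(2 * pi), tolerance = 5e-3)
  expect_equal(g$center, 3, tolerance = 1e-3)
  # linearity: scaling the spectrum scales the integral
  g4 <- fit_gaba_peak(edited_spectrum(x, 4 * truth))
  expect_equal(g4$integral, 4 * g$integral, tolerance = 1e-6)
  # 1% noise: median integral error < 3% over seeds
  errs <- vapply(1:40, function(s) {
    set.seed(600 + s)
    noisy <- truth + rnorm(length(x), sd = 0.05)
    abs(fit_gaba_peak(edited_spectrum(x, noisy))$integral /
          (5 * 0.03 * sqrt(2 * pi)) - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("the broadening-aware fit undoes the pipeline's own Lorentzian", {
  x <- make_axis()
  truth <- 5 * exp(-(x - 3)^2 / (2 * 0.03^2))
  sp <- line_broaden(edited_spectrum(x, truth), 3)
  naive <- fit_gaba_peak(sp)
  aware <- fit_gaba_peak(sp, lb_hz = 3)
  want <- 5 * 0.03 * sqrt(2 * pi)
  expect_lt(abs(aware$integral / want - 1), 0.01)
  # the aware fit must beat the plain Gaussian fit on the broadened line
  expect_lt(abs(aware$integral - want), abs(naive$integral - want))
})

test_that("the water pseudo-Voigt fit identifies the line-shape mixture", {
  x <- make_axis()
  # pure Gaussian water: eta ~ 0, integral within 1%
  g <- 1000 / (0.025 * sqrt(2 * pi)) * exp(-(x - 4.7)^2 / (2 * 0.025^2))
  fg <- fit_water_peak(edited_spectrum(x, g))
  expect_lt(fg$eta, 0.05)
  expect_equal(fg$integral, 1000, tolerance = 0.01)
  # pure Lorentzian water: eta ~ 1
  gam <- sqrt(2 * log(2)) * 0.025
  l <- (1000 / (pi * gam)) * gam^2 / ((x - 4.7)^2 + gam^2)
  fl <- fit_water_peak(edited_spectrum(x, l))
  expect_gt(fl$eta, 0.95)
  expect_equal(fl$integral, 1000, tolerance = 0.03)
  # linearity in overall scale
  f2 <- fit_water_peak(edited_spectrum(x, 2 * g))
  expect_equal(f2$integral, 2 * fg$integral, tolerance = 1e-4)
})

test_that("tissue correction satisfies its closed-form identities", {
  expect_equal(tissue_correct(0.01, 1, 0, 0), 0.01)          # pure gray
  expect_equal(tissue_correct(0.01, 0, 1, 0, alpha = 0.5), 0.02)
  expect_equal(tissue_correct(0.01, 0.6, 0.4, 0, alpha = 1), 0.01)
  # monotone decreasing in gray-matter fraction
  expect_gt(tissue_correct(0.01, 0.3, 0.3, 0.4),
            tissue_correct(0.01, 0.6, 0.3, 0.1))
  expect_error(tissue_correct(0.01, 0, 0, 1), "positive")
  expect_error(tissue_correct(0.01, 0.8, 0.8, 0), "sum")
})

test_that("generated spectra are quantified back to their ground truth", {
  # noise -> 0 limit: ratio equals the generating ratio
  sp0 <- gen_spectrum(noise_sd = 0, seed = 1)
  q0 <- quantify_gaba(sp0, f_gm = 0.6, f_wm = 0.3, f_csf = 0.1)
  expect_true(q0$valid)
  expect_lt(abs(q0$raw_ratio / attr(sp0, "ground_truth")$ratio - 1), 0.01)
  # at 320-average noise, median ratio error stays below 5%
  errs <- vapply(1:40, function(s) {
    sp <- gen_spectrum(seed = 700 + s)
    q <- quantify_gaba(sp, 0.5, 0.4, 0.1)
    abs(q$raw_ratio / attr(sp, "ground_truth")$ratio - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  # corrected value invariant to global spectrum scaling
  sp <- gen_spectrum(seed = 5)
  spk <- sp
  spk$amplitude <- 7 * sp$amplitude
  spk$water_amplitude <- 7 * sp$water_amplitude
  q1 <- quantify_gaba(sp, 0.5, 0.4, 0.1)
  qk <- quantify_gaba(spk, 0.5, 0.4, 0.1)
  expect_equal(qk$corrected, q1$corrected, tolerance = 1e-6)
})

test_that("injected outlier averages are flagged", {
  sp <- gen_spectrum(n_outliers = 2, seed = 13)
  mask <- reject_artifacts(sp$correction_params)
  expect_true(all(attr(sp, "ground_truth")$outlier_idx %in% which(mask)))
  expect_length(sp$ppm, 2048)
})

test_that("rank order of corrected ratios tracks raw ratios across a population", {
  # consistent voxel placement (tissue-fraction SD ~0.03) against ~20%
  # inter-subject spread in the raw ratio: the correction preserves rank
  # order (median Spearman over seeded cohorts)
  n <- 24
  sp <- vapply(1:50, function(s) {
    set.seed(s)
    raw <- exp(rnorm(n, log(0.005), 0.2))
    f_gm <- pmin(pmax(rnorm(n, 0.45, 0.03), 0.35), 0.55)
    f_wm <- pmin(pmax(rnorm(n, 0.33, 0.03), 0.25), 0.42)
    f_csf <- pmax(1 - f_gm - f_wm - runif(n, 0, 0.05), 0)
    cor(raw, tissue_correct(raw, f_gm, f_wm, f_csf), method = "spearman")
  }, numeric(1))
  expect_gt(median(sp), 0.9)
})

test_that("spectrum CSV + sidecar round-trip preserves the data", {
  sp <- gen_spectrum(seed = 3)
  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(ppm = sp$ppm, amplitude = sp$amplitude),
                   file.path(dir, "diff.csv"), row.names = FALSE)
  utils::write.csv(data.frame(ppm = sp$ppm, amplitude = sp$water_amplitude),
                   file.path(dir, "water.csv"), row.names = FALSE)
  jsonlite::write_json(list(field_mhz = 127.7,
                            correction_params = sp$correction_params,
                            f_gm = 0.5, f_wm = 0.4, f_csf = 0.1),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  back <- read_spectrum_csv(file.path(dir, "diff.csv"),
                            file.path(dir, "water.csv"),
                            file.path(dir, "meta.json"))
  expect_equal(back$amplitude, sp$amplitude, tolerance = 1e-9)
  expect_equal(back$water_amplitude, sp$water_amplitude, tolerance = 1e-9)
  expect_equal(back$correction_params, sp$correction_params,
               tolerance = 1e-9)
  expect_equal(attr(back, "tissue")$f_gm, 0.5)
  q <- quantify_gaba(back, 0.5, 0.4, 0.1)
  expect_true(q$valid)
})
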