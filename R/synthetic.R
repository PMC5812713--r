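#' Simulated 2AFC observer
#'
#' Builds an observer function whose accuracy follows the fixed-guess,
#' fixed-lapse Weibull psychometric function, with the scale chosen per
#' condition so that accuracy is exactly 80% at the specified true threshold
#' (typically thresholds predicted by the normalization model).
#'
#' @param condition_thresholds Named numeric vector mapping condition labels
#'   to true 80%-correct duration thresholds in ms (> 0).
#' @param slope_beta Weibull shape shared across conditions (default 3).
#' @param guess,lapse Fixed guess and lapse rates.
#' @return A function `observer(duration, condition)` returning P(correct);
#'   the per-condition Weibull scales are attached as attribute `"alpha"`.
#' @export
gen_observer <- function(condition_thresholds, slope_beta = 3,
                         guess = 0.5, lapse = 0.04) {
  stopifnot(is.numeric(condition_thresholds),
            !is.null(names(condition_thresholds)),
            all(condition_thresholds > 0), slope_beta > 0)
  alphas <- alpha_for_threshold(condition_thresholds, slope_beta,
                                0.8, guess, lapse)
  obs <- function(duration, condition) {
    if (!condition %in% names(alphas))
      stop("unknown condition '", condition, "'")
    weibull_p_correct(duration, alphas[[condition]], slope_beta,
                      guess, lapse)
  }
  attr(obs, "alpha") <- alphas
  obs
}

#' Condition labels used throughout the package
#'
#' @param contrasts Contrast fractions.
#' @param sizes Diameters in degrees.
#' @return Character vector like `"c3_d1"` (contrast percent, diameter).
#' @export
condition_label <- function(contrasts, sizes) {
  paste0("c", round(contrasts * 100), "_d", sizes)
}

#' Simulated subject population with a GABA-performance correlation
#'
#' Draws per-subject overall ability and GABA+ level from a bivariate normal
#' on (log threshold scale, GABA) with correlation
#' `rho_gaba_performance` between GABA+ and the log geometric-mean threshold
#' (negative = more GABA+, better performance). Each subject's per-condition
#' true thresholds are the model-predicted thresholds scaled by the
#' subject's ability factor; because size indices are invariant to that
#' common scaling, GABA+ relates to overall performance but not to
#' suppression strength, by construction.
#'
#' @param n_subjects Number of subjects (default 22).
#' @param model A [norm_model()]; its predicted condition thresholds form
#'   the population mean.
#' @param sizes,contrasts,criteria Passed to [predict.norm_model()].
#' @param between_subject_sd SD of the per-subject log-threshold scaling
#'   (default 0.15, about 16% between-subject spread).
#' @param gaba_mean,gaba_sd GABA+ population mean and SD in institutional
#'   units (defaults 1 and 0.15).
#' @param rho_gaba_performance Correlation between GABA+ and log
#'   geometric-mean threshold (default -0.46).
#' @param drug_effect_profile Optional named vector of additive
#'   log10-threshold shifts per condition (the lorazepam arm; largest for
#'   the smallest sizes).
#' @param seed Optional integer seed.
#' @return Data frame (one row per subject: `subject`, `gaba`, `ability`,
#'   one `true_<condition>` column per condition) with the generating
#'   parameters attached as attribute `"ground_truth"`.
#' @export
gen_population <- function(n_subjects = 22, model = norm_model(),
                           sizes = c(1, 2, 12), contrasts = c(0.03, 0.98),
                           criteria = NULL, between_subject_sd = 0.15,
                           gaba_mean = 1, gaba_sd = 0.15,
                           rho_gaba_performance = -0.46,
                           drug_effect_profile = NULL, seed = NULL) {
  stopifnot(n_subjects >= 2, abs(rho_gaba_performance) <= 1,
            between_subject_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  pred <- predict(model, sizes = sizes, contrasts = contrasts,
                  criteria = criteria)
  th <- pred$thresholds
  labels <- condition_label(th$contrast, th$diameter_deg)
  base <- stats::setNames(th$predicted_threshold_ms, labels)
  rho <- rho_gaba_performance
  z1 <- stats::rnorm(n_subjects)           # log-ability axis
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_subjects)
  ability <- exp(between_subject_sd * z1)  # multiplies all thresholds
  gaba <- gaba_mean + gaba_sd * z2
  out <- data.frame(subject = sprintf("S%02d", seq_len(n_subjects)),
                    gaba = gaba, ability = ability)
  for (lab in labels) {
    v <- base[[lab]] * ability
    if (!is.null(drug_effect_profile) && lab %in%
        names(drug_effect_profile))
      v <- v * 10^drug_effect_profile[[lab]]
    out[[paste0("true_", lab)]] <- v
  }
  attr(out, "ground_truth") <- list(base_thresholds = base,
                                    rho_gaba_performance = rho,
                                    between_subject_sd = between_subject_sd,
                                    gaba_mean = gaba_mean, gaba_sd = gaba_sd,
                                    drug_effect_profile = drug_effect_profile)
  out
}

#' Simulate a full psychophysical experiment
#'
#' For each subject and run, six Psi staircases (one per size x contrast
#' condition) are interleaved in randomized condition order, 30 trials each,
#' plus 10 catch trials (big high-contrast stimulus at the 333 ms domain
#' maximum) answered correctly at a fixed high rate. One run therefore
#' contains 6 x 30 + 10 = 190 trials.
#'
#' @param population Subject table from [gen_population()].
#' @param n_runs Runs per subject (default 4).
#' @param n_trials Staircase trials per condition per run (default 30).
#' @param n_catch Catch trials per run (default 10).
#' @param catch_p Probability correct on catch trials (default 0.99).
#' @param slope_beta Observer Weibull shape (default 3).
#' @param seed Optional integer seed.
#' @return Data frame of trials with columns `subject`, `run`,
#'   `condition_contrast_pct`, `condition_diameter_deg`, `trial_index`,
#'   `duration_ms`, `correct`, `is_catch`.
#' @export
gen_experiment <- function(population, n_runs = 4, n_trials = 30,
                           n_catch = 10, catch_p = 0.99, slope_beta = 3,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond_cols <- grep("^true_", names(population), value = TRUE)
  labels <- sub("^true_", "", cond_cols)
  parse_lab <- function(lab) {
    m <- regmatches(lab, regexec("^c([0-9.]+)_d([0-9.]+)$", lab))[[1]]
    c(contrast_pct = as.numeric(m[2]), diameter = as.numeric(m[3]))
  }
  meta <- vapply(labels, parse_lab, numeric(2))
  catch_lab <- labels[which.max(meta["contrast_pct", ] *
                                  meta["diameter", ])]
  template <- psi_init()
  res <- vector("list", nrow(population) * n_runs)
  k <- 0L
  for (si in seq_len(nrow(population))) {
    ths <- stats::setNames(as.numeric(population[si, cond_cols]), labels)
    obs <- gen_observer(ths, slope_beta = slope_beta)
    for (run in seq_len(n_runs)) {
      states <- stats::setNames(replicate(length(labels),
                                          psi_reset(template),
                                          simplify = FALSE), labels)
      order_vec <- sample(rep(labels, n_trials))
      catch_pos <- sort(sample.int(length(order_vec) + n_catch, n_catch))
      n_total <- length(order_vec) + n_catch
      rows <- data.frame(trial_index = seq_len(n_total),
                         condition = NA_character_,
                         duration_ms = NA_real_, correct = NA,
                         is_catch = FALSE)
      ci <- 1L
      for (t in seq_len(n_total)) {
        if (t %in% catch_pos) {
          rows$condition[t] <- catch_lab
          rows$duration_ms[t] <- 333
          rows$correct[t] <- stats::runif(1) < catch_p
          rows$is_catch[t] <- TRUE
        } else {
          lab <- order_vec[ci]; ci <- ci + 1L
          d <- psi_select(states[[lab]])
          r <- stats::runif(1) < obs(d, lab)
          states[[lab]] <- psi_update(states[[lab]], d, r)
          rows$condition[t] <- lab
          rows$duration_ms[t] <- d
          rows$correct[t] <- r
        }
      }
      k <- k + 1L
      res[[k]] <- data.frame(subject = population$subject[si], run = run,
                             condition_contrast_pct =
                               meta["contrast_pct", rows$condition],
                             condition_diameter_deg =
                               meta["diameter", rows$condition],
                             rows[, c("trial_index", "duration_ms",
                                      "correct", "is_catch")])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t Time in seconds.
#' @return HRF values, scaled to a peak of 1.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(stats::dgamma(0:30, shape = 6, scale = 1) -
            stats::dgamma(0:30, shape = 16, scale = 1) / 6)
}

#' Simulate a blocked BOLD run
#'
#' Alternating small/large stimulus blocks (small first: 13 small, 12 large
#' by default, 10 s each at TR = 2 s, 125 samples), each block type with its
#' own percent-signal amplitude. The block boxcar is convolved with the
#' canonical double-gamma HRF, scaled onto a positive baseline, and white
#' noise is added. Onsets of the large blocks are annotated for the
#' surround-suppression analysis.
#'
#' @param amplitudes Named vector `c(small = , big = )` of block response
#'   amplitudes in percent signal change.
#' @param noise_sd White-noise SD in scanner units (default 0.5, i.e. 0.5%
#'   of the default baseline of 100).
#' @param tr_s Repetition time (default 2 s).
#' @param n_blocks Total block count (default 25).
#' @param block_duration_s Block duration (default 10 s).
#' @param baseline Mean signal level in scanner units (default 100).
#' @param seed Optional integer seed.
#' @return A [roi_timecourse()] whose `block_onsets` mark the big blocks;
#'   the generating amplitudes are attached as attribute `"ground_truth"`.
#' @export
gen_bold_run <- function(amplitudes = c(small = 1, big = 0.8),
                         noise_sd = 0.5, tr_s = 2, n_blocks = 25,
                         block_duration_s = 10, baseline = 100,
                         seed = NULL) {
  stopifnot(all(is.finite(amplitudes)), noise_sd >= 0,
            all(c("small", "big") %in% names(amplitudes)))
  if (!is.null(seed)) set.seed(seed)
  spb <- round(block_duration_s / tr_s)
  n <- n_blocks * spb
  types <- rep(rep_len(c("small", "big"), n_blocks), each = spb)
  box <- unname(amplitudes[types])
  hrf <- canonical_hrf(seq(0, 30, by = tr_s))
  resp <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n)]
  resp <- resp / sum(hrf)  # unit-gain: a sustained block plateaus at its amplitude
  signal <- baseline * (1 + resp / 100) +
    stats::rnorm(n, sd = noise_sd)
  big_onsets <- (which(rep_len(c("small", "big"), n_blocks) == "big") - 1) *
    spb + 1
  ts <- roi_timecourse(signal, tr_s = tr_s, block_onsets = big_onsets,
                       block_duration_s = block_duration_s)
  attr(ts, "ground_truth") <- list(amplitudes = amplitudes,
                                   noise_sd = noise_sd,
                                   true_contrast = unname(amplitudes["big"] -
                                                            amplitudes["small"]))
  ts
}

#' Simulate an edited MRS spectrum with water reference
#'
#' A 2048-point axis spanning the 2 kHz spectral width, carrying a Gaussian
#' GABA+ peak at 3.0 ppm with a specified area, a pseudo-Voigt water
#' resonance at 4.7 ppm, and white noise whose SD scales as
#' `1 / sqrt(n_averages)`. Per-average frequency-correction magnitudes are
#' drawn, with optional injected outliers that the 3-SD rule should flag.
#'
#' @param gaba_area,water_area True peak areas (amplitude x ppm), > 0.
#' @param gaba_sd_ppm GABA+ Gaussian SD (default 0.03 ppm).
#' @param water_width_ppm Water Gaussian-SD-equivalent width (default
#'   0.025 ppm).
#' @param water_eta Lorentzian fraction of the water line (default 0.3).
#' @param noise_sd Per-average noise SD in amplitude units (default 20).
#' @param n_averages Number of averages (default 320).
#' @param n_points Spectral points (default 2048).
#' @param spectral_width_hz Acquisition bandwidth (default 2000 Hz).
#' @param field_mhz Spectrometer frequency (default 127.7 MHz).
#' @param n_outliers Number of corrupted averages whose correction
#'   magnitudes are pushed far above the population (default 0).
#' @param seed Optional integer seed.
#' @return An [edited_spectrum()] with attribute `"ground_truth"` holding
#'   the true areas and their ratio.
#' @export
gen_spectrum <- function(gaba_area = 5, water_area = 1000,
                         gaba_sd_ppm = 0.03, water_width_ppm = 0.025,
                         water_eta = 0.3, noise_sd = 20, n_averages = 320,
                         n_points = 2048, spectral_width_hz = 2000,
                         field_mhz = 127.7, n_outliers = 0, seed = NULL) {
  stopifnot(gaba_area > 0, water_area > 0, noise_sd >= 0, n_averages >= 1)
  if (!is.null(seed)) set.seed(seed)
  span <- spectral_width_hz / field_mhz
  ppm <- seq(4.5 - span / 2, 4.5 + span / 2, length.out = n_points)
  eff_noise <- noise_sd / sqrt(n_averages)
  gaba_amp <- gaba_area / (gaba_sd_ppm * sqrt(2 * pi))
  amplitude <- gaba_amp * exp(-(ppm - 3.0)^2 / (2 * gaba_sd_ppm^2)) +
    stats::rnorm(n_points, sd = eff_noise)
  s2l <- sqrt(2 * log(2))
  gam <- s2l * water_width_ppm
  unit_area <- water_eta * pi * gam +
    (1 - water_eta) * water_width_ppm * sqrt(2 * pi)
  water_amp <- water_area / unit_area
  water <- water_amp * (water_eta * gam^2 / ((ppm - 4.7)^2 + gam^2) +
                          (1 - water_eta) *
                            exp(-(ppm - 4.7)^2 /
                                  (2 * water_width_ppm^2))) +
    stats::rnorm(n_points, sd = eff_noise)
  cp <- abs(stats::rnorm(n_averages, mean = 1, sd = 0.2))
  if (n_outliers > 0) {
    idx <- sample.int(n_averages, n_outliers)
    cp[idx] <- mean(cp) + 8 * stats::sd(cp)
  }
  sp <- edited_spectrum(ppm, amplitude, water_amplitude = water,
                        correction_params = cp, field_mhz = field_mhz)
  attr(sp, "ground_truth") <- list(gaba_area = gaba_area,
                                   water_area = water_area,
                                   ratio = gaba_area / water_area,
                                   outlier_idx = if (n_outliers > 0) idx
                                                 else integer(0))
  sp
}

#' Simulate experiments from a fitted normalization model
#'
#' `simulate()` on a [norm_model()] draws complete psychophysical
#' experiments: a subject population whose true thresholds come from the
#' model, interrogated by interleaved Psi staircases.
#'
#' @param object A [norm_model()].
#' @param nsim Number of subjects (default 1).
#' @param seed Optional integer seed.
#' @param n_runs Runs per subject.
#' @param ... Passed to [gen_population()].
#' @return Trial data frame from [gen_experiment()], with the population
#'   table attached as attribute `"population"`.
#' @export
simulate.norm_model <- function(object, nsim = 1, seed = NULL,
                                n_runs = 4, ...) {
  if (!is.null(seed)) set.seed(seed)
  pop <- gen_population(n_subjects = max(nsim, 2), model = object, ...)
  pop <- pop[seq_len(nsim), , drop = FALSE]
  trials <- gen_experiment(pop, n_runs = n_runs)
  attr(trials, "population") <- pop
  trials
}

#' Read / write trial logs
#'
#' Trial CSVs use the columns written by [gen_experiment()].
#'
#' @param path File path.
#' @return `read_trials_csv`: the trial data frame.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "run", "condition_contrast_pct",
            "condition_diameter_deg", "trial_index", "duration_ms",
            "correct", "is_catch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial CSV is missing columns: ",
                         paste(miss, collapse = ", "))
  df$correct <- as.logical(df$correct)
  df$is_catch <- as.logical(df$is_catch)
  df
}

#' @rdname read_trials_csv
#' @param trials Trial data frame.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Fit per-run thresholds from a trial log
#'
#' Fits a Weibull to each (subject, run, condition) cell of staircase trials
#' (catch trials excluded), then combines run-level thresholds into a
#' subject-level threshold per condition by geometric mean over
#' non-excluded runs.
#'
#' @param trials Trial data frame (see [gen_experiment()]).
#' @return List with `runs` (per-run fits: subject, run, contrast_pct,
#'   diameter_deg, alpha, beta, threshold80_ms, excluded) and `subjects`
#'   (subject, contrast_pct, diameter_deg, threshold_ms, n_runs_used).
#' @export
fit_trials <- function(trials) {
  tr <- trials[!trials$is_catch, ]
  key <- interaction(tr$subject, tr$run, tr$condition_contrast_pct,
                     tr$condition_diameter_deg, drop = TRUE)
  runs <- do.call(rbind, lapply(split(tr, key), function(d) {
    f <- fit_weibull(d$duration_ms, d$correct)
    data.frame(subject = d$subject[1], run = d$run[1],
               contrast_pct = d$condition_contrast_pct[1],
               diameter_deg = d$condition_diameter_deg[1],
               alpha = f$alpha, beta = f$beta,
               threshold80_ms = f$threshold80, excluded = f$excluded)
  }))
  rownames(runs) <- NULL
  ok <- runs[!runs$excluded, ]
  skey <- interaction(ok$subject, ok$contrast_pct, ok$diameter_deg,
                      drop = TRUE)
  subjects <- do.call(rbind, lapply(split(ok, skey), function(d) {
    data.frame(subject = d$subject[1], contrast_pct = d$contrast_pct[1],
               diameter_deg = d$diameter_deg[1],
               threshold_ms = geometric_mean_threshold(d$threshold80_ms),
               n_runs_used = nrow(d))
  }))
  rownames(subjects) <- NULL
  list(runs = runs, subjects = subjects)
}
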