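#' Stimulus specification
#'
#' Describes a drifting sinusoidal grating presented in a circular window with
#' a Gaussian-blurred edge, the physical input to the normalization model.
#'
#' @param contrast Michelson contrast as a fraction of maximum luminance
#'   modulation, in `[0, 1]`. Percent values are not accepted here; divide by
#'   100 on ingest.
#' @param diameter Stimulus diameter in degrees of visual angle (> 0).
#' @param edge_sd Standard deviation, in degrees, of the Gaussian blur applied
#'   to the aperture edge. Default 0.25 deg.
#' @param spatial_frequency Carrier spatial frequency in cycles/degree.
#'   Metadata only; the one-dimensional spatial model does not render the
#'   carrier.
#'
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(contrast, diameter, edge_sd = 0.25,
                          spatial_frequency = 1) {
  stopifnot(is.numeric(contrast), length(contrast) == 1L,
            is.numeric(diameter), length(diameter) == 1L)
  if (contrast < 0 || contrast > 1)
    stop("`contrast` must lie in [0, 1] (got ", contrast,
         "); percent values must be divided by 100 on ingest")
  if (diameter <= 0) stop("`diameter` must be > 0")
  if (edge_sd < 0) stop("`edge_sd` must be >= 0")
  structure(list(contrast = contrast, diameter = diameter,
                 edge_sd = edge_sd, spatial_frequency = spatial_frequency),
            class = "stimulus_spec")
}

#' Divisive normalization model of visual cortical responses
#'
#' Constructs a steady-state divisive-normalization model in which the
#' response at each point of a (space x motion-direction) population is the
#' excitatory drive divided by a spatially and feature-wise broader
#' suppressive drive plus a semi-saturation constant:
#' \deqn{R = g_r \, E / (S + \sigma)}
#' E and S are the stimulus drive pooled with unit-area Gaussian kernels; the
#' suppressive kernels are broader than the excitatory ones, which is the
#' single assumption that produces spatial suppression at high contrast. At
#' low contrast the suppressive drive is small relative to \eqn{\sigma} and
#' the same model produces spatial summation. Predicted duration thresholds
#' follow from the winner-take-all readout via `threshold = criterion / R`.
#'
#' Gain variants model pharmacological manipulations: `contrast_gain` (with an
#' optional exponent > 1 for a compounded, exponential reduction of input
#' gain) scales the effective stimulus contrast; `response_gain` scales the
#' output; `criterion` shifts all predicted thresholds without touching size
#' indices.
#'
#' @param sigma Semi-saturation constant (dimensionless response units, > 0).
#'   Controls sensitivity at low input strength; summation at a given contrast
#'   requires sigma within roughly two orders of magnitude of that contrast.
#' @param exc_space_width Spatial pooling SD of the excitatory drive, degrees.
#' @param sup_space_width Spatial pooling SD of the suppressive drive,
#'   degrees; must exceed `exc_space_width`.
#' @param exc_feature_width,sup_feature_width Feature (motion-direction)
#'   pooling SDs in degrees of direction; suppressive >= excitatory.
#' @param drive_exponent Accelerating nonlinearity of the stimulus drive
#'   (default 2, the contrast-energy form standard in divisive-normalization
#'   models of visual cortex); the drive is
#'   `((contrast * contrast_gain)^contrast_gain_exponent)^drive_exponent`.
#' @param contrast_gain Multiplicative factor on input contrast (> 0).
#' @param contrast_gain_exponent Exponent applied to the gain-scaled contrast;
#'   values > 1 implement the compounded input-gain reduction variant.
#' @param response_gain Multiplicative factor on the model response (> 0).
#' @param criterion Accumulated-response value required for a perceptual
#'   decision, in ms x response units; `predict()` accepts per-contrast
#'   overrides.
#' @param preset Optional named parameter set: `"baseline"`,
#'   `"lorazepam_contrast_gain"`, `"lorazepam_response_gain"`, or
#'   `"criterion_shift"`. Explicit arguments override preset values.
#'
#' @return An object of class `norm_model`.
#' @seealso [predict.norm_model()], [normalized_response()], [readout_peak()]
#' @examples
#' m <- norm_model()
#' pred <- predict(m, sizes = c(1, 2, 12), contrasts = c(0.03, 0.98))
#' pred$si
#' @export
norm_model <- function(sigma = 0.03,
                       exc_space_width = 0.4,
                       sup_space_width = 2,
                       exc_feature_width = 30,
                       sup_feature_width = 100,
                       drive_exponent = 2,
                       contrast_gain = 1,
                       contrast_gain_exponent = 1,
                       response_gain = 1,
                       criterion = 94,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("baseline", "lorazepam_contrast_gain",
                                  "lorazepam_response_gain", "criterion_shift"))
    mods <- switch(preset,
      baseline = list(),
      # input-gain reduction, compounded across processing stages
      lorazepam_contrast_gain = list(contrast_gain = 0.5,
                                     contrast_gain_exponent = 1.25),
      # overall scaling-down of predicted responses
      lorazepam_response_gain = list(response_gain = 0.5),
      # lower criterion: faster decisions, size indices untouched
      criterion_shift = list(criterion = 47))
    supplied <- names(as.list(match.call())[-1])
    for (nm in setdiff(names(mods), supplied))
      assign(nm, mods[[nm]])
  }
  stopifnot(sigma > 0, exc_space_width > 0, sup_space_width > 0,
            exc_feature_width > 0, sup_feature_width > 0,
            drive_exponent > 0, contrast_gain > 0,
            contrast_gain_exponent > 0, response_gain > 0, criterion > 0)
  if (sup_space_width <= exc_space_width)
    stop("suppressive spatial pooling must be broader than excitatory ",
         "(sup_space_width > exc_space_width)")
  if (sup_feature_width < exc_feature_width)
    stop("suppressive feature pooling must be at least as broad as excitatory")
  structure(list(sigma = sigma,
                 exc_space_width = exc_space_width,
                 sup_space_width = sup_space_width,
                 exc_feature_width = exc_feature_width,
                 sup_feature_width = sup_feature_width,
                 drive_exponent = drive_exponent,
                 contrast_gain = contrast_gain,
                 contrast_gain_exponent = contrast_gain_exponent,
                 response_gain = response_gain,
                 criterion = criterion,
                 preset = if (is.null(preset)) "baseline" else preset),
            class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat("Divisive normalization model (preset: ", x$preset, ")\n", sep = "")
  cat(sprintf("  R = %.3g * E / (S + %.3g)\n", x$response_gain, x$sigma))
  cat(sprintf("  spatial pooling SD (deg): exc %.3g, sup %.3g\n",
              x$exc_space_width, x$sup_space_width))
  cat(sprintf("  feature pooling SD (deg): exc %.3g, sup %.3g\n",
              x$exc_feature_width, x$sup_feature_width))
  cat(sprintf(paste0("  drive exponent %.3g, contrast gain %.3g ",
                     "(exponent %.3g), criterion %.3g\n"),
              x$drive_exponent, x$contrast_gain, x$contrast_gain_exponent,
              x$criterion))
  invisible(x)
}

#' @export
coef.norm_model <- function(object, ...) {
  unlist(object[c("sigma", "exc_space_width", "sup_space_width",
                  "exc_feature_width", "sup_feature_width",
                  "drive_exponent", "contrast_gain",
                  "contrast_gain_exponent", "response_gain", "criterion")])
}

#' Discretization grid for the population response
#'
#' One-dimensional space (a line through the stimulus centre, exploiting the
#' circular symmetry of the stimuli) crossed with a circular motion-direction
#' axis. Positions are uniformly spaced and symmetric about 0 so the
#' winner-take-all readout can compare the field maximum with the centre
#' sample.
#'
#' @param spacing Grid spacing in degrees (default 0.05, resolving a 1 deg
#'   stimulus with 20 samples).
#' @param half_extent Half-width of the spatial axis in degrees. The default
#'   `6 + 3 * sup_space_width` leaves room for non-truncated pooling kernels
#'   around the largest (12 deg) stimulus.
#' @param n_feature Number of direction samples covering `[0, 360)`.
#' @param sup_space_width Suppressive pooling SD used for the default extent.
#' @return An object of class `spatial_grid` with elements `positions` and
#'   `features`.
#' @export
spatial_grid <- function(spacing = 0.05, half_extent = NULL, n_feature = 24,
                         sup_space_width = 2) {
  if (is.null(half_extent)) half_extent <- 6 + 3 * sup_space_width
  stopifnot(spacing > 0, half_extent > 0, n_feature >= 1)
  n_half <- ceiling(half_extent / spacing)
  positions <- seq(-n_half, n_half) * spacing
  features <- seq(0, 360 - 360 / n_feature, by = 360 / n_feature)
  structure(list(positions = positions, features = features,
                 spacing = spacing,
                 feature_spacing = 360 / n_feature),
            class = "spatial_grid")
}

new_population_response <- function(values, grid) {
  structure(list(values = values, grid = grid),
            class = "population_response")
}

#' Stimulus drive over the population
#'
#' The effective contrast-energy field driving the model: contrast (scaled by
#' the contrast gain, raised to the gain exponent, then passed through the
#' accelerating drive nonlinearity) inside the circular
#' aperture, falling to zero across the Gaussian-blurred edge, and uniform
#' over the direction axis (a single drifting grating has one direction; the
#' feature axis exists so broader suppressive feature pooling is
#' representable).
#'
#' @param stim A [stimulus_spec()].
#' @param grid A [spatial_grid()].
#' @param params A [norm_model()] (its gain parameters set the effective
#'   contrast).
#' @return A `population_response` with values in `[0, 1]`.
#' @export
build_stimulus_drive <- function(stim, grid, params) {
  stopifnot(inherits(stim, "stimulus_spec"), inherits(grid, "spatial_grid"),
            inherits(params, "norm_model"))
  r <- stim$diameter / 2
  max_pos <- max(grid$positions)
  need <- r + 3 * stim$edge_sd
  if (need > max_pos)
    stop(sprintf(paste0("stimulus (radius + 3*edge_sd = %.2f deg) exceeds ",
                        "the grid half-extent %.2f deg; rebuild the grid ",
                        "with half_extent >= %.2f"), need, max_pos, need))
  eff <- ((params$contrast_gain * stim$contrast)^
            params$contrast_gain_exponent)^params$drive_exponent
  # aperture profile: disc indicator convolved with the Gaussian edge blur
  if (stim$edge_sd > 0) {
    profile <- stats::pnorm((r - grid$positions) / stim$edge_sd) -
      stats::pnorm((-r - grid$positions) / stim$edge_sd)
  } else {
    profile <- as.numeric(abs(grid$positions) <= r)
  }
  values <- matrix(eff * profile, nrow = length(grid$positions),
                   ncol = length(grid$features))
  new_population_response(values, grid)
}

gauss_kernel <- function(width, spacing, truncate = 5) {
  k_half <- ceiling(truncate * width / spacing)
  offs <- seq(-k_half, k_half) * spacing
  k <- stats::dnorm(offs, sd = width)
  k / sum(k)  # unit area on the discrete grid
}

wrapped_gauss_kernel <- function(width, spacing, n) {
  # wrapped Gaussian on a circular axis of period n*spacing
  centers <- seq(0L, n - 1L) * spacing
  period <- n * spacing
  k <- numeric(n)
  for (w in -5:5) k <- k + stats::dnorm(centers + w * period, sd = width)
  k / sum(k)
}

#' Pooled drive (separable Gaussian convolution)
#'
#' Convolves a drive field with a unit-area Gaussian over space (linear,
#' zero-padded; kernels truncated at 5 SD and renormalized) and a unit-area
#' wrapped Gaussian over the circular direction axis. The total sum of a
#' compactly supported field is conserved.
#'
#' @param drive A `population_response`.
#' @param space_width Spatial kernel SD in degrees (> 0).
#' @param feature_width Feature kernel SD in degrees of direction (> 0).
#' @return A `population_response` of the same shape.
#' @export
pooled_drive <- function(drive, space_width, feature_width) {
  stopifnot(inherits(drive, "population_response"),
            space_width > 0, feature_width > 0)
  grid <- drive$grid
  half_extent <- max(grid$positions)
  if (5 * space_width > 2 * half_extent)
    stop(sprintf(paste0("spatial kernel (5 SD = %.2f deg) exceeds the grid ",
                        "span; enlarge the grid"), 5 * space_width))
  ks <- gauss_kernel(space_width, grid$spacing)
  k_half <- (length(ks) - 1L) / 2L
  v <- drive$values
  n <- nrow(v)
  # zero-padded linear convolution along space, one column per direction
  out <- apply(v, 2L, function(col) {
    full <- stats::convolve(col, rev(ks), type = "open")
    full[(k_half + 1L):(k_half + n)]
  })
  out <- matrix(out, nrow = n)
  # circular convolution along the direction axis
  nf <- length(grid$features)
  if (nf > 1L) {
    kf <- wrapped_gauss_kernel(feature_width, grid$feature_spacing, nf)
    fk <- stats::fft(kf)
    tr <- t(out)
    conv <- Re(stats::mvfft(stats::mvfft(tr) * fk, inverse = TRUE)) / nf
    out <- t(conv)
  }
  out[out < 0 & out > -1e-12] <- 0  # clip FFT round-off
  new_population_response(out, grid)
}

#' Normalized population response
#'
#' Evaluates `R = response_gain * E / (S + sigma)` where E and S are the
#' stimulus drive pooled with the excitatory and (broader) suppressive
#' kernels.
#'
#' @inheritParams build_stimulus_drive
#' @return A `population_response`; all values finite and non-negative.
#' @export
normalized_response <- function(stim, grid, params) {
  drive <- build_stimulus_drive(stim, grid, params)
  e <- pooled_drive(drive, params$exc_space_width, params$exc_feature_width)
  s <- pooled_drive(drive, params$sup_space_width, params$sup_feature_width)
  r <- params$response_gain * e$values / (s$values + params$sigma)
  new_population_response(r, grid)
}

#' Winner-take-all readout
#'
#' The decision rule reads out the response at the centre of the population
#' (the response to the centre of a centred stimulus), taking the maximum
#' over the direction axis there. For stimuli up to a few times the
#' excitatory pooling width this is also the maximum of the whole field; for
#' much larger stimuli the model response forms a slightly higher ring just
#' inside the aperture edge (suppressive pooling extends beyond the
#' stimulus there), and the centre sample remains the readout. An asymmetry
#' of the field about position 0 beyond 1e-9 indicates a mis-centred
#' stimulus or grid and triggers a warning.
#'
#' @param resp A `population_response`.
#' @return Scalar centre (peak) response.
#' @export
readout_peak <- function(resp) {
  stopifnot(inherits(resp, "population_response"))
  v <- resp$values
  if (length(v) == 0L) stop("empty population response")
  asym <- max(abs(v - v[nrow(v):1, , drop = FALSE]))
  if (asym > 1e-9)
    warning("population response is asymmetric about the centre (max ",
            format(asym), "); stimulus or grid may be off-centre")
  ic <- which.min(abs(resp$grid$positions))
  max(v[ic, ])
}

#' Predicted duration threshold from the criterion rule
#'
#' `threshold = criterion / response`: the time needed to accumulate a fixed
#' amount of response. Strictly decreasing in the peak response and strictly
#' increasing in the criterion.
#'
#' @param peak_response Scalar peak population response (> 0).
#' @param criterion Accumulated-response criterion (> 0), ms x response units.
#' @return Predicted duration threshold in ms.
#' @export
predict_threshold <- function(peak_response, criterion) {
  if (any(peak_response <= 0))
    stop("peak response must be > 0: the model configuration is unresponsive")
  if (any(criterion <= 0)) stop("criterion must be > 0")
  criterion / peak_response
}

#' Predicted thresholds and size indices over a condition table
#'
#' Evaluates the model at every (size, contrast) combination, converts peak
#' responses to duration thresholds via the criterion rule, and computes size
#' indices (smallest size vs each larger size, per contrast). A lower
#' criterion is typically used for low-contrast stimuli; size indices do not
#' depend on the criterion at all.
#'
#' @param object A [norm_model()].
#' @param sizes Stimulus diameters in degrees (default 1, 2, 12).
#' @param contrasts Contrast fractions (default 0.03, 0.98).
#' @param criteria Criterion per contrast, recycled to `length(contrasts)`.
#'   Defaults to 2.4 for contrasts below 10% and the model's `criterion`
#'   otherwise (a lower criterion for low-contrast stimuli, reflecting the
#'   less sensory evidence needed there).
#' @param edge_sd Aperture edge blur passed to [stimulus_spec()].
#' @param grid Optional [spatial_grid()]; by default one wide enough for the
#'   largest stimulus and non-truncated suppressive kernels is built.
#' @param ... Unused.
#' @return An object of class `norm_prediction`: a list with `thresholds`
#'   (data.frame: contrast, diameter_deg, peak_response,
#'   predicted_threshold_ms) and `si` (data.frame: contrast, pair, si).
#' @export
predict.norm_model <- function(object, sizes = c(1, 2, 12),
                               contrasts = c(0.03, 0.98),
                               criteria = NULL, edge_sd = 0.25,
                               grid = NULL, ...) {
  stopifnot(length(sizes) >= 1, length(contrasts) >= 1)
  if (is.null(criteria))
    criteria <- ifelse(contrasts < 0.1, 2.4, object$criterion)
  criteria <- rep_len(criteria, length(contrasts))
  if (is.null(grid)) {
    half <- max(6 + 3 * object$sup_space_width,
                max(sizes) / 2 + 3 * (object$sup_space_width + edge_sd))
    grid <- spatial_grid(half_extent = half,
                         sup_space_width = object$sup_space_width)
  }
  rows <- expand.grid(diameter_deg = sizes, contrast = contrasts,
                      KEEP.OUT.ATTRS = FALSE)
  rows$criterion <- rep(criteria, each = length(sizes))
  # peak responses without the output gain: size indices are computed from
  # these, so scaling criterion or response_gain cannot perturb them even at
  # the level of floating-point rounding
  ungained <- object
  ungained$response_gain <- 1
  peak_base <- vapply(seq_len(nrow(rows)), function(i) {
    stim <- stimulus_spec(rows$contrast[i], rows$diameter_deg[i], edge_sd)
    readout_peak(normalized_response(stim, grid, ungained))
  }, numeric(1))
  rows$peak_response <- object$response_gain * peak_base
  rows$predicted_threshold_ms <-
    predict_threshold(rows$peak_response, rows$criterion)
  sizes_sorted <- sort(sizes)
  si <- NULL
  if (length(sizes_sorted) >= 2) {
    small <- sizes_sorted[1]
    si <- do.call(rbind, lapply(contrasts, function(ct) {
      sel <- rows$contrast == ct
      pb <- stats::setNames(peak_base[sel], rows$diameter_deg[sel])
      inv_s <- 1 / pb[[as.character(small)]]
      data.frame(contrast = ct,
                 pair = paste0(small, "-", sizes_sorted[-1]),
                 si = vapply(sizes_sorted[-1], function(lg) {
                   size_index(inv_s, 1 / pb[[as.character(lg)]])
                 }, numeric(1)))
    }))
  }
  structure(list(thresholds = rows[, c("contrast", "diameter_deg",
                                       "peak_response",
                                       "predicted_threshold_ms")],
                 si = si, model = object),
            class = "norm_prediction")
}

#' @export
print.norm_prediction <- function(x, ...) {
  cat("Model-predicted duration thresholds:\n")
  print(format(x$thresholds, digits = 4), row.names = FALSE)
  if (!is.null(x$si)) {
    cat("\nSize indices (negative = suppression, positive = summation):\n")
    print(format(x$si, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Read model parameters from a JSON configuration file
#'
#' The file holds a `model` object whose fields mirror the [norm_model()]
#' arguments, and optionally a `preset` name applied first (explicit fields
#' override the preset). Values absent from the file keep the package
#' defaults.
#'
#' @param path Path to a JSON file, e.g.
#'   `{"preset": "baseline", "model": {"sigma": 0.05}}`.
#' @return A [norm_model()].
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- as.list(cfg$model)
  known <- setdiff(names(formals(norm_model)), "preset")
  bad <- setdiff(names(args), known)
  if (length(bad) > 0)
    stop("unknown model config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$preset)) {
    preset_obj <- norm_model(preset = cfg$preset)
    defaults <- lapply(formals(norm_model)[known], eval)
    for (nm in known)
      if (!identical(preset_obj[[nm]], defaults[[nm]]) &&
          is.null(args[[nm]]))
        args[[nm]] <- preset_obj[[nm]]
  }
  do.call(norm_model, args)
}
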