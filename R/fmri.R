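#' ROI BOLD time course container
#'
#' A preprocessed, ROI-averaged BOLD signal sampled at the repetition time,
#' with the onsets of the blocks of interest annotated. In the alternating
#' block design the pre-onset baseline window of a large-stimulus block lies
#' inside the preceding small-stimulus block, which is exactly the intended
#' reference.
#'
#' @param samples Numeric signal values (arbitrary scanner units).
#' @param tr_s Repetition time in seconds (default 2).
#' @param block_onsets 1-based sample indices at which blocks of interest
#'   start.
#' @param block_duration_s Block duration in seconds (default 10).
#' @return An object of class `roi_timecourse`.
#' @export
roi_timecourse <- function(samples, tr_s = 2, block_onsets,
                           block_duration_s = 10) {
  stopifnot(is.numeric(samples), tr_s > 0, block_duration_s > 0,
            all(block_onsets == round(block_onsets)))
  structure(list(samples = as.numeric(samples), tr_s = tr_s,
                 block_onsets = as.integer(block_onsets),
                 block_duration_s = block_duration_s),
            class = "roi_timecourse")
}

#' @export
print.roi_timecourse <- function(x, ...) {
  cat("ROI time course: ", length(x$samples), " samples at TR = ", x$tr_s,
      " s, ", length(x$block_onsets), " blocks of ", x$block_duration_s,
      " s\n", sep = "")
  invisible(x)
}

#' Split a time course into block-locked epochs
#'
#' One epoch per block onset, spanning 4 s before the block start to 2 s
#' after its end, on the TR grid. Epochs that would run off either end of the
#' run are dropped with a warning reporting the count.
#'
#' @param ts A [roi_timecourse()].
#' @param pre_s,post_s Seconds before onset and after block end (defaults 4
#'   and 2).
#' @return A matrix (epochs x samples) with onset-relative times, in
#'   seconds, as attribute `"time_s"`; zero rows when there are no usable
#'   onsets.
#' @export
epoch_blocks <- function(ts, pre_s = 4, post_s = 2) {
  stopifnot(inherits(ts, "roi_timecourse"))
  n_pre <- round(pre_s / ts$tr_s)
  n_len <- round((pre_s + ts$block_duration_s + post_s) / ts$tr_s)
  time_s <- (seq_len(n_len) - 1 - n_pre) * ts$tr_s
  n <- length(ts$samples)
  first <- ts$block_onsets - n_pre
  ok <- first >= 1 & (first + n_len - 1) <= n
  if (any(!ok))
    warning(sum(!ok), " epoch(s) dropped: outside the sampled run")
  starts <- first[ok]
  out <- matrix(NA_real_, nrow = length(starts), ncol = n_len)
  for (i in seq_along(starts))
    out[i, ] <- ts$samples[starts[i]:(starts[i] + n_len - 1)]
  attr(out, "time_s") <- time_s
  out
}

#' Convert epochs to percent signal change
#'
#' The baseline is one number per run: the mean over the pre-onset windows
#' (onset-relative time in `[-pre_s, 0)`) of all epochs. Each sample becomes
#' `100 * (x - baseline) / baseline`, which is exactly invariant under
#' rescaling the whole time course.
#'
#' @param epochs Epoch matrix from [epoch_blocks()] (attribute `"time_s"`
#'   required).
#' @return Matrix of the same shape, in percent signal change, with the
#'   baseline attached as attribute `"baseline"`.
#' @export
percent_signal_change <- function(epochs) {
  time_s <- attr(epochs, "time_s")
  if (is.null(time_s)) stop("epochs must carry a \"time_s\" attribute")
  if (nrow(epochs) == 0) stop("no epochs to convert")
  pre <- time_s < 0
  if (!any(pre)) stop("no pre-onset baseline samples in the epochs")
  b <- mean(epochs[, pre, drop = FALSE])
  if (!is.finite(b) || b <= 0)
    stop("non-positive baseline (", format(b),
         "): input looks unnormalized or corrupt")
  out <- 100 * (epochs - b) / b
  attr(out, "time_s") <- time_s
  attr(out, "baseline") <- b
  out
}

#' Peak-window fMRI response
#'
#' The mean percent signal change over onset-relative times t with
#' `8 <= t < 12` s (half-open on the TR grid; at TR = 2 s these are the
#' samples at 8 and 10 s). This late window sits at the peak of the
#' hemodynamic response to a 10 s block.
#'
#' @param epoch_psc A percent-signal-change epoch matrix (or a single epoch
#'   vector with a `"time_s"` attribute).
#' @param window Half-open window in seconds (default `c(8, 12)`).
#' @return One peak response (percent) per epoch.
#' @export
peak_response <- function(epoch_psc, window = c(8, 12)) {
  time_s <- attr(epoch_psc, "time_s")
  if (is.null(time_s)) stop("input must carry a \"time_s\" attribute")
  sel <- time_s >= window[1] & time_s < window[2]
  if (!any(sel)) stop("no samples fall inside the peak window [",
                      window[1], ", ", window[2], ") s")
  if (is.matrix(epoch_psc))
    rowMeans(epoch_psc[, sel, drop = FALSE])
  else
    mean(epoch_psc[sel])
}

#' Analyze one ROI run: epochs -> percent signal change -> peak response
#'
#' @param ts A [roi_timecourse()].
#' @return The run-level response: mean peak percent signal change across
#'   epochs.
#' @export
analyze_roi_run <- function(ts) {
  psc <- percent_signal_change(epoch_blocks(ts))
  mean(peak_response(psc))
}

#' Aggregate epoch responses to a subject-level response
#'
#' Nested arithmetic means in the stated order: across epochs within each
#' (run, hemisphere), then across hemispheres within each run, then across
#' runs. With unbalanced counts this differs from a pooled mean, and the
#' nesting order matters. A run missing one hemisphere is averaged over
#' whatever is available, with a message (some subjects lack one hMT+
#' sub-ROI).
#'
#' @param responses Data frame with columns `run`, `hemisphere`, and `value`
#'   (one row per epoch).
#' @return Scalar subject-level response.
#' @export
aggregate_responses <- function(responses) {
  stopifnot(all(c("run", "hemisphere", "value") %in% names(responses)),
            nrow(responses) > 0)
  n_hemi <- length(unique(responses$hemisphere))
  run_means <- vapply(split(responses, responses$run), function(r) {
    hm <- vapply(split(r$value, r$hemisphere), mean, numeric(1))
    if (length(hm) < n_hemi)
      message("run ", r$run[1], ": only ", length(hm),
              " hemisphere(s) available; averaging over those")
    mean(hm)
  }, numeric(1))
  mean(run_means)
}

#' Read a per-run ROI time-course TSV
#'
#' Expects a `signal` column and `# key=value` header lines for `tr_s`,
#' `onsets` (comma-separated 1-based sample indices) and `block_duration_s`,
#' the format written by [write_roi_tsv()].
#'
#' @param path File path.
#' @return A [roi_timecourse()].
#' @export
read_roi_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(m) == 0) stop("missing header '# ", key, "=' in ", path)
    sub(paste0("^#\\s*", key, "\\s*="), "", m[1])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"))
  if (!"signal" %in% names(df)) stop("no 'signal' column in ", path)
  roi_timecourse(df$signal,
                 tr_s = as.numeric(get("tr_s")),
                 block_onsets = as.integer(strsplit(get("onsets"),
                                                    ",")[[1]]),
                 block_duration_s = as.numeric(get("block_duration_s")))
}

#' Write a per-run ROI time-course TSV
#'
#' @param ts A [roi_timecourse()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roi_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timecourse"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# tr_s=", ts$tr_s),
               paste0("# onsets=", paste(ts$block_onsets, collapse = ",")),
               paste0("# block_duration_s=", ts$block_duration_s),
               "signal",
               format(ts$samples, digits = 10, trim = TRUE)), con)
  invisible(path)
}
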