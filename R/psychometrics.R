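#' Weibull psychometric function for 2AFC accuracy
#'
#' \deqn{P(x) = \gamma + (1 - \gamma - \lambda)(1 - e^{-(x/\alpha)^\beta})}
#' with guess rate \eqn{\gamma} fixed at 0.5 (two-alternative forced choice)
#' and lapse rate \eqn{\lambda} fixed at 0.04 throughout this package.
#'
#' @param duration Stimulus duration(s) in ms, >= 0.
#' @param alpha Weibull scale in ms (> 0).
#' @param beta Weibull shape (> 0).
#' @param guess Guess rate (default 0.5).
#' @param lapse Lapse rate (default 0.04).
#' @return Probability of a correct response, in `[guess, 1 - lapse]`.
#' @export
weibull_p_correct <- function(duration, alpha, beta,
                              guess = 0.5, lapse = 0.04) {
  stopifnot(all(duration >= 0), all(alpha > 0), all(beta > 0))
  guess + (1 - guess - lapse) * (1 - exp(-(duration / alpha)^beta))
}

#' Duration threshold at a fixed accuracy level, in closed form
#'
#' Inverts the Weibull psychometric function at accuracy `p` (default 0.8,
#' the 80%-correct threshold).
#'
#' @inheritParams weibull_p_correct
#' @param p Target proportion correct, strictly between `guess` and
#'   `1 - lapse`.
#' @return Duration in ms.
#' @export
weibull_threshold <- function(alpha, beta, p = 0.8, guess = 0.5,
                              lapse = 0.04) {
  stopifnot(p > guess, p < 1 - lapse)
  alpha * (-log(1 - (p - guess) / (1 - guess - lapse)))^(1 / beta)
}

#' Weibull scale parameter placing the threshold at a given duration
#'
#' Inverse of [weibull_threshold()]: the scale alpha such that accuracy `p`
#' is reached exactly at `threshold` ms. Used to build simulated observers
#' from target thresholds.
#'
#' @inheritParams weibull_threshold
#' @param threshold Target duration in ms at accuracy `p`.
#' @return Weibull scale in ms.
#' @export
alpha_for_threshold <- function(threshold, beta, p = 0.8, guess = 0.5,
                                lapse = 0.04) {
  threshold / (-log(1 - (p - guess) / (1 - guess - lapse)))^(1 / beta)
}

weibull_negloglik <- function(logab, duration, correct, guess, lapse) {
  p <- weibull_p_correct(duration, exp(logab[1]), exp(logab[2]), guess, lapse)
  # p is bounded in [guess, 1 - lapse], so logs are finite
  -sum(log(ifelse(correct, p, 1 - p)))
}

#' Maximum-likelihood Weibull fit to 2AFC trial data
#'
#' Fits scale and shape by maximizing the Bernoulli likelihood with guess and
#' lapse rates fixed (0.5 and 0.04). Optimization is a deterministic
#' multi-start Nelder-Mead on (log alpha, log beta) over a 5 x 5 start grid,
#' so repeated fits of the same data are identical. The 80%-correct threshold
#' is recovered in closed form from the fitted parameters; estimates below
#' 0 ms or above 500 ms are flagged excluded. All-correct or all-incorrect
#' trial sets cannot constrain the scale and are flagged degenerate, with the
#' threshold pinned to the corresponding domain boundary and excluded.
#'
#' @param duration Per-trial stimulus durations in ms, or a data.frame with
#'   columns `duration_ms` and `correct` (e.g. from [run_staircase()] or
#'   [read_trials_csv()]).
#' @param correct Logical (or 0/1) vector of per-trial outcomes; omitted when
#'   `duration` is a data.frame.
#' @param guess,lapse Fixed guess and lapse rates.
#' @param exclude_above Upper exclusion bound on the fitted threshold, ms.
#' @return An object of class `weibull_fit` with elements `alpha`, `beta`,
#'   `threshold80`, `loglik`, `excluded`, `degenerate`, `n`.
#' @examples
#' set.seed(1)
#' d <- exp(runif(400, log(5), log(300)))
#' y <- runif(400) < weibull_p_correct(d, alpha = 50, beta = 3)
#' fit_weibull(d, y)
#' @export
fit_weibull <- function(duration, correct = NULL, guess = 0.5, lapse = 0.04,
                        exclude_above = 500) {
  if (is.data.frame(duration)) {
    correct <- duration$correct
    duration <- duration$duration_ms
  }
  correct <- as.logical(correct)
  stopifnot(length(duration) == length(correct), length(duration) >= 2,
            all(duration >= 0), !anyNA(correct))
  out <- list(guess = guess, lapse = lapse, n = length(duration))
  if (all(correct) || all(!correct)) {
    # unconstrained scale: pin to the relevant domain boundary and exclude
    out$alpha <- if (all(correct)) min(duration[duration > 0], 1) else Inf
    out$beta <- NA_real_
    out$threshold80 <- if (all(correct)) 0 else Inf
    out$loglik <- 0
    out$degenerate <- TRUE
    out$excluded <- TRUE
    class(out) <- "weibull_fit"
    return(out)
  }
  la_grid <- seq(log(max(min(duration), 1e-3)), log(max(duration)),
                 length.out = 5)
  lb_grid <- seq(log(0.5), log(16), length.out = 5)
  starts <- as.matrix(expand.grid(la = la_grid, lb = lb_grid))
  scores <- apply(starts, 1, weibull_negloglik, duration = duration,
                  correct = correct, guess = guess, lapse = lapse)
  # polish from the three best grid starts (deterministic order)
  best <- NULL
  for (i in order(scores)[1:3]) {
    fit <- stats::optim(starts[i, ], weibull_negloglik,
                        duration = duration, correct = correct,
                        guess = guess, lapse = lapse,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out$alpha <- unname(exp(best$par[1]))
  out$beta <- unname(exp(best$par[2]))
  out$threshold80 <- weibull_threshold(out$alpha, out$beta, 0.8, guess, lapse)
  out$loglik <- -best$value
  out$degenerate <- FALSE
  out$excluded <- out$threshold80 < 0 || out$threshold80 > exclude_above
  class(out) <- "weibull_fit"
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull psychometric fit (MLE, guess ", x$guess, ", lapse ", x$lapse,
      ")\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate trial set (all responses identical); threshold pinned ",
        "to ", x$threshold80, " ms and excluded\n", sep = "")
  } else {
    cat(sprintf("  alpha = %.2f ms, beta = %.2f, logLik = %.2f (n = %d)\n",
                x$alpha, x$beta, x$loglik, x$n))
    cat(sprintf("  80%%-correct threshold = %.1f ms%s\n", x$threshold80,
                if (x$excluded) "  [EXCLUDED]" else ""))
  }
  invisible(x)
}

#' @export
coef.weibull_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta,
    threshold80 = object$threshold80)
}

#' @export
logLik.weibull_fit <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$n, class = "logLik")
}

#' @export
predict.weibull_fit <- function(object, newdata, ...) {
  weibull_p_correct(newdata, object$alpha, object$beta,
                    object$guess, object$lapse)
}

#' Size index: the log-ratio effect of stimulus size on thresholds
#'
#' `SI = log10(threshold at smaller size) - log10(threshold at larger size)`.
#' Negative values mean larger stimuli need more time (spatial suppression);
#' positive values mean larger stimuli need less (spatial summation). The SI
#' is invariant under any common scaling of the two thresholds.
#'
#' @param threshold_smaller,threshold_larger Duration thresholds in ms, > 0
#'   and not excluded.
#' @return Numeric size index (vectorized).
#' @export
size_index <- function(threshold_smaller, threshold_larger) {
  if (any(!is.finite(threshold_smaller)) || any(!is.finite(threshold_larger)) ||
      any(threshold_smaller <= 0) || any(threshold_larger <= 0))
    stop("size_index requires finite positive thresholds; ",
         "excluded estimates must not be propagated here")
  log10(threshold_smaller) - log10(threshold_larger)
}

#' Geometric mean of duration thresholds
#'
#' Used when averaging thresholds across conditions whose ranges differ by an
#' order of magnitude; excluded thresholds must be dropped by the caller.
#'
#' @param thresholds Positive durations in ms.
#' @return Geometric mean in ms.
#' @export
geometric_mean_threshold <- function(thresholds) {
  if (length(thresholds) == 0) stop("no thresholds supplied")
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("all thresholds must be finite and > 0")
  exp(mean(log(thresholds)))
}

#' Within-subject drug-minus-placebo threshold differences
#'
#' Computes per-subject, per-condition differences between matched drug and
#' placebo sessions, plus the across-subject mean and standard error per
#' condition.
#'
#' @param drug,placebo Data frames with columns `subject`, `condition`, and
#'   `threshold_ms`; every (subject, condition) cell present in one must be
#'   present in the other.
#' @return A list with `differences` (subject, condition, diff_ms) and
#'   `summary` (condition, mean_diff_ms, sem_ms, n).
#' @export
drug_effect <- function(drug, placebo) {
  need <- c("subject", "condition", "threshold_ms")
  stopifnot(all(need %in% names(drug)), all(need %in% names(placebo)))
  key <- function(d) paste(d$subject, d$condition, sep = "\r")
  kd <- key(drug); kp <- key(placebo)
  miss <- c(setdiff(kd, kp), setdiff(kp, kd))
  if (length(miss) > 0)
    stop("unmatched (subject, condition) cells: ",
         paste(gsub("\r", " / ", miss), collapse = ", "))
  placebo_ord <- placebo[match(kd, kp), ]
  diffs <- data.frame(subject = drug$subject, condition = drug$condition,
                      diff_ms = drug$threshold_ms - placebo_ord$threshold_ms)
  agg <- do.call(rbind, lapply(split(diffs, diffs$condition), function(d) {
    data.frame(condition = d$condition[1], mean_diff_ms = mean(d$diff_ms),
               sem_ms = stats::sd(d$diff_ms) / sqrt(nrow(d)), n = nrow(d))
  }))
  rownames(agg) <- NULL
  list(differences = diffs, summary = agg)
}
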