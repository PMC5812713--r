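#' Initialize a Psi adaptive staircase
#'
#' Builds the Bayesian state of the Psi method: a uniform prior over a grid
#' of candidate Weibull thresholds (alpha) and slopes (beta), a log-spaced
#' stimulus domain of candidate durations, and precomputed likelihood tables
#' so stimulus selection and posterior updates are matrix-vector products.
#'
#' @param alpha_range,n_alpha Range (ms) and number of log-spaced candidate
#'   thresholds (defaults 3-500 ms, 40 points; the upper end matches the
#'   exclusion bound on fitted thresholds).
#' @param beta_range,n_beta Range and number of log-spaced candidate slopes
#'   (defaults 0.5-16, 25 points).
#' @param stimulus_range,n_stimulus Range (ms) and number of log-spaced
#'   candidate durations (defaults 6.7-333 ms, 60 points).
#' @param guess,lapse Fixed guess and lapse rates of the Weibull observer
#'   model (0.5 and 0.04).
#' @return An object of class `psi_state`.
#' @references Kontsevich & Tyler (1999), Vision Research 39, 2729-2737.
#' @export
psi_init <- function(alpha_range = c(3, 500), n_alpha = 40,
                     beta_range = c(0.5, 16), n_beta = 25,
                     stimulus_range = c(6.7, 333), n_stimulus = 60,
                     guess = 0.5, lapse = 0.04) {
  stopifnot(all(alpha_range > 0), all(beta_range > 0),
            all(stimulus_range > 0), n_alpha >= 1, n_beta >= 1,
            n_stimulus >= 1)
  alpha_grid <- exp(seq(log(alpha_range[1]), log(alpha_range[2]),
                        length.out = n_alpha))
  beta_grid <- exp(seq(log(beta_range[1]), log(beta_range[2]),
                       length.out = n_beta))
  domain <- exp(seq(log(stimulus_range[1]), log(stimulus_range[2]),
                    length.out = n_stimulus))
  ab <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                    KEEP.OUT.ATTRS = FALSE)
  # P[x, j] = P(correct | duration x, parameter cell j)
  p <- outer(seq_along(domain), seq_len(nrow(ab)), function(i, j) {
    weibull_p_correct(domain[i], ab$alpha[j], ab$beta[j], guess, lapse)
  })
  q <- 1 - p
  xlx <- function(m) ifelse(m > 0, m * log(m), 0)
  state <- list(alpha_grid = alpha_grid, beta_grid = beta_grid,
                ab = ab, stimulus_domain = domain,
                posterior = rep(1 / nrow(ab), nrow(ab)),
                log_posterior = rep(-log(nrow(ab)), nrow(ab)),
                guess = guess, lapse = lapse, trial_count = 0L,
                lik_correct = p, lik_incorrect = q,
                log_lik_correct = log(p), log_lik_incorrect = log(q),
                plogp = xlx(p), qlogq = xlx(q))
  class(state) <- "psi_state"
  state
}

#' @export
print.psi_state <- function(x, ...) {
  cat("Psi staircase state: ", length(x$alpha_grid), " x ",
      length(x$beta_grid), " (alpha x beta) grid, ",
      length(x$stimulus_domain), " candidate durations [",
      round(min(x$stimulus_domain), 1), ", ",
      round(max(x$stimulus_domain), 1), "] ms, ",
      x$trial_count, " trials\n", sep = "")
  est <- psi_estimate(x)
  cat(sprintf("  posterior mean: alpha = %.1f ms, beta = %.2f\n",
              est["alpha"], est["beta"]))
  invisible(x)
}

#' Reset a Psi state to its uniform prior
#'
#' Returns the state with a fresh uniform posterior and zero trial count,
#' keeping the precomputed likelihood tables; useful when running many
#' staircases over the same grids.
#'
#' @param state A `psi_state`.
#' @return The reset `psi_state`.
#' @export
psi_reset <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  n <- nrow(state$ab)
  state$posterior <- rep(1 / n, n)
  state$log_posterior <- rep(-log(n), n)
  state$trial_count <- 0L
  state
}

#' Posterior-mean parameter estimate of a Psi state
#'
#' @param state A `psi_state`.
#' @return Named vector with posterior-mean `alpha` (ms) and `beta`.
#' @export
psi_estimate <- function(state) {
  c(alpha = sum(state$posterior * state$ab$alpha),
    beta = sum(state$posterior * state$ab$beta))
}

#' Select the next stimulus duration (expected-entropy minimization)
#'
#' For each candidate duration, computes the entropy of the joint posterior
#' over (alpha, beta) expected after observing the next response, and returns
#' the duration minimizing it. Deterministic given the state; ties are broken
#' toward the shorter duration. If the posterior has collapsed onto a single
#' cell, the duration nearest that cell's alpha is returned with a warning.
#'
#' @param state A `psi_state`.
#' @return Duration in ms, an element of `state$stimulus_domain`.
#' @export
psi_select <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  post <- state$posterior
  if (max(post) >= 1 - 1e-12) {
    warning("posterior is degenerate; returning the duration nearest the ",
            "remaining threshold estimate")
    a <- state$ab$alpha[which.max(post)]
    return(state$stimulus_domain[which.min(abs(state$stimulus_domain - a))])
  }
  # expected posterior entropy per candidate x, via
  # sum_j q_j log q_j = (1/pc) [ sum_j m_j log m_j - pc log pc ],
  # m_j = post_j * P[x, j]; all sums are matrix-vector products
  pl <- post * log(post)
  pl[post == 0] <- 0
  pc <- as.vector(state$lik_correct %*% post)
  pi_ <- 1 - pc
  sc <- as.vector(state$lik_correct %*% pl + state$plogp %*% post)
  si <- as.vector(state$lik_incorrect %*% pl + state$qlogq %*% post)
  h_c <- -(sc / pc - log(pc))
  h_i <- -(si / pi_ - log(pi_))
  eh <- pc * h_c + pi_ * h_i
  state$stimulus_domain[which.min(eh)]  # first minimum = shortest duration
}

#' Update the Psi posterior after a trial
#'
#' Bayes rule with the fixed-guess, fixed-lapse Weibull likelihood, computed
#' in log space to avoid underflow over long trial sequences.
#'
#' @param state A `psi_state`.
#' @param duration Presented duration in ms; must be an element of the
#'   stimulus domain (matched to within 1e-6 relative tolerance).
#' @param correct Logical trial outcome.
#' @return The updated `psi_state` (trial count incremented).
#' @export
psi_update <- function(state, duration, correct) {
  stopifnot(inherits(state, "psi_state"), is.logical(correct) ||
              correct %in% c(0, 1))
  idx <- which.min(abs(state$stimulus_domain - duration))
  if (abs(state$stimulus_domain[idx] - duration) >
      1e-6 * max(duration, 1e-6))
    stop("duration ", duration, " ms is not in the stimulus domain")
  ll <- if (as.logical(correct)) state$log_lik_correct[idx, ]
        else state$log_lik_incorrect[idx, ]
  lp <- state$log_posterior + ll
  m <- max(lp)
  if (!is.finite(m)) stop("likelihood is identically zero over the grid")
  w <- exp(lp - m)
  state$posterior <- w / sum(w)
  state$log_posterior <- lp - (m + log(sum(w)))
  state$trial_count <- state$trial_count + 1L
  state
}

#' Run a Psi staircase against an observer
#'
#' Alternates select / respond / update for `n_trials` trials. The observer
#' is a function `observer(duration, condition)` returning the probability of
#' a correct response (e.g. from [gen_observer()]); responses are drawn from
#' the current R random stream, so results are reproducible given `seed`.
#'
#' @param observer Function mapping (duration, condition) to P(correct).
#' @param condition Condition label passed through to the observer and the
#'   trial records (e.g. `"c98_d12"`).
#' @param n_trials Number of staircase trials (default 30, one run).
#' @param state Optional starting `psi_state` (default [psi_init()]);
#'   interleaving across conditions is handled by the caller.
#' @param seed Optional integer seed for the response stream.
#' @return A data.frame of trial records (`trial_index`, `condition`,
#'   `duration_ms`, `correct`, `is_catch`) with the final `psi_state`
#'   attached as attribute `"state"`.
#' @export
run_staircase <- function(observer, condition, n_trials = 30,
                          state = psi_init(), seed = NULL) {
  stopifnot(is.function(observer), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  duration <- numeric(n_trials)
  correct <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    d <- psi_select(state)
    p <- observer(d, condition)
    r <- stats::runif(1) < p
    state <- psi_update(state, d, r)
    duration[i] <- d
    correct[i] <- r
  }
  out <- data.frame(trial_index = seq_len(n_trials), condition = condition,
                    duration_ms = duration, correct = correct,
                    is_catch = FALSE)
  attr(out, "state") <- state
  out
}
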