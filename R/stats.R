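#' Repeated-measures ANOVA with subjects as a random effect
#'
#' Standard within-subject sums-of-squares decomposition via an
#' `aov(dv ~ f1 * f2 + Error(subject/(f1 * f2)))` model for one or two
#' within-subject factors. Subjects with incomplete cells are excluded
#' listwise (with a message reporting the count). A factor can instead be
#' treated as a continuous predictor (`continuous =`), in which case the
#' linear trend is tested by a one-sample t test on per-subject slopes and
#' reported as its squared value, an F with (1, n - 1) degrees of freedom.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param continuous Optional name of one `within` column to treat as a
#'   continuous (linear-trend) predictor.
#' @return Data frame with columns `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova <- function(data, dv, subject, within, continuous = NULL) {
  stopifnot(length(within) %in% 1:2, all(c(dv, subject, within) %in%
                                           names(data)))
  data <- data[stats::complete.cases(data[, c(dv, subject, within)]), ]
  # listwise exclusion: keep subjects with a full factorial crossing
  cells <- interaction(data[within], drop = FALSE)
  n_cells <- length(levels(cells))
  counts <- table(data[[subject]], cells)
  keep <- rownames(counts)[apply(counts > 0, 1, all)]
  if (length(keep) < length(unique(data[[subject]])))
    message(length(unique(data[[subject]])) - length(keep),
            " subject(s) excluded listwise (incomplete cells)")
  data <- data[data[[subject]] %in% keep, ]
  n_subj <- length(unique(data[[subject]]))
  if (n_subj < 2) stop("need at least 2 subjects with complete data")
  if (n_cells < 2) stop("need at least 2 within-subject cells")
  if (!is.null(continuous)) {
    stopifnot(continuous %in% within)
    xs <- as.numeric(as.character(data[[continuous]]))
    if (anyNA(xs)) stop("continuous factor has non-numeric levels")
    slopes <- vapply(split(seq_len(nrow(data)), data[[subject]]),
                     function(i) {
                       stats::coef(stats::lm(data[[dv]][i] ~ xs[i]))[2]
                     }, numeric(1))
    tt <- stats::t.test(slopes)
    return(data.frame(effect = paste0(continuous, " (linear trend)"),
                      df1 = 1, df2 = n_subj - 1,
                      F = unname(tt$statistic)^2, p = tt$p.value))
  }
  df <- data.frame(dv = data[[dv]], subject = factor(data[[subject]]))
  for (w in within) df[[w]] <- factor(data[[w]])
  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(paste0("dv ~ ", rhs, " + Error(subject/(",
                                   rhs, "))"))
  fit <- stats::aov(form, data = df)
  ss_total <- sum((df$dv - mean(df$dv))^2)
  out <- do.call(rbind, lapply(summary(fit), function(stratum) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    sel <- eff != "Residuals" & !is.na(tab[["F value"]])
    if (!any(sel)) return(NULL)
    data.frame(effect = eff[sel], df1 = tab$Df[sel],
               df2 = tab$Df[eff == "Residuals"],
               F = tab[["F value"]][sel], p = tab[["Pr(>F)"]][sel],
               ss = tab[["Sum Sq"]][sel])
  }))
  rownames(out) <- NULL
  # an effect whose sum of squares is pure round-off (dv constant across
  # its cells) is a zero effect, not a 0/0 ratio
  nil <- is.nan(out$F) | out$ss <= 1e-12 * max(ss_total, 1e-300)
  out$F[nil] <- 0
  out$p[nil] <- 1
  out$ss <- NULL
  out
}

#' Friedman test (non-parametric repeated-measures ANOVA)
#'
#' Rank-based test across within-subject conditions, delegated to
#' [stats::friedman.test()] (mid-rank ties). Subjects with incomplete cells
#' are excluded listwise.
#'
#' @inheritParams rm_anova
#' @param factor_col Name of the within-subject factor column.
#' @return Data frame with `chisq`, `df`, `p`.
#' @export
friedman_test <- function(data, dv, subject, factor_col) {
  stopifnot(all(c(dv, subject, factor_col) %in% names(data)))
  data <- data[stats::complete.cases(data[, c(dv, subject, factor_col)]), ]
  m <- tapply(data[[dv]], list(data[[subject]], data[[factor_col]]), mean)
  complete <- stats::complete.cases(m)
  if (any(!complete))
    message(sum(!complete), " subject(s) excluded listwise")
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 subjects and 2 levels")
  ft <- stats::friedman.test(m)
  chisq <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(chisq)) {  # all ranks tied (dv constant across levels)
    chisq <- 0
    p <- 1
  }
  data.frame(chisq = chisq, df = unname(ft$parameter), p = p)
}

#' Pearson correlation with permutation significance
#'
#' Computes the two-tailed Pearson coefficient and a permutation p-value:
#' one vector is randomly shuffled across subjects in each iteration, and
#' p is the proportion of permuted correlations whose absolute value is
#' strictly greater than the observed one. The strict-inequality rule means
#' a perfect correlation can yield p = 0; the conventional
#' `(b + 1) / (m + 1)` estimator is available via `add_one = TRUE`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @param n_iter Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param add_one Use the (b + 1)/(m + 1) estimator instead of the strict
#'   proportion (default `FALSE`).
#' @return List with `r`, `p`, `n`, `n_iter`.
#' @export
permutation_correlation <- function(x, y, n_iter = 10000, seed = NULL,
                                    add_one = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3, n_iter >= 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: cannot correlate a constant vector")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(x, y)
  n <- length(x)
  # r is linear in the permuted y once x and y are standardized
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- (y - mean(y)) / stats::sd(y)
  r_perm <- vapply(seq_len(n_iter), function(i) {
    sum(zx * zy[sample.int(n)]) / (n - 1)
  }, numeric(1))
  b <- sum(abs(r_perm) > abs(r_obs))
  p <- if (add_one) (b + 1) / (n_iter + 1) else b / n_iter
  list(r = r_obs, p = p, n = n, n_iter = n_iter)
}

#' Minimum detectable correlation at a given power
#'
#' Solves, via the Fisher z approximation, for the population correlation at
#' which a two-tailed test at level `alpha` reaches the target power:
#' \deqn{r = \tanh\left(\frac{z_{1-\alpha/2} + z_{power}}{\sqrt{n - 3}}\right)}
#' Monotone decreasing in n. With alpha = 0.05 and power = 0.80 this gives
#' 0.52 at n = 27 and 0.58 at n = 21.
#'
#' @param n Sample size(s), >= 4.
#' @param alpha Two-tailed significance level (default 0.05).
#' @param power Target power (default 0.80, i.e. type II error below 20%).
#' @return Minimum detectable Pearson r.
#' @export
min_detectable_r <- function(n, alpha = 0.05, power = 0.80) {
  if (any(n < 4)) stop("n must be at least 4")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}

#' Median split into low and high groups
#'
#' Splits values into below-median and above-median groups. Even n always
#' yields two groups of n/2; ties at the median are resolved by stable rank
#' order (first occurrence goes to the lower group) with a message.
#'
#' @param values Numeric vector of length >= 2.
#' @return Factor with levels `"low"` and `"high"`, same length as
#'   `values`.
#' @export
median_split <- function(values) {
  stopifnot(length(values) >= 2)
  n <- length(values)
  r <- rank(values, ties.method = "first")
  n_low <- floor(n / 2)
  med <- stats::median(values)
  if (sum(values == med) > 1)
    message("tie at the median resolved by stable rank order")
  factor(ifelse(r <= n_low, "low", "high"), levels = c("low", "high"))
}

#' Report the more conservative of parametric and rank-based tests
#'
#' Normality screening: the dependent variable is tested per condition with
#' Shapiro-Wilk; both the repeated-measures ANOVA and the Friedman test are
#' computed, and the larger of the two p-values is reported along with which
#' test produced it and the screening outcome.
#'
#' @inheritParams friedman_test
#' @param shapiro_alpha Level of the per-condition normality screen
#'   (default 0.05).
#' @return List with `reported` (`"rm_anova"` or `"friedman"`), `p`,
#'   `anova`, `friedman`, `normality_ok`.
#' @export
screen_and_test <- function(data, dv, subject, factor_col,
                            shapiro_alpha = 0.05) {
  a <- rm_anova(data, dv, subject, factor_col)
  f <- friedman_test(data, dv, subject, factor_col)
  sw <- vapply(split(data[[dv]], data[[factor_col]]), function(v) {
    if (length(unique(v)) < 3) return(0)  # degenerate: fails the screen
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normality_ok <- all(sw > shapiro_alpha)
  p_a <- a$p[1]
  use_friedman <- !normality_ok && f$p > p_a
  list(reported = if (use_friedman) "friedman" else "rm_anova",
       p = max(p_a, if (normality_ok) p_a else f$p),
       anova = a, friedman = f, normality_ok = normality_ok,
       shapiro_p = sw)
}
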