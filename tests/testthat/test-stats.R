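test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # 3 subjects x 2 conditions, worked by hand:
  # values S1: 10, 14; S2: 20, 26; S3: 30, 32
  # condition means 20, 24 -> SS_cond = 3 * (2^2 + 2^2) = 24 (df 1)
  # SS_error (cond x subj) = sum((x - subj_mean - cond_mean + grand)^2) = 4
  # F = 24 / (4 / 2) = 12
  d <- data.frame(subject = rep(c("S1", "S2", "S3"), each = 2),
                  cond = rep(c("a", "b"), 3),
                  y = c(10, 14, 20, 26, 30, 32))
  out <- rm_anova(d, "y", "subject", "cond")
  expect_equal(out$F, 12, tolerance = 1e-10)
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 2)
  # location invariance
  d2 <- d; d2$y <- d$y + 100
  expect_equal(rm_anova(d2, "y", "subject", "cond")$F, out$F,
               tolerance = 1e-10)
  # dv constant across conditions (but varying across subjects) -> F = 0
  dc <- d; dc$y <- rep(c(5, 9, 11), each = 2)
  expect_equal(rm_anova(dc, "y", "subject", "cond")$F, 0)
})

test_that("two-level RM-ANOVA F equals the squared paired t statistic", {
  set.seed(14)
  a <- rnorm(9, 10, 2); b <- a + rnorm(9, 1, 1)
  d <- data.frame(subject = rep(sprintf("S%d", 1:9), 2),
                  cond = rep(c("a", "b"), each = 9), y = c(a, b))
  f <- rm_anova(d, "y", "subject", "cond")$F
  t2 <- unname(t.test(b - a)$statistic)^2
  expect_equal(f, t2, tolerance = 1e-8)
})

test_that("two within factors and the continuous linear trend are supported", {
  set.seed(15)
  d <- expand.grid(subject = sprintf("S%d", 1:8), size = c(1, 2, 12),
                   contrast = c("lo", "hi"))
  d$y <- rnorm(nrow(d)) + as.numeric(d$size) * 0.3
  out <- rm_anova(d, "y", "subject", c("size", "contrast"))
  expect_setequal(out$effect, c("size", "contrast", "size:contrast"))
  lin <- rm_anova(d, "y", "subject", "size", continuous = "size")
  expect_equal(lin$df1, 1)
  expect_equal(lin$df2, 7)
  expect_gt(lin$F, 1)  # built-in positive trend
  # and it equals the squared one-sample t over per-subject slopes
  slopes <- sapply(split(d, d$subject), function(s)
    coef(lm(y ~ as.numeric(as.character(size)), s))[2])
  expect_equal(lin$F, unname(t.test(slopes)$statistic)^2, tolerance = 1e-8)
})

test_that("subjects with incomplete cells are excluded listwise", {
  d <- data.frame(subject = rep(c("S1", "S2", "S3"), each = 2),
                  cond = rep(c("a", "b"), 3),
                  y = c(10, 14, 20, 26, 30, 32))
  d <- d[-6, ]  # S3 loses condition b
  expect_message(out <- rm_anova(d, "y", "subject", "cond"), "excluded")
  expect_equal(out$df2, 1)  # only 2 complete subjects remain
})

test_that("Friedman test is rank-based with the expected extremes", {
  d <- data.frame(subject = rep(sprintf("S%d", 1:5), each = 3),
                  cond = rep(c("a", "b", "c"), 5),
                  y = rep(c(4, 4, 4), 5))
  expect_equal(friedman_test(d, "y", "subject", "cond")$chisq, 0)
  # monotone shift on every subject attains the n=3,k=3 maximum, which by
  # exhaustive enumeration of rank permutations is chi^2 = 6
  d3 <- data.frame(subject = rep(sprintf("S%d", 1:3), each = 3),
                   cond = rep(c("a", "b", "c"), 3),
                   y = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  stat <- friedman_test(d3, "y", "subject", "cond")$chisq
  max_enum <- max(apply(
    expand.grid(replicate(3, list(1:6))), 1, function(perms) {
      ranks <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))[unlist(perms), ]
      rs <- colSums(ranks)
      12 / (3 * 3 * 4) * sum((rs - 6)^2)
    }))
  expect_equal(stat, max_enum)
  # invariant under monotone transforms of the dv
  d4 <- d3; d4$y <- exp(d3$y)
  expect_equal(friedman_test(d4, "y", "subject", "cond")$chisq, stat)
})

test_that("permutation correlation reproduces the quoted estimator", {
  x <- 1:10
  out <- permutation_correlation(x, x, n_iter = 500, seed = 1)
  expect_equal(out$r, 1)
  expect_equal(out$p, 0)  # strict inequality: nothing beats |r| = 1
  # symmetric in x and y
  set.seed(3)
  a <- rnorm(15); b <- rnorm(15)
  p1 <- permutation_correlation(a, b, n_iter = 2000, seed = 42)
  p2 <- permutation_correlation(b, a, n_iter = 2000, seed = 42)
  expect_equal(p1$r, cor(a, b))
  expect_lt(abs(p1$p - p2$p), 0.03)
  # the add-one estimator can never return exactly zero
  p3 <- permutation_correlation(x, x, n_iter = 500, seed = 1,
                                add_one = TRUE)
  expect_equal(p3$p, 1 / 501)
  expect_error(permutation_correlation(rep(1, 5), rnorm(5)), "variance")
})

test_that("permutation p agrees with the analytic t-distribution p for normal data", {
  set.seed(20)
  devs <- vapply(1:25, function(i) {
    x <- rnorm(25); y <- rnorm(25)
    pp <- permutation_correlation(x, y, n_iter = 2000, seed = 100 + i)$p
    r <- cor(x, y)
    tt <- r * sqrt(23) / sqrt(1 - r^2)
    pa <- 2 * pt(-abs(tt), df = 23)
    pp - pa
  }, numeric(1))
  expect_lt(max(abs(devs)), 0.05)
  expect_lt(abs(mean(devs)), 0.02)
})

test_that("minimum detectable correlation reproduces the printed power analysis", {
  expect_equal(round(min_detectable_r(27), 2), 0.52)
  expect_equal(round(min_detectable_r(21), 2), 0.58)
  # monotone decreasing toward zero
  r <- min_detectable_r(c(10, 50, 200, 5000))
  expect_true(all(diff(r) < 0))
  expect_lt(r[4], 0.05)
  expect_error(min_detectable_r(3), "at least 4")
})

test_that("min_detectable_r matches a brute-force power simulation", {
  # at r = min_detectable_r(n) the two-tailed test should reject ~80% of
  # the time; simulate bivariate normal draws and count rejections
  for (n in c(21, 27)) {
    rho <- min_detectable_r(n)
    set.seed(n)
    rej <- vapply(1:4000, function(i) {
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      cor.test(x, y)$p.value < 0.05
    }, logical(1))
    expect_lt(abs(mean(rej) - 0.80), 0.03)
  }
})

test_that("median split halves even cohorts and is stable under ties", {
  v22 <- rnorm(22)
  g <- median_split(v22)
  expect_equal(as.vector(table(g)), c(11, 11))
  expect_true(max(v22[g == "low"]) <= min(v22[g == "high"]))
  expect_identical(as.character(median_split(1:4)), c("low", "low",
                                                      "high", "high"))
  expect_message(gt <- median_split(rep(1, 6)), "tie")
  expect_equal(as.vector(table(gt)), c(3, 3))
})

test_that("normality screening reports the more conservative test", {
  set.seed(33)
  d <- data.frame(subject = rep(sprintf("S%d", 1:12), each = 2),
                  cond = rep(c("a", "b"), 12),
                  y = c(rnorm(12), rnorm(12, 0.3)))
  out <- screen_and_test(d, "y", "subject", "cond")
  expect_true(out$reported %in% c("rm_anova", "friedman"))
  expect_gte(out$p, out$anova$p[1] - 1e-12)
})
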