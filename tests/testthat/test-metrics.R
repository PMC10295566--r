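test_that("missing samples are filled by mean or carried forward", {
  expect_equal(fill_missing(c(1, NA, 3), "mean"), c(1, 2, 3))
  expect_equal(fill_missing(c(NA, 2, NA, 4), "locf"), c(2, 2, 2, 4))
  expect_equal(fill_missing(c(NA, NA, 5), "locf"), c(5, 5, 5))
  x <- c(10, NA, 30, NA)
  expect_equal(fill_missing(x, "mean"), c(10, 20, 30, 20))
  # angle_signal input comes back as angle_signal, other columns untouched
  sig <- angle_signal(c(1, NA, 3), visibility = c(1, 0, 1), fps = 30)
  out <- fill_missing(sig, "locf")
  expect_s3_class(out, "angle_signal")
  expect_equal(out$theta, c(1, 1, 3))
  expect_equal(out$visibility, sig$visibility)
  expect_error(fill_missing(c(NA_real_, NA_real_), "mean"),
               class = "posegait_metric_error")
})

test_that("percentage error matches the closed form under constant offset", {
  t <- 0:99
  gold <- 90 + 10 * sin(2 * pi * t / 20)   # extrema at t = 5, 15: range R = 20
  for (c_off in c(1, 2.5, 7)) {
    dat <- tibble::tibble(sample = 1L, joint = "knee",
                          pred = gold + c_off, gold = gold)
    expect_equal(percentage_error(dat), 100 * c_off / 20, tolerance = 1e-10)
  }
  # identical signals score zero
  dat0 <- tibble::tibble(sample = 1L, joint = "knee", pred = gold, gold = gold)
  expect_equal(percentage_error(dat0), 0)
})

test_that("percentage error aggregates joints within samples, then samples", {
  set.seed(71)
  dat <- tidyr::expand_grid(sample = 1:3, joint = c("a", "b"), frame = 1:40) |>
    dplyr::mutate(gold = 90 + 10 * sin(2 * pi * frame / 20) +
                    2 * as.integer(factor(joint)),
                  pred = gold + rnorm(dplyr::n()))
  expect_equal(percentage_error(dat), oracle_pe(dat), tolerance = 1e-10)
  # invariant to a common rescaling of both signals
  scaled <- dplyr::mutate(dat, pred = pred * 3, gold = gold * 3)
  expect_equal(percentage_error(scaled), percentage_error(dat),
               tolerance = 1e-10)
  flat <- tibble::tibble(sample = 1L, joint = "a", pred = 1:5, gold = rep(2, 5))
  expect_error(percentage_error(flat), class = "posegait_metric_error")
  expect_error(percentage_error(tibble::tibble(pred = 1, gold = 1)),
               class = "posegait_metric_error")
})

test_that("DTW equals the cheapest alignment over all monotone paths", {
  set.seed(72)
  for (i in 1:12) {
    g <- round(stats::rnorm(sample(2:5, 1), 0, 5), 2)
    p <- round(stats::rnorm(sample(2:5, 1), 0, 5), 2)
    brute <- min(oracle_dtw_paths(g, p))
    expect_equal(dtw_distance(g, p, normalise = FALSE), brute,
                 tolerance = 1e-10)
    expect_equal(dtw_distance(g, p), brute / (length(g) + length(p)),
                 tolerance = 1e-10)
  }
})

test_that("DTW is symmetric, zero on identical series, tolerant of time shifts", {
  set.seed(73)
  x <- stats::rnorm(30, 90, 10)
  y <- stats::rnorm(25, 90, 10)
  expect_equal(dtw_distance(x, y), dtw_distance(y, x))
  expect_equal(dtw_distance(x, x), 0)
  # a time-shifted copy aligns far better than pointwise comparison suggests
  t <- seq(0, 4 * pi, length.out = 120)
  a <- 10 * sin(t)
  b <- 10 * sin(t - 0.4)
  expect_lt(dtw_distance(a, b) * (length(a) + length(b)),
            sum(abs(a - b)))
  expect_error(dtw_distance(numeric(0), x), class = "posegait_metric_error")
  expect_error(dtw_distance(c(1, NA), c(1, 2)), class = "posegait_metric_error")
})

test_that("Bland-Altman reproduces hand-computed agreement statistics", {
  set.seed(74)
  gold <- stats::rnorm(40, 50, 8)
  pred <- gold + stats::rnorm(40, 1.5, 2)
  ba <- bland_altman(tibble::tibble(pred = pred, gold = gold))
  d <- pred - gold
  expect_equal(ba$n, 40L)
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$sd_diff, stats::sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * stats::sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * stats::sd(d))
  tq <- stats::qt(0.975, 39)
  expect_equal(ba$ci_mean_lower, mean(d) - tq * stats::sd(d) / sqrt(40))
  se_loa <- sqrt(3 * stats::sd(d)^2 / 40)
  expect_equal(ba$ci_loa_high_upper, ba$loa_high + tq * se_loa)
  expect_true(ba$ks_p >= 0 && ba$ks_p <= 1)
  diffs <- attr(ba, "differences")
  expect_equal(diffs$diff, d)
  expect_equal(diffs$mean_pair, (pred + gold) / 2)
})

test_that("relative Bland-Altman reports percentage-of-gold differences", {
  gold <- c(10, 20, 40, 50)
  pred <- gold * 1.1
  ba <- bland_altman(tibble::tibble(pred = pred, gold = gold), relative = TRUE)
  expect_equal(ba$mean_diff, 10, tolerance = 1e-10)
  expect_equal(ba$sd_diff, 0, tolerance = 1e-10)
  bad <- tibble::tibble(pred = c(1, 2, 3), gold = c(1, 0, 3))
  expect_error(bland_altman(bad, relative = TRUE),
               class = "posegait_metric_error")
  expect_error(bland_altman(tibble::tibble(pred = 1:2, gold = 1:2)),
               class = "posegait_metric_error")
})

test_that("correlation and regression recover a known linear relation", {
  set.seed(75)
  x <- stats::runif(50, 0, 10)
  y <- 2.5 * x - 4
  out <- correlation_regression(tibble::tibble(x = x, y = y))
  expect_equal(out$pearson_r, 1, tolerance = 1e-12)
  expect_equal(out$slope, 2.5, tolerance = 1e-10)
  expect_equal(out$intercept, -4, tolerance = 1e-9)
  noisy <- correlation_regression(tibble::tibble(x = x, y = y + rnorm(50)))
  expect_equal(noisy$pearson_r, stats::cor(x, y + 0), tolerance = 0.1)
  expect_error(correlation_regression(tibble::tibble(x = rep(1, 5), y = 1:5)),
               class = "posegait_metric_error")
})

test_that("signal agreement combines per-joint scores with an average row", {
  t <- 0:89
  mk <- function(offset, amp) angle_signal(offset + amp * sin(2 * pi * t / 30),
                                           fps = 30)
  gold <- list(near_knee = mk(140, 20), near_hip = mk(160, 10))
  pred <- list(near_knee = mk(140, 20), near_hip = mk(161, 10))
  tab <- signal_agreement(pred, gold)
  expect_equal(tab$joint, c("near_knee", "near_hip", "average"))
  expect_equal(tab$pe[3], mean(tab$pe[1:2]))
  expect_equal(tab$dtw[3], mean(tab$dtw[1:2]))
  expect_equal(tab$pe[1], 0)
  expect_gt(tab$pe[2], 0)
  short <- list(near_knee = mk(140, 20)[1:10, ])
  expect_error(signal_agreement(short, gold), class = "posegait_metric_error")
  expect_error(signal_agreement(list(a = mk(1, 1)), gold),
               class = "posegait_metric_error")
})
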