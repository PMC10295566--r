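#' Fill missing samples of a signal
#'
#' Unfiltered ("original") signals contain missing angles where the geometry
#' could not be computed. Before scoring them, missing values are substituted:
#' `"mean"` uses the mean of the valid samples (used for percentage error, so
#' gaps do not inflate the squared error) and `"locf"` carries the most recent
#' valid value forward (used for DTW, preserving local shape), with a leading
#' gap back-filled from the first valid value.
#'
#' @param signal An [angle_signal()] or a numeric vector with `NA`s.
#' @param mode `"mean"` or `"locf"`.
#' @return Same type as the input, gap-free.
#' @export
#' @examples
#' fill_missing(c(1, NA, 3), "mean") # 1 2 3
#' fill_missing(c(NA, 2), "locf")    # 2 2
fill_missing <- function(signal, mode = c("mean", "locf")) {
  mode <- match.arg(mode)
  fill_vec <- function(x) {
    if (all(is.na(x))) {
      rlang::abort("all samples missing; nothing to fill from",
                   class = "posegait_metric_error")
    }
    if (mode == "mean") {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    } else {
      x <- zoo::na.locf(x, na.rm = FALSE)
      zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)
    }
  }
  if (is.numeric(signal)) {
    return(fill_vec(signal))
  }
  assert_angle_signal(signal)
  out <- tibble::as_tibble(signal)
  out$theta <- fill_vec(out$theta)
  rewrap_signal(out, signal)
}

#' Percentage error between predicted and gold-standard signals
#'
#' For each (sample, joint) pair the frame-wise RMSE is divided by the gold
#' signal's range (its flexion); the ratios are averaged over joints within a
#' sample, then over samples, and expressed as a percentage. The measure is
#' invariant to a common rescaling of prediction and gold.
#'
#' @param data Data frame with columns `sample`, `joint`, `pred`, `gold`
#'   (one row per frame).
#' @return Percentage error (a single nonnegative number).
#' @export
percentage_error <- function(data) {
  needed <- c("sample", "joint", "pred", "gold")
  if (!all(needed %in% names(data))) {
    rlang::abort("data needs columns sample, joint, pred, gold",
                 class = "posegait_metric_error")
  }
  per_joint <- data |>
    dplyr::group_by(.data$sample, .data$joint) |>
    dplyr::summarise(
      rmse = sqrt(mean((.data$pred - .data$gold)^2)),
      range = max(.data$gold) - min(.data$gold),
      .groups = "drop"
    )
  if (any(per_joint$range <= 0)) {
    bad <- per_joint[per_joint$range <= 0, ][1, ]
    rlang::abort(sprintf("gold signal is constant for sample %s, joint %s",
                         format(bad$sample), format(bad$joint)),
                 class = "posegait_metric_error")
  }
  per_sample <- per_joint |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(pe = mean(.data$rmse / .data$range), .groups = "drop")
  100 * mean(per_sample$pe)
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW between two series with absolute difference
#' as the point-matching cost and boundary `DTW(1,1) = |g1 - p1|`; each cell
#' extends the cheapest of its left, diagonal and lower neighbours. With
#' `normalise = TRUE` the distance is divided by the total length
#' `length(g) + length(p)` (equal-length series: `2m`).
#'
#' @param g,p Nonempty numeric series (no NAs).
#' @param normalise Divide by total length? Default `TRUE`.
#' @return Nonnegative distance.
#' @export
dtw_distance <- function(g, p, normalise = TRUE) {
  if (!length(g) || !length(p)) {
    rlang::abort("series must be nonempty", class = "posegait_metric_error")
  }
  if (anyNA(g) || anyNA(p)) {
    rlang::abort("series must not contain missing values (see fill_missing)",
                 class = "posegait_metric_error")
  }
  n <- length(g)
  m <- length(p)
  cost <- abs(outer(g, p, "-"))
  D <- matrix(0, n, m)
  D[1, ] <- cumsum(cost[1, ])
  if (n > 1) {
    D[, 1] <- cumsum(cost[, 1])
    for (i in 2:n) {
      for (j in seq_len(m)[-1]) {
        D[i, j] <- cost[i, j] + min(D[i - 1, j], D[i - 1, j - 1], D[i, j - 1])
      }
    }
  }
  d <- D[n, m]
  if (normalise) d <- d / (n + m)
  d
}

#' Bland-Altman agreement analysis
#'
#' Computes the mean difference `d` and its standard deviation `s_d` over
#' paired measurements, the 95% limits of agreement `d +/- 1.96 s_d`, 95%
#' confidence intervals for the mean (t-based) and for each limit (standard
#' error `sqrt(3 s_d^2 / n)`), and a Kolmogorov-Smirnov normality p-value for
#' the differences. Differences are `pred - gold`, or `100 (pred - gold)/gold`
#' in relative mode.
#'
#' @param data Data frame with columns `pred` and `gold` (n >= 3 rows).
#' @param relative Report relative (percentage-of-gold) differences?
#' @return One-row tibble of class `bland_altman`: `n, mean_diff, sd_diff,
#'   loa_low, loa_high, ci_mean_lower, ci_mean_upper, ci_loa_low_lower,
#'   ci_loa_low_upper, ci_loa_high_lower, ci_loa_high_upper, ks_p`, with the
#'   differences attached as attribute `"differences"` for plotting.
#' @export
bland_altman <- function(data, relative = FALSE) {
  if (!all(c("pred", "gold") %in% names(data))) {
    rlang::abort("data needs columns pred and gold", class = "posegait_metric_error")
  }
  pred <- data$pred
  gold <- data$gold
  n <- length(pred)
  if (n < 3L) {
    rlang::abort("Bland-Altman needs at least 3 pairs",
                 class = "posegait_metric_error")
  }
  if (relative) {
    if (any(gold == 0)) {
      rlang::abort("relative differences undefined: gold contains zero",
                   class = "posegait_metric_error")
    }
    d <- 100 * (pred - gold) / gold
  } else {
    d <- pred - gold
  }
  dbar <- mean(d)
  sd_d <- stats::sd(d)
  loa_low <- dbar - 1.96 * sd_d
  loa_high <- dbar + 1.96 * sd_d
  tq <- stats::qt(0.975, n - 1)
  se_mean <- sd_d / sqrt(n)
  se_loa <- sqrt(3 * sd_d^2 / n)
  ks_p <- if (sd_d > 0) {
    suppressWarnings(stats::ks.test(d, "pnorm", mean = dbar, sd = sd_d)$p.value)
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    n = n,
    mean_diff = dbar,
    sd_diff = sd_d,
    loa_low = loa_low,
    loa_high = loa_high,
    ci_mean_lower = dbar - tq * se_mean,
    ci_mean_upper = dbar + tq * se_mean,
    ci_loa_low_lower = loa_low - tq * se_loa,
    ci_loa_low_upper = loa_low + tq * se_loa,
    ci_loa_high_lower = loa_high - tq * se_loa,
    ci_loa_high_upper = loa_high + tq * se_loa,
    ks_p = ks_p
  )
  structure(out, class = c("bland_altman", class(out)),
            differences = tibble::tibble(mean_pair = (pred + gold) / 2, diff = d),
            relative = relative)
}

#' Pearson correlation and OLS regression of paired values
#'
#' Ordinary least squares of `y` on `x` plus the Pearson correlation
#' coefficient, as used to relate predicted striding speeds and T-squared
#' scores to gold-standard values.
#'
#' @param data Data frame with columns `x` and `y` (n >= 3, `x` not constant).
#' @return One-row tibble: `pearson_r`, `slope`, `intercept`.
#' @export
correlation_regression <- function(data) {
  if (!all(c("x", "y") %in% names(data))) {
    rlang::abort("data needs columns x and y", class = "posegait_metric_error")
  }
  x <- data$x
  y <- data$y
  if (length(x) < 3L) {
    rlang::abort("need at least 3 pairs", class = "posegait_metric_error")
  }
  if (stats::sd(x) <= .Machine$double.eps) {
    rlang::abort("x has no variance; regression undefined",
                 class = "posegait_metric_error")
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    pearson_r = stats::cor(x, y),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1])
  )
}

#' Full agreement report between predicted and gold signals
#'
#' Convenience wrapper combining [percentage_error()] (missing values filled
#' with the signal mean) and [dtw_distance()] (missing values carried forward)
#' per joint, as used by the `evaluate` CLI subcommand.
#'
#' @param pred,gold Named lists of [angle_signal()]s with matching names; each
#'   pred/gold pair must have equal length.
#' @return Tibble with one row per joint: `joint`, `pe`, `dtw`, plus an
#'   `"average"` row following the mean-of-joints aggregation convention.
#' @export
signal_agreement <- function(pred, gold) {
  joints <- intersect(names(pred), names(gold))
  if (!length(joints)) {
    rlang::abort("pred and gold share no joint names",
                 class = "posegait_metric_error")
  }
  rows <- purrr::map(joints, function(j) {
    ps <- pred[[j]]$theta
    gs <- gold[[j]]$theta
    if (length(ps) != length(gs)) {
      rlang::abort(sprintf("length mismatch for joint %s", j),
                   class = "posegait_metric_error")
    }
    pe <- percentage_error(tibble::tibble(
      sample = 1L, joint = j,
      pred = fill_missing(ps, "mean"),
      gold = fill_missing(gs, "mean")
    ))
    dtw <- dtw_distance(fill_missing(gs, "locf"), fill_missing(ps, "locf"),
                        normalise = TRUE)
    tibble::tibble(joint = j, pe = pe, dtw = dtw)
  })
  tab <- dplyr::bind_rows(rows)
  dplyr::bind_rows(tab, tibble::tibble(joint = "average",
                                       pe = mean(tab$pe),
                                       dtw = mean(tab$dtw)))
}
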