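#' Kalman filter configuration
#'
#' A constant-acceleration Kalman filter on the state (angle, angular
#' velocity, angular acceleration) with scalar angle measurements. The process
#' noise covariance is `Q = alpha * I3` and the measurement noise variance is
#' `beta` (the measurement is scalar, so `R` collapses to a scalar). Missing
#' measurements - frames whose visibility falls below `visibility_threshold` -
#' are substituted according to `mode`: `"KF1"` feeds back the prior
#' prediction of the current step, `"KF2"` the posterior estimate of the
#' previous step. KF2 keeps the filter anchored to its last corrected value
#' instead of extrapolating the kinematic model through non-linear intervals.
#'
#' @param alpha Process-noise coefficient (> 0).
#' @param beta Measurement-noise variance (> 0).
#' @param dt Inter-frame interval in seconds (> 0), typically `1 / fps`, so
#'   velocity and acceleration carry per-second units.
#' @param p0_scale Diagonal of the initial error covariance (default 100).
#' @param mode `"KF2"` or `"KF1"` missing-measurement substitution.
#' @param visibility_threshold Fraction below which a frame counts as missing.
#' @return Object of class `kalman_config`.
#' @export
kalman_config <- function(alpha, beta, dt,
                          p0_scale = 100,
                          mode = c("KF2", "KF1"),
                          visibility_threshold = 0.40) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(p0_scale), length(p0_scale) == 1L, p0_scale > 0,
            is.numeric(visibility_threshold), length(visibility_threshold) == 1L,
            visibility_threshold >= 0, visibility_threshold <= 1)
  structure(list(alpha = alpha, beta = beta, dt = dt, p0_scale = p0_scale,
                 mode = mode, visibility_threshold = visibility_threshold),
            class = "kalman_config")
}

#' Kalman filter state
#'
#' Holds the posterior state vector `s = (theta, v, a)`, its covariance `P`,
#' and after [kf_predict()] the one-step prior `prior_s`, `prior_P`.
#'
#' @param theta Initial angle (degrees).
#' @param v,a Initial angular velocity / acceleration (degrees per s, s^2).
#' @param p0_scale Diagonal of the initial `P`.
#' @return Object of class `kalman_state`.
#' @export
kalman_state <- function(theta, v = 0, a = 0, p0_scale = 100) {
  structure(list(s = c(theta, v, a),
                 P = diag(p0_scale, 3),
                 prior_s = NULL, prior_P = NULL),
            class = "kalman_state")
}

transition_matrix <- function(dt) {
  matrix(c(1, dt, dt^2 / 2,
           0, 1, dt,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Kalman prediction step
#'
#' Propagates the posterior through the constant-acceleration model:
#' `prior_s = A s`, `prior_P = A P A' + Q` with `Q = alpha * I3`.
#'
#' @param state A [kalman_state()].
#' @param config A [kalman_config()].
#' @return The state with `prior_s` / `prior_P` filled in.
#' @export
kf_predict <- function(state, config) {
  A <- transition_matrix(config$dt)
  state$prior_s <- drop(A %*% state$s)
  state$prior_P <- A %*% state$P %*% t(A) + diag(config$alpha, 3)
  state
}

#' Kalman update step
#'
#' Scalar-measurement update with `H = (1, 0, 0)`: gain
#' `K = prior_P H' / (H prior_P H' + beta)`, then
#' `s = prior_s + K (z - H prior_s)` and `P = (I - K H) prior_P`.
#' `P` is re-symmetrised after the update to keep it positive semidefinite
#' over long runs.
#'
#' @param state A [kalman_state()] on which [kf_predict()] has been applied.
#' @param z Measured angle in degrees (finite).
#' @param config A [kalman_config()].
#' @return The state with posterior `s`, `P` replaced.
#' @export
kf_update <- function(state, z, config) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z)) {
    rlang::abort("measurement `z` must be a finite number",
                 class = "posegait_kalman_error")
  }
  if (is.null(state$prior_s)) {
    rlang::abort("kf_update called before kf_predict",
                 class = "posegait_kalman_error")
  }
  pP <- state$prior_P
  S <- pP[1, 1] + config$beta
  K <- pP[, 1] / S
  state$s <- state$prior_s + K * (z - state$prior_s[1])
  P <- (diag(3) - K %*% t(c(1, 0, 0))) %*% pP
  state$P <- (P + t(P)) / 2
  state
}

#' Filter an angle signal with visibility-gated measurement substitution
#'
#' Runs the forward Kalman filter over the signal. The filter is seeded at the
#' first frame whose visibility reaches the threshold, with state
#' `(theta, 0, 0)` and covariance `p0_scale * I`; frames before the seed are
#' back-filled with the seed value. From the next frame on, the measurement
#' fed to the update is the observed angle when visibility >= threshold, else
#' the substitution dictated by `config$mode`. The measurement actually used
#' is logged per frame in column `z`, with `measured` flagging real
#' observations, so the substitution strategy is directly inspectable.
#'
#' @param signal An [angle_signal()].
#' @param config A [kalman_config()].
#' @return An [angle_signal()] whose `theta` is the posterior estimate, with
#'   extra columns `z`, `measured` and `raw` (the input angles).
#' @export
kf_filter_signal <- function(signal, config) {
  assert_angle_signal(signal)
  theta <- signal$theta
  vis <- signal$visibility
  n <- length(theta)
  if (n == 0L) {
    rlang::abort("empty signal", class = "posegait_kalman_error")
  }
  valid <- !is.na(theta) & vis >= config$visibility_threshold
  if (!any(valid)) {
    rlang::abort("no frame reaches the visibility threshold; filter cannot initialise",
                 class = "posegait_kalman_error")
  }
  i0 <- which(valid)[1]
  post <- rep(NA_real_, n)
  zlog <- rep(NA_real_, n)
  measured <- rep(NA, n)

  seed <- theta[i0]
  post[seq_len(i0)] <- seed
  zlog[seq_len(i0)] <- seed
  measured[i0] <- TRUE
  state <- kalman_state(seed, p0_scale = config$p0_scale)

  if (i0 < n) {
    for (t in (i0 + 1L):n) {
      prev_post <- state$s[1]
      state <- kf_predict(state, config)
      if (valid[t]) {
        z <- theta[t]
        measured[t] <- TRUE
      } else {
        z <- if (config$mode == "KF1") state$prior_s[1] else prev_post
        measured[t] <- FALSE
      }
      state <- kf_update(state, z, config)
      post[t] <- state$s[1]
      zlog[t] <- z
    }
  }

  out <- tibble::tibble(frame = signal$frame,
                        theta = pmax(0, pmin(180, post)),
                        visibility = vis,
                        z = zlog,
                        measured = measured,
                        raw = theta)
  rewrap_signal(out, signal)
}

#' Kalman configuration for a body side
#'
#' Far-side joints are occluded and noisier than near-side joints when a
#' monocular camera films the sagittal plane, so each side gets its own
#' process/measurement noise coefficients from the pipeline config.
#'
#' @param side `"near"` or `"far"`.
#' @param config A [gait_config()].
#' @return A [kalman_config()] with `(alpha_far, beta_far)` for the far side
#'   and `(alpha_near, beta_near)` for the near side, `dt = 1 / fps`.
#' @export
select_side_config <- function(side, config = gait_config()) {
  side <- match.arg(side, c("near", "far"))
  if (side == "far") {
    alpha <- config$alpha_far
    beta <- config$beta_far
  } else {
    alpha <- config$alpha_near
    beta <- config$beta_near
  }
  kalman_config(alpha = alpha, beta = beta, dt = 1 / config$fps,
                p0_scale = config$p0_scale, mode = config$kf_mode,
                visibility_threshold = config$visibility_threshold)
}

#' Grid search over Kalman noise coefficients
#'
#' The harness used to pick side-specific `(alpha, beta)` pairs: for every
#' combination it runs the Kalman filter plus the frequency-domain filter over
#' each (signal, gold) pair and accumulates the summed normalised DTW distance
#' and summed percentage error against the cut-matched gold standard.
#'
#' @param pairs List of `list(signal = <angle_signal>, gold = <angle_signal>)`.
#' @param alphas,betas Numeric vectors of candidate coefficients.
#' @param config A [gait_config()] supplying fps, cut, component count, mode
#'   and visibility threshold.
#' @return Tibble with columns `alpha`, `beta`, `dtw` (summed normalised DTW)
#'   and `pe` (summed percentage error), one row per combination.
#' @export
noise_grid_search <- function(pairs, alphas, betas, config = gait_config()) {
  if (!length(pairs)) {
    rlang::abort("`pairs` must contain at least one (signal, gold) pair",
                 class = "posegait_validation_error")
  }
  if (!length(alphas) || !length(betas)) {
    rlang::abort("alpha/beta grids must be nonempty",
                 class = "posegait_validation_error")
  }
  grid <- tidyr::expand_grid(alpha = alphas, beta = betas)
  res <- purrr::pmap(grid, function(alpha, beta) {
    kcfg <- kalman_config(alpha = alpha, beta = beta, dt = 1 / config$fps,
                          p0_scale = config$p0_scale, mode = config$kf_mode,
                          visibility_threshold = config$visibility_threshold)
    per_pair <- purrr::map(pairs, function(p) {
      filt <- fdf_filter(kf_filter_signal(p$signal, kcfg), config)
      gold <- apply_cut(p$gold, config$cut)
      rng <- max(gold$theta) - min(gold$theta)
      if (rng <= 0) {
        rlang::abort("gold signal is constant; percentage error undefined",
                     class = "posegait_metric_error")
      }
      rmse <- sqrt(mean((filt$theta - gold$theta)^2))
      c(dtw = dtw_distance(gold$theta, filt$theta, normalise = TRUE),
        pe = 100 * rmse / rng)
    })
    mat <- do.call(rbind, per_pair)
    tibble::tibble(dtw = sum(mat[, "dtw"]), pe = sum(mat[, "pe"]))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}
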