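test_that("prediction propagates the constant-acceleration model", {
  cfg <- kalman_config(alpha = 0.5, beta = 1, dt = 1 / 30)
  st <- kf_predict(kalman_state(10), cfg)
  expect_equal(st$prior_s[1], 10)
  st <- kf_predict(kalman_state(0, v = 30), cfg)
  expect_equal(st$prior_s[1], 1.0)
  set.seed(21)
  for (i in 1:20) {
    s0 <- rnorm(3, sd = 10)
    st <- kalman_state(s0[1], s0[2], s0[3], p0_scale = runif(1, 1, 100))
    st$P <- crossprod(matrix(rnorm(9), 3))  # random PSD covariance
    dt <- runif(1, 0.01, 0.2)
    cfg <- kalman_config(alpha = runif(1, 0.01, 10), beta = 1, dt = dt)
    A <- matrix(c(1, dt, dt^2 / 2, 0, 1, dt, 0, 0, 1), 3, 3, byrow = TRUE)
    pred <- kf_predict(st, cfg)
    expect_equal(pred$prior_s, drop(A %*% st$s), tolerance = 1e-12)
    expect_equal(pred$prior_P, A %*% st$P %*% t(A) + cfg$alpha * diag(3),
                 tolerance = 1e-12)
  }
})

test_that("update matches a textbook scalar-measurement Kalman oracle", {
  set.seed(22)
  for (i in 1:30) {
    dt <- runif(1, 0.01, 0.2)
    alpha <- 10^runif(1, -3, 1)
    beta <- 10^runif(1, -3, 1)
    cfg <- kalman_config(alpha = alpha, beta = beta, dt = dt)
    st <- kalman_state(rnorm(1, 90, 20), rnorm(1), rnorm(1))
    st$P <- crossprod(matrix(rnorm(9), 3))
    z <- rnorm(1, 90, 20)
    ours <- kf_update(kf_predict(st, cfg), z, cfg)
    ref <- oracle_kf_step(st$s, st$P, z, dt, alpha, beta)
    expect_equal(ours$s, ref$s, tolerance = 1e-10)
    expect_equal(ours$P, ref$P, tolerance = 1e-10)
  }
})

test_that("update limits: exact measurement as beta -> 0, ignored as beta -> Inf", {
  st <- kalman_state(10)
  cfg0 <- kalman_config(alpha = 1, beta = 1e-12, dt = 1 / 30)
  out0 <- kf_update(kf_predict(st, cfg0), 42, cfg0)
  expect_equal(out0$s[1], 42, tolerance = 1e-6)
  cfgI <- kalman_config(alpha = 1e-6, beta = 1e12, dt = 1 / 30)
  stI <- kf_predict(kalman_state(10), cfgI)
  outI <- kf_update(stI, 42, cfgI)
  expect_equal(outI$s[1], stI$prior_s[1], tolerance = 1e-6)
  expect_error(kf_update(stI, NaN, cfgI), class = "posegait_kalman_error")
})

test_that("filtering a constant fully-visible signal converges to it", {
  sig <- angle_signal(rep(90, 100), fps = 30)
  cfg <- kalman_config(alpha = 1, beta = 1, dt = 1 / 30)
  out <- kf_filter_signal(sig, cfg)
  expect_lt(max(abs(out$theta[50:100] - 90)), 0.01)
})

test_that("with all frames visible and tiny beta the filter passes the signal through", {
  sig <- generate_gait_signal(aligned_hip_spec(noise_sd = 1, seed = 5))
  cfg <- kalman_config(alpha = 1, beta = 1e-10, dt = 1 / 30)
  out <- kf_filter_signal(sig, cfg)
  expect_equal(out$theta, sig$theta, tolerance = 1e-6)
})

test_that("the logged measurement sequence obeys the substitution strategy", {
  drop_win <- list(c(50, 10, 0.2))
  sig <- generate_gait_signal(aligned_hip_spec(noise_sd = 0.5, dropout = drop_win,
                                               seed = 9))
  for (mode in c("KF1", "KF2")) {
    cfg <- kalman_config(alpha = 10, beta = 1, dt = 1 / 30, mode = mode)
    out <- kf_filter_signal(sig, cfg)
    vis_idx <- which(out$visibility >= 0.4)
    expect_true(all(out$measured[vis_idx]))
    expect_equal(out$z[vis_idx], sig$theta[vis_idx])
    hid <- which(out$visibility < 0.4)
    expect_true(all(!out$measured[hid]))
    if (mode == "KF2") {
      # missing measurement = previous posterior, exactly
      expect_equal(out$z[hid], out$theta[hid - 1])
    }
  }
})

test_that("KF1 and KF2 agree when no frame falls below the threshold", {
  sig <- generate_gait_signal(aligned_hip_spec(noise_sd = 2, seed = 3))
  c1 <- kalman_config(alpha = 10, beta = 1, dt = 1 / 30, mode = "KF1")
  c2 <- kalman_config(alpha = 10, beta = 1, dt = 1 / 30, mode = "KF2")
  expect_equal(kf_filter_signal(sig, c1)$theta, kf_filter_signal(sig, c2)$theta)
})

test_that("error covariance stays symmetric positive semidefinite over long runs", {
  cfg <- kalman_config(alpha = 0.01, beta = 0.001, dt = 1 / 30)
  st <- kalman_state(90)
  set.seed(24)
  min_eig <- Inf
  for (t in 1:10000) {
    st <- kf_update(kf_predict(st, cfg), 90 + rnorm(1, sd = 3), cfg)
    if (t %% 100 == 0) {
      expect_equal(st$P, t(st$P))
      min_eig <- min(min_eig, min(eigen(st$P, symmetric = TRUE,
                                        only.values = TRUE)$values))
    }
  }
  expect_gt(min_eig, -1e-9)
})

test_that("posterior substitution beats prior substitution across dropout placements", {
  rmse_mode <- function(mode, seed) {
    start <- withr::with_seed(seed * 7L, sample(40:130, 1))
    sp <- gait_signal_spec(fundamental = 0.9,
                           harmonics = list(c(1, 12, 0), c(2, 3, 0.6)),
                           offset = 160, noise_sd = 1, duration = 150, fps = 30,
                           seed = seed, dropout = list(c(start, 15, 0.2)))
    s <- generate_gait_signal(sp)
    f <- kf_filter_signal(s, kalman_config(alpha = 10, beta = 1, dt = 1 / 30,
                                           mode = mode))
    win <- which(s$visibility < 0.4)
    sqrt(mean((f$theta[win] - s$truth[win])^2))
  }
  seeds <- 1:100
  r1 <- vapply(seeds, function(s) rmse_mode("KF1", s), numeric(1))
  r2 <- vapply(seeds, function(s) rmse_mode("KF2", s), numeric(1))
  expect_lte(mean(r2), mean(r1))
})

test_that("side-specific noise configs follow the pipeline defaults", {
  cfg <- gait_config()
  far <- select_side_config("far", cfg)
  expect_equal(far$alpha, 1e-2)
  expect_equal(far$beta, 1e-3)
  near <- select_side_config("near", cfg)
  expect_equal(near$alpha, 10)
  expect_equal(near$beta, 1)
  custom <- gait_config(alpha_far = 7, beta_far = 0.5)
  expect_equal(select_side_config("far", custom)$alpha, 7)
  expect_equal(select_side_config("far", custom)$beta, 0.5)
})

test_that("a signal never reaching the threshold refuses to initialise", {
  sig <- angle_signal(rep(90, 50), visibility = rep(0.1, 50), fps = 30)
  cfg <- kalman_config(alpha = 1, beta = 1, dt = 1 / 30)
  expect_error(kf_filter_signal(sig, cfg), class = "posegait_kalman_error")
})

test_that("the noise grid search recomputes each cell consistently", {
  mk_pair <- function(seed) {
    noisy <- generate_gait_signal(aligned_hip_spec(noise_sd = 2, seed = seed))
    gold <- angle_signal(noisy$truth, fps = 30)
    list(signal = noisy, gold = gold)
  }
  pairs <- list(mk_pair(31), mk_pair(32))
  cfg <- gait_config()
  tab <- noise_grid_search(pairs, alphas = c(0.1, 10), betas = c(0.01, 1), cfg)
  expect_equal(nrow(tab), 4L)
  # each cell equals an independent per-pair recomputation
  for (r in seq_len(nrow(tab))) {
    kcfg <- kalman_config(alpha = tab$alpha[r], beta = tab$beta[r], dt = 1 / 30)
    vals <- vapply(pairs, function(p) {
      filt <- fdf_filter(kf_filter_signal(p$signal, kcfg), cfg)
      gold <- apply_cut(p$gold, cfg$cut)
      c(dtw_distance(gold$theta, filt$theta),
        100 * sqrt(mean((filt$theta - gold$theta)^2)) /
          (max(gold$theta) - min(gold$theta)))
    }, numeric(2))
    expect_equal(tab$dtw[r], sum(vals[1, ]), tolerance = 1e-12)
    expect_equal(tab$pe[r], sum(vals[2, ]), tolerance = 1e-12)
  }
  # a noiseless signal scores ~0 percentage error in every cell
  clean <- mk_pair(33)
  clean$signal <- angle_signal(clean$gold$theta, fps = 30)
  tab0 <- noise_grid_search(list(clean), alphas = 1, betas = 1e-6, cfg)
  expect_equal(nrow(tab0), 1L)
  expect_lt(tab0$pe, 0.5)
  expect_error(noise_grid_search(list(), 1, 1, cfg),
               class = "posegait_validation_error")
  expect_error(noise_grid_search(pairs, numeric(0), 1, cfg),
               class = "posegait_validation_error")
})
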