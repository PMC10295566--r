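test_that("angle_between matches the cosine-law formula and clamps", {
  expect_equal(angle_between(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(angle_between(c(0, 1, 0), c(1, -1, 0)), 135)
  # near-antiparallel vectors must not produce NaN from rounding
  u <- c(1, 1e-9, 0)
  expect_true(is.finite(angle_between(u, -u)))
  set.seed(11)
  for (i in 1:25) {
    u <- rnorm(3)
    v <- rnorm(3)
    expected <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(angle_between(u, v), expected, tolerance = 1e-9)
  }
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)),
               class = "posegait_geometry_error")
})

test_that("knee angle is the included angle at the knee", {
  expect_equal(knee_angle(c(0, 1, 0), c(0, 0, 0), c(0, -1, 0)), 180)
  expect_equal(knee_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 90)
  expect_error(knee_angle(c(0, 1, 0), c(0, 1, 0), c(1, 0, 0)),
               class = "posegait_geometry_error")
})

test_that("virtual forward vector is the rotated, flattened shoulder vector", {
  f <- virtual_forward_vector(c(-1, 0, 0), c(1, 0, 0), "+y")
  expect_equal(f, c(0, 0, -1))
  # vertical offset between shoulders leaves no vertical component
  f2 <- virtual_forward_vector(c(-1, 0.4, 0), c(1, -0.2, 0), "+y")
  expect_equal(f2[2], 0)
  set.seed(12)
  for (i in 1:25) {
    l <- rnorm(3)
    r <- l + rnorm(3)
    f <- virtual_forward_vector(l, r, "+z")
    expect_equal(sum(f * c(0, 0, 1)), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum(f^2)), 1, tolerance = 1e-12)
  }
  expect_error(virtual_forward_vector(c(0, 0, 0), c(0, 1, 0), "+y"),
               class = "posegait_geometry_error")
})

test_that("hip angle measures the thigh against the forward ray", {
  expect_equal(hip_angle(c(0, 0, 1), c(0, 0, 0), c(0, -1, 1)), 45)
  expect_equal(hip_angle(c(1, 0, 0), c(0, 2, 0), c(0, 1, 0)), 90)
})

test_that("stick-walker signals recover the generating profiles", {
  w <- make_walker()
  sigs <- extract_angle_signals(w$pose)
  expect_lt(max(abs(sigs$near_knee$theta - w$profiles$right_knee)), 1e-6)
  expect_lt(max(abs(sigs$near_hip$theta - w$profiles$right_hip)), 1e-6)
  expect_lt(max(abs(sigs$far_knee$theta - w$profiles$left_knee)), 1e-6)
  expect_lt(max(abs(sigs$far_hip$theta - w$profiles$left_hip)), 1e-6)
})

test_that("hip angle avoids the 180-degree fold of the naive construction", {
  # thigh swinging through alignment with the trunk: the shoulder-hip-knee
  # angle saturates at 180 and folds back, while the forward-referenced hip
  # angle tracks the generating profile smoothly through the crossing
  w <- generate_walker(walker_spec(
    hip_spec = gait_signal_spec(fundamental = 0.9,
                                harmonics = list(c(1, 20, 0)), offset = 90,
                                duration = 111, fps = 30),
    knee_spec = aligned_knee_spec()
  ))
  sigs <- extract_angle_signals(w$pose)
  pose <- w$pose
  frames <- sort(unique(pose$frame))
  naive <- vapply(frames, function(t) {
    at <- function(j) unlist(pose[pose$frame == t & pose$joint == j, c("x", "y", "z")])
    sh <- (at("left_shoulder") + at("right_shoulder")) / 2
    angle_between(sh - at("right_hip"), at("right_knee") - at("right_hip"))
  }, numeric(1))
  # the naive angle hits the 180 ceiling and reverses; the generating profile
  # is monotone between its extrema, so naive acquires extra turning points
  turning <- function(x) sum(diff(sign(diff(x))) != 0)
  # ceiling below 180 because of the lateral hip offset, but saturation and
  # reversal still occur there
  expect_gt(max(naive), 160)
  expect_gt(turning(naive), turning(w$profiles$right_hip))
  # forward-referenced signal is fold-free: it still matches the generator
  expect_lt(max(abs(sigs$near_hip$theta - w$profiles$right_hip)), 1e-6)
})

test_that("side assignment follows visibility, ties fall back to depth then left", {
  w_right_near <- make_walker()
  s1 <- extract_angle_signals(w_right_near$pose)
  expect_identical(attr(s1$near_knee, "body_side"), "right")
  w_left_near <- make_walker(near_side = "left")
  s2 <- extract_angle_signals(w_left_near$pose)
  expect_identical(attr(s2$near_knee, "body_side"), "left")
  # equal visibility: depth axis decides (near = smaller depth coordinate)
  w_tie <- make_walker(near_visibility = 1, far_visibility = 1)
  s3 <- extract_angle_signals(w_tie$pose, depth_axis = "+z")
  expect_identical(attr(s3$near_knee, "body_side"), "right")
  s4 <- extract_angle_signals(w_tie$pose)
  expect_identical(attr(s4$near_knee, "body_side"), "left")
})

test_that("signal visibility is the minimum over constituent joints", {
  w <- make_walker()
  pose <- w$pose
  pose$visibility[pose$frame == 10 & pose$joint == "right_knee"] <- 0.2
  pose <- pose_sequence(tibble::as_tibble(pose), fps = 30)
  sigs <- extract_angle_signals(pose)
  expect_equal(sigs$near_knee$visibility[sigs$near_knee$frame == 10], 0.2)
  expect_equal(sigs$near_hip$visibility[sigs$near_hip$frame == 10], 0.2)
  expect_equal(sigs$far_knee$visibility[sigs$far_knee$frame == 10], 0.85)
})

test_that("angles are invariant to rigid translation and vertical-axis rotation", {
  w <- make_walker()
  base <- extract_angle_signals(w$pose)
  ang <- 0.7
  R <- matrix(c(cos(ang), 0, sin(ang),
                0, 1, 0,
                -sin(ang), 0, cos(ang)), 3, 3, byrow = TRUE)
  moved <- tibble::as_tibble(w$pose)
  xyz <- as.matrix(moved[, c("x", "y", "z")]) %*% t(R)
  moved$x <- xyz[, 1] + 5
  moved$y <- xyz[, 2] - 2
  moved$z <- xyz[, 3] + 1
  rotated <- extract_angle_signals(pose_sequence(moved, fps = 30))
  for (nm in names(base)) {
    expect_equal(rotated[[nm]]$theta, base[[nm]]$theta, tolerance = 1e-9)
  }
})

test_that("degenerate frames become missing samples with zero visibility", {
  w <- make_walker()
  pose <- tibble::as_tibble(w$pose)
  hiprow <- pose$frame == 5 & pose$joint == "right_hip"
  kneerow <- pose$frame == 5 & pose$joint == "right_knee"
  pose[hiprow, c("x", "y", "z")] <- pose[kneerow, c("x", "y", "z")]
  expect_warning(
    sigs <- extract_angle_signals(pose_sequence(pose, fps = 30)),
    "degenerate"
  )
  expect_true(is.na(sigs$near_knee$theta[sigs$near_knee$frame == 5]))
  expect_equal(sigs$near_knee$visibility[sigs$near_knee$frame == 5], 0)
})
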