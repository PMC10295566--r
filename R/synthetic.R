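#' Specification of a synthetic cosine-composed gait signal
#'
#' Joint-angle signals during walking are quasi-periodic and well approximated
#' by a sum of a few cosine harmonics of the stride frequency. This spec
#' describes such a signal plus Gaussian measurement noise and visibility
#' dropout windows emulating occlusion.
#'
#' @param fundamental Stride frequency in strides per second (> 0).
#' @param harmonics List of `c(multiple, amplitude_degrees, phase_rad)`
#'   triples; amplitudes >= 0.
#' @param offset Baseline angle in degrees.
#' @param noise_sd Gaussian noise standard deviation in degrees (>= 0).
#' @param dropout List of `c(start_frame, length, visibility)` windows
#'   (0-based start) whose frames get the given visibility instead of 1.
#' @param duration Number of frames.
#' @param fps Frame rate.
#' @param seed RNG seed for reproducibility.
#' @return Object of class `gait_signal_spec`.
#' @export
gait_signal_spec <- function(fundamental = 0.9,
                             harmonics = list(c(1, 12, 0), c(2, 3, 0.6)),
                             offset = 160,
                             noise_sd = 0,
                             dropout = list(),
                             duration = 150,
                             fps = 30,
                             seed = 1L) {
  if (!is.numeric(fundamental) || fundamental <= 0) {
    rlang::abort("`fundamental` must be positive", class = "posegait_validation_error")
  }
  if (!length(harmonics) ||
      !all(vapply(harmonics, function(h) length(h) == 3 && h[2] >= 0, logical(1)))) {
    rlang::abort("`harmonics` must be (multiple, amplitude >= 0, phase) triples",
                 class = "posegait_validation_error")
  }
  if (noise_sd < 0 || duration < 2 || fps <= 0) {
    rlang::abort("invalid noise_sd / duration / fps",
                 class = "posegait_validation_error")
  }
  for (w in dropout) {
    if (length(w) != 3 || w[1] < 0 || w[2] < 1 ||
        w[1] + w[2] > duration || w[3] < 0 || w[3] > 1) {
      rlang::abort("dropout windows must be (start, length, visibility) within the duration",
                   class = "posegait_validation_error")
    }
  }
  structure(list(fundamental = fundamental, harmonics = harmonics,
                 offset = offset, noise_sd = noise_sd, dropout = dropout,
                 duration = as.integer(duration), fps = fps,
                 seed = as.integer(seed)),
            class = "gait_signal_spec")
}

signal_truth <- function(spec) {
  t <- 0:(spec$duration - 1L)
  theta <- rep(spec$offset, spec$duration)
  for (h in spec$harmonics) {
    theta <- theta + h[2] * cos(2 * pi * h[1] * spec$fundamental * t / spec$fps + h[3])
  }
  theta
}

#' Generate a synthetic gait angle signal
#'
#' Realises a [gait_signal_spec()]: the noiseless cosine composition is kept
#' in column `truth`, Gaussian noise is added to produce `theta`, and
#' visibility is 1 except inside dropout windows. Bit-reproducible under the
#' spec's seed.
#'
#' @param spec A [gait_signal_spec()].
#' @return An [angle_signal()] with an extra `truth` column.
#' @export
generate_gait_signal <- function(spec) {
  stopifnot(inherits(spec, "gait_signal_spec"))
  truth <- signal_truth(spec)
  theta <- withr::with_seed(spec$seed, truth + stats::rnorm(spec$duration, 0, spec$noise_sd))
  theta <- pmax(0, pmin(180, theta))
  vis <- rep(1, spec$duration)
  for (w in spec$dropout) {
    idx <- seq.int(w[1] + 1L, length.out = w[2])
    vis[idx] <- w[3]
  }
  angle_signal(theta, visibility = vis, fps = spec$fps, truth = truth)
}

#' Specification of a kinematic stick walker
#'
#' A forward-kinematics walker that plants shoulders, hips, knees and ankles
#' in 3D from prescribed hip and knee angle profiles, walking along `+x` with
#' `+y` up and camera depth along `+z`. The same angle definitions used by the
#' kinematics stage drive the construction, so extracted signals recover the
#' generating profiles exactly at zero noise. One body side is offset along
#' the depth axis and given lower base visibility, creating a far side.
#'
#' @param hip_spec,knee_spec [gait_signal_spec()]s for the right-side hip and
#'   knee profiles; the left side uses the same spec with the fundamental
#'   phase shifted by pi (legs in antiphase) and a distinct noise seed.
#' @param thigh,shank,trunk,shoulder_width,hip_width Segment lengths (m).
#' @param speed Forward hip-centre speed (m/s; > 0 so the forward-vector
#'   handedness disambiguation sees a net displacement).
#' @param near_side `"right"` or `"left"`: the side closest to the camera.
#' @param depth_offset Depth (m) added to the far side's joints.
#' @param near_visibility,far_visibility Base visibility per side.
#' @param dropout_far Dropout windows (as in [gait_signal_spec()]) applied to
#'   the far side's lower-limb joints.
#' @return Object of class `walker_spec`.
#' @export
walker_spec <- function(hip_spec = gait_signal_spec(offset = 160,
                                                    harmonics = list(c(1, 12, 0), c(2, 3, 0.6))),
                        knee_spec = gait_signal_spec(offset = 140,
                                                     harmonics = list(c(1, 20, 0.3), c(2, 10, 1.1))),
                        thigh = 0.45, shank = 0.45, trunk = 0.55,
                        shoulder_width = 0.35, hip_width = 0.25,
                        speed = 1.2,
                        near_side = c("right", "left"),
                        depth_offset = 0.6,
                        near_visibility = 1.0,
                        far_visibility = 0.85,
                        dropout_far = list()) {
  near_side <- match.arg(near_side)
  stopifnot(inherits(hip_spec, "gait_signal_spec"),
            inherits(knee_spec, "gait_signal_spec"),
            thigh > 0, shank > 0, trunk > 0, shoulder_width > 0, hip_width > 0,
            depth_offset >= 0, speed >= 0,
            near_visibility >= 0, near_visibility <= 1,
            far_visibility >= 0, far_visibility <= 1)
  if (hip_spec$duration != knee_spec$duration || hip_spec$fps != knee_spec$fps) {
    rlang::abort("hip and knee specs must share duration and fps",
                 class = "posegait_validation_error")
  }
  structure(list(hip_spec = hip_spec, knee_spec = knee_spec,
                 thigh = thigh, shank = shank, trunk = trunk,
                 shoulder_width = shoulder_width, hip_width = hip_width,
                 speed = speed, near_side = near_side,
                 depth_offset = depth_offset,
                 near_visibility = near_visibility,
                 far_visibility = far_visibility,
                 dropout_far = dropout_far),
            class = "walker_spec")
}

shift_spec <- function(spec, phase, seed_offset) {
  spec$harmonics <- lapply(spec$harmonics, function(h) {
    c(h[1], h[2], h[3] + h[1] * phase)
  })
  spec$seed <- spec$seed + as.integer(seed_offset)
  spec
}

#' Generate a stick-walker pose sequence
#'
#' Realises a [walker_spec()] into a [pose_sequence()] plus the generating
#' (noisy, as-realised) angle profiles per side. Profiles are validated to lie
#' inside \[0, 180\] degrees so the arccos-based angle recovery is exact.
#'
#' @param spec A [walker_spec()].
#' @return List with `pose` (a [pose_sequence()]) and `profiles` (named list
#'   of numeric vectors: `right_hip`, `right_knee`, `left_hip`, `left_knee`,
#'   plus noiseless `*_truth` versions).
#' @export
generate_walker <- function(spec) {
  stopifnot(inherits(spec, "walker_spec"))
  fps <- spec$hip_spec$fps
  nfr <- spec$hip_spec$duration
  sides <- c("right", "left")
  far_side <- setdiff(sides, spec$near_side)

  profiles <- list()
  angles <- list()
  for (s in sides) {
    hs <- if (s == "right") spec$hip_spec else shift_spec(spec$hip_spec, pi, 101L)
    ks <- if (s == "right") spec$knee_spec else shift_spec(spec$knee_spec, pi, 202L)
    hsig <- generate_gait_signal(hs)
    ksig <- generate_gait_signal(ks)
    for (sig in list(hsig, ksig)) {
      if (any(sig$theta <= 0 | sig$theta >= 180)) {
        rlang::abort("walker angle profile leaves (0, 180); adjust the spec",
                     class = "posegait_validation_error")
      }
    }
    angles[[s]] <- list(hip = hsig$theta, knee = ksig$theta)
    profiles[[paste0(s, "_hip")]] <- hsig$theta
    profiles[[paste0(s, "_knee")]] <- ksig$theta
    profiles[[paste0(s, "_hip_truth")]] <- hsig$truth
    profiles[[paste0(s, "_knee_truth")]] <- ksig$truth
  }

  up <- c(0, 1, 0)
  lat <- c(0, 0, 1)       # depth axis
  dirvec <- function(a_deg) {
    a <- a_deg * pi / 180
    c(cos(a), -sin(a), 0) # rotates from forward (+x) downward
  }
  leg <- spec$thigh + spec$shank
  vis_base <- stats::setNames(c(spec$near_visibility, spec$far_visibility),
                              c(spec$near_side, far_side))
  vis_frames <- list()
  for (s in sides) {
    v <- rep(vis_base[[s]], nfr)
    if (s == far_side) {
      for (w in spec$dropout_far) {
        v[seq.int(w[1] + 1L, length.out = w[2])] <- w[3]
      }
    }
    vis_frames[[s]] <- v
  }

  rows <- vector("list", nfr)
  for (t in seq_len(nfr)) {
    x0 <- spec$speed * (t - 1) / fps
    hip_c <- c(x0, leg, 0)
    shoulder_c <- hip_c + spec$trunk * up
    # left shoulder at -z so the right-hand 90-degree rotation of l->r about +y
    # lands on +x (then the net-displacement flip is a no-op)
    l_sh <- shoulder_c - (spec$shoulder_width / 2) * lat
    r_sh <- shoulder_c + (spec$shoulder_width / 2) * lat
    joints <- list(left_shoulder = l_sh, right_shoulder = r_sh)
    for (s in sides) {
      zoff <- (if (s == "left") -spec$hip_width / 2 else spec$hip_width / 2) +
        (if (s == far_side) spec$depth_offset else 0)
      hip <- hip_c + zoff * lat
      phi <- angles[[s]]$hip[t]
      kap <- angles[[s]]$knee[t]
      knee <- hip + spec$thigh * dirvec(phi)
      ankle <- knee + spec$shank * dirvec(phi + 180 - kap)
      joints[[paste0(s, "_hip")]] <- hip
      joints[[paste0(s, "_knee")]] <- knee
      joints[[paste0(s, "_ankle")]] <- ankle
    }
    vis <- vapply(names(joints), function(j) {
      if (grepl("shoulder", j)) 1 else vis_frames[[sub("_.*", "", j)]][t]
    }, numeric(1))
    xyz <- do.call(rbind, joints)
    rows[[t]] <- tibble::tibble(frame = t - 1L, joint = names(joints),
                                x = unname(xyz[, 1]), y = unname(xyz[, 2]),
                                z = unname(xyz[, 3]),
                                visibility = unname(vis))
  }
  pose <- pose_sequence(dplyr::bind_rows(rows), fps = fps)
  list(pose = pose, profiles = profiles,
       near_side = spec$near_side, far_side = far_side)
}

#' Generate a synthetic subject cohort
#'
#' Draws seeded Gaussian gait feature vectors (see [gait_feature_names]) with
#' per-feature means and standard deviations, truncated to physiologically
#' valid ranges, for feature-model testing. Defaults emulate a young-adult
#' cohort: ages around 20, stride frequency around 0.9 strides/s, knee range
#' of motion near 60 degrees and hip near 30.
#'
#' @param n Number of subjects (>= 1).
#' @param stratum `"female"` or `"male"`; recorded in the `gender` column.
#' @param means,sds Named numeric vectors over [gait_feature_names]; defaults
#'   provided.
#' @param seed RNG seed.
#' @return Tibble with `gender` plus the eight features, `n` rows.
#' @export
generate_cohort <- function(n,
                            stratum = c("female", "male"),
                            means = NULL, sds = NULL,
                            seed = 1L) {
  stratum <- match.arg(stratum)
  if (!is.numeric(n) || n < 1) {
    rlang::abort("`n` must be >= 1", class = "posegait_validation_error")
  }
  def_means <- c(age = 20, mass = if (stratum == "female") 60 else 75,
                 height = if (stratum == "female") 1.66 else 1.78,
                 flexion_far_knee = 55, flexion_far_hip = 28,
                 flexion_near_knee = 60, flexion_near_hip = 30,
                 striding_speed = 0.9)
  def_sds <- c(age = 3, mass = 9, height = 0.07,
               flexion_far_knee = 8, flexion_far_hip = 5,
               flexion_near_knee = 8, flexion_near_hip = 5,
               striding_speed = 0.12)
  m <- def_means
  s <- def_sds
  if (!is.null(means)) m[names(means)] <- means
  if (!is.null(sds)) s[names(sds)] <- sds
  if (any(s < 0) || anyNA(m[gait_feature_names]) || anyNA(s[gait_feature_names])) {
    rlang::abort("invalid feature distribution", class = "posegait_validation_error")
  }
  lo <- c(age = 10, mass = 30, height = 1.2,
          flexion_far_knee = 1, flexion_far_hip = 1,
          flexion_near_knee = 1, flexion_near_hip = 1,
          striding_speed = 0.2)
  hi <- c(age = 90, mass = 160, height = 2.2,
          flexion_far_knee = 150, flexion_far_hip = 120,
          flexion_near_knee = 150, flexion_near_hip = 120,
          striding_speed = 2.5)
  draws <- withr::with_seed(seed, {
    vapply(gait_feature_names, function(f) {
      pmin(hi[[f]], pmax(lo[[f]], stats::rnorm(n, m[[f]], s[[f]])))
    }, numeric(n))
  })
  if (n == 1L) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, gait_feature_names))
  out <- tibble::as_tibble(as.data.frame(draws))
  dplyr::bind_cols(tibble::tibble(gender = rep(stratum, n)), out)
}
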