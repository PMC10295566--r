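#' Angle between two 3D vectors
#'
#' The elementary operation of the kinematics stage: the included angle from
#' the cosine law, `acos(u . v / (|u||v|))`, in degrees. The cosine argument is
#' clamped to \[-1, 1\] so collinear vectors never produce `NaN`.
#'
#' @param u,v Length-3 numeric vectors with nonzero norm.
#' @return Angle in degrees, in \[0, 180\].
#' @export
#' @examples
#' angle_between(c(0, 1, 0), c(1, -1, 0)) # 135
angle_between <- function(u, v) {
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu < .Machine$double.eps || nv < .Machine$double.eps) {
    rlang::abort("cannot take an angle with a zero-length vector",
                 class = "posegait_geometry_error")
  }
  ca <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, ca))) * 180 / pi
}

vec_norm <- function(x) sqrt(sum(x^2))

#' Knee angle from hip, knee and ankle keypoints
#'
#' The angle at the knee between the knee-to-hip and knee-to-ankle vectors;
#' 180 degrees is a fully extended leg.
#'
#' @param hip,knee,ankle Length-3 coordinates of the joints, one body side.
#' @return Angle in degrees.
#' @export
knee_angle <- function(hip, knee, ankle) {
  angle_between(hip - knee, ankle - knee)
}

#' Virtual forward vector from the shoulders
#'
#' Rotates the left-to-right shoulder vector by 90 degrees about the vertical
#' axis (right-hand rule), drops any residual vertical component and
#' normalises. The result is a horizontal unit vector parallel to the walking
#' direction, used as the reference ray for the hip angle so the signal never
#' folds at 180 degrees the way a shoulder-hip-knee construction does when the
#' three points align.
#'
#' @param l_shoulder,r_shoulder Length-3 shoulder coordinates.
#' @param vertical_axis Signed axis label, see [gait_config()].
#' @return Horizontal unit 3-vector.
#' @export
virtual_forward_vector <- function(l_shoulder, r_shoulder, vertical_axis = "+y") {
  k <- axis_vector(vertical_axis)
  v <- r_shoulder - l_shoulder
  if (vec_norm(v) < .Machine$double.eps) {
    rlang::abort("shoulders coincide; forward vector undefined",
                 class = "posegait_geometry_error")
  }
  # 90-degree right-hand rotation about k, then projection off k, reduces to k x v
  f <- cross3(k, v)
  nf <- vec_norm(f)
  if (nf < 1e-9 * vec_norm(v)) {
    rlang::abort("shoulder vector is parallel to the vertical axis",
                 class = "posegait_geometry_error")
  }
  f / nf
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Hip angle against the virtual forward vector
#'
#' Angle between the forward unit vector and the hip-to-knee (thigh) vector.
#'
#' @param forward Unit 3-vector from [virtual_forward_vector()].
#' @param hip,knee Length-3 joint coordinates.
#' @return Angle in degrees.
#' @export
hip_angle <- function(forward, hip, knee) {
  angle_between(forward, knee - hip)
}

lower_limb_joints <- function(side) paste0(side, c("_hip", "_knee", "_ankle"))

#' Extract the four sagittal-plane angle signals from a pose sequence
#'
#' Computes per-frame knee and hip angles for both body sides, assigns
#' near/far side labels and propagates visibility. The angle is computed on
#' every frame whose coordinates exist; a frame's signal visibility is the
#' minimum of its constituent joints' visibilities (knee: hip, knee, ankle;
#' hip: both shoulders, hip, knee), so the least reliable joint governs the
#' gating downstream. Degenerate geometry on a frame (coincident keypoints)
#' yields a missing sample with visibility 0 and a warning rather than an
#' error.
#'
#' The per-frame forward vector is flipped globally when its mean opposes the
#' subject's net hip displacement over the clip, making the construction
#' independent of walking direction and of the rotation handedness.
#'
#' Side assignment: the side whose lower-limb joints (hip, knee, ankle) have
#' the greater mean visibility over the clip is "near" (occlusion of the far
#' side manifests as lower visibility); ties fall back to the smaller mean
#' coordinate along `depth_axis` when given, else the left side is "near".
#'
#' @param pose A [pose_sequence()].
#' @param config A [gait_config()]; supplies `fps` consistency and the
#'   vertical axis.
#' @param depth_axis Optional signed axis label for the camera depth direction,
#'   used only to break visibility ties in side assignment.
#' @return Named list of four [angle_signal()]s: `far_knee`, `far_hip`,
#'   `near_knee`, `near_hip`. Each carries the originating body side in
#'   attribute `"body_side"`.
#' @export
extract_angle_signals <- function(pose, config = gait_config(), depth_axis = NULL) {
  assert_pose_sequence(pose)
  fps <- attr(pose, "fps")
  frames <- sort(unique(pose$frame))
  nf <- length(frames)

  coord <- function(joint) {
    rows <- pose[pose$joint == joint, , drop = FALSE]
    rows <- rows[match(frames, rows$frame), , drop = FALSE]
    list(xyz = cbind(rows$x, rows$y, rows$z), vis = rows$visibility)
  }
  J <- lapply(stats::setNames(pose_joint_vocabulary, pose_joint_vocabulary), coord)

  # per-frame forward vectors
  fwd <- matrix(NA_real_, nf, 3)
  fwd_ok <- rep(TRUE, nf)
  for (t in seq_len(nf)) {
    fwd[t, ] <- tryCatch(
      virtual_forward_vector(J$left_shoulder$xyz[t, ], J$right_shoulder$xyz[t, ],
                             config$vertical_axis),
      posegait_geometry_error = function(e) {
        fwd_ok[t] <<- FALSE
        rep(NA_real_, 3)
      })
  }
  # disambiguate handedness against net hip-centre displacement
  hipc <- (J$left_hip$xyz + J$right_hip$xyz) / 2
  disp <- hipc[nf, ] - hipc[1, ]
  mean_fwd <- colMeans(fwd, na.rm = TRUE)
  if (all(is.finite(disp)) && all(is.finite(mean_fwd)) &&
      sum(disp * mean_fwd) < 0) {
    fwd <- -fwd
  }

  n_degenerate <- 0L
  side_signal <- function(body_side, which) {
    hipx <- J[[paste0(body_side, "_hip")]]
    kneex <- J[[paste0(body_side, "_knee")]]
    anklex <- J[[paste0(body_side, "_ankle")]]
    theta <- rep(NA_real_, nf)
    if (which == "knee") {
      vis <- pmin(hipx$vis, kneex$vis, anklex$vis)
    } else {
      vis <- pmin(J$left_shoulder$vis, J$right_shoulder$vis, hipx$vis, kneex$vis)
    }
    vis[is.na(vis)] <- 0
    for (t in seq_len(nf)) {
      theta[t] <- tryCatch({
        if (which == "knee") {
          knee_angle(hipx$xyz[t, ], kneex$xyz[t, ], anklex$xyz[t, ])
        } else {
          if (!fwd_ok[t] || anyNA(fwd[t, ])) {
            rlang::abort("no forward vector", class = "posegait_geometry_error")
          }
          hip_angle(fwd[t, ], hipx$xyz[t, ], kneex$xyz[t, ])
        }
      },
      posegait_geometry_error = function(e) NA_real_,
      error = function(e) NA_real_)
      if (is.na(theta[t])) {
        vis[t] <- 0
        n_degenerate <<- n_degenerate + 1L
      }
    }
    angle_signal(theta, visibility = vis, joint = which, fps = fps)
  }

  mean_limb_vis <- function(body_side) {
    mean(unlist(lapply(lower_limb_joints(body_side), function(j) J[[j]]$vis)),
         na.rm = TRUE)
  }
  vl <- mean_limb_vis("left")
  vr <- mean_limb_vis("right")
  near_body <- if (vl > vr) {
    "left"
  } else if (vr > vl) {
    "right"
  } else if (!is.null(depth_axis)) {
    d <- axis_vector(depth_axis)
    depth_of <- function(body_side) {
      mean(unlist(lapply(lower_limb_joints(body_side),
                         function(j) J[[j]]$xyz %*% d)), na.rm = TRUE)
    }
    if (depth_of("left") <= depth_of("right")) "left" else "right"
  } else {
    "left"
  }
  far_body <- setdiff(c("left", "right"), near_body)

  label <- function(sig, side, body_side) {
    out <- rewrap_signal(sig, sig)
    attr(out, "side") <- side
    attr(out, "body_side") <- body_side
    out
  }
  out <- list(
    far_knee  = label(side_signal(far_body, "knee"), "far", far_body),
    far_hip   = label(side_signal(far_body, "hip"), "far", far_body),
    near_knee = label(side_signal(near_body, "knee"), "near", near_body),
    near_hip  = label(side_signal(near_body, "hip"), "near", near_body)
  )
  if (n_degenerate > 0L) {
    rlang::warn(sprintf(
      "%d frame-angle(s) had degenerate geometry; stored as missing with visibility 0",
      n_degenerate))
  }
  out
}
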