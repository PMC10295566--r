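#' Construct an angle signal
#'
#' An angle signal is the pipeline's central currency: one joint's angle time
#' series in degrees with a per-frame visibility score. It is a tibble with
#' columns `frame`, `theta` and `visibility`, carrying the joint name, the body
#' side relative to the camera (`"near"` / `"far"`) and the frame rate as
#' attributes.
#'
#' @param theta Numeric vector of angles in degrees; `NA` marks a missing
#'   sample. Present values must lie in \[0, 180\].
#' @param visibility Numeric vector in \[0, 1\], same length as `theta`.
#'   Defaults to 1 everywhere.
#' @param joint Joint label, typically `"knee"` or `"hip"`.
#' @param side `"near"`, `"far"` or `NA` when not yet assigned.
#' @param fps Frame rate in frames per second.
#' @param frame Integer frame indices (0-based by convention).
#' @param ... Additional equal-length columns stored alongside (e.g. a
#'   noiseless `truth` column from a generator).
#'
#' @return A tibble of class `angle_signal`.
#' @export
#' @examples
#' s <- angle_signal(90 + 10 * cos(2 * pi * 0.9 * (0:59) / 30), fps = 30)
#' signal_fps(s)
angle_signal <- function(theta,
                         visibility = rep(1, length(theta)),
                         joint = NA_character_,
                         side = NA_character_,
                         fps = 30,
                         frame = seq_along(theta) - 1L,
                         ...) {
  if (length(visibility) != length(theta) || length(frame) != length(theta)) {
    rlang::abort("`theta`, `visibility` and `frame` must have equal lengths",
                 class = "posegait_signal_error")
  }
  ok <- is.na(theta) | (theta >= 0 & theta <= 180)
  if (!all(ok)) {
    rlang::abort("angles must lie in [0, 180] degrees where present",
                 class = "posegait_signal_error")
  }
  if (any(visibility < 0 | visibility > 1, na.rm = TRUE)) {
    rlang::abort("`visibility` must lie in [0, 1]",
                 class = "posegait_signal_error")
  }
  out <- tibble::tibble(frame = as.integer(frame),
                        theta = as.numeric(theta),
                        visibility = as.numeric(visibility), ...)
  new_angle_signal(out, joint = joint, side = side, fps = fps)
}

new_angle_signal <- function(data, joint, side, fps, selection = NULL) {
  structure(
    data,
    class = c("angle_signal", class(tibble::as_tibble(data))),
    joint = joint,
    side = side,
    fps = fps,
    selection = selection
  )
}

# rebuild an angle_signal from `template`'s metadata with new data
rewrap_signal <- function(data, template, selection = attr(template, "selection")) {
  new_angle_signal(tibble::as_tibble(data),
                   joint = signal_joint(template),
                   side = signal_side(template),
                   fps = signal_fps(template),
                   selection = selection)
}

#' Angle-signal metadata accessors
#'
#' @param signal An [angle_signal()].
#' @return The frame rate (`signal_fps`), joint label (`signal_joint`) or side
#'   label (`signal_side`).
#' @export
signal_fps <- function(signal) attr(signal, "fps")

#' @rdname signal_fps
#' @export
signal_joint <- function(signal) attr(signal, "joint")

#' @rdname signal_fps
#' @export
signal_side <- function(signal) attr(signal, "side")

#' @export
print.angle_signal <- function(x, ...) {
  cat(sprintf("<angle_signal> joint=%s side=%s fps=%s frames=%d\n",
              signal_joint(x), signal_side(x), format(signal_fps(x)), nrow(x)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

assert_angle_signal <- function(signal, arg = "signal") {
  if (!inherits(signal, "angle_signal")) {
    rlang::abort(sprintf("`%s` must be an angle_signal", arg),
                 class = "posegait_signal_error")
  }
  invisible(signal)
}
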