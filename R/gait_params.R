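#' Fixed feature order of a gait feature vector
#'
#' The eight numeric features of the PCA feature model, in the documented,
#' versioned order. Stored feature models record this order so that models
#' serialised by one session remain compatible with later ones.
#'
#' @format Character vector of length 8.
#' @export
gait_feature_names <- c(
  "age", "mass", "height",
  "flexion_far_knee", "flexion_far_hip",
  "flexion_near_knee", "flexion_near_hip",
  "striding_speed"
)

gait_feature_version <- "1"

#' Joint flexion (range of motion) of a filtered signal
#'
#' The discrete summary of a joint-angle signal: its range of motion,
#' `max(theta) - min(theta)`, in degrees. Invariant to adding a constant to
#' the signal. A constant signal yields 0 with a warning.
#'
#' @param signal A filtered [angle_signal()] with no missing samples.
#' @return Flexion in degrees (>= 0).
#' @export
flexion <- function(signal) {
  assert_angle_signal(signal)
  if (!nrow(signal) || anyNA(signal$theta)) {
    rlang::abort("signal must be nonempty with no missing samples",
                 class = "posegait_validation_error")
  }
  rom <- max(signal$theta) - min(signal$theta)
  if (rom == 0) {
    rlang::warn("constant signal: flexion is 0")
  }
  rom
}

#' Striding speed from the near-side hip signal
#'
#' Strides per second, read off as the dominant (largest-magnitude, non-DC)
#' frequency of the least-RMSE DFT selection of the near-side hip angle
#' signal. If the signal carries a selection from [fdf_filter()] it is reused,
#' otherwise the selection is recomputed with `config$n_components`.
#' Invariant to amplitude scaling of the signal.
#'
#' @param near_hip Filtered near-side hip [angle_signal()].
#' @param config A [gait_config()].
#' @return Striding speed in strides per second (Hz).
#' @export
striding_speed <- function(near_hip, config = gait_config()) {
  assert_angle_signal(near_hip)
  sel <- attr(near_hip, "selection")
  if (is.null(sel)) {
    sel <- lrmse_select(near_hip$theta, config$n_components,
                        fs = signal_fps(near_hip))
  }
  dominant_frequency(sel)
}

#' Assemble a gait feature vector
#'
#' Combines subject metadata with the four joint flexions and the striding
#' speed into a one-row tibble in the fixed [gait_feature_names] order, plus a
#' `gender` column used only as a stratification key.
#'
#' @param subject Named list or one-row data frame with `age` (years), `mass`
#'   (kg), `height` (m) and `gender`.
#' @param signals Named list of the four filtered [angle_signal()]s:
#'   `far_knee`, `far_hip`, `near_knee`, `near_hip`.
#' @param config A [gait_config()].
#' @return One-row tibble: `gender` plus the eight numeric features.
#' @export
assemble_features <- function(subject, signals, config = gait_config()) {
  subject <- as.list(subject)
  needed <- c("age", "mass", "height", "gender")
  missing_meta <- setdiff(needed, names(subject))
  if (length(missing_meta)) {
    rlang::abort(paste0("subject metadata lacks field(s): ",
                        paste(missing_meta, collapse = ", ")),
                 class = "posegait_validation_error")
  }
  for (f in c("age", "mass", "height")) {
    if (!is.numeric(subject[[f]]) || length(subject[[f]]) != 1L ||
        !is.finite(subject[[f]])) {
      rlang::abort(paste0("subject `", f, "` must be a finite number"),
                   class = "posegait_validation_error")
    }
  }
  needed_sig <- c("far_knee", "far_hip", "near_knee", "near_hip")
  if (!all(needed_sig %in% names(signals))) {
    rlang::abort(paste0("signals must be named: ",
                        paste(needed_sig, collapse = ", ")),
                 class = "posegait_validation_error")
  }
  out <- tibble::tibble(
    gender = as.character(subject$gender),
    age = subject$age,
    mass = subject$mass,
    height = subject$height,
    flexion_far_knee = flexion(signals$far_knee),
    flexion_far_hip = flexion(signals$far_hip),
    flexion_near_knee = flexion(signals$near_knee),
    flexion_near_hip = flexion(signals$near_hip),
    striding_speed = striding_speed(signals$near_hip, config)
  )
  attr(out, "feature_version") <- gait_feature_version
  out
}
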