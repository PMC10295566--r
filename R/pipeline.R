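#' Run the full markerless gait pipeline
#'
#' End-to-end orchestration: keypoints are converted to the four sagittal
#' knee/hip angle signals, each signal is Kalman-filtered with its side's
#' noise coefficients (missing measurements substituted per the configured
#' strategy), denoised by the frequency-domain filter after the burn-in cut,
#' and decoded into discrete gait parameters (joint flexions and striding
#' speed). When a feature model is supplied the subject's Hotelling
#' T-squared score against it is added.
#'
#' Sequences shorter than 40 frames are refused: below one short walking
#' period there is not enough signal for the filters or the stride-frequency
#' readout.
#'
#' @param pose A [pose_sequence()] (>= 40 frames).
#' @param subject Named list / one-row data frame with `age`, `mass`,
#'   `height`, `gender`.
#' @param model Optional [build_feature_model()] result (matching the
#'   subject's stratum is the caller's responsibility).
#' @param config A [gait_config()].
#' @return Object of class `gait_report`: filtered `signals` (named list of
#'   four equal-length [angle_signal()]s), `features` (one-row tibble),
#'   `t2` (number or `NULL`), `config`, `provenance`.
#' @export
run_pipeline <- function(pose, subject, model = NULL, config = gait_config()) {
  assert_pose_sequence(pose)
  if (n_frames(pose) < 40L) {
    rlang::abort(sprintf(
      "pose sequence has %d frames; at least 40 (one short walking period) are required",
      n_frames(pose)), class = "posegait_validation_error")
  }
  max_vis <- tapply(pose$visibility, pose$joint, max)
  dead <- names(max_vis)[max_vis <= 0]
  if (length(dead)) {
    rlang::abort(paste0("joint(s) never visible: ", paste(dead, collapse = ", ")),
                 class = "posegait_validation_error")
  }

  raw <- extract_angle_signals(pose, config)
  filtered <- purrr::imap(raw, function(sig, name) {
    kcfg <- select_side_config(signal_side(sig), config)
    fdf_filter(kf_filter_signal(sig, kcfg), config)
  })

  features <- assemble_features(subject, filtered, config)
  t2 <- if (!is.null(model)) {
    t2_score(features, model, normalisation = config$t2_normalisation)
  } else {
    NULL
  }

  structure(
    list(signals = filtered,
         features = features,
         t2 = t2,
         config = config,
         provenance = list(
           config_hash = rlang::hash(config),
           input_hash = rlang::hash(as.data.frame(pose)),
           n_frames = n_frames(pose),
           feature_version = gait_feature_version
         )),
    class = "gait_report"
  )
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>\n")
  feats <- x$features
  cat(sprintf("  frames analysed: %d (per filtered signal: %d)\n",
              x$provenance$n_frames, nrow(x$signals[[1]])))
  cat(sprintf("  flexion far knee/hip:  %.1f / %.1f deg\n",
              feats$flexion_far_knee, feats$flexion_far_hip))
  cat(sprintf("  flexion near knee/hip: %.1f / %.1f deg\n",
              feats$flexion_near_knee, feats$flexion_near_hip))
  cat(sprintf("  striding speed: %.3f strides/s\n", feats$striding_speed))
  if (!is.null(x$t2)) cat(sprintf("  Hotelling T2: %.4f\n", x$t2))
  invisible(x)
}

#' Tidy a gait report
#'
#' @param x A `gait_report`.
#' @param ... Unused.
#' @return The one-row feature tibble with the T-squared score appended as a
#'   `t2` column (`NA` when no feature model was supplied).
#' @method tidy gait_report
#' @export
tidy.gait_report <- function(x, ...) {
  dplyr::mutate(x$features, t2 = if (is.null(x$t2)) NA_real_ else x$t2)
}

#' Write a gait report as JSON
#'
#' Serialises the filtered signals, discrete gait parameters, T-squared score
#' (when present) and provenance (config hash, input hash) to a JSON document.
#'
#' @param report A `gait_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gait_report <- function(report, path) {
  stopifnot(inherits(report, "gait_report"))
  payload <- list(
    features = as.list(report$features),
    t2 = report$t2,
    signals = lapply(report$signals, function(s) {
      list(joint = signal_joint(s), side = signal_side(s),
           fps = signal_fps(s), frame = s$frame, theta = s$theta)
    }),
    config = report$config[setdiff(names(report$config),
                                   "pose_estimator_passthrough")],
    pose_estimator_passthrough = report$config$pose_estimator_passthrough,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
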