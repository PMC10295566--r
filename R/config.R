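#' Pipeline configuration
#'
#' Bundles every tunable of the markerless gait pipeline. Defaults are the
#' operating point of the system this package implements: visibility threshold
#' 40%, 10% burn-in cut before the frequency-domain filter, 5 retained DFT
#' components, side-specific Kalman noise coefficients
#' (far: alpha = 1e-2, beta = 1e-3; near: alpha = 10, beta = 1) and a PCA
#' feature model retaining 90% of variance.
#'
#' @param fps Frame rate of the keypoint stream, frames per second (> 0).
#' @param visibility_threshold Fraction in \[0, 1\]; frames whose signal
#'   visibility falls below it are treated as missing measurements by the
#'   Kalman filter.
#' @param cut Fraction in \[0, 1) of prefix frames discarded before the
#'   frequency-domain filter (Kalman burn-in).
#' @param n_components Number of DFT components (DC and each conjugate pair
#'   counting as one) retained by the least-RMSE selection.
#' @param alpha_far,beta_far,alpha_near,beta_near Positive Kalman process- and
#'   measurement-noise coefficients for the far and near body side.
#' @param variance_threshold Fraction in (0, 1\]; PCA components are retained
#'   until this much cumulative variance is explained.
#' @param vertical_axis Signed coordinate axis pointing up, one of
#'   `"+x","-x","+y","-y","+z","-z"`; used to rotate the shoulder vector into
#'   the virtual forward vector.
#' @param kf_mode Missing-measurement substitution strategy: `"KF2"` feeds the
#'   previous posterior estimate, `"KF1"` the current prior prediction.
#' @param p0_scale Diagonal of the initial Kalman error covariance.
#' @param t2_normalisation `"none"` (raw Hotelling T-squared) or `"per_pc"`
#'   (divided by the number of retained components).
#' @param pose_estimator_passthrough Free-form named list recorded verbatim in
#'   reports (e.g. a pose estimator's SM/MDC/MTC settings); never interpreted.
#'
#' @return An object of class `gait_config` (a named list).
#' @export
#' @examples
#' cfg <- gait_config(fps = 30)
#' cfg$visibility_threshold
gait_config <- function(fps = 30,
                        visibility_threshold = 0.40,
                        cut = 0.10,
                        n_components = 5,
                        alpha_far = 1e-2,
                        beta_far = 1e-3,
                        alpha_near = 10,
                        beta_near = 1,
                        variance_threshold = 0.90,
                        vertical_axis = "+y",
                        kf_mode = c("KF2", "KF1"),
                        p0_scale = 100,
                        t2_normalisation = c("none", "per_pc"),
                        pose_estimator_passthrough = list()) {
  kf_mode <- match.arg(kf_mode)
  t2_normalisation <- match.arg(t2_normalisation)
  check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                           lower_open = FALSE, upper_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      config_abort("`{name}` must be a single finite number", name = name)
    }
    lo_ok <- if (lower_open) x > lower else x >= lower
    hi_ok <- if (upper_open) x < upper else x <= upper
    if (!lo_ok || !hi_ok) {
      config_abort("`{name}` = {x} is outside its valid range", name = name, x = x)
    }
    x
  }
  config_abort <- function(msg, ...) {
    rlang::abort(glue_msg(msg, ...), class = "posegait_config_error")
  }

  check_scalar(fps, "fps", lower = 0, lower_open = TRUE)
  check_scalar(visibility_threshold, "visibility_threshold", 0, 1)
  check_scalar(cut, "cut", 0, 1, upper_open = TRUE)
  if (!is.numeric(n_components) || length(n_components) != 1L ||
      n_components < 1 || n_components != round(n_components)) {
    config_abort("`n_components` must be a positive integer")
  }
  check_scalar(alpha_far, "alpha_far", 0, lower_open = TRUE)
  check_scalar(beta_far, "beta_far", 0, lower_open = TRUE)
  check_scalar(alpha_near, "alpha_near", 0, lower_open = TRUE)
  check_scalar(beta_near, "beta_near", 0, lower_open = TRUE)
  check_scalar(variance_threshold, "variance_threshold", 0, 1, lower_open = TRUE)
  check_scalar(p0_scale, "p0_scale", 0, lower_open = TRUE)
  axis_vector(vertical_axis)  # validates
  if (!is.list(pose_estimator_passthrough)) {
    config_abort("`pose_estimator_passthrough` must be a list")
  }

  structure(
    list(
      fps = fps,
      visibility_threshold = visibility_threshold,
      cut = cut,
      n_components = as.integer(n_components),
      alpha_far = alpha_far,
      beta_far = beta_far,
      alpha_near = alpha_near,
      beta_near = beta_near,
      variance_threshold = variance_threshold,
      vertical_axis = vertical_axis,
      kf_mode = kf_mode,
      p0_scale = p0_scale,
      t2_normalisation = t2_normalisation,
      pose_estimator_passthrough = pose_estimator_passthrough
    ),
    class = "gait_config"
  )
}

# minimal glue-like interpolation without depending on glue directly
glue_msg <- function(msg, ...) {
  env <- list2env(list(...), parent = parent.frame())
  while (grepl("\\{[^}]+\\}", msg)) {
    token <- regmatches(msg, regexpr("\\{[^}]+\\}", msg))
    expr <- substr(token, 2L, nchar(token) - 1L)
    val <- tryCatch(eval(parse(text = expr), envir = env), error = function(e) token)
    msg <- sub("\\{[^}]+\\}", paste(format(val), collapse = ", "), msg)
  }
  msg
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  flat <- x[!vapply(x, is.list, logical(1))]
  cat(paste0("  ", names(flat), " = ", vapply(flat, format, character(1)),
             collapse = "\n"), "\n")
  if (length(x$pose_estimator_passthrough)) {
    cat("  pose_estimator_passthrough:",
        paste(names(x$pose_estimator_passthrough),
              unlist(lapply(x$pose_estimator_passthrough, format)),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Unit vector for a signed axis label
#'
#' @param axis One of `"+x","-x","+y","-y","+z","-z"`.
#' @return Length-3 unit vector.
#' @keywords internal
axis_vector <- function(axis) {
  table <- list(
    "+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
    "+y" = c(0, 1, 0), "-y" = c(0, -1, 0),
    "+z" = c(0, 0, 1), "-z" = c(0, 0, -1)
  )
  if (!is.character(axis) || length(axis) != 1L || !axis %in% names(table)) {
    rlang::abort(
      "`vertical_axis` must be one of \"+x\", \"-x\", \"+y\", \"-y\", \"+z\", \"-z\"",
      class = "posegait_config_error"
    )
  }
  table[[axis]]
}
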