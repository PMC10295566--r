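#' Joint vocabulary
#'
#' The eight keypoints the pipeline consumes.
#'
#' @format Character vector of length 8.
#' @export
pose_joint_vocabulary <- c(
  "left_shoulder", "right_shoulder",
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_ankle", "right_ankle"
)

#' Rename table from a pose estimator's landmark names
#'
#' Pure renaming tables mapping common pose-estimator landmark labels onto the
#' package's joint vocabulary; apply to a keypoint table's `joint` column
#' before [pose_sequence()].
#'
#' @param dialect Currently `"blazepose"` (upper-case MediaPipe landmark names).
#' @return Named character vector: names are estimator labels, values are
#'   vocabulary names.
#' @export
#' @examples
#' joint_name_adapter("blazepose")[["LEFT_KNEE"]]
joint_name_adapter <- function(dialect = c("blazepose")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    blazepose = stats::setNames(pose_joint_vocabulary,
                                toupper(pose_joint_vocabulary))
  )
}

#' Construct a pose sequence
#'
#' A pose sequence is a long-format tibble of per-frame 3D keypoints with
#' visibility scores: columns `frame`, `joint`, `x`, `y`, `z`, `visibility`,
#' one row per frame and joint, with the frame rate as an attribute. All eight
#' joints of [pose_joint_vocabulary] must appear; (frame, joint) combinations
#' absent from `data` are completed with visibility 0, and frames are made
#' contiguous and sorted.
#'
#' @param data Data frame with the columns above (visibility clipped to
#'   \[0, 1\] with a warning if outside).
#' @param fps Frame rate, frames per second.
#' @return A tibble of class `pose_sequence`.
#' @export
pose_sequence <- function(data, fps = 30) {
  needed <- c("frame", "joint", "x", "y", "z", "visibility")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0("pose data lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "posegait_validation_error")
  }
  data <- tibble::as_tibble(data)[needed]
  unknown <- setdiff(unique(data$joint), pose_joint_vocabulary)
  if (length(unknown)) {
    rlang::abort(paste0("unknown joint name(s): ", paste(unknown, collapse = ", ")),
                 class = "posegait_validation_error")
  }
  absent <- setdiff(pose_joint_vocabulary, unique(data$joint))
  if (length(absent)) {
    rlang::abort(paste0("joint(s) never observed: ", paste(absent, collapse = ", ")),
                 class = "posegait_validation_error")
  }
  if (any(duplicated(data[c("frame", "joint")]))) {
    rlang::abort("duplicated (frame, joint) rows", class = "posegait_validation_error")
  }
  out_of_range <- !is.na(data$visibility) &
    (data$visibility < 0 | data$visibility > 1)
  if (any(out_of_range)) {
    rlang::warn(sprintf("%d visibility value(s) outside [0, 1] were clipped",
                        sum(out_of_range)))
    data$visibility <- pmax(0, pmin(1, data$visibility))
  }
  data$visibility[is.na(data$visibility)] <- 0

  frames <- seq(min(data$frame), max(data$frame))
  grid <- tidyr::expand_grid(frame = frames, joint = pose_joint_vocabulary)
  data <- dplyr::left_join(grid, data, by = c("frame", "joint"))
  data$visibility[is.na(data$visibility)] <- 0
  data <- dplyr::arrange(data, .data$frame, .data$joint)

  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    rlang::abort("`fps` must be a positive number", class = "posegait_validation_error")
  }
  structure(data, class = c("pose_sequence", class(data)), fps = fps)
}

assert_pose_sequence <- function(pose) {
  if (!inherits(pose, "pose_sequence")) {
    rlang::abort("`pose` must be a pose_sequence (see `pose_sequence()`)",
                 class = "posegait_validation_error")
  }
  invisible(pose)
}

n_frames <- function(pose) length(unique(pose$frame))

#' Read a keypoint file into a pose sequence
#'
#' Reads long-format delimited text (one row per frame and joint; comma- or
#' tab-separated, chosen from the file extension) and validates it into a
#' [pose_sequence()]. Column names can be remapped through `schema`.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param schema Named character vector mapping the canonical names
#'   (`frame, joint, x, y, z, visibility`) to the file's column names.
#' @param fps Frame rate of the recording.
#' @return A [pose_sequence()].
#' @export
read_pose_sequence <- function(path, schema = NULL, fps = 30) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "posegait_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    rlang::abort(sprintf("malformed keypoint file %s: first problem at line %d (%s)",
                         path, probs$row[1], probs$expected[1]),
                 class = "posegait_io_error")
  }
  canonical <- c("frame", "joint", "x", "y", "z", "visibility")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) map[names(schema)] <- unlist(schema)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("keypoint file lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "posegait_validation_error")
  }
  data <- stats::setNames(raw[unname(map)], names(map))
  if (!is.numeric(data$frame) || any(data$frame != round(data$frame), na.rm = TRUE)) {
    rlang::abort("`frame` column must be integer-valued",
                 class = "posegait_validation_error")
  }
  pose_sequence(data, fps = fps)
}

#' Write a pose sequence to delimited text
#'
#' Inverse of [read_pose_sequence()]; writes the long-format schema so that a
#' round trip is field-identical.
#'
#' @param pose A [pose_sequence()].
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_pose_sequence <- function(pose, path) {
  assert_pose_sequence(pose)
  tab <- tibble::as_tibble(pose)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(tab, path)
  } else {
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a gold-standard angle file
#'
#' Expects delimited text with columns `frame`, `joint` and `angle` (degrees);
#' returns one [angle_signal()] per joint label found.
#'
#' @param path Path to the file.
#' @param fps Frame rate.
#' @return Named list of [angle_signal()]s.
#' @export
read_angle_file <- function(path, fps = 30) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "posegait_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  needed <- c("frame", "joint", "angle")
  if (!all(needed %in% names(raw))) {
    rlang::abort("angle file needs columns frame, joint, angle",
                 class = "posegait_validation_error")
  }
  split_tabs <- split(raw, raw$joint)
  lapply(split_tabs, function(tab) {
    tab <- tab[order(tab$frame), ]
    angle_signal(tab$angle, joint = unique(tab$joint), fps = fps,
                 frame = tab$frame)
  })
}
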