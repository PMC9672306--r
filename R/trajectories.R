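#' Build a trajectory table from coordinate vectors
#'
#' A trajectory is an ordered 2D polyline in millimetres. Trajectory tables
#' are plain tibbles with columns `traj_id`, `point_idx`, `x_mm`, `y_mm`;
#' all ipwalk functions that consume paths accept this format.
#'
#' @param x,y numeric vectors of coordinates in mm (equal length, >= 2).
#' @param id trajectory label (length-1 character).
#' @return A tibble with columns `traj_id`, `point_idx`, `x_mm`, `y_mm`.
#' @examples
#' trajectory(c(0, 3, 3), c(0, 0, 4))
#' @export
trajectory <- function(x, y, id = "traj_1") {
  stopifnot(length(x) == length(y), length(x) >= 2, length(id) == 1)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("trajectory coordinates must be finite", class = "ipwalk_validation_error")
  }
  tibble(
    traj_id = as.character(id),
    point_idx = seq_along(x),
    x_mm = as.numeric(x),
    y_mm = as.numeric(y)
  )
}

#' Validate a trajectory table
#'
#' Checks the column contract (`traj_id`, `point_idx`, `x_mm`, `y_mm`),
#' finiteness of coordinates, and that every trajectory has at least two
#' points; returns the data ordered by id and point index.
#'
#' @param data a trajectory table.
#' @return The validated tibble, ordered by `traj_id` then `point_idx`.
#' @export
validate_trajectories <- function(data) {
  required <- c("traj_id", "point_idx", "x_mm", "y_mm")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(
      paste0("missing required columns: ", paste(missing, collapse = ", ")),
      class = "ipwalk_format_error"
    )
  }
  bad <- which(!is.finite(data$x_mm) | !is.finite(data$y_mm))
  if (length(bad) > 0) {
    abort(
      paste0("non-finite coordinate in row(s): ", paste(head(bad, 5), collapse = ", ")),
      class = "ipwalk_validation_error"
    )
  }
  data <- dplyr::arrange(as_tibble(data), .data$traj_id, .data$point_idx)
  counts <- dplyr::count(data, .data$traj_id)
  if (any(counts$n < 2)) {
    abort(
      paste0(
        "trajectories with fewer than 2 points: ",
        paste(head(counts$traj_id[counts$n < 2], 5), collapse = ", ")
      ),
      class = "ipwalk_validation_error"
    )
  }
  data
}

#' Read trajectories from a delimited text file
#'
#' The file dialect is delimiter-separated text (comma or tab, auto-detected
#' from the header line) with required columns `traj_id`, `point_idx`,
#' `x_mm`, `y_mm`; extra columns (e.g. timestamps) are ignored. Units are
#' fixed to millimetres throughout the package.
#'
#' @param path file path.
#' @return A validated trajectory tibble ordered by id and point index.
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ipwalk_format_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  data <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  required <- c("traj_id", "point_idx", "x_mm", "y_mm")
  if (!all(required %in% names(data))) {
    abort(
      paste0(
        "missing required columns: ",
        paste(setdiff(required, names(data)), collapse = ", ")
      ),
      class = "ipwalk_format_error"
    )
  }
  data$traj_id <- as.character(data$traj_id)
  data$point_idx <- as.integer(data$point_idx)
  suppressWarnings({
    data$x_mm <- as.numeric(data$x_mm)
    data$y_mm <- as.numeric(data$y_mm)
  })
  validate_trajectories(data)
}

#' Write trajectories to a delimited text file
#'
#' Emits the same schema that [read_trajectories()] consumes.
#'
#' @param data a trajectory table.
#' @param path output file path.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(data, path, delim = ",") {
  data <- validate_trajectories(data)
  readr::write_delim(
    data[, c("traj_id", "point_idx", "x_mm", "y_mm")],
    path,
    delim = delim
  )
  invisible(path)
}

# low-level polyline length; zero-length segments contribute 0
path_length <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Total path length per trajectory
#'
#' @param data a trajectory table.
#' @return A tibble with one row per trajectory: `traj_id`, `n_points`,
#'   `length_mm` (sum of consecutive point distances).
#' @examples
#' trajectory_lengths(trajectory(c(0, 3, 3), c(0, 0, 4))) # 3 + 4 = 7 mm
#' @export
trajectory_lengths <- function(data) {
  data <- validate_trajectories(data)
  data |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      length_mm = path_length(.data$x_mm, .data$y_mm),
      .groups = "drop"
    )
}

#' Total length of a single trajectory
#'
#' @param data a trajectory table containing exactly one trajectory.
#' @return The path length in mm (numeric scalar).
#' @export
total_length <- function(data) {
  lens <- trajectory_lengths(data)
  if (nrow(lens) != 1) {
    abort("total_length() expects a single trajectory; see trajectory_lengths()",
      class = "ipwalk_validation_error"
    )
  }
  lens$length_mm
}

#' Translate and rotate trajectories
#'
#' Rigid motion used to place a path on the source circle: each trajectory is
#' translated so that its first point coincides with `new_start`, then rotated
#' about that starting point by `angle` (radians, counter-clockwise positive,
#' measured from the +x axis). Inter-point distances are preserved exactly up
#' to floating point.
#'
#' @param data a trajectory table (one or more trajectories).
#' @param new_start numeric length-2, the common starting point `(x, y)` in mm.
#' @param angle rotation angle in radians, counter-clockwise.
#' @return The transformed trajectory tibble.
#' @examples
#' translate_rotate(trajectory(c(0, 1), c(0, 0)), c(0, 0), pi / 2)
#' @export
translate_rotate <- function(data, new_start, angle = 0) {
  stopifnot(length(new_start) == 2, is.finite(new_start), is.finite(angle))
  data <- validate_trajectories(data)
  ca <- cos(angle)
  sa <- sin(angle)
  data |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::mutate(
      .rx = .data$x_mm - .data$x_mm[1],
      .ry = .data$y_mm - .data$y_mm[1],
      x_mm = new_start[1] + ca * .data$.rx - sa * .data$.ry,
      y_mm = new_start[2] + sa * .data$.rx + ca * .data$.ry
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".rx", -".ry")
}
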