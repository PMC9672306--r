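# Mean-free-path estimation via 1D projections: movement patterns are
# projected onto the x- and y-axes, turns are identified unambiguously where
# the direction of travel changes in a projection, and steps are measured
# between consecutive turns.

#' Project a trajectory onto one axis
#'
#' @param data a trajectory table containing a single trajectory.
#' @param axis `"x"` or `"y"`.
#' @return Numeric vector of the chosen coordinate of each vertex, in order.
#' @export
project_1d <- function(data, axis = c("x", "y")) {
  axis <- match.arg(axis)
  data <- validate_trajectories(data)
  if (length(unique(data$traj_id)) != 1) {
    abort("project_1d() expects a single trajectory",
      class = "ipwalk_validation_error"
    )
  }
  if (axis == "x") data$x_mm else data$y_mm
}

#' Detect turns in a 1D movement pattern
#'
#' A turn occurs at a vertex where the direction of travel changes: the
#' increment leaving the vertex is nonzero and opposite in sign to the most
#' recent nonzero increment before it. Zero increments (plateaus from
#' repeated digitized positions) never create or terminate a step; they
#' inherit the previous travel direction.
#'
#' @param coords numeric vector of 1D positions (length >= 2).
#' @return Integer vector of turn vertex indices (1-based). Empty when the
#'   coordinate never reverses (including the all-constant case).
#' @examples
#' detect_turns_1d(c(0, 1, 2, 1, 0)) # turn at vertex 3, the peak
#' detect_turns_1d(c(0, 1, 1, 2)) # plateau, no turn
#' @export
detect_turns_1d <- function(coords) {
  if (length(coords) < 2) {
    abort("need at least 2 coordinates", class = "ipwalk_validation_error")
  }
  d <- diff(coords)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  sn <- s[nz]
  flips <- which(sn[-1] != sn[-length(sn)])
  # vertex index where the reversing increment starts
  sort(nz[flips + 1])
}

#' Discretize a trajectory into steps between turns
#'
#' Combines the x- and y-projection turns into a step series. With
#' `method = "pooled2d"` (default) a turn is flagged at every vertex where
#' the sign pattern of the 2D increment `(sign(dx), sign(dy))` changes
#' between consecutive non-repeat segments — for paths with no axis-aligned
#' segments this equals the union of the strict 1D reversals of the two
#' projections, and it additionally catches right-angle turns of
#' axis-aligned paths, making the discretization lossless on orthogonal-turn
#' paths. Step lengths are the *path* lengths along the trajectory between
#' consecutive turn vertices — the least-interpretive reading that yields a
#' 2D length scale. Pure repeated points (both increments zero) never create
#' or break a step. With `method = "per_axis"` each projection yields its own
#' series of absolute 1D displacements between its strict
#' [detect_turns_1d()] reversals.
#'
#' @param data a trajectory table containing a single trajectory.
#' @param method `"pooled2d"` or `"per_axis"`.
#' @return A tibble of class `step_series` with columns `source_id`, `axis`
#'   (`"pooled2d"`, `"x"` or `"y"`) and `step_mm`; turn vertex indices are
#'   carried in the `turns` attribute.
#' @export
steps_from_turns <- function(data, method = c("pooled2d", "per_axis")) {
  method <- match.arg(method)
  data <- validate_trajectories(data)
  if (length(unique(data$traj_id)) != 1) {
    abort("steps_from_turns() expects a single trajectory",
      class = "ipwalk_validation_error"
    )
  }
  id <- data$traj_id[1]
  n <- nrow(data)
  if (method == "pooled2d") {
    dx <- diff(data$x_mm)
    dy <- diff(data$y_mm)
    moving <- which(dx != 0 | dy != 0) # segment indices, repeats dropped
    turns <- integer(0)
    if (length(moving) > 1) {
      sx <- sign(dx[moving])
      sy <- sign(dy[moving])
      k <- length(moving)
      changed <- sx[-1] != sx[-k] | sy[-1] != sy[-k]
      # turn at the vertex where the direction-changing segment starts
      turns <- moving[-1][changed]
    }
    arc <- c(0, cumsum(sqrt(diff(data$x_mm)^2 + diff(data$y_mm)^2)))
    bounds <- unique(c(1L, turns, n))
    steps <- diff(arc[bounds])
    steps <- steps[steps > 0]
    out <- tibble(source_id = id, axis = "pooled2d", step_mm = steps)
    attr(out, "turns") <- turns
  } else {
    tx <- detect_turns_1d(data$x_mm)
    ty <- detect_turns_1d(data$y_mm)
    series <- purrr::map2(
      list(data$x_mm, data$y_mm), list(tx, ty),
      function(coords, turns) {
        bounds <- unique(c(1L, turns, n))
        steps <- abs(diff(coords[bounds]))
        steps[steps > 0]
      }
    )
    out <- tibble(
      source_id = id,
      axis = rep(c("x", "y"), vapply(series, length, integer(1))),
      step_mm = unlist(series, use.names = FALSE)
    )
    attr(out, "turns") <- list(x = tx, y = ty)
  }
  class(out) <- c("step_series", class(out))
  out
}

#' Turn-detection probability under isotropic turning
#'
#' For a walker whose headings are independent uniform draws on `[0, 2*pi)`,
#' a true turning point is detected by the pooled 1D-projection rule whenever
#' the new heading leaves the quadrant of the old one (the sign of cos or of
#' sin flips), which happens with probability 3/4. The value can be
#' re-derived by simulation with `simulate = TRUE`; undetected turns merge
#' adjacent steps, inflating the mean detected step length by the inverse of
#' this probability.
#'
#' @param simulate re-derive the probability by Monte Carlo instead of
#'   returning the closed-form 3/4.
#' @param n number of heading pairs when simulating.
#' @return Detection probability (scalar).
#' @export
turn_detection_probability <- function(simulate = FALSE, n = 1e5) {
  if (!simulate) return(3 / 4)
  h1 <- runif(n, 0, 2 * pi)
  h2 <- runif(n, 0, 2 * pi)
  detected <- sign(cos(h1)) != sign(cos(h2)) | sign(sin(h1)) != sign(sin(h2))
  mean(detected)
}

#' Estimate the mean free path from a step series
#'
#' The uncorrected estimate is the mean detected step length. For pooled-2D
#' series from isotropically turning walkers the `corrected` estimate
#' multiplies by the turn-detection probability (3/4 for uniform headings,
#' see [turn_detection_probability()]), compensating for undetected turns
#' that merge consecutive steps. The correction factor is
#' distribution-dependent: leave it off for walkers whose turning-angle
#' distribution is unknown.
#'
#' @param series a `step_series` from [steps_from_turns()], or any tibble
#'   with a `step_mm` column.
#' @param corrected apply the turn-detection correction (pooled2d only).
#' @param detection_prob detection probability used by the correction.
#' @return A one-row tibble: `mfp_mm`, `n_steps`, `mean_step_mm`,
#'   `corrected`.
#' @export
estimate_mfp <- function(series, corrected = TRUE,
                         detection_prob = turn_detection_probability()) {
  if (!is.data.frame(series) || !"step_mm" %in% names(series) ||
    nrow(series) == 0) {
    abort("series must contain at least one step", class = "ipwalk_validation_error")
  }
  if (corrected && !all(series$axis == "pooled2d")) {
    abort("the detection correction applies to pooled2d series only",
      class = "ipwalk_config_error"
    )
  }
  m <- mean(series$step_mm)
  tibble(
    mfp_mm = if (corrected) m * detection_prob else m,
    n_steps = nrow(series),
    mean_step_mm = m,
    corrected = corrected
  )
}

#' Mean free path across a trajectory set
#'
#' Convenience wrapper: discretizes every trajectory with
#' [steps_from_turns()] and pools the steps into a single estimate, plus
#' per-trajectory estimates.
#'
#' @param data a trajectory table.
#' @param method passed to [steps_from_turns()] (`"pooled2d"` only for the
#'   corrected pooled estimate).
#' @param corrected apply the turn-detection correction.
#' @return A list with `pooled` (one-row tibble from [estimate_mfp()]) and
#'   `by_trajectory` (tibble with one row per trajectory).
#' @export
estimate_mfp_trajset <- function(data, method = "pooled2d", corrected = TRUE) {
  data <- validate_trajectories(data)
  series <- split(data, data$traj_id) |>
    purrr::map(steps_from_turns, method = method) |>
    dplyr::bind_rows()
  by_traj <- series |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(
      mfp_mm = mean(.data$step_mm) * (if (corrected) turn_detection_probability() else 1),
      n_steps = dplyr::n(), .groups = "drop"
    )
  list(
    pooled = estimate_mfp(series, corrected = corrected),
    by_trajectory = by_traj
  )
}
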