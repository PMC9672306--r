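#' Place a trajectory on the source circle and clip it to entry events
#'
#' Implements one placement of the virtual-medium construction: the
#' trajectory is translated so its first point sits on the source circle at
#' `(R_e cos(source_angle), R_e sin(source_angle))`, rotated about that
#' starting point by `rotation`, and clipped against the inner disk of radius
#' `spec$R` into entry events.
#'
#' @param data a trajectory table (one or more trajectories; the same
#'   placement is applied to each).
#' @param spec a [medium_spec()].
#' @param rotation rotation angle about the starting point, radians.
#' @param source_angle angular position of the starting point on the source
#'   circle, radians (default 0 — equivalent by symmetry to a random angle).
#' @return The entry-event tibble of [clip_to_entry_events()].
#' @export
place_and_measure <- function(data, spec, rotation, source_angle = 0) {
  stopifnot(inherits(spec, "medium_spec"))
  placed <- translate_rotate(
    data,
    new_start = spec$R_e * c(cos(source_angle), sin(source_angle)),
    angle = rotation
  )
  clip_to_entry_events(placed, spec)
}

# per-trajectory placement aggregates for the replay estimator:
# relative coordinates are rotated in bulk per placement (fast path)
replay_cell <- function(rel, spec, n_placements, random_source_angle) {
  n_traj <- length(rel)
  traj_of <- rep_len(seq_len(n_traj), n_placements)
  rot <- runif(n_placements, 0, 2 * pi)
  alpha <- if (random_source_angle) runif(n_placements, 0, 2 * pi) else numeric(n_placements)
  sum_L <- numeric(n_traj)
  n_ev <- numeric(n_traj)
  for (i in seq_len(n_placements)) {
    j <- traj_of[i]
    ca <- cos(rot[i])
    sa <- sin(rot[i])
    sx <- spec$R_e * cos(alpha[i])
    sy <- spec$R_e * sin(alpha[i])
    x <- sx + ca * rel[[j]]$x - sa * rel[[j]]$y
    y <- sy + sa * rel[[j]]$x + ca * rel[[j]]$y
    L <- clip_events_xy(x, y, spec$R)
    if (length(L) > 0) {
      sum_L[j] <- sum_L[j] + sum(L)
      n_ev[j] <- n_ev[j] + length(L)
    }
  }
  list(sum_L = sum_L, n_ev = n_ev)
}

#' Mean path length inside the inner disk (replay estimator)
#'
#' Estimates \eqn{\langle L \rangle} by repeatedly placing recorded (or
#' synthetic) trajectories on the source circle with independent uniform
#' rotations, clipping them against the inner disk, and averaging the entry
#' event lengths. Placements cycle through the trajectories of `data`. Each
#' re-entry counts as a new entry event; placements that never enter the disk
#' contribute to neither numerator nor denominator (set
#' `denominator = "placements"` for the alternative reading in which every
#' placement counts). The standard error comes from a nonparametric bootstrap
#' over the distinct source trajectories, reflecting that the information
#' content is limited by the number of different recorded paths.
#'
#' @param data a trajectory table.
#' @param spec a [medium_spec()].
#' @param n_placements number of placements (>= 1).
#' @param seed optional integer seed.
#' @param bootstrap_B bootstrap replicates for the standard error.
#' @param denominator `"entries"` (default: average per entry event) or
#'   `"placements"` (divide the summed length by the number of placements).
#' @param random_source_angle draw a uniform source angle per placement
#'   instead of the symmetry-equivalent fixed angle 0.
#' @return A one-row tibble of class `ip_mpl` with columns `R_mm`, `d_mm`,
#'   `mean_L_mm`, `se_L_mm`, `ip_mm`, `ratio`, `n_entries`, `n_placements`,
#'   `valid`. When no placement ever enters the disk, `mean_L_mm` is `NaN`
#'   and `valid` is `FALSE`.
#' @export
mean_path_length <- function(data, spec, n_placements = 1e4, seed = NULL,
                             bootstrap_B = 200,
                             denominator = c("entries", "placements"),
                             random_source_angle = FALSE) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(spec, "medium_spec"), n_placements >= 1)
  data <- validate_trajectories(data)
  if (!is.null(seed)) set.seed(seed)
  rel <- purrr::map(split(data, data$traj_id), function(tr) {
    list(x = tr$x_mm - tr$x_mm[1], y = tr$y_mm - tr$y_mm[1])
  })
  agg <- replay_cell(rel, spec, as.integer(n_placements), random_source_angle)
  n_entries <- sum(agg$n_ev)
  denom <- if (denominator == "entries") n_entries else n_placements
  mean_L <- if (n_entries > 0) sum(agg$sum_L) / denom else NaN

  se_L <- NA_real_
  if (n_entries > 0 && bootstrap_B > 0) {
    n_traj <- length(rel)
    boots <- vapply(seq_len(bootstrap_B), function(b) {
      idx <- sample.int(n_traj, n_traj, replace = TRUE)
      nb <- sum(agg$n_ev[idx])
      if (denominator == "entries") {
        if (nb == 0) NA_real_ else sum(agg$sum_L[idx]) / nb
      } else {
        sum(agg$sum_L[idx]) / n_placements
      }
    }, numeric(1))
    se_L <- sd(boots, na.rm = TRUE)
  }

  ip <- ip_mean(spec$S, spec$P)
  out <- tibble(
    R_mm = spec$R, d_mm = spec$d,
    mean_L_mm = mean_L, se_L_mm = se_L, ip_mm = ip, ratio = mean_L / ip,
    n_entries = n_entries, n_placements = as.integer(n_placements),
    valid = n_entries > 0
  )
  new_mpl_tbl(list(out))
}

#' Sweep the mean-path-length estimate over a grid of media
#'
#' Runs one mean-path-length cell per `(R, d)` combination, in replay mode
#' (placing the trajectories of `data`) or synthetic mode (the Monte Carlo
#' kernel of [simulate_ip()]). Failed cells are carried as flagged rows
#' (`valid = FALSE`) rather than aborting the sweep.
#'
#' @param config an [ip_config()].
#' @param data a trajectory table (required for `mode = "replay"`).
#' @return A tibble of class `ip_mpl`, one row per cell, ordered by `d_mm`
#'   then `R_mm`.
#' @export
ip_sweep <- function(config, data = NULL) {
  stopifnot(inherits(config, "ip_config"))
  grid <- if (isTRUE(config$paired)) {
    tibble(d_mm = config$d_mm, R_mm = config$R_mm)
  } else {
    tidyr::expand_grid(d_mm = config$d_mm, R_mm = config$R_mm)
  }
  grid <- dplyr::arrange(grid, .data$d_mm, .data$R_mm)
  if (nrow(grid) == 0) {
    abort("empty R/d grid", class = "ipwalk_config_error")
  }
  if (config$mode == "synthetic") {
    return(simulate_ip(
      R_mm = grid$R_mm, d_mm = grid$d_mm, model = config$model,
      launch = config$launch, n_walkers = config$n_walkers,
      budget_mm = config$budget_mm, seed = config$seed,
      random_source = config$random_source
    ))
  }
  if (is.null(data)) {
    abort("replay mode needs trajectory data", class = "ipwalk_config_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  rows <- purrr::pmap(grid, function(d_mm, R_mm) {
    tryCatch(
      mean_path_length(
        data, medium_spec(R = R_mm, d = d_mm),
        n_placements = config$n_placements,
        bootstrap_B = config$bootstrap_B,
        denominator = config$denominator,
        random_source_angle = config$random_source
      ),
      error = function(e) {
        tibble(
          R_mm = R_mm, d_mm = d_mm, mean_L_mm = NaN, se_L_mm = NA_real_,
          ip_mm = ip_mean_disk(R_mm), ratio = NaN, n_entries = 0,
          n_placements = as.integer(config$n_placements), valid = FALSE
        )
      }
    )
  })
  new_mpl_tbl(rows)
}

# shared constructor for entrance-angle histograms
new_angle_profile <- function(counts, n_bins) {
  edges <- seq(-pi / 2, pi / 2, length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  p_ref <- (sin(edges[-1]) - sin(edges[-(n_bins + 1)])) / 2
  n <- sum(counts)
  if (n == 0) {
    abort("no entry events to histogram", class = "ipwalk_validation_error")
  }
  gof <- suppressWarnings(chisq.test(counts, p = p_ref))
  width <- diff(edges)
  out <- tibble(
    theta_mid = mids,
    count = as.numeric(counts),
    density = counts / (n * width),
    lambertian_density = cos(mids) / 2
  )
  class(out) <- c("ip_angles", class(out))
  attr(out, "n_events") <- n
  attr(out, "chisq") <- unname(gof$statistic)
  attr(out, "df") <- unname(gof$parameter)
  attr(out, "p_value") <- unname(gof$p.value)
  out
}

#' Entrance-angle profile from entry events
#'
#' Histograms the signed angle between the entry heading and the inward
#' boundary normal over `(-pi/2, pi/2)` and compares it against the
#' Lambertian reference `cos(theta)/2` with a chi-square goodness-of-fit
#' test. A Lambertian entrance profile is the key hypothesis under which the
#' invariance property holds exactly.
#'
#' @param events an entry-event tibble from [clip_to_entry_events()] or
#'   [place_and_measure()].
#' @param n_bins number of histogram bins (>= 2).
#' @return A tibble of class `ip_angles` with columns `theta_mid`, `count`,
#'   `density`, `lambertian_density`, carrying the chi-square statistic, df,
#'   and p-value as attributes (see `glance()`).
#' @export
entrance_angle_profile <- function(events, n_bins = 18) {
  if (n_bins < 2) abort("n_bins must be >= 2", class = "ipwalk_config_error")
  if (nrow(events) == 0) {
    abort("no entry events", class = "ipwalk_validation_error")
  }
  nrm <- atan2(-events$entry_y_mm, -events$entry_x_mm)
  theta <- events$entry_heading - nrm
  theta <- atan2(sin(theta), cos(theta))
  theta <- theta[is.finite(theta) & abs(theta) < pi / 2]
  if (length(theta) == 0) {
    abort("no finite entrance angles", class = "ipwalk_validation_error")
  }
  edges <- seq(-pi / 2, pi / 2, length.out = n_bins + 1)
  counts <- tabulate(findInterval(theta, edges, rightmost.closed = TRUE),
    nbins = n_bins
  )
  new_angle_profile(counts, n_bins)
}
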