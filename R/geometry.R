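#' Virtual medium specification
#'
#' The virtual medium is an inner disk of radius `R` centred at the origin,
#' with a concentric source circle at radius `R_e = R + d` from which walkers
#' are introduced. Surface `S = pi R^2` and perimeter `P = 2 pi R` are derived.
#'
#' @param R inner-disk radius in mm (> 0).
#' @param d source-to-disk gap in mm (>= 0).
#' @return An object of class `medium_spec`: a list with elements `R`, `d`,
#'   `R_e`, `S`, `P`.
#' @examples
#' medium_spec(R = 100, d = 100)
#' @export
medium_spec <- function(R, d) {
  stopifnot(is.finite(R), is.finite(d))
  if (R <= 0) abort("R must be > 0", class = "ipwalk_config_error")
  if (d < 0) abort("d must be >= 0", class = "ipwalk_config_error")
  structure(
    list(R = R, d = d, R_e = R + d, S = pi * R^2, P = 2 * pi * R),
    class = "medium_spec"
  )
}

#' @export
print.medium_spec <- function(x, ...) {
  cat(sprintf(
    "<medium_spec> inner disk R = %g mm, gap d = %g mm (source R_e = %g mm)\n",
    x$R, x$d, x$R_e
  ))
  cat(sprintf(
    "  S = %.6g mm^2, P = %.6g mm, <L>_IP = pi*S/P = %.6g mm\n",
    x$S, x$P, ip_mean(x$S, x$P)
  ))
  invisible(x)
}

# Parameter interval [t0, t1] in which the segment p(t) = p0 + t*(p1-p0)
# lies inside the circle of radius r about the origin. Vectorized over
# segments. Tangency (double root) is treated as no crossing so that
# measure-zero grazing contacts cannot open zero-length events.
segment_circle_interval <- function(x0, y0, x1, y1, r) {
  dx <- x1 - x0
  dy <- y1 - y0
  a <- dx * dx + dy * dy
  c0 <- x0 * x0 + y0 * y0
  tm <- ifelse(a > 0, -(x0 * dx + y0 * dy) / a, 0)
  q <- tm * tm - (c0 - r * r) / ifelse(a > 0, a, 1)
  has <- a > 0 & q > 0
  h <- sqrt(pmax(q, 0))
  list(has = has, t0 = tm - h, t1 = tm + h, seg_len = sqrt(a))
}

#' Length of a segment inside a disk
#'
#' Exact (closed-form) length of the intersection of the segment
#' `(x0, y0) -> (x1, y1)` with the closed disk of radius `R` about the
#' origin. Vectorized over segments; additive under segment subdivision.
#'
#' @param x0,y0,x1,y1 segment endpoints in mm (numeric vectors, recycled).
#' @param R disk radius in mm (> 0).
#' @return Numeric vector of lengths in mm, each in `[0, |p1 - p0|]`.
#' @examples
#' segment_disk_overlap(-2, 0.5, 2, 0.5, 1) # chord 2*sqrt(1 - 0.25)
#' @export
segment_disk_overlap <- function(x0, y0, x1, y1, R) {
  if (R <= 0) abort("R must be > 0", class = "ipwalk_config_error")
  iv <- segment_circle_interval(x0, y0, x1, y1, R)
  ov <- pmax(0, pmin(iv$t1, 1) - pmax(iv$t0, 0)) * iv$seg_len
  ifelse(iv$has, ov, 0)
}

# Entry-event lengths for one trajectory given as coordinate vectors.
# Fast internal path: returns only the numeric event lengths (and optionally
# entry records). Used by clip_to_entry_events() and the replay estimator.
clip_events_xy <- function(x, y, R, details = FALSE) {
  n <- length(x)
  tol <- 1 + 1e-12
  inside_v <- (x * x + y * y) <= R * R * tol
  i0 <- seq_len(n - 1)
  iv <- segment_circle_interval(x[i0], y[i0], x[i0 + 1], y[i0 + 1], R)
  ov <- pmax(0, pmin(iv$t1, 1) - pmax(iv$t0, 0)) * iv$seg_len
  ov[!iv$has] <- 0
  # an entry opens where a contributing segment starts at an outside vertex;
  # a path starting inside the disk opens event 1 at its first vertex
  entry <- iv$has & ov > 0 & !inside_v[i0]
  started_inside <- inside_v[1]
  ev_id <- cumsum(entry) + as.integer(started_inside)
  keep <- ov > 0 & ev_id > 0
  n_events <- max(0L, max(ev_id, 0L))
  if (n_events == 0L) {
    if (!details) return(numeric(0))
    return(list(
      L = numeric(0), entry_x = numeric(0), entry_y = numeric(0),
      heading = numeric(0), exited = logical(0)
    ))
  }
  L <- as.numeric(rowsum(ov[keep], ev_id[keep], reorder = TRUE))
  ids_present <- sort(unique(ev_id[keep]))
  L_full <- numeric(n_events)
  L_full[ids_present] <- L
  if (!details) return(L_full)

  entry_x <- entry_y <- heading <- rep(NA_real_, n_events)
  seg_head <- atan2(y[i0 + 1] - y[i0], x[i0 + 1] - x[i0])
  if (started_inside) {
    entry_x[1] <- x[1]
    entry_y[1] <- y[1]
    nz <- which(iv$seg_len > 0)
    heading[1] <- if (length(nz) > 0) seg_head[nz[1]] else NA_real_
  }
  eseg <- which(entry)
  if (length(eseg) > 0) {
    eid <- ev_id[eseg]
    t0c <- pmax(iv$t0[eseg], 0)
    entry_x[eid] <- x[eseg] + t0c * (x[eseg + 1] - x[eseg])
    entry_y[eid] <- y[eseg] + t0c * (y[eseg + 1] - y[eseg])
    heading[eid] <- seg_head[eseg]
  }
  exited <- rep(TRUE, n_events)
  exited[n_events] <- !inside_v[n]
  list(L = L_full, entry_x = entry_x, entry_y = entry_y,
       heading = heading, exited = exited)
}

#' Clip trajectories to entry events in the inner disk
#'
#' Splits each trajectory into its maximal excursions inside the closed inner
#' disk (`|p| <= R`). Each excursion is one *entry event* — when a path exits
#' the disk and later re-enters, the re-entry counts as a new event. A path
#' that starts inside the disk opens an event at its first vertex. The sum of
#' event lengths equals the total clipped length from
#' [segment_disk_overlap()].
#'
#' @param data a trajectory table.
#' @param spec a [medium_spec()] (only its inner radius `R` is used) or a
#'   single positive number interpreted as `R` in mm.
#' @return A tibble with one row per entry event: `traj_id`, `entry_idx`
#'   (ordinal of the passage within its parent path), `L_mm` (length inside
#'   the disk), `entry_x_mm`, `entry_y_mm` (boundary crossing point),
#'   `entry_heading` (radians, direction of the crossing segment), `exited`
#'   (FALSE when the path ends inside the disk).
#' @examples
#' path <- trajectory(c(-2, 2, -2), c(0, 0, 1e-4))
#' clip_to_entry_events(path, medium_spec(R = 1, d = 1))
#' @export
clip_to_entry_events <- function(data, spec) {
  R <- if (inherits(spec, "medium_spec")) spec$R else spec
  if (!is.numeric(R) || length(R) != 1 || R <= 0) {
    abort("spec must be a medium_spec or a positive radius",
      class = "ipwalk_config_error"
    )
  }
  data <- validate_trajectories(data)
  parts <- split(data, data$traj_id)
  rows <- purrr::map(parts, function(tr) {
    ev <- clip_events_xy(tr$x_mm, tr$y_mm, R, details = TRUE)
    if (length(ev$L) == 0) return(NULL)
    tibble(
      traj_id = tr$traj_id[1],
      entry_idx = seq_along(ev$L),
      L_mm = ev$L,
      entry_x_mm = ev$entry_x,
      entry_y_mm = ev$entry_y,
      entry_heading = ev$heading,
      exited = ev$exited
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      traj_id = character(), entry_idx = integer(), L_mm = numeric(),
      entry_x_mm = numeric(), entry_y_mm = numeric(),
      entry_heading = numeric(), exited = logical()
    )
  }
  out
}

#' Partition a disk into equal-area concentric annuli
#'
#' Edges follow the closed form `r_k = R_outer * sqrt(k / n)`, which makes
#' every annulus area exactly `pi R_outer^2 / n`. The representative radius
#' `r_mid_mm` is the area-weighted mean radius of each annulus,
#' `(2/3) (r_k^3 - r_{k-1}^3) / (r_k^2 - r_{k-1}^2)`.
#'
#' @param R_outer outer radius in mm (> 0).
#' @param n number of annuli (>= 1).
#' @return A tibble of class `annulus_partition` with columns `annulus`,
#'   `r_inner_mm`, `r_outer_mm`, `r_mid_mm`, `area_mm2`.
#' @examples
#' equal_area_annuli(200, 4)
#' @export
equal_area_annuli <- function(R_outer, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("n must be a positive integer", class = "ipwalk_config_error")
  }
  if (!is.numeric(R_outer) || R_outer <= 0) {
    abort("R_outer must be > 0", class = "ipwalk_config_error")
  }
  edges <- R_outer * sqrt(seq(0, n) / n)
  out <- tibble(
    annulus = seq_len(n),
    r_inner_mm = edges[-(n + 1)],
    r_outer_mm = edges[-1],
    r_mid_mm = (2 / 3) * (edges[-1]^3 - edges[-(n + 1)]^3) /
      (edges[-1]^2 - edges[-(n + 1)]^2),
    area_mm2 = pi * R_outer^2 / n
  )
  class(out) <- c("annulus_partition", class(out))
  attr(out, "R_outer") <- R_outer
  out
}

#' Path length travelled in each annulus
#'
#' Clips every trajectory segment against the partition's circle edges and
#' accumulates, per annulus, the total path length travelled inside it
#' (pooled over all trajectories in `data`). The per-annulus lengths sum to
#' the total clipped length inside the outer disk, independent of the number
#' of annuli.
#'
#' @param data a trajectory table.
#' @param partition an [equal_area_annuli()] partition.
#' @return A tibble with columns `annulus` and `length_mm`.
#' @export
path_length_per_annulus <- function(data, partition) {
  stopifnot(inherits(partition, "annulus_partition"))
  data <- validate_trajectories(data)
  # segments across all trajectories; trajectory breaks excluded via lead id
  idx <- which(data$traj_id == dplyr::lead(data$traj_id, default = ""))
  x0 <- data$x_mm[idx]
  y0 <- data$y_mm[idx]
  x1 <- data$x_mm[idx + 1]
  y1 <- data$y_mm[idx + 1]
  edges <- partition$r_outer_mm
  cum <- vapply(
    edges,
    function(r) sum(segment_disk_overlap(x0, y0, x1, y1, r)),
    numeric(1)
  )
  tibble(annulus = partition$annulus, length_mm = diff(c(0, cum)))
}
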