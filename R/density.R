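# shared constructor: per-annulus lengths -> density profile tibble
new_density_profile <- function(partition, length_mm, se_length = NULL,
                                n_units = NA_integer_) {
  dens <- length_mm / partition$area_mm2
  outer_dens <- dens[nrow(partition)]
  norm_ok <- is.finite(outer_dens) && outer_dens > 0
  if (!norm_ok) {
    warn("outermost annulus density is zero: normalized profile undefined")
  }
  out <- tibble(
    annulus = partition$annulus,
    r_inner_mm = partition$r_inner_mm,
    r_outer_mm = partition$r_outer_mm,
    r_mid_mm = partition$r_mid_mm,
    area_mm2 = partition$area_mm2,
    length_mm = length_mm,
    density = dens,
    se_density = if (is.null(se_length)) NA_real_ else se_length / partition$area_mm2,
    normalized = if (norm_ok) dens / outer_dens else NA_real_
  )
  class(out) <- c("ip_density", class(out))
  attr(out, "R_outer") <- attr(partition, "R_outer")
  attr(out, "norm_ok") <- norm_ok
  attr(out, "n_units") <- n_units
  out
}

#' Radial trajectory-density profile in equal-area annuli
#'
#' Divides the disk of radius `R_e_mm` into `n_annuli` concentric annuli of
#' equal area and registers the path length travelled in each, pooled over
#' all trajectories in `data`. *Density* is trajectory length per unit area
#' (mm per mm^2); a constant density is the equilibrium signature under which
#' the invariance property holds. The profile is normalized by the outermost
#' annulus, matching the convention of plotting against `r / R_e`.
#'
#' @param data a trajectory table (typically already placed on the source
#'   circle).
#' @param R_e_mm outer (source-circle) radius in mm.
#' @param n_annuli number of equal-area annuli (>= 2, default 20).
#' @return A tibble of class `ip_density` with columns `annulus`,
#'   `r_inner_mm`, `r_outer_mm`, `r_mid_mm`, `area_mm2`, `length_mm`,
#'   `density`, `se_density`, `normalized`.
#' @export
density_profile <- function(data, R_e_mm, n_annuli = 20) {
  if (n_annuli < 2) abort("n_annuli must be >= 2", class = "ipwalk_config_error")
  part <- equal_area_annuli(R_e_mm, n_annuli)
  len <- path_length_per_annulus(data, part)
  new_density_profile(part, len$length_mm)
}

#' Flatness of a density profile
#'
#' Summarizes how constant the trajectory density is across the annuli deeper
#' than `min_depth_mm` from the outer boundary (representative radius
#' `r_mid < R_outer - min_depth_mm`): the statistic is
#' `max |density_k / mean - 1|` with the mean taken over the qualifying
#' annuli. Near-boundary annuli are excluded because a non-Lambertian source
#' imprint persists up to about one mean free path of depth.
#'
#' @param profile an `ip_density` tibble.
#' @param min_depth_mm minimum depth below the outer radius for an annulus to
#'   qualify (e.g. the mean free path); `0` keeps all annuli.
#' @return A one-row tibble: `max_rel_dev`, `annulus_at_max`,
#'   `n_qualifying`, `se_at_max` (Monte Carlo SE of the deviation at the
#'   maximizing annulus, `NA` when the profile carries no SE).
#' @export
density_flatness <- function(profile, min_depth_mm = 0) {
  stopifnot(inherits(profile, "ip_density"))
  R_outer <- attr(profile, "R_outer")
  qual <- profile$r_mid_mm < R_outer - min_depth_mm
  if (!any(qual)) {
    abort("no annulus qualifies at this depth", class = "ipwalk_config_error")
  }
  dens <- profile$density[qual]
  m <- mean(dens)
  dev <- abs(dens / m - 1)
  k <- which.max(dev)
  se_at_max <- profile$se_density[qual][k] / m
  tibble(
    max_rel_dev = dev[k],
    annulus_at_max = profile$annulus[qual][k],
    n_qualifying = sum(qual),
    se_at_max = se_at_max
  )
}
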